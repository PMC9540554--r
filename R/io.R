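#' Serialise an assembly run to a directory
#'
#' Writes the standard output file set of a run: \code{trajectory.csv}
#' (one row per iteration), \code{events.jsonl} (one JSON record per
#' lineage: consumer and resource births and deaths with cause tags),
#' \code{state.json} (the final community: ids, base attack rates, attack
#' matrix, biomasses if present) and \code{manifest.json} (schema version,
#' configuration snapshot, seed, formulation, iteration range, and an
#' md5 checksum per output file).
#'
#' @param run An \code{lv_run}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
write_run_outputs <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  traj_path <- file.path(dir, "trajectory.csv")
  utils::write.csv(run$trajectory, traj_path, row.names = FALSE)

  ev_path <- file.path(dir, "events.jsonl")
  con_txt <- vapply(seq_len(nrow(run$consumers)), function(i)
    jsonlite::toJSON(c(list(record = "consumer"),
                       as.list(run$consumers[i, , drop = FALSE])),
                     auto_unbox = TRUE, digits = NA, na = "null"),
    character(1))
  res_txt <- vapply(seq_len(nrow(run$resources)), function(i)
    jsonlite::toJSON(c(list(record = "resource"),
                       as.list(run$resources[i, , drop = FALSE])),
                     auto_unbox = TRUE, digits = NA, na = "null"),
    character(1))
  writeLines(c(con_txt, res_txt), ev_path)

  st <- run$final_state
  state_path <- file.path(dir, "state.json")
  jsonlite::write_json(
    list(resource_ids = st$resource_ids, consumer_ids = st$consumer_ids,
         a = st$a, H = st$H, B_R = st$B_R, B_C = st$B_C,
         iteration = st$iteration),
    state_path, auto_unbox = TRUE, digits = NA, na = "null")

  files <- c("trajectory.csv", "events.jsonl", "state.json")
  manifest <- list(
    schema_version = 1L,
    formulation = run$formulation,
    seed = run$seed,
    n_iterations = run$n_iterations,
    params = run$params[.lv_params_keys],
    checksums = as.list(tools::md5sum(file.path(dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read back a serialised run directory
#'
#' Validates the manifest checksums and reconstructs the trajectory,
#' event log and final state written by \code{\link{write_run_outputs}}.
#'
#' @param dir Directory written by \code{\link{write_run_outputs}}.
#' @return List with \code{manifest}, \code{params}, \code{trajectory},
#'   \code{consumers}, \code{resources} and \code{final_state}.
#' @export
read_run_outputs <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  for (f in names(man$checksums)) {
    actual <- unname(tools::md5sum(file.path(dir, f)))
    if (is.na(actual) || actual != man$checksums[[f]])
      stop("checksum mismatch for ", f, " in ", dir)
  }
  traj <- utils::read.csv(file.path(dir, "trajectory.csv"))
  ev <- lapply(readLines(file.path(dir, "events.jsonl")),
               function(l) jsonlite::fromJSON(l))
  kind <- vapply(ev, `[[`, character(1), "record")
  as_df <- function(rows) {
    if (length(rows) == 0L) return(NULL)
    do.call(rbind, lapply(rows, function(r) {
      r$record <- NULL
      as.data.frame(lapply(r, function(x) if (is.null(x)) NA else x),
                    stringsAsFactors = FALSE)
    }))
  }
  stj <- jsonlite::read_json(file.path(dir, "state.json"),
                             simplifyVector = TRUE)
  H <- stj$H
  if (is.null(dim(H))) H <- matrix(H, nrow = length(stj$resource_ids))
  opt_vec <- function(x) if (length(x) == 0L) NULL else as.numeric(x)
  st <- new_community(H, stj$a, resource_ids = stj$resource_ids,
                      consumer_ids = stj$consumer_ids,
                      B_R = opt_vec(stj$B_R), B_C = opt_vec(stj$B_C),
                      iteration = stj$iteration)
  list(manifest = man, params = do.call(lv_params, man$params),
       trajectory = traj,
       consumers = as_df(ev[kind == "consumer"]),
       resources = as_df(ev[kind == "resource"]),
       final_state = st)
}

#' Hand-built fixture communities
#'
#' Small communities with analytically known behaviour, used in tests and
#' examples:
#' \describe{
#'   \item{starved}{one consumer whose column sum is below 1: it decays
#'     below the biomass floor and its resources return to carrying
#'     capacity.}
#'   \item{two-species-eq}{one consumer, one resource, H = 2: the
#'     dynamics converge to the fixed point (B_R, B_C) = (0.5, 0.25).}
#'   \item{pair-exclusion}{a specialist resident (H = (2, 1e-9)) that
#'     excludes a generalist invader (H = (0.6, 0.6)) through
#'     exploitative competition.}
#'   \item{apparent}{a single consumer with column (3, 1.5, 1.5) that
#'     extirpates its main resource through apparent competition.}
#'   \item{pyrrhic}{two consumers, H_k = (6, 2, 1) and H_l = (4, 1, 5),
#'     whose joint equilibrium drives consumer k's main resource
#'     negative.}
#' }
#'
#' @param name Fixture name.
#' @param params An \code{\link{lv_params}} object (used for biomass
#'   initialisation).
#' @return An \code{\link{lv_community}} with biomasses (resources at 1,
#'   consumers at \code{Mmin}).
#' @export
make_fixture <- function(name, params = lv_params()) {
  mk <- function(H, a = rep(1e-4, ncol(H)))
    new_community(H, a, B_R = rep(1, nrow(H)),
                  B_C = rep(params$Mmin, ncol(H)))
  switch(name,
    "starved" = mk(matrix(c(0.3, 0.3), 2, 1)),
    "two-species-eq" = mk(matrix(2, 1, 1)),
    "pair-exclusion" = mk(cbind(c(0.6, 0.6), c(2, 1e-9))),
    "apparent" = mk(matrix(c(3, 1.5, 1.5), 3, 1)),
    "pyrrhic" = mk(cbind(c(6, 2, 1), c(4, 1, 5))),
    stop("unknown fixture: ", name))
}
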