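#' Community state container
#'
#' A community is described by the dimensionless attack matrix \code{H}
#' (rows = resources, columns = consumers), the consumers' heritable base
#' attack rates \code{a}, stable integer species identifiers, and (for the
#' full ODE formulation) dimensionless biomasses: resources in units of the
#' carrying capacity \code{K}, consumers in units of \eqn{\alpha_0 r}.
#' The deconstructed formulation carries no biomass state.
#'
#' @param H Numeric matrix of strictly positive dimensionless attack rates;
#'   rows are resources, columns consumers.
#' @param a Numeric vector of base attack rates, one per consumer column.
#' @param resource_ids,consumer_ids Integer identifiers aligned with the
#'   rows/columns of \code{H}.
#' @param B_R,B_C Optional dimensionless biomass vectors (full formulation).
#' @param iteration Invasion-iteration count at which this state was taken.
#' @return An object of class \code{lv_community}.
#' @export
new_community <- function(H, a, resource_ids = seq_len(nrow(H)),
                          consumer_ids = seq_len(ncol(H)),
                          B_R = NULL, B_C = NULL, iteration = 0L) {
  H <- as.matrix(H)
  storage.mode(H) <- "double"
  if (length(a) != ncol(H))
    stop("length(a) must equal ncol(H)")
  if (length(resource_ids) != nrow(H) || length(consumer_ids) != ncol(H))
    stop("id vectors must match the dimensions of H")
  if (nrow(H) * ncol(H) > 0 && (any(!is.finite(H)) || any(H <= 0)))
    stop("H must be strictly positive and finite")
  if (!is.null(B_R) && length(B_R) != nrow(H))
    stop("length(B_R) must equal nrow(H)")
  if (!is.null(B_C) && length(B_C) != ncol(H))
    stop("length(B_C) must equal ncol(H)")
  structure(list(H = H, a = as.numeric(a),
                 resource_ids = as.integer(resource_ids),
                 consumer_ids = as.integer(consumer_ids),
                 B_R = B_R, B_C = B_C, iteration = as.integer(iteration)),
            class = "lv_community")
}

#' @export
print.lv_community <- function(x, ...) {
  cat(sprintf("LV community: %d resources x %d consumers (iteration %d)\n",
              nrow(x$H), ncol(x$H), x$iteration))
  if (length(x$a) > 0)
    cat(sprintf("  mean log10 base attack rate: %.3f\n",
                mean(log10(x$a))))
  if (!is.null(x$B_R))
    cat(sprintf("  biomass: resources in [%.3g, %.3g], consumers in [%.3g, %.3g]\n",
                min(x$B_R), max(x$B_R),
                if (length(x$B_C)) min(x$B_C) else NA,
                if (length(x$B_C)) max(x$B_C) else NA))
  invisible(x)
}

#' Number of resources / consumers in a community
#' @param community An \code{lv_community}.
#' @return Integer count.
#' @export
n_resources <- function(community) nrow(community$H)

#' @rdname n_resources
#' @export
n_consumers <- function(community) ncol(community$H)

#' Seed community for an assembly run
#'
#' Builds the initial community: \code{SR0} resources and \code{SC0}
#' consumers that all share the base attack rate \code{a_init}.  Every
#' pairwise coefficient is drawn from the model's log-normal scheme,
#' \eqn{H_{jk} = \alpha_0 a_k e^{\sigma \xi_{jk}}}.  Each seed consumer's
#' column is redrawn until it satisfies the invasibility criterion
#' (its column sum exceeds 1), mirroring the establishment filter that all
#' later invaders must pass; without this, small seed communities can lose
#' every consumer in the first adjustment sweep.
#'
#' In the full formulation, resources start at carrying capacity
#' (\code{B_R = 1}) and consumers at the extirpation threshold
#' (\code{B_C = Mmin}).
#'
#' @param params An \code{\link{lv_params}} object.
#' @param with_biomass If \code{TRUE}, attach the initial biomasses used by
#'   the full formulation.
#' @return An \code{lv_community}.
#' @export
init_community <- function(params, with_biomass = FALSE) {
  p <- params
  a0 <- alpha0(p)
  H <- matrix(0, p$SR0, p$SC0)
  for (k in seq_len(p$SC0)) {
    for (try in seq_len(p$candidate_cap)) {
      h <- a0 * p$a_init * exp(p$sigma * stats::rnorm(p$SR0))
      if (sum(h) > 1) break
      if (try == p$candidate_cap)
        stop("could not sample a viable seed consumer; a_init too small?")
    }
    H[, k] <- h
  }
  new_community(H, a = rep(p$a_init, p$SC0),
                B_R = if (with_biomass) rep(1, p$SR0) else NULL,
                B_C = if (with_biomass) rep(p$Mmin, p$SC0) else NULL)
}
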