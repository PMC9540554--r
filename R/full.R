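#' Dimensionless Lotka-Volterra derivatives
#'
#' Right-hand side of the two-level system in dimensionless form:
#' \deqn{dB_j^R/dt = r\,(1 - B_j^R - \textstyle\sum_k H_{jk} B_k^C)\,B_j^R,}
#' \deqn{dB_k^C/dt = \rho\,(\textstyle\sum_j H_{jk} B_j^R - 1)\,B_k^C.}
#' Zero biomass is absorbing; with no consumers every resource has a fixed
#' point at carrying capacity \eqn{B^R = 1}.
#'
#' @param B_R,B_C Non-negative dimensionless biomass vectors.
#' @param H Attack matrix (resources x consumers).
#' @param params An \code{\link{lv_params}} object.
#' @return List with elements \code{dB_R} and \code{dB_C}.
#' @export
#' @examples
#' lv_derivatives(0.5, 0.25, matrix(2), lv_params())  # fixed point: both zero
lv_derivatives <- function(B_R, B_C, H, params) {
  H <- as.matrix(H)
  if (length(B_R) != nrow(H) || length(B_C) != ncol(H))
    stop("dimension mismatch between biomasses and H")
  cons <- if (ncol(H) > 0) as.vector(H %*% B_C) else numeric(length(B_R))
  gain <- if (nrow(H) > 0) as.vector(crossprod(H, B_R)) else numeric(length(B_C))
  list(dB_R = params$r * (1 - B_R - cons) * B_R,
       dB_C = params$rho * (gain - 1) * B_C)
}

.install_lv_model <- function(H, params, thresh) {
  H <- as.matrix(H)
  storage.mode(H) <- "double"
  .Call(C_lv_set_model, H, as.numeric(params$r), as.numeric(params$rho),
        as.numeric(thresh))
  invisible(NULL)
}

#' Relax a community to population-dynamical equilibrium
#'
#' Integrates the dimensionless Lotka-Volterra system with a stiff-capable
#' adaptive integrator (\code{deSolve::lsodar}, compiled right-hand side)
#' until equilibrium or the cut-off time.  Species whose biomass crosses
#' the extirpation threshold \code{Mmin} are detected by event-style root
#' finding during the integration (not only at segment ends), removed, and
#' the integration continues on the reduced system; simultaneous crossings
#' are processed in species-id order.
#'
#' Equilibrium is declared when the largest scaled rate
#' \eqn{\max_i |dB_i/dt| / \max(B_i, M_{min})} stays below
#' \code{params$equil_tol} at two consecutive checks
#' \code{check_interval} time units apart; integration is cut off at
#' \code{params$t_equil_cutoff} regardless.
#'
#' @param state An \code{\link{lv_community}} with biomasses.
#' @param params An \code{\link{lv_params}} object.
#' @param check_interval Spacing of equilibrium checks (time units).
#' @return List with \code{state} (the relaxed community),
#'   \code{extirpated} (data frame: kind, id, time of crossing),
#'   \code{t_end}, and \code{converged}.
#' @export
integrate_to_equilibrium <- function(state, params, check_interval = 100) {
  p <- params
  if (is.null(state$B_R) || (ncol(state$H) > 0 && is.null(state$B_C)))
    stop("state must carry biomasses (see init_community(with_biomass = TRUE))")
  thresh <- p$Mmin * (1 - 1e-3)
  H <- state$H
  rid <- state$resource_ids
  cid <- state$consumer_ids
  avec <- state$a
  y <- c(state$B_R, state$B_C)
  ext_kind <- character(0); ext_id <- integer(0); ext_t <- numeric(0)
  t_cur <- 0
  converged <- FALSE
  crit <- NA_real_
  ## One integrator call per extirpation-free segment, with output
  ## checkpoints spaced geometrically from check_interval up to the
  ## cut-off.  The returned checkpoint states are scanned for the
  ## equilibrium criterion (two consecutive passes); integrating each
  ## segment in a single call avoids per-chunk restart ramp-up, which
  ## otherwise dominates when near-neutral modes creep for long times.
  .install_lv_model(H, p, thresh)
  while (t_cur < p$t_equil_cutoff && !converged) {
    cps <- t_cur + check_interval * 2^(0:40)
    cps <- cps[cps < p$t_equil_cutoff]
    times <- c(t_cur, cps, p$t_equil_cutoff)
    out <- suppressWarnings(
      deSolve::lsodar(y = y, times = times,
                      func = "C_lv_derivs", dllname = "prudentweb",
                      initfunc = NULL, parms = NULL,
                      rootfunc = "C_lv_root", nroot = length(y),
                      jacfunc = "C_lv_jac", jactype = "fullusr",
                      atol = 1e-9, rtol = 1e-6, maxsteps = 100000L))
    t_hit <- out[nrow(out), 1L]
    istate <- attr(out, "istate")[1L]
    if (istate < 0L && t_hit <= t_cur + 1e-12)
      stop("integrator failure (no progress) at t = ", t_cur)
    if (istate == 3L) {
      ## a root: one or more species crossed the extirpation threshold
      y <- pmax(unname(out[nrow(out), -1L]), 0)
      SR <- nrow(H)
      dead <- which(y <= thresh + 1e-15)
      if (length(dead) == 0L) dead <- which.min(y)  # root at interpolation noise
      dr <- dead[dead <= SR]
      dc <- dead[dead > SR] - SR
      if (length(dr) > 0L) {
        ext_kind <- c(ext_kind, rep("resource", length(dr)))
        ext_id <- c(ext_id, rid[dr]); ext_t <- c(ext_t, rep(t_hit, length(dr)))
        H <- H[-dr, , drop = FALSE]; rid <- rid[-dr]
      }
      if (length(dc) > 0L) {
        ext_kind <- c(ext_kind, rep("consumer", length(dc)))
        ext_id <- c(ext_id, cid[dc]); ext_t <- c(ext_t, rep(t_hit, length(dc)))
        H <- H[, -dc, drop = FALSE]; cid <- cid[-dc]; avec <- avec[-dc]
      }
      y <- y[-dead]
      t_cur <- t_hit
      if (length(y) == 0L) { converged <- TRUE; break }
      .install_lv_model(H, p, thresh)
      next
    }
    if (istate < 0L) {
      ## early stop (e.g. step budget): resume from where it stopped
      y <- pmax(unname(out[nrow(out), -1L]), 0)
      t_cur <- t_hit
      next
    }
    ## no extirpation in this segment: scan checkpoints for equilibrium
    SR <- nrow(H)
    nC <- length(y) - SR
    prev_pass <- FALSE
    for (i in 2:nrow(out)) {
      yy <- pmax(unname(out[i, -1L]), 0)
      d <- lv_derivatives(yy[seq_len(SR)], yy[seq_len(nC) + SR], H, p)
      crit <- max(abs(c(d$dB_R, d$dB_C)) / pmax(yy, p$Mmin))
      if (crit < p$equil_tol) {
        if (prev_pass) {
          y <- yy; t_cur <- out[i, 1L]; converged <- TRUE
          break
        }
        prev_pass <- TRUE
      } else prev_pass <- FALSE
    }
    if (!converged) {
      y <- pmax(unname(out[nrow(out), -1L]), 0)
      t_cur <- t_hit
    }
  }
  SR <- nrow(H)
  st <- new_community(H, avec, resource_ids = rid, consumer_ids = cid,
                      B_R = y[seq_len(SR)],
                      B_C = y[seq_len(length(y) - SR) + SR],
                      iteration = state$iteration)
  list(state = st,
       extirpated = data.frame(kind = ext_kind, id = ext_id, time = ext_t,
                               stringsAsFactors = FALSE),
       t_end = t_cur, converged = converged, final_rate = crit)
}

#' Invasion fitness of a candidate at the current equilibrium
#'
#' The initial per-capita growth rate (in units of \eqn{\rho} for
#' consumers, \eqn{r} for resources) of a rare invader against the
#' resident equilibrium: \eqn{\sum_j H_{jk} B_j^R - 1} for a consumer
#' candidate, \eqn{1 - \sum_k H_{jk} B_k^C} for a resource candidate.
#' The candidate can invade iff this is strictly positive.
#'
#' @param candidate An \code{lv_candidate} from
#'   \code{\link{sample_consumer_candidate}} or
#'   \code{\link{sample_resource_candidate}}.
#' @param state An \code{\link{lv_community}} at equilibrium (with
#'   biomasses).
#' @param params An \code{\link{lv_params}} object (unused; kept for a
#'   uniform operation signature).
#' @return Numeric growth-rate sign/magnitude.
#' @export
invasion_fitness <- function(candidate, state, params = NULL) {
  if (candidate$kind == "consumer") {
    sum(candidate$H_entries * state$B_R) - 1
  } else {
    bc <- if (is.null(state$B_C)) numeric(0) else state$B_C
    1 - sum(candidate$H_entries * bc)
  }
}

#' Run the full (ODE) assembly formulation
#'
#' Assembly through iterative invasion with explicit population dynamics:
#' the seed community (resources at carrying capacity, consumers at the
#' biomass floor \code{Mmin}) is relaxed to equilibrium; then, per
#' iteration, a fair coin picks the invader type, candidates are
#' rejection-sampled until one has positive \code{\link{invasion_fitness}},
#' the invader is added at biomass \code{Mmin}, and
#' \code{\link{integrate_to_equilibrium}} relaxes the community, removing
#' any species that crosses the floor (logged as dynamical extirpations
#' together with the kind of invasion that triggered the relaxation).
#'
#' @param params An \code{\link{lv_params}} object.
#' @param n_iterations,seed Run length and seed.
#' @param check_interval Spacing of equilibrium checks (time units).
#' @param verbose Print progress every 100 iterations.
#' @return An \code{lv_run} (see \code{\link{run_deconstructed_assembly}})
#'   with \code{formulation = "full"}, an \code{extirpations} data frame
#'   (iteration, kind, id, time within the relaxation, invader kind of the
#'   iteration), and a biomass-carrying \code{final_state}.  All death
#'   causes are \code{"dynamical_extirpation"}.
#' @export
run_full_assembly <- function(params, n_iterations = params$n_iterations,
                              seed = params$seed, check_interval = 100,
                              verbose = FALSE) {
  validate_lv_params(params)
  p <- params
  set.seed(seed)
  a0 <- alpha0(p)
  n_iterations <- as.integer(n_iterations)

  comm <- init_community(p, with_biomass = TRUE)
  n_con <- ncol(comm$H); n_res <- nrow(comm$H)
  con_a <- comm$a; con_birth <- rep(0L, n_con)
  con_parent <- rep(NA_integer_, n_con); con_death <- rep(NA_integer_, n_con)
  res_birth <- rep(0L, n_res); res_death <- rep(NA_integer_, n_res)

  ext_it <- integer(0); ext_kind <- character(0); ext_id <- integer(0)
  ext_time <- numeric(0); ext_invader <- character(0)

  log_extirpations <- function(ex, it, invader_kind) {
    if (nrow(ex) == 0L) return(invisible(NULL))
    for (i in seq_len(nrow(ex))) {
      if (ex$kind[i] == "resource") res_death[ex$id[i]] <<- it
      else con_death[ex$id[i]] <<- it
    }
    ext_it <<- c(ext_it, rep(it, nrow(ex)))
    ext_kind <<- c(ext_kind, ex$kind)
    ext_id <<- c(ext_id, ex$id)
    ext_time <<- c(ext_time, ex$time)
    ext_invader <<- c(ext_invader, rep(invader_kind, nrow(ex)))
    invisible(NULL)
  }

  rel <- integrate_to_equilibrium(comm, p, check_interval)
  log_extirpations(rel$extirpated, 0L, "seed")
  comm <- rel$state

  traj_SR <- integer(n_iterations + 1L); traj_SC <- integer(n_iterations + 1L)
  traj_mean <- numeric(n_iterations + 1L); traj_var <- numeric(n_iterations + 1L)
  traj_trelax <- numeric(n_iterations + 1L)
  traj_conv <- logical(n_iterations + 1L)
  snap <- function(slot) {
    traj_SR[slot] <<- nrow(comm$H); traj_SC[slot] <<- ncol(comm$H)
    if (ncol(comm$H) > 0L) {
      la <- log10(comm$a)
      traj_mean[slot] <<- mean(la)
      traj_var[slot] <<- if (length(la) > 1L) stats::var(la) else 0
    } else {
      traj_mean[slot] <<- NA_real_; traj_var[slot] <<- NA_real_
    }
    invisible(NULL)
  }
  snap(1L)
  traj_trelax[1L] <- rel$t_end; traj_conv[1L] <- rel$converged
  skipped <- 0L; total_candidates <- 0L

  for (it in seq_len(n_iterations)) {
    if (ncol(comm$H) < 1L)
      stop("all consumers extirpated at iteration ", it)
    consumer_turn <- stats::runif(1) < 0.5
    attempts <- 0L; ok <- FALSE
    while (attempts < p$candidate_cap) {
      attempts <- attempts + 1L
      if (consumer_turn) {
        d <- .draw_consumer(comm$a, nrow(comm$H), p, a0)
        if (sum(d$h * comm$B_R) - 1 > 0) { ok <- TRUE; break }
      } else {
        h <- .draw_resource(comm$a, p, a0)
        if (1 - sum(h * comm$B_C) > 0) { ok <- TRUE; break }
      }
    }
    total_candidates <- total_candidates + attempts
    if (!ok) {
      skipped <- skipped + 1L
      snap(it + 1L)
      next
    }
    if (consumer_turn) {
      n_con <- n_con + 1L
      con_a <- c(con_a, d$a); con_birth <- c(con_birth, it)
      con_parent <- c(con_parent, comm$consumer_ids[d$parent])
      con_death <- c(con_death, NA_integer_)
      comm <- new_community(cbind(comm$H, d$h, deparse.level = 0L),
                            c(comm$a, d$a),
                            resource_ids = comm$resource_ids,
                            consumer_ids = c(comm$consumer_ids, n_con),
                            B_R = comm$B_R, B_C = c(comm$B_C, p$Mmin),
                            iteration = it)
    } else {
      n_res <- n_res + 1L
      res_birth <- c(res_birth, it); res_death <- c(res_death, NA_integer_)
      comm <- new_community(rbind(comm$H, h, deparse.level = 0L),
                            comm$a,
                            resource_ids = c(comm$resource_ids, n_res),
                            consumer_ids = comm$consumer_ids,
                            B_R = c(comm$B_R, p$Mmin), B_C = comm$B_C,
                            iteration = it)
    }
    rel <- integrate_to_equilibrium(comm, p, check_interval)
    log_extirpations(rel$extirpated, it,
                     if (consumer_turn) "consumer" else "resource")
    comm <- rel$state
    traj_trelax[it + 1L] <- rel$t_end; traj_conv[it + 1L] <- rel$converged
    snap(it + 1L)
    if (verbose && it %% 100L == 0L)
      message(sprintf("iteration %d: S_R = %d, S_C = %d", it,
                      nrow(comm$H), ncol(comm$H)))
  }

  consumers <- data.frame(
    id = seq_len(n_con), a = con_a, birth_iteration = con_birth,
    parent_id = con_parent, death_iteration = con_death,
    death_cause = ifelse(is.na(con_death), NA_character_,
                         "dynamical_extirpation"),
    stringsAsFactors = FALSE)
  resources <- data.frame(
    id = seq_len(n_res), birth_iteration = res_birth,
    death_iteration = res_death,
    death_cause = ifelse(is.na(res_death), NA_character_,
                         "dynamical_extirpation"),
    stringsAsFactors = FALSE)
  structure(list(
    formulation = "full", params = p, seed = as.integer(seed),
    n_iterations = n_iterations,
    trajectory = data.frame(iteration = 0:n_iterations, S_R = traj_SR,
                            S_C = traj_SC, mean_log10_a = traj_mean,
                            var_log10_a = traj_var, t_relax = traj_trelax,
                            converged = traj_conv),
    consumers = consumers, resources = resources,
    pair_samples = NULL,
    extirpations = data.frame(iteration = ext_it, kind = ext_kind,
                              id = ext_id, time = ext_time,
                              invader_kind = ext_invader,
                              stringsAsFactors = FALSE),
    final_state = comm,
    skipped_iterations = skipped, total_candidates = total_candidates),
    class = "lv_run")
}
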