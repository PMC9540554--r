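#' Run the deconstructed assembly formulation
#'
#' Executes the condition-based assembly algorithm: population dynamics are
#' replaced by a sequence of closed-form ecological criteria applied per
#' invasion iteration.  Each iteration flips a fair coin between a consumer
#' and a resource invasion.  A consumer candidate is resampled until it
#' satisfies the invasibility criterion and is not excluded through
#' exploitative competition by any resident; it then loses resources it
#' overexploits during its boom phase, may bust after the boom, and
#' serially extirpates its main resource while the apparent-competition
#' condition holds.  A resource invader is added unconditionally, after
#' which consumers satisfying the apparent-competition condition (chosen at
#' random one at a time) extirpate their main resources and starving
#' consumers are removed.  Every iteration closes with three adjustment
#' sweeps: simultaneous exploitative-competitive exclusions evaluated on a
#' snapshot, simultaneous Pyrrhic main-resource removals evaluated on a
#' snapshot, and removal of consumers failing the invasibility criterion.
#'
#' Only the attack matrix, base attack rates and species identities are
#' tracked; no biomass state exists in this formulation.  Runs are
#' bit-reproducible for a given seed.
#'
#' @param params An \code{\link{lv_params}} object.
#' @param n_iterations Number of invasion iterations.
#' @param seed Random seed for the run.
#' @param snapshot_every Interval (iterations) at which random ordered
#'   consumer pairs are sampled for the competition-term regressions;
#'   spacing snapshots reduces autocorrelation between sampled pairs.
#' @param pairs_per_snapshot Number of ordered pairs recorded per snapshot.
#' @param refresh_every Interval at which the incrementally maintained
#'   column sums and cross-product matrix are recomputed from the attack
#'   matrix to prevent floating-point drift.
#' @param verbose Print progress every 1000 iterations.
#'
#' @return An object of class \code{lv_run} with elements
#'   \describe{
#'     \item{trajectory}{data frame, one row per iteration (plus the seed
#'       state): resource and consumer richness, community mean and
#'       variance of log10 base attack rate.}
#'     \item{consumers}{per-lineage records: id, base attack rate, birth
#'       and death iteration (NA while extant), parent id, death cause
#'       (\code{starvation_eq13}, \code{exploitative_eq14} or
#'       \code{bust_after_boom}).}
#'     \item{resources}{per-resource records with death causes
#'       \code{boom_overexploitation}, \code{apparent_competition} or
#'       \code{pyrrhic_competition}.}
#'     \item{pair_samples}{sampled ordered pairs (k, l): iteration,
#'       \code{a_k}, focal growth term C, interspecific term D, and the
#'       resident's terms A and B.}
#'     \item{final_state}{the final \code{\link{new_community}} state.}
#'   }
#' @export
run_deconstructed_assembly <- function(params,
                                       n_iterations = params$n_iterations,
                                       seed = params$seed,
                                       snapshot_every = 100L,
                                       pairs_per_snapshot = 12L,
                                       refresh_every = 1000L,
                                       verbose = FALSE) {
  validate_lv_params(params)
  p <- params
  set.seed(seed)
  a0 <- alpha0(p)
  sig <- p$sigma
  g0 <- p$gamma0
  g1 <- p$gamma1
  boom_thr <- -log(p$Mmin)
  cap <- p$candidate_cap
  n_iterations <- as.integer(n_iterations)

  ## cause codes (consumers / resources)
  CC_STARV <- 1L; CC_EXPL <- 2L; CC_BUST <- 3L
  RC_BOOM <- 1L; RC_APP <- 2L; RC_PYR <- 3L
  ccauses <- c("starvation_eq13", "exploitative_eq14", "bust_after_boom")
  rcauses <- c("boom_overexploitation", "apparent_competition",
               "pyrrhic_competition")

  ## ---- seed community ------------------------------------------------
  comm0 <- init_community(p)
  Hm <- comm0$H
  avec <- comm0$a
  SR <- nrow(Hm); SC <- ncol(Hm)

  ## per-lineage records (preallocated, grown by doubling)
  ccap <- 4096L
  con_a <- numeric(ccap); con_birth <- integer(ccap)
  con_parent <- rep(NA_integer_, ccap); con_death <- rep(NA_integer_, ccap)
  con_cause <- rep(NA_integer_, ccap)
  n_con <- SC
  con_a[1:SC] <- avec; con_birth[1:SC] <- 0L
  cids <- 1:SC

  rcap <- 4096L
  res_birth <- integer(rcap); res_death <- rep(NA_integer_, rcap)
  res_cause <- rep(NA_integer_, rcap)
  n_res <- SR
  res_birth[1:SR] <- 0L
  rids <- 1:SR

  ## incrementally maintained summaries
  S <- colSums(Hm)          # column sums: R_k
  Q <- colSums(Hm^2)        # intraspecific terms B_k
  Dm <- crossprod(Hm)       # interspecific terms D_kl

  ## trajectory
  traj_SR <- integer(n_iterations + 1L)
  traj_SC <- integer(n_iterations + 1L)
  traj_mean <- numeric(n_iterations + 1L)
  traj_var <- numeric(n_iterations + 1L)
  la <- log10(avec)
  traj_SR[1L] <- SR; traj_SC[1L] <- SC
  traj_mean[1L] <- mean(la); traj_var[1L] <- stats::var(la)

  ## pair snapshots
  np_max <- (n_iterations %/% max(1L, snapshot_every) + 1L) * pairs_per_snapshot
  pr_it <- integer(np_max); pr_a <- numeric(np_max); pr_C <- numeric(np_max)
  pr_D <- numeric(np_max); pr_A <- numeric(np_max); pr_B <- numeric(np_max)
  n_pr <- 0L

  skipped <- 0L
  total_candidates <- 0L

  for (it in seq_len(n_iterations)) {

    if (SC < 1L)
      stop("all consumers extirpated at iteration ", it,
           "; the model requires at least one resident consumer")

    if (stats::runif(1) < 0.5) {
      ## ================= consumer invasion ===========================
      ratio <- (S - 1) / Q
      attempts <- 0L
      ok <- FALSE
      while (attempts < cap) {
        attempts <- attempts + 1L
        parent <- sample.int(SC, 1L)
        anew <- g0 * g1^stats::rnorm(1L) * avec[parent]
        h <- a0 * anew * exp(sig * stats::rnorm(SR))
        Cn <- sum(h) - 1
        if (Cn <= 0) next
        d <- crossprod(Hm, h)
        if (any(Cn < d * ratio)) next
        ok <- TRUE
        break
      }
      total_candidates <- total_candidates + attempts
      if (!ok) {
        skipped <- skipped + 1L
      } else {
        ## add the established invader
        parent_id <- cids[parent]
        Dn <- matrix(0, SC + 1L, SC + 1L)
        Dn[1:SC, 1:SC] <- Dm
        Dn[SC + 1L, 1:SC] <- d
        Dn[1:SC, SC + 1L] <- d
        Dn[SC + 1L, SC + 1L] <- sum(h * h)
        Dm <- Dn
        S <- c(S, sum(h)); Q <- c(Q, sum(h * h))
        avec <- c(avec, anew)
        Hm <- cbind(Hm, h, deparse.level = 0L)
        SC <- SC + 1L
        n_con <- n_con + 1L
        if (n_con > length(con_a)) {
          con_a <- c(con_a, numeric(length(con_a)))
          con_birth <- c(con_birth, integer(length(con_birth)))
          con_parent <- c(con_parent, rep(NA_integer_, length(con_parent)))
          con_death <- c(con_death, rep(NA_integer_, length(con_death)))
          con_cause <- c(con_cause, rep(NA_integer_, length(con_cause)))
        }
        con_a[n_con] <- anew; con_birth[n_con] <- it
        con_parent[n_con] <- parent_id
        cids <- c(cids, n_con)

        ## Spread: boom-phase overexploitation of the invader's resources
        rr <- which(h > boom_thr)
        if (length(rr) > 0L) {
          hrows <- Hm[rr, , drop = FALSE]
          S <- S - .colSums(hrows, length(rr), SC)
          Q <- Q - .colSums(hrows^2, length(rr), SC)
          Dm <- Dm - crossprod(hrows)
          res_death[rids[rr]] <- it; res_cause[rids[rr]] <- RC_BOOM
          Hm <- Hm[-rr, , drop = FALSE]; rids <- rids[-rr]
          SR <- SR - length(rr)
        }

        ## Bust after boom
        if (S[SC] - 1 <= 0) {
          con_death[cids[SC]] <- it; con_cause[cids[SC]] <- CC_BUST
          Hm <- Hm[, -SC, drop = FALSE]; avec <- avec[-SC]; cids <- cids[-SC]
          S <- S[-SC]; Q <- Q[-SC]; Dm <- Dm[-SC, -SC, drop = FALSE]
          SC <- SC - 1L
        } else {
          ## Impact: serial apparent-competition extirpations
          repeat {
            hk <- Hm[, SC]
            mk <- which.max(hk)
            if (!(S[SC] - 1 > Q[SC] / hk[mk])) break
            hrows <- Hm[mk, , drop = FALSE]
            S <- S - hrows[1L, ]
            Q <- Q - hrows[1L, ]^2
            Dm <- Dm - crossprod(hrows)
            res_death[rids[mk]] <- it; res_cause[rids[mk]] <- RC_APP
            Hm <- Hm[-mk, , drop = FALSE]; rids <- rids[-mk]
            SR <- SR - 1L
          }
        }
      }
    } else {
      ## ================= resource invasion ===========================
      h <- a0 * avec * exp(sig * stats::rnorm(SC))
      S <- S + h; Q <- Q + h * h; Dm <- Dm + outer(h, h)
      Hm <- rbind(Hm, h, deparse.level = 0L)
      SR <- SR + 1L
      n_res <- n_res + 1L
      if (n_res > length(res_birth)) {
        res_birth <- c(res_birth, integer(length(res_birth)))
        res_death <- c(res_death, rep(NA_integer_, length(res_death)))
        res_cause <- c(res_cause, rep(NA_integer_, length(res_cause)))
      }
      res_birth[n_res] <- it
      rids <- c(rids, n_res)

      ## Expansion & Impact: consumer-mediated resource extirpations
      repeat {
        sat <- .Call(C_eq16_set, Hm, S, Q)
        if (length(sat) == 0L) break
        l <- if (length(sat) == 1L) sat else sat[sample.int(length(sat), 1L)]
        mk <- which.max(Hm[, l])
        hrows <- Hm[mk, , drop = FALSE]
        S <- S - hrows[1L, ]
        Q <- Q - hrows[1L, ]^2
        Dm <- Dm - crossprod(hrows)
        res_death[rids[mk]] <- it; res_cause[rids[mk]] <- RC_APP
        Hm <- Hm[-mk, , drop = FALSE]; rids <- rids[-mk]
        SR <- SR - 1L
        starv <- which(S - 1 <= 0)
        if (length(starv) > 0L) {
          con_death[cids[starv]] <- it; con_cause[cids[starv]] <- CC_STARV
          Hm <- Hm[, -starv, drop = FALSE]
          avec <- avec[-starv]; cids <- cids[-starv]
          S <- S[-starv]; Q <- Q[-starv]
          Dm <- Dm[-starv, -starv, drop = FALSE]
          SC <- SC - length(starv)
          if (SC == 0L) break
        }
      }
    }

    ## ============ Adjustment sweeps (every iteration) ================
    ## exploitative competitive exclusion: snapshot, then remove together
    if (SC >= 2L) {
      kill <- .Call(C_excl_sweep, S, Q, Dm)
      if (length(kill) > 0L) {
        con_death[cids[kill]] <- it; con_cause[cids[kill]] <- CC_EXPL
        Hm <- Hm[, -kill, drop = FALSE]
        avec <- avec[-kill]; cids <- cids[-kill]
        S <- S[-kill]; Q <- Q[-kill]
        Dm <- Dm[-kill, -kill, drop = FALSE]
        SC <- SC - length(kill)
      }
    }

    ## Pyrrhic competition: snapshot, remove main resources together
    if (SC >= 2L && SR >= 1L) {
      rr <- .Call(C_pyrrhic_sweep, Hm, S, Q, Dm)
      if (length(rr) > 0L) {
        hrows <- Hm[rr, , drop = FALSE]
        S <- S - .colSums(hrows, length(rr), SC)
        Q <- Q - .colSums(hrows^2, length(rr), SC)
        Dm <- Dm - crossprod(hrows)
        res_death[rids[rr]] <- it; res_cause[rids[rr]] <- RC_PYR
        Hm <- Hm[-rr, , drop = FALSE]; rids <- rids[-rr]
        SR <- SR - length(rr)
      }
    }

    ## starvation
    starv <- which(S - 1 <= 0)
    if (length(starv) > 0L) {
      con_death[cids[starv]] <- it; con_cause[cids[starv]] <- CC_STARV
      Hm <- Hm[, -starv, drop = FALSE]
      avec <- avec[-starv]; cids <- cids[-starv]
      S <- S[-starv]; Q <- Q[-starv]
      Dm <- Dm[-starv, -starv, drop = FALSE]
      SC <- SC - length(starv)
    }

    ## ============ bookkeeping ========================================
    if (it %% refresh_every == 0L && SR > 0L && SC > 0L) {
      S <- colSums(Hm); Q <- colSums(Hm^2); Dm <- crossprod(Hm)
    }

    traj_SR[it + 1L] <- SR; traj_SC[it + 1L] <- SC
    if (SC > 0L) {
      la <- log10(avec)
      traj_mean[it + 1L] <- mean(la)
      traj_var[it + 1L] <- if (SC > 1L) stats::var(la) else 0
    } else {
      traj_mean[it + 1L] <- NA_real_; traj_var[it + 1L] <- NA_real_
    }

    if (SC >= 2L && snapshot_every > 0L && it %% snapshot_every == 0L) {
      ks <- sample.int(SC, pairs_per_snapshot, replace = TRUE)
      ls <- sample.int(SC - 1L, pairs_per_snapshot, replace = TRUE)
      ls <- ls + (ls >= ks)
      idx <- n_pr + seq_len(pairs_per_snapshot)
      pr_it[idx] <- it
      pr_a[idx] <- avec[ks]
      pr_C[idx] <- S[ks] - 1
      pr_D[idx] <- Dm[cbind(ks, ls)]
      pr_A[idx] <- S[ls] - 1
      pr_B[idx] <- Q[ls]
      n_pr <- n_pr + pairs_per_snapshot
    }

    if (verbose && it %% 1000L == 0L)
      message(sprintf("iteration %d: S_R = %d, S_C = %d, mean log10 a = %.3f",
                      it, SR, SC, traj_mean[it + 1L]))
  }

  ## ---- assemble outputs ----------------------------------------------
  consumers <- data.frame(
    id = seq_len(n_con),
    a = con_a[seq_len(n_con)],
    birth_iteration = con_birth[seq_len(n_con)],
    parent_id = con_parent[seq_len(n_con)],
    death_iteration = con_death[seq_len(n_con)],
    death_cause = ccauses[con_cause[seq_len(n_con)]],
    stringsAsFactors = FALSE)
  resources <- data.frame(
    id = seq_len(n_res),
    birth_iteration = res_birth[seq_len(n_res)],
    death_iteration = res_death[seq_len(n_res)],
    death_cause = rcauses[res_cause[seq_len(n_res)]],
    stringsAsFactors = FALSE)
  trajectory <- data.frame(
    iteration = 0:n_iterations,
    S_R = traj_SR, S_C = traj_SC,
    mean_log10_a = traj_mean, var_log10_a = traj_var)
  pair_samples <- data.frame(
    iteration = pr_it[seq_len(n_pr)], a_k = pr_a[seq_len(n_pr)],
    C = pr_C[seq_len(n_pr)], D = pr_D[seq_len(n_pr)],
    A = pr_A[seq_len(n_pr)], B = pr_B[seq_len(n_pr)])

  structure(list(
    formulation = "deconstructed",
    params = p, seed = as.integer(seed), n_iterations = n_iterations,
    trajectory = trajectory, consumers = consumers, resources = resources,
    pair_samples = pair_samples,
    final_state = new_community(Hm, avec, resource_ids = rids,
                                consumer_ids = cids,
                                iteration = n_iterations),
    skipped_iterations = skipped, total_candidates = total_candidates),
    class = "lv_run")
}

#' @export
print.lv_run <- function(x, ...) {
  tr <- x$trajectory[nrow(x$trajectory), ]
  cat(sprintf("%s assembly run: %d iterations (seed %d)\n",
              x$formulation, x$n_iterations, x$seed))
  cat(sprintf("  final richness: S_R = %d, S_C = %d; mean log10 a = %.3f\n",
              tr$S_R, tr$S_C, tr$mean_log10_a))
  cat(sprintf("  lineages: %d consumers, %d resources; %d skipped iterations\n",
              nrow(x$consumers), nrow(x$resources), x$skipped_iterations))
  invisible(x)
}

#' Post-burn-in steady-state averages of an assembly run
#'
#' Convenience summary of a run's quasi-steady state: time averages of
#' resource richness, consumer richness, and the community mean and
#' variance of log10 base attack rate over the post-burn-in trajectory.
#'
#' @param run An \code{lv_run}.
#' @param burn_in Iterations to discard.
#' @return A list with \code{S_R}, \code{S_C}, \code{mean_log10_a},
#'   \code{var_log10_a}, and \code{n_iterations_used}.
#' @export
steady_state_means <- function(run, burn_in = run$params$burn_in) {
  tr <- run$trajectory[run$trajectory$iteration > burn_in, , drop = FALSE]
  if (nrow(tr) == 0L) stop("burn_in leaves no iterations")
  list(S_R = mean(tr$S_R), S_C = mean(tr$S_C),
       mean_log10_a = mean(tr$mean_log10_a, na.rm = TRUE),
       var_log10_a = mean(tr$var_log10_a, na.rm = TRUE),
       n_iterations_used = nrow(tr))
}
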