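#' Per-lineage records from an assembly event log
#'
#' Turns the consumer event log of an assembly run into lineage records:
#' the population "lifetime" L (iterations between establishment and
#' extirpation, time measured in units of invasion iterations) and the
#' lineage's reproductive output R (the number of established invaders
#' that inherited their base attack rate from it).  Consumers still extant
#' at the end of the run have no complete lifetime and are flagged
#' \code{censored}; estimates of L and R downstream exclude them.
#'
#' @param run An \code{lv_run}, or a data frame with columns \code{id},
#'   \code{a}, \code{birth_iteration}, \code{parent_id},
#'   \code{death_iteration}, \code{death_cause}.
#' @param burn_in Iterations discarded: only consumers established after
#'   \code{burn_in} are returned (offspring are counted over the full log
#'   regardless).
#' @return Data frame with columns \code{id}, \code{a}, \code{log10_a},
#'   \code{birth_iteration}, \code{death_iteration}, \code{parent_id},
#'   \code{death_cause} (\code{"censored"} for extant lineages), \code{L},
#'   \code{R_offspring}, \code{censored}.
#' @export
lineage_metrics <- function(run, burn_in = 0L) {
  cons <- if (inherits(run, "lv_run")) run$consumers else run
  need <- c("id", "a", "birth_iteration", "parent_id", "death_iteration",
            "death_cause")
  if (!all(need %in% names(cons)))
    stop("consumer log lacks columns: ",
         paste(setdiff(need, names(cons)), collapse = ", "))
  pid <- cons$parent_id[!is.na(cons$parent_id)]
  if (length(pid) > 0 && !all(pid %in% cons$id))
    stop("dangling parent ids in event log")
  ## offspring counted over the whole log: late parents keep full credit
  off <- table(factor(pid, levels = cons$id))
  keep <- cons$birth_iteration > burn_in
  rec <- cons[keep, , drop = FALSE]
  censored <- is.na(rec$death_iteration)
  data.frame(
    id = rec$id, a = rec$a, log10_a = log10(rec$a),
    birth_iteration = rec$birth_iteration,
    death_iteration = rec$death_iteration,
    parent_id = rec$parent_id,
    death_cause = ifelse(censored, "censored", rec$death_cause),
    L = rec$death_iteration - rec$birth_iteration,
    R_offspring = as.integer(off[match(rec$id, cons$id)]),
    censored = censored,
    stringsAsFactors = FALSE)
}

#' Rolling-mean metacommunity fitness landscape
#'
#' Estimates the fitness landscape over log10 base attack rate from
#' lineage records: rolling means (window = a fraction of the sample) of
#' reproductive output R and lifetime L against the rolling mean of
#' log10 a, after sorting records by the trait.  The population "birth
#' rate" is derived from the same records as b = (rolling R)/(rolling L),
#' so the decomposition log10 R = log10 b + log10 L holds by construction.
#' A quadratic least-squares fit to log10 R on the rolling grid summarises
#' the landscape; its tangent at the steady-state trait mean is compared
#' with the mutation-bias prediction by \code{\link{tangency_check}}.
#'
#' The steady-state trait statistics (\code{a_star_log10},
#' \code{var_log10_a}) are lifetime-weighted means over records, which
#' estimate the community (resident-weighted) distribution.
#'
#' @param records Output of \code{\link{lineage_metrics}} (censored rows
#'   are dropped internally); at least 100 complete records are required.
#' @param window_fraction Rolling-window size as a fraction of the sample.
#' @return Object of class \code{fitness_landscape}: list with the
#'   complete records, grid \code{x} (rolling log10 a), \code{R_roll},
#'   \code{L_roll}, \code{b_roll}, quadratic coefficients \code{quad_R}
#'   (intercept, linear, quadratic), \code{a_star_log10},
#'   \code{var_log10_a}, \code{n}, \code{n_censored}, \code{window}.
#' @export
rolling_fitness_curves <- function(records, window_fraction = 0.01) {
  cc <- records[!records$censored, , drop = FALSE]
  if (nrow(cc) < 100L)
    stop("need at least 100 complete (non-censored) records")
  cc <- cc[order(cc$log10_a), , drop = FALSE]
  n <- nrow(cc)
  w <- max(2L, as.integer(round(window_fraction * n)))
  x <- zoo::rollmean(cc$log10_a, w)
  R_roll <- zoo::rollmean(as.numeric(cc$R_offspring), w)
  L_roll <- zoo::rollmean(as.numeric(cc$L), w)
  b_roll <- ifelse(L_roll > 0, R_roll / L_roll, NA_real_)
  ok <- is.finite(x) & R_roll > 0
  quad_R <- stats::coef(stats::lm(log10(R_roll[ok]) ~ x[ok] + I(x[ok]^2)))
  names(quad_R) <- c("b0", "b1", "b2")
  wL <- cc$L
  a_star <- if (sum(wL) > 0) sum(wL * cc$log10_a) / sum(wL) else mean(cc$log10_a)
  v <- if (sum(wL) > 0) sum(wL * (cc$log10_a - a_star)^2) / sum(wL)
       else stats::var(cc$log10_a)
  structure(list(records = cc, x = x, R_roll = R_roll, L_roll = L_roll,
                 b_roll = b_roll, quad_R = quad_R,
                 a_star_log10 = a_star, var_log10_a = v,
                 n = n, n_censored = sum(records$censored), window = w),
            class = "fitness_landscape")
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat(sprintf("Fitness landscape over log10 a: %d records (window %d, %d censored)\n",
              x$n, x$window, x$n_censored))
  cat(sprintf("  a* (log10) = %.3f, var(log10 a) = %.4f\n",
              x$a_star_log10, x$var_log10_a))
  cat(sprintf("  quadratic log10 R fit: %.3f + %.3f x + %.3f x^2\n",
              x$quad_R[1], x$quad_R[2], x$quad_R[3]))
  invisible(x)
}

#' Analytic establishment probability of an invading consumer
#'
#' Approximates the probability that a consumer with base attack rate
#' \code{a} establishes: the sum of its \code{SR} log-normal dimensionless
#' attack rates, discounted by the abundance scaling factor \code{beta}
#' (the mean scaled biomass of the resources an invader encounters), must
#' exceed one.  The sum is approximated by a single log-normal matched to
#' its first two moments, giving a cumulative-normal dependence on
#' log10 a.
#'
#' @param a Base attack rate(s).
#' @param params An \code{\link{lv_params}} object.
#' @param SR Resource richness experienced by invaders.
#' @param beta Abundance scaling factor in (0, 1].
#' @return Establishment probability/probabilities in [0, 1].
#' @export
predicted_birth_rate <- function(a, params, SR, beta = params$beta) {
  if (any(a < 0)) stop("a must be >= 0")
  s2 <- params$sigma^2
  m <- SR * alpha0(params) * a            # mean of the sum
  if (s2 == 0) return(as.numeric(beta * m > 1))
  sd2 <- log(1 + (exp(s2) - 1) / SR)      # log-variance of matched log-normal
  mu <- log(m) + s2 / 2 - sd2 / 2
  p <- stats::pnorm((mu + log(beta)) / sqrt(sd2))
  p[a == 0] <- 0
  p
}

#' Fit the abundance scaling factor to a measured birth-rate curve
#'
#' Converts the analytic establishment probability into a per-iteration
#' population birth rate — one consumer establishment per two iterations,
#' credited to a resident lineage in proportion to its establishment
#' probability relative to the community mean — and finds the single
#' scaling factor \code{beta} that best matches the measured rolling
#' b(a) curve in least squares on log10 axes:
#' \deqn{b(a) = \tfrac{1}{2}\, P(a; \beta) / (\bar S_C \bar P),}
#' where \eqn{\bar P} is the lifetime-weighted community mean of
#' \eqn{P(\cdot; \beta)} over the records.
#'
#' @param landscape A \code{\link{rolling_fitness_curves}} object.
#' @param params An \code{\link{lv_params}} object.
#' @param SR_mean Steady-state mean resource richness.
#' @param SC_mean Steady-state mean consumer richness.
#' @param interval Search interval for beta.
#' @return List with \code{beta}, the least-squares \code{objective}, and
#'   the fitted \code{curve} (data frame x, log10_b_measured,
#'   log10_b_predicted).
#' @export
fit_beta <- function(landscape, params, SR_mean, SC_mean,
                     interval = c(0.02, 1.5)) {
  x <- landscape$x
  bm <- landscape$b_roll
  ok <- is.finite(x) & is.finite(bm) & bm > 0
  if (sum(ok) < 10L) stop("too few usable points on the b(a) rolling curve")
  x <- x[ok]; lbm <- log10(bm[ok])
  recs <- landscape$records
  wts <- recs$L / sum(recs$L)
  pred_log10_b <- function(beta) {
    P <- predicted_birth_rate(10^x, params, SR_mean, beta)
    Pbar <- sum(wts * predicted_birth_rate(recs$a, params, SR_mean, beta))
    log10(0.5 * P / (SC_mean * Pbar))
  }
  obj <- function(beta) {
    lp <- pred_log10_b(beta)
    use <- is.finite(lp)
    sum((lbm[use] - lp[use])^2)
  }
  opt <- stats::optimize(obj, interval = interval)
  list(beta = opt$minimum, objective = opt$objective,
       curve = data.frame(x = x, log10_b_measured = lbm,
                          log10_b_predicted = pred_log10_b(opt$minimum)))
}

#' Evolutionary steady-state tangency condition
#'
#' At an evolutionary steady state the fitness landscape satisfies two
#' conditions simultaneously: richness equilibrium,
#' \eqn{\log_{10} R(a^\ast) = 0}, and tangency — the slope of
#' \eqn{\log_{10} R(a)} at the trait mean equals the mutation-bias
#' prediction
#' \eqn{-\log_{10}(e)\,\log_{10}\gamma_0 / \mathrm{var}(\log_{10} a)}.
#' With unbiased mutation (\eqn{\gamma_0 = 1}) the predicted slope is zero
#' and the steady state sits at a fitness maximum.
#'
#' @param landscape A \code{\link{rolling_fitness_curves}} object.
#' @param params An \code{\link{lv_params}} object.
#' @param var_log10_a Steady-state variance of log10 a; defaults to the
#'   lifetime-weighted estimate carried by the landscape.
#' @return List with \code{lhs_slope} (fitted slope at a*),
#'   \code{rhs_slope} (mutation-bias prediction), \code{residual}
#'   (lhs - rhs) and \code{log10_R_at_star}.
#' @export
tangency_check <- function(landscape, params,
                           var_log10_a = landscape$var_log10_a) {
  xs <- landscape$a_star_log10
  if (xs < min(landscape$x) || xs > max(landscape$x))
    stop("a* lies outside the fitted trait range")
  cf <- landscape$quad_R
  lhs <- unname(cf["b1"] + 2 * cf["b2"] * xs)
  rhs <- -log10(exp(1)) * log10(params$gamma0) / var_log10_a
  list(lhs_slope = lhs, rhs_slope = rhs, residual = lhs - rhs,
       log10_R_at_star = unname(cf["b0"] + cf["b1"] * xs + cf["b2"] * xs^2))
}

#' Bootstrap the landscape summaries over consumer records
#'
#' Resamples complete lineage records with replacement and recomputes the
#' rolling landscape, its tangency residual and the fitness at the trait
#' mean, yielding confidence intervals for \code{\link{tangency_check}}.
#'
#' @param records Output of \code{\link{lineage_metrics}}.
#' @param params An \code{\link{lv_params}} object.
#' @param n_boot Number of bootstrap resamples.
#' @param window_fraction Passed to \code{\link{rolling_fitness_curves}}.
#' @return Data frame with one row per resample: \code{lhs_slope},
#'   \code{rhs_slope}, \code{residual}, \code{log10_R_at_star}.
#' @export
bootstrap_tangency <- function(records, params, n_boot = 200L,
                               window_fraction = 0.01) {
  cc <- records[!records$censored, , drop = FALSE]
  out <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(cc), nrow(cc), replace = TRUE)
    rs <- cc[idx, , drop = FALSE]
    ls <- rolling_fitness_curves(rs, window_fraction)
    tc <- tryCatch(tangency_check(ls, params), error = function(e) NULL)
    if (!is.null(tc))
      out[[b]] <- data.frame(lhs_slope = tc$lhs_slope,
                             rhs_slope = tc$rhs_slope,
                             residual = tc$residual,
                             log10_R_at_star = tc$log10_R_at_star)
  }
  do.call(rbind, out)
}

#' Regressions of competition terms on base attack rate
#'
#' OLS slopes of log10 C (focal growth term) and log10 D (interspecific
#' competition term) on log10 a over random ordered resident pairs sampled
#' from steady-state snapshots (the \code{pair_samples} element of an
#' \code{lv_run}).  The naive expectation from fresh log-normal sampling
#' is a slope near 1 for both; assembled communities flatten the C slope
#' to a slightly negative value while D keeps most of its increase — the
#' signature of serial resource extirpation.
#'
#' @param pairs Data frame with columns \code{a_k}, \code{C}, \code{D}
#'   (e.g. \code{run$pair_samples}), optionally filtered to post-burn-in
#'   iterations.
#' @return List with \code{C_slope}, \code{C_se}, \code{D_slope},
#'   \code{D_se}, intercepts and the number of pairs used.
#' @export
term_regressions <- function(pairs) {
  use <- is.finite(pairs$a_k) & pairs$a_k > 0 & pairs$C > 0 & pairs$D > 0
  d <- pairs[use, , drop = FALSE]
  if (nrow(d) < 10L) stop("too few pairs with positive terms")
  la <- log10(d$a_k)
  if (stats::sd(la) == 0) stop("degenerate variance in log10 a")
  fC <- stats::lm(log10(d$C) ~ la)
  fD <- stats::lm(log10(d$D) ~ la)
  sC <- summary(fC)$coefficients
  sD <- summary(fD)$coefficients
  list(C_slope = sC[2, 1], C_se = sC[2, 2], C_intercept = sC[1, 1],
       D_slope = sD[2, 1], D_se = sD[2, 2], D_intercept = sD[1, 1],
       n = nrow(d))
}

#' Fractions of consumer extirpations by cause
#'
#' Normalised tally of death causes among consumers extirpated after the
#' burn-in, over the closed cause vocabulary.
#'
#' @param run An \code{lv_run} or its \code{consumers} data frame.
#' @param burn_in Only deaths after this iteration are counted.
#' @return Named numeric vector over
#'   \code{c("starvation_eq13", "exploitative_eq14", "bust_after_boom",
#'   "dynamical_extirpation")}; sums to 1.
#' @export
extirpation_cause_fractions <- function(run, burn_in = 0L) {
  cons <- if (inherits(run, "lv_run")) run$consumers else run
  dead <- cons[!is.na(cons$death_iteration) &
                 cons$death_iteration > burn_in, , drop = FALSE]
  if (nrow(dead) == 0L) stop("no consumer extirpations after burn_in")
  if (any(is.na(dead$death_cause)))
    stop("extirpation events without a cause tag")
  vocab <- c("starvation_eq13", "exploitative_eq14", "bust_after_boom",
             "dynamical_extirpation")
  bad <- setdiff(unique(dead$death_cause), vocab)
  if (length(bad) > 0)
    stop("unknown death causes: ", paste(bad, collapse = ", "))
  tab <- table(factor(dead$death_cause, levels = vocab))
  as.numeric(tab) / nrow(dead) -> fr
  stats::setNames(fr, vocab)
}

#' Establishment-time basic reproduction number
#'
#' The mean basic reproduction number of invading consumers implied by a
#' steady state: \eqn{\alpha_0 \, \bar a \, e^{\sigma^2/2} \, \bar S_R},
#' with \eqn{\bar a = 10^{\overline{\log_{10} a}}} the geometric-mean base
#' attack rate.  Evolved prudence keeps this moderately above one.
#'
#' @param params An \code{\link{lv_params}} object.
#' @param mean_log10_a Steady-state community mean of log10 a.
#' @param SR_mean Steady-state mean resource richness.
#' @return Numeric scalar.
#' @export
#' @examples
#' establishment_R(lv_params(), -4.96, 224)  # about 7.3
establishment_R <- function(params, mean_log10_a, SR_mean) {
  alpha0(params) * 10^mean_log10_a * exp(params$sigma^2 / 2) * SR_mean
}
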