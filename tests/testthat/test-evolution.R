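test_that("lineage metrics do the basic bookkeeping", {
  log <- data.frame(
    id = 1:3, a = c(1e-5, 1.1e-5, 0.9e-5),
    birth_iteration = c(10L, 20L, 30L),
    parent_id = c(NA, 1L, 1L),
    death_iteration = c(50L, NA, NA),
    death_cause = c("exploitative_eq14", NA, NA),
    stringsAsFactors = FALSE)
  rec <- lineage_metrics(log, burn_in = 0L)
  r1 <- rec[rec$id == 1L, ]
  expect_equal(r1$L, 40L)              # death 50 - birth 10
  expect_equal(r1$R_offspring, 2L)     # two successful offspring
  expect_false(r1$censored)
  expect_true(all(rec$censored[rec$id != 1L]))
  expect_equal(rec$death_cause[rec$id == 2L], "censored")
  # burn-in past every birth leaves nothing
  expect_equal(nrow(lineage_metrics(log, burn_in = 100L)), 0L)
  # dangling parent ids are an error
  log$parent_id[2] <- 99L
  expect_error(lineage_metrics(log, 0L), "dangling")
})

test_that("rolling curves are flat for constant records", {
  set.seed(40)
  n <- 500L
  rec <- data.frame(id = 1:n, a = 10^runif(n, -6, -4),
                    log10_a = 0, birth_iteration = 1L,
                    death_iteration = 2L, parent_id = NA,
                    death_cause = "starvation_eq13",
                    L = 1L, R_offspring = 2L, censored = FALSE)
  rec$log10_a <- log10(rec$a)
  ls <- rolling_fitness_curves(rec, window_fraction = 0.05)
  expect_true(all(abs(log10(ls$R_roll) - log10(2)) < 1e-12))
  expect_true(all(abs(ls$b_roll - 2) < 1e-12))
})

test_that("a known quadratic log-fitness profile is recovered", {
  set.seed(41)
  n <- 2e4
  x <- runif(n, -6, -4)
  q <- function(x) -0.5 - 0.8 * (x + 5) - 0.6 * (x + 5)^2
  R <- rpois(n, 10^pmin(q(x), 2))
  rec <- data.frame(id = 1:n, a = 10^x, log10_a = x, birth_iteration = 1L,
                    death_iteration = 2L, parent_id = NA,
                    death_cause = "starvation_eq13",
                    L = 1L, R_offspring = R, censored = FALSE)
  ls <- rolling_fitness_curves(rec)
  # compare fitted polynomial against truth on the bulk of the range
  xs <- seq(-5.8, -4.2, by = 0.1)
  fitted <- ls$quad_R["b0"] + ls$quad_R["b1"] * xs + ls$quad_R["b2"] * xs^2
  expect_lt(max(abs(fitted - q(xs))), 0.15)
})

test_that("analytic establishment curve behaves at its limits", {
  p <- lv_params()
  expect_equal(predicted_birth_rate(0, p, 200), 0)
  expect_lt(predicted_birth_rate(1e-9, p, 200), 1e-4)
  expect_gt(predicted_birth_rate(1e3, p, 200), 0.999)
  expect_true(all(diff(predicted_birth_rate(10^seq(-8, 2, 0.5), p, 200)) >= 0))
  # beta = 1, sigma = 0: a step at a = 1/(alpha0 SR)
  p0 <- lv_params(sigma = 0)
  expect_equal(predicted_birth_rate(1 / 200 * 0.999, p0, 200, beta = 1), 0)
  expect_equal(predicted_birth_rate(1 / 200 * 1.001, p0, 200, beta = 1), 1)
  # Monte-Carlo check of the moment-matched log-normal the curve evaluates
  set.seed(42)
  SR <- 150; sig <- 1.2; a <- 5e-3; beta <- 0.7
  s2 <- log(1 + (exp(sig^2) - 1) / SR)
  mu <- log(SR * a) + sig^2 / 2 - s2 / 2
  mc <- mean(beta * rlnorm(1e5, mu, sqrt(s2)) > 1)
  an <- predicted_birth_rate(a, lv_params(sigma = sig), SR, beta)
  expect_lt(abs(mc - an), 3 * sqrt(an * (1 - an) / 1e5))
  # at moderate spread the approximation tracks the true sum closely
  sums <- colSums(matrix(a * exp(sig * rnorm(SR * 2e4)), SR))
  expect_lt(abs(mean(beta * sums > 1) - an), 0.05)
})

test_that("the abundance scaling factor is recovered from synthetic curves", {
  p <- lv_params()
  SRm <- 200; SCm <- 120
  set.seed(43)
  n <- 5000L
  a <- 10^rnorm(n, -4.9, 0.25)
  recs <- data.frame(a = a, L = rep(200, n))
  x <- seq(-5.5, -4.3, length.out = 150)
  beta_true <- 0.3
  Pbar <- mean(predicted_birth_rate(recs$a, p, SRm, beta_true))
  b_true <- 0.5 * predicted_birth_rate(10^x, p, SRm, beta_true) / (SCm * Pbar)
  ls <- structure(list(x = x, b_roll = b_true, records = recs),
                  class = "fitness_landscape")
  fit <- fit_beta(ls, p, SRm, SCm)
  expect_equal(fit$beta, beta_true, tolerance = 0.02)
})

test_that("tangency arithmetic matches the mutation-bias prediction", {
  p <- lv_params()
  # the numerator -log10(e) * log10(gamma0) at the default bias
  expect_equal(-log10(exp(1)) * log10(p$gamma0), 0.02105, tolerance = 5e-4)
  # hand-built landscape: log10 R = -0.1 (x + 5)^2 around a* = -5
  ls <- structure(list(x = seq(-6, -4, 0.01),
                       quad_R = c(b0 = -0.1 * 25, b1 = -0.1 * 10, b2 = -0.1),
                       a_star_log10 = -5, var_log10_a = 0.04),
                  class = "fitness_landscape")
  tc <- tangency_check(ls, p)
  expect_equal(tc$lhs_slope, 0)             # apex at a*
  expect_equal(tc$rhs_slope, 0.02105 / 0.04, tolerance = 1e-3)
  expect_equal(tc$log10_R_at_star, 0)
  # unbiased mutation predicts a fitness maximum (slope 0)
  tc0 <- tangency_check(ls, lv_params(gamma0_sq = 1))
  expect_equal(tc0$rhs_slope, 0)
  ls$a_star_log10 <- -7
  expect_error(tangency_check(ls, p), "outside")
})

test_that("term regressions recover known slopes", {
  set.seed(44)
  n <- 4000L
  a <- 10^runif(n, -5, -2)
  # C independent of a: slope indistinguishable from zero
  pairs <- data.frame(a_k = a, C = exp(rnorm(n, 0, 0.3)),
                      D = exp(rnorm(n, 0, 0.3)))
  tr <- term_regressions(pairs)
  expect_lt(abs(tr$C_slope), 3 * tr$C_se)
  # freshly sampled columns (no assembly): C = sum H - 1 scales linearly
  # with a when a is large, and so does D against a fixed partner column
  SR <- 100L
  Hl <- exp(4 * rnorm(SR))
  Cv <- Dv <- numeric(n)
  for (i in seq_len(n)) {
    h <- a[i] * 1e3 * exp(4 * rnorm(SR))   # shift a upward: C >> 1 regime
    Cv[i] <- sum(h) - 1
    Dv[i] <- sum(h * Hl)
  }
  tr2 <- term_regressions(data.frame(a_k = a, C = Cv, D = Dv))
  expect_equal(tr2$C_slope, 1, tolerance = 0.1)
  expect_equal(tr2$D_slope, 1, tolerance = 0.1)
  expect_error(term_regressions(data.frame(a_k = rep(1e-4, 20),
                                           C = 1:20, D = 1:20)),
               "degenerate")
})

test_that("cause fractions cover the closed vocabulary and sum to one", {
  log <- data.frame(id = 1:4, a = 1e-5, birth_iteration = 1L,
                    parent_id = NA,
                    death_iteration = c(10L, 20L, NA, 30L),
                    death_cause = c("exploitative_eq14", "exploitative_eq14",
                                    NA, "exploitative_eq14"),
                    stringsAsFactors = FALSE)
  fr <- extirpation_cause_fractions(log)
  expect_equal(unname(fr["exploitative_eq14"]), 1)
  expect_equal(sum(fr), 1)
  log$death_cause[1] <- NA
  expect_error(extirpation_cause_fractions(log), "without a cause")
})

test_that("establishment-time reproduction numbers match the steady states", {
  p <- lv_params()
  expect_equal(establishment_R(p, -4.96, 224), 7.32, tolerance = 0.01)
  expect_equal(establishment_R(p, -4.67, 260), 16.6, tolerance = 0.01)
  expect_equal(establishment_R(p, -Inf, 224), 0)
})
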