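test_that("invasibility criterion is strict and handles empty diets", {
  expect_true(invasibility(c(0.6, 0.6)))    # sum 1.2
  expect_false(invasibility(c(0.5, 0.5)))   # boundary excluded
  expect_false(invasibility(numeric(0)))    # no resources: starvation
})

test_that("exploitative exclusion matches its worked example and limits", {
  # A = 1, B = 4, C = 0.2, D = 1.2 -> 0.2 < 0.3: excluded
  expect_true(exploitative_exclusion(c(0.6, 0.6), c(2, 1e-9)))
  # disjoint diets: D ~ 0, no exclusion
  expect_false(exploitative_exclusion(c(1e-12, 1.5), c(2, 1e-12)))
  # a clone is not excluded (strict inequality)
  expect_false(exploitative_exclusion(c(2, 0.3), c(2, 0.3)))
  expect_error(exploitative_exclusion(c(2, 2), c(0.2, 0.2)), "invasibility")
  expect_error(exploitative_exclusion(c(1, 2), c(1, 2, 3)), "same resource")
})

test_that("boom pruning thresholds at -ln(Mmin)", {
  expect_equal(boom_prune(c(12, 5), 1e-5), 1L)       # -ln(1e-5) = 11.513
  expect_length(boom_prune(c(11.5), 1e-5), 0)
  expect_length(boom_prune(c(500, 600), 1e-300), 0)  # Mmin -> 0: never prunes
  expect_error(boom_prune(c(1), 2), "Mmin")
})

test_that("apparent extirpation agrees with the single-consumer equilibrium", {
  r <- apparent_extirpation(c(3, 1.5, 1.5))   # 5 > 13.5/3
  expect_true(r$extirpates)
  expect_equal(r$main, 1L)
  eq <- oracle_single_eq(c(3, 1.5, 1.5))
  expect_equal(eq$B_C, 5 / 13.5)
  expect_lt(eq$B_R[1], 0)                     # main resource negative
  expect_false(apparent_extirpation(c(3, 0.5))$extirpates)
  expect_gt(oracle_single_eq(c(3, 0.5))$B_R[1], 0)
  # a monophagous linear consumer never extirpates its only resource
  expect_false(apparent_extirpation(c(2))$extirpates)
  expect_error(apparent_extirpation(c(0.2, 0.3)), "invasibility")
})

test_that("Pyrrhic competition matches the joint-equilibrium oracle", {
  Hk <- c(6, 2, 1); Hl <- c(4, 1, 5)
  expect_true(pyrrhic_competition(Hk, Hl))    # 761 < 826
  eq <- oracle_joint_eq(Hk, Hl)
  expect_equal(eq$B_k, 57 / 761)
  expect_equal(eq$B_l, 121 / 761)
  expect_gt(6 * eq$B_k + 4 * eq$B_l, 1)       # overconsumption of resource 1
  expect_false(pyrrhic_competition(c(4, 1, 1), c(1, 1, 4)))  # symmetric pair
  # disjoint diets with H_ik B_Ck < 1: no extirpation
  expect_false(pyrrhic_competition(c(2, 1, 0), c(0, 0, 3)))
  expect_error(pyrrhic_competition(c(2, 2), c(2, 2)), "infeasible")
  expect_error(pyrrhic_competition(c(0.1, 0.1), c(2, 1)), "invasibility")
})

test_that("competition terms decompose the exclusion condition", {
  ct <- competition_terms(c(2, 1e-9), c(2, 1e-9))
  expect_equal(ct$lhs, 0, tolerance = 1e-8)   # self-competition boundary
  ct2 <- competition_terms(c(0.6, 0.6), c(2, 1e-9))
  expect_equal(ct2$A, 1, tolerance = 1e-8)
  expect_equal(ct2$B, 4, tolerance = 1e-8)
  expect_equal(ct2$C, 0.2)
  expect_equal(ct2$D, 1.2, tolerance = 1e-8)
  expect_equal(ct2$lhs, log10(2 / 3), tolerance = 1e-7)
  expect_lt(ct2$lhs, 0)                       # exclusion, consistent with Eq 14
  expect_true(exploitative_exclusion(c(0.6, 0.6), c(2, 1e-9)))
  expect_false(competition_terms(c(0.2, 0.2), c(2, 1))$lhs_defined)
})

test_that("conditions agree with closed-form equilibrium signs on random instances", {
  # 1e4 randomized small instances per condition; zero disagreements
  # outside machine-precision ties.
  set.seed(20)
  n_checked <- c(excl = 0L, app = 0L, pyr = 0L)
  n_wrong <- c(excl = 0L, app = 0L, pyr = 0L)
  for (i in seq_len(10000L)) {
    SR <- sample(2:6, 1)
    Hk <- rand_column(SR, scale = 10^runif(1, -1, 0.7))
    Hl <- rand_column(SR, scale = 10^runif(1, -1, 0.7))
    # exploitative exclusion <=> invader growth negative at l's equilibrium
    if (sum(Hl) > 1) {
      g <- oracle_invader_growth(Hk, Hl)
      if (abs(g) > 1e-9 * (1 + sum(Hk))) {
        n_wrong["excl"] <- n_wrong["excl"] +
          (exploitative_exclusion(Hk, Hl) != (g < 0))
        n_checked["excl"] <- n_checked["excl"] + 1L
      }
    }
    # apparent competition <=> main resource negative at own equilibrium
    if (sum(Hk) > 1) {
      eq <- oracle_single_eq(Hk)
      bmain <- min(eq$B_R)
      if (abs(bmain) > 1e-9) {
        n_wrong["app"] <- n_wrong["app"] +
          (apparent_extirpation(Hk)$extirpates != (bmain < 0))
        n_checked["app"] <- n_checked["app"] + 1L
      }
    }
    # Pyrrhic competition <=> k's main resource negative at joint equilibrium
    if (sum(Hk) > 1 && sum(Hl) > 1) {
      eq <- oracle_joint_eq(Hk, Hl)
      if (eq$det > 1e-9) {
        bmain <- eq$B_R[which.max(Hk)]
        if (abs(bmain) > 1e-9) {
          n_wrong["pyr"] <- n_wrong["pyr"] +
            (pyrrhic_competition(Hk, Hl) != (bmain < 0))
          n_checked["pyr"] <- n_checked["pyr"] + 1L
        }
      }
    }
  }
  expect_identical(unname(n_wrong), c(0L, 0L, 0L))
  expect_true(all(n_checked > 2000L))  # the sweeps actually exercised cases
})

test_that("exclusion condition agrees with explicit two-consumer dynamics", {
  # ODE oracle on the worked pair: the generalist invader decays against
  # the established specialist.
  p <- lv_params()
  st <- make_fixture("pair-exclusion", p)
  st$B_C <- c(p$Mmin, 0.2)   # resident near equilibrium, invader rare
  st$B_R <- c(0.55, 1)
  rel <- integrate_to_equilibrium(st, p)
  expect_false(1L %in% rel$state$consumer_ids)  # the generalist decays out
  expect_true(2L %in% rel$state$consumer_ids)   # the specialist persists
})
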