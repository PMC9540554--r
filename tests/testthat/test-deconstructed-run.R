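test_that("deconstructed runs are bit-reproducible for a given seed", {
  p <- lv_params(n_iterations = 300L, seed = 5L)
  r1 <- run_deconstructed_assembly(p)
  r2 <- run_deconstructed_assembly(p)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$consumers, r2$consumers)
  expect_identical(r1$resources, r2$resources)
  expect_identical(r1$final_state$H, r2$final_state$H)
})

test_that("a zero-iteration run returns only the seed state", {
  r <- run_deconstructed_assembly(lv_params(n_iterations = 0L, seed = 2L))
  expect_equal(nrow(r$trajectory), 1L)
  expect_equal(r$trajectory$S_R, 20)
  expect_equal(r$trajectory$S_C, 10)
})

test_that("every extant consumer satisfies the invasibility criterion", {
  r <- run_deconstructed_assembly(lv_params(n_iterations = 2000L, seed = 8L))
  H <- r$final_state$H
  expect_true(all(colSums(H) - 1 > 0))
  expect_true(all(H > 0) && all(is.finite(H)))
  expect_equal(length(r$final_state$a), ncol(H))
  expect_equal(length(r$final_state$resource_ids), nrow(H))
})

test_that("the event log is internally consistent", {
  r <- run_deconstructed_assembly(lv_params(n_iterations = 2000L, seed = 8L))
  cons <- r$consumers
  dead <- !is.na(cons$death_iteration)
  expect_true(all(cons$death_iteration[dead] >= cons$birth_iteration[dead]))
  expect_true(all(cons$death_cause[dead] %in%
                    c("starvation_eq13", "exploitative_eq14",
                      "bust_after_boom")))
  expect_true(all(is.na(cons$death_cause[!dead])))
  # extant consumers are exactly the final-state columns
  expect_setequal(cons$id[!dead], r$final_state$consumer_ids)
  res <- r$resources
  rdead <- !is.na(res$death_iteration)
  expect_true(all(res$death_cause[rdead] %in%
                    c("boom_overexploitation", "apparent_competition",
                      "pyrrhic_competition")))
  expect_setequal(res$id[!rdead], r$final_state$resource_ids)
  # parents exist and predate their offspring
  ok <- !is.na(cons$parent_id)
  expect_true(all(cons$parent_id[ok] %in% cons$id))
  expect_true(all(cons$birth_iteration[ok] >
                    cons$birth_iteration[match(cons$parent_id[ok], cons$id)] |
                    cons$birth_iteration[match(cons$parent_id[ok], cons$id)] == 0))
})

test_that("compiled sweeps match plain-R references on random communities", {
  set.seed(33)
  for (rep in seq_len(40L)) {
    SR <- sample(3:12, 1); SC <- sample(2:8, 1)
    H <- matrix(exp(rnorm(SR * SC, sd = 1.5)) * 10^runif(1, -1, 0.3), SR, SC)
    S <- colSums(H); Q <- colSums(H^2); D <- crossprod(H)
    ## exploitative sweep reference (viable residents only)
    kill_ref <- which(vapply(seq_len(SC), function(k)
      any(vapply(setdiff(seq_len(SC), k), function(l)
        S[l] > 1 && (S[k] - 1) < D[k, l] * (S[l] - 1) / Q[l], TRUE)), TRUE))
    expect_equal(.Call(prudentweb:::C_excl_sweep, S, Q, D), kill_ref,
                 ignore_attr = TRUE)
    ## Pyrrhic sweep reference built on the exported pairwise condition
    rr_ref <- integer(0)
    for (k in seq_len(SC)) {
      if (S[k] - 1 <= 0) next
      for (l in setdiff(seq_len(SC), k)) {
        if (S[l] - 1 <= 0) next
        if (Q[k] * Q[l] - D[k, l]^2 <= 0) next
        if (pyrrhic_competition(H[, k], H[, l])) {
          rr_ref <- c(rr_ref, which.max(H[, k])); break
        }
      }
    }
    expect_equal(.Call(prudentweb:::C_pyrrhic_sweep, H, S, Q, D),
                 sort(unique(rr_ref)), ignore_attr = TRUE)
    ## apparent-competition set reference
    sat_ref <- which(vapply(seq_len(SC), function(k)
      S[k] - 1 > Q[k] / max(H[, k]), TRUE))
    expect_equal(.Call(prudentweb:::C_eq16_set, H, S, Q), sat_ref,
                 ignore_attr = TRUE)
  }
})

test_that("trajectory statistics track the community state", {
  r <- run_deconstructed_assembly(lv_params(n_iterations = 500L, seed = 4L),
                                  snapshot_every = 50L,
                                  pairs_per_snapshot = 5L)
  last <- nrow(r$trajectory)
  expect_equal(r$trajectory$S_R[last], nrow(r$final_state$H))
  expect_equal(r$trajectory$S_C[last], ncol(r$final_state$H))
  expect_equal(r$trajectory$mean_log10_a[last],
               mean(log10(r$final_state$a)))
  expect_true(all(r$trajectory$S_R >= 0) && all(r$trajectory$S_C >= 0))
  # pair samples carry positive terms from viable snapshot communities
  expect_gt(nrow(r$pair_samples), 0)
  expect_true(all(r$pair_samples$C > 0))   # extant consumers pass Eq 13
  expect_true(all(r$pair_samples$D > 0))
  expect_true(all(r$pair_samples$B > 0))
})
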