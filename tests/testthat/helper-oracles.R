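# Closed-form equilibrium oracles used to cross-check the pairwise
# ecological conditions.  These solve the linearised equilibria directly
# and are kept independent of the condition implementations.

# Single-consumer linear equilibrium: B_C = (sum H - 1) / sum H^2,
# resource biomasses 1 - H_j B_C (positivity not enforced).
oracle_single_eq <- function(H_l) {
  B_C <- (sum(H_l) - 1) / sum(H_l^2)
  list(B_C = B_C, B_R = 1 - H_l * B_C)
}

# Growth rate of a rare invader k at resident l's single-consumer
# equilibrium (in units of rho).
oracle_invader_growth <- function(H_k, H_l) {
  eq <- oracle_single_eq(H_l)
  sum(H_k * eq$B_R) - 1
}

# Joint equilibrium of two coexisting consumers (2 x 2 linear system).
oracle_joint_eq <- function(H_k, H_l) {
  Qk <- sum(H_k^2); Ql <- sum(H_l^2); D <- sum(H_k * H_l)
  C <- sum(H_k) - 1; A <- sum(H_l) - 1
  det <- Qk * Ql - D^2
  B_k <- (C * Ql - A * D) / det
  B_l <- (A * Qk - C * D) / det
  list(B_k = B_k, B_l = B_l, B_R = 1 - H_k * B_k - H_l * B_l, det = det)
}

# Random positive attack column with heavy spread, loosely mimicking the
# model's log-normal scheme at small richness.
rand_column <- function(SR, scale = 1) {
  scale * exp(stats::rnorm(SR, sd = 1.5))
}
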