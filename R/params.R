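#' Model parameters for the two-level food-web assembly model
#'
#' Constructs the parameter set shared by the full (ODE) and deconstructed
#' (condition-based) assembly formulations.  Defaults are the study
#' conditions of the model: identical resource growth rates and carrying
#' capacities, identical consumer assimilation efficiencies and
#' respiration+mortality rates, log-normal pairwise attack rates with
#' spread \code{sigma}, and a biased log-normal mutation kernel for the
#' heritable base attack rate.
#'
#' The mutation parameters are stored as their squares (\code{gamma0_sq},
#' \code{gamma1_sq}) because those are the exactly-representable constants;
#' the bias \eqn{\gamma_0 = \sqrt{0.8}} and size \eqn{\gamma_1 = \sqrt{1.3}}
#' are derived at construction.  The attack-rate scaling factor
#' \eqn{\alpha_0 = \epsilon K / \rho} is always derived (see
#' \code{\link{alpha0}}), never stored.
#'
#' @param r Resource intrinsic per-capita growth rate (1/time).
#' @param K Resource carrying capacity in absence of consumers (biomass).
#' @param epsilon Assimilation efficiency (dimensionless, in (0, 1]).
#' @param rho Consumer respiration+mortality rate (1/time).
#' @param sigma Spread (standard deviation) of log attack rates; a measure
#'   of consumer specialisation.
#' @param gamma0_sq Squared mutation bias of base attack rate (in (0, 1]).
#' @param gamma1_sq Squared mutational variation of base attack rate (> 1).
#' @param Mmin Extirpation threshold on dimensionless biomass (in (0, 1)).
#' @param beta Abundance scaling factor in the establishment ("birth")
#'   probability formula (in (0, 1]).
#' @param SR0,SC0 Initial resource and consumer species richness.
#' @param a_init Common base attack rate of the seed consumers.  The model
#'   steady state is independent of this value, so it is a free knob.
#' @param n_iterations Default number of invasion iterations for runs.
#' @param burn_in Default number of initial iterations discarded in
#'   steady-state analyses.
#' @param seed Default random seed recorded in run outputs.
#' @param t_equil_cutoff Cut-off time (in model time units) for ODE
#'   relaxation towards equilibrium in the full formulation.
#' @param equil_tol Equilibrium-detection tolerance: relaxation stops when
#'   the largest scaled rate |dB/dt| / max(B, Mmin) stays below this value
#'   at two checks 100 time units apart.
#' @param candidate_cap Maximum number of candidate invaders sampled per
#'   iteration before the iteration is skipped (logged as a rejection
#'   exhaustion).
#'
#' @return An object of class \code{lv_params}: a named list of the above
#'   with derived fields \code{gamma0} and \code{gamma1}.
#' @seealso \code{\link{alpha0}}, \code{\link{run_deconstructed_assembly}},
#'   \code{\link{run_full_assembly}}
#' @export
#' @examples
#' p <- lv_params()
#' alpha0(p)   # = epsilon * K / rho = 1 at the defaults
lv_params <- function(r = 1, K = 1, epsilon = 0.1, rho = 0.1,
                      sigma = 4, gamma0_sq = 0.8, gamma1_sq = 1.3,
                      Mmin = 1e-5, beta = 0.45,
                      SR0 = 20L, SC0 = 10L, a_init = 1e-5,
                      n_iterations = 1000L, burn_in = 0L, seed = 1L,
                      t_equil_cutoff = 1e5, equil_tol = 1e-6,
                      candidate_cap = 10000L) {
  p <- list(r = r, K = K, epsilon = epsilon, rho = rho, sigma = sigma,
            gamma0_sq = gamma0_sq, gamma1_sq = gamma1_sq, Mmin = Mmin,
            beta = beta, SR0 = as.integer(SR0), SC0 = as.integer(SC0),
            a_init = a_init, n_iterations = as.integer(n_iterations),
            burn_in = as.integer(burn_in), seed = as.integer(seed),
            t_equil_cutoff = t_equil_cutoff, equil_tol = equil_tol,
            candidate_cap = as.integer(candidate_cap))
  p$gamma0 <- sqrt(gamma0_sq)
  p$gamma1 <- sqrt(gamma1_sq)
  class(p) <- "lv_params"
  validate_lv_params(p)
  p
}

#' Attack-rate scaling factor
#'
#' Returns \eqn{\alpha_0 = \epsilon K / \rho}, the factor converting a raw
#' attack rate into the dimensionless coefficient
#' \eqn{H_{jk} = \alpha_0 a_{jk}}.  It is derived from the stored
#' parameters, never stored independently.
#'
#' @param params An \code{\link{lv_params}} object.
#' @return Numeric scalar.
#' @export
alpha0 <- function(params) {
  params$epsilon * params$K / params$rho
}

validate_lv_params <- function(p) {
  stopifnot(inherits(p, "lv_params"))
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid parameters: ", msg,
                                                 call. = FALSE)
  chk(p$r > 0, "r must be > 0")
  chk(p$K > 0, "K must be > 0")
  chk(p$epsilon > 0 && p$epsilon <= 1, "epsilon must be in (0, 1]")
  chk(p$rho > 0, "rho must be > 0")
  chk(p$sigma >= 0, "sigma must be >= 0")
  chk(p$gamma0_sq > 0 && p$gamma0_sq <= 1, "gamma0_sq must be in (0, 1]")
  chk(p$gamma1_sq > 1, "gamma1_sq must be > 1")
  chk(p$Mmin > 0 && p$Mmin < 1, "Mmin must be in (0, 1)")
  chk(p$beta > 0 && p$beta <= 1, "beta must be in (0, 1]")
  chk(p$SR0 >= 1, "SR0 must be >= 1")
  chk(p$SC0 >= 1, "SC0 must be >= 1")
  chk(p$a_init > 0, "a_init must be > 0")
  chk(p$n_iterations >= 0, "n_iterations must be >= 0")
  chk(p$burn_in >= 0, "burn_in must be >= 0")
  chk(p$t_equil_cutoff > 0, "t_equil_cutoff must be > 0")
  chk(p$equil_tol > 0, "equil_tol must be > 0")
  chk(p$candidate_cap >= 1, "candidate_cap must be >= 1")
  invisible(p)
}

#' @export
print.lv_params <- function(x, ...) {
  cat("Two-level LV assembly parameters\n")
  cat(sprintf("  r = %g, K = %g, epsilon = %g, rho = %g (alpha0 = %g)\n",
              x$r, x$K, x$epsilon, x$rho, alpha0(x)))
  cat(sprintf("  sigma = %g, gamma0 = sqrt(%g), gamma1 = sqrt(%g)\n",
              x$sigma, x$gamma0_sq, x$gamma1_sq))
  cat(sprintf("  Mmin = %g, beta = %g\n", x$Mmin, x$beta))
  cat(sprintf("  init: SR0 = %d, SC0 = %d, a_init = %g\n",
              x$SR0, x$SC0, x$a_init))
  cat(sprintf("  run: n_iterations = %d, burn_in = %d, seed = %d\n",
              x$n_iterations, x$burn_in, x$seed))
  invisible(x)
}

# Keys serialised to/from JSON configuration files (derived fields omitted).
.lv_params_keys <- c("r", "K", "epsilon", "rho", "sigma", "gamma0_sq",
                     "gamma1_sq", "Mmin", "beta", "SR0", "SC0", "a_init",
                     "n_iterations", "burn_in", "seed", "t_equil_cutoff",
                     "equil_tol", "candidate_cap")

#' Read or write a parameter configuration as JSON
#'
#' The JSON keys follow the model's symbol table (\code{r}, \code{K},
#' \code{epsilon}, \code{rho}, \code{sigma}, \code{gamma0_sq},
#' \code{gamma1_sq}, \code{Mmin}, \code{beta}, \code{SR0}, \code{SC0},
#' \code{a_init}, \code{n_iterations}, \code{burn_in}, \code{seed}).
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' \code{\link{lv_params}}.
#'
#' @param path File path.
#' @param params An \code{\link{lv_params}} object (for writing).
#' @return \code{read_params_json} returns an \code{lv_params} object;
#'   \code{write_params_json} returns \code{path} invisibly.
#' @export
read_params_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), .lv_params_keys)
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(lv_params, raw)
}

#' @rdname read_params_json
#' @export
write_params_json <- function(params, path) {
  validate_lv_params(params)
  jsonlite::write_json(params[.lv_params_keys], path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
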