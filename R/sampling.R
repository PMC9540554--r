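#' Mutate a base attack rate
#'
#' Applies the model's multiplicative mutation kernel to a parent's base
#' attack rate: \eqn{a = \gamma_0 \gamma_1^{\zeta} a_{parent}} with
#' \eqn{\zeta} a standard normal draw.  On a log10 scale the kernel adds
#' \eqn{\log_{10}\gamma_0} (bias, negative for \eqn{\gamma_0 < 1}) plus
#' noise with standard deviation \eqn{\log_{10}\gamma_1}.
#'
#' @param a_parent Positive base attack rate of the parent lineage.
#' @param params An \code{\link{lv_params}} object.
#' @param zeta Optional standard-normal deviate; drawn from the current RNG
#'   stream when \code{NULL}.  Exposed so that deterministic cases (e.g.
#'   \code{zeta = 0}) can be exercised directly.
#' @return Mutated base attack rate (strictly positive scalar).
#' @export
#' @examples
#' p <- lv_params()
#' mutate_base_attack(1e-5, p, zeta = 0)  # = sqrt(0.8) * 1e-5
mutate_base_attack <- function(a_parent, params, zeta = NULL) {
  if (!is.numeric(a_parent) || length(a_parent) != 1L || a_parent <= 0)
    stop("a_parent must be a positive scalar")
  if (is.null(zeta)) zeta <- stats::rnorm(1)
  params$gamma0 * params$gamma1^zeta * a_parent
}

#' Probability that a mutation raises base attack rate
#'
#' For the log-normal mutation kernel, the probability that a child's base
#' attack rate exceeds its parent's is
#' \eqn{P(a' > a) = 1 - \Phi(\ln(1/\gamma_0) / \ln\gamma_1)}, with
#' \eqn{\Phi} the standard normal CDF.  For biased mutation
#' (\eqn{\gamma_0 \le 1}) this lies in (0, 0.5]; at the default parameters
#' it is about 0.20.
#'
#' @param gamma0 Mutation bias (> 0; degeneration of the trait for values
#'   below 1).
#' @param gamma1 Mutational variation (> 1).
#' @return Probability in (0, 1).
#' @export
#' @examples
#' mutation_increase_probability(sqrt(0.8), sqrt(1.3))  # about 0.20
mutation_increase_probability <- function(gamma0, gamma1) {
  if (gamma0 <= 0) stop("gamma0 must be > 0")
  if (gamma1 <= 1) stop("gamma1 must be > 1 (degenerate mutation kernel)")
  1 - stats::pnorm(log(1 / gamma0) / log(gamma1))
}

# Low-level candidate draws shared by the exported samplers and the
# assembly loops, so that all code paths consume the RNG stream in the same
# order: parent index, then zeta, then the xi column in resource-id order.
.draw_consumer <- function(a_res, SR, p, a0 = alpha0(p)) {
  parent <- sample.int(length(a_res), 1L)
  a_new <- p$gamma0 * p$gamma1^stats::rnorm(1) * a_res[parent]
  h <- a0 * a_new * exp(p$sigma * stats::rnorm(SR))
  list(parent = parent, a = a_new, h = h)
}

.draw_resource <- function(a_res, p, a0 = alpha0(p)) {
  a0 * a_res * exp(p$sigma * stats::rnorm(length(a_res)))
}

#' Sample a candidate invader
#'
#' \code{sample_consumer_candidate} draws a consumer invader: an ancestor
#' is chosen uniformly among resident consumers, its base attack rate is
#' mutated with \code{\link{mutate_base_attack}}, and one dimensionless
#' attack coefficient \eqn{H_{jk} = \alpha_0 a_k e^{\sigma \xi_{jk}}} is
#' drawn per extant resource.  \code{sample_resource_candidate} draws a
#' resource invader: one coefficient per resident consumer \eqn{k}, scaled
#' by that consumer's own base attack rate \eqn{a_k}.
#'
#' Both samplers implement the mean-field assumption that the focal
#' community is statistically representative of the surrounding
#' metacommunity, and are scale free: multiplying all resident base attack
#' rates by a constant multiplies all sampled quantities by the same
#' constant.
#'
#' @param community An \code{\link{lv_community}} with at least one
#'   resident consumer.
#' @param params An \code{\link{lv_params}} object.
#' @return A list of class \code{lv_candidate} with fields \code{kind}
#'   (\code{"consumer"} or \code{"resource"}), \code{base_attack} (consumers
#'   only), \code{H_entries} (against resources for a consumer candidate,
#'   against consumers for a resource candidate) and \code{parent_id}
#'   (consumers only).
#' @export
sample_consumer_candidate <- function(community, params) {
  if (n_consumers(community) < 1L)
    stop("community has no resident consumers; the model requires the seed community")
  d <- .draw_consumer(community$a, n_resources(community), params)
  structure(list(kind = "consumer", base_attack = d$a, H_entries = d$h,
                 parent_id = community$consumer_ids[d$parent]),
            class = "lv_candidate")
}

#' @rdname sample_consumer_candidate
#' @export
sample_resource_candidate <- function(community, params) {
  if (n_consumers(community) < 1L)
    stop("community has no resident consumers; the model requires the seed community")
  structure(list(kind = "resource", base_attack = NULL,
                 H_entries = .draw_resource(community$a, params),
                 parent_id = NULL),
            class = "lv_candidate")
}
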