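#' Stock-recruitment curve of a Lotka-Volterra stock under fishing
#'
#' Traces the equilibrium stock-recruitment relation of a single consumer
#' ("stock") feeding on one logistic resource while exposed to fishing
#' mortality \code{F}.  At equilibrium with total loss rate
#' \eqn{\rho + F}, the resource settles at
#' \eqn{B_R^\ast = (\rho + F)/(\epsilon a)} and the spawning stock biomass
#' at \eqn{SSB = (s/a)\,(1 - (\rho + F)/(\epsilon a K))}.  Recruitment is
#' operationalised as the equilibrium replacement production
#' \eqn{Rec = (\rho + F)\, SSB}: along the unfished replacement line each
#' adult has exactly one recruit offspring on average.  Eliminating
#' \eqn{F} gives the parabola
#' \eqn{Rec(SSB) = \rho R \, SSB \, (1 - a\,SSB/s)} with basic
#' reproduction number \eqn{R = \epsilon a K / \rho}.
#'
#' @param stock_params List with fields \code{s} (resource growth rate),
#'   \code{K}, \code{epsilon}, \code{rho} and \code{attack} (the attack
#'   rate a).  Values default to the reference configuration
#'   \code{s = 1, K = 100, epsilon = 0.1, rho = 0.1}.
#' @param F_grid Fishing mortalities; defaults to 201 values from 0 to the
#'   extinction boundary \eqn{F = \rho (R - 1)}.
#' @return An object of class \code{sr_curve}: data frame columns
#'   \code{F}, \code{SSB}, \code{Rec}, plus attributes \code{SSB0},
#'   \code{R} and the input parameters.
#' @seealso \code{\link{steepness_from_curve}},
#'   \code{\link{steepness_closed_form}}, \code{\link{multi_resource_curve}}
#' @export
#' @examples
#' cv <- trace_curve(stock_params(attack = 3 / 100))  # R = 3
#' attr(cv, "SSB0")                                   # about 22.22
#' steepness_from_curve(cv)                           # 0.52
trace_curve <- function(stock_params, F_grid = NULL) {
  sp <- stock_params
  R <- sp$epsilon * sp$attack * sp$K / sp$rho
  if (R <= 1) stop("basic reproduction number R <= 1: no viable unfished stock")
  F_ext <- sp$rho * (R - 1)
  if (is.null(F_grid)) F_grid <- seq(0, F_ext, length.out = 201L)
  SSB <- (sp$s / sp$attack) * (1 - (sp$rho + F_grid) / (sp$epsilon * sp$attack * sp$K))
  Rec <- (sp$rho + F_grid) * SSB
  out <- data.frame(F = F_grid, SSB = SSB, Rec = Rec)
  structure(out, class = c("sr_curve", "data.frame"),
            SSB0 = (sp$s / sp$attack) * (1 - 1 / R), R = R, params = sp)
}

#' @rdname trace_curve
#' @param s,K,epsilon,rho,attack Stock parameters; see above.
#' @export
stock_params <- function(s = 1, K = 100, epsilon = 0.1, rho = 0.1,
                         attack = 3 / 100) {
  if (any(c(s, K, epsilon, rho, attack) <= 0))
    stop("all stock parameters must be positive")
  list(s = s, K = K, epsilon = epsilon, rho = rho, attack = attack)
}

#' Steepness of a stock-recruitment curve
#'
#' Steepness is the ratio of recruitment at 20\% of the unfished spawning
#' stock biomass to recruitment at the unfished level,
#' \eqn{h = Rec(0.2\,SSB_0) / Rec(SSB_0)}.  Because the traced relation is
#' exactly a parabola in SSB, the curve points are interpolated by an
#' exact quadratic fit before evaluating the two recruitment values.
#'
#' @param curve An \code{sr_curve} from \code{\link{trace_curve}} or
#'   \code{\link{multi_resource_curve}}; it must cover
#'   \eqn{SSB = 0.2\,SSB_0}.
#' @return Steepness h (> 0); h < 1 iff R < 6.
#' @export
steepness_from_curve <- function(curve) {
  SSB0 <- attr(curve, "SSB0")
  if (is.null(SSB0) || !is.finite(SSB0)) stop("curve lacks a valid SSB0")
  if (min(curve$SSB) > 0.2 * SSB0 + 1e-12)
    stop("curve does not cover SSB = 0.2 * SSB0; extend F_grid")
  fit <- stats::lm(Rec ~ SSB + I(SSB^2), data = curve)
  rec_at <- function(ssb)
    sum(stats::coef(fit) * c(1, ssb, ssb^2))
  rec_at(0.2 * SSB0) / rec_at(SSB0)
}

#' Closed-form steepness from the basic reproduction number
#'
#' For a Lotka-Volterra stock (single or multiple resources) the steepness
#' of the equilibrium stock-recruitment relation is
#' \eqn{h = (1 + 4R)/25}, with \eqn{R} the stock's basic reproduction
#' number.  \eqn{h = 1} exactly at \eqn{R = 6}; the empirically preferred
#' \eqn{h = 0.8} corresponds to \eqn{R = 4.75}.
#'
#' @param R Basic reproduction number (> 1).
#' @return Steepness h.
#' @export
#' @examples
#' steepness_closed_form(6)     # 1
#' steepness_closed_form(4.75)  # 0.8
steepness_closed_form <- function(R) {
  if (any(R <= 1)) stop("R must be > 1")
  (1 + 4 * R) / 25
}

#' Stock-recruitment curve for a stock feeding on multiple resources
#'
#' Dimensionless analogue of \code{\link{trace_curve}} for a consumer with
#' attack-rate column \code{H_col} over several resources.  With fishing
#' mortality F the equilibrium consumer biomass is
#' \eqn{B_C = (\sum_j H_j - 1 - F/\rho)/\sum_j H_j^2}, the spawning stock
#' biomass is \eqn{SSB = B_C} and recruitment \eqn{Rec = (\rho + F) B_C}.
#' The resulting steepness equals \eqn{(1 + 4\sum_j H_j)/25}.
#'
#' The unfished equilibrium must leave every resource extant; a column in
#' the apparent-competition regime (main resource driven negative) is
#' rejected with an error instructing prior removal of that resource.
#'
#' @param H_col Positive dimensionless attack-rate column with sum > 1.
#' @param params An \code{\link{lv_params}} object (supplies \code{rho}).
#' @param F_grid Fishing mortalities; defaults to 201 values spanning 0 to
#'   the extinction boundary \eqn{F = \rho(\sum_j H_j - 1)}.
#' @return An \code{sr_curve} object (see \code{\link{trace_curve}}).
#' @export
multi_resource_curve <- function(H_col, params = lv_params(), F_grid = NULL) {
  R <- sum(H_col)
  if (R <= 1) stop("column sum <= 1: no viable unfished stock")
  Q <- sum(H_col^2)
  B_C0 <- (R - 1) / Q
  if (any(1 - H_col * B_C0 <= 0))
    stop("resource(s) driven extinct at the unfished equilibrium ",
         "(apparent-competition regime); remove the offending resource(s) first")
  rho <- params$rho
  if (is.null(F_grid)) F_grid <- seq(0, rho * (R - 1), length.out = 201L)
  B_C <- (R - 1 - F_grid / rho) / Q
  out <- data.frame(F = F_grid, SSB = B_C, Rec = (rho + F_grid) * B_C)
  structure(out, class = c("sr_curve", "data.frame"),
            SSB0 = B_C0, R = R, params = list(rho = rho, H_col = H_col))
}
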