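#' Invasibility criterion
#'
#' A consumer with dimensionless attack coefficients \code{H_col} can
#' persist only if its basic reproduction number exceeds one:
#' \eqn{\sum_j H_{jk} - 1 > 0} (strict).  An empty column returns
#' \code{FALSE}: with no resources the consumer starves.
#'
#' @param H_col Numeric vector of positive dimensionless attack rates of
#'   one consumer on the extant resources.
#' @return Logical scalar.
#' @export
#' @examples
#' invasibility(c(0.6, 0.6))  # TRUE  (sum 1.2)
#' invasibility(c(0.5, 0.5))  # FALSE (boundary is excluded)
invasibility <- function(H_col) {
  if (length(H_col) == 0L) return(FALSE)
  sum(H_col) - 1 > 0
}

#' Exploitative competitive exclusion of one consumer by another
#'
#' Tests whether a focal consumer \code{k} is excluded through exploitative
#' competition with a resident \code{l}.  With
#' \eqn{A = \sum_j H_{jl} - 1}, \eqn{B = \sum_j H_{jl}^2},
#' \eqn{C = \sum_j H_{jk} - 1} and \eqn{D = \sum_j H_{jk} H_{jl}},
#' exclusion occurs iff \eqn{C < D A / B}; equivalently, \code{k}'s growth
#' rate at \code{l}'s single-consumer equilibrium is negative.
#'
#' @param H_k,H_l Attack-rate columns of the focal consumer and the
#'   resident over the same resource set.  The resident must itself satisfy
#'   the invasibility criterion, otherwise the condition is undefined.
#' @return Logical scalar: \code{TRUE} if \code{k} is excluded by \code{l}.
#' @export
#' @examples
#' exploitative_exclusion(c(0.6, 0.6), c(2, 1e-9))  # TRUE: 0.2 < 0.3
exploitative_exclusion <- function(H_k, H_l) {
  if (length(H_k) != length(H_l))
    stop("H_k and H_l must cover the same resource set")
  A <- sum(H_l) - 1
  if (A <= 0)
    stop("resident l fails the invasibility criterion; exclusion condition undefined")
  B <- sum(H_l^2)
  C <- sum(H_k) - 1
  D <- sum(H_k * H_l)
  C < D * A / B
}

#' Resources overexploited during an invader's boom phase
#'
#' When a consumer invades at the biomass floor \code{Mmin} and booms to
#' its equilibrium, resources it attacks very strongly crash below the
#' floor before the boom saturates.  The deconstructed formulation removes
#' resource \eqn{j} when \eqn{H_{jk} > -\ln M_{min}} (natural logarithm:
#' the boom-phase resource crash is an exponential decay in natural time).
#' For \code{Mmin = 1e-5} the threshold is about 11.513.
#'
#' @param H_col Attack-rate column of the invading consumer.
#' @param Mmin Extirpation threshold on dimensionless biomass, in (0, 1).
#' @return Integer indices (into \code{H_col}) of overexploited resources.
#' @export
boom_prune <- function(H_col, Mmin) {
  if (Mmin <= 0 || Mmin >= 1) stop("Mmin must be in (0, 1)")
  which(H_col > -log(Mmin))
}

#' Consumer-mediated ("apparent") extirpation of a main resource
#'
#' At a single consumer's linear equilibrium, \eqn{B_C = (\sum_j H_{jk} -
#' 1)/\sum_j H_{jk}^2}, the most-attacked ("main") resource has biomass
#' \eqn{1 - \max_j H_{jk} \, B_C}.  This is negative — i.e. the consumer
#' extirpates its own main resource through apparent competition — iff
#' \eqn{\sum_j H_{jk} - 1 > \sum_j H_{jk}^2 / \max_j H_{jk}}.
#'
#' @param H_col Attack-rate column of a consumer satisfying the
#'   invasibility criterion.
#' @return List with \code{extirpates} (logical) and \code{main} (index of
#'   the main resource; ties broken towards the lowest index).
#' @export
#' @examples
#' apparent_extirpation(c(3, 1.5, 1.5))  # TRUE, main = 1
apparent_extirpation <- function(H_col) {
  C <- sum(H_col) - 1
  if (C <= 0)
    stop("column fails the invasibility criterion; condition undefined")
  main <- which.max(H_col)  # which.max takes the first maximum: lowest id
  list(extirpates = C > sum(H_col^2) / H_col[main], main = main)
}

#' Pyrrhic competition between two consumers
#'
#' At the joint two-consumer equilibrium, competition between consumers
#' \code{k} and \code{l} can be resolved not by excluding a consumer but by
#' extirpating \code{k}'s main resource \eqn{i}.  With
#' \eqn{B_k = \sum_j H_{jk}^2}, \eqn{B_l = \sum_j H_{jl}^2},
#' \eqn{D = \sum_j H_{jk} H_{jl}}, \eqn{C = \sum_j H_{jk} - 1} and
#' \eqn{A = \sum_j H_{jl} - 1}, the main resource's joint-equilibrium
#' biomass is negative iff
#' \deqn{B_k B_l - D^2 < C (H_{ik} B_l - H_{il} D) + A (H_{il} B_k - H_{ik} D).}
#' The condition requires a feasible joint equilibrium,
#' \eqn{B_k B_l - D^2 > 0}; for an infeasible pair the function errors
#' (the assembly algorithm treats such pairs as resolved by exploitative
#' competition instead).
#'
#' @param H_k,H_l Attack-rate columns over the same resource set; both must
#'   satisfy the invasibility criterion.
#' @return Logical scalar: \code{TRUE} if the pair extirpates \code{k}'s
#'   main resource.
#' @export
#' @examples
#' pyrrhic_competition(c(6, 2, 1), c(4, 1, 5))  # TRUE: 761 < 826
pyrrhic_competition <- function(H_k, H_l) {
  if (length(H_k) != length(H_l))
    stop("H_k and H_l must cover the same resource set")
  C <- sum(H_k) - 1
  A <- sum(H_l) - 1
  if (C <= 0 || A <= 0)
    stop("both consumers must satisfy the invasibility criterion")
  Bk <- sum(H_k^2)
  Bl <- sum(H_l^2)
  D <- sum(H_k * H_l)
  lhs <- Bk * Bl - D^2
  if (lhs <= 0)
    stop("infeasible joint equilibrium (B_k B_l <= D^2); condition undefined")
  i <- which.max(H_k)
  rhs <- C * (H_k[i] * Bl - H_l[i] * D) + A * (H_l[i] * Bk - H_k[i] * D)
  lhs < rhs
}

#' The four terms of the exploitative-exclusion condition
#'
#' Decomposes the pairwise exclusion condition into its named terms:
#' the resident's growth term \eqn{A = \sum_j H_{jl} - 1}, the resident's
#' intraspecific competition term \eqn{B = \sum_j H_{jl}^2}, the focal
#' consumer's growth term \eqn{C = \sum_j H_{jk} - 1} and the
#' interspecific competition term \eqn{D = \sum_j H_{jk} H_{jl}}.
#' The focal consumer is excluded iff
#' \eqn{\log_{10} C - \log_{10} D - \log_{10} A + \log_{10} B < 0}.
#'
#' @param H_k,H_l Attack-rate columns over the same resource set.
#' @return List with \code{A}, \code{B}, \code{C}, \code{D}, the
#'   log-scale left-hand side \code{lhs} (set to \code{NA} with
#'   \code{lhs_defined = FALSE} when \code{A} or \code{C} is non-positive)
#'   and \code{R_k = C + 1}.
#' @export
competition_terms <- function(H_k, H_l) {
  if (length(H_k) != length(H_l))
    stop("H_k and H_l must cover the same resource set")
  A <- sum(H_l) - 1
  B <- sum(H_l^2)
  C <- sum(H_k) - 1
  D <- sum(H_k * H_l)
  defined <- A > 0 && C > 0 && B > 0 && D > 0
  lhs <- if (defined) log10(C) - log10(D) - log10(A) + log10(B) else NA_real_
  list(A = A, B = B, C = C, D = D, R_k = C + 1,
       lhs = lhs, lhs_defined = defined)
}
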