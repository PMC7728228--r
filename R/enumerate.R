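#' Exact Maximum Caliber path distribution by enumeration
#'
#' Evaluates the Maximum Caliber trajectory distribution
#' \eqn{P_\Gamma = Z^{-1} \exp[\sum_{i,t} (h_i(t) + \frac{1}{2} \sum_{j,s}
#' K_{ij}(t,s) v_j(s)) v_i(t)]} by brute-force summation over all
#' \eqn{2^{NT}} spin trajectories.  This is the oracle every approximation in
#' the package is tested against; it is only feasible for small systems
#' (\eqn{NT \le 20}).
#'
#' @param mult a time-resolved [multiplier_set()] (spin convention: zero
#'   coupling diagonal).
#' @param N,T optional dimension checks against \code{mult}.
#'
#' @return A list of class \code{maxcal_path_distribution}: \code{states}
#'   (\eqn{2^{NT} \times NT} matrix of spin trajectories, site index
#'   node-fastest), \code{p} (probabilities, summing to one), \code{logZ}.
#' @export
exact_path_distribution <- function(mult, N = mult$N, T = mult$T) {
  stopifnot(inherits(mult, "maxcal_multipliers"), !mult$stationary)
  if (N != mult$N || T != mult$T) stop("dimension mismatch")
  n <- N * T
  if (n > 20L) stop("system too large for exact oracle")
  states <- spin_states(n)
  h <- as.vector(mult$h)
  E <- as.vector(states %*% h) +
    0.5 * rowSums((states %*% mult$K) * states)
  logZ <- logsumexp(E)
  structure(list(states = states, p = exp(E - logZ), logZ = logZ,
                 N = N, T = T),
            class = "maxcal_path_distribution")
}

#' Moments of an enumerated path distribution
#'
#' @param pd a \code{maxcal_path_distribution}.
#' @return A [constraint_set()] with the exact \eqn{M_i(t)} and
#'   \eqn{\chi_{ij}(t,s)}.
#' @export
path_moments <- function(pd) {
  stopifnot(inherits(pd, "maxcal_path_distribution"))
  M <- as.vector(crossprod(pd$states, pd$p))
  chi <- crossprod(pd$states, pd$states * pd$p)
  chi <- (chi + t(chi)) / 2
  constraint_set(matrix(M, nrow = pd$N), chi, alphabet = "spin")
}

#' Exact inverse Maximum Caliber on enumerable systems
#'
#' Recovers the Lagrange multipliers \eqn{(h, K)} whose Maximum Caliber
#' distribution reproduces a given set of constraints, by convex
#' moment-matching over the enumerated trajectory space.  The gradient of the
#' dual objective is (model moments - target moments); convergence is declared
#' when the largest moment residual falls below \code{tol}.  Gauge: the
#' self-coupling at zero lag, \eqn{K_{ii}(t,t)}, is fixed to zero (for spins
#' \eqn{v^2 = 1} makes it degenerate with the normalizer).
#'
#' @param cons a time-resolved \code{maxcal_constraints} derived from a
#'   realizable spin distribution.
#' @param N,T optional dimension checks.
#' @param tol maximum moment residual accepted.
#' @return A [multiplier_set()] with \code{flavor = "exact"}.
#' @export
exact_inverse_maxcal <- function(cons, N = cons$N, T = cons$T, tol = 1e-10) {
  stopifnot(inherits(cons, "maxcal_constraints"), !cons$stationary)
  if (N != cons$N || T != cons$T) stop("dimension mismatch")
  n <- N * T
  if (n > 20L) stop("system too large for exact oracle")
  states <- spin_states(n)
  pf <- pair_feature_matrix(states)
  target <- c(as.vector(cons$M), cons$chi[pf$pairs])
  fit <- fit_moment_match(pf$F, target, tol = tol)
  if (!fit$converged || fit$residual > sqrt(tol))
    stop(sprintf("infeasible constraints (moment residual %.3g)",
                 fit$residual))
  if (max(abs(fit$theta)) > 10)
    stop("infeasible constraints (boundary moments: multipliers diverge)")
  h <- matrix(fit$theta[seq_len(n)], nrow = N)
  K <- matrix(0, n, n)
  K[pf$pairs] <- fit$theta[-seq_len(n)]
  K <- K + t(K)
  multiplier_set(h, K, flavor = "exact", logZ = fit$logZ, nodes = cons$nodes)
}
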