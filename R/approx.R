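#' Uncoupled (factorized) Maximum Caliber fit
#'
#' Fits the Uncoupled Approximation: the trajectory distribution is
#' factorized over nodes, all cross-couplings are forced to zero, and each
#' node's effective multipliers \eqn{(\tilde h_i(t), \tilde K_{ii}(t,s))} are
#' chosen so that the single-node Maximum Caliber distribution reproduces that
#' node's own constraints \eqn{M_i(t)} and \eqn{\chi_{ii}(t,s)} (the
#' forward-KL optimum: the factorized moments match the true one-body
#' moments exactly).  The neglected interactions are thereby absorbed into
#' the effective fields.
#'
#' For time-resolved constraints each node is an enumerable \eqn{T}-spin
#' problem; for stationary constraints each node is a \eqn{(\tau_{max}+1)}-spin
#' window problem with a uniform bias and lag couplings \eqn{\tilde
#' K_{ii}(\tau)} (with the defaults of the neural application,
#' \eqn{\tau_{max} = 3}, a 4-spin Ising model), solved exactly by enumeration.
#'
#' @param cons a \code{maxcal_constraints} (spin alphabet).
#' @param tol moment-residual tolerance of the per-node fit.
#' @return A [multiplier_set()] with \code{flavor = "uncoupled"}.
#' @export
fit_uncoupled <- function(cons, tol = 1e-10) {
  stopifnot(inherits(cons, "maxcal_constraints"))
  if (cons$stationary) {
    W <- cons$tau_max + 1L
    N <- cons$N
    h <- numeric(N)
    K <- array(0, dim = c(N, N, W))
    for (i in seq_len(N)) {
      sol <- solve_stationary_window(cons$M[i], cons$chi[i, i, ], tol = tol,
                                     label = cons$nodes[i])
      h[i] <- sol$h
      if (W > 1L) K[i, i, 2:W] <- sol$K_lag
    }
    multiplier_set(h, K, flavor = "uncoupled", nodes = cons$nodes, window = W)
  } else {
    N <- cons$N; T <- cons$T
    if (T > 20L) stop("system too large for exact oracle")
    states <- spin_states(T)
    pf <- pair_feature_matrix(states)
    h <- matrix(0, N, T)
    K <- matrix(0, N * T, N * T)
    for (i in seq_len(N)) {
      sites <- site_index(i, seq_len(T), N)
      target <- c(cons$M[i, ], cons$chi[sites, sites][pf$pairs])
      fit <- fit_moment_match(pf$F, target, tol = tol)
      if (!fit$converged || fit$residual > sqrt(tol))
        stop(sprintf("infeasible constraints for node %s (residual %.3g)",
                     cons$nodes[i], fit$residual))
      h[i, ] <- fit$theta[seq_len(T)]
      Ki <- matrix(0, T, T)
      Ki[pf$pairs] <- fit$theta[-seq_len(T)]
      K[sites, sites] <- Ki + t(Ki)
    }
    multiplier_set(h, K, flavor = "uncoupled", nodes = cons$nodes)
  }
}

# Exact solution of the stationary single-node window problem: W consecutive
# spins with uniform bias h and lag couplings K(tau); sufficient statistics
# are sum_t v_t and sum over lag-tau pairs of v_t v_{t+tau}; targets are W*M
# and (W - tau) * chi(tau).
solve_stationary_window <- function(M, chi_lag, tol = 1e-10, label = "?") {
  W <- length(chi_lag)                  # chi_lag[tau + 1], tau = 0..W-1
  states <- spin_states(W)
  Fh <- rowSums(states)
  Flag <- vapply(seq_len(W - 1L), function(tau) {
    idx <- seq_len(W - tau)
    rowSums(states[, idx, drop = FALSE] * states[, idx + tau, drop = FALSE])
  }, numeric(nrow(states)))
  Fmat <- cbind(Fh, Flag)
  target <- c(W * M, (W - seq_len(W - 1L)) * chi_lag[-1])
  fit <- fit_moment_match(Fmat, target, tol = tol)
  if (!fit$converged || fit$residual > sqrt(tol))
    stop(sprintf("infeasible constraints for node %s (residual %.3g)",
                 label, fit$residual))
  list(h = fit$theta[1], K_lag = fit$theta[-1], logZ = fit$logZ)
}

#' Linear Coupling estimate of the cross-couplings
#'
#' Linear-response inversion: the cross-couplings are estimated as the
#' negated off-diagonal (node \eqn{i \ne j}) entries of the inverse covariance
#' matrix, \eqn{K'_{ij}(t,s) = -(C^{-1})_{ij}(t,s)}.  Within-node (\eqn{i =
#' j}) entries are \emph{not} taken from \eqn{C^{-1}}; they come from the
#' Uncoupled fit.
#'
#' For stationary constraints the covariance is assembled as an
#' \eqn{(NW) \times (NW)} block-Toeplitz matrix over a window of
#' \eqn{W = \tau_{max} + 1} time slices, inverted, and coupling estimates at
#' equal \eqn{|\tau|} are averaged and symmetrized in \eqn{(i, j)}.
#'
#' @param cons a \code{maxcal_constraints}.
#' @param rcond_min reciprocal-condition-number threshold below which the
#'   covariance is declared non-invertible.
#' @param ridge optional nonnegative ridge added to the diagonal of the
#'   covariance before inversion (off by default; recorded in the result's
#'   attributes when used).
#' @param margin stationary form only: number of window-edge time slices
#'   excluded when averaging the inverse-covariance blocks (central-block
#'   readout).  The default 0 averages over all equal-lag blocks; a positive
#'   margin discards edge blocks, whose entries are distorted by the window
#'   truncation of out-of-window correlations.
#' @return Time-resolved form: an \eqn{(NT) \times (NT)} matrix with
#'   within-node blocks zero.  Stationary form: an array
#'   \code{c(N, N, tau_max + 1)} with zero node-diagonals.
#' @export
linear_coupling_K <- function(cons, rcond_min = 1e-10, ridge = 0,
                              margin = 0L) {
  stopifnot(inherits(cons, "maxcal_constraints"))
  if (cons$stationary) {
    N <- cons$N; W <- cons$tau_max + 1L
    Cbig <- assemble_block_covariance(cons$C, N, W)
  } else {
    N <- cons$N; W <- cons$T
    Cbig <- cons$C
  }
  if (ridge > 0) Cbig <- Cbig + diag(ridge, nrow(Cbig))
  rc <- rcond(Cbig)
  if (!is.finite(rc) || rc < rcond_min)
    stop("covariance not invertible; more samples or regularization required")
  Cinv <- solve(Cbig)
  if (!cons$stationary) {
    Kp <- -Cinv
    for (i in seq_len(N)) {
      sites <- site_index(i, seq_len(W), N)
      Kp[sites, sites] <- 0
    }
    Kp <- (Kp + t(Kp)) / 2
    attr(Kp, "ridge") <- ridge
    attr(Kp, "window") <- W
    return(Kp)
  }
  Kp <- array(0, dim = c(N, N, W))
  for (tau in 0:(W - 1L)) {
    marg <- min(margin, (W - tau - 1L) %/% 2L)   # keep >= 1 block per lag
    ws <- (1L + marg):(W - tau - marg)
    acc <- matrix(0, N, N)
    for (w in ws) {
      rows <- site_index(seq_len(N), w + tau, N)
      cols <- site_index(seq_len(N), w, N)
      acc <- acc - Cinv[rows, cols]
    }
    blk <- acc / length(ws)
    blk <- (blk + t(blk)) / 2        # K_ij(tau) = K_ji(tau), per tau = |t-s|
    diag(blk) <- 0
    Kp[, , tau + 1L] <- blk
  }
  attr(Kp, "ridge") <- ridge
  attr(Kp, "window") <- W
  Kp
}

# Block-Toeplitz covariance over a window of W time slices: block (w, w') is
# C(w - w'), with C(-tau) = t(C(tau)).
assemble_block_covariance <- function(C_lag, N, W) {
  big <- matrix(0, N * W, N * W)
  for (w in seq_len(W)) for (wp in seq_len(W)) {
    tau <- w - wp
    blk <- if (tau >= 0) C_lag[, , tau + 1L] else t(C_lag[, , -tau + 1L])
    big[site_index(seq_len(N), w, N), site_index(seq_len(N), wp, N)] <- blk
  }
  (big + t(big)) / 2
}

#' Mean-field reconstruction of the biases
#'
#' Combines an Uncoupled fit with Linear Coupling cross-coupling estimates to
#' reconstruct the full multiplier set: \eqn{h'_i(t) = \tilde h_i(t) -
#' \sum_{j \ne i} \sum_s K'_{ij}(t,s) M_j(s)}, \eqn{K'_{ii} = \tilde K_{ii}},
#' and \eqn{K'_{ij}} as supplied.  Computed in one pass from the empirical
#' means (no self-consistent iteration).  For stationary systems the sum over
#' \eqn{s} runs over both past and future lags:
#' \eqn{h'_i = \tilde h_i - \sum_{j\ne i} [K'_{ij}(0) + 2\sum_{\tau \ge 1}
#' K'_{ij}(\tau)] M_j}.
#'
#' @param uncoupled a \code{maxcal_multipliers} with
#'   \code{flavor = "uncoupled"}.
#' @param Kprime cross-couplings from [linear_coupling_K()] (matching form).
#' @param M means: an \eqn{N \times T} matrix, or length-N vector for the
#'   stationary form.
#' @return A [multiplier_set()] with \code{flavor = "linear_coupling"}.
#' @export
mean_field_h <- function(uncoupled, Kprime, M) {
  stopifnot(inherits(uncoupled, "maxcal_multipliers"))
  if (uncoupled$flavor != "uncoupled")
    stop("`uncoupled` must have flavor 'uncoupled'")
  if (uncoupled$stationary) {
    stopifnot(length(dim(Kprime)) == 3L, is.numeric(M),
              length(M) == uncoupled$N)
    N <- uncoupled$N; W <- dim(Kprime)[3]
    Ksum <- Kprime[, , 1]
    if (W > 1L) for (l in 2:W) Ksum <- Ksum + 2 * Kprime[, , l]
    diag(Ksum) <- 0
    h <- uncoupled$h - as.vector(Ksum %*% M)
    K <- Kprime
    for (l in seq_len(W)) diag(K[, , l]) <- diag(uncoupled$K[, , l])
    multiplier_set(h, K, flavor = "linear_coupling", nodes = uncoupled$nodes,
                   window = uncoupled$window)
  } else {
    stopifnot(is.matrix(Kprime), is.matrix(M))
    N <- uncoupled$N; T <- uncoupled$T
    stopifnot(nrow(Kprime) == N * T, nrow(M) == N, ncol(M) == T)
    h <- uncoupled$h - matrix(Kprime %*% as.vector(M), N, T)
    K <- Kprime + uncoupled$K
    multiplier_set(h, K, flavor = "linear_coupling", nodes = uncoupled$nodes)
  }
}

#' Full Linear Coupling inference pipeline
#'
#' Convenience wrapper: [fit_uncoupled()] then [linear_coupling_K()] then
#' [mean_field_h()].
#'
#' @inheritParams linear_coupling_K
#' @param tol per-node moment tolerance for the Uncoupled stage.
#' @return A [multiplier_set()] with \code{flavor = "linear_coupling"}.
#' @export
fit_linear_coupling <- function(cons, tol = 1e-10, rcond_min = 1e-10,
                                ridge = 0) {
  unc <- fit_uncoupled(cons, tol = tol)
  Kp <- linear_coupling_K(cons, rcond_min = rcond_min, ridge = ridge)
  mean_field_h(unc, Kp, cons$M)
}
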