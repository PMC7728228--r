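#' Synthetic neural-network ground truth
#'
#' Generates the ground-truth multipliers of the dynamic Ising neural
#' network: uniform bias \eqn{h_i = h_0} (negative: neurons tend to silence),
#' heterogeneous pair couplings \eqn{K_{ij}(\tau) \sim
#' \mathcal{N}(K_0 a^{-\tau}, (K_\delta a^{-\tau})^2)} drawn once per
#' unordered pair per lag and assigned symmetrically, strong self-couplings
#' \eqn{K_{ii}(\tau) = 20 K_0 a^{-\tau}} for \eqn{\tau \ge 1} with
#' \eqn{K_{ii}(0) = 0}, and couplings truncated beyond \eqn{\tau_{max}}.
#' All multipliers are scaled by the inverse temperature \eqn{\beta}.  With
#' the defaults the network sits near a critical point where weak pairwise
#' correlations (about 0.02 on average) occasionally sum into avalanches of
#' activity.
#'
#' @param N neuron count.
#' @param h0 uniform bias.
#' @param K0 coupling mean scale.
#' @param K_delta coupling standard-deviation scale (default equal to
#'   \code{K0}).
#' @param a lag decay base (> 1).
#' @param tau_max coupling range; couplings at larger lags are zero.
#' @param self_factor self-coupling multiple of \code{K0}.
#' @param beta inverse-temperature scale applied to all multipliers.
#' @param seed RNG seed.
#' @return A stationary [multiplier_set()] with \code{flavor = "exact"}.
#' @export
neural_ground_truth <- function(N = 40L, h0 = -0.1, K0 = 0.015,
                                K_delta = K0, a = 4, tau_max = 3L,
                                self_factor = 20, beta = 1, seed = 1L) {
  stopifnot(N >= 2L, a > 1, tau_max >= 1L, beta >= 0)
  set.seed(seed)
  K <- array(0, dim = c(N, N, tau_max + 1L))
  up <- upper.tri(matrix(0, N, N))
  npair <- sum(up)
  for (tau in 0:tau_max) {
    sc <- a^(-tau)
    slice <- matrix(0, N, N)
    slice[up] <- stats::rnorm(npair, mean = K0 * sc, sd = K_delta * sc)
    slice <- slice + t(slice)
    if (tau >= 1L) diag(slice) <- self_factor * K0 * sc
    K[, , tau + 1L] <- slice
  }
  multiplier_set(rep(h0, N) * beta, K * beta, flavor = "exact",
                 nodes = paste0("neuron", seq_len(N)))
}

#' Scale all multipliers by an inverse temperature
#'
#' \eqn{h \to \beta h}, \eqn{K \to \beta K}: modulates the overall
#' interaction strength of a model.
#'
#' @param mult a [multiplier_set()].
#' @param beta positive scale.
#' @return A rescaled \code{maxcal_multipliers} of the same flavor.
#' @export
scale_multipliers <- function(mult, beta) {
  stopifnot(inherits(mult, "maxcal_multipliers"), beta >= 0)
  out <- mult
  out$h <- mult$h * beta
  out$K <- mult$K * beta
  out
}

#' Space-time Metropolis sampling of a stationary spin model
#'
#' Samples whole spin trajectories \eqn{\{v_i(t)\}} from the Maximum Caliber
#' distribution of a stationary multiplier set by single-site Metropolis
#' flips on the space-time lattice.  One sweep attempts \eqn{N T} flips at
#' uniformly random sites.  After a burn-in, every \code{thin}-th sweep's
#' configuration is retained as one (approximately decorrelated) sample of
#' the ensemble.  Reproducible by seed.
#'
#' @param mult a stationary [multiplier_set()] (any flavor).
#' @param T trajectory length in time steps; must exceed the coupling range.
#' @param n_keep retained configurations.
#' @param burn_sweeps discarded initial sweeps.
#' @param thin sweeps between retained configurations.
#' @param seed RNG seed.
#' @param init optional initial N x T spin matrix (default: all silent, -1).
#' @return A [trajectory_ensemble()] (spin alphabet) with \code{n_keep}
#'   samples.
#' @export
sample_network <- function(mult, T = 256L, n_keep = 100L, burn_sweeps = 200L,
                           thin = 2L, seed = 1L, init = NULL) {
  stopifnot(inherits(mult, "maxcal_multipliers"), mult$stationary)
  N <- mult$N
  tau_max <- dim(mult$K)[3] - 1L
  if (T <= tau_max) stop("T must exceed the coupling range")
  if (is.null(init)) init <- matrix(-1L, N, T)
  stopifnot(nrow(init) == N, ncol(init) == T)
  set.seed(seed)
  arr <- mcmc_spin_lattice(as.numeric(mult$h), as.numeric(mult$K),
                           as.integer(N), as.integer(T), as.integer(tau_max),
                           as.integer(n_keep), as.integer(burn_sweeps),
                           as.integer(thin), as.integer(init))
  dim(arr) <- c(N, T, n_keep)
  trajectory_ensemble(aperm(arr, c(3, 1, 2)), alphabet = "spin",
                      nodes = mult$nodes)
}

#' Mean pairwise equal-time correlation
#'
#' Average over all neuron pairs of the Pearson correlation between
#' \eqn{v_i(t)} and \eqn{v_j(t)}, pooling retained configurations and time
#' points.
#'
#' @param ens a spin [trajectory_ensemble()].
#' @return A single number.
#' @export
mean_pairwise_correlation <- function(ens) {
  stopifnot(inherits(ens, "maxcal_ensemble"), ens$alphabet == "spin")
  N <- ens$n_nodes
  # N x (samples * times) observation matrix
  x <- matrix(aperm(ens$values, c(2, 1, 3)), nrow = N)
  cc <- stats::cor(t(x))
  mean(cc[upper.tri(cc)])
}

#' Exact Uncoupled solution for one neuron
#'
#' Solves the stationary single-neuron window problem: a
#' \eqn{(\tau_{max}+1)}-spin Ising chain (4 spins with the default lag range)
#' with uniform bias \eqn{\tilde h_i} and lag couplings
#' \eqn{\tilde K_{ii}(\tau)} matching the neuron's mean and autocorrelations,
#' by exact enumeration inside the exponential-family fit.
#'
#' @param M stationary mean activity of the neuron.
#' @param chi_auto autocorrelations \eqn{\chi_{ii}(\tau)} for \eqn{\tau = 0
#'   \ldots \tau_{max}} (the \eqn{\tau = 0} entry is 1 for spins).
#' @param tol moment residual tolerance.
#' @return list with \code{h} and \code{K_lag} (\eqn{\tau = 1 \ldots
#'   \tau_{max}}).
#' @export
solve_uncoupled_neuron <- function(M, chi_auto, tol = 1e-10) {
  solve_stationary_window(M, chi_auto, tol = tol)
}

#' Linear Coupling inference of a stationary network
#'
#' Full reconstruction of a stationary network model from constraints:
#' per-node Uncoupled solves for biases and self-couplings (the
#' \eqn{(\tau_{max}+1)}-spin window problems), linear-response inversion of
#' the block-lag covariance for the cross-couplings, and the mean-field bias
#' correction.  Couplings beyond \code{coupling_range} are zero by
#' construction.
#'
#' When the supplied constraints carry more lags than \code{coupling_range},
#' the covariance inversion uses the full available window with
#' central-block readout (edge blocks dropped) and only couplings up to
#' \code{coupling_range} are retained.  Inverting a window barely wider than
#' the coupling range folds the out-of-window correlations (which a coupled
#' chain always has) into the retained couplings, inflating them slightly;
#' the wider window with central readout suppresses this truncation bias.
#'
#' @param cons stationary \code{maxcal_constraints} with lags
#'   \eqn{0 \ldots \tau_{max}} (use more lags than \code{coupling_range} to
#'   enable the wide-window inversion).
#' @param coupling_range largest lag of retained couplings (default: all lags
#'   present in \code{cons}).
#' @param ... passed to [linear_coupling_K()] (e.g. \code{ridge},
#'   \code{rcond_min}).
#' @return A [multiplier_set()] with \code{flavor = "linear_coupling"} and
#'   \code{coupling_range + 1} lag slices.
#' @export
infer_network <- function(cons, coupling_range = NULL, ...) {
  stopifnot(inherits(cons, "maxcal_constraints"), cons$stationary)
  if (is.null(coupling_range)) coupling_range <- cons$tau_max
  stopifnot(coupling_range <= cons$tau_max)
  cons_short <- truncate_constraints(cons, coupling_range)
  unc <- fit_uncoupled(cons_short)
  W <- cons$tau_max + 1L
  margin <- max(0L, (W - (coupling_range + 1L)) %/% 2L)
  Kp <- linear_coupling_K(cons, margin = margin, ...)
  Kp_short <- Kp[, , seq_len(coupling_range + 1L), drop = FALSE]
  mean_field_h(unc, Kp_short, cons$M)
}

# restrict a stationary constraint set to lags 0..tau_max
truncate_constraints <- function(cons, tau_max) {
  stopifnot(cons$stationary, tau_max <= cons$tau_max)
  out <- constraint_set(cons$M, cons$chi[, , seq_len(tau_max + 1L), drop = FALSE],
                        nodes = cons$nodes, alphabet = cons$alphabet)
  out$n_obs <- cons$n_obs
  out
}

#' Neural synchrony analysis
#'
#' Computes the population-averaged activity \eqn{s(t) = \sum_i v_i(t) / N}
#' for every retained configuration, its histogram over the natural discrete
#' support (multiples of \eqn{2/N}), the mean and variance of \eqn{s}, and
#' the spike frequency \eqn{P(s > 0)}.
#'
#' @param ens a spin [trajectory_ensemble()].
#' @return An object of class \code{maxcal_synchrony}: list with \code{s}
#'   (samples x times matrix), \code{support}, \code{pmf}, \code{mean_s},
#'   \code{var_s}, \code{p_spike}.
#' @export
synchrony_analysis <- function(ens) {
  stopifnot(inherits(ens, "maxcal_ensemble"), ens$alphabet == "spin")
  N <- ens$n_nodes
  s <- apply(ens$values, c(1, 3), sum) / N
  support <- seq(-1, 1, by = 2 / N)
  counts <- tabulate(match(round(s * N), round(support * N)),
                     nbins = length(support))
  structure(list(s = s, support = support, pmf = counts / sum(counts),
                 mean_s = mean(s), var_s = stats::var(as.vector(s)),
                 p_spike = mean(s > 0), N = N),
            class = "maxcal_synchrony")
}

#' @export
print.maxcal_synchrony <- function(x, ...) {
  cat(sprintf("<maxcal_synchrony> mean(s) = %.4f, Var(s) = %.5f, P(s > 0) = %.4f\n",
              x$mean_s, x$var_s, x$p_spike))
  invisible(x)
}

#' Inverse-temperature sweep of model fidelity
#'
#' For each \eqn{\beta}: scale the ground truth, sample it, infer both the
#' Uncoupled and Linear Coupling models from the sampled constraints,
#' re-simulate each inferred model, and record synchrony statistics.  All
#' models are expected to match the mean synchrony; only the Linearly
#' Coupled model tracks the variance (the avalanche fluctuations).
#'
#' @param truth a stationary ground-truth [multiplier_set()] (at
#'   \eqn{\beta = 1}).
#' @param betas inverse temperatures to visit.
#' @param T,n_keep,burn_sweeps,thin sampling controls per model (see
#'   [sample_network()]).
#' @param seed base RNG seed; each (beta, model) stage derives its own.
#' @return A data.frame with columns \code{beta}, \code{model}
#'   (\code{"truth"}, \code{"uncoupled"}, \code{"linear"}), \code{mean_s},
#'   \code{var_s}, \code{p_spike}.
#' @export
beta_sweep <- function(truth, betas = c(0.5, 0.75, 1.0), T = 256L,
                       n_keep = 100L, burn_sweeps = 200L, thin = 2L,
                       seed = 1L) {
  stopifnot(inherits(truth, "maxcal_multipliers"), truth$stationary)
  tau_max <- dim(truth$K)[3] - 1L
  rows <- list()
  for (k in seq_along(betas)) {
    beta <- betas[k]
    gt <- scale_multipliers(truth, beta)
    ens <- sample_network(gt, T = T, n_keep = n_keep,
                          burn_sweeps = burn_sweeps, thin = thin,
                          seed = seed + 101L * k)
    cons <- empirical_constraints(ens, stationary = TRUE,
                                  tau_max = 2L * (tau_max + 1L) - 1L)
    unc <- fit_uncoupled(truncate_constraints(cons, tau_max))
    lin <- infer_network(cons, coupling_range = tau_max)
    sims <- list(truth = ens,
                 uncoupled = sample_network(unc, T = T, n_keep = n_keep,
                                            burn_sweeps = burn_sweeps,
                                            thin = thin,
                                            seed = seed + 101L * k + 1L),
                 linear = sample_network(lin, T = T, n_keep = n_keep,
                                         burn_sweeps = burn_sweeps,
                                         thin = thin,
                                         seed = seed + 101L * k + 2L))
    for (m in names(sims)) {
      sy <- synchrony_analysis(sims[[m]])
      rows[[length(rows) + 1L]] <-
        data.frame(beta = beta, model = m, mean_s = sy$mean_s,
                   var_s = sy$var_s, p_spike = sy$p_spike)
    }
  }
  do.call(rbind, rows)
}
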