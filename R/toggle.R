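#' Toggle switch model parameters
#'
#' Maximum Caliber model of the two-gene genetic toggle switch (mutual
#' repression).  Per short interval \eqn{\delta t}, each gene may produce at
#' most one new protein (\eqn{l_\alpha, l_\beta \in \{0,1\}}) and each
#' existing protein independently survives or degrades (\eqn{l_A \le N_A},
#' \eqn{l_B \le N_B} survivors, with binomial multiplicity).  The step
#' distribution is
#' \deqn{P(l_A,l_B,l_\alpha,l_\beta) \propto \binom{N_A}{l_A}\binom{N_B}{l_B}
#' e^{h_P[l_\alpha+l_\beta] + h_S[l_A+l_B] + K[l_A l_\beta + l_B l_\alpha]}}
#' with \eqn{h_P} the production multiplier, \eqn{h_S} the survival
#' multiplier, and \eqn{K \le 0} the repression coupling.
#'
#' @param h_P production Lagrange multiplier (dimensionless).
#' @param h_S survival Lagrange multiplier.
#' @param K coupling (repression) multiplier; repressive circuits have
#'   \eqn{K \le 0} (positive values are permitted with a warning).
#' @param dt interval label (metadata).
#' @return An object of class \code{toggle_params} with derived
#'   \eqn{\Lambda = e^{h_P + h_S}}.
#' @export
toggle_params <- function(h_P, h_S, K, dt = 1) {
  if (K > 0) warning("K > 0 is not a repressive circuit")
  structure(list(h_P = h_P, h_S = h_S, K = K, Lambda = exp(h_P + h_S),
                 dt = dt),
            class = "toggle_params")
}

#' @export
print.toggle_params <- function(x, ...) {
  cat(sprintf("<toggle_params> h_P = %g, h_S = %g, K = %g (Lambda = %g, K_c = %g)\n",
              x$h_P, x$h_S, x$K, x$Lambda, toggle_critical_K(x)))
  invisible(x)
}

#' Exact one-step event distribution of the toggle switch
#'
#' Enumerates the full finite event space \eqn{(l_A, l_B, l_\alpha,
#' l_\beta)} for given current copy numbers and returns exact probabilities
#' (partition function by direct summation).
#'
#' @param N_A,N_B current protein copy numbers (nonnegative integers).
#' @param p a [toggle_params()].
#' @return A data.frame with columns \code{l_A, l_B, l_alpha, l_beta, prob};
#'   attribute \code{logZ} holds \eqn{\log Z(N_A, N_B)}.
#' @export
toggle_step_distribution <- function(N_A, N_B, p) {
  stopifnot(inherits(p, "toggle_params"), N_A >= 0, N_B >= 0)
  ev <- expand.grid(l_A = 0:N_A, l_B = 0:N_B, l_alpha = 0:1, l_beta = 0:1)
  logw <- lchoose(N_A, ev$l_A) + lchoose(N_B, ev$l_B) +
    p$h_P * (ev$l_alpha + ev$l_beta) + p$h_S * (ev$l_A + ev$l_B) +
    p$K * (ev$l_A * ev$l_beta + ev$l_B * ev$l_alpha)
  logZ <- logsumexp(logw)
  ev$prob <- exp(logw - logZ)
  attr(ev, "logZ") <- logZ
  ev
}

#' Ground-truth toggle switch sampler
#'
#' Simulates trajectories of the toggle switch by sampling each step from the
#' exact one-step distribution and updating \eqn{N_A \leftarrow l_A +
#' l_\alpha}, \eqn{N_B \leftarrow l_B + l_\beta}.  Sampling exploits the
#' factorization of the step distribution into independent
#' \eqn{(l_A, l_\beta)} and \eqn{(l_B, l_\alpha)} pairs: the production event
#' is drawn from its exact marginal and the survivor count is then binomial
#' with success probability \eqn{\sigma(h_S + K l_{\beta})} (logistic), which
#' is algebraically identical to the full enumeration.  Chains are vectorized
#' and reproducible by seed.
#'
#' @param p a [toggle_params()].
#' @param init length-2 integer vector \code{c(N_A, N_B)} or an
#'   \code{n_chains x 2} matrix of per-chain initial states.
#' @param n_steps number of intervals to simulate.
#' @param seed RNG seed.
#' @param n_chains number of independent chains.
#' @return A [trajectory_ensemble()] (count alphabet) with nodes
#'   \code{c("A", "B")} and \code{n_steps + 1} time points.
#' @export
simulate_toggle <- function(p, init = c(10L, 10L), n_steps = 1000L,
                            seed = 1L, n_chains = 1L) {
  stopifnot(inherits(p, "toggle_params"), n_steps >= 1L)
  set.seed(seed)
  if (is.matrix(init)) {
    stopifnot(nrow(init) == n_chains, ncol(init) == 2L)
    NA_ <- as.integer(init[, 1]); NB_ <- as.integer(init[, 2])
  } else {
    NA_ <- rep(as.integer(init[1]), n_chains)
    NB_ <- rep(as.integer(init[2]), n_chains)
  }
  out <- array(0L, dim = c(n_chains, 2L, n_steps + 1L))
  out[, 1, 1] <- NA_; out[, 2, 1] <- NB_
  for (step in seq_len(n_steps)) {
    # production marginals: log w(l) = h_P*l + N*log(1 + e^{h_S + K*l})
    lw1 <- p$h_P + NA_ * log1p(exp(p$h_S + p$K))
    lw0 <- NA_ * log1p(exp(p$h_S))
    l_beta <- as.integer(stats::runif(n_chains) < stats::plogis(lw1 - lw0))
    lw1 <- p$h_P + NB_ * log1p(exp(p$h_S + p$K))
    lw0 <- NB_ * log1p(exp(p$h_S))
    l_alpha <- as.integer(stats::runif(n_chains) < stats::plogis(lw1 - lw0))
    l_A <- stats::rbinom(n_chains, NA_, stats::plogis(p$h_S + p$K * l_beta))
    l_B <- stats::rbinom(n_chains, NB_, stats::plogis(p$h_S + p$K * l_alpha))
    NA_ <- l_A + l_alpha
    NB_ <- l_B + l_beta
    out[, 1, step + 1L] <- NA_
    out[, 2, step + 1L] <- NB_
  }
  trajectory_ensemble(out, alphabet = "count", nodes = c("A", "B"),
                      dt = p$dt)
}

#' Uncoupled effective fields of the toggle switch
#'
#' The mean-field (Uncoupled) production and survival multipliers that absorb
#' the repression: \eqn{\tilde h_{S,A} = h_S + K\langle l_\beta\rangle},
#' \eqn{\tilde h_{P,A} = h_P + K\langle l_B\rangle} (and symmetrically for B).
#'
#' @param p a [toggle_params()].
#' @param moments named list or vector with elements \code{l_alpha},
#'   \code{l_A}, \code{l_beta}, \code{l_B}: the event-count means.
#' @return Named numeric vector \code{c(h_S_A, h_P_A, h_S_B, h_P_B)}.
#' @export
toggle_effective_fields <- function(p, moments) {
  stopifnot(inherits(p, "toggle_params"))
  m <- as.list(moments)
  c(h_S_A = p$h_S + p$K * m$l_beta,
    h_P_A = p$h_P + p$K * m$l_B,
    h_S_B = p$h_S + p$K * m$l_alpha,
    h_P_B = p$h_P + p$K * m$l_A)
}

#' Self-consistent Uncoupled solution
#'
#' Iterates effective fields and uncoupled moments to a damped fixed point.
#' Under the Uncoupled step distribution the moments are
#' \eqn{\langle l_\alpha \rangle = \sigma(\tilde h_{P,A})},
#' \eqn{\langle l_A \rangle = N_A \sigma(\tilde h_{S,A})} with the stationary
#' copy number \eqn{N_A = \langle l_A \rangle + \langle l_\alpha \rangle}.
#'
#' @param p a [toggle_params()].
#' @param init length-2 numeric starting guess for \eqn{(N_A, N_B)}.
#' @param damping damping factor in (0, 1]; new state =
#'   damping * update + (1 - damping) * old.
#' @param tol convergence tolerance on the copy-number update.
#' @param max_iter iteration cap.
#' @return list with \code{N_A}, \code{N_B}, \code{fields} (effective
#'   multipliers), \code{moments}, \code{iterations}.
#' @export
toggle_self_consistent <- function(p, init = c(p$Lambda, p$Lambda),
                                   damping = 0.5, tol = 1e-10,
                                   max_iter = 10000L) {
  stopifnot(inherits(p, "toggle_params"))
  N_A <- init[1]; N_B <- init[2]
  m <- list(l_alpha = stats::plogis(p$h_P), l_beta = stats::plogis(p$h_P),
            l_A = N_A * stats::plogis(p$h_S),
            l_B = N_B * stats::plogis(p$h_S))
  for (it in seq_len(max_iter)) {
    f <- toggle_effective_fields(p, m)
    # stationary copy number of a single gene under fixed effective fields:
    # production sigma(h_P) balances loss N (1 - sigma(h_S))
    N_A_new <- stats::plogis(f[["h_P_A"]]) / (1 - stats::plogis(f[["h_S_A"]]))
    N_B_new <- stats::plogis(f[["h_P_B"]]) / (1 - stats::plogis(f[["h_S_B"]]))
    dN <- max(abs(N_A_new - N_A), abs(N_B_new - N_B))
    N_A <- damping * N_A_new + (1 - damping) * N_A
    N_B <- damping * N_B_new + (1 - damping) * N_B
    m <- list(l_alpha = stats::plogis(f[["h_P_A"]]),
              l_A = N_A * stats::plogis(f[["h_S_A"]]),
              l_beta = stats::plogis(f[["h_P_B"]]),
              l_B = N_B * stats::plogis(f[["h_S_B"]]))
    if (dN < tol) {
      fields <- toggle_effective_fields(p, m)
      return(list(N_A = N_A, N_B = N_B, fields = fields, moments = m,
                  iterations = it))
    }
  }
  stop(sprintf("self-consistency iteration did not converge (residual %.3g)",
               dN))
}

# Composed fixed-point map for N_A: F(N) = Lambda * exp(K * Lambda * e^{K N})
toggle_composed_map <- function(N, p) {
  p$Lambda * exp(p$K * p$Lambda * exp(p$K * N))
}

# Symmetric fixed point: unique root of N = Lambda e^{K N} for K <= 0.
toggle_symmetric_point <- function(p, tol = 1e-13) {
  g <- function(N) N - p$Lambda * exp(p$K * N)
  hi <- max(p$Lambda, 1)
  while (g(hi) < 0) hi <- hi * 2
  stats::uniroot(g, c(0, hi), tol = tol)$root
}

#' Fixed points of the Uncoupled toggle switch
#'
#' Solves the stationary conditions \eqn{N_A = \Lambda e^{K N_B}},
#' \eqn{N_B = \Lambda e^{K N_A}}.  The symmetric solution always exists; a
#' pair of asymmetric solutions appears below the critical coupling
#' \eqn{K_c}.  Roots are found by reducing to the scalar composed map
#' \eqn{N = \Lambda\exp(K\Lambda e^{K N})} and bracketing on the interval
#' below the symmetric point.  Stability comes from the Jacobian of the force
#' field \eqn{(F_A, F_B) = (\Lambda e^{K N_B} - N_A,\ \Lambda e^{K N_A} -
#' N_B)}, whose eigenvalues are \eqn{-1 \pm K\sqrt{N_A N_B}}: a point is
#' stable iff \eqn{K^2 N_A N_B < 1}.
#'
#' @param p a [toggle_params()].
#' @param tol root-finder tolerance.
#' @return A data.frame with columns \code{N_A}, \code{N_B}, \code{stable}.
#' @export
toggle_fixed_points <- function(p, tol = 1e-12) {
  stopifnot(inherits(p, "toggle_params"))
  N0 <- toggle_symmetric_point(p)
  pts <- data.frame(N_A = N0, N_B = N0)
  if (p$K < 0) {
    G <- function(N) toggle_composed_map(N, p) - N
    # one asymmetric root below the symmetric point iff G dips negative there
    if (N0 > 1e-12) {
      opt <- stats::optimize(G, c(1e-12, N0 * (1 - 1e-10)))
      if (opt$objective < -1e-12 && G(1e-12) > 0) {
        r <- stats::uniroot(G, c(1e-12, opt$minimum), tol = tol)$root
        partner <- p$Lambda * exp(p$K * r)
        pts <- rbind(pts,
                     data.frame(N_A = r, N_B = partner),
                     data.frame(N_A = partner, N_B = r))
      }
    }
  }
  pts$stable <- p$K^2 * pts$N_A * pts$N_B < 1
  rownames(pts) <- NULL
  pts
}

#' Critical coupling of the toggle switch (closed form)
#'
#' \eqn{K_c = -e^{1 - h_P - h_S}}: below this repression strength the circuit
#' is a bistable toggle; above it a single symmetric state is stable.
#'
#' @param p a [toggle_params()] (its \code{K} is ignored).
#' @return The critical coupling \eqn{K_c} (negative).
#' @export
toggle_critical_K <- function(p) {
  stopifnot(inherits(p, "toggle_params"))
  -exp(1 - p$h_P - p$h_S)
}

#' Numerical bifurcation point of the fixed-point structure
#'
#' Locates, by bisection in \eqn{K}, the coupling at which the fixed-point
#' count of the stationary conditions changes between one and three.  The
#' predicate uses the slope of the composed map at the symmetric point
#' (evaluated by central finite differences, with the symmetric point found
#' by root bracketing): the asymmetric pair exists iff that slope exceeds
#' one.  This provides an independent numerical check of the closed-form
#' critical coupling.
#'
#' @param p a [toggle_params()] supplying \eqn{h_P, h_S}.
#' @param K_lo,K_hi bracketing couplings (defaults bracket generously).
#' @param tol relative bisection tolerance on \eqn{K}.
#' @return The bifurcation coupling.
#' @export
toggle_bifurcation_K <- function(p, K_lo = NULL, K_hi = NULL, tol = 1e-9) {
  stopifnot(inherits(p, "toggle_params"))
  slope_at_sym <- function(K) {
    pk <- toggle_params(p$h_P, p$h_S, K)
    N0 <- toggle_symmetric_point(pk)
    eps <- max(1e-6, 1e-7 * N0)
    (toggle_composed_map(N0 + eps, pk) -
       toggle_composed_map(N0 - eps, pk)) / (2 * eps)
  }
  guess <- -exp(1 - p$h_P - p$h_S)
  if (is.null(K_lo)) K_lo <- guess * 4     # strongly repressive: 3 points
  if (is.null(K_hi)) K_hi <- guess / 4     # weakly repressive: 1 point
  if (slope_at_sym(K_lo) <= 1 || slope_at_sym(K_hi) >= 1)
    stop("bifurcation not bracketed")
  while (abs(K_hi - K_lo) > tol * abs(K_lo)) {
    Km <- (K_lo + K_hi) / 2
    if (slope_at_sym(Km) > 1) K_lo <- Km else K_hi <- Km
  }
  (K_lo + K_hi) / 2
}

#' Uncoupled stationary copy-number distribution
#'
#' The Uncoupled birth--death process has a Poisson stationary distribution
#' centred on a stable fixed point.  Supercritical (\eqn{K > K_c}): a single
#' Poisson at the symmetric point.  Subcritical: the per-protein marginal is
#' an equal-weight mixture of Poissons at the two stable asymmetric points
#' (equal weights forced by the A/B exchange symmetry).  Near the critical
#' point the Poisson prediction is returned but flagged: there the true
#' occupancy is broad (truncated-power-law-like) and the Uncoupled form is
#' known to be inaccurate.
#'
#' @param p a [toggle_params()].
#' @param n_max largest copy number tabulated (default: generous multiple of
#'   the largest fixed point).
#' @return A data.frame with columns \code{N}, \code{prob}; attributes
#'   \code{regime} (\code{"supercritical"}, \code{"subcritical"} or
#'   \code{"near_critical"}) and \code{means} (the Poisson centres).
#' @export
toggle_stationary_pmf <- function(p, n_max = NULL) {
  stopifnot(inherits(p, "toggle_params"))
  fp <- toggle_fixed_points(p)
  stab <- fp[fp$stable, , drop = FALSE]
  if (nrow(stab) == 0L) stab <- fp[1, , drop = FALSE]  # marginal case
  means <- sort(unique(round(c(stab$N_A, stab$N_B), 12)))
  if (is.null(n_max))
    n_max <- max(20, ceiling(max(means) + 8 * sqrt(max(means) + 1)))
  Ns <- 0:n_max
  prob <- rowMeans(vapply(means, function(m) stats::dpois(Ns, m),
                          numeric(length(Ns))))
  out <- data.frame(N = Ns, prob = prob)
  N0 <- fp$N_A[1]
  crit_margin <- p$K^2 * N0^2 - 1
  regime <- if (nrow(fp) > 1L) "subcritical" else "supercritical"
  if (abs(crit_margin) < 0.05) regime <- "near_critical"
  attr(out, "regime") <- regime
  attr(out, "means") <- means
  attr(out, "known_inaccurate") <- identical(regime, "near_critical")
  out
}

#' Canonical toggle-switch demonstration conditions
#'
#' The package's standard operating points for the toggle-switch experiments
#' (simulation, phase diagram, occupancy comparison).  The fields are
#' \eqn{h_P = -6}, \eqn{h_S = 10}: production is rare per interval and
#' degradation slow (the short-interval regime in which the closed-form
#' stationary analysis is accurate), with \eqn{\Lambda = e^4 \approx 55}
#' proteins at the uncoupled fixed point, a copy number typical of strongly
#' expressed bacterial circuits.  The coupling is placed relative to the
#' critical value \eqn{K_c}: well below it (\code{"subcritical"},
#' \eqn{K = 3 K_c}, a clean bistable toggle), at it (\code{"critical"}), or
#' above it (\code{"supercritical"}, \eqn{K = K_c / 2}, single stable state).
#'
#' @param regime one of \code{"subcritical"}, \code{"critical"},
#'   \code{"supercritical"}.
#' @param h_P,h_S base fields (defaults as above).
#' @return A [toggle_params()].
#' @export
toggle_example_params <- function(regime = c("subcritical", "critical",
                                             "supercritical"),
                                  h_P = -6, h_S = 10) {
  regime <- match.arg(regime)
  Kc <- -exp(1 - h_P - h_S)
  K <- switch(regime, subcritical = 3 * Kc, critical = Kc,
              supercritical = Kc / 2)
  toggle_params(h_P, h_S, K)
}
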