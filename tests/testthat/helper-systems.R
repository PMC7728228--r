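# Small seeded systems used across the suite.

# random time-resolved multiplier set for an enumerable N x T spin system
random_multipliers <- function(N, T, seed, h_scale = 0.4, K_scale = 0.3) {
  set.seed(seed)
  n <- N * T
  h <- matrix(rnorm(n, 0, h_scale), N, T)
  K <- matrix(0, n, n)
  K[upper.tri(K)] <- rnorm(n * (n - 1) / 2, 0, K_scale)
  K <- K + t(K)
  multiplier_set(h, K, flavor = "exact")
}

# stationary lag-coupled pair of nodes, embedded as a time-resolved system
# (couplings at |t - s| <= tau_max), for oracle comparisons
lagged_pair_multipliers <- function(h, K_lag_array, T) {
  N <- dim(K_lag_array)[1]
  tau_max <- dim(K_lag_array)[3] - 1L
  n <- N * T
  K <- matrix(0, n, n)
  for (t in seq_len(T)) for (s in seq_len(T)) {
    if (abs(t - s) <= tau_max)
      K[(t - 1) * N + seq_len(N), (s - 1) * N + seq_len(N)] <-
        K_lag_array[, , abs(t - s) + 1]
  }
  diag(K) <- 0
  multiplier_set(matrix(h, N, T), K, flavor = "exact")
}

# independently written moment summation (second implementation, kept naive
# on purpose): moments of an enumerated path distribution via an explicit
# loop over states
naive_moments <- function(pd) {
  n <- ncol(pd$states)
  M <- numeric(n)
  chi <- matrix(0, n, n)
  for (k in seq_len(nrow(pd$states))) {
    v <- pd$states[k, ]
    M <- M + pd$p[k] * v
    chi <- chi + pd$p[k] * outer(v, v)
  }
  list(M = M, chi = chi)
}

# independently coded exhaustive moment sum for the toggle one-step model
naive_toggle_moment <- function(N_A, N_B, p, fun) {
  tot <- 0; Z <- 0
  for (lA in 0:N_A) for (lB in 0:N_B) for (la in 0:1) for (lb in 0:1) {
    w <- choose(N_A, lA) * choose(N_B, lB) *
      exp(p$h_P * (la + lb) + p$h_S * (lA + lB) +
            p$K * (lA * lb + lB * la))
    Z <- Z + w
    tot <- tot + w * fun(lA, lB, la, lb)
  }
  tot / Z
}
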