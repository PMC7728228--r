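test_that("uncoupled fit is exact when cross-couplings vanish", {
  # 2 spins, equal-time only, no cross coupling: K = 0 between nodes
  set.seed(2)
  h <- matrix(c(0.5, -0.3), 2, 1)
  K <- matrix(0, 2, 2)
  mult <- multiplier_set(h, K, flavor = "exact")
  cons <- path_moments(exact_path_distribution(mult))
  unc <- fit_uncoupled(cons)
  expect_lt(max(abs(unc$h - h)), 1e-7)
  expect_lt(max(abs(unc$K)), 1e-7)

  # self-lag couplings, still no cross: uncoupled equals exact
  Klag <- array(0, dim = c(2, 2, 2))
  Klag[, , 2] <- diag(c(0.4, 0.2))
  mult2 <- lagged_pair_multipliers(c(0.2, -0.1), Klag, T = 3)
  cons2 <- path_moments(exact_path_distribution(mult2))
  unc2 <- fit_uncoupled(cons2)
  expect_lt(max(abs(unc2$h - mult2$h)), 1e-6)
  expect_lt(max(abs(unc2$K - mult2$K)), 1e-6)
})

test_that("a node with zero mean and autocovariance is an unbiased free spin", {
  chi <- diag(2)  # T = 2 window, single node: chi(t,t)=1, chi(1,2)=0
  cons <- constraint_set(matrix(0, 1, 2), chi)
  unc <- fit_uncoupled(cons)
  expect_lt(max(abs(unc$h)), 1e-8)
  expect_lt(max(abs(unc$K)), 1e-8)
})

test_that("uncoupled fit matches one-body moments but not cross-correlations", {
  Klag <- array(0, dim = c(2, 2, 1))
  Klag[1, 2, 1] <- Klag[2, 1, 1] <- 0.15   # weak cross-coupling
  mult <- lagged_pair_multipliers(c(0.3, -0.2), Klag, T = 2)
  pd <- exact_path_distribution(mult)
  cons <- path_moments(pd)
  unc <- fit_uncoupled(cons)
  # forward-KL contract: per-node moments reproduced to high accuracy
  pd_unc <- exact_path_distribution(unc)
  mom_unc <- path_moments(pd_unc)
  expect_lt(max(abs(mom_unc$M - cons$M)), 1e-8)
  for (i in 1:2) {
    sites <- c(i, i + 2)
    expect_lt(max(abs(mom_unc$chi[sites, sites] - cons$chi[sites, sites])),
              1e-8)
  }
  # but the factorized model carries no cross-node correlation
  expect_lt(max(abs(mom_unc$C[1, 2])), 1e-10)
  expect_gt(abs(cons$C[1, 2]), 0.05)
})

test_that("linear response recovers weak couplings with quadratic error decay", {
  errs <- sapply(c(0.1, 0.05, 0.025), function(kk) {
    Klag <- array(0, dim = c(2, 2, 1))
    Klag[1, 2, 1] <- Klag[2, 1, 1] <- kk
    mult <- lagged_pair_multipliers(c(0.3, -0.2), Klag, T = 1)
    cons <- path_moments(exact_path_distribution(mult))
    Kp <- linear_coupling_K(cons)
    abs(Kp[1, 2] - kk)
  })
  expect_lt(errs[1], 0.1^2)                      # within O(K*^2)
  expect_lt(errs[2] / errs[1], 0.5)              # decays
  expect_lt(errs[3] / errs[2], 0.45)             # at least ~quadratically
})

test_that("diagonal covariance gives zero cross-couplings", {
  chi <- diag(4)  # 2 nodes, T = 2, fully uncorrelated spins
  cons <- constraint_set(matrix(0, 2, 2), chi)
  Kp <- linear_coupling_K(cons)
  expect_true(all(abs(Kp) < 1e-12))
})

test_that("singular covariances are refused with a helpful error", {
  M <- matrix(0, 2, 1)
  chi <- matrix(c(1, 1, 1, 1), 2, 2)  # perfectly correlated: C singular
  cons <- constraint_set(M, chi)
  expect_error(linear_coupling_K(cons), "not invertible")
})

test_that("linear_coupling_K on a Gaussian block system matches the closed form", {
  # two agents, T = 3 'time points' each, assembled node-fastest
  g <- gaussian_instance(3, b_norm = 0.2, seed = 4)
  n <- 3
  chi <- matrix(0, 2 * n, 2 * n)
  for (t in 1:n) for (s in 1:n) {
    chi[(t - 1) * 2 + 1, (s - 1) * 2 + 1] <- g$C_A[t, s]
    chi[(t - 1) * 2 + 2, (s - 1) * 2 + 2] <- g$C_A[t, s]
    chi[(t - 1) * 2 + 1, (s - 1) * 2 + 2] <- g$C_C[t, s]
    chi[(t - 1) * 2 + 2, (s - 1) * 2 + 1] <- g$C_C[t, s]
  }
  cons <- constraint_set(matrix(0, 2, n), chi, alphabet = "count")
  Kp <- linear_coupling_K(cons)
  # exact off-diagonal of -C^{-1} vs the perturbative form C_A^-1 C_C C_A^-1:
  # these agree to O(B^2)
  KC_pert <- solve(g$C_A) %*% g$C_C %*% solve(g$C_A)
  KC_est <- matrix(0, n, n)
  for (t in 1:n) for (s in 1:n) KC_est[t, s] <- Kp[(t - 1) * 2 + 1, (s - 1) * 2 + 2]
  expect_lt(norm(KC_est - KC_pert, "2") / norm(KC_pert, "2"), 0.2^2 * 2)
})

test_that("mean-field bias reconstruction obeys its limiting cases", {
  Klag <- array(0, dim = c(2, 2, 1))
  Klag[1, 2, 1] <- Klag[2, 1, 1] <- 0.1
  mult <- lagged_pair_multipliers(c(0.4, -0.2), Klag, T = 2)
  cons <- path_moments(exact_path_distribution(mult))
  unc <- fit_uncoupled(cons)

  # zero couplings: h' = h_tilde
  lin0 <- mean_field_h(unc, matrix(0, 4, 4), cons$M)
  expect_equal(lin0$h, unc$h, tolerance = 1e-12)
  expect_identical(lin0$flavor, "linear_coupling")

  # zero means: h' = h_tilde regardless of K'
  unc0 <- fit_uncoupled(constraint_set(matrix(0, 2, 2), diag(4)))
  Kp <- matrix(0.3, 4, 4); diag(Kp) <- 0
  Kp[c(1, 3), c(1, 3)] <- 0; Kp[c(2, 4), c(2, 4)] <- 0
  lin1 <- mean_field_h(unc0, (Kp + t(Kp)) / 2, matrix(0, 2, 2))
  expect_equal(lin1$h, unc0$h, tolerance = 1e-12)

  # flavor guard
  expect_error(mean_field_h(mult, Kp, cons$M), "flavor")
})

test_that("reverse-KL consistency: effective fields absorb couplings to first order", {
  # h_tilde_i - h_i - sum_{j != i} K_ij M_tilde_j -> 0 quadratically
  resid <- sapply(c(0.2, 0.1), function(kk) {
    Klag <- array(0, dim = c(2, 2, 1))
    Klag[1, 2, 1] <- Klag[2, 1, 1] <- kk
    mult <- lagged_pair_multipliers(c(0.4, -0.3), Klag, T = 1)
    cons <- path_moments(exact_path_distribution(mult))
    unc <- fit_uncoupled(cons)
    Mt <- path_moments(exact_path_distribution(unc))$M
    r1 <- unc$h[1, 1] - mult$h[1, 1] - kk * Mt[2, 1]
    r2 <- unc$h[2, 1] - mult$h[2, 1] - kk * Mt[1, 1]
    max(abs(c(r1, r2)))
  })
  expect_lt(resid[2] / resid[1], 0.35)  # ~quadratic shrinkage (1/4 ideal)
})

test_that("inference error grows with overall coupling strength", {
  err_at <- function(beta) {
    Klag <- array(0, dim = c(2, 2, 1))
    Klag[1, 2, 1] <- Klag[2, 1, 1] <- 0.5 * beta
    mult <- lagged_pair_multipliers(c(0.3 * beta, -0.2 * beta), Klag, T = 1)
    cons <- path_moments(exact_path_distribution(mult))
    lin <- fit_linear_coupling(cons)
    max(abs(lin$K - mult$K))
  }
  errs <- sapply(c(1, 0.5, 0.25), err_at)
  expect_true(all(diff(errs) < 0))  # monotone improvement as beta shrinks
})
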