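test_that("one-step distribution normalizes and factorizes at K = 0", {
  p0 <- toggle_params(0.8, 0.5, 0)
  d <- toggle_step_distribution(5, 3, p0)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  # closed-form Z: product of per-gene factors (1 + e^hP)(1 + e^hS)^N
  Z_closed <- (1 + exp(0.8))^2 * (1 + exp(0.5))^5 * (1 + exp(0.5))^3
  expect_equal(exp(attr(d, "logZ")), Z_closed, tolerance = 1e-12)

  # the closed-form factorization holds for all N up to 50
  for (N in c(1, 10, 50)) {
    dN <- toggle_step_distribution(N, 0, p0)
    expect_equal(exp(attr(dN, "logZ")),
                 (1 + exp(0.8))^2 * (1 + exp(0.5))^N, tolerance = 1e-10)
  }
})

test_that("empty cells only produce, with logistic production probability", {
  p <- toggle_params(-1, 2, -0.3)
  d <- toggle_step_distribution(0, 0, p)
  expect_true(all(d$l_A == 0 & d$l_B == 0))
  p_alpha <- sum(d$prob[d$l_alpha == 1])
  expect_equal(p_alpha, exp(-1) / (1 + exp(-1)), tolerance = 1e-12)
})

test_that("step moments match an independently coded exhaustive sum", {
  p <- toggle_params(0.3, -0.2, -0.1)
  d <- toggle_step_distribution(2, 2, p)
  m1 <- sum(d$prob * d$l_alpha)
  m2 <- sum(d$prob * d$l_A * d$l_beta)
  expect_equal(m1, naive_toggle_moment(2, 2, p, function(lA, lB, la, lb) la),
               tolerance = 1e-12)
  expect_equal(m2, naive_toggle_moment(2, 2, p,
                                       function(lA, lB, la, lb) lA * lb),
               tolerance = 1e-12)
})

test_that("the factorized sampler agrees with the enumerated step law", {
  # one-step transition from a fixed state, many chains, vs exact expectation
  p <- toggle_params(0.5, 0.8, -0.4)
  d <- toggle_step_distribution(6, 4, p)
  eNA <- sum(d$prob * (d$l_A + d$l_alpha))
  vNA <- sum(d$prob * (d$l_A + d$l_alpha)^2) - eNA^2
  ens <- simulate_toggle(p, init = c(6L, 4L), n_steps = 1, seed = 42,
                         n_chains = 20000)
  got <- mean(ens$values[, 1, 2])
  expect_lt(abs(got - eNA), 4 * sqrt(vNA / 20000))
})

test_that("forbidding production and survival drains the system", {
  p <- suppressWarnings(toggle_params(-30, -30, 0))
  ens <- simulate_toggle(p, init = c(10L, 10L), n_steps = 50, seed = 1,
                         n_chains = 5)
  expect_true(all(ens$values[, , 51] == 0))
})

test_that("effective fields reduce to bare fields when K = 0", {
  p <- toggle_params(0.2, 0.4, 0)
  f <- toggle_effective_fields(p, list(l_alpha = 0.3, l_beta = 0.7,
                                       l_A = 2, l_B = 5))
  expect_equal(unname(f), c(0.4, 0.2, 0.4, 0.2))
})

test_that("stationarity relation N = Lambda e^{K(<l_beta> + <l_B>)} holds", {
  p <- toggle_example_params("supercritical")
  sc <- toggle_self_consistent(p)
  # the closed-form relation is the short-interval limit; at these fields the
  # finite-interval correction is (1 + e^-hS)/(1 + e^-hP) - 1, below 0.5%
  expect_equal(sc$N_A,
               p$Lambda * exp(p$K * (sc$moments$l_beta + sc$moments$l_B)),
               tolerance = 0.005)
  # symmetric parameters: A and B agree
  expect_equal(sc$N_A, sc$N_B, tolerance = 1e-8)
})

test_that("fixed points decouple at K = 0 and bifurcate below K_c", {
  p0 <- toggle_params(1, 0.5, 0)
  fp0 <- toggle_fixed_points(p0)
  expect_equal(nrow(fp0), 1L)
  expect_equal(fp0$N_A, p0$Lambda, tolerance = 1e-10)

  Kc <- toggle_critical_K(p0)
  above <- toggle_fixed_points(toggle_params(1, 0.5, Kc * 0.98))
  below <- toggle_fixed_points(toggle_params(1, 0.5, Kc * 1.02))
  expect_equal(nrow(above), 1L)
  expect_equal(nrow(below), 3L)
  expect_false(below$stable[1])           # symmetric point destabilized
  expect_true(all(below$stable[2:3]))     # asymmetric pair stable
  # A <-> B exchange symmetry of the asymmetric pair
  expect_equal(below$N_A[2], below$N_B[3], tolerance = 1e-9)
})

test_that("at the critical point the symmetric solution satisfies Kc^2 N0^2 = 1", {
  for (hs in list(c(0, 1), c(-2, 4), c(1.5, 1.5))) {
    p <- toggle_params(hs[1], hs[2], toggle_critical_K(toggle_params(hs[1], hs[2], 0)))
    N0 <- maxcalnet:::toggle_symmetric_point(p)
    expect_equal(p$K^2 * N0^2, 1, tolerance = 1e-8)
    expect_equal(N0, p$Lambda * exp(-1), tolerance = 1e-8)
  }
})

test_that("closed-form critical coupling matches direct substitution", {
  expect_equal(toggle_critical_K(toggle_params(0.5, 0.5, 0)), -1)
  expect_equal(toggle_critical_K(toggle_params(0, 0, 0)), -exp(1))
})

test_that("numerical bifurcation detection agrees with the closed form", {
  set.seed(7)
  for (i in 1:3) {
    hP <- runif(1, -2, 1); hS <- runif(1, 0, 3)
    p <- toggle_params(hP, hS, 0)
    expect_equal(toggle_bifurcation_K(p), toggle_critical_K(p),
                 tolerance = 1e-7)
  }
})

test_that("stability convention is confirmed by simulation near fixed points", {
  # subcritical switch: trajectories started at the asymmetric (stable)
  # points stay there; started at the symmetric (unstable) point they leave
  p <- toggle_example_params("subcritical")
  fp <- toggle_fixed_points(p)
  st <- fp[fp$stable, ]
  expect_equal(nrow(st), 2L)
  hi <- round(max(st$N_A)); lo <- round(min(st$N_A))
  ens <- simulate_toggle(p, init = c(hi, lo), n_steps = 30000, seed = 3,
                         n_chains = 8)
  late <- ens$values[, 1, 20001:30001]
  expect_gt(mean(late), hi * 0.8)   # still in the A-high basin
  sym <- round(fp$N_A[!fp$stable])
  ens2 <- simulate_toggle(p, init = c(sym, sym), n_steps = 100000, seed = 4,
                          n_chains = 8)
  gap <- abs(ens2$values[, 1, 100001] - ens2$values[, 2, 100001])
  expect_gt(mean(gap), (hi - lo) * 0.5)  # chains broke symmetry
})

test_that("stationary pmf is a single Poisson above Kc and bimodal below", {
  sup <- toggle_example_params("supercritical")
  fp <- toggle_fixed_points(sup)
  pmf <- toggle_stationary_pmf(sup, n_max = 120)
  expect_equal(attr(pmf, "regime"), "supercritical")
  expect_equal(pmf$prob, dpois(0:120, fp$N_A[1]), tolerance = 1e-12)

  sub <- toggle_example_params("subcritical")
  fps <- toggle_fixed_points(sub)
  st <- sort(fps$N_A[fps$stable])
  pmf2 <- toggle_stationary_pmf(sub, n_max = 120)
  expect_equal(attr(pmf2, "regime"), "subcritical")
  expect_equal(pmf2$prob, 0.5 * dpois(0:120, st[1]) + 0.5 * dpois(0:120, st[2]),
               tolerance = 1e-12)
  # two modes at the stable copy numbers
  expect_equal(pmf2$N[which.max(pmf2$prob)], 0)  # low state near zero
  hi_region <- pmf2$prob[pmf2$N > 20]
  expect_equal(pmf2$N[pmf2$N > 20][which.max(hi_region)], round(st[2]),
               tolerance = 1.01)

  crit <- toggle_example_params("critical")
  pmf3 <- toggle_stationary_pmf(crit)
  expect_equal(attr(pmf3, "regime"), "near_critical")
  expect_true(attr(pmf3, "known_inaccurate"))
})

test_that("simulated ensembles respect the A/B exchange symmetry", {
  p <- toggle_example_params("supercritical")
  ens <- simulate_toggle(p, init = c(55L, 55L), n_steps = 50000, seed = 9,
                         n_chains = 10)
  a <- mean(ens$values[, 1, 20001:50001])
  b <- mean(ens$values[, 2, 20001:50001])
  expect_lt(abs(a - b) / (a + b), 0.05)
})
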