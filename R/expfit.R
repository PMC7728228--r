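# Moment-matching fit of a discrete exponential family by damped Newton.
#
# The model is P(state k) = exp(sum_a F[k, a] * theta[a]) / Z.  Fitting the
# Lagrange multipliers theta so that model moments E[F] equal `target` is the
# convex dual problem minimize f(theta) = log Z(theta) - theta . target, whose
# gradient is (model moments - target) and whose Hessian is the feature
# covariance (positive semi-definite).  Convergence is declared on the maximum
# moment residual.

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

fit_moment_match <- function(Fmat, target, init = NULL, tol = 1e-10,
                             max_iter = 500L) {
  p_of <- function(theta) {
    e <- as.vector(Fmat %*% theta)
    lz <- logsumexp(e)
    list(p = exp(e - lz), logZ = lz)
  }
  np <- ncol(Fmat)
  theta <- if (is.null(init)) numeric(np) else init
  st <- p_of(theta)
  fval <- st$logZ - sum(theta * target)
  for (iter in seq_len(max_iter)) {
    mom <- as.vector(crossprod(Fmat, st$p))
    grad <- mom - target
    if (max(abs(grad)) < tol)
      return(list(theta = theta, logZ = st$logZ, moments = mom,
                  residual = max(abs(grad)), converged = TRUE, iter = iter))
    H <- crossprod(Fmat, Fmat * st$p) - tcrossprod(mom)
    step <- tryCatch(solve(H + diag(1e-12, np), grad),
                     error = function(e) grad)
    # damped line search on the dual objective
    alpha <- 1
    repeat {
      th_new <- theta - alpha * step
      st_new <- p_of(th_new)
      f_new <- st_new$logZ - sum(th_new * target)
      if (is.finite(f_new) && f_new <= fval + 1e-14) break
      alpha <- alpha / 2
      if (alpha < 1e-12) break
    }
    theta <- theta - alpha * step
    st <- p_of(theta)
    fval <- st$logZ - sum(theta * target)
  }
  mom <- as.vector(crossprod(Fmat, st$p))
  list(theta = theta, logZ = st$logZ, moments = mom,
       residual = max(abs(mom - target)), converged = FALSE, iter = max_iter)
}

# All spin configurations of n sites as a (2^n) x n matrix of -1/+1.
spin_states <- function(n) {
  if (n > 20L) stop("system too large for exact oracle")
  k <- 0:(2^n - 1)
  m <- matrix(0L, length(k), n)
  for (b in seq_len(n)) m[, b] <- bitwAnd(k, bitwShiftL(1L, b - 1L)) > 0
  m * 2L - 1L
}

# Feature matrix for a full pairwise spin model on `n` sites: one column per
# site (v_a) then one per unordered pair a < b (v_a * v_b).  The site diagonal
# (a, a) is excluded: v^2 = 1 is constant and degenerate with log Z.
pair_feature_matrix <- function(states) {
  n <- ncol(states)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  Fp <- states[, pairs[, 1], drop = FALSE] * states[, pairs[, 2], drop = FALSE]
  list(F = cbind(states, Fp), pairs = pairs)
}
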