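#' Two-agent Gaussian system
#'
#' The exactly solvable benchmark for the Linear Coupling Approximation: two
#' stationary, jointly Gaussian agents whose activities have per-agent
#' auto-covariance \eqn{C_A} and cross-covariance \eqn{C_C}, with full
#' covariance in block form \eqn{C = (C_A\; C_C; C_C\; C_A)}.  For a Gaussian,
#' the Maximum Caliber multipliers are known exactly: \eqn{K = -C^{-1}},
#' \eqn{h = -K M}.
#'
#' @param C_A symmetric positive-definite auto-covariance block (n x n).
#' @param C_C symmetric cross-covariance block (same size); the full block
#'   matrix must be positive definite.
#' @param M mean vector (length 2n), default zero.
#' @return An object of class \code{gaussian_two_agent} with elements
#'   \code{C_A}, \code{C_C}, \code{C} (the assembled block matrix), \code{M}.
#' @export
gaussian_two_agent <- function(C_A, C_C, M = NULL) {
  C_A <- as.matrix(C_A); C_C <- as.matrix(C_C)
  n <- nrow(C_A)
  stopifnot(ncol(C_A) == n, nrow(C_C) == n, ncol(C_C) == n)
  if (max(abs(C_A - t(C_A))) > 1e-10) stop("C_A must be symmetric")
  if (max(abs(C_C - t(C_C))) > 1e-10) stop("C_C must be symmetric")
  C <- rbind(cbind(C_A, C_C), cbind(C_C, C_A))
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("full covariance must be positive definite")
  if (is.null(M)) M <- numeric(2L * n)
  stopifnot(length(M) == 2L * n)
  structure(list(C_A = C_A, C_C = C_C, C = C, M = as.numeric(M), n = n),
            class = "gaussian_two_agent")
}

#' Exact Gaussian multipliers
#'
#' @param g a [gaussian_two_agent()].
#' @return list with \code{K = -C^{-1}} (full block matrix) and
#'   \code{h = -K M}.
#' @export
gaussian_exact_multipliers <- function(g) {
  stopifnot(inherits(g, "gaussian_two_agent"))
  K <- -solve(g$C)
  list(K = K, h = as.vector(-K %*% g$M))
}

#' Linear Coupling on the Gaussian system, with error bound
#'
#' Computes the Linear Coupling estimates for the two-agent Gaussian system:
#' the Uncoupled stage ignores the cross-covariance, giving
#' \eqn{K'_A = -C_A^{-1}}; the linear-response stage gives
#' \eqn{K'_C = C_A^{-1} C_C C_A^{-1}}.  Reconstructing the covariance from
#' these estimates gives \eqn{C' = -(K')^{-1} = (I - B^2)^{-1} C \approx
#' (I + B^2) C} with \eqn{B = \mathrm{diag}(C_A^{-1}C_C,\, C_A^{-1}C_C)},
#' so the first-order reconstruction error is \eqn{\|B^2 C\|/\|C\|}, bounded
#' above by \eqn{\alpha = \|B\|^2} (matrix 2-norm, i.e. largest singular
#' value; for non-symmetric \eqn{B} this dominates the largest eigenvalue
#' magnitude, so the bound is conservative).  The exact reconstruction error
#' \eqn{\|C' - C\|/\|C\|} carries the additional factor
#' \eqn{\|(I - B^2)^{-1}\|} and is reported separately; it can slightly
#' exceed \eqn{\alpha} when \eqn{\|B\|} is not small.
#'
#' @param g a [gaussian_two_agent()].
#' @return list with elements \code{K_A_prime}, \code{K_C_prime},
#'   \code{K_prime} (assembled block matrix), \code{C_prime}
#'   (\eqn{-(K')^{-1}}), \code{B_norm} (\eqn{\|B\|}), \code{alpha}
#'   (\eqn{\|B\|^2}), \code{err_linear} (\eqn{\|B^2C\|/\|C\|}; always
#'   \eqn{\le \alpha}) and \code{err_exact} (\eqn{\|C'-C\|/\|C\|}).
#' @export
gaussian_linear_coupling <- function(g) {
  stopifnot(inherits(g, "gaussian_two_agent"))
  n <- g$n
  CAinv <- solve(g$C_A)
  B1 <- CAinv %*% g$C_C
  spec <- max(Mod(eigen(B1, only.values = TRUE)$values))
  if (spec >= 1) stop("outside perturbative regime")
  K_A <- -CAinv
  K_C <- CAinv %*% g$C_C %*% CAinv
  K_prime <- rbind(cbind(K_A, K_C), cbind(K_C, K_A))
  C_prime <- -solve(K_prime)
  B <- rbind(cbind(B1, matrix(0, n, n)), cbind(matrix(0, n, n), B1))
  B_norm <- norm(B1, type = "2")
  alpha <- B_norm^2
  err_linear <- norm(B %*% B %*% g$C, type = "2") / norm(g$C, type = "2")
  err_exact <- norm(C_prime - g$C, type = "2") / norm(g$C, type = "2")
  list(K_A_prime = K_A, K_C_prime = K_C, K_prime = K_prime,
       C_prime = C_prime, B = B, B_norm = B_norm, alpha = alpha,
       err_linear = err_linear, err_exact = err_exact,
       spectral_radius = spec)
}

#' Seeded Gaussian instance with prescribed coupling-to-autocorrelation ratio
#'
#' Constructs a random two-agent Gaussian system whose matrix
#' \eqn{B = C_A^{-1} C_C} has a prescribed 2-norm, by drawing a random
#' symmetric positive-definite \eqn{C_A} and a random symmetric \eqn{C_C}
#' rescaled to the target.  Because \eqn{\|B\| < 1} implies
#' \eqn{C_A \pm C_C \succ 0}, the assembled block covariance is positive
#' definite by construction.
#'
#' @param n block size.
#' @param b_norm target \eqn{\|B\|} in (0, 1).
#' @param seed RNG seed.
#' @return A [gaussian_two_agent()].
#' @export
gaussian_instance <- function(n = 4L, b_norm = 0.3, seed = 1L) {
  stopifnot(b_norm > 0, b_norm < 1)
  set.seed(seed)
  Q <- qr.Q(qr(matrix(stats::rnorm(n * n), n)))
  C_A <- Q %*% diag(stats::runif(n, 0.5, 2), n) %*% t(Q)
  C_A <- (C_A + t(C_A)) / 2
  R <- matrix(stats::rnorm(n * n), n)
  C_C0 <- (R + t(R)) / 2
  sc <- b_norm / norm(solve(C_A, C_C0), type = "2")
  gaussian_two_agent(C_A, C_C0 * sc)
}
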