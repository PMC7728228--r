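#' Empirical Maximum Caliber constraints
#'
#' Extracts from a trajectory ensemble the averages that Maximum Caliber
#' constrains: first moments \eqn{M_i(t) = \langle v_i(t)\rangle}, second
#' moments \eqn{\chi_{ij}(t,s) = \langle v_i(t) v_j(s)\rangle} and covariances
#' \eqn{C_{ij}(t,s) = \chi_{ij}(t,s) - M_i(t) M_j(s)}.  Averages run over the
#' sample dimension; the stationary form additionally averages over time and
#' indexes second moments by the lag \eqn{\tau = t - s}.
#'
#' @param ens a [trajectory_ensemble()].
#' @param stationary if \code{TRUE}, return the time-translation-invariant
#'   form: \code{M} a length-N vector and lag-indexed matrices
#'   \code{C[, , tau + 1]} with \eqn{C_{ij}(\tau) =
#'   \mathrm{cov}(v_i(t+\tau), v_j(t))} averaged over all valid
#'   \eqn{(t, t+\tau)} windows and samples jointly.
#' @param tau_max largest lag retained in the stationary form (must satisfy
#'   \code{tau_max < n_times}).
#'
#' @return An object of class \code{maxcal_constraints}; time-resolved form
#'   has \code{M} (N x T), \code{chi} and \code{C} ((N*T) x (N*T), site index
#'   running node-fastest); stationary form has vector \code{M} and arrays
#'   \code{chi}, \code{C} of dimension \code{c(N, N, tau_max + 1)}.
#' @export
empirical_constraints <- function(ens, stationary = FALSE, tau_max = 0L) {
  stopifnot(inherits(ens, "maxcal_ensemble"))
  v <- ens$values
  N <- ens$n_nodes; T <- ens$n_times; S <- ens$n_samples
  if (stationary) {
    tau_max <- as.integer(tau_max)
    if (tau_max < 0L) stop("tau_max must be >= 0")
    if (tau_max >= T) stop("insufficient trajectory length")
    if (S * (T - tau_max) < 2L) stop("insufficient data")
    M <- numeric(N)
    for (i in seq_len(N)) M[i] <- mean(v[, i, , drop = FALSE])
    chi <- array(0, dim = c(N, N, tau_max + 1L))
    for (tau in 0:tau_max) {
      acc <- matrix(0, N, N); nwin <- T - tau
      for (s in seq_len(S)) {
        a <- matrix(v[s, , (1L + tau):T], nrow = N)  # v(t + tau)
        b <- matrix(v[s, , 1L:(T - tau)], nrow = N)  # v(t)
        acc <- acc + tcrossprod(a, b)
      }
      chi[, , tau + 1L] <- acc / (S * nwin)
    }
    C <- chi - array(outer(M, M), dim = dim(chi))
    out <- list(M = M, chi = chi, C = C, stationary = TRUE,
                tau_max = tau_max, nodes = ens$nodes, N = N,
                n_obs = S * T, alphabet = ens$alphabet)
  } else {
    M <- apply(v, c(2, 3), mean)                     # N x T
    flat <- matrix(v, nrow = S)                      # S x (N*T), node fastest
    chi <- crossprod(flat) / S
    C <- chi - tcrossprod(as.vector(M))
    lab <- site_labels(ens$nodes, T)
    dimnames(chi) <- dimnames(C) <- list(lab, lab)
    out <- list(M = M, chi = chi, C = C, stationary = FALSE,
                nodes = ens$nodes, N = N, T = T, n_obs = S,
                alphabet = ens$alphabet)
  }
  structure(out, class = "maxcal_constraints")
}

#' Assemble constraints directly from moment matrices
#'
#' Builds a \code{maxcal_constraints} object from already-computed moments
#' (e.g. from exact enumeration), bypassing a trajectory ensemble.
#'
#' @param M mean matrix (N x T) or, for the stationary form, length-N vector.
#' @param chi second-moment matrix ((N*T) x (N*T)) or lag array
#'   \code{c(N, N, tau_max + 1)}.
#' @param nodes optional labels.
#' @param alphabet \code{"spin"} or \code{"count"}.
#' @return A \code{maxcal_constraints}.
#' @export
constraint_set <- function(M, chi, nodes = NULL, alphabet = "spin") {
  if (is.matrix(M)) {
    N <- nrow(M); T <- ncol(M)
    stopifnot(nrow(chi) == N * T, ncol(chi) == N * T)
    if (max(abs(chi - t(chi))) > 1e-10)
      stop("chi must be symmetric under (i,t) <-> (j,s)")
    C <- chi - tcrossprod(as.vector(M))
    if (is.null(nodes)) nodes <- paste0("n", seq_len(N))
    structure(list(M = M, chi = chi, C = C, stationary = FALSE,
                   nodes = nodes, N = N, T = T, n_obs = NA_integer_,
                   alphabet = alphabet),
              class = "maxcal_constraints")
  } else {
    N <- length(M)
    stopifnot(length(dim(chi)) == 3L, dim(chi)[1] == N, dim(chi)[2] == N)
    tau_max <- dim(chi)[3] - 1L
    C <- chi - array(outer(M, M), dim = dim(chi))
    if (is.null(nodes)) nodes <- paste0("n", seq_len(N))
    structure(list(M = M, chi = chi, C = C, stationary = TRUE,
                   tau_max = tau_max, nodes = nodes, N = N,
                   n_obs = NA_integer_, alphabet = alphabet),
              class = "maxcal_constraints")
  }
}

#' @export
print.maxcal_constraints <- function(x, ...) {
  if (x$stationary)
    cat(sprintf("<maxcal_constraints> stationary, N = %d, lags 0..%d\n",
                x$N, x$tau_max))
  else
    cat(sprintf("<maxcal_constraints> N = %d, T = %d\n", x$N, x$T))
  invisible(x)
}

#' Serialize constraint sets
#'
#' JSON with explicit index labels; round-trips losslessly to within double
#' precision.
#' @param cons a \code{maxcal_constraints}.
#' @param path file path.
#' @export
write_constraints <- function(cons, path) {
  stopifnot(inherits(cons, "maxcal_constraints"))
  obj <- list(stationary = cons$stationary, nodes = cons$nodes,
              alphabet = cons$alphabet, M = cons$M, chi = cons$chi,
              dims = if (cons$stationary) c(cons$N, cons$tau_max)
                     else c(cons$N, cons$T))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_constraints
#' @export
read_constraints <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$stationary) {
    N <- obj$dims[1]; tau_max <- obj$dims[2]
    chi <- array(as.numeric(unlist(obj$chi)), dim = c(N, N, tau_max + 1L))
    constraint_set(as.numeric(obj$M), chi, nodes = obj$nodes,
                   alphabet = obj$alphabet)
  } else {
    N <- obj$dims[1]; T <- obj$dims[2]
    M <- matrix(as.numeric(unlist(obj$M)), nrow = N)
    chi <- matrix(as.numeric(unlist(obj$chi)), nrow = N * T)
    constraint_set(M, chi, nodes = obj$nodes, alphabet = obj$alphabet)
  }
}
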