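#' Lagrange multiplier set
#'
#' Container for the parameters of a Maximum Caliber trajectory distribution:
#' biases \eqn{h_i(t)} (conjugate to the means) and couplings
#' \eqn{K_{ij}(t,s)} (conjugate to the pairwise correlations), together with
#' the log-normalizer \eqn{\log Z}.  The coupling matrix is stored symmetric
#' with the \eqn{1/2} double-counting convention: the trajectory
#' log-probability is \eqn{\sum_{i,t} h_i(t) v_i(t) + \frac{1}{2}
#' \sum_{i,t,j,s} K_{ij}(t,s) v_i(t) v_j(s)}, so each unordered site pair
#' contributes \eqn{K\, v v} once.
#'
#' @param h bias matrix (N x T), or a length-N vector for the stationary form.
#' @param K coupling matrix ((N*T) x (N*T), symmetric, zero diagonal for spin
#'   systems), or for the stationary form a lag-indexed array
#'   \code{c(N, N, tau_max + 1)} with \code{K[, , tau + 1]} the couplings at
#'   lag \eqn{\tau} (each symmetric in \eqn{i, j}).
#' @param flavor which estimate this is: \code{"exact"}, \code{"uncoupled"}
#'   (cross-couplings identically zero) or \code{"linear_coupling"}.
#' @param logZ optional log-normalizer.
#' @param nodes optional node labels.
#' @param window for stationary sets produced by windowed linear-response
#'   inference, the number of time slices used (provenance metadata).
#'
#' @return An object of class \code{maxcal_multipliers}.
#' @export
multiplier_set <- function(h, K,
                           flavor = c("exact", "uncoupled", "linear_coupling"),
                           logZ = NA_real_, nodes = NULL, window = NA_integer_) {
  flavor <- match.arg(flavor)
  if (is.matrix(h)) {
    N <- nrow(h); T <- ncol(h)
    stopifnot(is.matrix(K), nrow(K) == N * T, ncol(K) == N * T)
    if (max(abs(K - t(K))) > 1e-9)
      stop("K must be symmetric under (i,t) <-> (j,s)")
    K <- (K + t(K)) / 2
    if (flavor == "uncoupled" && N > 1L) {
      for (t in seq_len(T)) for (s in seq_len(T)) {
        blk <- K[site_index(seq_len(N), t, N), site_index(seq_len(N), s, N)]
        if (max(abs(blk - diag(diag(blk), N))) > 1e-12)
          stop("uncoupled flavor requires zero cross-node couplings")
      }
    }
    stationary <- FALSE
  } else {
    N <- length(h); T <- NA_integer_
    stopifnot(length(dim(K)) == 3L, dim(K)[1] == N, dim(K)[2] == N)
    for (l in seq_len(dim(K)[3]))
      if (max(abs(K[, , l] - t(K[, , l]))) > 1e-9)
        stop("each lag slice of K must be symmetric in (i, j)")
    if (flavor == "uncoupled") {
      offd <- vapply(seq_len(dim(K)[3]), function(l) {
        max(abs(K[, , l] - diag(diag(K[, , l]), N)))
      }, numeric(1))
      if (any(offd > 1e-12))
        stop("uncoupled flavor requires zero cross-node couplings")
    }
    stationary <- TRUE
  }
  if (is.null(nodes)) nodes <- paste0("n", seq_len(N))
  structure(list(h = h, K = K, flavor = flavor, logZ = logZ, nodes = nodes,
                 stationary = stationary, N = N, T = T, window = window),
            class = "maxcal_multipliers")
}

#' @export
print.maxcal_multipliers <- function(x, ...) {
  if (x$stationary)
    cat(sprintf("<maxcal_multipliers> stationary, N = %d, lags 0..%d, flavor = %s\n",
                x$N, dim(x$K)[3] - 1L, x$flavor))
  else
    cat(sprintf("<maxcal_multipliers> N = %d, T = %d, flavor = %s\n",
                x$N, x$T, x$flavor))
  invisible(x)
}

#' Serialize multiplier sets
#'
#' JSON with explicit dimensions, flavor and provenance; round-trips to within
#' double precision.
#' @param mult a \code{maxcal_multipliers}.
#' @param path file path.
#' @export
write_multipliers <- function(mult, path) {
  stopifnot(inherits(mult, "maxcal_multipliers"))
  obj <- list(stationary = mult$stationary, flavor = mult$flavor,
              nodes = mult$nodes, logZ = mult$logZ, window = mult$window,
              h = mult$h, K = mult$K,
              dims = if (mult$stationary) c(mult$N, dim(mult$K)[3] - 1L)
                     else c(mult$N, mult$T))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_multipliers
#' @export
read_multipliers <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$stationary) {
    N <- obj$dims[1]; tau_max <- obj$dims[2]
    K <- array(as.numeric(unlist(obj$K)), dim = c(N, N, tau_max + 1L))
    h <- as.numeric(obj$h)
  } else {
    N <- obj$dims[1]; T <- obj$dims[2]
    h <- matrix(as.numeric(unlist(obj$h)), nrow = N)
    K <- matrix(as.numeric(unlist(obj$K)), nrow = N * T)
  }
  multiplier_set(h, K, flavor = obj$flavor,
                 logZ = if (is.null(obj$logZ)) NA_real_ else obj$logZ,
                 nodes = obj$nodes,
                 window = if (is.null(obj$window)) NA_integer_ else obj$window)
}
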