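#' Trajectory ensemble
#'
#' Container for an ensemble of discrete-time activity trajectories at the
#' nodes of a network: the raw input to all Maximum Caliber inference.  A
#' trajectory records the activity \eqn{v_i(t)} of every node \eqn{i} at every
#' time tick \eqn{t}; an ensemble holds many independent trajectories.
#'
#' @param values numeric array with dimensions
#'   \code{c(n_samples, n_nodes, n_times)}; integer-valued.
#' @param alphabet \code{"spin"} for binary activities in \{-1, +1\} (e.g.
#'   neurons firing/silent) or \code{"count"} for nonnegative integer copy
#'   numbers (e.g. protein molecules).
#' @param nodes optional character vector of node labels (unique); defaults to
#'   \code{"n1" ... "nN"}.
#' @param dt time step label (dimensionless tick), metadata only.
#'
#' @return An object of class \code{maxcal_ensemble}: a list with elements
#'   \code{values}, \code{alphabet}, \code{nodes}, \code{dt}, and the
#'   dimensions \code{n_samples}, \code{n_nodes}, \code{n_times}.
#' @export
trajectory_ensemble <- function(values, alphabet = c("spin", "count"),
                                nodes = NULL, dt = 1) {
  alphabet <- match.arg(alphabet)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-d array: (sample, node, time)")
  storage.mode(values) <- "integer"
  d <- dim(values)
  if (any(d < 1L)) stop("n_samples, n_nodes and n_times must all be >= 1")
  if (anyNA(values)) stop("missing values in trajectory ensemble")
  if (alphabet == "spin") {
    if (!all(values == 1L | values == -1L))
      stop("spin alphabet requires every value in {-1, +1}")
  } else {
    if (any(values < 0L))
      stop("count alphabet requires nonnegative values")
  }
  if (is.null(nodes)) nodes <- paste0("n", seq_len(d[2]))
  if (length(nodes) != d[2] || anyDuplicated(nodes))
    stop("node labels must be unique and match n_nodes")
  structure(list(values = values, alphabet = alphabet, nodes = nodes,
                 dt = dt, n_samples = d[1], n_nodes = d[2], n_times = d[3]),
            class = "maxcal_ensemble")
}

#' @export
print.maxcal_ensemble <- function(x, ...) {
  cat(sprintf("<maxcal_ensemble> %d sample(s) x %d node(s) x %d time(s), %s alphabet\n",
              x$n_samples, x$n_nodes, x$n_times, x$alphabet))
  invisible(x)
}

#' Write / read trajectory ensembles
#'
#' Long-format tab-separated text with columns \code{sample_id},
#' \code{node_id}, \code{time_index}, \code{value}; round-trips losslessly.
#' With \code{format = "rds"} a binary container is used instead (convenient
#' for large ensembles).
#'
#' @param ens a \code{maxcal_ensemble}.
#' @param path file path.
#' @param format \code{"tsv"} (default) or \code{"rds"}.
#' @return \code{write_trajectories} returns \code{path} invisibly;
#'   \code{read_trajectories} returns a \code{maxcal_ensemble}.
#' @export
write_trajectories <- function(ens, path, format = c("tsv", "rds")) {
  format <- match.arg(format)
  stopifnot(inherits(ens, "maxcal_ensemble"))
  if (format == "rds") {
    saveRDS(ens, path)
    return(invisible(path))
  }
  d <- dim(ens$values)
  df <- data.frame(
    sample_id  = rep(seq_len(d[1]), times = d[2] * d[3]),
    node_id    = rep(rep(ens$nodes, each = d[1]), times = d[3]),
    time_index = rep(seq_len(d[3]), each = d[1] * d[2]),
    value      = as.vector(ens$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @param alphabet,dt passed to [trajectory_ensemble()] when reading tsv.
#' @export
read_trajectories <- function(path, alphabet = c("spin", "count"), dt = 1,
                              format = c("tsv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    ens <- readRDS(path)
    stopifnot(inherits(ens, "maxcal_ensemble"))
    return(ens)
  }
  alphabet <- match.arg(alphabet)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "node_id", "time_index", "value")
  if (!all(need %in% names(df))) stop("malformed trajectory file")
  nodes <- unique(df$node_id)
  samples <- sort(unique(df$sample_id))
  times <- sort(unique(df$time_index))
  arr <- array(NA_integer_,
               dim = c(length(samples), length(nodes), length(times)))
  arr[cbind(match(df$sample_id, samples),
            match(df$node_id, nodes),
            match(df$time_index, times))] <- df$value
  trajectory_ensemble(arr, alphabet = alphabet, nodes = nodes, dt = dt)
}

# flat site index over (node, time): node runs fastest within a time slice
site_index <- function(i, t, N) (t - 1L) * N + i

site_labels <- function(nodes, T) {
  as.vector(outer(nodes, seq_len(T), function(n, t) paste0(n, "@t", t)))
}
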