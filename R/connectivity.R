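#' Fisher-z functional connectivity matrix
#'
#' Correlates the time series of every ROI pair (Pearson) and applies the
#' variance-stabilizing Fisher z-transform, `z = atanh(r)`. The diagonal is a
#' sentinel (`NA`): a node's self-correlation is never an edge and never
#' enters any downstream mean or ranking. Perfect correlations are clipped to
#' `+/-(1 - clip_eps)` before the transform so every entry is finite.
#'
#' @param ts [roi_timeseries()] with >= 3 timepoints and no zero-variance
#'   node (enforce upstream with [exclude_missing_nodes()]).
#' @param clip_eps clipping margin for `|r| = 1`; default `1e-7`.
#' @return Object of class `connectivity_matrix`: list with `z` (symmetric
#'   numeric matrix, `NA` diagonal) and `node_ids`.
#' @export
compute_connectivity <- function(ts, clip_eps = 1e-7) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (ncol(ts$data) < 3)
    stop("need >= 3 timepoints to correlate, got ", ncol(ts$data))
  if (any(!is.finite(ts$data)))
    stop("non-finite values in time series of subject ", ts$subject_id)
  v <- apply(ts$data, 1L, var)
  if (any(v == 0))
    stop("zero-variance node(s): ",
         paste(ts$node_ids[v == 0], collapse = ", "))
  r <- cor(t(ts$data))
  r <- pmin(pmax(r, -(1 - clip_eps)), 1 - clip_eps)
  z <- atanh(r)
  diag(z) <- .diag_sentinel
  connectivity_matrix(z, ts$node_ids)
}

#' @rdname compute_connectivity
#' @param z symmetric numeric matrix of Fisher-z values (diagonal ignored and
#'   set to `NA`).
#' @param node_ids node labels aligned to rows/columns.
#' @export
connectivity_matrix <- function(z, node_ids = rownames(z)) {
  z <- as.matrix(z)
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(nrow(z)))
  node_ids <- as.character(node_ids)
  if (nrow(z) != ncol(z)) stop("z must be square")
  if (length(node_ids) != nrow(z) || anyDuplicated(node_ids))
    stop("node_ids must be unique and match the matrix dimension")
  diag(z) <- .diag_sentinel
  off <- z[upper.tri(z) | lower.tri(z)]
  if (any(!is.finite(off))) stop("off-diagonal z values must be finite")
  if (!isTRUE(all.equal(z[upper.tri(z)], t(z)[upper.tri(z)], tolerance = 1e-12)))
    stop("z must be symmetric")
  dimnames(z) <- list(node_ids, node_ids)
  structure(list(z = z, node_ids = node_ids), class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix>", length(x$node_ids), "nodes, mean |z| =",
      format(mean(abs(x$z), na.rm = TRUE), digits = 4), "\n")
  invisible(x)
}

# upper-triangle pair table of a connectivity matrix, in lexicographic
# (i, j), i < j order
.pair_table <- function(z) {
  n <- nrow(z)
  ut <- upper.tri(z)
  idx <- which(ut, arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]
  list(i = idx[, 1L], j = idx[, 2L], value = z[ut][ord])
}

#' Binarize a connectivity matrix at a connection density
#'
#' Keeps the `floor(density * P)` strongest of the `P = n(n-1)/2` node pairs
#' as edges of an unweighted, undirected graph. Ranking uses signed z by
#' default (most-positive first), the convention of proportional thresholding
#' in the resting-state literature; `ranking = "absolute"` ranks by `|z|`.
#' Ties at the cutoff are broken by lexicographic node-pair order so the edge
#' set is deterministic.
#'
#' @param cm [connectivity_matrix()].
#' @param density fraction of pairs to keep, in (0, 1]. Must yield >= 1 edge.
#' @param ranking `"signed"` (default) or `"absolute"`.
#' @return Object of class `binary_graph`: list with `adjacency` (0/1 matrix,
#'   zero diagonal), `density` and `node_ids`.
#' @export
threshold_by_density <- function(cm, density, ranking = c("signed", "absolute")) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  ranking <- match.arg(ranking)
  if (!is.numeric(density) || length(density) != 1 ||
      density <= 0 || density > 1)
    stop("density must be a single number in (0, 1]")
  pt <- .pair_table(cm$z)
  P <- length(pt$value)
  m <- floor(density * P)
  if (m < 1)
    stop("density ", density, " yields 0 edges on ", P, " pairs")
  key <- if (ranking == "absolute") -abs(pt$value) else -pt$value
  ord <- order(key, pt$i, pt$j)
  take <- ord[seq_len(m)]
  n <- length(cm$node_ids)
  A <- matrix(0L, n, n, dimnames = list(cm$node_ids, cm$node_ids))
  A[cbind(pt$i[take], pt$j[take])] <- 1L
  A <- A + t(A)
  structure(list(adjacency = A, density = density, node_ids = cm$node_ids),
            class = "binary_graph")
}

#' @rdname threshold_by_density
#' @param adjacency symmetric 0/1 matrix with zero diagonal.
#' @param node_ids node labels; default rownames or `n1, n2, ...`.
#' @export
binary_graph <- function(adjacency, density = NULL,
                         node_ids = rownames(adjacency)) {
  A <- as.matrix(adjacency)
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(nrow(A)))
  node_ids <- as.character(node_ids)
  if (nrow(A) != ncol(A) || !all(A %in% c(0, 1)) ||
      !identical(unname(A), unname(t(A))) || any(diag(A) != 0))
    stop("adjacency must be a symmetric 0/1 matrix with zero diagonal")
  storage.mode(A) <- "integer"
  if (length(node_ids) != nrow(A) || anyDuplicated(node_ids))
    stop("node_ids must be unique and match the matrix dimension")
  dimnames(A) <- list(node_ids, node_ids)
  P <- nrow(A) * (nrow(A) - 1) / 2
  structure(list(adjacency = A, density = density %||% (sum(A) / 2 / P),
                 node_ids = node_ids),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat("<binary_graph>", length(x$node_ids), "nodes,",
      sum(x$adjacency) / 2, "edges at density", x$density, "\n")
  invisible(x)
}

#' Edge-persistence matrix over a density sweep
#'
#' Entrywise mean of the binary adjacencies over a set of connection
#' densities: entry (i, j) is the proportion of thresholds at which the edge
#' i--j is present, in \[0, 1\]. This is the threshold-averaged adjacency used
#' to visualize within- versus between-module connections.
#'
#' @param cm [connectivity_matrix()].
#' @param densities increasing vector of densities in (0, 1].
#' @inheritParams threshold_by_density
#' @return numeric node x node matrix with zero diagonal.
#' @export
mean_adjacency <- function(cm, densities = seq(0.02, 0.10, by = 0.02),
                           ranking = c("signed", "absolute")) {
  ranking <- match.arg(ranking)
  if (length(densities) < 1) stop("need >= 1 density")
  acc <- 0
  for (d in densities)
    acc <- acc + threshold_by_density(cm, d, ranking)$adjacency
  acc / length(densities)
}

#' Read / write square connectivity matrices and graphs
#'
#' Square delimited text with node ids as both the header row and the first
#' column; the diagonal is written as `NA` for connectivity matrices and `0`
#' for binary graphs. [write_edgelist()] writes one `node_i<sep>node_j` line
#' per edge with `i < j` in lexicographic row order.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return [connectivity_matrix()] for `read_connectivity`.
#' @export
read_connectivity <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, header = TRUE, row.names = 1,
                   check.names = FALSE)
  z <- as.matrix(df)
  connectivity_matrix(z, rownames(df))
}

#' @rdname read_connectivity
#' @param cm [connectivity_matrix()] to write.
#' @export
write_connectivity <- function(cm, path, sep = "\t") {
  .write_square(cm$z, cm$node_ids, path, sep)
}

#' @rdname read_connectivity
#' @param g [binary_graph()] object (from [threshold_by_density()]).
#' @export
write_graph_matrix <- function(g, path, sep = "\t") {
  .write_square(g$adjacency, g$node_ids, path, sep)
}

#' @rdname read_connectivity
#' @export
write_edgelist <- function(g, path, sep = "\t") {
  idx <- which(g$adjacency == 1L & upper.tri(g$adjacency), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  df <- data.frame(node_i = g$node_ids[idx[, 1L]],
                   node_j = g$node_ids[idx[, 2L]])
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_square <- function(mat, ids, path, sep) {
  df <- data.frame(node_id = ids, mat, check.names = FALSE)
  colnames(df) <- c("node_id", ids)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
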