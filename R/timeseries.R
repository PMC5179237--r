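#' ROI time-series container
#'
#' Holds one subject's parcellated BOLD signal: one row per region of interest
#' (ROI, the network node), one column per acquisition volume. Units are
#' arbitrary; all downstream statistics are correlation-based and therefore
#' invariant to per-node positive affine rescaling.
#'
#' @param subject_id opaque subject label.
#' @param data numeric matrix, nodes x timepoints (>= 2 timepoints).
#' @param node_ids character vector of unique node labels aligned to rows;
#'   defaults to the rownames of `data`, or `n1, n2, ...` when absent.
#' @return An object of class `roi_timeseries` with fields `subject_id`,
#'   `data` (rownames set to `node_ids`) and `node_ids`.
#' @export
roi_timeseries <- function(subject_id, data, node_ids = rownames(data)) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(nrow(data)))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != nrow(data))
    stop("node_ids length (", length(node_ids), ") != number of rows (",
         nrow(data), ")")
  if (anyDuplicated(node_ids))
    stop("node_ids must be unique")
  if (ncol(data) < 2)
    stop("need >= 2 timepoints, got ", ncol(data))
  dimnames(data) <- list(node_ids, NULL)
  structure(list(subject_id = as.character(subject_id)[1],
                 data = data, node_ids = node_ids),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat("<roi_timeseries> subject", x$subject_id, "-", length(x$node_ids),
      "nodes x", ncol(x$data), "timepoints\n")
  invisible(x)
}

#' Drop nodes with missing coverage across a cohort
#'
#' A node (ROI) is considered to have missing coverage when its series is
#' degenerate in at least one subject; such nodes are removed from *every*
#' subject so that all connectivity matrices share one node set. The rule
#' operationalizing "missing coverage" flags a node when its series has zero
#' variance or contains any non-finite sample.
#'
#' @param cohort list of [roi_timeseries()] objects sharing an identical node
#'   set (same labels, same order).
#' @return list with `cohort` (same subjects, flagged nodes removed, original
#'   node order preserved) and `excluded` (character vector of dropped node
#'   ids, possibly empty).
#' @export
exclude_missing_nodes <- function(cohort) {
  if (length(cohort) == 0) stop("cohort is empty")
  if (!all(vapply(cohort, inherits, logical(1), "roi_timeseries")))
    stop("cohort must be a list of roi_timeseries objects")
  ids <- cohort[[1]]$node_ids
  for (ts in cohort)
    if (!identical(ts$node_ids, ids))
      stop("subject ", ts$subject_id,
           " has a node set differing from subject ", cohort[[1]]$subject_id)
  flagged <- rep(FALSE, length(ids))
  for (ts in cohort) {
    bad <- apply(ts$data, 1L, function(row)
      any(!is.finite(row)) || var(row) == 0)
    flagged <- flagged | bad
  }
  if (all(flagged))
    stop("all nodes excluded by the missing-coverage rule ",
         "(zero variance or non-finite sample in any subject)")
  keep <- !flagged
  out <- lapply(cohort, function(ts)
    roi_timeseries(ts$subject_id, ts$data[keep, , drop = FALSE],
                   ids[keep]))
  list(cohort = out, excluded = ids[flagged])
}

#' Read / write ROI time series as delimited text
#'
#' Format: one row per node, first column the node id, remaining columns the
#' timepoints; an optional header row carries timepoint labels. `sep` defaults
#' by extension (`.csv` comma, otherwise tab). Header presence is
#' auto-detected: a first row whose non-id fields are not all numeric is
#' treated as a header.
#'
#' @param path file path.
#' @param subject_id subject label; defaults to the file name without
#'   extension.
#' @param sep field separator; `NULL` to infer from the extension.
#' @return [roi_timeseries()] object.
#' @export
read_timeseries <- function(path, subject_id = NULL, sep = NULL) {
  sep <- sep %||% (if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t")
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first[-1]))))
  df <- read.delim(path, sep = sep, header = has_header,
                   check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  roi_timeseries(subject_id %||% sub("\\.[^.]*$", "", basename(path)),
                 mat, as.character(df[[1]]))
}

#' @rdname read_timeseries
#' @param ts [roi_timeseries()] object to write.
#' @export
write_timeseries <- function(ts, path, sep = "\t") {
  df <- data.frame(node_id = ts$node_ids, ts$data,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("node_id", paste0("t", seq_len(ncol(ts$data))))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
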