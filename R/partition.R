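#' Node-to-module partition with functional groupings
#'
#' A fixed community partition: every node belongs to exactly one module, and
#' each module belongs to a functional group. With the Power-style 14-label
#' scheme, the sensory-motor group contains the auditory, somatomotor (hand
#' and mouth) and visual modules; the association group contains the
#' cingulo-opercular, default-mode, dorsal-attention, fronto-parietal,
#' salience and ventral-attention modules; remaining modules are `other`.
#'
#' @param assignment named character vector (names = node ids, values =
#'   module labels) or a two-column data frame (node_id, module).
#' @param group_of named character vector mapping module labels to one of
#'   `"sensory-motor"`, `"association"`, `"other"`; unlisted modules default
#'   to `"other"`. `NULL` maps every module to `"other"`.
#' @return Object of class `module_partition`: list with `assignment`,
#'   `modules` (labels in order of first appearance), `m` (module count) and
#'   `group_of`.
#' @export
module_partition <- function(assignment, group_of = NULL) {
  if (is.data.frame(assignment)) {
    if (ncol(assignment) < 2) stop("assignment data frame needs 2 columns")
    assignment <- setNames(as.character(assignment[[2]]),
                           as.character(assignment[[1]]))
  }
  if (is.null(names(assignment)) || anyDuplicated(names(assignment)))
    stop("assignment must be named by unique node ids")
  assignment <- setNames(as.character(assignment), names(assignment))
  if (any(is.na(assignment) | assignment == ""))
    stop("every node needs a module label")
  modules <- unique(assignment)
  grp <- setNames(rep("other", length(modules)), modules)
  if (!is.null(group_of)) {
    group_of <- setNames(as.character(group_of), names(group_of))
    bad <- setdiff(group_of, c("sensory-motor", "association", "other"))
    if (length(bad))
      stop("unknown group label(s): ", paste(bad, collapse = ", "))
    known <- intersect(names(group_of), modules)
    grp[known] <- group_of[known]
  }
  structure(list(assignment = assignment, modules = modules,
                 m = length(modules), group_of = grp),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("<module_partition>", length(x$assignment), "nodes in", x$m,
      "modules (", sum(x$group_of == "sensory-motor"), "sensory-motor,",
      sum(x$group_of == "association"), "association )\n")
  invisible(x)
}

#' Read partition and module-group tables
#'
#' The partition file is two-column delimited text `(node_id, module_label)`;
#' the group file is two-column `(module_label, group_label)`. A bundled
#' module-group table for the Power-style 14-label scheme with the standard
#' sensory-motor/association grouping ships with the package; read it with
#' `read_module_groups(netgain_module_groups_file())`.
#'
#' @param path file path.
#' @param group_path optional module-group file combined into the partition.
#' @param sep field separator (default tab).
#' @return [module_partition()] for `read_partition`; a named character
#'   vector (module -> group) for `read_module_groups`.
#' @export
read_partition <- function(path, group_path = NULL, sep = "\t") {
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  grp <- if (!is.null(group_path)) read_module_groups(group_path, sep)
  module_partition(df, grp)
}

#' @rdname read_partition
#' @export
read_module_groups <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  setNames(df[[2]], df[[1]])
}

#' @rdname read_partition
#' @param p [module_partition()] to write.
#' @export
write_partition <- function(p, path, group_path = NULL, sep = "\t") {
  write.table(data.frame(node_id = names(p$assignment),
                         module = unname(p$assignment)),
              path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(group_path))
    write.table(data.frame(module = names(p$group_of),
                           group = unname(p$group_of)),
                group_path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_partition
#' @export
netgain_module_groups_file <- function() {
  system.file("extdata", "power_style_module_groups.tsv",
              package = "netgain", mustWork = TRUE)
}
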