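#' Newman modularity under a fixed community partition
#'
#' Computes, for one binarized graph, the per-module quantities
#' `e_ii` (fraction of edges with both endpoints in module i),
#' `a_i` (fraction of edge ends attached to module i) and
#' `q_i = e_ii - a_i^2`, and the network modularity `Q = sum_i q_i`.
#' Q compares the observed within-module edge fraction to the expectation
#' under random wiring with the same module edge-end fractions: near 1 when
#' connections fall almost entirely within modules, 0 when within-module
#' connectivity is at chance. Isolated nodes contribute 0 to `e_ii` and
#' `a_i`; modules with no incident edges appear with zeros.
#'
#' @param g `binary_graph` with at least one edge.
#' @param p [module_partition()] covering every node of `g`.
#' @return Object of class `modularity_fit`: list with `per_module` (data
#'   frame: module, group, size, e_ii, a_i, q_i), `Q`, `n_edges` and
#'   `density`.
#' @export
modularity_fixed_partition <- function(g, p) {
  stopifnot(inherits(g, "binary_graph"), inherits(p, "module_partition"))
  mod <- p$assignment[g$node_ids]
  if (any(is.na(mod)))
    stop("node(s) missing from partition: ",
         paste(g$node_ids[is.na(mod)], collapse = ", "))
  A <- g$adjacency
  idx <- which(A == 1L & upper.tri(A), arr.ind = TRUE)
  E <- nrow(idx)
  if (E == 0)
    stop("edgeless graph: modularity undefined (zero edge count)")
  levs <- unique(unname(mod))
  mi <- factor(mod[idx[, 1L]], levels = levs)
  mj <- factor(mod[idx[, 2L]], levels = levs)
  within <- as.integer(mi) == as.integer(mj)
  e_ii <- tabulate(mi[within], nbins = length(levs)) / E
  ends <- c(tabulate(mi, nbins = length(levs)),
            tabulate(mj, nbins = length(levs)))
  a_i <- (ends[seq_along(levs)] + ends[-seq_along(levs)]) / (2 * E)
  q_i <- e_ii - a_i^2
  per_module <- data.frame(
    module = levs,
    group = unname(p$group_of[levs]),
    size = as.integer(table(factor(mod, levels = levs))),
    e_ii = e_ii, a_i = a_i, q_i = q_i,
    stringsAsFactors = FALSE)
  structure(list(per_module = per_module, Q = sum(q_i), n_edges = E,
                 density = g$density),
            class = "modularity_fit")
}

#' @export
print.modularity_fit <- function(x, ...) {
  cat("<modularity_fit> Q =", format(x$Q, digits = 4), "over",
      nrow(x$per_module), "modules,", x$n_edges, "edges\n")
  invisible(x)
}

#' Mean modularity of a functional module group
#'
#' Averages the per-module `q_i` values over the modules of one functional
#' group (e.g. the association-cortex sub-networks), giving the group's
#' sub-network modularity at that density. The mean is unweighted by module
#' size by default, i.e. each sub-network counts equally.
#'
#' @param fit `modularity_fit` from [modularity_fixed_partition()].
#' @param group group label: `"sensory-motor"`, `"association"` or `"other"`.
#' @param weights `"none"` (default, unweighted) or `"size"` (weight modules
#'   by node count).
#' @return scalar mean q over the group's modules.
#' @export
subnetwork_modularity <- function(fit, group, weights = c("none", "size")) {
  stopifnot(inherits(fit, "modularity_fit"))
  weights <- match.arg(weights)
  if (!group %in% c("sensory-motor", "association", "other"))
    stop("unknown group label: ", group)
  sel <- fit$per_module$group == group
  if (!any(sel))
    stop("no modules in group '", group, "'")
  q <- fit$per_module$q_i[sel]
  if (weights == "size")
    stats::weighted.mean(q, fit$per_module$size[sel])
  else mean(q)
}

#' Aggregate a per-density metric over the threshold sweep
#'
#' `mode = "mean"` is the arithmetic mean over thresholds; `mode =
#' "integrate"` is the trapezoidal area under the metric-versus-density
#' curve (so a constant c over densities d integrates to c * (max(d) -
#' min(d))).
#'
#' @param values numeric metric values, one per density.
#' @param densities strictly increasing densities aligned to `values`.
#' @param mode `"mean"` or `"integrate"` (trapezoid; needs >= 2 densities).
#' @return scalar aggregate.
#' @export
aggregate_over_densities <- function(values, densities,
                                     mode = c("mean", "integrate")) {
  mode <- match.arg(mode)
  if (length(values) == 0) stop("empty input")
  if (length(values) != length(densities))
    stop("values and densities differ in length")
  if (any(diff(densities) <= 0)) stop("densities must be strictly increasing")
  if (mode == "mean") return(mean(values))
  if (length(densities) < 2) stop("integrate needs >= 2 densities")
  sum(diff(densities) * (head(values, -1) + tail(values, -1)) / 2)
}

#' Modularity profile over a density sweep
#'
#' Runs [threshold_by_density()] and [modularity_fixed_partition()] at each
#' density and collects whole-brain Q, the per-module decomposition and the
#' sensory-motor / association group means, together with the threshold
#' aggregates (mean and trapezoidal integral of Q).
#'
#' @param cm [connectivity_matrix()].
#' @param p [module_partition()].
#' @param densities increasing densities in (0, 1].
#' @inheritParams threshold_by_density
#' @return Object of class `modularity_profile`: list with `per_density`
#'   (data frame: density, module, group, size, e_ii, a_i, q_i), `Q` (named
#'   vector per density), `group_q` (data frame: density, group, q), `Q_mean`
#'   and `Q_integrated` (`NA` with a single density).
#' @export
modularity_profile <- function(cm, p, densities = seq(0.02, 0.10, by = 0.02),
                               ranking = c("signed", "absolute")) {
  ranking <- match.arg(ranking)
  if (any(diff(densities) <= 0)) stop("densities must be strictly increasing")
  fits <- lapply(densities, function(d)
    modularity_fixed_partition(threshold_by_density(cm, d, ranking), p))
  per_density <- do.call(rbind, Map(function(f, d)
    cbind(density = d, f$per_module), fits, densities))
  Q <- setNames(vapply(fits, `[[`, numeric(1), "Q"), densities)
  groups <- intersect(c("sensory-motor", "association", "other"),
                      unique(per_density$group))
  group_q <- do.call(rbind, Map(function(f, d) data.frame(
    density = d, group = groups,
    q = vapply(groups, function(g) subnetwork_modularity(f, g), numeric(1)),
    stringsAsFactors = FALSE), fits, densities))
  structure(list(per_density = per_density, Q = Q, group_q = group_q,
                 densities = densities,
                 Q_mean = mean(Q),
                 Q_integrated = if (length(densities) >= 2)
                   aggregate_over_densities(Q, densities, "integrate")
                 else NA_real_),
            class = "modularity_profile")
}

#' @export
print.modularity_profile <- function(x, ...) {
  cat("<modularity_profile>", length(x$Q), "densities; Q_mean =",
      format(x$Q_mean, digits = 4), "\n")
  invisible(x)
}
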