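#' Within/between-module segregation of weighted connectivity
#'
#' For each module, `Zw` is the mean Fisher-z correlation over the module's
#' within-module node pairs and `Zb` the mean over all pairs linking the
#' module's nodes to nodes of any other module; segregation is
#' `S = (Zw - Zb) / Zw`. S > 0 means within-module connectivity exceeds
#' between-module connectivity; S = 1 means no between-module connectivity
#' at all (`Zb = 0`), and S = 0 means none in excess (`Zw = Zb`). Unlike the
#' density-thresholded modularity, this statistic uses the unthresholded
#' matrix, so every connection weight contributes.
#'
#' Sign handling of negative correlations:
#' \describe{
#'   \item{`all`}{use z values as they are (default),}
#'   \item{`positive`}{drop z < 0 from both means (if every between-module z
#'     is negative, `Zb` is taken as 0, i.e. S = 1),}
#'   \item{`absolute`}{use |z|; identical to `all` when no z is negative.}
#' }
#'
#' @param cm [connectivity_matrix()] (unthresholded).
#' @param p [module_partition()] covering every node; every module needs
#'   >= 2 nodes.
#' @param variant `"all"`, `"positive"` or `"absolute"`.
#' @param weights `"none"` (default) or `"size"` for the whole-brain and
#'   group means over modules.
#' @return Object of class `segregation_profile`: list with `per_module`
#'   (data frame: module, group, size, Zw, Zb, S), `whole_brain` (mean S over
#'   all modules), `group_means` (named vector over the groups present) and
#'   `variant`.
#' @export
module_segregation <- function(cm, p,
                               variant = c("all", "positive", "absolute"),
                               weights = c("none", "size")) {
  stopifnot(inherits(cm, "connectivity_matrix"),
            inherits(p, "module_partition"))
  variant <- match.arg(variant)
  weights <- match.arg(weights)
  mod <- p$assignment[cm$node_ids]
  if (any(is.na(mod)))
    stop("node(s) missing from partition: ",
         paste(cm$node_ids[is.na(mod)], collapse = ", "))
  z <- cm$z
  if (variant == "absolute") z <- abs(z)
  levs <- unique(unname(mod))
  sizes <- as.integer(table(factor(mod, levels = levs)))
  if (any(sizes < 2))
    stop("module(s) of size 1 (no within-module pairs): ",
         paste(levs[sizes < 2], collapse = ", "))
  rows <- lapply(levs, function(mlab) {
    inm <- mod == mlab
    zw_vals <- z[inm, inm][upper.tri(z[inm, inm])]
    zb_vals <- as.vector(z[inm, !inm])
    if (variant == "positive") {
      zw_vals <- zw_vals[zw_vals >= 0]
      zb_vals <- zb_vals[zb_vals >= 0]
    }
    if (length(zw_vals) == 0)
      stop("module ", mlab, ": no within-module connections under variant '",
           variant, "'")
    Zw <- mean(zw_vals)
    Zb <- if (length(zb_vals) == 0) 0 else mean(zb_vals)
    if (Zw == 0)
      stop("module ", mlab, ": Zw = 0, segregation undefined")
    data.frame(module = mlab, group = unname(p$group_of[mlab]),
               size = sum(inm), Zw = Zw, Zb = Zb, S = (Zw - Zb) / Zw,
               stringsAsFactors = FALSE)
  })
  per_module <- do.call(rbind, rows)
  wts <- if (weights == "size") per_module$size else rep(1, nrow(per_module))
  groups <- intersect(c("sensory-motor", "association", "other"),
                      unique(per_module$group))
  group_means <- vapply(groups, function(g) {
    sel <- per_module$group == g
    stats::weighted.mean(per_module$S[sel], wts[sel])
  }, numeric(1))
  structure(list(per_module = per_module,
                 whole_brain = stats::weighted.mean(per_module$S, wts),
                 group_means = group_means,
                 variant = variant),
            class = "segregation_profile")
}

#' @export
print.segregation_profile <- function(x, ...) {
  cat("<segregation_profile> variant =", x$variant, "; whole-brain S =",
      format(x$whole_brain, digits = 4), "\n")
  invisible(x)
}
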