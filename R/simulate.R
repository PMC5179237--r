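# Spearman <-> Gaussian-copula Pearson conversion for bivariate normal
# latents: rho_s = (6/pi) asin(rho/2)
.spearman_to_latent <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Build an evenly sized synthetic module partition
#'
#' Distributes `n_nodes` over the given module labels as evenly as possible
#' (earlier modules get the remainder), in label order, and attaches the
#' functional grouping.
#'
#' @param n_nodes total node count.
#' @param module_labels module labels in order.
#' @param group_of named character vector module -> group.
#' @return [module_partition()].
#' @export
synthetic_partition <- function(n_nodes, module_labels, group_of = NULL) {
  k <- length(module_labels)
  if (n_nodes < 2 * k)
    stop("need >= 2 nodes per module (", n_nodes, " nodes, ", k, " modules)")
  sizes <- rep(n_nodes %/% k, k)
  extra <- n_nodes %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- rep(module_labels, sizes)
  module_partition(setNames(labels, sprintf("n%03d", seq_len(n_nodes))),
                   group_of)
}

#' Simulation specification for a synthetic training cohort
#'
#' Describes the study conditions the generator emulates: a two-group
#' randomized design (wait-list control vs. trained) with block-structured
#' resting-state ROI time series whose within-module correlation varies
#' across subjects ("strength"), and gain scores whose rank correlations
#' with network strength and with baseline score are planted via a Gaussian
#' copula.
#'
#' Defaults follow the emulated design: n = 14 control / 15 trained
#' subjects; five connection densities 2-10%; a planted strength-gain
#' Spearman of 0.65 in the trained group only; a planted baseline-gain
#' Spearman of -0.80 in both groups; and a mild negative strength-baseline
#' dependence (-0.33, the non-significant value observed in the emulated
#' trained group) which is what makes the three planted correlations
#' jointly representable (with independent strength and baseline the first
#' two alone would demand more than unit variance on the copula scale —
#' such infeasible requests are rejected with a diagnostic).
#'
#' The default network scale (60 nodes, 6 modules, 120 timepoints) keeps
#' simulation studies fast; `preset = "paper"` switches to a 255-node,
#' 14-module layout matching the retained-ROI count of the Power-style
#' parcellation.
#'
#' @param preset `"default"` (60 nodes, 6 modules) or `"paper"` (255 nodes,
#'   14 modules).
#' @param n_nodes,partition override the preset layout; `partition` must be
#'   a [module_partition()] covering `n_nodes` nodes.
#' @param timepoints BOLD volumes per subject (default 120, i.e. a 4-minute
#'   scan at TR = 2 s).
#' @param within_r population mean within-module correlation (default 0.19;
#'   with `between_r = 0.05` this matches the weak-connectivity regime of
#'   ROI-averaged resting-state data, where the within- and between-module
#'   correlation distributions overlap at T = 120 so that the thresholded
#'   edge set — and hence measured modularity — responds smoothly to
#'   subject strength).
#' @param between_r between-module correlation (default 0.05).
#' @param strength_range total spread of the subject-level within-module
#'   correlation: subject i's within-module r is
#'   `within_r + strength_range * (u_i - 0.5)` with `u_i ~ U(0,1)`
#'   (default 0.26, i.e. within-module r from 0.06 to 0.32).
#' @param plant_in `"all"` (strength modulates every module) or
#'   `"association"` (strength modulates association-group modules only;
#'   sensory-motor and other modules stay at `within_r`).
#' @param n_control,n_smart group sizes (>= 4 each).
#' @param rho_target planted Spearman between measured modularity and gain
#'   in the trained group (control gains are strength-independent).
#' @param attenuation rank reliability of threshold-averaged modularity as
#'   an estimator of latent strength (the Spearman between the two under
#'   the default regime, estimated once by simulation at 400 subjects:
#'   0.974). The generator plants the strength-gain copula at
#'   `rho_target / attenuation` so that the population Spearman between
#'   *measured* modularity and gain equals `rho_target`; set to 1 to plant
#'   on latent strength directly.
#' @param rho_baseline_gain planted Spearman between baseline score and
#'   gain, both groups (negative: high scorers gain less).
#' @param rho_strength_baseline planted Spearman between strength and
#'   baseline score.
#' @param baseline_mean,baseline_sd baseline score distribution (normal).
#' @param gain_mean_smart,gain_mean_control,gain_sd gain score location per
#'   group and common scale.
#' @param fd_meanlog,fd_sdlog log-normal parameters of the mean framewise
#'   displacement covariate (drawn independently of everything else).
#' @param seed default RNG seed consumed by [simulate_cohort()].
#' @return Object of class `sim_spec` (validated list of the above).
#' @export
sim_spec <- function(preset = c("default", "paper"),
                     n_nodes = NULL, partition = NULL,
                     timepoints = 120,
                     within_r = 0.19, between_r = 0.05,
                     strength_range = 0.26,
                     plant_in = c("all", "association"),
                     n_control = 14, n_smart = 15,
                     rho_target = 0.65, attenuation = 0.974,
                     rho_baseline_gain = -0.80,
                     rho_strength_baseline = -0.33,
                     baseline_mean = 40, baseline_sd = 8,
                     gain_mean_smart = 5, gain_mean_control = 0,
                     gain_sd = 4,
                     fd_meanlog = log(0.14), fd_sdlog = 0.4,
                     seed = NULL) {
  preset <- match.arg(preset)
  plant_in <- match.arg(plant_in)
  if (is.null(partition)) {
    if (preset == "paper") {
      n_nodes <- n_nodes %||% 255
      labels <- names(read_module_groups(netgain_module_groups_file()))
      groups <- read_module_groups(netgain_module_groups_file())
    } else {
      n_nodes <- n_nodes %||% 60
      labels <- c("visual", "somatomotor-hand", "auditory",
                  "default-mode", "fronto-parietal", "dorsal-attention")
      groups <- setNames(c(rep("sensory-motor", 3), rep("association", 3)),
                         labels)
    }
    partition <- synthetic_partition(n_nodes, labels, groups)
  } else {
    n_nodes <- length(partition$assignment)
  }
  stopifnot(inherits(partition, "module_partition"))
  if (timepoints < 3) stop("timepoints must be >= 3")
  w_lo <- within_r - strength_range / 2
  w_hi <- within_r + strength_range / 2
  if (abs(between_r) >= 1 || w_hi >= 1 || w_lo <= -1)
    stop("correlations must stay in (-1, 1) over the strength range")
  if (w_lo < between_r)
    stop("within_r - strength_range/2 must not fall below between_r ",
         "(equality gives the structureless null generator)")
  if (n_control < 4 || n_smart < 4) stop("group sizes must be >= 4")
  if (attenuation <= 0 || attenuation > 1)
    stop("attenuation must be in (0, 1]")
  if (abs(rho_target) / attenuation >= 1)
    stop("rho_target / attenuation must stay below 1")
  spec <- structure(list(
    preset = preset, n_nodes = n_nodes, partition = partition,
    timepoints = timepoints, within_r = within_r, between_r = between_r,
    strength_range = strength_range, plant_in = plant_in,
    n_control = n_control, n_smart = n_smart,
    rho_target = rho_target, attenuation = attenuation,
    rho_baseline_gain = rho_baseline_gain,
    rho_strength_baseline = rho_strength_baseline,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    gain_mean_smart = gain_mean_smart,
    gain_mean_control = gain_mean_control, gain_sd = gain_sd,
    fd_meanlog = fd_meanlog, fd_sdlog = fd_sdlog, seed = seed),
    class = "sim_spec")
  .gain_coefficients(spec)   # errors now if the planted triple is infeasible
  spec
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("<sim_spec>", x$n_nodes, "nodes /", x$partition$m, "modules, T =",
      x$timepoints, "; n =", x$n_control, "control +", x$n_smart,
      "trained; planted rho(strength, gain) =", x$rho_target, "\n")
  invisible(x)
}

# Copula-scale coefficients for the gain construction. On the latent
# Gaussian scale, gain_lat = alpha * z_u + beta * z_b + sqrt(resid) * z_e
# with cor(z_u, z_b) = r_ub; alpha and beta are solved so that the latent
# correlations hit the converted Spearman targets exactly.
.gain_coefficients <- function(spec) {
  r_ub <- .spearman_to_latent(spec$rho_strength_baseline)
  solve_one <- function(rho_ug_s, rho_bg_s, label) {
    r_ug <- .spearman_to_latent(rho_ug_s)
    r_bg <- .spearman_to_latent(rho_bg_s)
    den <- 1 - r_ub^2
    alpha <- (r_ug - r_bg * r_ub) / den
    beta <- (r_bg - r_ug * r_ub) / den
    expl <- alpha^2 + beta^2 + 2 * alpha * beta * r_ub
    if (expl > 1 + 1e-12)
      stop("infeasible planted correlations for the ", label, " group: ",
           sprintf("Spearman targets (strength-gain %.2f, baseline-gain %.2f, strength-baseline %.2f) ",
                   rho_ug_s, rho_bg_s, spec$rho_strength_baseline),
           sprintf("require latent variance %.3f > 1; ", expl),
           "weaken a target or strengthen the strength-baseline dependence")
    list(alpha = alpha, beta = beta, resid = max(0, 1 - expl))
  }
  list(r_ub = r_ub,
       smart = solve_one(spec$rho_target / spec$attenuation,
                         spec$rho_baseline_gain, "trained"),
       control = solve_one(0, spec$rho_baseline_gain, "control"))
}

# block-structured correlation matrix for one subject; `strength` drives the
# gain-linked (planted) modules, `nuisance_strength` the remaining modules
.block_sigma <- function(spec, strength, nuisance_strength = 0.5) {
  w_of <- function(u) spec$within_r + spec$strength_range * (u - 0.5)
  mod <- spec$partition$assignment
  grp <- spec$partition$group_of
  n <- length(mod)
  Sigma <- matrix(spec$between_r, n, n)
  for (mlab in spec$partition$modules) {
    inm <- which(mod == mlab)
    planted <- spec$plant_in == "all" || grp[mlab] == "association"
    Sigma[inm, inm] <- w_of(if (planted) strength else nuisance_strength)
  }
  diag(Sigma) <- 1
  Sigma
}

#' Simulate one subject's modular ROI time series
#'
#' Draws `timepoints` i.i.d. samples from a multivariate normal with a
#' block-structured correlation matrix: unit variance, `between_r` between
#' modules, and a within-module correlation set by the subject's strength
#' (see [sim_spec()]). A covariance that is not positive semi-definite is
#' repaired to the nearest correlation matrix before sampling.
#'
#' @param spec [sim_spec()].
#' @param subject_strength strength quantile in \[0, 1\] for the planted
#'   modules (all modules when `plant_in = "all"`, association-group
#'   modules when `plant_in = "association"`).
#' @param nuisance_strength strength quantile for the non-planted modules
#'   under `plant_in = "association"` (independent between-subject
#'   variability that is unrelated to gain); ignored when every module is
#'   planted.
#' @param subject_id label for the output.
#' @param seed optional RNG seed (otherwise the current stream is used).
#' @return [roi_timeseries()] (nodes x timepoints).
#' @export
simulate_timeseries <- function(spec, subject_strength,
                                nuisance_strength = 0.5, subject_id = "sim",
                                seed = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  if (subject_strength < 0 || subject_strength > 1 ||
      nuisance_strength < 0 || nuisance_strength > 1)
    stop("strength quantiles must be in [0, 1]")
  Sigma <- .block_sigma(spec, subject_strength, nuisance_strength)
  ev_min <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) {
    Sigma <- as.matrix(Matrix::nearPD(Sigma, corr = TRUE)$mat)
    ev_min <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < -1e-8)
      stop("block covariance not positive semi-definite after repair")
  }
  X <- with_seed(seed,
                 MASS::mvrnorm(spec$timepoints, mu = rep(0, spec$n_nodes),
                               Sigma = Sigma))
  roi_timeseries(subject_id, t(X), names(spec$partition$assignment))
}

#' Simulate a full two-group training cohort
#'
#' Draws, for every subject, a latent strength quantile `u ~ U(0, 1)` that
#' sets the within-module correlation of their simulated time series, a
#' baseline score, and a gain score built on the Gaussian-copula scale so
#' that the population rank correlations match the planted targets exactly:
#' in the trained group Spearman(strength, gain) = `rho_target`, in the
#' control group 0, and in both groups Spearman(baseline, gain) =
#' `rho_baseline_gain` (see [sim_spec()] for the feasibility constraint).
#' The framewise-displacement covariate is drawn independently. Everything
#' is reproducible from the seed.
#'
#' @param spec [sim_spec()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @param timeseries set `FALSE` to skip the (comparatively expensive) BOLD
#'   simulation and return only the behavioural table — handy for
#'   simulation studies of the statistical layer. The behavioural draws are
#'   identical either way.
#' @return list with `timeseries` (list of [roi_timeseries()], or `NULL`),
#'   `cohort` (data frame: subject_id, group, score_pre, score_post, fd,
#'   true_strength) and `spec`.
#' @export
simulate_cohort <- function(spec, seed = spec$seed, timeseries = TRUE) {
  stopifnot(inherits(spec, "sim_spec"))
  co <- .gain_coefficients(spec)
  n <- spec$n_control + spec$n_smart
  group <- rep(c("Control", "SMART"), c(spec$n_control, spec$n_smart))
  with_seed(seed, {
    z_u <- rnorm(n)
    z_b <- co$r_ub * z_u + sqrt(1 - co$r_ub^2) * rnorm(n)
    z_e <- rnorm(n)
    u <- pnorm(z_u)
    baseline <- spec$baseline_mean + spec$baseline_sd * z_b
    g_lat <- numeric(n)
    for (grp in c("Control", "SMART")) {
      cf <- if (grp == "SMART") co$smart else co$control
      sel <- group == grp
      g_lat[sel] <- cf$alpha * z_u[sel] + cf$beta * z_b[sel] +
        sqrt(cf$resid) * z_e[sel]
    }
    gain <- ifelse(group == "SMART", spec$gain_mean_smart,
                   spec$gain_mean_control) + spec$gain_sd * g_lat
    fd <- rlnorm(n, spec$fd_meanlog, spec$fd_sdlog)
    u2 <- runif(n)      # nuisance strength, never linked to gain
    ids <- sprintf("sub%02d", seq_len(n))
    ts <- if (timeseries)
      lapply(seq_len(n), function(i)
        simulate_timeseries(spec, u[i], u2[i], ids[i]))
    cohort <- data.frame(subject_id = ids, group = group,
                         score_pre = baseline,
                         score_post = baseline + gain,
                         fd = fd, true_strength = u,
                         stringsAsFactors = FALSE)
    list(timeseries = ts, cohort = cohort, spec = spec)
  })
}

#' Write a simulated cohort as a pipeline-ready run directory
#'
#' Emits exactly the file formats the pipeline consumes: one time-series TSV
#' per subject under `timeseries/`, `partition.tsv`, `module_groups.tsv`,
#' `cohort.tsv`, and the simulation parameters as `sim_spec.yaml`.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(file.path(dir, "timeseries"), recursive = TRUE,
             showWarnings = FALSE)
  for (ts in sim$timeseries)
    write_timeseries(ts, file.path(dir, "timeseries",
                                   paste0(ts$subject_id, ".tsv")))
  write_partition(sim$spec$partition, file.path(dir, "partition.tsv"),
                  file.path(dir, "module_groups.tsv"))
  write.table(sim$cohort, file.path(dir, "cohort.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- sim$spec[setdiff(names(sim$spec), "partition")]
  yaml::write_yaml(cfg, file.path(dir, "sim_spec.yaml"))
  invisible(dir)
}
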