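# Independent oracles and fixture builders used across the suite.

# Brute-force modularity straight from the definition: loop over node
# pairs, count edges and edge ends per module. Deliberately naive.
oracle_modularity <- function(A, membership) {
  n <- nrow(A)
  mods <- unique(membership)
  e <- setNames(numeric(length(mods)), mods)
  ends <- setNames(numeric(length(mods)), mods)
  E <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) if (A[i, j] == 1) {
    E <- E + 1
    if (membership[i] == membership[j])
      e[membership[i]] <- e[membership[i]] + 1
    ends[membership[i]] <- ends[membership[i]] + 1
    ends[membership[j]] <- ends[membership[j]] + 1
  }
  stopifnot(E > 0)
  list(e = e / E, a = ends / (2 * E), Q = sum(e / E - (ends / (2 * E))^2))
}

random_adjacency <- function(n, p) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

# planted-partition graph: within-block edge prob p_in, between p_out
planted_graph <- function(block_sizes, p_in, p_out) {
  labels <- rep(seq_along(block_sizes), block_sizes)
  n <- length(labels)
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- if (labels[i] == labels[j]) p_in else p_out
    A[i, j] <- A[j, i] <- rbinom(1, 1, p)
  }
  list(A = A, labels = labels)
}

clique_adjacency <- function(sizes, bridges = list()) {
  labels <- rep(seq_along(sizes), sizes)
  n <- length(labels)
  A <- outer(labels, labels, "==") * 1L
  diag(A) <- 0L
  for (b in bridges) A[b[1], b[2]] <- A[b[2], b[1]] <- 1L
  A
}

# connectivity matrix with constant within-module z and constant
# between-module z, given a module label vector
block_z_matrix <- function(labels, z_within, z_between) {
  n <- length(labels)
  z <- matrix(z_between, n, n)
  same <- outer(labels, labels, "==")
  z[same] <- z_within
  diag(z) <- NA_real_
  connectivity_matrix(z, paste0("n", seq_len(n)))
}

block_partition <- function(labels, group_of = NULL) {
  module_partition(setNames(paste0("m", labels),
                            paste0("n", seq_along(labels))), group_of)
}

# all set partitions of 1..n as membership vectors (restricted growth)
all_set_partitions <- function(n) {
  out <- list()
  recurse <- function(m, k) {
    i <- length(m) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- m; return(invisible()) }
    for (v in seq_len(k + 1L)) recurse(c(m, v), max(k, v))
  }
  recurse(integer(0), 0L)
  out
}

# brute-force sums-of-squares decomposition for the 2 x 2 mixed design:
# returns the group-by-time interaction F and partial eta squared
oracle_mixed_anova <- function(cohort) {
  g <- factor(cohort$group)
  y <- cbind(cohort$score_pre, cohort$score_post)
  N <- nrow(y)
  grand <- mean(y)
  cell <- matrix(0, 2, 2)   # group x time cell means
  for (gi in 1:2) for (ti in 1:2) cell[gi, ti] <- mean(y[g == levels(g)[gi], ti])
  gmean <- rowMeans(cell)
  tmean <- colMeans(cell)
  ng <- as.vector(table(g))
  ss_int <- sum(outer(ng, rep(1, 2)) *
                  (cell - outer(gmean, rep(1, 2)) -
                     outer(rep(1, 2), tmean) + grand)^2)
  # within-subject error: subject-by-time deviations after removing
  # subject means and the time + interaction structure
  subj_mean <- rowMeans(y)
  resid <- y - subj_mean
  for (gi in 1:2) for (ti in 1:2)
    resid[g == levels(g)[gi], ti] <-
      resid[g == levels(g)[gi], ti] - (cell[gi, ti] - gmean[gi])
  ss_err <- sum(resid^2)
  Fv <- (ss_int / 1) / (ss_err / (N - 2))
  list(F = Fv, eta_p2 = ss_int / (ss_int + ss_err))
}

# tie-free random connectivity matrix
random_cm <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(0, n, n)
  z[upper.tri(z)] <- rnorm(n * (n - 1) / 2)
  z <- z + t(z)
  diag(z) <- NA_real_
  connectivity_matrix(z, paste0("n", seq_len(n)))
}

tiny_sim_spec <- function(...) {
  part <- synthetic_partition(
    10, c("alpha", "beta"),
    setNames(c("sensory-motor", "association"), c("alpha", "beta")))
  sim_spec(partition = part, n_control = 6, n_smart = 6, ...)
}
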