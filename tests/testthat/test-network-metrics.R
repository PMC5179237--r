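test_that("fixed-partition modularity reproduces closed-form graphs", {
  # two triangles joined by one bridge edge, modules = the triangles
  A <- clique_adjacency(c(3, 3), bridges = list(c(3, 4)))
  g <- binary_graph(A)
  p <- block_partition(rep(1:2, each = 3))
  fit <- modularity_fixed_partition(g, p)
  expect_equal(fit$per_module$e_ii, c(3 / 7, 3 / 7), tolerance = 1e-14)
  expect_equal(fit$per_module$a_i, c(1 / 2, 1 / 2), tolerance = 1e-14)
  expect_equal(fit$Q, 5 / 14, tolerance = 1e-14)

  # two modules, all edges within, equal edge counts -> Q = 0.5
  A2 <- clique_adjacency(c(3, 3))
  fit2 <- modularity_fixed_partition(binary_graph(A2), p)
  expect_equal(fit2$Q, 0.5, tolerance = 1e-14)

  # single module containing every node -> Q = 0
  p1 <- block_partition(rep(1, 6))
  expect_equal(modularity_fixed_partition(binary_graph(A), p1)$Q, 0,
               tolerance = 1e-14)
})

test_that("modularity matches the brute-force edge-count oracle and igraph", {
  skip_if_not_installed("igraph")
  set.seed(10)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    A <- random_adjacency(n, 0.5)
    if (sum(A) == 0) next
    labels <- sample(1:3, n, replace = TRUE)
    g <- binary_graph(A)
    p <- block_partition(labels)
    fit <- modularity_fixed_partition(g, p)
    orc <- oracle_modularity(A, paste0("m", labels))
    expect_equal(fit$Q, orc$Q, tolerance = 1e-12)
    expect_equal(sum(fit$per_module$a_i), 1, tolerance = 1e-12)
    expect_equal(fit$Q, sum(fit$per_module$e_ii - fit$per_module$a_i^2),
                 tolerance = 1e-14)
    ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(fit$Q, igraph::modularity(ig, labels), tolerance = 1e-12)
  }
})

test_that("edgeless graphs and uncovered nodes are rejected", {
  A <- matrix(0L, 4, 4)
  expect_error(modularity_fixed_partition(binary_graph(A),
                                          block_partition(rep(1, 4))),
               "edgeless")
  A[1, 2] <- A[2, 1] <- 1L
  p_short <- module_partition(setNames(c("m1", "m1"), c("n1", "n2")))
  expect_error(modularity_fixed_partition(binary_graph(A), p_short),
               "missing from partition")
})

test_that("isolated nodes contribute zero to e_ii and a_i", {
  A <- clique_adjacency(c(3, 3))
  A <- rbind(cbind(A, 0L), 0L)       # seventh, isolated node
  p <- block_partition(c(1, 1, 1, 2, 2, 2, 3))
  fit <- modularity_fixed_partition(binary_graph(A), p)
  row3 <- fit$per_module[fit$per_module$module == "m3", ]
  expect_equal(row3$e_ii, 0)
  expect_equal(row3$a_i, 0)
  expect_equal(fit$Q, 0.5)
})

test_that("sub-network modularity averages q over a group's modules", {
  labels <- rep(1:3, each = 4)
  grp <- setNames(c("association", "association", "sensory-motor"),
                  paste0("m", 1:3))
  A <- clique_adjacency(c(4, 4, 4), bridges = list(c(1, 5), c(5, 9)))
  fit <- modularity_fixed_partition(binary_graph(A),
                                    block_partition(labels, grp))
  q <- setNames(fit$per_module$q_i, fit$per_module$module)
  expect_equal(subnetwork_modularity(fit, "association"),
               mean(q[c("m1", "m2")]), tolerance = 1e-14)
  expect_equal(subnetwork_modularity(fit, "sensory-motor"),
               unname(q["m3"]), tolerance = 1e-14)
  expect_error(subnetwork_modularity(fit, "limbic"), "unknown group")
  # weighted and unweighted agree for equal-size modules
  expect_equal(subnetwork_modularity(fit, "association", "size"),
               subnetwork_modularity(fit, "association"))
})

test_that("group means are insensitive to the other group's modules", {
  q_assoc <- c(0.10, 0.02, 0.06)
  fake <- structure(list(per_module = data.frame(
    module = paste0("m", 1:5),
    group = c(rep("association", 3), rep("sensory-motor", 2)),
    size = rep(4L, 5), e_ii = 0, a_i = 0,
    q_i = c(q_assoc, 0.5, -0.3))), class = "modularity_fit")
  expect_equal(subnetwork_modularity(fake, "association"), 0.06)
  fake$per_module$q_i[4:5] <- c(9, -9)
  expect_equal(subnetwork_modularity(fake, "association"), 0.06)
})

test_that("density aggregation: mean and trapezoidal integral", {
  expect_equal(aggregate_over_densities(rep(0.3, 5), seq(0.02, 0.10, 0.02),
                                        "mean"), 0.3)
  expect_equal(aggregate_over_densities(rep(0.3, 5), seq(0.02, 0.10, 0.02),
                                        "integrate"), 0.3 * 0.08,
               tolerance = 1e-14)
  expect_equal(aggregate_over_densities(c(0.2, 0.4), c(0.02, 0.04),
                                        "mean"), 0.3)
  expect_equal(aggregate_over_densities(c(0.2, 0.4), c(0.02, 0.04),
                                        "integrate"), 0.006,
               tolerance = 1e-14)
  expect_equal(aggregate_over_densities(1:5, seq(0.02, 0.10, 0.02),
                                        "mean"), 3)
  expect_error(aggregate_over_densities(numeric(0), numeric(0)), "empty")
  expect_error(aggregate_over_densities(c(1, 2), c(0.04, 0.02)),
               "strictly increasing")
  expect_error(aggregate_over_densities(1, 0.02, "integrate"), ">= 2")
})

test_that("segregation reproduces its closed forms", {
  labels <- rep(1:3, each = 4)
  s1 <- module_segregation(block_z_matrix(labels, 0.6, 0),
                           block_partition(labels))
  expect_equal(s1$per_module$S, rep(1, 3))
  expect_equal(s1$whole_brain, 1)

  s0 <- module_segregation(block_z_matrix(labels, 0.5, 0.5),
                           block_partition(labels))
  expect_equal(s0$per_module$S, rep(0, 3))

  sh <- module_segregation(block_z_matrix(labels, 0.6, 0.3),
                           block_partition(labels))
  expect_equal(sh$per_module$S, rep(0.5, 3), tolerance = 1e-14)
  expect_equal(sh$per_module$Zw, rep(0.6, 3))
  expect_equal(sh$per_module$Zb, rep(0.3, 3))
})

test_that("segregation sign variants behave as documented", {
  set.seed(11)
  labels <- rep(1:2, each = 5)
  # non-negative matrix: absolute variant identical to all-connections
  z <- matrix(abs(rnorm(100, 0.3, 0.2)), 10)
  z <- (z + t(z)) / 2
  diag(z) <- NA
  cm <- connectivity_matrix(z)
  p <- block_partition(labels)
  expect_identical(module_segregation(cm, p, "all")$per_module$S,
                   module_segregation(cm, p, "absolute")$per_module$S)

  # all between-module z negative: positive-only variant gives S = 1
  neg <- block_z_matrix(labels, 0.5, -0.2)
  spos <- module_segregation(neg, p, "positive")
  expect_equal(spos$per_module$S, rep(1, 2))
  # absolute variant sees |z| = 0.2 between instead
  sabs <- module_segregation(neg, p, "absolute")
  expect_equal(sabs$per_module$S, rep((0.5 - 0.2) / 0.5, 2),
               tolerance = 1e-14)
})

test_that("segregation rejects degenerate modules", {
  labels <- c(1, 1, 1, 2)
  expect_error(module_segregation(block_z_matrix(labels, 0.5, 0.1),
                                  block_partition(labels)), "size 1")
  labels2 <- rep(1:2, each = 3)
  expect_error(module_segregation(block_z_matrix(labels2, 0, 0.2),
                                  block_partition(labels2)), "Zw = 0")
})

test_that("raising within-module connectivity raises S and Q monotonically", {
  labels <- rep(1:3, each = 5)
  p <- block_partition(labels)
  base <- module_segregation(block_z_matrix(labels, 0.4, 0.1), p)
  up <- module_segregation(block_z_matrix(labels, 0.45, 0.1), p)
  expect_true(all(up$per_module$S > base$per_module$S))

  # with within-z lifted above every between-z, added edges at a fixed
  # density are all within modules and Q cannot decrease
  set.seed(12)
  z <- matrix(rnorm(225, 0, 0.05), 15)
  z <- (z + t(z)) / 2
  same <- outer(labels, labels, "==")
  z[same] <- z[same] + 0.3
  diag(z) <- NA
  cm1 <- connectivity_matrix(z)
  z2 <- z; z2[same & !is.na(z2)] <- z2[same & !is.na(z2)] + 0.2
  cm2 <- connectivity_matrix(z2)
  q1 <- modularity_fixed_partition(threshold_by_density(cm1, 0.2), p)$Q
  q2 <- modularity_fixed_partition(threshold_by_density(cm2, 0.2), p)$Q
  expect_gte(q2, q1)
})

test_that("module and group labels carry through the modularity profile", {
  set.seed(13)
  labels <- rep(1:4, each = 5)
  grp <- setNames(c("sensory-motor", "sensory-motor", "association",
                    "association"), paste0("m", 1:4))
  p <- block_partition(labels, grp)
  cm <- random_cm(20)
  prof <- modularity_profile(cm, p, densities = c(0.1, 0.2, 0.3))
  expect_equal(length(prof$Q), 3)
  expect_equal(prof$Q_mean, mean(prof$Q))
  expect_equal(prof$Q_integrated,
               aggregate_over_densities(prof$Q, c(0.1, 0.2, 0.3),
                                        "integrate"))
  expect_setequal(unique(prof$group_q$group),
                  c("sensory-motor", "association"))
  # profile rows reconstruct Q exactly at each density
  for (d in c(0.1, 0.2, 0.3)) {
    sub <- prof$per_density[prof$per_density$density == d, ]
    expect_equal(sum(sub$e_ii - sub$a_i^2), unname(prof$Q[as.character(d)]),
                 tolerance = 1e-12)
    expect_equal(sum(sub$a_i), 1, tolerance = 1e-12)
  }
})
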