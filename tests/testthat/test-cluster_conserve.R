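test_that("two well-separated bundles are split exactly as the exhaustive oracle", {
  set.seed(31)
  x <- rbind(matrix(rnorm(4 * 3, mean = 0, sd = 0.3), 4),
             matrix(rnorm(4 * 3, mean = 8, sd = 0.3), 4))
  rownames(x) <- paste0("g", 1:8)
  res <- quiet(kmeans_cluster(x, k = 2, seed = 1))
  oracle <- oracle_min_inertia(x, 2)
  expect_equal(res$inertia, oracle$inertia, tolerance = 1e-9)
  expect_identical(canonical_partition(unname(res$assignments)),
                   canonical_partition(oracle$assign))
})

test_that("k equal to the gene count gives singleton clusters with zero inertia", {
  set.seed(2)
  x <- matrix(rnorm(15), 5, dimnames = list(paste0("g", 1:5), NULL))
  res <- quiet(kmeans_cluster(x, k = 5, seed = 3))
  expect_equal(res$inertia, 0)
  expect_equal(sort(unname(res$assignments)), 1:5)
  expect_equal(res$per_cluster_max_dist, rep(0, 5))
  expect_error(kmeans_cluster(x, k = 6), "between 1")
})

test_that("clustering satisfies its fixed-point and centroid-mean invariants", {
  sim <- small_sim()
  prof <- percent_of_max(collapse_replicates(sim$a))
  res <- quiet(kmeans_cluster(prof, k = 4, seed = 7))
  expect_true(res$converged)
  # centroids are exactly the member means
  for (j in seq_len(res$k)) {
    members <- prof[res$assignments == j, , drop = FALSE]
    expect_equal(unname(res$centroids[j, ]), unname(colMeans(members)),
                 tolerance = 1e-9)
  }
  # reassigning every gene to its nearest centroid changes nothing
  d2 <- vapply(seq_len(res$k), function(j)
    rowSums(sweep(prof, 2, res$centroids[j, ])^2), numeric(nrow(prof)))
  expect_identical(unname(res$assignments), max.col(-d2, ties.method = "first"))
  # determinism
  res2 <- quiet(kmeans_cluster(prof, k = 4, seed = 7))
  expect_identical(res$assignments, res2$assignments)
  expect_identical(res$inertia, res2$inertia)
})

test_that("small random instances match the exhaustive minimum-inertia partition", {
  set.seed(17)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    k <- sample(2:3, 1)
    x <- matrix(rnorm(n * 3), n, dimnames = list(paste0("g", 1:n), NULL))
    res <- quiet(kmeans_cluster(x, k = k, seed = i, n_restarts = 100))
    oracle <- oracle_min_inertia(x, k)
    expect_equal(res$inertia, oracle$inertia, tolerance = 1e-8)
  }
})

test_that("generator archetypes are recovered at k = 10", {
  cfg <- simulation_config(n_dev = 120, n_hk = 30, n_maternal = 30, n_env = 60,
                           env_swap_prob = 0, divergence_scale = 0, seed = 3)
  sim <- simulate_two_species_dataset(cfg)
  prof <- percent_of_max(collapse_replicates(sim$a))
  res <- quiet(kmeans_cluster(prof, k = 10, seed = 17, n_restarts = 20))
  expect_gte(adjusted_rand(sim$truth$archetype_a,
                           res$assignments[sim$truth$ref_id]), 0.9)
})

test_that("conservation cutoffs follow their rules", {
  # all members on the centroid -> cutoff 0
  x <- matrix(rep(c(1, 2, 3), each = 4), 4, dimnames = list(paste0("g", 1:4), NULL))
  res0 <- quiet(kmeans_cluster(x, k = 1, seed = 1))
  expect_equal(conservation_cutoff(res0, "max"), 0)

  sim <- default_sim()
  prof <- percent_of_max(collapse_replicates(sim$a))
  res <- quiet(kmeans_cluster(prof, k = 6, seed = 5))
  expect_identical(conservation_cutoff(res, "max"), res$per_cluster_max_dist)
  expect_equal(conservation_cutoff(res, "global_max"),
               rep(max(res$per_cluster_max_dist), 6))
  # quantile rule agrees with an independent sort-based quantile
  q95 <- conservation_cutoff(res, "quantile:0.95")
  for (j in 1:6) {
    d <- res$member_dist[res$assignments == j]
    expect_equal(q95[j], oracle_quantile(d, 0.95), tolerance = 1e-12)
  }
  expect_error(conservation_cutoff(res, "banana"), "unknown cutoff rule")
})

test_that("conservation calls behave on constructed cases", {
  set.seed(13)
  prof_a <- matrix(runif(60, 0, 100), 12,
                   dimnames = list(paste0("g", 1:12), NULL))
  res <- quiet(kmeans_cluster(prof_a, k = 3, seed = 2))
  map <- data.frame(ref = rownames(prof_a), target = paste0("h", 1:12))
  prof_b <- prof_a
  rownames(prof_b) <- map$target

  # identical profiles are conserved under both methods
  for (meth in c("distance", "membership")) {
    calls <- classify_conservation(res, prof_b, map, method = meth)
    expect_equal(nrow(calls), 12L)
    expect_true(all(calls$label == "conserved"))
  }

  # a perturbation of norm cutoff + 1 along one time point diverges
  g <- "g1"
  cl <- res$assignments[[g]]
  cutoff <- conservation_cutoff(res, "max")[cl]
  pert <- res$centroids[cl, ]
  pert[1] <- pert[1] + cutoff + 1
  prof_b2 <- rbind(prof_b, h13 = pert)
  map2 <- rbind(map, data.frame(ref = g, target = "h13"))
  # g1 now maps to two targets -> drop the original pair to keep 1:1
  map2 <- map2[map2$target != "h1", ]
  calls2 <- classify_conservation(res, prof_b2, map2)
  expect_equal(calls2$label[calls2$target_id == "h13"], "diverged")
  expect_equal(calls2$distance[calls2$target_id == "h13"], cutoff + 1)

  # grid mismatch errors
  expect_error(classify_conservation(res, prof_b[, 1:3], map), "grid mismatch")
})

test_that("self-comparison is fully conserved under the max cutoff", {
  sim <- default_sim()
  prof <- percent_of_max(collapse_replicates(sim$a))
  res <- quiet(kmeans_cluster(prof, k = 10, seed = 11))
  self_map <- data.frame(ref = rownames(prof), target = rownames(prof))
  calls <- classify_conservation(res, prof, self_map)
  expect_true(all(calls$label == "conserved"))
})

test_that("class enrichment equals the hypergeometric summation oracle", {
  # 500-gene background, 20 in class; 50-gene target with 10 in class
  background <- paste0("g", 1:500)
  labels <- data.frame(gene_id = background,
                       class = c(rep("membrane", 20), rep("other", 480)))
  target <- c(paste0("g", 1:10), paste0("g", 101:140))
  tab <- class_enrichment(target, background, labels)
  expect_equal(tab$p_value[tab$class == "membrane"],
               oracle_hyper_tail(10, 20, 500, 50), tolerance = 1e-12)
  expect_equal(tab$p_adjust, pmin(1, tab$p_value * 2 / rank(tab$p_value)),
               tolerance = 1e-12)

  # a target set equal to one whole class is that class's extreme enrichment
  labels2 <- data.frame(gene_id = paste0("g", 1:100),
                        class = rep(c("a", "b", "c", "d"), each = 25))
  tab2 <- class_enrichment(paste0("g", 1:25), paste0("g", 1:100), labels2)
  expect_equal(tab2$class[which.min(tab2$p_value)], "a")
  expect_equal(tab2$n_target_in[tab2$class == "a"], 25L)

  # unlabeled target -> empty table with a warning
  expect_warning(
    empty <- class_enrichment("gX", c("gX", "gY"),
                              data.frame(gene_id = "gZ", class = "a")),
    "no class labels")
  expect_equal(nrow(empty), 0L)
  expect_error(class_enrichment("g1", character(0), labels), "empty background")
})
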