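test_that("self-comparison yields a unit diagonal", {
  sim <- small_sim()
  am <- collapse_replicates(sim$a)
  sc <- interspecies_correlation_matrix(am, am, method = "pearson")
  expect_equal(unname(diag(sc$matrix)), rep(1, ncol(am)))
  sc2 <- interspecies_correlation_matrix(am, am, method = "spearman")
  expect_equal(unname(diag(sc2$matrix)), rep(1, ncol(am)))
  expect_true(all(sc$matrix >= -1 & sc$matrix <= 1))
})

test_that("spearman is invariant to monotone columnwise transforms", {
  sim <- small_sim()
  am <- collapse_replicates(sim$a)
  bm <- collapse_replicates(sim$b)
  base <- interspecies_correlation_matrix(am, bm, method = "spearman")
  warped <- interspecies_correlation_matrix(am, exp(bm / 50), method = "spearman")
  expect_equal(base$matrix, warped$matrix, tolerance = 1e-12)
})

test_that("toy matrices match the explicit arithmetic oracle", {
  a <- matrix(c(1, 2, 4, 8, 5, 3, 1, 6), 4,
              dimnames = list(paste0("g", 1:4), c("0", "6")))
  b <- matrix(c(2, 3, 5, 9, 6, 4, 2, 7), 4,
              dimnames = list(paste0("h", 1:4), c("0", "6")))
  eps <- max(1e-6, min(c(a, b)) / 10)   # same pseudocount rule as the package
  sc <- interspecies_correlation_matrix(a, b, method = "pearson")
  for (s in 1:2) for (t in 1:2) {
    expect_equal(sc$matrix[s, t],
                 oracle_pearson(log(a[, s] + eps), log(b[, t] + eps)),
                 tolerance = 1e-12)
  }
  scs <- interspecies_correlation_matrix(a, b, method = "spearman")
  for (s in 1:2) for (t in 1:2) {
    expect_equal(scs$matrix[s, t], oracle_spearman(a[, s], b[, t]),
                 tolerance = 1e-12)
  }
  expect_error(interspecies_correlation_matrix(a[1:2, ], b[1:2, ]),
               "at least 3 genes")
})

test_that("per-gene technical factors cancel under per-gene normalization", {
  sim <- small_sim()
  am <- collapse_replicates(sim$a)
  bm <- collapse_replicates(sim$b)
  set.seed(4)
  scaled <- bm * runif(nrow(bm), 0.5, 2)   # per-gene platform factors
  for (meth in c("pearson", "spearman")) {
    base <- interspecies_correlation_matrix(am, bm, method = meth,
                                            per_gene_normalize = TRUE)
    resc <- interspecies_correlation_matrix(am, scaled, method = meth,
                                            per_gene_normalize = TRUE)
    expect_equal(base$matrix, resc$matrix, tolerance = 1e-12)
  }
  # without normalization, a species-wide platform factor still cancels:
  # spearman exactly, pearson on logs up to the pseudocount
  base <- interspecies_correlation_matrix(am, bm, method = "spearman")
  glob <- interspecies_correlation_matrix(am, bm * 7.3, method = "spearman")
  expect_equal(base$matrix, glob$matrix, tolerance = 1e-12)
})

test_that("divergence profiles localize interspecies differences", {
  sim <- small_sim()
  am <- collapse_replicates(sim$a)
  dp0 <- divergence_profile(list(am, am))
  expect_equal(unname(dp0$variance), rep(0, ncol(am)))

  # one stage's values shifted -> variance elevated only at that stage
  # (on fixed profiles; per-gene renormalization would redistribute it)
  shifted <- am
  shifted[, 3] <- shifted[, 3] * 3
  dp <- divergence_profile(list(am, shifted), normalize = FALSE)
  expect_gt(dp$variance[3], 0)
  expect_equal(unname(dp$variance[-3]), rep(0, ncol(am) - 1))
  expect_true(all(dp$variance >= 0))
  expect_error(divergence_profile(list(am)), "at least 2")
})

test_that("developmental divergence is lowest at mid-development", {
  sim <- default_sim()
  ali <- quiet(align_orthologs(sim$a, sim$b, sim$map))
  dev <- sim$classes$gene_id[sim$classes$class == "developmental"]
  am <- collapse_replicates(ali$a)[dev, ]
  bm <- collapse_replicates(ali$b)[sim$map$target[match(dev, sim$map$ref)], ]
  dp <- divergence_profile(list(am, bm))
  expect_true(which.min(dp$variance) %in% 3:5)   # interior minimum
  expect_gt(dp$variance[1], min(dp$variance))
  expect_gt(dp$variance[7], min(dp$variance))
})

test_that("PCA projection groups equivalent stages across species", {
  sim <- default_sim()
  am <- log(collapse_replicates(sim$a) + 1e-3)
  bm <- log(collapse_replicates(sim$b) + 1e-3)
  stacked <- stack_stage_samples(am, bm)
  p <- pca_sample_projection(stacked, n_components = 3)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_equal(sum(p$var_explained), 1)
  # duplicated samples project identically
  p2 <- pca_sample_projection(rbind(stacked, stacked[1, , drop = FALSE]))
  expect_equal(unname(p2$scores[1, ]), unname(p2$scores[nrow(stacked) + 1, ]))
  # each reference stage's nearest target sample is its equivalent stage
  n <- ncol(am)
  hits <- vapply(seq_len(n), function(s) {
    d <- colSums((t(p$scores[(n + 1):(2 * n), ]) - p$scores[s, ])^2)
    which.min(d) == s
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  expect_error(pca_sample_projection(stacked[1:2, ]), "at least 3")
})

test_that("pattern shapes are classified from constructed series", {
  mk <- function(series) {
    structure(list(method = "pearson",
                   matrix = diag(series) + 0,
                   n_genes = 10L, gene_set = "toy"),
              class = "StageCorrelation")
  }
  eq <- cbind(1:3, 1:3)
  hb <- pattern_summary(mk(c(0.5, 0.9, 0.5)), eq, margin = 0.1)
  expect_equal(hb$shape, "hourglass")
  expect_equal(hb$peak_stage, 2)   # interior peak

  eq5 <- cbind(1:5, 1:5)
  fun <- pattern_summary(mk(c(0.2, 0.4, 0.6, 0.8, 0.9)), eq5)
  expect_equal(fun$shape, "funnel")

  flat <- pattern_summary(mk(c(0.8, 0.81, 0.8, 0.82, 0.8)), eq5)
  expect_equal(flat$shape, "flat")

  expect_error(pattern_summary(mk(c(0.5, 0.9, 0.5)), cbind(1:2, 1:2)),
               "at least 3")
})

test_that("self-comparison has diagonality one", {
  sim <- small_sim()
  am <- collapse_replicates(sim$a)
  sc <- interspecies_correlation_matrix(am, am, method = "pearson")
  ps <- pattern_summary(sc, cbind(seq_len(ncol(am)), seq_len(ncol(am))))
  expect_equal(ps$diagonality, 1)
})

test_that("gene classes decompose into hourglass and funnel contributions", {
  sim <- default_sim()
  ali <- quiet(align_orthologs(sim$a, sim$b, sim$map))
  am <- collapse_replicates(ali$a)
  bm <- collapse_replicates(ali$b)
  eq <- cbind(1:7, 1:7)
  series <- list()
  for (cls in c("developmental", "housekeeping", "environmental", "maternal")) {
    gs <- sim$classes$gene_id[sim$classes$class == cls]
    sc <- interspecies_correlation_matrix(am, bm, method = "pearson",
                                          gene_set = gs, label = cls)
    series[[cls]] <- pattern_summary(sc, eq)$series
  }
  all_ps <- pattern_summary(
    interspecies_correlation_matrix(am, bm, method = "pearson"), eq)
  # the all-genes series lies within the envelope of the class series
  env_lo <- do.call(pmin, series)
  env_hi <- do.call(pmax, series)
  expect_true(all(all_ps$series >= env_lo - 0.05))
  expect_true(all(all_ps$series <= env_hi + 0.05))
})
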