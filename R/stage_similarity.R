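# Stage-by-stage interspecies conservation: correlation matrices,
# divergence profiles, PCA sample grouping and hourglass/funnel summaries.

#' Interspecies stage-correlation matrix
#'
#' For every pair of measured stages (s in species A, t in species B),
#' correlates expression across orthologous genes between A's stage-s
#' column and B's stage-t column. Pearson measures the linear relationship
#' (computed on `log(value + eps)` here, where technical level differences
#' are additive); Spearman measures monotone association on the raw values
#' and is invariant to per-gene monotone transforms. Higher correlation at
#' a stage pair means stronger conservation of the relative expression
#' levels of different genes at those stages.
#'
#' @param a,b row-aligned gene x stage matrices (e.g. from
#'   [collapse_replicates()] after [align_orthologs()]): row i of `a` and
#'   row i of `b` are orthologues. `ExpressionMatrix` objects are
#'   collapsed automatically.
#' @param method `"pearson"` or `"spearman"`.
#' @param gene_set optional integer/logical/character row selector
#'   restricting the gene set (character ids refer to rownames of `a`).
#' @param label free-text name for the gene set (e.g. a class label).
#' @param per_gene_normalize percent-of-max normalize each gene's profile
#'   per species before correlating. This makes the matrix exactly
#'   invariant to per-gene technical level factors (primer efficiency,
#'   platform), at the cost of collapsing the cross-gene signal at stages
#'   where most profiles sit at their maximum; the default (`FALSE`)
#'   correlates measured levels, as absolute-level analyses do.
#' @return A `StageCorrelation` list: `method`, `matrix` (stages A x
#'   stages B, dimnames are the hpf grids), `n_genes`, `gene_set`.
#' @export
interspecies_correlation_matrix <- function(a, b,
                                            method = c("pearson", "spearman"),
                                            gene_set = NULL, label = "all",
                                            per_gene_normalize = FALSE) {
  method <- match.arg(method)
  if (inherits(a, "ExpressionMatrix")) a <- collapse_replicates(a)
  if (inherits(b, "ExpressionMatrix")) b <- collapse_replicates(b)
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("matrices must be row-aligned on orthologues")
  if (!is.null(gene_set)) {
    if (is.character(gene_set)) gene_set <- match(gene_set, rownames(a))
    a <- a[gene_set, , drop = FALSE]
    b <- b[gene_set, , drop = FALSE]
  }
  if (nrow(a) < 3) stop("need at least 3 genes to correlate, got ", nrow(a))
  if (per_gene_normalize) {
    a <- percent_of_max(a)
    b <- percent_of_max(b)
  }
  if (method == "pearson") {
    pos <- c(a[a > 0 & !is.na(a)], b[b > 0 & !is.na(b)])
    eps <- max(1e-6, if (length(pos)) min(pos) / 10 else 1e-6)
    a <- log(a + eps); b <- log(b + eps)
  }
  cm <- cor(a, b, method = method, use = "pairwise.complete.obs")
  structure(list(method = method, matrix = cm, n_genes = nrow(a),
                 gene_set = label), class = "StageCorrelation")
}

#' @export
print.StageCorrelation <- function(x, ...) {
  cat(sprintf("StageCorrelation (%s, gene set '%s', n=%d): %d x %d stages\n",
              x$method, x$gene_set, x$n_genes, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Cross-species expression divergence per time point
#'
#' For two or more species on a matched (scaled) time grid, computes at
#' every time point the variance of each gene's expression across species
#' and averages it over genes. Profiles are percent-of-max normalized per
#' gene and species first (disable with `normalize = FALSE` if already
#' normalized). A low variance at a stage means high interspecies
#' conservation there.
#'
#' @param matrices list of >= 2 row-aligned gene x stage matrices with
#'   identical dimensions (orthologues in matching rows).
#' @param normalize apply [percent_of_max()] per matrix first.
#' @return A `DivergenceProfile` list: `time` (colnames of the first
#'   matrix, if any), `variance` (per-stage mean across genes of the
#'   across-species variance), `n_species`, `n_genes`.
#' @export
divergence_profile <- function(matrices, normalize = TRUE) {
  if (!is.list(matrices) || length(matrices) < 2) {
    stop("need at least 2 species matrices")
  }
  dims <- vapply(matrices, dim, integer(2))
  if (any(dims != dims[, 1])) stop("all matrices must have identical dimensions")
  if (normalize) matrices <- lapply(matrices, percent_of_max)
  arr <- simplify2array(matrices)           # genes x stages x species
  v <- apply(arr, c(1, 2), var)
  tm <- suppressWarnings(as.numeric(colnames(matrices[[1]])))
  structure(list(time = tm, variance = colMeans(v, na.rm = TRUE),
                 n_species = length(matrices), n_genes = nrow(matrices[[1]])),
            class = "DivergenceProfile")
}

#' PCA projection of stage samples
#'
#' Projects stacked stage samples (each row one (species, stage) sample,
#' genes as features) onto principal components, for visual grouping of
#' equivalent developmental stages across species: with accurate temporal
#' staging, equivalent stages of the two species map together.
#'
#' @param samples numeric matrix, samples x genes, with informative
#'   rownames (e.g. `"A_t6"`); >= 3 samples required.
#' @param n_components number of leading components to return.
#' @return list with `scores` (samples x `n_components`), `var_explained`
#'   (fractions for all components, non-increasing, summing to 1) and
#'   `sdev`.
#' @export
pca_sample_projection <- function(samples, n_components = 2) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 3) stop("need at least 3 samples")
  if (n_components > min(dim(samples))) {
    stop("fewer samples/genes than requested components")
  }
  p <- prcomp(samples, center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(n_components), drop = FALSE],
       var_explained = ve, sdev = p$sdev)
}

#' Stack two species' stage columns into a sample matrix
#'
#' @param a,b row-aligned gene x stage matrices (orthologues in matching
#'   rows); for Pearson-style geometry values are typically logged first.
#' @param labels species prefixes for the sample names.
#' @return samples x genes matrix whose rows are all stages of `a`
#'   followed by all stages of `b`.
#' @export
stack_stage_samples <- function(a, b, labels = c("A", "B")) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b))
  out <- t(cbind(a, b))
  rownames(out) <- c(paste0(labels[1], "_t", colnames(a) %||% seq_len(ncol(a))),
                     paste0(labels[2], "_t", colnames(b) %||% seq_len(ncol(b))))
  out
}

#' Hourglass/funnel summary of a stage-correlation matrix
#'
#' Reduces a stage-correlation matrix to its *equivalent-stage series*
#' (the correlations at matched developmental stages) and classifies its
#' shape:
#' * `"hourglass"` — the series peaks at an interior stage that exceeds
#'   both the first and last stage by at least the margin `m`
#'   (conservation maximal at mid-development);
#' * `"funnel"` — the series rises with developmental progression:
#'   positive Spearman trend over the zygotic stages, significant at
#'   `alpha` (one-sided);
#' * `"flat"` — total range of the series below `m`;
#' * `"mixed"` — anything else (e.g. superimposed hourglass and funnel
#'   contributions of different gene classes).
#'
#' The *diagonality index* is the fraction of reference stages whose
#' best-correlated target stage is their equivalent stage.
#'
#' @param corr a `StageCorrelation`.
#' @param equivalence two-column matrix/data.frame of matched stage
#'   indices (reference index, target index), e.g. from
#'   [equivalent_stages()]; >= 3 pairs required.
#' @param margin shape margin `m` in correlation units (default 0.05).
#' @param alpha significance level for the funnel trend test.
#' @param zygotic_stages indices *into the equivalence list* over which
#'   the funnel trend is assessed; the default drops the first (maternal,
#'   pre-zygotic) stage.
#' @return A `PatternSummary` list: `series`, `diagonality`, `peak_stage`
#'   (reference hpf of the series maximum), `trend_rho`, `trend_p`,
#'   `shape`, `margin`, `alpha`.
#' @export
pattern_summary <- function(corr, equivalence, margin = 0.05, alpha = 0.05,
                            zygotic_stages = NULL) {
  stopifnot(inherits(corr, "StageCorrelation"))
  eq <- as.matrix(equivalence)[, 1:2, drop = FALSE]
  if (nrow(eq) < 3) stop("need at least 3 equivalent stage pairs")
  cm <- corr$matrix
  series <- cm[eq]
  n <- length(series)
  best_b <- apply(cm[eq[, 1], , drop = FALSE], 1, which.max)
  diagonality <- mean(best_b == eq[, 2])
  ref_times <- suppressWarnings(as.numeric(rownames(cm)))[eq[, 1]]
  peak_idx <- which.max(series)
  if (is.null(zygotic_stages)) zygotic_stages <- seq_len(n)[-1]
  zyg <- series[zygotic_stages]
  tr <- suppressWarnings(
    cor.test(seq_along(zyg), zyg, method = "spearman", alternative = "greater"))
  shape <- if (peak_idx > 1 && peak_idx < n &&
               series[peak_idx] >= series[1] + margin &&
               series[peak_idx] >= series[n] + margin) {
    "hourglass"
  } else if (is.finite(tr$estimate) && tr$estimate > 0 && tr$p.value <= alpha) {
    "funnel"
  } else if (diff(range(series)) < margin) {
    "flat"
  } else {
    "mixed"
  }
  structure(list(series = series, diagonality = diagonality,
                 peak_stage = if (all(is.finite(ref_times))) ref_times[peak_idx] else peak_idx,
                 trend_rho = unname(tr$estimate), trend_p = tr$p.value,
                 shape = shape, margin = margin, alpha = alpha),
            class = "PatternSummary")
}

#' @export
print.PatternSummary <- function(x, ...) {
  cat(sprintf("PatternSummary: shape '%s', diagonality %.2f, peak at %s\n",
              x$shape, x$diagonality, format(x$peak_stage)))
  cat("equivalent-stage series:", paste(sprintf("%.3f", x$series), collapse = " "), "\n")
  invisible(x)
}
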