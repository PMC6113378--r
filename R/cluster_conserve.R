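# k-means clustering of temporal profiles, orthologue conservation calls
# and gene-class enrichment.

#' k-means clustering of temporal expression profiles
#'
#' Lloyd's algorithm with random-profile initialization: k measured gene
#' profiles are drawn as initial means, each gene is assigned to the
#' cluster with the nearest (Euclidean) mean, means are recomputed, and
#' the two steps repeat until no gene moves. The whole procedure is run
#' `n_restarts` times from sub-seeds derived deterministically from
#' `seed`; the lowest-inertia restart wins, ties broken by the
#' lexicographically smallest canonical assignment.
#'
#' @param profiles numeric matrix, genes x matched time points, typically
#'   percent-of-max normalized ([percent_of_max()]); rownames are gene ids.
#' @param k number of clusters, `1 <= k <= nrow(profiles)`. With about 7
#'   developmental stages, `k = 10` resolves the main temporal archetypes.
#' @param seed integer seed controlling all restarts.
#' @param n_restarts independent random initializations (default 20).
#' @param max_iter iteration cap per restart.
#' @return A `ClusteringResult` list: `k`, `centroids` (k x time matrix;
#'   each row is exactly the mean of its members), `assignments` (named
#'   integer vector, gene -> cluster), `inertia` (total within-cluster
#'   squared distance), `member_dist` (per-gene Euclidean distance to its
#'   centroid), `per_cluster_max_dist`, `sizes` and `converged`.
#' @details If a cluster empties during iteration its mean is re-seeded at
#'   the profile currently farthest from its own centroid (logged).
#' @export
kmeans_cluster <- function(profiles, k, seed = 1L, n_restarts = 20L,
                           max_iter = 100L) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles))) {
    rownames(profiles) <- paste0("g", seq_len(nrow(profiles)))
  }
  n <- nrow(profiles)
  if (k < 1 || k > n) stop("k must be between 1 and the number of genes (", n, ")")
  if (anyNA(profiles)) stop("profiles must not contain NA")
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max, n_restarts)
  best <- NULL
  for (s in sub_seeds) {
    res <- lloyd_once(profiles, k, s, max_iter)
    if (is.null(best) ||
        res$inertia < best$inertia - 1e-12 ||
        (abs(res$inertia - best$inertia) <= 1e-12 &&
         lexico_less(canonical_labels(res$assign), canonical_labels(best$assign)))) {
      best <- res
    }
  }
  assign <- canonical_labels(best$assign)
  centroids <- rowsum(profiles, assign) / as.vector(table(assign))
  rownames(centroids) <- NULL
  d <- sqrt(rowSums((profiles - centroids[assign, , drop = FALSE])^2))
  structure(list(
    k = as.integer(k),
    centroids = centroids,
    assignments = setNames(assign, rownames(profiles)),
    inertia = sum(d^2),
    member_dist = setNames(d, rownames(profiles)),
    per_cluster_max_dist = vapply(seq_len(max(assign)), function(j)
      if (any(assign == j)) max(d[assign == j]) else 0, numeric(1)),
    sizes = as.vector(table(factor(assign, levels = seq_len(max(assign))))),
    converged = best$converged
  ), class = "ClusteringResult")
}

lloyd_once <- function(x, k, sub_seed, max_iter) {
  set.seed(sub_seed)
  n <- nrow(x)
  centroids <- x[sample.int(n, k), , drop = FALSE]
  assign <- integer(n)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    d2 <- dist2_to_centroids(x, centroids)
    new_assign <- max.col(-d2, ties.method = "first")
    # re-seed emptied clusters at the profile farthest from its centroid
    repeat {
      empty <- setdiff(seq_len(k), unique(new_assign))
      if (length(empty) == 0) break
      cur <- sqrt(d2[cbind(seq_len(n), new_assign)])
      far <- which.max(cur)
      message("empty cluster re-seeded at profile ", rownames(x)[far])
      centroids[empty[1], ] <- x[far, ]
      d2 <- dist2_to_centroids(x, centroids)
      new_assign <- max.col(-d2, ties.method = "first")
    }
    if (identical(new_assign, assign)) {
      converged <- TRUE
      break
    }
    assign <- new_assign
    centroids <- rowsum(x, assign) / as.vector(table(assign))
  }
  d2 <- dist2_to_centroids(x, centroids)
  list(assign = assign, inertia = sum(d2[cbind(seq_len(n), assign)]),
       converged = converged)
}

dist2_to_centroids <- function(x, centroids) {
  d2 <- matrix(0, nrow(x), nrow(centroids))
  for (j in seq_len(nrow(centroids))) {
    d2[, j] <- rowSums(sweep(x, 2, centroids[j, ])^2)
  }
  d2
}

# relabel clusters in order of first appearance
canonical_labels <- function(assign) {
  match(assign, unique(assign))
}

lexico_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

#' @export
print.ClusteringResult <- function(x, ...) {
  cat(sprintf("ClusteringResult: k=%d, %d genes, inertia %.4g%s\n",
              x$k, length(x$assignments), x$inertia,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Per-cluster conservation cutoffs
#'
#' The divergence cutoff is anchored in the reference species itself:
#' by default it is the maximal distance of any reference-species member
#' from its own cluster centroid ("max" rule). Alternatives: a per-cluster
#' quantile of member distances (`"quantile:q"`, e.g. `"quantile:0.95"`) or
#' a single global maximum (`"global_max"`).
#'
#' @param result a `ClusteringResult`.
#' @param rule cutoff rule string.
#' @return Numeric vector of length `k` of cutoff distances.
#' @export
conservation_cutoff <- function(result, rule = "max") {
  stopifnot(inherits(result, "ClusteringResult"))
  if (!result$converged) warning("clustering did not converge; cutoffs unreliable")
  if (identical(rule, "max")) {
    return(result$per_cluster_max_dist)
  }
  if (identical(rule, "global_max")) {
    return(rep(max(result$per_cluster_max_dist), result$k))
  }
  m <- regmatches(rule, regexec("^quantile:([0-9.]+)$", rule))[[1]]
  if (length(m)) {
    q <- as.numeric(m[2])
    if (!is.finite(q) || q < 0 || q > 1) stop("quantile must be in [0, 1]")
    return(vapply(seq_len(result$k), function(j) {
      d <- result$member_dist[result$assignments == j]
      if (length(d)) unname(quantile(d, q)) else 0
    }, numeric(1)))
  }
  stop("unknown cutoff rule: ", rule)
}

#' Classify orthologues as conserved or diverged
#'
#' Genes are first clustered by their expression kinetics in the reference
#' species A; each orthologue's profile in species B (resampled onto the
#' equivalent scaled time grid and percent-of-max normalized) is then
#' compared against A's clustering. Under `method = "distance"` a pair is
#' *conserved* when the Euclidean distance of the B profile from the A
#' cluster centroid of its partner is at most that cluster's cutoff, and
#' *diverged* otherwise. Under `method = "membership"` the B profile is
#' assigned to its nearest A centroid and the pair is conserved when that
#' cluster equals the partner's.
#'
#' @param result_a `ClusteringResult` for the reference species.
#' @param profiles_b matrix of target-species profiles (genes x time
#'   points) on the same grid as the centroids; rownames are target ids.
#' @param ortholog_map data.frame with columns `ref`, `target` (see
#'   [read_ortholog_map()]); every pair whose ref gene was clustered and
#'   whose target profile is present receives exactly one call.
#' @param method `"distance"` (default) or `"membership"`.
#' @param cutoff_rule passed to [conservation_cutoff()] (distance method).
#' @return data.frame of `ConservationCall`s: `ref_id`, `target_id`,
#'   `cluster`, `distance`, `cutoff`, `label` (`"conserved"`/`"diverged"`),
#'   `method`.
#' @export
classify_conservation <- function(result_a, profiles_b, ortholog_map,
                                  method = c("distance", "membership"),
                                  cutoff_rule = "max") {
  method <- match.arg(method)
  stopifnot(inherits(result_a, "ClusteringResult"))
  profiles_b <- as.matrix(profiles_b)
  if (ncol(profiles_b) != ncol(result_a$centroids)) {
    stop("time-grid mismatch: centroids have ", ncol(result_a$centroids),
         " stages, target profiles ", ncol(profiles_b))
  }
  map <- data.frame(ref = as.character(ortholog_map[[1]]),
                    target = as.character(ortholog_map[[2]]),
                    stringsAsFactors = FALSE)
  keep <- map$ref %in% names(result_a$assignments) &
    map$target %in% rownames(profiles_b)
  if (any(!keep)) {
    warning(sum(!keep), " pair(s) without clustered/target profile dropped")
  }
  map <- map[keep, , drop = FALSE]
  if (nrow(map) == 0) stop("no orthologue pairs to classify")
  cl <- unname(result_a$assignments[map$ref])
  bmat <- profiles_b[map$target, , drop = FALSE]
  dist_to_own <- sqrt(rowSums((bmat - result_a$centroids[cl, , drop = FALSE])^2))
  if (method == "distance") {
    cutoffs <- conservation_cutoff(result_a, cutoff_rule)
    cut <- cutoffs[cl]
    label <- ifelse(dist_to_own <= cut, "conserved", "diverged")
  } else {
    d2 <- dist2_to_centroids(bmat, result_a$centroids)
    nearest <- max.col(-d2, ties.method = "first")
    cut <- NA_real_
    label <- ifelse(nearest == cl, "conserved", "diverged")
  }
  data.frame(ref_id = map$ref, target_id = map$target, cluster = cl,
             distance = dist_to_own, cutoff = cut, label = label,
             method = method, stringsAsFactors = FALSE)
}

#' Gene-class over-representation in a gene set
#'
#' Hypergeometric over-representation test of each class label within a
#' target gene set (e.g. the conserved genes of one cluster) against a
#' background (all clustered genes), standing in for GO enrichment when
#' the user supplies their own class labels. P-values are
#' Benjamini-Hochberg adjusted across classes.
#'
#' @param target character vector of target gene ids.
#' @param background character vector of background gene ids (must be
#'   non-empty; target genes outside it are dropped with a warning).
#' @param labels data.frame with columns `gene_id`, `class`
#'   (see [read_gene_classes()]).
#' @return data.frame, one row per class present in the background:
#'   `class`, `n_target`, `n_target_in`, `n_background`,
#'   `n_background_in`, `p_value`, `p_adjust`, sorted by p-value. Empty
#'   (with a warning) when no target gene carries a label.
#' @export
class_enrichment <- function(target, background, labels) {
  if (length(background) == 0) stop("empty background set")
  target <- unique(as.character(target))
  background <- unique(as.character(background))
  out_of_bg <- setdiff(target, background)
  if (length(out_of_bg)) {
    warning(length(out_of_bg), " target gene(s) outside background dropped")
    target <- intersect(target, background)
  }
  lab <- setNames(labels$class, labels$gene_id)[background]
  classes <- sort(unique(lab[!is.na(lab)]))
  if (length(classes) == 0 || all(is.na(lab[target]))) {
    warning("no class labels on the target set; empty enrichment table")
    return(data.frame(class = character(), n_target = integer(),
                      n_target_in = integer(), n_background = integer(),
                      n_background_in = integer(), p_value = numeric(),
                      p_adjust = numeric()))
  }
  N <- length(background)
  n <- length(target)
  rows <- lapply(classes, function(cl) {
    K <- sum(lab == cl, na.rm = TRUE)
    x <- sum(lab[target] == cl, na.rm = TRUE)
    data.frame(class = cl, n_target = n, n_target_in = x,
               n_background = N, n_background_in = K,
               p_value = phyper(x - 1, K, N - K, n, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  out$p_adjust <- p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), , drop = FALSE]
}
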