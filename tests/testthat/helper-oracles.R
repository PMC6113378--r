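# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

# closed-form ordinary least squares via the normal equations
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  c(intercept = intercept, slope = slope)
}

# brute-force sigmoid fit: grid over the nonlinear parameters (c, t_i),
# exact linear least squares for (a, b) at each grid point
oracle_grid_sigmoid <- function(t, y, c_grid = c(0.25, 0.5, 1, 2, 4),
                                ti_grid = seq(0, 20, by = 0.1)) {
  best <- NULL
  for (cc in c_grid) {
    for (ti in ti_grid) {
      s <- 1 / (1 + exp(cc * (t - ti)))
      X <- cbind(1, -s)
      ab <- solve(crossprod(X), crossprod(X, y))
      rss <- sum((X %*% ab - y)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(a = ab[1], b = ab[2], c = cc, t_i = ti, rss = rss)
      }
    }
  }
  best
}

# all partitions of n items into at most k non-empty blocks, as
# restricted-growth strings
enumerate_partitions <- function(n, k) {
  out <- list()
  recurse <- function(assign, used) {
    i <- length(assign) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- assign
      return()
    }
    for (j in seq_len(min(used + 1, k))) {
      recurse(c(assign, j), max(used, j))
    }
  }
  recurse(integer(0), 0L)
  out
}

# global minimum within-cluster sum of squares by exhaustive enumeration
oracle_min_inertia <- function(x, k) {
  parts <- enumerate_partitions(nrow(x), k)
  best <- NULL
  inertias <- numeric(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    inertia <- 0
    for (j in unique(p)) {
      xs <- x[p == j, , drop = FALSE]
      inertia <- inertia + sum(sweep(xs, 2, colMeans(xs))^2)
    }
    inertias[i] <- inertia
    if (is.null(best) || inertia < best$inertia) {
      best <- list(inertia = inertia, assign = p)
    }
  }
  best$n_ties <- sum(inertias <= best$inertia + 1e-9)
  best
}

# type-7 sample quantile from an explicit sort
oracle_quantile <- function(x, q) {
  xs <- sort(unname(x))
  h <- (length(xs) - 1) * q
  lo <- floor(h)
  xs[lo + 1] + (h - lo) * (xs[min(lo + 2, length(xs))] - xs[lo + 1])
}

# hypergeometric upper tail P(X >= x) by direct summation over the support
oracle_hyper_tail <- function(x, K, N, n) {
  i <- x:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# explicit product-moment correlation
oracle_pearson <- function(u, v) {
  du <- u - mean(u); dv <- v - mean(v)
  sum(du * dv) / sqrt(sum(du^2) * sum(dv^2))
}

# Spearman: average ranks, then the product-moment formula
oracle_spearman <- function(u, v) {
  oracle_pearson(rank(u, ties.method = "average"),
                 rank(v, ties.method = "average"))
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  (si - expected) / ((sa + sb) / 2 - expected)
}

canonical_partition <- function(p) match(p, unique(p))
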