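# Sigmoidal activation kinetics: model, least-squares fitting, initiation
# (half-rise) time extraction.

#' Four-parameter activation-sigmoid parameters
#'
#' Zygotic gene activation in log expression is modelled as
#' \deqn{\log mRNA(t) = a - \frac{b}{1 + e^{c (t - t_i)}}}
#' where `a` is the final (plateau) log level, `b` the total log-scale rise
#' above the basal level (the t -> -Inf asymptote is `a - b`), `c` the
#' slope (per hour), and `t_i` the *initiation time*: the half-rise time at
#' which log expression equals `a - b/2`.
#'
#' @param a final log-expression level.
#' @param b total rise in log units; activation fits require `b >= 0`.
#' @param c slope, per hour; activation fits require `c > 0`.
#' @param t_i initiation (half-rise) time, hpf.
#' @return Object of class `sigmoid_params`.
#' @export
#' @examples
#' p <- sigmoid_params(a = 0.8, b = 0.6, c = 1, t_i = 8)
#' sigmoid_eval(p, 8)  # half-rise: a - b/2 = 0.5
sigmoid_params <- function(a, b, c, t_i) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c), is.finite(t_i))
  structure(list(a = a, b = b, c = c, t_i = t_i), class = "sigmoid_params")
}

#' @export
print.sigmoid_params <- function(x, ...) {
  cat(sprintf("sigmoid: a=%.4g b=%.4g c=%.4g t_i=%.4g hpf\n",
              x$a, x$b, x$c, x$t_i))
  invisible(x)
}

#' Evaluate the activation sigmoid
#'
#' @param params a [sigmoid_params()] object (or list with `a,b,c,t_i`).
#' @param t time(s) in hpf; any finite value.
#' @return `a - b / (1 + exp(c * (t - t_i)))`, vectorised over `t`. For
#'   `c > 0` this approaches `a` as `t -> Inf` and `a - b` as `t -> -Inf`;
#'   at `t = t_i` it is exactly `a - b/2`.
#' @export
sigmoid_eval <- function(params, t) {
  params$a - params$b * stats::plogis(-params$c * (t - params$t_i))
}

sigmoid_rss <- function(par, t, y) {
  f <- par[1] - par[2] * stats::plogis(-par[3] * (t - par[4]))
  sum((f - y)^2)
}

sigmoid_rss_grad <- function(par, t, y) {
  s <- stats::plogis(-par[3] * (t - par[4]))   # 1/(1+e^{c(t-ti)})
  f <- par[1] - par[2] * s
  r <- f - y
  ds <- s * (1 - s)
  c(2 * sum(r),
    -2 * sum(r * s),
    2 * par[2] * sum(r * ds * (t - par[4])),
    -2 * par[2] * par[3] * sum(r * ds))
}

# (a, b, c, ti) with c < 0 describes the same curve as
# (a - b, -b, -c, ti); canonicalise to c > 0 so the sign of b alone
# distinguishes rising from decaying kinetics.
canonical_sigmoid <- function(par) {
  if (par[3] < 0) par <- c(par[1] - par[2], -par[2], -par[3], par[4])
  par
}

#' Fit the activation sigmoid to one gene's log-expression series
#'
#' Least-squares fit of the four-parameter sigmoid by quasi-Newton
#' minimisation from a fixed deterministic grid of 12 starts
#' (`c` in 0.3/1/3 times the natural slope scale, `t_i` at the 20/40/60/80%
#' quantiles of the time window); the start with the lowest refined RSS
#' wins, ties broken by smallest `t_i`. Replicates enter as repeated
#' `(t, y)` points so replicate scatter informs the RSS.
#'
#' @param t time points, hpf (repeated values allowed for replicates).
#' @param y log-expression values, same length as `t`.
#' @param rise_threshold minimal fitted rise `b` (natural-log units) to
#'   call a gene "activated"; the default 0.5 is about a 1.65-fold rise.
#' @return A `FitReport` list: `classification` (one of `"activated"`,
#'   `"flat"`, `"decaying"`, `"unfit"`), `rss`, `converged`, `params` (a
#'   [sigmoid_params()], present only for `"activated"` fits) and `coef`
#'   (raw canonical estimates, for diagnostics).
#' @details Classification: `"activated"` requires fitted rise
#'   `b >= rise_threshold`, slope `c > 0`, and `t_i` inside the observed
#'   window extended by one sampling interval; `"decaying"` is a fitted
#'   *drop* of at least the threshold (maternal transcripts); `"flat"` is a
#'   fitted |rise| below threshold (or a constant series); anything else,
#'   including an activation-shaped fit whose `t_i` falls outside the
#'   extended window, is `"unfit"`.
#' @export
fit_sigmoid <- function(t, y, rise_threshold = 0.5) {
  stopifnot(length(t) == length(y))
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  ut <- sort(unique(t))
  if (length(ut) < 5) stop("need at least 5 distinct time points, got ", length(ut))
  if (diff(range(y)) < 1e-12) {
    return(list(classification = "flat", rss = 0, converged = TRUE,
                params = NULL, coef = NULL))
  }
  span <- diff(range(ut))
  a0 <- max(y)
  b0 <- max(diff(range(y)), 1e-3)
  # natural slope scale: a rise spread over ~1/4 of the window
  c_scale <- 4 / span
  starts <- expand.grid(c = c(0.3, 1, 3) * c_scale,
                        t_i = unname(quantile(ut, c(0.2, 0.4, 0.6, 0.8))))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(c(a0, b0, starts$c[i], starts$t_i[i]), sigmoid_rss,
            gr = sigmoid_rss_grad, t = t, y = y, method = "BFGS",
            control = list(maxit = 200, reltol = 1e-9)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cand <- list(par = canonical_sigmoid(fit$par), rss = fit$value,
                 conv = fit$convergence == 0)
    if (is.null(best) || cand$rss < best$rss - 1e-10 ||
        (abs(cand$rss - best$rss) <= 1e-10 && cand$par[4] < best$par[4])) {
      best <- cand
    }
  }
  if (is.null(best)) {
    return(list(classification = "unfit", rss = NA_real_, converged = FALSE,
                params = NULL, coef = NULL))
  }
  # polish the winning start to tight tolerance
  polish <- tryCatch(
    optim(best$par, sigmoid_rss, gr = sigmoid_rss_grad, t = t, y = y,
          method = "BFGS", control = list(maxit = 1000, reltol = 1e-14)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$rss) {
    best <- list(par = canonical_sigmoid(polish$par), rss = polish$value,
                 conv = polish$convergence == 0)
  }
  par <- best$par
  interval <- median(diff(ut))
  in_window <- par[4] >= min(ut) - interval && par[4] <= max(ut) + interval
  cls <- if (par[2] >= rise_threshold && par[3] > 0 && in_window) {
    "activated"
  } else if (par[2] <= -rise_threshold) {
    "decaying"
  } else if (abs(par[2]) < rise_threshold) {
    "flat"
  } else {
    "unfit"
  }
  coef <- c(a = par[1], b = par[2], c = par[3], t_i = par[4])
  list(classification = cls,
       rss = best$rss,
       converged = best$conv,
       params = if (cls == "activated")
         sigmoid_params(par[1], par[2], par[3], par[4]) else NULL,
       coef = coef)
}

#' Initiation times for a set of genes
#'
#' Applies [fit_sigmoid()] to each requested gene of an expression matrix.
#' Linear values are log-transformed internally with a pseudocount
#' `eps = max(1e-6, smallest positive value / 10)`; replicate measurements
#' enter the fit jointly as repeated time points. Genes with more than 25%
#' missing cells are excluded (see [complete_genes()]).
#'
#' @param x an `ExpressionMatrix` of linear-scale values.
#' @param genes character vector of gene ids to fit; `NULL` for all.
#' @param rise_threshold passed to [fit_sigmoid()].
#' @return data.frame with one row per requested gene: `gene_id`, fitted
#'   `a`, `b`, `c`, `t_i` (`NA` unless classified `"activated"`), `rss` and
#'   `classification`.
#' @export
initiation_times_batch <- function(x, genes = NULL, rise_threshold = 0.5) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  keep <- complete_genes(x)
  if (is.null(genes)) genes <- keep
  genes <- as.character(genes)
  if (length(genes) == 0) stop("empty gene subset")
  missing <- setdiff(genes, gene_ids(x))
  if (length(missing)) stop("unknown gene id(s): ", paste(missing, collapse = ", "))
  pos <- x$values[x$values > 0 & !is.na(x$values)]
  eps <- max(1e-6, if (length(pos)) min(pos) / 10 else 1e-6)
  rows <- lapply(genes, function(g) {
    if (!g %in% keep) {
      return(data.frame(gene_id = g, a = NA_real_, b = NA_real_, c = NA_real_,
                        t_i = NA_real_, rss = NA_real_,
                        classification = "unfit"))
    }
    yv <- x$values[g, ]
    ok <- !is.na(yv)
    rep <- fit_sigmoid(x$col_time[ok], log(yv[ok] + eps),
                       rise_threshold = rise_threshold)
    cf <- rep$coef %||% c(a = NA_real_, b = NA_real_, c = NA_real_, t_i = NA_real_)
    data.frame(gene_id = g,
               a = if (rep$classification == "activated") cf[["a"]] else NA_real_,
               b = if (rep$classification == "activated") cf[["b"]] else NA_real_,
               c = if (rep$classification == "activated") cf[["c"]] else NA_real_,
               t_i = if (rep$classification == "activated") cf[["t_i"]] else NA_real_,
               rss = rep$rss,
               classification = rep$classification)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Recommended sampling interval for a developmental time course
#'
#' Accurate initiation-time fitting needs sampling intervals short enough
#' to resolve the activation dynamics; the rule of thumb is one tenth of
#' the developmental window studied (e.g. 3 h for a 30 hpf window, 4.8 h
#' for 48 hpf).
#'
#' @param total_duration_h length of the developmental window, hours.
#' @return Recommended interval in hours (`total_duration_h / 10`).
#' @export
recommend_sampling_interval <- function(total_duration_h) {
  if (!is.numeric(total_duration_h) || any(total_duration_h <= 0)) {
    stop("duration must be positive")
  }
  total_duration_h / 10
}
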