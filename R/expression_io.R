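# Expression matrices, orthologue maps and gene-class labels: constructors,
# validation, delimited-text I/O and orthologue alignment.

#' Construct an ExpressionMatrix
#'
#' An `ExpressionMatrix` holds one species' expression time course: a
#' genes-by-measurement matrix of non-negative linear-scale values (counts,
#' TPM, QPCR or nanostring levels), where each measurement column is one
#' (time point, replicate) combination. Time is in hours post fertilization
#' (hpf).
#'
#' @param values numeric matrix, genes in rows (rownames are gene ids),
#'   measurement columns. Values must be non-negative; `NA` marks missing
#'   cells.
#' @param timepoints numeric vector of length `ncol(values)` giving the hpf
#'   of each column.
#' @param species free-text species label.
#' @param replicates optional character/integer vector of per-column
#'   replicate labels; `NULL` means one unreplicated column per time point.
#' @return An object of class `ExpressionMatrix` with fields `species`,
#'   `values`, `col_time`, `col_rep` and `timepoints` (sorted unique hpf).
#' @details Columns are stored sorted by (time, replicate); unsorted input
#'   columns are reordered with a warning. Gene ids must be unique and
#'   non-empty, time points non-negative and finite.
#' @export
#' @examples
#' m <- expression_matrix(
#'   matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), NULL)),
#'   timepoints = c(0, 6, 12), species = "demo"
#' )
#' m
expression_matrix <- function(values, timepoints, species = "", replicates = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  ids <- rownames(values)
  if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids)) {
    stop("gene ids (rownames) must be present and non-empty")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) != ncol(values)) {
    stop("'timepoints' must give one hpf value per column")
  }
  if (anyNA(timepoints) || any(!is.finite(timepoints)) || any(timepoints < 0)) {
    stop("time points must be finite, non-negative hpf values")
  }
  if (is.null(replicates)) {
    replicates <- rep(NA_character_, ncol(values))
  } else {
    replicates <- as.character(replicates)
    if (length(replicates) != ncol(values)) {
      stop("'replicates' must give one label per column")
    }
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("expression values must be non-negative (linear scale)")
  }
  ord <- order(timepoints, replicates)
  if (is.unsorted(timepoints)) {
    warning("time columns were not sorted; reordering by hpf")
  }
  values <- values[, ord, drop = FALSE]
  timepoints <- timepoints[ord]
  replicates <- replicates[ord]
  colnames(values) <- ifelse(is.na(replicates),
                             paste0("t", format_hpf(timepoints)),
                             paste0("t", format_hpf(timepoints), "_r", replicates))
  structure(
    list(species = as.character(species)[1],
         values = values,
         col_time = timepoints,
         col_rep = replicates,
         timepoints = sort(unique(timepoints))),
    class = "ExpressionMatrix"
  )
}

# shortest decimal representation that still round-trips the double
format_hpf <- function(t) {
  vapply(t, function(x) {
    s <- format(x, digits = 15, scientific = FALSE)
    if (as.numeric(s) != x) s <- sprintf("%.17g", x)
    s
  }, character(1))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  nrep <- length(unique(x$col_rep[!is.na(x$col_rep)]))
  cat(sprintf(
    "ExpressionMatrix '%s': %d genes x %d time points (%s hpf)%s\n",
    x$species, nrow(x$values), length(x$timepoints),
    paste(sprintf("%.4g", range(x$timepoints)), collapse = "-"),
    if (nrep > 0) sprintf(", %d replicates", nrep) else ""
  ))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene identifiers of an ExpressionMatrix
#' @param x an `ExpressionMatrix`.
#' @return Character vector of gene ids (row order).
#' @export
gene_ids <- function(x) rownames(x$values)

#' Read an expression matrix from delimited text
#'
#' Expects a header row with a gene-id column first and measurement columns
#' named `t<hpf>` or `t<hpf>_r<rep>` (hpf as decimal hours, e.g. `t6`,
#' `t4.5_r2`), one gene per row. `NA` (or empty) cells mark missing values.
#'
#' @param path file path; `.csv` is comma-separated, anything else
#'   tab-separated unless `sep` is given.
#' @param species species label to attach (defaults to the file base name).
#' @param sep field separator; `NULL` to infer from the extension.
#' @return A validated [expression_matrix()]. A message reports the number
#'   of genes, time points and replicates parsed.
#' @export
read_expression_table <- function(path, species = NULL, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", na.strings = c("NA", ""))
  if (ncol(raw) < 2) stop("expected a gene-id column plus measurement columns")
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  heads <- colnames(raw)[-1]
  parsed <- parse_time_headers(heads)
  vals <- matrix(NA_real_, nrow(raw), length(heads),
                 dimnames = list(ids, heads))
  for (j in seq_along(heads)) {
    col <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at gene '%s', column '%s'",
                   col[bad[1]], ids[bad[1]], heads[j]))
    }
    vals[, j] <- num
  }
  m <- expression_matrix(vals, parsed$time, species %||% basename(path),
                         replicates = parsed$rep)
  nrep <- length(unique(m$col_rep[!is.na(m$col_rep)]))
  message(sprintf("read %d genes, %d time points, %d replicate(s) from %s",
                  nrow(m$values), length(m$timepoints), max(nrep, 1L), path))
  m
}

parse_time_headers <- function(heads) {
  m <- regmatches(heads, regexec("^t([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)(?:_r(.+))?$", heads))
  bad <- vapply(m, length, 1L) == 0
  if (any(bad)) {
    stop("cannot parse time header(s): ", paste(heads[bad], collapse = ", "),
         " (expected 't<hpf>' or 't<hpf>_r<rep>')")
  }
  list(time = vapply(m, function(p) as.numeric(p[2]), numeric(1)),
       rep = vapply(m, function(p) if (nzchar(p[3])) p[3] else NA_character_,
                    character(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an ExpressionMatrix to delimited text
#'
#' Values are written with enough digits to round-trip doubles exactly, so
#' `read_expression_table(write_expression_table(x, f))` reproduces `x`
#' bit-identically.
#'
#' @param x an `ExpressionMatrix`.
#' @param path output file; `.csv` gets commas, else tabs.
#' @param sep field separator; `NULL` to infer from the extension.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- apply(x$values, 2, function(col)
    ifelse(is.na(col), "NA", vapply(col, format_hpf, character(1))))
  out <- cbind(gene_id = rownames(x$values), out)
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a two-column orthologue map
#'
#' @param path TSV with two columns (reference-species gene id,
#'   target-species gene id); a header row is detected and skipped if the
#'   first line matches common header words.
#' @return data.frame with columns `ref` and `target`.
#' @export
read_ortholog_map <- function(path) {
  df <- read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("orthologue map must have two columns")
  if (tolower(df[1, 1]) %in% c("ref", "gene_a", "reference", "gene_id_a")) {
    df <- df[-1, , drop = FALSE]
  }
  data.frame(ref = df[[1]], target = df[[2]], stringsAsFactors = FALSE)
}

#' Read gene-class labels
#'
#' @param path TSV with two columns: gene id, class label (free text such
#'   as `"developmental"`, `"ribosomal"`, `"environmental"`).
#' @return data.frame with columns `gene_id` and `class`.
#' @export
read_gene_classes <- function(path) {
  df <- read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("class-label table must have two columns")
  if (tolower(df[1, 1]) %in% c("gene_id", "gene", "id")) df <- df[-1, , drop = FALSE]
  out <- data.frame(gene_id = df[[1]], class = df[[2]], stringsAsFactors = FALSE)
  if (any(!nzchar(out$class)) || anyNA(out$class)) stop("class labels must be non-empty")
  out
}

#' Align two expression matrices on orthologue pairs
#'
#' Restricts both matrices to genes related by the map, in matched row
#' order: row i of the returned reference matrix is the orthologue of row i
#' of the returned target matrix. Many-to-many map entries are dropped:
#' only pairs in which both gene ids occur exactly once in the map are
#' kept (the analysis is framed per one-to-one orthologue pair). Pairs
#' referencing ids absent from either matrix are dropped with a warning.
#'
#' @param a,b `ExpressionMatrix` objects for the two species.
#' @param map data.frame as from [read_ortholog_map()] (columns `ref` for
#'   species `a`, `target` for species `b`).
#' @return list with elements `a`, `b` (row-aligned `ExpressionMatrix`
#'   objects) and `pairs` (the retained map rows).
#' @export
align_orthologs <- function(a, b, map) {
  stopifnot(inherits(a, "ExpressionMatrix"), inherits(b, "ExpressionMatrix"))
  map <- data.frame(ref = as.character(map[[1]]),
                    target = as.character(map[[2]]),
                    stringsAsFactors = FALSE)
  one2one <- !(map$ref %in% map$ref[duplicated(map$ref)]) &
    !(map$target %in% map$target[duplicated(map$target)])
  n_m2m <- sum(!one2one)
  if (n_m2m > 0) {
    message(n_m2m, " many-to-many map entr(ies) dropped; keeping one-to-one pairs")
  }
  map <- map[one2one, , drop = FALSE]
  present <- map$ref %in% gene_ids(a) & map$target %in% gene_ids(b)
  if (any(!present)) {
    warning(sum(!present), " pair(s) referenced absent gene id(s) and were dropped")
  }
  map <- map[present, , drop = FALSE]
  if (nrow(map) == 0) stop("no orthologue pairs remain after alignment")
  message(nrow(map), " orthologue pair(s) aligned (",
          nrow(a$values) - nrow(map), " unmapped in ", a$species, ", ",
          nrow(b$values) - nrow(map), " in ", b$species, ")")
  list(
    a = expression_matrix(a$values[map$ref, , drop = FALSE], a$col_time,
                          a$species, a$col_rep),
    b = expression_matrix(b$values[map$target, , drop = FALSE], b$col_time,
                          b$species, b$col_rep),
    pairs = map
  )
}

#' Average replicate columns into one profile per time point
#'
#' @param x an `ExpressionMatrix`.
#' @return numeric matrix, genes x time points (colnames are hpf), replicate
#'   mean on the linear scale with `NA` cells ignored.
#' @export
collapse_replicates <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  grp <- match(x$col_time, x$timepoints)
  out <- vapply(seq_along(x$timepoints), function(i)
    rowMeans(x$values[, grp == i, drop = FALSE], na.rm = TRUE),
    numeric(nrow(x$values)))
  out <- matrix(out, nrow = nrow(x$values),
                dimnames = list(rownames(x$values), format_hpf(x$timepoints)))
  out[is.nan(out)] <- NA_real_
  out
}

#' Drop genes with too many missing cells
#'
#' Genes with more than `max_na_frac` of their measurement columns missing
#' are excluded from curve fitting and clustering; the count is logged.
#'
#' @param x an `ExpressionMatrix`.
#' @param max_na_frac maximum tolerated fraction of `NA` cells per gene.
#' @return Character vector of retained gene ids.
#' @export
complete_genes <- function(x, max_na_frac = 0.25) {
  frac <- rowMeans(is.na(x$values))
  drop <- frac > max_na_frac
  if (any(drop)) {
    message(sum(drop), " gene(s) excluded (>", round(100 * max_na_frac),
            "% missing values)")
  }
  rownames(x$values)[!drop]
}

#' Read a plain-text run configuration
#'
#' One `key: value` pair per line; blank lines and `#` comments ignored.
#' Values that parse as numbers are returned numeric.
#'
#' @param path configuration file.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^:]+):(.*)$", ln))[[1]]
    if (length(kv) == 0) stop("malformed config line: ", ln)
    key <- trimws(kv[2]); val <- trimws(kv[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
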