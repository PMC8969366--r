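# Count-to-expression conversion and normalization.
#
# The expression pipeline mirrors the standard voom-based workflow: raw
# counts are converted to log2CPM with a prior count of 0.5 added to the
# counts and 1 added to the (scaled) library sizes, optionally quantile
# normalized on the log scale, or scaled by TMM factors, and converted to
# log2FPKM by subtracting log2(effective length / 1000).

#' Counts per million
#'
#' `value = (count + prior) / library_size * 1e6`, with library sizes taken
#' from the count matrix (assigned totals by default).
#'
#' @param x A [count_matrix] or integer matrix with dimnames.
#' @param prior Prior count added to the raw counts (default 0; the
#'   expression filter uses prior 0).
#' @param lib_sizes Optional explicit library sizes (named or in column
#'   order).
#' @return Numeric matrix of CPM values.
#' @export
cpm <- function(x, prior = 0, lib_sizes = NULL) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  ls <- lib_sizes %||% if (inherits(x, "count_matrix")) library_sizes(x) else colSums(m)
  if (any(ls <= 0)) {
    abort(sprintf("library '%s' has zero library size",
                  colnames(m)[which(ls <= 0)[1]]))
  }
  t(t(m + prior) / ls) * 1e6
}

#' Expression matrix container
#'
#' Genes-by-libraries real-valued expression tagged with its scale
#' (`log2CPM` or `log2FPKM`) and normalization method.
#'
#' @param values Numeric matrix with gene rownames and library colnames.
#' @param scale `"log2CPM"` or `"log2FPKM"`.
#' @param normalization `"library_size"`, `"quantile"` or `"TMM"`.
#' @param prior Prior count used in the log transform.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, scale = c("log2CPM", "log2FPKM"),
                              normalization = c("library_size", "quantile", "TMM"),
                              prior = 0.5) {
  scale <- match.arg(scale)
  normalization <- match.arg(normalization)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("expression matrix must have gene rownames and library colnames")
  }
  structure(list(values = values),
            scale = scale, normalization = normalization, prior = prior,
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d libraries [%s, %s normalized, prior %.3g]\n",
              nrow(x$values), ncol(x$values), attr(x, "scale"),
              attr(x, "normalization"), attr(x, "prior")))
  invisible(x)
}

#' @describeIn expression_matrix Long tidy view (`gene_id`, `library_id`,
#'   `expression`).
#' @param x An `expression_matrix`.
#' @param ... Unused.
#' @method tidy expression_matrix
#' @export
tidy.expression_matrix <- function(x, ...) {
  as_tibble(x$values, rownames = "gene_id") |>
    pivot_longer(-"gene_id", names_to = "library_id", values_to = "expression")
}

#' voom-style log2 counts per million
#'
#' `value = log2((count + prior) / (library_size * factor + 1) * 1e6)`, the
#' transform applied by voom. With all factors equal to 1 this is plain
#' library-size normalization. A plain variant without the +1 library-size
#' offset is available via `voom_offset = FALSE`.
#'
#' @param x A [count_matrix] or integer matrix.
#' @param factors Optional per-library normalization factors (e.g. from
#'   [tmm_factors()]); default all 1.
#' @param prior Prior count (default 0.5).
#' @param lib_sizes Optional explicit library sizes.
#' @param voom_offset Add 1 to the scaled library sizes (default TRUE,
#'   matching voom).
#' @param normalization Normalization tag recorded on the result.
#' @return An [expression_matrix] on the log2CPM scale.
#' @export
log2cpm <- function(x, factors = NULL, prior = 0.5, lib_sizes = NULL,
                    voom_offset = TRUE,
                    normalization = if (is.null(factors)) "library_size" else "TMM") {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  ls <- lib_sizes %||% if (inherits(x, "count_matrix")) library_sizes(x) else colSums(m)
  if (any(ls <= 0)) {
    abort(sprintf("library '%s' has zero library size",
                  colnames(m)[which(ls <= 0)[1]]))
  }
  f <- factors %||% rep(1, ncol(m))
  if (any(f <= 0)) abort("normalization factors must be positive")
  denom <- ls * f + if (voom_offset) 1 else 0
  vals <- log2(t(t(m + prior) / denom) * 1e6)
  expression_matrix(vals, scale = "log2CPM", normalization = normalization,
                    prior = prior)
}

#' Convert log2CPM to log2FPKM
#'
#' `log2FPKM = log2CPM - log2(effective_length / 1000)`.
#'
#' @param x An [expression_matrix] on the log2CPM scale.
#' @param lengths Gene effective lengths: a tibble
#'   (`gene_id`, `effective_length`) as returned by [effective_lengths()],
#'   or a named numeric vector.
#' @return An [expression_matrix] on the log2FPKM scale.
#' @export
log2fpkm <- function(x, lengths) {
  if (attr(x, "scale") != "log2CPM") abort("log2fpkm expects a log2CPM matrix")
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$effective_length, lengths$gene_id)
  }
  miss <- setdiff(rownames(x$values), names(lengths))
  if (length(miss)) {
    abort(sprintf("no effective length for gene '%s'", miss[1]))
  }
  len <- lengths[rownames(x$values)]
  vals <- x$values - log2(len / 1000)
  out <- expression_matrix(vals, scale = "log2FPKM",
                           normalization = attr(x, "normalization"),
                           prior = attr(x, "prior"))
  out
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors (Robinson & Oshlack), as computed
#' by edgeR's `calcNormFactors`: the reference library is the one whose
#' upper-quartile CPM is closest to the mean upper-quartile; each library's
#' factor is 2 to the weighted trimmed mean of the M values against the
#' reference (trimming `logratio_trim` of M and `abs_trim` of A, weights the
#' inverse asymptotic binomial variances), rescaled so the factors have
#' geometric mean 1.
#'
#' @param x A [count_matrix] or integer matrix (>= 2 libraries, not all
#'   zero).
#' @param logratio_trim Fraction of M values trimmed from each tail
#'   (default 0.3).
#' @param abs_trim Fraction of A values trimmed from each tail
#'   (default 0.05).
#' @return Named numeric vector of per-library factors, geometric mean 1.
#' @export
tmm_factors <- function(x, logratio_trim = 0.3, abs_trim = 0.05) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (ncol(m) < 2) abort("TMM needs at least two libraries")
  if (all(m == 0)) abort("TMM is undefined when all counts are zero")
  f <- edgeR::calcNormFactors(m, method = "TMM",
                              logratioTrim = logratio_trim,
                              sumTrim = abs_trim)
  setNames(as.numeric(f), colnames(m))
}

#' Quantile normalization
#'
#' Forces every column to the same distribution: each column's sorted values
#' become the across-column means of the order statistics; ties within a
#' column receive the mean of the rank means they span (limma's
#' `normalizeQuantiles` with `ties = TRUE`). In the expression pipeline this
#' operates on the log2CPM matrix, mirroring voom's
#' `normalize.method = "quantile"`.
#'
#' @param x An [expression_matrix] or numeric matrix (no missing values).
#' @return Same type as the input.
#' @export
quantile_normalize <- function(x) {
  is_em <- inherits(x, "expression_matrix")
  m <- if (is_em) x$values else as.matrix(x)
  if (anyNA(m)) abort("quantile normalization requires a complete matrix")
  q <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(q) <- dimnames(m)
  if (!is_em) return(q)
  expression_matrix(q, scale = attr(x, "scale"), normalization = "quantile",
                    prior = attr(x, "prior"))
}

#' Filter lowly expressed genes
#'
#' A gene is retained iff its CPM (prior 0, raw library sizes) is at least
#' `min_cpm` in at least `min_libraries` libraries. Defaults reproduce the
#' common 0.5 CPM in >= 4 libraries rule used with four-replicate designs;
#' both bounds are inclusive.
#'
#' @param x A [count_matrix].
#' @param min_cpm CPM threshold (default 0.5).
#' @param min_libraries Minimum number of libraries at or above the
#'   threshold (default 4).
#' @return Character vector of retained gene ids.
#' @export
filter_low_expression <- function(x, min_cpm = 0.5, min_libraries = 4L) {
  cp <- cpm(x, prior = 0)
  keep <- rowSums(cp >= min_cpm) >= min_libraries
  rownames(cp)[keep]
}

#' Per-library expression intensity summary
#'
#' Standard boxplot statistics per library: median, quartiles (type-7 linear
#' interpolation), IQR and the 1.5 x IQR whisker range clipped to the data.
#'
#' @param x An [expression_matrix].
#' @return Tibble with one row per library.
#' @export
intensity_range_summary <- function(x) {
  vals <- x$values
  purrr::map(colnames(vals), function(lib) {
    v <- vals[, lib]
    qs <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- qs[3] - qs[1]
    lo <- min(v[v >= qs[1] - 1.5 * iqr])
    hi <- max(v[v <= qs[3] + 1.5 * iqr])
    tibble(library_id = lib, median = qs[2], q1 = qs[1], q3 = qs[3],
           iqr = iqr, whisker_low = lo, whisker_high = hi)
  }) |> list_rbind()
}

#' Full count-to-expression conversion
#'
#' Applies the standard pipeline for one normalization method: voom-style
#' log2CPM (library-size denominators; TMM factors folded into the
#' denominator for `"TMM"`; quantile normalization applied to the log2CPM
#' matrix for `"quantile"`), then conversion to log2FPKM using effective
#' gene lengths.
#'
#' @param x A [count_matrix].
#' @param method `"library_size"`, `"quantile"` or `"TMM"`.
#' @param lengths Effective gene lengths (see [log2fpkm()]).
#' @param prior Prior count (default 0.5).
#' @param lib_size_type `"assigned"` (default) or `"input"` fragment totals
#'   as the per-million denominator.
#' @return An [expression_matrix] on the log2FPKM scale (log2CPM if
#'   `lengths` is NULL).
#' @export
normalize_expression <- function(x, method = c("library_size", "quantile", "TMM"),
                                 lengths = NULL, prior = 0.5,
                                 lib_size_type = c("assigned", "input")) {
  method <- match.arg(method)
  lib_size_type <- match.arg(lib_size_type)
  ls <- library_sizes(x, type = lib_size_type)
  em <- switch(method,
    library_size = log2cpm(x, prior = prior, lib_sizes = ls),
    TMM = log2cpm(x, factors = tmm_factors(x), prior = prior, lib_sizes = ls,
                  normalization = "TMM"),
    quantile = {
      em0 <- log2cpm(x, prior = prior, lib_sizes = ls)
      quantile_normalize(em0)
    })
  if (is.null(lengths)) em else log2fpkm(em, lengths)
}
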