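# Titration-monotonicity assessment for SEQC-style mixture designs.
#
# Samples C and D are linear mixtures of reference samples A and B (by
# default 3:1 and 1:3). On the linear scale, a gene with A-vs-B fold change
# 2^x must then show a C-vs-D log2 fold change of
#   E(x) = log2((p * 2^x + (1 - p)) / (q * 2^x + (1 - q)))
# which at p = 0.75, q = 0.25 is log2((3 * 2^x + 1) / (2^x + 3)). Deviation
# of the observed C-vs-D fold changes from this expected titration curve is
# summarized as a mean squared error; a per-gene monotonicity flag records
# whether expression is ordered A >= C >= D >= B (or the reverse).

#' SEQC-style mixture design
#'
#' Describes the samples as mixtures of two reference samples and maps
#' libraries (replicates) to samples. The default is the SEQC design: pure
#' samples A and B, C = 3:1 and D = 1:3 mixtures of A and B, four replicate
#' libraries per sample named `A_1` ... `D_4`.
#'
#' @param replicates Number of replicate libraries per sample.
#' @param p_c,p_d Proportion of sample A in the C and D mixtures.
#' @param samples Optional tibble (`sample`, `prop_a`, `prop_b`) overriding
#'   the default four samples.
#' @param libraries Optional tibble (`library_id`, `sample`) overriding the
#'   default replicate map.
#' @return An object of class `mixture_design`: list of tibbles `samples`
#'   and `libraries`.
#' @export
mixture_design <- function(replicates = 4L, p_c = 0.75, p_d = 0.25,
                           samples = NULL, libraries = NULL) {
  if (is.null(samples)) {
    samples <- tibble(
      sample = c("A", "B", "C", "D"),
      prop_a = c(1, 0, p_c, p_d),
      prop_b = c(0, 1, 1 - p_c, 1 - p_d)
    )
  }
  if (any(samples$prop_a < 0 | samples$prop_a > 1) ||
      any(abs(samples$prop_a + samples$prop_b - 1) > 1e-12)) {
    abort("mixture proportions must lie in [0, 1] and sum to 1 per sample")
  }
  if (is.null(libraries)) {
    libraries <- tidyr::expand_grid(sample = samples$sample,
                                    replicate = seq_len(replicates)) |>
      mutate(library_id = paste(.data$sample, .data$replicate, sep = "_")) |>
      select("library_id", "sample")
  }
  if (!all(libraries$sample %in% samples$sample)) {
    abort("every library must map to a declared sample")
  }
  structure(list(samples = samples, libraries = libraries),
            class = "mixture_design")
}

#' @export
print.mixture_design <- function(x, ...) {
  cat(sprintf("<mixture_design> %d samples, %d libraries\n",
              nrow(x$samples), nrow(x$libraries)))
  invisible(x)
}

#' Expected C-vs-D log2 fold change under linear mixing
#'
#' @param x A-vs-B log2 fold change (vectorized; NaN propagates).
#' @param p,q Proportions of sample A in the two mixtures (defaults 0.75 and
#'   0.25, the 3:1 / 1:3 design).
#' @return The expected log2 fold change of the `p`-mixture over the
#'   `q`-mixture. At the defaults this is `log2((3*2^x + 1)/(2^x + 3))`,
#'   an odd, increasing function of `x` bounded by `±log2(3)`.
#' @export
expected_log2fc <- function(x, p = 0.75, q = 0.25) {
  if (p <= 0 || p >= 1 || q <= 0 || q >= 1) abort("p and q must lie in (0, 1)")
  r <- 2^x
  out <- log2((p * r + (1 - p)) / (q * r + (1 - q)))
  # analytic limits for infinite fold changes
  out[is.infinite(x) & x > 0] <- log2(p / q)
  out[is.infinite(x) & x < 0] <- log2((1 - p) / (1 - q))
  out
}

#' Average replicate libraries into per-sample expression
#'
#' Arithmetic mean, on the matrix's stated scale (log2 for the standard
#' pipeline), of each sample's replicate libraries.
#'
#' @param x An [expression_matrix] (or numeric matrix with library columns).
#' @param design A [mixture_design] mapping libraries to samples.
#' @return Numeric matrix genes x samples.
#' @export
replicate_mean_expression <- function(x, design) {
  m <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  libs <- design$libraries
  missing <- setdiff(colnames(m), libs$library_id)
  if (length(missing)) {
    abort(sprintf("library '%s' is not mapped to a sample", missing[1]))
  }
  out <- vapply(design$samples$sample, function(s) {
    cols <- libs$library_id[libs$sample == s]
    cols <- intersect(colnames(m), cols)
    if (!length(cols)) abort(sprintf("sample '%s' has no libraries", s))
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  rownames(out) <- rownames(m)
  out
}

#' Observed log2 fold change between two samples
#'
#' Difference of replicate-mean log2 expression, `mean(s1) - mean(s2)`.
#'
#' @param means Genes x samples matrix from [replicate_mean_expression()].
#' @param s1,s2 Sample identifiers.
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
observed_log2fc <- function(means, s1, s2) {
  for (s in c(s1, s2)) {
    if (!s %in% colnames(means)) abort(sprintf("unknown sample '%s'", s))
  }
  means[, s1] - means[, s2]
}

#' Per-gene titration monotonicity
#'
#' TRUE iff expression follows `A >= C >= D >= B` when `A >= B`, or
#' `A <= C <= D <= B` when `A <= B` (all inequalities non-strict).
#'
#' @param means Genes x samples matrix with columns for the four samples.
#' @param samples Character vector naming the pure-A, mixture-C, mixture-D
#'   and pure-B columns, in that order.
#' @return Logical vector per gene.
#' @export
monotonicity_preserved <- function(means, samples = c("A", "C", "D", "B")) {
  a <- means[, samples[1]]; c_ <- means[, samples[2]]
  d <- means[, samples[3]]; b <- means[, samples[4]]
  ifelse(a >= b,
         a >= c_ & c_ >= d & d >= b,
         a <= c_ & c_ <= d & d <= b)
}

#' Titration mean squared error
#'
#' Mean over genes (with finite values) of
#' `(observed_cd - expected_log2fc(x))^2`.
#'
#' @param x Per-gene A-vs-B log2 fold changes.
#' @param observed_cd Per-gene observed C-vs-D log2 fold changes.
#' @param p,q Mixture proportions (see [expected_log2fc()]).
#' @return The MSE (scalar).
#' @export
titration_mse <- function(x, observed_cd, p = 0.75, q = 0.25) {
  e <- expected_log2fc(x, p, q)
  ok <- is.finite(x) & is.finite(observed_cd)
  if (!any(ok)) abort("no genes with finite fold changes")
  mean((observed_cd[ok] - e[ok])^2)
}

#' Assess titration monotonicity of an expression matrix
#'
#' Computes per-gene A-vs-B and C-vs-D log2 fold changes from replicate-mean
#' expression, the expected C-vs-D fold change under the design's mixing
#' proportions, per-gene monotonicity flags, and the summary MSE.
#'
#' @param x An [expression_matrix] on a log2 scale.
#' @param design A [mixture_design].
#' @param genes Optional gene ids to restrict to (e.g. an expression-filtered
#'   or common-gene set).
#' @return An object of class `titration_assessment`; see [tidy()] /
#'   [glance()] methods.
#' @export
assess_titration <- function(x, design = mixture_design(), genes = NULL) {
  means <- replicate_mean_expression(x, design)
  if (!is.null(genes)) means <- means[rownames(means) %in% genes, , drop = FALSE]
  if (!nrow(means)) abort("no genes left to assess")
  pa <- setNames(design$samples$prop_a, design$samples$sample)
  p <- pa[["C"]]; q <- pa[["D"]]
  lfc_ab <- observed_log2fc(means, "A", "B")
  lfc_cd <- observed_log2fc(means, "C", "D")
  per_gene <- tibble(
    gene_id = rownames(means),
    lfc_ab = unname(lfc_ab),
    lfc_cd = unname(lfc_cd),
    expected_cd = expected_log2fc(unname(lfc_ab), p, q),
    monotonic = unname(monotonicity_preserved(means))
  )
  finite <- is.finite(per_gene$lfc_ab) & is.finite(per_gene$lfc_cd)
  structure(
    list(
      genes = per_gene,
      mse = titration_mse(per_gene$lfc_ab, per_gene$lfc_cd, p, q),
      monotone_fraction = mean(per_gene$monotonic[finite]),
      n_genes = sum(finite),
      n_nonfinite = sum(!finite)
    ),
    p = p, q = q,
    scale = attr(x, "scale"), normalization = attr(x, "normalization"),
    class = "titration_assessment"
  )
}

#' @export
print.titration_assessment <- function(x, ...) {
  cat(sprintf("<titration_assessment> %d genes (%s, %s): MSE %.4g, monotone fraction %.3f\n",
              x$n_genes, attr(x, "scale") %||% "?",
              attr(x, "normalization") %||% "?", x$mse, x$monotone_fraction))
  invisible(x)
}

#' @describeIn assess_titration Per-gene table (`gene_id`, `lfc_ab`,
#'   `lfc_cd`, `expected_cd`, `monotonic`).
#' @param ... Unused.
#' @method tidy titration_assessment
#' @export
tidy.titration_assessment <- function(x, ...) x$genes

#' @describeIn assess_titration One-row summary (`mse`,
#'   `monotone_fraction`, `n_genes`, `n_nonfinite`, normalization).
#' @method glance titration_assessment
#' @export
glance.titration_assessment <- function(x, ...) {
  tibble(mse = x$mse, monotone_fraction = x$monotone_fraction,
         n_genes = x$n_genes, n_nonfinite = x$n_nonfinite,
         normalization = attr(x, "normalization") %||% NA_character_,
         scale = attr(x, "scale") %||% NA_character_)
}

#' @describeIn assess_titration Observed C-vs-D fold changes against A-vs-B
#'   with the expected titration curve overlaid.
#' @param object A `titration_assessment`.
#' @method autoplot titration_assessment
#' @export
autoplot.titration_assessment <- function(object, ...) {
  p <- attr(object, "p"); q <- attr(object, "q")
  curve <- tibble(x = seq(min(object$genes$lfc_ab, na.rm = TRUE),
                          max(object$genes$lfc_ab, na.rm = TRUE),
                          length.out = 400)) |>
    mutate(y = expected_log2fc(.data$x, p, q))
  ggplot2::ggplot(object$genes, ggplot2::aes(.data$lfc_ab, .data$lfc_cd)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_line(data = curve, ggplot2::aes(.data$x, .data$y),
                       colour = "red", linewidth = 0.8) +
    ggplot2::labs(
      x = "log2 fold change, A vs B",
      y = "log2 fold change, C vs D",
      subtitle = sprintf("MSE %.4g, monotone fraction %.3f",
                         object$mse, object$monotone_fraction)
    ) +
    ggplot2::theme_minimal()
}

#' Write a titration assessment to disk
#'
#' Writes the per-gene TSV and a JSON summary.
#'
#' @param x A `titration_assessment`.
#' @param path_genes TSV output path; the JSON summary is written next to it
#'   with suffix `.summary.json` unless `path_summary` is given.
#' @param path_summary Optional JSON output path.
#' @return `path_genes`, invisibly.
#' @export
write_titration <- function(x, path_genes, path_summary = NULL) {
  write_tsv_det(x$genes, path_genes)
  write_json_det(
    list(mse = x$mse, monotone_fraction = x$monotone_fraction,
         n_genes = x$n_genes, n_nonfinite = x$n_nonfinite),
    path_summary %||% sub("\\.tsv$", ".summary.json", path_genes)
  )
  invisible(path_genes)
}
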