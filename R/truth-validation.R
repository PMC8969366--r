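# Validation of RNA-seq expression against external truth tables.
#
# Truth tables carry per-sample log2 expression measured on an independent
# platform: an RT-PCR-like table keyed by gene, or a microarray-like table
# keyed by (probe, gene) with possibly several probes per gene. RNA-seq
# expression (replicate-averaged, log2 scale) is matched to the truth by
# identifier and compared by per-sample Pearson correlation.

#' Read an external truth table
#'
#' @param path TSV with an id column (`gene_id`; plus `probe_id` for
#'   microarray tables) and one column per sample.
#' @param platform `"rtpcr"` or `"microarray"`. RT-PCR tables must have
#'   unique gene ids; microarray tables may carry several probes per gene.
#' @param log2_transform Apply `log2` to the values on read. Default TRUE
#'   for `rtpcr` (raw RT-PCR values are linear scale), FALSE otherwise.
#' @param samples Sample column names expected (default `A`, `B`, `C`, `D`).
#' @return A tibble of class `truth_table` with attributes `platform`,
#'   `samples`.
#' @export
read_truth_table <- function(path, platform = c("rtpcr", "microarray"),
                             log2_transform = NULL,
                             samples = c("A", "B", "C", "D")) {
  platform <- match.arg(platform)
  tab <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  truth_table(tab, platform = platform, log2_transform = log2_transform,
              samples = samples)
}

#' @rdname read_truth_table
#' @param x A data frame with the columns described above.
#' @export
truth_table <- function(x, platform = c("rtpcr", "microarray"),
                        log2_transform = NULL,
                        samples = c("A", "B", "C", "D")) {
  platform <- match.arg(platform)
  log2_transform <- log2_transform %||% (platform == "rtpcr")
  x <- as_tibble(x)
  if (!"gene_id" %in% names(x)) abort("truth table must have a gene_id column")
  missing <- setdiff(samples, names(x))
  if (length(missing)) {
    abort(sprintf("truth table is missing sample column '%s'", missing[1]))
  }
  if (platform == "rtpcr") {
    if (anyDuplicated(x$gene_id)) {
      abort("rtpcr truth tables must have one row per gene (duplicate gene_id found)")
    }
  } else if (!"probe_id" %in% names(x)) {
    x$probe_id <- paste0(x$gene_id, "_p1")
  }
  if (log2_transform) {
    x[samples] <- lapply(x[samples], log2)
  }
  if (any(!is.finite(as.matrix(x[samples])))) {
    abort("truth table values must be finite (on the log2 scale)")
  }
  id_cols <- intersect(c("probe_id", "gene_id"), names(x))
  out <- x[c(id_cols, samples)]
  structure(out, platform = platform, samples = samples,
            class = c("truth_table", class(out)))
}

#' Select one representative probe per gene
#'
#' For multi-probe platforms, keeps for each gene the probe with the highest
#' mean expression across the samples; exact ties break to the
#' lexicographically smallest probe id.
#'
#' @param x A `truth_table` (microarray-style, with `probe_id`).
#' @return A `truth_table` with one row per gene.
#' @export
select_representative_probe <- function(x) {
  samples <- attr(x, "samples")
  if (!"probe_id" %in% names(x)) return(x)
  out <- as_tibble(x) |>
    mutate(.mean = rowMeans(across(dplyr::all_of(samples)))) |>
    group_by(.data$gene_id) |>
    arrange(desc(.data$.mean), .data$probe_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-".mean")
  structure(out, platform = attr(x, "platform"), samples = samples,
            class = c("truth_table", class(as_tibble(out))))
}

#' Match expressed RNA-seq genes to a truth table
#'
#' @param gene_ids Character vector of (already expression-filtered) RNA-seq
#'   gene ids.
#' @param truth A `truth_table`.
#' @param map Optional identifier map from RNA-seq ids to truth ids (see
#'   [id_map()]); by default ids are compared directly. Only one-to-one
#'   mapped pairs are kept.
#' @return List with tibble `matched` (`rnaseq_gene`, `truth_gene`) and
#'   counts `n_unmatched_rnaseq`, `n_unmatched_truth`.
#' @export
match_to_truth <- function(gene_ids, truth, map = NULL) {
  truth_ids <- unique(truth$gene_id)
  if (is.null(map)) {
    matched <- tibble(rnaseq_gene = intersect(gene_ids, truth_ids)) |>
      mutate(truth_gene = .data$rnaseq_gene)
  } else {
    map <- as_tibble(map) |>
      filter(.data$source_id %in% gene_ids, .data$target_id %in% truth_ids)
    one2one <- map |>
      group_by(.data$source_id) |> filter(dplyr::n() == 1L) |> ungroup() |>
      group_by(.data$target_id) |> filter(dplyr::n() == 1L) |> ungroup()
    matched <- tibble(rnaseq_gene = one2one$source_id,
                      truth_gene = one2one$target_id)
  }
  list(
    matched = arrange(matched, .data$rnaseq_gene),
    n_unmatched_rnaseq = length(setdiff(gene_ids, matched$rnaseq_gene)),
    n_unmatched_truth = length(setdiff(truth_ids, matched$truth_gene))
  )
}

#' Pearson validation of RNA-seq expression against a truth table
#'
#' Per sample, the Pearson correlation across matched genes between
#' replicate-averaged RNA-seq log2 expression and the truth table's log2
#' expression. Multi-probe truth tables are first reduced with
#' [select_representative_probe()].
#'
#' @param x An [expression_matrix] on a log2 scale (already
#'   expression-filtered).
#' @param truth A `truth_table`.
#' @param design A [mixture_design].
#' @param map Optional identifier map RNA-seq -> truth (see
#'   [match_to_truth()]).
#' @param genes Optional restriction of the RNA-seq gene set (e.g. genes
#'   common to several annotations) before matching.
#' @param gene_set_mode Label recorded in the report
#'   (`"per-annotation"` or `"common"`).
#' @return A tibble of class `correlation_report`: one row per sample with
#'   `platform`, `normalization`, `gene_set_mode`, `sample`, `n`, `r`.
#'   `r` is `NA` with a warning when either side has zero variance.
#' @export
pearson_validation <- function(x, truth, design = mixture_design(), map = NULL,
                               genes = NULL, gene_set_mode = "per-annotation") {
  samples <- attr(truth, "samples")
  truth <- select_representative_probe(truth)
  gene_ids <- rownames(x$values)
  if (!is.null(genes)) gene_ids <- intersect(gene_ids, genes)
  m <- match_to_truth(gene_ids, truth, map)
  if (nrow(m$matched) < 3) abort("fewer than 3 matched genes; correlation not reported")
  means <- replicate_mean_expression(x, design)
  rna <- means[m$matched$rnaseq_gene, samples, drop = FALSE]
  tr <- as.matrix(as_tibble(truth)[match(m$matched$truth_gene, truth$gene_id), samples])
  rows <- purrr::map(samples, function(s) {
    vr <- var(rna[, s]); vt <- var(tr[, s])
    r <- if (vr == 0 || vt == 0) {
      warn(sprintf("zero variance in sample '%s'; correlation undefined", s))
      NA_real_
    } else {
      cor(rna[, s], tr[, s], method = "pearson")
    }
    tibble(platform = attr(truth, "platform"),
           normalization = attr(x, "normalization") %||% NA_character_,
           gene_set_mode = gene_set_mode, sample = s,
           n = nrow(m$matched), r = r)
  })
  out <- list_rbind(rows)
  class(out) <- c("correlation_report", class(out))
  out
}

#' @describeIn pearson_validation Plot per-sample correlations.
#' @param object A `correlation_report` (rows may be pooled across
#'   normalizations/platforms with `dplyr::bind_rows`).
#' @param ... Unused.
#' @method autoplot correlation_report
#' @export
autoplot.correlation_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$sample, .data$r)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(normalization ~ platform + gene_set_mode) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "sample", y = "Pearson r") +
    ggplot2::theme_minimal()
}
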