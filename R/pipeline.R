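# End-to-end benchmark orchestration: annotations -> counting ->
# normalization -> filtering -> titration + truth validation, producing the
# report tables that summarize each stage. Deterministic given its inputs
# and seed; when an output directory is given, every table is written as
# TSV/JSON with a manifest, and re-running reproduces byte-identical files.

#' Assemble a benchmark configuration from explicit inputs
#'
#' @param annotations Named list of [annotation_set] objects (or GTF paths;
#'   see `dialects`).
#' @param counts Named list (same names) of [count_matrix] objects, or of
#'   named per-library fragment tibbles/BED/SAM paths to be counted.
#' @param maps Named list of pairwise identifier maps keyed
#'   `"nameA:nameB"` (see [id_map()]); optional maps to the truth id space
#'   under `"<name>:truth"`.
#' @param design A [mixture_design].
#' @param dialects GTF dialects for path inputs (recycled).
#' @param normalizations Normalization methods to run.
#' @param min_cpm,min_libraries Expression-filter parameters.
#' @param truth Optional named list with elements `rtpcr` and/or
#'   `microarray`: truth tables (or TSV paths).
#' @param truth_maps Optional named list: per annotation, an identifier map
#'   from its gene ids to the truth tables' id space (defaults to maps
#'   keyed `"<name>:symbol"`, then to direct id matching).
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(annotations, counts, maps = list(),
                             design = mixture_design(),
                             dialects = "generic",
                             normalizations = c("library_size", "quantile", "TMM"),
                             min_cpm = 0.5, min_libraries = 4L,
                             truth = list(), truth_maps = NULL) {
  if (!length(annotations)) abort("at least one annotation is required")
  nms <- names(annotations)
  if (is.null(nms) || any(!nzchar(nms))) abort("annotations must be named")
  dialects <- rep_len(dialects, length(annotations))
  annotations <- purrr::imap(annotations, function(a, nm) {
    if (inherits(a, "annotation_set")) a
    else read_gtf(a, dialect = dialects[[match(nm, nms)]], name = nm)
  })
  counts <- purrr::imap(counts, function(cm, nm) {
    if (inherits(cm, "count_matrix")) return(cm)
    frags <- purrr::imap(cm, function(f, lib) {
      if (is.data.frame(f)) f
      else if (grepl("\\.sam(\\.gz)?$", f)) read_fragments_sam(f, lib)
      else read_fragments_bed(f, lib)
    })
    count_fragments(frags, annotations[[nm]])
  })
  if (!setequal(names(counts), nms)) {
    abort("counts must be supplied for every annotation")
  }
  truth <- purrr::imap(truth, function(tt, platform) {
    if (inherits(tt, "truth_table")) tt
    else read_truth_table(tt, platform = platform)
  })
  structure(
    list(annotations = annotations, counts = counts[nms], maps = maps,
         design = design, normalizations = normalizations,
         min_cpm = min_cpm, min_libraries = min_libraries,
         truth = truth, truth_maps = truth_maps),
    class = "benchmark_config"
  )
}

# Subset a count matrix to a gene set (stats no longer apply and are
# dropped; library sizes become the subset column sums).
subset_count_matrix <- function(x, genes) {
  count_matrix(x$counts[rownames(x$counts) %in% genes, , drop = FALSE],
               annotation = attr(x, "annotation"))
}

#' Run the full annotation benchmark
#'
#' For each annotation: summary statistics and pairwise comparisons,
#' assignment statistics (when counts came from fragment assignment), the
#' expression filter, per-normalization intensity summaries, titration
#' assessment on the all-genes / filtered / common gene sets, and Pearson
#' validation against the configured truth platforms on per-annotation and
#' common gene sets. With a [synthetic_config], the whole input bundle is
#' generated first (counts mode) and validated against the generated truth
#' tables.
#'
#' @param config A `benchmark_config` or [synthetic_config].
#' @param out_dir Optional directory; all report tables are written there
#'   (byte-identical across re-runs on the same inputs).
#' @return A list of class `benchmark_report` of tidy tables; blocks that
#'   could not be computed are listed in `$skipped` with a reason.
#' @export
run_benchmark <- function(config, out_dir = NULL) {
  if (inherits(config, "synthetic_config")) {
    bundle <- generate_bundle(config)
    truth_maps <- purrr::map(
      setNames(names(bundle$annotations), names(bundle$annotations)),
      function(nm) bundle$maps[[map_key(nm, "symbol")]])
    config <- benchmark_config(
      annotations = bundle$annotations, counts = bundle$counts,
      maps = bundle$maps, design = config$design,
      truth = bundle$truth, truth_maps = truth_maps
    )
  }
  stopifnot(inherits(config, "benchmark_config"))
  anns <- config$annotations
  nms <- names(anns)
  design <- config$design
  skipped <- list()
  note_skip <- function(block, reason) {
    skipped[[length(skipped) + 1L]] <<- tibble(block = block, reason = reason)
  }

  ann_summary <- purrr::map(anns, glance) |> list_rbind()

  filtered <- purrr::map(config$counts, filter_low_expression,
                         min_cpm = config$min_cpm,
                         min_libraries = config$min_libraries)
  ann_summary$n_genes_filtered <- purrr::map_int(filtered[nms], length)

  # pairwise comparison blocks
  venn <- NULL; ratios <- NULL
  have_all_maps <- length(nms) >= 2 && all(
    utils::combn(nms, 2, function(p) {
      !inherits(try(lookup_map(config$maps, p[1], p[2]), silent = TRUE), "try-error")
    }))
  if (have_all_maps) {
    venn <- overlap_counts(anns, config$maps)
    ratios <- purrr::map(utils::combn(nms, 2, simplify = FALSE), function(p) {
      gm <- match_genes(anns[[p[1]]], anns[[p[2]]],
                        lookup_map(config$maps, p[1], p[2]))
      lr <- length_ratio_distribution(gm, anns[[p[1]]], anns[[p[2]]])
      tibble(pair = map_key(p[1], p[2]), n = nrow(lr),
             q25 = quantile(lr$log2_ratio, 0.25),
             median = median(lr$log2_ratio),
             q75 = quantile(lr$log2_ratio, 0.75))
    }) |> list_rbind()
  } else if (length(nms) >= 2) {
    note_skip("annotation_compare", "pairwise identifier maps not supplied for all pairs")
  }

  assignment <- purrr::imap(config$counts, function(cm, nm) {
    if (is.null(cm$stats)) return(NULL)
    glance(cm) |> mutate(annotation = nm, .before = 1)
  }) |> purrr::compact()
  assignment <- if (length(assignment)) list_rbind(assignment) else NULL
  if (is.null(assignment)) {
    note_skip("assignment_stats", "counts were supplied directly; no assignment statistics")
  }

  # common gene set across annotations (after filtering): genes whose 1:1
  # partners exist and are filtered-in in every other annotation
  common <- NULL
  if (have_all_maps) {
    common <- purrr::map(setNames(nms, nms), function(x) {
      ids <- filtered[[x]]
      for (y in setdiff(nms, x)) {
        gm <- match_genes(anns[[x]], anns[[y]], lookup_map(config$maps, x, y))
        partner <- gm$matched$gene_id_b[match(ids, gm$matched$gene_id_a)]
        ids <- ids[!is.na(partner) & partner %in% filtered[[y]]]
      }
      ids
    })
    ann_summary$n_genes_common_filtered <- purrr::map_int(common[nms], length)
  }

  lengths_tbl <- purrr::map(anns, effective_lengths)

  intensity <- list(); titration <- list(); correlations <- list()
  for (nm in nms) {
    cm <- config$counts[[nm]]
    len <- lengths_tbl[[nm]]
    gene_sets <- list(all = rownames(cm$counts), filtered = filtered[[nm]])
    if (!is.null(common)) gene_sets$common <- common[[nm]]
    for (norm in config$normalizations) {
      em_all <- normalize_expression(cm, method = norm, lengths = len)
      intensity[[paste(nm, norm)]] <- intensity_range_summary(em_all) |>
        mutate(annotation = nm, normalization = norm, .before = 1)
      for (mode in names(gene_sets)) {
        em <- if (mode == "all") em_all else {
          normalize_expression(subset_count_matrix(cm, filtered[[nm]]),
                               method = norm, lengths = len)
        }
        ta <- assess_titration(em, design, genes = gene_sets[[mode]])
        titration[[paste(nm, norm, mode)]] <- glance(ta) |>
          mutate(annotation = nm, gene_set = mode, .before = 1)
      }
      # truth validation on the filtered expression
      em_f <- normalize_expression(subset_count_matrix(cm, filtered[[nm]]),
                                   method = norm, lengths = len)
      for (platform in names(config$truth)) {
        tmap <- (config$truth_maps %||% list())[[nm]] %||%
          config$maps[[map_key(nm, "symbol")]]
        for (mode in c("per-annotation", if (!is.null(common)) "common")) {
          genes <- if (mode == "common") common[[nm]] else NULL
          res <- tryCatch(
            pearson_validation(em_f, config$truth[[platform]], design,
                               map = tmap, genes = genes,
                               gene_set_mode = mode) |>
              mutate(annotation = nm, .before = 1),
            error = function(e) {
              note_skip(paste("validation", platform, nm, norm, mode),
                        conditionMessage(e))
              NULL
            })
          correlations[[paste(nm, norm, platform, mode)]] <- res
        }
      }
    }
  }
  if (!length(config$truth)) {
    note_skip("truth_validation", "no truth tables supplied")
  }

  report <- structure(list(
    annotation_summary = ann_summary,
    venn = venn,
    length_ratio_summary = ratios,
    assignment_stats = assignment,
    intensity = list_rbind(purrr::compact(intensity)),
    titration = list_rbind(purrr::compact(titration)),
    correlations = if (length(purrr::compact(correlations))) {
      list_rbind(purrr::compact(correlations))
    } else NULL,
    skipped = if (length(skipped)) list_rbind(skipped) else
      tibble(block = character(), reason = character())
  ), class = "benchmark_report")
  if (!is.null(out_dir)) write_benchmark_report(report, out_dir)
  report
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report>\n")
  cat(sprintf("  annotations: %s\n",
              paste(x$annotation_summary$name, collapse = ", ")))
  cat(sprintf("  titration rows: %d; correlation rows: %d; skipped blocks: %d\n",
              nrow(x$titration) %||% 0L,
              if (is.null(x$correlations)) 0L else nrow(x$correlations),
              nrow(x$skipped)))
  invisible(x)
}

#' Write a benchmark report to disk
#'
#' One TSV per report block plus a JSON manifest; outputs are byte-identical
#' across re-runs on identical inputs.
#'
#' @param x A `benchmark_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_benchmark_report <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (block in c("annotation_summary", "venn", "length_ratio_summary",
                  "assignment_stats", "intensity", "titration",
                  "correlations", "skipped")) {
    if (!is.null(x[[block]])) {
      write_tsv_det(x[[block]], file.path(dir, paste0(block, ".tsv")))
    }
  }
  write_json_det(list(package = "annobench",
                      blocks = names(purrr::compact(unclass(x)))),
                 file.path(dir, "manifest.json"))
  invisible(dir)
}
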