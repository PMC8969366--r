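# Cross-annotation gene matching and concordance summaries.
#
# Genes are matched between annotations purely by identifier, through
# user-supplied (or generator-supplied) mapping tables; no coordinate-based
# matching is attempted. All overlap analyses restrict to one-to-one matches,
# mirroring common practice when comparing Ensembl and RefSeq gene sets.

#' Read an identifier mapping table
#'
#' A mapping table is a two-column TSV of `(source_id, target_id)` pairs.
#' Pairs may be many-to-many as loaded; matching operations restrict to
#' one-to-one subsets.
#'
#' @param path Path to a TSV file with two identifier columns. A header line
#'   is interpreted as the namespace labels of the two sides.
#' @param namespaces Optional character vector of length 2 overriding the
#'   namespace labels.
#' @return A tibble with columns `source_id`, `target_id` and a
#'   `namespaces` attribute.
#' @export
read_id_map <- function(path, namespaces = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tab) < 2) abort(sprintf("mapping table '%s' must have two columns", path))
  ns <- namespaces %||% names(tab)[1:2]
  id_map(tab[[1]], tab[[2]], namespaces = ns)
}

#' @rdname read_id_map
#' @param source_id,target_id Character vectors of paired identifiers.
#' @export
id_map <- function(source_id, target_id, namespaces = c("source", "target")) {
  out <- tibble(source_id = as.character(source_id),
                target_id = as.character(target_id)) |> distinct()
  attr(out, "namespaces") <- namespaces
  out
}

#' Match genes between two annotations via an identifier map
#'
#' Restricts a (possibly many-to-many) identifier map to the genes actually
#' present in the two annotations and keeps only pairs that are one-to-one in
#' both directions. Genes involved in many-to-many mappings are reported in
#' `dropped_multimap`; genes with no mapping row are reported unmatched.
#'
#' @param a,b [annotation_set] objects.
#' @param map An identifier map from `a`'s id space to `b`'s (see
#'   [id_map()]).
#' @return An object of class `gene_match`: list with tibble `matched`
#'   (`gene_id_a`, `gene_id_b`), character vectors `unmatched_a`,
#'   `unmatched_b`, `dropped_multimap`.
#' @export
match_genes <- function(a, b, map) {
  map <- as_tibble(map)
  present <- map |>
    filter(.data$source_id %in% gene_ids(a), .data$target_id %in% gene_ids(b)) |>
    distinct()
  amb <- present |>
    group_by(.data$source_id) |> mutate(n_t = dplyr::n()) |> ungroup() |>
    group_by(.data$target_id) |> mutate(n_s = dplyr::n()) |> ungroup()
  matched <- amb |> filter(.data$n_t == 1L, .data$n_s == 1L) |>
    select(gene_id_a = "source_id", gene_id_b = "target_id") |>
    arrange(.data$gene_id_a)
  dropped <- amb |> filter(.data$n_t > 1L | .data$n_s > 1L)
  dropped_ids <- sort(unique(c(dropped$source_id, dropped$target_id)))
  structure(
    list(
      matched = matched,
      unmatched_a = setdiff(gene_ids(a), c(matched$gene_id_a, dropped$source_id)),
      unmatched_b = setdiff(gene_ids(b), c(matched$gene_id_b, dropped$target_id)),
      dropped_multimap = dropped_ids
    ),
    names_ab = c(annotation_name(a), annotation_name(b)),
    class = "gene_match"
  )
}

#' @export
print.gene_match <- function(x, ...) {
  nm <- attr(x, "names_ab")
  cat(sprintf("<gene_match> %s vs %s: %d one-to-one pairs, %d/%d unmatched, %d dropped (many-to-many)\n",
              nm[1], nm[2], nrow(x$matched), length(x$unmatched_a),
              length(x$unmatched_b), length(x$dropped_multimap)))
  invisible(x)
}

#' @describeIn match_genes Tidy view: one row per gene with its match status.
#' @param x A `gene_match`.
#' @param ... Unused.
#' @method tidy gene_match
#' @export
tidy.gene_match <- function(x, ...) {
  bind_rows(
    x$matched |> mutate(status = "matched"),
    tibble(gene_id_a = x$unmatched_a, gene_id_b = NA_character_, status = "unmatched_a"),
    tibble(gene_id_a = NA_character_, gene_id_b = x$unmatched_b, status = "unmatched_b")
  )
}

# Canonical key for a named list of pairwise maps: "nameA:nameB".
map_key <- function(na, nb) paste(na, nb, sep = ":")

lookup_map <- function(maps, na, nb) {
  k1 <- map_key(na, nb); k2 <- map_key(nb, na)
  if (!is.null(maps[[k1]])) return(maps[[k1]])
  if (!is.null(maps[[k2]])) {
    m <- maps[[k2]]
    return(id_map(m$target_id, m$source_id, rev(attr(m, "namespaces") %||% c(nb, na))))
  }
  abort(sprintf("no identifier map supplied for pair %s / %s", na, nb))
}

#' Venn-region gene counts across two or three annotations
#'
#' Assigns every gene of every annotation to exactly one Venn region based on
#' one-to-one identifier matches. For three annotations a gene is "common to
#' all three" only when the three pairwise matches agree transitively;
#' non-transitive triples are demoted to the largest consistent pairwise
#' region and counted in the `n_nontransitive` attribute.
#'
#' @param annotations Named list of 2 or 3 [annotation_set] objects.
#' @param maps Named list of pairwise identifier maps, keyed
#'   `"nameA:nameB"` (either direction accepted).
#' @return A tibble with columns `region` (e.g. `"ensembl&refseq"`),
#'   `annotation`, `n_genes`: for each region, the number of that
#'   annotation's genes assigned to it. Per annotation the counts sum to its
#'   gene count.
#' @export
overlap_counts <- function(annotations, maps) {
  nms <- names(annotations) %||% vapply(annotations, annotation_name, character(1))
  names(annotations) <- nms
  if (!length(nms) %in% 2:3) abort("overlap_counts supports 2 or 3 annotations")
  membership <- venn_membership(annotations, maps)
  membership |>
    count(.data$region, .data$annotation, name = "n_genes") |>
    arrange(.data$region, .data$annotation)
}

# Per-gene Venn region membership; one row per (annotation, gene).
venn_membership <- function(annotations, maps) {
  nms <- names(annotations)
  pairs <- utils::combn(nms, 2, simplify = FALSE)
  match_tbl <- list()
  for (p in pairs) {
    gm <- match_genes(annotations[[p[1]]], annotations[[p[2]]],
                      lookup_map(maps, p[1], p[2]))
    match_tbl[[map_key(p[1], p[2])]] <- gm$matched
  }
  # partner(gene in X) in Y, or NA
  partner <- function(gx, x, y) {
    k1 <- map_key(x, y)
    if (!is.null(match_tbl[[k1]])) {
      m <- match_tbl[[k1]]
      return(m$gene_id_b[match(gx, m$gene_id_a)])
    }
    m <- match_tbl[[map_key(y, x)]]
    m$gene_id_a[match(gx, m$gene_id_b)]
  }
  n_nontrans <- 0L
  rows <- list()
  for (x in nms) {
    gx <- gene_ids(annotations[[x]])
    others <- setdiff(nms, x)
    has <- vapply(others, function(y) !is.na(partner(gx, x, y)), logical(length(gx)))
    if (length(gx) == 1L) has <- matrix(has, nrow = 1, dimnames = list(NULL, others))
    in_all <- if (length(others) == 2L) has[, 1] & has[, 2] else has[, 1]
    region <- character(length(gx))
    if (length(others) == 2L) {
      y <- others[1]; z <- others[2]
      py <- partner(gx, x, y); pz <- partner(gx, x, z)
      # transitivity: partner-of-partner must come back to the same gene in z
      pyz <- ifelse(is.na(py), NA_character_, partner(py, y, z))
      transitive <- !is.na(py) & !is.na(pz) & !is.na(pyz) & pyz == pz
      triple <- in_all & transitive
      n_nontrans <- n_nontrans + sum(in_all & !transitive)
      # demote non-transitive triples to the pairwise region with partner y
      region[triple] <- region_label(c(x, y, z), nms)
      region[!triple & has[, 1] & !has[, 2]] <- region_label(c(x, y), nms)
      region[!triple & !has[, 1] & has[, 2]] <- region_label(c(x, z), nms)
      region[!triple & has[, 1] & has[, 2]] <- region_label(c(x, y), nms)  # demoted
      region[!has[, 1] & !has[, 2]] <- region_label(x, nms)
    } else {
      region[has[, 1]] <- region_label(c(x, others), nms)
      region[!has[, 1]] <- region_label(x, nms)
    }
    rows[[x]] <- tibble(annotation = x, gene_id = gx, region = region)
  }
  out <- bind_rows(rows)
  attr(out, "n_nontransitive") <- n_nontrans
  out
}

region_label <- function(members, all_names) {
  paste(all_names[all_names %in% members], collapse = "&")
}

#' Per-gene effective-length ratios between two matched annotations
#'
#' For every one-to-one matched gene pair, the log2 ratio of effective
#' lengths in annotation `a` over annotation `b`.
#'
#' @param match A `gene_match` from [match_genes()] between `a` and `b`.
#' @param a,b The [annotation_set] objects the match was produced from.
#' @return Tibble with columns `gene_id_a`, `gene_id_b`, `log2_ratio`.
#' @export
length_ratio_distribution <- function(match, a, b) {
  la <- effective_lengths(a); lb <- effective_lengths(b)
  match$matched |>
    mutate(
      len_a = la$effective_length[match(.data$gene_id_a, la$gene_id)],
      len_b = lb$effective_length[match(.data$gene_id_b, lb$gene_id)],
      log2_ratio = log2(.data$len_a / .data$len_b)
    ) |>
    select("gene_id_a", "gene_id_b", "log2_ratio")
}

#' Venn-region counts restricted to one biotype
#'
#' As [overlap_counts()], but only genes whose biotype (in their home
#' annotation) equals `biotype` are considered; matches to genes of other
#' biotypes still count as presence.
#'
#' @inheritParams overlap_counts
#' @param biotype Biotype label to restrict to.
#' @return A tibble as in [overlap_counts()]; empty if the biotype is absent
#'   everywhere.
#' @export
biotype_overlap <- function(annotations, maps, biotype) {
  nms <- names(annotations) %||% vapply(annotations, annotation_name, character(1))
  names(annotations) <- nms
  membership <- venn_membership(annotations, maps)
  keep <- purrr::imap(annotations, function(ann, nm) {
    g <- ann$genes |>
      mutate(biotype = ifelse(is.na(.data$biotype), "unannotated", .data$biotype)) |>
      filter(.data$biotype == !!biotype)
    tibble(annotation = nm, gene_id = g$gene_id)
  }) |> list_rbind()
  membership |>
    inner_join(keep, by = c("annotation", "gene_id")) |>
    count(.data$region, .data$annotation, name = "n_genes") |>
    arrange(.data$region, .data$annotation)
}
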