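# featureCounts-style assignment of mapped fragments to genes.
#
# A fragment (read pair) is represented by one or more candidate mapping
# locations; each candidate is a set of aligned reference blocks (both ends'
# blocks combined). A fragment is assigned to a gene if any of its blocks
# overlaps any exon of the gene by at least one base, unstranded. Fragments
# overlapping exons of two or more genes are ambiguous and not counted;
# fragments overlapping no exon are "no feature". Multi-mapping fragments are
# first resolved to a single candidate location: the unique exon-overlapping
# candidate if there is exactly one, otherwise the first candidate in
# canonical genomic order (chromosome order of the annotation, then start,
# then input order) among the exon-overlapping candidates if any, else among
# all candidates.

#' Build an exon overlap index for fragment assignment
#'
#' Collapses each gene's exons and prepares a query structure for overlap
#' assignment.
#'
#' @param annotation An [annotation_set].
#' @return An object of class `exon_index`.
#' @export
build_exon_index <- function(annotation) {
  col <- collapse_exons(annotation)
  structure(
    list(gr = exon_granges(col), genes = annotation$genes),
    chrom_order = chrom_order(annotation),
    name = annotation_name(annotation),
    gene_ids = gene_ids(annotation),
    class = "exon_index"
  )
}

as_exon_index <- function(x) {
  if (inherits(x, "exon_index")) x else build_exon_index(x)
}

#' Read fragment alignments from BED
#'
#' BED3+ input, 0-based half-open coordinates. An optional fourth (name)
#' column groups lines into multi-mapping candidates: lines sharing a name
#' become one fragment with several single-block candidates. Unnamed lines
#' are independent single-candidate fragments.
#'
#' @param path Path to a BED file (optionally gzipped).
#' @param library_id Library label attached to every fragment.
#' @return A fragment tibble with columns `library_id`, `fragment_id`,
#'   `candidate`, `block`, `chrom`, `start`, `end`.
#' @export
read_fragments_bed <- function(path, library_id = "library") {
  tab <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         comment = "#")
  if (!nrow(tab)) {
    return(empty_fragments(library_id))
  }
  if (ncol(tab) < 3) abort(sprintf("BED file '%s' must have at least 3 columns", path))
  start <- suppressWarnings(as.integer(tab[[2]]))
  end <- suppressWarnings(as.integer(tab[[3]]))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad)) {
    abort(sprintf("malformed interval on line %d of '%s'", bad[1], path))
  }
  name <- if (ncol(tab) >= 4) tab[[4]] else sprintf("frag%07d", seq_len(nrow(tab)))
  name[is.na(name) | name == "."] <- sprintf("frag%07d", which(is.na(name) | name == "."))
  tibble(
    library_id = library_id, fragment_id = name,
    chrom = tab[[1]], start = start, end = end
  ) |>
    group_by(.data$fragment_id) |>
    mutate(candidate = dplyr::row_number(), block = 1L) |>
    ungroup() |>
    select("library_id", "fragment_id", "candidate", "block",
           "chrom", "start", "end")
}

empty_fragments <- function(library_id = character()) {
  tibble(library_id = library_id[0], fragment_id = character(),
         candidate = integer(), block = integer(),
         chrom = character(), start = integer(), end = integer())
}

#' Read fragment alignments from a minimal SAM subset
#'
#' Uses only QNAME, FLAG, RNAME, POS and CIGAR. Mates are paired by QNAME;
#' the primary records of a fragment (both ends) form its first candidate,
#' and each secondary record (FLAG 0x100) contributes one extra candidate.
#' Candidate blocks are the CIGAR M/=/X reference spans (N and D introduce
#' gaps; I and soft/hard clips consume no reference). Unmapped records (FLAG
#' 0x4) are skipped; a pair with only one mapped end yields that end's
#' blocks.
#'
#' @param path Path to a SAM file (plain or gzipped; header optional).
#' @param library_id Library label attached to every fragment.
#' @return A fragment tibble (see [read_fragments_bed()]).
#' @export
read_fragments_sam <- function(path, library_id = "library") {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(lines)) return(empty_fragments(library_id))
  f <- stringr::str_split_fixed(lines, "\t", 12)
  qname <- f[, 1]
  flag <- suppressWarnings(as.integer(f[, 2]))
  rname <- f[, 3]
  pos <- suppressWarnings(as.integer(f[, 4]))
  cigar <- f[, 6]
  mapped <- !bitwAnd(flag, 4L) & rname != "*" & cigar != "*"
  if (!any(mapped)) return(empty_fragments(library_id))
  qname <- qname[mapped]; flag <- flag[mapped]; rname <- rname[mapped]
  pos <- pos[mapped]; cigar <- cigar[mapped]
  bad_cigar <- !grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
  if (any(bad_cigar)) {
    abort(sprintf("cannot parse CIGAR '%s' for record QNAME '%s' in '%s'",
                  cigar[which(bad_cigar)[1]], qname[which(bad_cigar)[1]], path))
  }
  blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = c("M", "=", "X"))
  nb <- S4Vectors::elementNROWS(blocks)
  flat <- unlist(blocks)
  secondary <- bitwAnd(flag, 256L) > 0L
  # candidate index within fragment: primaries -> 1, k-th secondary -> 1 + k
  rec <- tibble(qname = qname, secondary = secondary) |>
    group_by(.data$qname) |>
    mutate(candidate = ifelse(.data$secondary, 1L + cumsum(.data$secondary), 1L)) |>
    ungroup()
  out <- tibble(
    library_id = library_id,
    fragment_id = rep(qname, nb),
    candidate = rep(rec$candidate, nb),
    chrom = rep(rname, nb),
    start = IRanges::start(flat) - 1L,
    end = IRanges::end(flat)
  ) |>
    group_by(.data$fragment_id, .data$candidate) |>
    mutate(block = dplyr::row_number()) |>
    ungroup() |>
    select("library_id", "fragment_id", "candidate", "block",
           "chrom", "start", "end")
  out
}

# Overlap every block row against the exon index; returns the input with a
# list-free long join: one row per (block row, overlapped gene).
block_gene_hits <- function(blocks, index) {
  if (!nrow(blocks)) {
    return(tibble(row = integer(), gene_id = character()))
  }
  idx_gr <- index$gr
  lev <- base::union(GenomeInfoDb::seqlevels(idx_gr), unique(blocks$chrom))
  qry <- GenomicRanges::GRanges(
    seqnames = factor(blocks$chrom, levels = lev),
    ranges = IRanges::IRanges(start = blocks$start + 1L, end = blocks$end)
  )
  GenomeInfoDb::seqlevels(idx_gr) <- lev
  hits <- GenomicRanges::findOverlaps(qry, idx_gr, ignore.strand = TRUE)
  tibble(
    row = S4Vectors::queryHits(hits),
    gene_id = S4Vectors::mcols(idx_gr)$gene_id[S4Vectors::subjectHits(hits)]
  ) |> distinct()
}

# Per-candidate summary: genes overlapped and canonical ordering key.
candidate_summary <- function(fragments, index) {
  fragments <- mutate(fragments, .row = dplyr::row_number())
  hits <- block_gene_hits(fragments, index)
  gene_sets <- fragments |>
    select(".row", "fragment_id", "candidate") |>
    left_join(hits, by = c(".row" = "row")) |>
    group_by(.data$fragment_id, .data$candidate) |>
    summarise(genes = list(sort(unique(.data$gene_id[!is.na(.data$gene_id)]))),
              .groups = "drop") |>
    mutate(n_genes = purrr::map_int(.data$genes, length))
  ord <- chrom_rank_key(fragments, attr(index, "chrom_order"))
  left_join(gene_sets, ord, by = c("fragment_id", "candidate"))
}

# Canonical position key of each candidate: smallest (chrom rank, start)
# over its blocks; chromosomes absent from the annotation order sort last,
# alphabetically.
chrom_rank_key <- function(fragments, chrom_order) {
  extra <- sort(setdiff(unique(fragments$chrom), chrom_order))
  ranks <- match(fragments$chrom, c(chrom_order, extra))
  fragments |>
    mutate(.rank = ranks) |>
    group_by(.data$fragment_id, .data$candidate) |>
    summarise(rank = min(.data$.rank),
              pos = min(.data$start[.data$.rank == min(.data$.rank)]),
              .groups = "drop")
}

#' Assign one candidate location to a gene
#'
#' @param blocks Tibble of aligned blocks for a single candidate location
#'   (columns `chrom`, `start`, `end`; 0-based half-open).
#' @param index An `exon_index` (or [annotation_set]).
#' @return The overlapped `gene_id`, or `"NO_FEATURE"` (no exon overlap) or
#'   `"AMBIGUOUS"` (exons of two or more genes overlapped).
#' @export
assign_fragment <- function(blocks, index) {
  index <- as_exon_index(index)
  hits <- block_gene_hits(as_tibble(blocks), index)
  genes <- unique(hits$gene_id)
  if (length(genes) == 0L) "NO_FEATURE"
  else if (length(genes) == 1L) genes
  else "AMBIGUOUS"
}

#' Resolve a multi-mapping fragment to one candidate location
#'
#' If exactly one candidate overlaps any gene's exon, that candidate is
#' selected. If several do, the exon-overlapping candidate that comes first
#' in canonical order is selected; if none does, the first candidate overall
#' in canonical order is selected.
#'
#' @param fragment Fragment tibble rows for one fragment (>= 2 candidates).
#' @param index An `exon_index` (or [annotation_set]).
#' @return The chosen candidate index (integer).
#' @export
resolve_multimapper <- function(fragment, index) {
  index <- as_exon_index(index)
  fragment <- as_tibble(fragment)
  if (length(unique(fragment$candidate)) < 2L) {
    abort("resolve_multimapper requires a fragment with >= 2 candidates")
  }
  cs <- candidate_summary(fragment, index)
  pick_candidate(cs)$candidate[1]
}

# Vectorised candidate choice: operates on a candidate_summary table and
# returns one row per fragment (the chosen candidate).
pick_candidate <- function(cs) {
  cs |>
    group_by(.data$fragment_id) |>
    mutate(any_exonic = any(.data$n_genes > 0L),
           eligible = !.data$any_exonic | .data$n_genes > 0L) |>
    filter(.data$eligible) |>
    arrange(.data$rank, .data$pos, .data$candidate, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
}

#' Classify a multi-mapping fragment by its candidate exon overlaps
#'
#' @inheritParams resolve_multimapper
#' @return `"multi_gene"` if the candidates collectively overlap exons of two
#'   or more genes, `"within_one_gene"` if all exon overlaps hit exactly one
#'   gene, `"no_exon"` if no candidate overlaps any exon.
#' @export
classify_multimapper <- function(fragment, index) {
  index <- as_exon_index(index)
  fragment <- as_tibble(fragment)
  if (length(unique(fragment$candidate)) < 2L) {
    abort("classify_multimapper requires a fragment with >= 2 candidates")
  }
  cs <- candidate_summary(fragment, index)
  n <- length(unique(unlist(cs$genes)))
  if (n == 0L) "no_exon" else if (n == 1L) "within_one_gene" else "multi_gene"
}

#' Count one library's fragments against an annotation
#'
#' Multi-mapping fragments are first resolved to a single candidate (see
#' [resolve_multimapper()]); every fragment is then assigned exactly once to
#' a gene, or to the no-feature or ambiguity category.
#'
#' @param fragments Fragment tibble (one library).
#' @param index An `exon_index` (or [annotation_set]).
#' @return List with `counts` (named integer vector over all annotation
#'   genes) and `stats` (one-row tibble: `library_id`, `total`, `assigned`,
#'   `unassigned_no_feature`, `unassigned_ambiguity`, `n_multimap`,
#'   `multi_gene`, `within_one_gene`, `no_exon`).
#' @export
count_library <- function(fragments, index) {
  index <- as_exon_index(index)
  fragments <- as_tibble(fragments)
  gids <- attr(index, "gene_ids")
  lib <- if (nrow(fragments)) fragments$library_id[1] else NA_character_
  if (!nrow(fragments)) {
    return(list(
      counts = setNames(integer(length(gids)), gids),
      stats = tibble(library_id = lib, total = 0L, assigned = 0L,
                     unassigned_no_feature = 0L, unassigned_ambiguity = 0L,
                     n_multimap = 0L, multi_gene = 0L, within_one_gene = 0L,
                     no_exon = 0L)
    ))
  }
  cs <- candidate_summary(fragments, index)
  n_cand <- cs |> count(.data$fragment_id, name = "n_candidates")
  cs <- left_join(cs, n_cand, by = "fragment_id")

  chosen <- bind_rows(
    filter(cs, .data$n_candidates == 1L),
    pick_candidate(filter(cs, .data$n_candidates > 1L))
  )
  chosen <- chosen |>
    mutate(outcome = dplyr::case_when(
      .data$n_genes == 0L ~ "NO_FEATURE",
      .data$n_genes == 1L ~ "ASSIGNED",
      TRUE ~ "AMBIGUOUS"
    ))
  assigned <- filter(chosen, .data$outcome == "ASSIGNED") |>
    mutate(gene_id = purrr::map_chr(.data$genes, 1))
  counts_tbl <- assigned |> count(.data$gene_id)
  counts <- setNames(integer(length(gids)), gids)
  counts[counts_tbl$gene_id] <- counts_tbl$n

  mm <- filter(cs, .data$n_candidates > 1L) |>
    group_by(.data$fragment_id) |>
    summarise(n_mm_genes = length(unique(unlist(.data$genes))), .groups = "drop") |>
    mutate(class = dplyr::case_when(
      .data$n_mm_genes == 0L ~ "no_exon",
      .data$n_mm_genes == 1L ~ "within_one_gene",
      TRUE ~ "multi_gene"
    ))
  stats <- tibble(
    library_id = lib,
    total = length(unique(fragments$fragment_id)),
    assigned = sum(chosen$outcome == "ASSIGNED"),
    unassigned_no_feature = sum(chosen$outcome == "NO_FEATURE"),
    unassigned_ambiguity = sum(chosen$outcome == "AMBIGUOUS"),
    n_multimap = nrow(mm),
    multi_gene = sum(mm$class == "multi_gene"),
    within_one_gene = sum(mm$class == "within_one_gene"),
    no_exon = sum(mm$class == "no_exon")
  )
  list(counts = counts, stats = stats)
}

#' Count fragments from several libraries into a count matrix
#'
#' @param fragments Fragment tibble covering one or more libraries (split on
#'   `library_id`), or a named list of per-library fragment tibbles.
#' @param annotation An [annotation_set] (or prebuilt `exon_index`).
#' @return A [count_matrix].
#' @export
count_fragments <- function(fragments, annotation) {
  index <- as_exon_index(annotation)
  if (is.data.frame(fragments)) {
    fragments <- split(fragments, fragments$library_id)
  }
  per_lib <- purrr::imap(fragments, function(fr, lib) {
    fr$library_id <- lib
    count_library(fr, index)
  })
  counts <- do.call(cbind, purrr::map(per_lib, "counts"))
  colnames(counts) <- names(per_lib)
  stats <- purrr::map(per_lib, "stats") |> list_rbind() |>
    mutate(library_id = names(per_lib))
  count_matrix(counts, stats = stats, annotation = attr(index, "name"))
}

#' Gene-by-library count matrix
#'
#' Container for integer fragment counts with per-library assignment
#' statistics. Column sums equal the per-library assigned-fragment tallies.
#'
#' @param counts Integer matrix, rownames = gene ids, colnames = library ids.
#' @param stats Optional per-library assignment statistics tibble (see
#'   [count_library()]).
#' @param annotation Annotation label.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, stats = NULL, annotation = "annotation") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("count matrix must have gene rownames and library colnames")
  }
  if (any(counts < 0)) abort("counts must be non-negative")
  storage.mode(counts) <- "integer"
  if (!is.null(stats)) {
    stopifnot(all(colnames(counts) %in% stats$library_id))
    stats <- stats[match(colnames(counts), stats$library_id), ]
    if (!all(colSums(counts) == stats$assigned)) {
      abort("count column sums must equal per-library assigned tallies")
    }
  }
  structure(list(counts = counts, stats = stats),
            annotation = annotation, class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d libraries (%s)\n",
              nrow(x$counts), ncol(x$counts), attr(x, "annotation")))
  invisible(x)
}

#' @rdname count_matrix
#' @param x A `count_matrix`.
#' @param type `"assigned"` (column sums; default) or `"input"` (total
#'   fragments entering assignment, requires stats). The choice feeds the
#'   per-million denominator of CPM/FPKM.
#' @export
library_sizes <- function(x, type = c("assigned", "input")) {
  type <- match.arg(type)
  if (type == "assigned" || is.null(x$stats)) {
    if (type == "input" && is.null(x$stats)) {
      warn("no assignment stats available; using assigned totals as library sizes")
    }
    colSums(x$counts)
  } else {
    setNames(as.double(x$stats$total), x$stats$library_id)
  }
}

#' @describeIn count_matrix Long tidy view (`gene_id`, `library_id`,
#'   `count`).
#' @param ... Unused.
#' @method tidy count_matrix
#' @export
tidy.count_matrix <- function(x, ...) {
  as_tibble(x$counts, rownames = "gene_id") |>
    pivot_longer(-"gene_id", names_to = "library_id", values_to = "count")
}

#' @describeIn count_matrix Per-library summary: totals and assignment
#'   fractions.
#' @method glance count_matrix
#' @export
glance.count_matrix <- function(x, ...) {
  base <- tibble(library_id = colnames(x$counts),
                 assigned = unname(colSums(x$counts)))
  if (is.null(x$stats)) return(base)
  x$stats |>
    mutate(assigned_fraction_of_total = .data$assigned / pmax(.data$total, 1L))
}

#' Fraction of assigned fragments per biotype
#'
#' @param x A [count_matrix].
#' @param annotation The [annotation_set] the counts were produced from.
#' @return Tibble `library_id`, `biotype`, `n_fragments`, `fraction`;
#'   fractions sum to 1 per library over assigned fragments (all zero, with
#'   a warning, if nothing was assigned).
#' @export
assigned_fraction_by_biotype <- function(x, annotation) {
  bt <- annotation$genes |>
    mutate(biotype = ifelse(is.na(.data$biotype), "unannotated", .data$biotype)) |>
    select("gene_id", "biotype")
  long <- tidy(x) |>
    inner_join(bt, by = "gene_id") |>
    group_by(.data$library_id, .data$biotype) |>
    summarise(n_fragments = sum(.data$count), .groups = "drop_last") |>
    mutate(total = sum(.data$n_fragments),
           fraction = ifelse(.data$total > 0, .data$n_fragments / .data$total, 0)) |>
    ungroup() |>
    select(-"total")
  if (any(tapply(long$n_fragments, long$library_id, sum) == 0)) {
    warn("some libraries have zero assigned fragments; fractions reported as 0")
  }
  long
}

#' Write a featureCounts-like count table and its summary
#'
#' @param x A [count_matrix].
#' @param annotation The matching [annotation_set] (for gene lengths).
#' @param path Output TSV path for the counts; the per-library summary is
#'   written next to it with suffix `.summary.tsv`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, annotation, path) {
  len <- effective_lengths(annotation)
  tab <- as_tibble(x$counts, rownames = "gene_id") |>
    left_join(len, by = "gene_id") |>
    relocate("effective_length", .after = "gene_id")
  write_tsv_det(tab, path)
  if (!is.null(x$stats)) {
    write_tsv_det(x$stats, sub("\\.tsv$", ".summary.tsv", path))
  }
  invisible(path)
}
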