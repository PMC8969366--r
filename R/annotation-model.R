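# Gene-model container and exon-union arithmetic.
#
# Coordinate convention: GTF files are 1-based inclusive on disk; internally
# every interval is 0-based half-open [start, end). All widths and unions are
# computed on that convention. Strand is stored but ignored for overlap and
# length computations (unstranded counting).

#' Construct an annotation set
#'
#' An `annotation_set` holds the exon-union gene models of one annotation:
#' a table of exon intervals (0-based half-open) and a table of per-gene
#' metadata. Genes admitted to an annotation set always have at least one
#' exon; intron-only entries in a GTF are excluded at parse time.
#'
#' @param exons Tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`. Coordinates 0-based half-open; `end > start >= 0`.
#' @param genes Optional tibble with columns `gene_id` and any of `symbol`,
#'   `biotype`, `entrez_id`. Defaults are derived from `exons`.
#' @param name Label for the annotation (e.g. source/version).
#' @param chrom_order Chromosome names in canonical order; defaults to order
#'   of first appearance in `exons`. Must cover every chromosome referenced.
#' @param n_excluded,excluded_ids Bookkeeping for genes dropped for having no
#'   exon records.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(exons, genes = NULL, name = "annotation",
                           chrom_order = NULL, n_excluded = 0L,
                           excluded_ids = character()) {
  exons <- as_tibble(exons)
  req <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(req %in% names(exons))) {
    abort(sprintf("exon table must have columns %s", paste(req, collapse = ", ")))
  }
  exons <- exons[req]
  if (nrow(exons)) {
    if (any(exons$end <= exons$start)) abort("exon intervals must satisfy end > start")
    if (any(exons$start < 0)) abort("exon starts must be >= 0")
  }
  if (is.null(genes)) {
    genes <- distinct(exons, .data$gene_id) |>
      mutate(symbol = NA_character_, biotype = NA_character_,
             entrez_id = NA_character_)
  } else {
    genes <- as_tibble(genes)
    if (!"gene_id" %in% names(genes)) abort("gene table must have a gene_id column")
    for (col in c("symbol", "biotype", "entrez_id")) {
      if (!col %in% names(genes)) genes[[col]] <- NA_character_
    }
    genes <- genes[c("gene_id", "symbol", "biotype", "entrez_id",
                     setdiff(names(genes), c("gene_id", "symbol", "biotype", "entrez_id")))]
  }
  if (anyDuplicated(genes$gene_id)) abort("gene_id must be unique within an annotation")
  missing_exons <- setdiff(genes$gene_id, exons$gene_id)
  if (length(missing_exons)) {
    abort(sprintf("genes without exons cannot be admitted: %s",
                  paste(head(missing_exons, 5), collapse = ", ")))
  }
  genes <- filter(genes, .data$gene_id %in% unique(exons$gene_id)) |>
    arrange(match(.data$gene_id, unique(exons$gene_id)))
  if (is.null(chrom_order)) chrom_order <- unique(exons$chrom)
  if (!all(exons$chrom %in% chrom_order)) {
    abort("chrom_order must contain every chromosome referenced by an exon")
  }
  structure(
    list(exons = exons, genes = genes),
    name = name, chrom_order = chrom_order,
    n_excluded = as.integer(n_excluded), excluded_ids = excluded_ids,
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %s: %d genes, %d exon records on %d chromosomes\n",
              annotation_name(x), nrow(x$genes), nrow(x$exons),
              length(attr(x, "chrom_order"))))
  if (attr(x, "n_excluded") > 0) {
    cat(sprintf("  (%d genes without exon records excluded at parse time)\n",
                attr(x, "n_excluded")))
  }
  invisible(x)
}

#' @rdname annotation_set
#' @param x An `annotation_set`.
#' @export
annotation_name <- function(x) attr(x, "name")

#' @rdname annotation_set
#' @export
chrom_order <- function(x) attr(x, "chrom_order")

#' @rdname annotation_set
#' @export
n_genes <- function(x) nrow(x$genes)

#' @rdname annotation_set
#' @export
gene_ids <- function(x) x$genes$gene_id

# GRanges view of the exon table (1-based closed, as GenomicRanges expects).
exon_granges <- function(x) {
  exons <- if (inherits(x, "annotation_set")) x$exons else as_tibble(x)
  GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = exons$start + 1L, end = exons$end),
    gene_id = exons$gene_id
  )
}

#' Read a GTF annotation into an annotation set
#'
#' Parses a GTF file (tab-separated, 9 columns, 1-based inclusive
#' coordinates) into an [annotation_set]. Only `exon` feature rows define the
#' quantification structure; `gene`/`transcript`/`CDS` rows contribute gene
#' metadata only. Genes with no exon rows are excluded and counted. Gzipped
#' files are read transparently.
#'
#' @param path Path to a GTF file (optionally gzipped).
#' @param dialect One of `"ensembl"`, `"refseq"`, `"generic"`. Both dialects
#'   read the biotype from the `gene_biotype` attribute with a fallback to
#'   `gene_type`; the RefSeq dialect additionally parses `db_xref
#'   "GeneID:<n>"` entries into `entrez_id`.
#' @param name Label for the annotation; defaults to the file name.
#' @return An [annotation_set].
#' @export
read_gtf <- function(path, dialect = c("ensembl", "refseq", "generic"),
                     name = NULL) {
  dialect <- match.arg(dialect)
  name <- name %||% sub("\\.(gtf|gff)(\\.gz)?$", "", basename(path))
  lines <- readr::read_lines(path, progress = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  if (!length(body)) {
    warn(sprintf("GTF file '%s' contains no feature lines; returning an empty annotation", path))
    return(annotation_set(
      tibble(gene_id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character()),
      name = name
    ))
  }
  nfields <- stringr::str_count(lines[body], stringr::fixed("\t")) + 1L
  bad <- body[nfields < 9L]
  if (length(bad)) {
    abort(sprintf("malformed GTF line %d in '%s': expected 9 tab-separated fields, found %d",
                  bad[1], path, nfields[match(bad[1], body)]))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)

  get_attr <- function(key) {
    if (!key %in% names(mc)) return(rep(NA_character_, length(gr)))
    v <- mc[[key]]
    if (methods::is(v, "List")) {
      v <- vapply(v, function(e) if (length(e)) paste(e, collapse = ";") else NA_character_, character(1))
    }
    as.character(v)
  }
  gid <- get_attr("gene_id")
  if (all(is.na(gid))) abort(sprintf("GTF file '%s' has no gene_id attributes", path))
  biotype <- get_attr("gene_biotype")
  fallback <- get_attr("gene_type")
  biotype <- ifelse(is.na(biotype), fallback, biotype)
  symbol <- get_attr("gene_name")
  symbol <- ifelse(is.na(symbol), get_attr("gene"), symbol)
  entrez <- rep(NA_character_, length(gr))
  if (dialect == "refseq") {
    xref <- get_attr("db_xref")
    m <- stringr::str_match(xref, "GeneID:([0-9]+)")[, 2]
    entrez <- m
  }

  feat <- tibble(
    type = as.character(mc$type),
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    symbol = symbol, biotype = biotype, entrez_id = entrez
  ) |>
    filter(!is.na(.data$gene_id)) |>
    mutate(strand = ifelse(.data$strand %in% c("+", "-"), .data$strand, "*"))

  exons <- filter(feat, .data$type == "exon")
  first_non_na <- function(v) {
    v <- v[!is.na(v)]
    if (length(v)) v[1] else NA_character_
  }
  meta <- feat |>
    group_by(.data$gene_id) |>
    summarise(symbol = first_non_na(.data$symbol),
              biotype = first_non_na(.data$biotype),
              entrez_id = first_non_na(.data$entrez_id), .groups = "drop")
  with_exons <- unique(exons$gene_id)
  excluded <- setdiff(unique(feat$gene_id), with_exons)
  genes <- meta |>
    filter(.data$gene_id %in% with_exons) |>
    arrange(match(.data$gene_id, with_exons))
  annotation_set(
    exons[c("gene_id", "chrom", "start", "end", "strand")],
    genes = genes, name = name,
    n_excluded = length(excluded), excluded_ids = excluded
  )
}

#' Write an annotation set to GTF
#'
#' Writes one `exon` feature row per exon interval, converting back to the
#' GTF 1-based inclusive convention. Gene metadata (biotype, symbol, Entrez
#' id) is emitted as attributes so that a read/write/read round trip
#' preserves identifiers, biotypes and effective lengths.
#'
#' @param x An [annotation_set].
#' @param path Output path (`.gtf` or `.gtf.gz`).
#' @return `path`, invisibly.
#' @export
write_gtf <- function(x, path) {
  ex <- left_join(x$exons, x$genes, by = "gene_id")
  gr <- GenomicRanges::GRanges(
    seqnames = factor(ex$chrom, levels = chrom_order(x)),
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ifelse(ex$strand %in% c("+", "-"), ex$strand, "*")
  )
  mc <- S4Vectors::DataFrame(
    source = "annobench", type = "exon",
    gene_id = ex$gene_id, transcript_id = paste0(ex$gene_id, ".t1")
  )
  if (any(!is.na(ex$biotype))) mc$gene_biotype <- ex$biotype
  if (any(!is.na(ex$symbol))) mc$gene_name <- ex$symbol
  if (any(!is.na(ex$entrez_id))) {
    mc$db_xref <- ifelse(is.na(ex$entrez_id), NA_character_,
                         paste0("GeneID:", ex$entrez_id))
  }
  S4Vectors::mcols(gr) <- mc
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Collapse overlapping exons within each gene
#'
#' Merges overlapping and book-ended (adjacent) exons of the same gene into
#' maximal disjoint intervals. Effective lengths are unchanged; the exon
#' representation becomes canonical and minimal.
#'
#' @param x An [annotation_set] or an exon tibble
#'   (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @return Same type as the input, with pairwise-disjoint exons per gene.
#' @export
collapse_exons <- function(x) {
  is_set <- inherits(x, "annotation_set")
  exons <- if (is_set) x$exons else as_tibble(x)
  if (!nrow(exons)) return(x)
  strand_of <- exons |> distinct(.data$gene_id, .keep_all = TRUE) |>
    select("gene_id", "strand")
  gr <- exon_granges(exons)
  parts <- S4Vectors::split(gr, S4Vectors::mcols(gr)$gene_id)
  red <- GenomicRanges::reduce(parts, ignore.strand = TRUE)  # merges adjacent
  flat <- unlist(red, use.names = TRUE)
  out <- tibble(
    gene_id = names(flat),
    chrom = as.character(GenomicRanges::seqnames(flat)),
    start = GenomicRanges::start(flat) - 1L,
    end = GenomicRanges::end(flat)
  ) |>
    left_join(strand_of, by = "gene_id") |>
    arrange(match(.data$gene_id, unique(exons$gene_id)), .data$chrom, .data$start)
  if (!is_set) return(out)
  annotation_set(out, genes = x$genes, name = annotation_name(x),
                 chrom_order = chrom_order(x),
                 n_excluded = attr(x, "n_excluded"),
                 excluded_ids = attr(x, "excluded_ids"))
}

#' Effective gene length
#'
#' The effective length of a gene is the number of unique bases in the union
#' of its exons ("exon-union length"). Exons on different chromosomes
#' contribute independent unions that are summed.
#'
#' @param exons A tibble of exon intervals for a single gene (columns
#'   `chrom`, `start`, `end`; 0-based half-open).
#' @return Integer number of bases.
#' @export
effective_length <- function(exons) {
  exons <- as_tibble(exons)
  if (!nrow(exons)) abort("a gene must have at least one exon")
  if (!"gene_id" %in% names(exons)) exons$gene_id <- "gene"
  if (!"strand" %in% names(exons)) exons$strand <- "*"
  gr <- exon_granges(exons)
  sum(GenomicRanges::width(GenomicRanges::reduce(gr, ignore.strand = TRUE)))
}

#' Effective lengths of every gene in an annotation
#'
#' @param x An [annotation_set].
#' @return Tibble with columns `gene_id`, `effective_length`, in annotation
#'   gene order.
#' @export
effective_lengths <- function(x) {
  gr <- exon_granges(x)
  parts <- S4Vectors::split(gr, factor(S4Vectors::mcols(gr)$gene_id,
                                       levels = gene_ids(x)))
  red <- GenomicRanges::reduce(parts, ignore.strand = TRUE)
  len <- sum(GenomicRanges::width(red))
  tibble(gene_id = names(len), effective_length = as.integer(unname(len)))
}

#' Transcriptome size of an annotation
#'
#' Sum of effective gene lengths over all genes. Bases shared between
#' overlapping genes are counted once per gene (a per-gene sum, not a genomic
#' union), so the figure represents the total annotated exonic bases summed
#' over gene models.
#'
#' @param x An [annotation_set].
#' @return Integer (double for very large annotations) number of bases.
#' @export
transcriptome_size <- function(x) {
  if (!nrow(x$exons)) return(0L)
  sum(as.numeric(effective_lengths(x)$effective_length))
}

#' Find pairs of genes with overlapping exons
#'
#' Returns every unordered pair of distinct genes that share at least one
#' exonic base. Strand is ignored.
#'
#' @param x An [annotation_set].
#' @return Tibble with columns `gene_id_a`, `gene_id_b` (each pair once,
#'   `gene_id_a < gene_id_b`).
#' @export
find_overlapping_gene_pairs <- function(x) {
  if (!nrow(x$exons)) {
    return(tibble(gene_id_a = character(), gene_id_b = character()))
  }
  gr <- exon_granges(x)
  hits <- GenomicRanges::findOverlaps(gr, ignore.strand = TRUE,
                                      drop.self = TRUE, drop.redundant = TRUE)
  g1 <- S4Vectors::mcols(gr)$gene_id[S4Vectors::queryHits(hits)]
  g2 <- S4Vectors::mcols(gr)$gene_id[S4Vectors::subjectHits(hits)]
  keep <- g1 != g2
  tibble(gene_id_a = pmin(g1[keep], g2[keep]),
         gene_id_b = pmax(g1[keep], g2[keep])) |>
    distinct() |>
    arrange(.data$gene_id_a, .data$gene_id_b)
}

#' Count genes per biotype
#'
#' @param x An [annotation_set].
#' @return Tibble with columns `biotype`, `n_genes`; genes without a biotype
#'   are grouped as `"unannotated"`. Counts sum to the number of genes.
#' @export
biotype_summary <- function(x) {
  if (!nrow(x$genes)) return(tibble(biotype = character(), n_genes = integer()))
  x$genes |>
    mutate(biotype = ifelse(is.na(.data$biotype), "unannotated", .data$biotype)) |>
    count(.data$biotype, name = "n_genes") |>
    arrange(desc(.data$n_genes), .data$biotype)
}

#' Per-gene summary table of an annotation
#'
#' One row per gene: identifiers, biotype, chromosome(s), strand, exon count
#' after collapsing, and effective length. This is the TSV gene table the
#' reporting pipeline writes.
#'
#' @param x An [annotation_set].
#' @return A tibble.
#' @export
gene_table <- function(x) {
  col <- collapse_exons(x)
  ex_sum <- col$exons |>
    group_by(.data$gene_id) |>
    summarise(chrom = paste(unique(.data$chrom), collapse = ";"),
              strand = paste(unique(.data$strand), collapse = ";"),
              n_exons = dplyr::n(), .groups = "drop")
  x$genes |>
    left_join(ex_sum, by = "gene_id") |>
    left_join(effective_lengths(x), by = "gene_id") |>
    select("gene_id", "symbol", "biotype", "chrom", "strand",
           "n_exons", "effective_length")
}

#' JSON-ready summary of an annotation
#'
#' @param x An [annotation_set].
#' @return A named list (annotation name, gene counts, exclusions,
#'   transcriptome size, biotype counts).
#' @export
annotation_summary <- function(x) {
  bt <- biotype_summary(x)
  list(
    name = annotation_name(x),
    n_genes = n_genes(x),
    n_excluded_no_exon = attr(x, "n_excluded"),
    n_exon_records = nrow(x$exons),
    transcriptome_size = transcriptome_size(x),
    median_effective_length = stats::median(effective_lengths(x)$effective_length),
    biotypes = setNames(as.list(bt$n_genes), bt$biotype)
  )
}

#' @describeIn annotation_set Tidy view: the per-gene table ([gene_table]).
#' @param ... Unused.
#' @method tidy annotation_set
#' @export
tidy.annotation_set <- function(x, ...) gene_table(x)

#' @describeIn annotation_set One-row summary (gene count, exclusions,
#'   transcriptome size, median effective length).
#' @method glance annotation_set
#' @export
glance.annotation_set <- function(x, ...) {
  tibble(name = annotation_name(x), n_genes = n_genes(x),
         n_excluded_no_exon = attr(x, "n_excluded"),
         transcriptome_size = transcriptome_size(x),
         median_effective_length =
           if (n_genes(x)) stats::median(effective_lengths(x)$effective_length) else NA_real_)
}

#' @describeIn annotation_set Boxplot of per-gene effective lengths
#'   (log2 scale).
#' @param object An `annotation_set`.
#' @method autoplot annotation_set
#' @export
autoplot.annotation_set <- function(object, ...) {
  dat <- effective_lengths(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = annotation_name(object),
                                    y = log2(.data$effective_length))) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "log2 effective gene length (bases)") +
    ggplot2::theme_minimal()
}
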