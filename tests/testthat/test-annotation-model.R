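# Gene-model parsing and exon-union arithmetic.

test_that("read_gtf converts coordinates, excludes exon-less genes, and handles empty files", {
  path <- write_toy_gtf(c(
    gtf_line("chr1", "gene", 101, 200, "gA"),
    gtf_line("chr1", "exon", 101, 200, "gA"),
    gtf_line("chr1", "gene", 501, 900, "gB"),   # intron-only gene: no exon rows
    gtf_line("chr1", "CDS", 501, 600, "gB")
  ))
  ann <- read_gtf(path, dialect = "ensembl")
  expect_equal(n_genes(ann), 1L)
  expect_equal(attr(ann, "n_excluded"), 1L)
  expect_equal(attr(ann, "excluded_ids"), "gB")
  # GTF start=101,end=200 (1-based inclusive) -> [100, 200), length 100
  expect_equal(ann$exons$start, 100L)
  expect_equal(ann$exons$end, 200L)
  expect_equal(effective_lengths(ann)$effective_length, 100L)

  empty <- write_toy_gtf("# only a comment")
  expect_warning(e <- read_gtf(empty, dialect = "ensembl"), "no feature lines")
  expect_equal(n_genes(e), 0L)
})

test_that("read_gtf reports malformed lines by number and rejects unknown dialects", {
  path <- write_toy_gtf(c(
    gtf_line("chr1", "exon", 101, 200, "gA"),
    "chr1\tbroken line without enough fields"
  ))
  expect_error(read_gtf(path, dialect = "ensembl"), "line 2")
  expect_error(read_gtf(path, dialect = "nonsense"), "arg")
})

test_that("GTF dialects pick up biotype fallbacks and RefSeq Entrez ids", {
  path <- write_toy_gtf(c(
    sprintf('chr1\ttoy\texon\t101\t200\t.\t+\t.\tgene_id "gA"; gene_type "lncRNA"; db_xref "GeneID:1234"; gene_name "ABC";'),
    gtf_line("chr1", "exon", 301, 400, "gB", biotype = "protein_coding")
  ))
  ann <- read_gtf(path, dialect = "refseq")
  ga <- ann$genes[ann$genes$gene_id == "gA", ]
  expect_equal(ga$biotype, "lncRNA")     # gene_type fallback
  expect_equal(ga$entrez_id, "1234")     # db_xref GeneID parsing
  expect_equal(ga$symbol, "ABC")
  ens <- read_gtf(path, dialect = "ensembl")
  expect_true(is.na(ens$genes$entrez_id[ens$genes$gene_id == "gA"]))
})

test_that("effective_length matches union arithmetic and the base-set oracle", {
  overlapping <- tibble::tibble(gene_id = "g", chrom = "chr1",
                                start = c(0L, 50L), end = c(100L, 150L), strand = "+")
  expect_equal(effective_length(overlapping), 150L)
  disjoint <- tibble::tibble(gene_id = "g", chrom = "chr1",
                             start = c(0L, 200L), end = c(100L, 300L), strand = "+")
  expect_equal(effective_length(disjoint), 200L)
  for (seed in 1:5) {
    ex <- random_exon_tbl(50, seed)
    expect_equal(effective_length(ex), oracle_union_length(ex))
  }
})

test_that("collapse_exons yields disjoint exons, merges adjacency, preserves length, is idempotent", {
  ex <- tibble::tibble(gene_id = "g", chrom = "chr1",
                       start = c(0L, 50L), end = c(100L, 150L), strand = "+")
  col <- collapse_exons(ex)
  expect_equal(nrow(col), 1L)
  expect_equal(c(col$start, col$end), c(0L, 150L))
  adjacent <- tibble::tibble(gene_id = "g", chrom = "chr1",
                             start = c(0L, 100L), end = c(100L, 200L), strand = "+")
  expect_equal(nrow(collapse_exons(adjacent)), 1L)
  expect_equal(effective_length(collapse_exons(adjacent)), 200L)
  for (seed in 6:10) {
    ex <- random_exon_tbl(30, seed)
    col <- collapse_exons(ex)
    expect_equal(effective_length(col), oracle_union_length(ex))
    expect_equal(collapse_exons(col), col)  # idempotence
    # pairwise disjoint within chromosome
    for (ch in unique(col$chrom)) {
      cc <- col[col$chrom == ch, ]
      cc <- cc[order(cc$start), ]
      if (nrow(cc) > 1) expect_true(all(cc$start[-1] > cc$end[-nrow(cc)]))
    }
  }
})

test_that("transcriptome_size is a per-gene sum, additive over partitions", {
  ex <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "chr1",
    start = c(0L, 200L), end = c(150L, 400L), strand = "+")
  a <- annotation_set(ex, name = "two")
  expect_equal(transcriptome_size(a), 350)
  empty <- annotation_set(ex[0, ], name = "none")
  expect_equal(transcriptome_size(empty), 0L)
  # two genes sharing 50 bases: counted once per gene
  shared <- annotation_set(tibble::tibble(
    gene_id = c("gx", "gy"), chrom = "chr1",
    start = c(0L, 50L), end = c(100L, 150L), strand = "+"), name = "shared")
  expect_equal(transcriptome_size(shared), 200)
  # additivity over a disjoint partition of genes
  big <- random_toy_annotation(20, seed = 11)
  half1 <- annotation_set(big$exons[big$exons$gene_id %in% sprintf("g%03d", 1:10), ],
                          name = "h1", chrom_order = chrom_order(big))
  half2 <- annotation_set(big$exons[big$exons$gene_id %in% sprintf("g%03d", 11:20), ],
                          name = "h2", chrom_order = chrom_order(big))
  expect_equal(transcriptome_size(big),
               transcriptome_size(half1) + transcriptome_size(half2))
})

test_that("find_overlapping_gene_pairs matches all-pairs brute force", {
  simple <- annotation_set(tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "chr1",
    start = c(0L, 50L), end = c(100L, 60L), strand = c("+", "-")), name = "s")
  expect_equal(nrow(find_overlapping_gene_pairs(simple)), 1L)  # strand ignored
  disjoint <- annotation_set(tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "chr1",
    start = c(0L, 500L), end = c(100L, 600L), strand = "+"), name = "d")
  expect_equal(nrow(find_overlapping_gene_pairs(disjoint)), 0L)
  for (seed in 21:23) {
    ann <- random_toy_annotation(100, seed)
    got <- as.data.frame(find_overlapping_gene_pairs(ann))
    want <- oracle_overlap_pairs(ann$exons)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("biotype_summary counts every gene, grouping missing biotypes", {
  ex <- tibble::tibble(gene_id = sprintf("g%d", 1:5), chrom = "chr1",
                       start = (0:4) * 1000L, end = (0:4) * 1000L + 100L,
                       strand = "+")
  genes <- tibble::tibble(gene_id = sprintf("g%d", 1:5),
                          biotype = c("protein_coding", "protein_coding",
                                      "protein_coding", "lncRNA", NA))
  a <- annotation_set(ex, genes = genes, name = "bt")
  bs <- biotype_summary(a)
  expect_equal(sum(bs$n_genes), 5L)
  expect_equal(bs$n_genes[bs$biotype == "protein_coding"], 3L)
  expect_equal(bs$n_genes[bs$biotype == "unannotated"], 1L)
  expect_equal(nrow(biotype_summary(annotation_set(ex[0, ], name = "e"))), 0L)
})

test_that("GTF write/read round trip preserves ids, biotypes and effective lengths", {
  ann <- random_toy_annotation(25, seed = 31)
  genes <- ann$genes
  genes$biotype <- sample(c("protein_coding", "lncRNA"), nrow(genes), TRUE)
  ann <- annotation_set(ann$exons, genes = genes, name = "rt",
                        chrom_order = chrom_order(ann))
  path <- tempfile(fileext = ".gtf")
  write_gtf(ann, path)
  back <- read_gtf(path, dialect = "ensembl")
  expect_setequal(gene_ids(back), gene_ids(ann))
  l1 <- effective_lengths(ann); l2 <- effective_lengths(back)
  expect_equal(l2$effective_length[match(l1$gene_id, l2$gene_id)],
               l1$effective_length)
  b1 <- ann$genes$biotype[match(gene_ids(back), gene_ids(ann))]
  expect_equal(back$genes$biotype, b1)
})

test_that("annotation_set enforces its invariants", {
  ex <- tibble::tibble(gene_id = "g", chrom = "chr1", start = 10L, end = 5L,
                       strand = "+")
  expect_error(annotation_set(ex), "end > start")
  ex2 <- tibble::tibble(gene_id = "g", chrom = "chr1", start = 0L, end = 10L,
                        strand = "+")
  expect_error(annotation_set(ex2, genes = tibble::tibble(gene_id = c("g", "h"))),
               "without exons")
  expect_error(annotation_set(ex2, chrom_order = "chr2"), "chrom_order")
})
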