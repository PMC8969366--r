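# featureCounts-style assignment: readers, decision rules, counting.

decision_annotation <- function() {
  # gene1: exons [100,200) and [500,600) (intron [200,500)); gene2: [300,400)
  # -- note gene2 sits inside gene1's intron, so nothing overlaps two genes
  annotation_set(tibble::tibble(
    gene_id = c("gene1", "gene1", "gene2"), chrom = "chr1",
    start = c(100L, 500L, 300L), end = c(200L, 600L, 400L), strand = "+"),
    name = "decision", chrom_order = c("chr1", "chr2"))
}

cand_block <- function(type, fragment_id = "f1", candidate = 1L) {
  pos <- switch(type,
    exonic_g1 = c(120L, 170L), exonic_g2 = c(320L, 370L),
    exonic_g1b = c(520L, 570L),           # second exon of gene1
    intronic = c(230L, 280L), intergenic = c(5000L, 5050L))
  tibble::tibble(library_id = "L1", fragment_id = fragment_id,
                 candidate = candidate, block = 1L, chrom = "chr1",
                 start = pos[1], end = pos[2])
}

test_that("BED reader groups multi-mapping candidates by name", {
  p <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t60", "chr1\t100\t160", "chr2\t5\t55"), p)
  fr <- read_fragments_bed(p, "L1")
  expect_equal(nrow(fr), 3L)
  expect_equal(length(unique(fr$fragment_id)), 3L)
  expect_true(all(fr$candidate == 1L))

  p2 <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t60\tf1", "chr2\t100\t160\tf1", "chr1\t0\t50\tf2"), p2)
  fr2 <- read_fragments_bed(p2, "L1")
  expect_equal(sort(unique(fr2$fragment_id)), c("f1", "f2"))
  expect_equal(max(fr2$candidate[fr2$fragment_id == "f1"]), 2L)

  p3 <- tempfile(fileext = ".bed")
  file.create(p3)
  expect_equal(nrow(read_fragments_bed(p3)), 0L)
  p4 <- tempfile(fileext = ".bed")
  writeLines("chr1\t50\t10", p4)
  expect_error(read_fragments_bed(p4), "malformed interval on line 1")
})

test_that("SAM reader combines mates, splits N gaps and adds secondary candidates", {
  p <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:100000",
    # proper pair: two ends, one 100M block each
    "p1\t99\tchr1\t1001\t255\t100M\t=\t1301\t400\t*\t*",
    "p1\t147\tchr1\t1301\t255\t100M\t=\t1001\t-400\t*\t*",
    # spliced read: 50M200N50M -> two blocks
    "s1\t0\tchr1\t2001\t255\t50M200N50M\t*\t0\t0\t*\t*",
    # primary + one secondary alignment
    "m1\t0\tchr1\t3001\t255\t60M\t*\t0\t0\t*\t*",
    "m1\t256\tchr1\t9001\t255\t60M\t*\t0\t0\t*\t*",
    # unmapped record: skipped
    "u1\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"
  ), p)
  fr <- read_fragments_sam(p, "L1")
  expect_setequal(unique(fr$fragment_id), c("p1", "s1", "m1"))
  p1 <- fr[fr$fragment_id == "p1", ]
  expect_equal(nrow(p1), 2L)                 # both ends' blocks, one candidate
  expect_true(all(p1$candidate == 1L))
  expect_equal(sort(p1$start), c(1000L, 1300L))
  s1 <- fr[fr$fragment_id == "s1", ]
  # reference-walk: 50M at 2001..2050, N skips 200, 50M at 2251..2300
  expect_equal(s1$start, c(2000L, 2250L))
  expect_equal(s1$end, c(2050L, 2300L))
  m1 <- fr[fr$fragment_id == "m1", ]
  expect_equal(sort(unique(m1$candidate)), c(1L, 2L))

  bad <- tempfile(fileext = ".sam")
  writeLines("q7\t0\tchr1\t100\t255\tBADCIGAR\t*\t0\t0\t*\t*", bad)
  expect_error(read_fragments_sam(bad), "q7")
})

test_that("assign_fragment implements the exon-overlap rule", {
  idx <- build_exon_index(decision_annotation())
  expect_equal(assign_fragment(cand_block("exonic_g1"), idx), "gene1")
  expect_equal(assign_fragment(cand_block("intronic"), idx), "NO_FEATURE")
  expect_equal(assign_fragment(cand_block("intergenic"), idx), "NO_FEATURE")
  # block spanning exons of two genes
  both <- tibble::tibble(library_id = "L1", fragment_id = "f", candidate = 1L,
                         block = 1L, chrom = "chr1", start = 150L, end = 350L)
  expect_equal(assign_fragment(both, idx), "AMBIGUOUS")
})

test_that("multi-mapper resolution and classification reproduce the decision table exhaustively", {
  ann <- decision_annotation()
  idx <- build_exon_index(ann)
  types <- c("exonic_g1", "exonic_g2", "exonic_g1b", "intronic", "intergenic")
  type_genes <- list(exonic_g1 = "gene1", exonic_g2 = "gene2",
                     exonic_g1b = "gene1", intronic = character(0),
                     intergenic = character(0))
  type_pos <- c(exonic_g1 = 120L, exonic_g2 = 320L, exonic_g1b = 520L,
                intronic = 230L, intergenic = 5000L)
  # independent evaluation of the stated rules
  expected_choice <- function(combo) {
    exonic <- unname(which(lengths(type_genes[combo]) > 0))
    if (length(exonic) == 1L) return(exonic)
    pool <- if (length(exonic) > 1L) exonic else seq_along(combo)
    unname(pool[order(type_pos[combo[pool]], pool)][1])
  }
  expected_class <- function(combo) {
    g <- unique(unlist(type_genes[combo]))
    if (length(g) == 0) "no_exon" else if (length(g) == 1) "within_one_gene"
    else "multi_gene"
  }
  combos <- c(
    lapply(seq_len(length(types)^2), function(i) {
      c(types[(i - 1) %/% 5 + 1], types[(i - 1) %% 5 + 1])
    }),
    lapply(seq_len(length(types)^3), function(i) {
      c(types[(i - 1) %/% 25 + 1], types[((i - 1) %/% 5) %% 5 + 1],
        types[(i - 1) %% 5 + 1])
    })
  )
  for (combo in combos) {
    fr <- dplyr::bind_rows(lapply(seq_along(combo), function(ci) {
      cand_block(combo[ci], candidate = ci)
    }))
    expect_equal(resolve_multimapper(fr, idx), expected_choice(combo),
                 info = paste(combo, collapse = "+"))
    expect_equal(classify_multimapper(fr, idx), expected_class(combo),
                 info = paste(combo, collapse = "+"))
  }
  # the intronic-vs-exonic preference, directly
  expect_equal(resolve_multimapper(dplyr::bind_rows(
    cand_block("intronic", candidate = 1L),
    cand_block("exonic_g1", candidate = 2L)), idx), 2L)
})

test_that("count_library matches the brute-force oracle on random toys", {
  for (seed in 1:6) {
    ann <- random_toy_annotation(60, seed = 100 + seed)
    frags <- random_toy_fragments(400, seed = 200 + seed)
    got <- count_library(frags, ann)
    want <- oracle_count_library(as.data.frame(frags),
                                 as.data.frame(collapse_exons(ann)$exons),
                                 chrom_order(ann))
    expect_equal(got$counts, want$counts)
    expect_equal(got$stats$assigned, want$assigned)
    expect_equal(got$stats$unassigned_no_feature, want$no_feature)
    expect_equal(got$stats$unassigned_ambiguity, want$ambiguous)
    expect_equal(got$stats$multi_gene, unname(want$mm_class["multi_gene"]))
    expect_equal(got$stats$within_one_gene, unname(want$mm_class["within_one_gene"]))
    expect_equal(got$stats$no_exon, unname(want$mm_class["no_exon"]))
    # conservation
    expect_equal(got$stats$assigned + got$stats$unassigned_no_feature +
                   got$stats$unassigned_ambiguity, got$stats$total)
  }
})

test_that("fragment input order does not change counts or tallies", {
  ann <- random_toy_annotation(40, seed = 301)
  frags <- random_toy_fragments(300, seed = 302)
  got1 <- count_library(frags, ann)
  perm <- withr::with_seed(1, frags[sample.int(nrow(frags)), ])
  got2 <- count_library(perm, ann)
  expect_equal(got1$counts, got2$counts)
  expect_equal(got1$stats, got2$stats)
})

test_that("count_library handles empty input and single-gene saturation", {
  ann <- decision_annotation()
  empty <- count_library(empty_frag_tbl(), ann)
  expect_true(all(empty$counts == 0L))
  expect_equal(empty$stats$total, 0L)

  ten <- dplyr::bind_rows(lapply(1:10, function(i) {
    cand_block("exonic_g1", fragment_id = sprintf("f%d", i))
  }))
  res <- count_library(ten, ann)
  expect_equal(unname(res$counts["gene1"]), 10L)
  expect_equal(res$stats$assigned, 10L)
})

test_that("count_fragments builds a consistent matrix and biotype fractions", {
  ann <- random_toy_annotation(30, seed = 401)
  genes <- ann$genes
  genes$biotype <- rep(c("protein_coding", "pseudogene"), length.out = nrow(genes))
  ann <- annotation_set(ann$exons, genes = genes, name = "bt",
                        chrom_order = chrom_order(ann))
  frags <- dplyr::bind_rows(
    dplyr::mutate(random_toy_fragments(150, seed = 402), library_id = "L1"),
    dplyr::mutate(random_toy_fragments(150, seed = 403), library_id = "L2"))
  cm <- count_fragments(frags, ann)
  expect_equal(unname(colSums(cm$counts)), cm$stats$assigned)
  fb <- assigned_fraction_by_biotype(cm, ann)
  sums <- tapply(fb$fraction, fb$library_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12 | sums == 0))
})
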