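# Independent oracles and toy-data builders. Everything here is written as
# literal, slow brute force (base enumeration, all-pairs loops, step-by-step
# formulas) so it shares no code path with the package implementation.

# Number of unique bases in a set of [start, end) intervals, by explicit
# base enumeration per chromosome.
oracle_union_length <- function(exons) {
  sum(vapply(split(exons, exons$chrom), function(e) {
    length(unique(unlist(Map(function(s, en) seq(s, en - 1L), e$start, e$end))))
  }, numeric(1)))
}

# All-pairs overlapping-gene search by quadratic loops over exons.
oracle_overlap_pairs <- function(exons) {
  out <- list()
  genes <- unique(exons$gene_id)
  for (i in seq_along(genes)) for (j in seq_len(i - 1L)) {
    ei <- exons[exons$gene_id == genes[i], ]
    ej <- exons[exons$gene_id == genes[j], ]
    hit <- FALSE
    for (a in seq_len(nrow(ei))) for (b in seq_len(nrow(ej))) {
      if (ei$chrom[a] == ej$chrom[b] &&
          ei$start[a] < ej$end[b] && ej$start[b] < ei$end[a]) hit <- TRUE
    }
    if (hit) {
      p <- sort(c(genes[i], genes[j]))
      out[[length(out) + 1L]] <- data.frame(gene_id_a = p[1], gene_id_b = p[2])
    }
  }
  if (!length(out)) {
    return(data.frame(gene_id_a = character(), gene_id_b = character()))
  }
  res <- do.call(rbind, out)
  res[order(res$gene_id_a, res$gene_id_b), , drop = FALSE]
}

# Genes overlapped by one candidate's blocks: every block is compared
# against every exon (all-pairs; the comparison over exons is vectorized).
oracle_candidate_genes <- function(blocks, exons) {
  hits <- character(0)
  for (b in seq_len(nrow(blocks))) {
    ok <- blocks$chrom[b] == exons$chrom &
      blocks$start[b] < exons$end & exons$start < blocks$end[b]
    hits <- c(hits, exons$gene_id[ok])
  }
  sort(unique(hits))
}

# Literal implementation of the assignment decision rules: resolve
# multi-mappers, then assign the chosen candidate; tally everything.
oracle_count_library <- function(fragments, exons, chrom_order) {
  gene_ids <- unique(exons$gene_id)
  counts <- setNames(integer(length(gene_ids)), gene_ids)
  assigned <- no_feature <- ambiguous <- 0L
  mm_class <- c(multi_gene = 0L, within_one_gene = 0L, no_exon = 0L)
  extra <- sort(setdiff(unique(fragments$chrom), chrom_order))
  rank_of <- function(ch) match(ch, c(chrom_order, extra))
  for (fid in unique(fragments$fragment_id)) {
    fr <- fragments[fragments$fragment_id == fid, ]
    cand_idx <- sort(unique(fr$candidate))
    genes_per_cand <- lapply(cand_idx, function(ci) {
      oracle_candidate_genes(fr[fr$candidate == ci, ], exons)
    })
    keys <- lapply(cand_idx, function(ci) {
      bl <- fr[fr$candidate == ci, ]
      r <- min(rank_of(bl$chrom))
      p <- min(bl$start[rank_of(bl$chrom) == r])
      c(r, p)
    })
    pick <- function(idx) {
      best <- idx[1]
      for (i in idx[-1]) {
        if (keys[[i]][1] < keys[[best]][1] ||
            (keys[[i]][1] == keys[[best]][1] && keys[[i]][2] < keys[[best]][2])) {
          best <- i
        }
      }
      best
    }
    if (length(cand_idx) > 1L) {
      all_genes <- unique(unlist(genes_per_cand))
      if (length(all_genes) == 0L) mm_class["no_exon"] <- mm_class["no_exon"] + 1L
      else if (length(all_genes) == 1L) mm_class["within_one_gene"] <- mm_class["within_one_gene"] + 1L
      else mm_class["multi_gene"] <- mm_class["multi_gene"] + 1L
      exonic <- which(vapply(genes_per_cand, length, integer(1)) > 0L)
      chosen <- if (length(exonic) == 1L) exonic
      else if (length(exonic) > 1L) pick(exonic)
      else pick(seq_along(cand_idx))
    } else {
      chosen <- 1L
    }
    g <- genes_per_cand[[chosen]]
    if (length(g) == 0L) no_feature <- no_feature + 1L
    else if (length(g) == 1L) { assigned <- assigned + 1L; counts[g] <- counts[g] + 1L }
    else ambiguous <- ambiguous + 1L
  }
  list(counts = counts, assigned = assigned, no_feature = no_feature,
       ambiguous = ambiguous, mm_class = mm_class)
}

# Step-by-step TMM (Robinson & Oshlack): reference by upper-quartile rule,
# doubly trimmed weighted mean of M values, geometric-mean-1 rescaling.
oracle_tmm <- function(m, logratio_trim = 0.3, abs_trim = 0.05) {
  lib <- colSums(m)
  f75 <- apply(m, 2, function(x) quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    obs <- m[, j] / lib[j]; rc <- m[, ref] / lib[ref]
    keep <- obs > 0 & rc > 0
    logR <- log2(obs[keep] / rc[keep])
    absE <- (log2(obs[keep]) + log2(rc[keep])) / 2
    v <- (lib[j] - m[keep, j]) / (lib[j] * m[keep, j]) +
      (lib[ref] - m[keep, ref]) / (lib[ref] * m[keep, ref])
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * abs_trim) + 1; hiS <- n + 1 - loS
    k2 <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[k2] / v[k2]) / sum(1 / v[k2]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# Literal evaluation of the expression-filter rule.
oracle_filter_low <- function(counts, min_cpm = 0.5, min_libraries = 4L) {
  lib <- colSums(counts)
  keep <- character(0)
  for (g in rownames(counts)) {
    n_ok <- 0L
    for (j in seq_len(ncol(counts))) {
      if (counts[g, j] / lib[j] * 1e6 >= min_cpm) n_ok <- n_ok + 1L
    }
    if (n_ok >= min_libraries) keep <- c(keep, g)
  }
  keep
}

# --- toy builders -----------------------------------------------------------

empty_frag_tbl <- function() {
  tibble::tibble(library_id = character(), fragment_id = character(),
                 candidate = integer(), block = integer(),
                 chrom = character(), start = integer(), end = integer())
}

random_exon_tbl <- function(n, seed, max_pos = 5000L, gene_id = "g") {
  withr::with_seed(seed, {
    start <- sample.int(max_pos, n, replace = TRUE)
    len <- sample.int(300L, n, replace = TRUE)
    tibble::tibble(gene_id = gene_id, chrom = sample(c("chr1", "chr2"), n, TRUE),
                   start = start, end = start + len, strand = "+")
  })
}

# A small annotation with many deliberately overlapping genes.
random_toy_annotation <- function(n_genes, seed, max_pos = 20000L) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_genes), function(i) {
      k <- sample(1:3, 1)
      start <- sample.int(max_pos, k, replace = TRUE)
      len <- sample.int(400L, k, replace = TRUE) + 20L
      tibble::tibble(gene_id = sprintf("g%03d", i),
                     chrom = sample(c("chr1", "chr2"), k, TRUE),
                     start = start, end = start + len, strand = "+")
    })
    exons <- dplyr::bind_rows(rows)
    annotation_set(exons, name = sprintf("toy%d", seed),
                   chrom_order = c("chr1", "chr2"))
  })
}

random_toy_fragments <- function(n, seed, max_pos = 20000L, library_id = "L1") {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      n_cand <- sample(1:3, 1, prob = c(0.7, 0.2, 0.1))
      cand_rows <- lapply(seq_len(n_cand), function(ci) {
        n_block <- sample(1:2, 1, prob = c(0.8, 0.2))
        start <- sample.int(max_pos, n_block, replace = TRUE)
        tibble::tibble(library_id = library_id,
                       fragment_id = sprintf("f%05d", i),
                       candidate = ci,
                       block = seq_len(n_block),
                       chrom = sample(c("chr1", "chr2", "chrUn"), n_block, TRUE,
                                      prob = c(0.55, 0.4, 0.05)),
                       start = start, end = start + sample.int(250L, n_block, TRUE))
      })
      dplyr::bind_rows(cand_rows)
    })
    dplyr::bind_rows(rows)
  })
}

random_nb_counts <- function(n_genes, n_libs, seed, mu_range = c(1, 6)) {
  withr::with_seed(seed, {
    mu <- exp(runif(n_genes * n_libs, mu_range[1], mu_range[2]))
    m <- matrix(rnbinom(n_genes * n_libs, mu = mu, size = 5), ncol = n_libs,
                dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                sprintf("L%02d", seq_len(n_libs))))
    m
  })
}

# Write a toy GTF (1-based inclusive on disk) directly, bypassing write_gtf.
write_toy_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_line <- function(chrom, type, start1, end1, gene, biotype = "protein_coding",
                     extra = "") {
  sprintf('%s\ttoy\t%s\t%d\t%d\t.\t+\t.\tgene_id "%s"; gene_biotype "%s";%s',
          chrom, type, start1, end1, gene, biotype, extra)
}
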