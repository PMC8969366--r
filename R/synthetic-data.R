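# Seeded synthetic data emulating the SEQC benchmark structure.
#
# The generator produces: two or three annotations with partially shared
# genes, divergent effective lengths, deliberately overlapping gene pairs
# and configurable biotype proportions; ground-truth identifier maps; count
# matrices for the 16-library mixture design (samples C and D are 3:1 and
# 1:3 linear mixtures of A and B) with negative-binomial noise; fragment
# files exercising the assignment semantics; and RT-PCR-like and
# microarray-like truth tables. Every random draw flows from one seed and
# all bookkeeping tables are exact by construction, so downstream stages can
# be validated against generator truth.

#' Synthetic benchmark configuration
#'
#' Defaults emulate the SEQC study design at desk scale: four samples
#' (A, B, C = 3:1 and D = 1:3 mixtures of A and B) with four replicate
#' libraries each, 2000 genes per annotation at a sequencing depth of two
#' million fragments per library (roughly 1000 fragments per gene, a
#' SEQC-like per-gene coverage), baseline log2 abundance spread of 2 and
#' A-vs-B log2 fold changes with standard deviation 2 (brain-vs-universal
#' reference RNA differences are of this magnitude), and mild
#' negative-binomial dispersion 0.01 typical of technical replicates.
#'
#' @param seed Integer seed; a fixed seed makes every output byte-identical.
#' @param n_annotations 2 or 3.
#' @param n_genes Genes per annotation.
#' @param shared_fraction Fraction of each annotation's genes common to all
#'   annotations.
#' @param pair_fraction Fraction of each annotation's genes shared with
#'   exactly one other annotation (split over the pairs; 3-annotation case).
#' @param biotype_props Named proportions of gene biotypes.
#' @param exon_count_lambda Mean extra exons per gene (exon count is
#'   `1 + Poisson(lambda)`).
#' @param exon_length_meanlog,exon_length_sdlog Log-normal exon length
#'   parameters (bases).
#' @param intron_length_meanlog,intron_length_sdlog Log-normal intron length
#'   parameters (bases).
#' @param length_divergence_sd SD of the per-annotation log2 length factor
#'   for shared genes (capped at ±2 log2; pairwise length ratios are then
#'   Normal with SD `sqrt(2)` times this).
#' @param overlap_fraction Fraction of genes placed in deliberately
#'   overlapping (same-start) pairs.
#' @param base_log2_sd SD of baseline log2 abundance across genes.
#' @param mix_log2fc_sd SD of the A-vs-B log2 fold change across genes.
#' @param silent_fraction Fraction of genes expressed near zero (annotated
#'   but essentially untranscribed; these are the genes the 0.5 CPM filter
#'   removes).
#' @param dispersion Negative-binomial dispersion phi (Var = mu + phi mu^2);
#'   0 gives deterministic rounded expectations.
#' @param depth Fragments per library for count generation (each library is
#'   generated at exactly this depth).
#' @param replicates Replicate libraries per sample.
#' @param p_c,p_d Proportion of sample A in mixtures C and D.
#' @param n_fragments Fragments per library for fragment-file generation.
#' @param fragment_length Fragment block length (bases).
#' @param noise_fraction Fraction of fragments placed outside any exon
#'   (intergenic; they must end up in the no-feature tally).
#' @param multimapper_fraction Fraction of gene-derived fragments given an
#'   extra (intergenic) candidate location.
#' @param rtpcr_coverage,microarray_coverage Fraction of genes covered by
#'   each truth platform.
#' @param truth_sigma SD (log2) of Gaussian truth noise.
#' @param max_probes Maximum probes per microarray gene (1..max_probes).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_annotations = 3L,
                             n_genes = 2000L,
                             shared_fraction = 0.5,
                             pair_fraction = 0.2,
                             biotype_props = c(protein_coding = 0.55,
                                               lncRNA = 0.25,
                                               pseudogene = 0.15,
                                               miRNA = 0.05),
                             exon_count_lambda = 7,
                             exon_length_meanlog = log(160),
                             exon_length_sdlog = 0.6,
                             intron_length_meanlog = log(1500),
                             intron_length_sdlog = 0.8,
                             length_divergence_sd = 0.25,
                             overlap_fraction = 0.05,
                             base_log2_sd = 2,
                             mix_log2fc_sd = 2,
                             silent_fraction = 0.1,
                             dispersion = 0.01,
                             depth = 2e6,
                             replicates = 4L,
                             p_c = 0.75, p_d = 0.25,
                             n_fragments = 5000L,
                             fragment_length = 200L,
                             noise_fraction = 0.05,
                             multimapper_fraction = 0.08,
                             rtpcr_coverage = 0.4,
                             microarray_coverage = 0.8,
                             truth_sigma = 0.25,
                             max_probes = 3L) {
  cfg <- as.list(environment())
  fracs <- c(shared_fraction, pair_fraction, overlap_fraction, noise_fraction,
             multimapper_fraction, rtpcr_coverage, microarray_coverage,
             silent_fraction)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  if (dispersion < 0) abort("dispersion must be >= 0")
  if (!n_annotations %in% 2:3) abort("n_annotations must be 2 or 3")
  if (n_genes < 2 && overlap_fraction > 0) {
    abort("overlap_fraction > 0 requires at least 2 genes")
  }
  if (abs(sum(biotype_props) - 1) > 1e-8) abort("biotype_props must sum to 1")
  n_all <- round(shared_fraction * n_genes)
  n_pair <- if (n_annotations == 3L) round(pair_fraction * n_genes / 2) else 0L
  if (n_all + 2 * n_pair > n_genes) {
    abort("shared_fraction + pair_fraction exceed the genes available")
  }
  cfg$design <- mixture_design(replicates = replicates, p_c = p_c, p_d = p_d)
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config> seed %d: %d annotations x %d genes, %d libraries at depth %g, phi %g\n",
              x$seed, x$n_annotations, x$n_genes,
              nrow(x$design$libraries), x$depth, x$dispersion))
  invisible(x)
}

ann_names_default <- c("ensembl_like", "refseq_like", "legacy_like")
ann_prefix_default <- c("ENSG", "LOC", "RSG")

# Membership design: which universe genes belong to which annotation.
universe_membership <- function(config) {
  n <- config$n_genes
  k <- config$n_annotations
  n_all <- round(config$shared_fraction * n)
  n_pair <- if (k == 3L) round(config$pair_fraction * n / 2) else 0L
  n_unique <- n - n_all - 2L * n_pair
  if (k == 2L) n_unique <- n - n_all
  nms <- ann_names_default[seq_len(k)]
  blocks <- list(list(members = nms, n = n_all))
  if (k == 3L && n_pair > 0) {
    pairs <- utils::combn(nms, 2, simplify = FALSE)
    for (p in pairs) blocks <- c(blocks, list(list(members = p, n = n_pair)))
  }
  for (nm in nms) blocks <- c(blocks, list(list(members = nm, n = n_unique)))
  rows <- purrr::map(blocks, function(b) {
    tibble(region = paste(b$members, collapse = "&"), n = b$n,
           members = list(b$members))
  }) |> list_rbind() |> filter(.data$n > 0)
  rows |>
    mutate(universe_id = purrr::map2(cumsum(.data$n) - .data$n, .data$n,
                                     function(off, nn) off + seq_len(nn))) |>
    select("region", "members", "universe_id") |>
    unnest("universe_id") |>
    arrange(.data$universe_id)
}

#' Generate synthetic annotations, identifier maps and bookkeeping
#'
#' Builds the configured number of annotations over a shared gene universe.
#' Shared genes get per-annotation exon lengths scaled by a drawn divergence
#' factor; a configured fraction of gene pairs is placed with identical
#' starts so their first exons overlap; biotypes are drawn from the
#' configured proportions. Identifier maps are exact ground truth.
#'
#' @param config A [synthetic_config].
#' @return List with `annotations` (named list of [annotation_set]), `maps`
#'   (named list of pairwise [id_map()]s, plus per-annotation maps to the
#'   shared symbol namespace under `"<name>:symbol"`), and `bookkeeping`
#'   (true Venn membership, per-pair drawn and realized length ratios, true
#'   biotype counts, true overlapping pairs).
#' @export
generate_annotations <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  memb <- universe_membership(config)
  n_univ <- nrow(memb)
  nms <- ann_names_default[seq_len(config$n_annotations)]
  prefixes <- ann_prefix_default[seq_len(config$n_annotations)]

  univ <- with_local_seed(child_seed(config$seed, "universe"), {
    biotype <- sample(names(config$biotype_props), n_univ, replace = TRUE,
                      prob = config$biotype_props)
    n_exons <- 1L + rpois(n_univ, config$exon_count_lambda)
    exon_len <- purrr::map(n_exons, function(k) {
      pmax(20L, as.integer(round(stats::rlnorm(k, config$exon_length_meanlog,
                                               config$exon_length_sdlog))))
    })
    intron_len <- purrr::map(n_exons, function(k) {
      if (k <= 1) integer(0)
      else pmax(50L, as.integer(round(stats::rlnorm(k - 1, config$intron_length_meanlog,
                                                    config$intron_length_sdlog))))
    })
    strand <- sample(c("+", "-"), n_univ, replace = TRUE)
    # overlapping pairs: consecutive universe genes flagged to share a start
    n_ov <- floor(config$overlap_fraction * n_univ / 2)
    ov_first <- if (n_ov > 0) sort(sample(seq_len(n_univ - 1), n_ov)) else integer(0)
    # avoid chained overlaps: drop pairs whose first member is also a second
    ov_first <- ov_first[!(ov_first %in% (ov_first + 1L))]
    list(biotype = biotype, n_exons = n_exons, exon_len = exon_len,
         intron_len = intron_len, strand = strand, ov_first = ov_first)
  })
  overlaps_prev <- rep(FALSE, n_univ)
  overlaps_prev[univ$ov_first + 1L] <- TRUE

  # per-annotation divergence factors (log2, capped at +/-2) for shared genes
  div <- with_local_seed(child_seed(config$seed, "divergence"), {
    m <- matrix(rnorm(n_univ * length(nms), 0, config$length_divergence_sd),
                nrow = n_univ, dimnames = list(NULL, nms))
    pmin(pmax(m, -2), 2)
  })
  # genes in a single annotation keep their baseline structure
  for (j in seq_along(nms)) {
    solo <- lengths(memb$members) == 1L
    div[solo, j] <- 0
  }

  n_chrom <- max(1L, min(20L, ceiling(n_univ / 100)))
  chrom_of <- sprintf("chr%d", ((seq_len(n_univ) - 1L) %% n_chrom) + 1L)
  # baseline gene starts per chromosome: sequential with defensive gaps so
  # that scaled exons can never bridge two unrelated genes
  base_span <- vapply(seq_len(n_univ), function(i) {
    sum(univ$exon_len[[i]]) + sum(univ$intron_len[[i]])
  }, numeric(1))
  exon_sum <- vapply(univ$exon_len, sum, numeric(1))
  start_of <- numeric(n_univ)
  cursor <- setNames(rep(1000, n_chrom), sprintf("chr%d", seq_len(n_chrom)))
  for (i in seq_len(n_univ)) {
    ch <- chrom_of[i]
    if (overlaps_prev[i]) {
      start_of[i] <- start_of[i - 1L]          # same-start overlap with previous
      chrom_of[i] <- chrom_of[i - 1L]
      ch <- chrom_of[i]
    } else {
      start_of[i] <- cursor[ch]
    }
    cursor[ch] <- max(cursor[ch],
                      start_of[i] + base_span[i] + 4 * exon_sum[i] + 10000)
  }

  symbols <- sprintf("GENE%05d", seq_len(n_univ))
  annotations <- list()
  for (j in seq_along(nms)) {
    in_ann <- purrr::map_lgl(memb$members, function(m) nms[j] %in% m)
    idx <- which(in_ann)
    gid <- sprintf("%s%07d", prefixes[j], idx)
    exon_rows <- purrr::map(seq_along(idx), function(ii) {
      i <- idx[ii]
      f <- 2^div[i, j]
      lens <- pmax(1L, as.integer(round(univ$exon_len[[i]] * f)))
      starts <- start_of[i] + cumsum(c(0L, head(univ$exon_len[[i]], -1) +
                                             univ$intron_len[[i]]))
      tibble(gene_id = gid[ii], chrom = chrom_of[i],
             start = as.integer(starts), end = as.integer(starts + lens),
             strand = univ$strand[i])
    }) |> list_rbind()
    exon_rows <- arrange(exon_rows,
                         match(.data$chrom, sprintf("chr%d", seq_len(n_chrom))),
                         .data$start, .data$gene_id)
    genes <- tibble(gene_id = gid, symbol = symbols[idx],
                    biotype = univ$biotype[idx], entrez_id = as.character(idx),
                    universe_id = idx)
    genes <- genes[match(unique(exon_rows$gene_id), genes$gene_id), ]
    annotations[[nms[j]]] <- annotation_set(
      exon_rows, genes = genes, name = nms[j],
      chrom_order = unique(exon_rows$chrom)
    )
  }

  # exact ground-truth maps
  maps <- list()
  if (length(nms) >= 2) {
    for (p in utils::combn(seq_along(nms), 2, simplify = FALSE)) {
      a <- annotations[[nms[p[1]]]]; b <- annotations[[nms[p[2]]]]
      shared <- intersect(a$genes$universe_id, b$genes$universe_id)
      maps[[map_key(nms[p[1]], nms[p[2]])]] <- id_map(
        a$genes$gene_id[match(shared, a$genes$universe_id)],
        b$genes$gene_id[match(shared, b$genes$universe_id)],
        namespaces = c(nms[p[1]], nms[p[2]])
      )
    }
  }
  for (nm in nms) {
    g <- annotations[[nm]]$genes
    maps[[map_key(nm, "symbol")]] <- id_map(g$gene_id, g$symbol,
                                            namespaces = c(nm, "symbol"))
  }

  # bookkeeping
  region_tbl <- memb |>
    mutate(region = purrr::map_chr(.data$members,
                                   function(m) region_label(m, nms))) |>
    select("universe_id", "region")
  true_ratios <- list()
  if (length(nms) >= 2) {
    for (p in utils::combn(seq_along(nms), 2, simplify = FALSE)) {
      na <- nms[p[1]]; nb <- nms[p[2]]
      a <- annotations[[na]]; b <- annotations[[nb]]
      shared <- intersect(a$genes$universe_id, b$genes$universe_id)
      la <- effective_lengths(a); lb <- effective_lengths(b)
      ga <- a$genes$gene_id[match(shared, a$genes$universe_id)]
      gb <- b$genes$gene_id[match(shared, b$genes$universe_id)]
      true_ratios[[map_key(na, nb)]] <- tibble(
        universe_id = shared, gene_id_a = ga, gene_id_b = gb,
        drawn_log2_ratio = div[shared, na] - div[shared, nb],
        realized_log2_ratio =
          log2(la$effective_length[match(ga, la$gene_id)] /
               lb$effective_length[match(gb, lb$gene_id)])
      )
    }
  }
  ov_pairs <- tibble(universe_a = univ$ov_first, universe_b = univ$ov_first + 1L)
  biotype_truth <- purrr::imap(annotations, function(a, nm) {
    count(mutate(a$genes, biotype = .data$biotype), .data$biotype,
          name = "n_genes") |> mutate(annotation = nm)
  }) |> list_rbind()

  list(
    annotations = annotations,
    maps = maps,
    bookkeeping = list(
      membership = region_tbl,
      divergence = div,
      length_ratios = true_ratios,
      overlap_pairs = ov_pairs,
      biotype_counts = biotype_truth,
      symbols = tibble(universe_id = seq_len(n_univ), symbol = symbols,
                       biotype = univ$biotype,
                       baseline_length = exon_sum)
    )
  )
}

# Per-universe-gene linear abundances in the two reference samples.
# Total abundance is equalized between A and B so that mixture proportions
# act per gene exactly; universe gene 1 is the depth sink (see
# generate_counts).
generate_abundance <- function(config, universe_ids) {
  n <- length(universe_ids)
  ab <- with_local_seed(child_seed(config$seed, "abundance"), {
    base <- rnorm(n, 0, config$base_log2_sd)
    delta <- rnorm(n, 0, config$mix_log2fc_sd)
    # a fraction of genes is annotated but untranscribed; their abundance
    # sits ~20 log2 units below the baseline so their expected counts are
    # far below one fragment at any realistic depth (the expression
    # filter's prey, never a borderline rounding case)
    n_silent <- floor(config$silent_fraction * n)
    silent <- if (n_silent > 0) 1L + sample(n - 1L, n_silent) else integer(0)
    base[silent] <- rnorm(n_silent, -20, 1)
    list(base = base, delta = delta)
  })
  a <- 2^(ab$base + ab$delta / 2)
  b <- 2^(ab$base - ab$delta / 2)
  # depth sink: a high-abundance gene with a fixed strong A:B ratio that can
  # absorb integer-rounding residuals without its titration ordering moving
  sink <- which(universe_ids == min(universe_ids))[1]
  a[sink] <- 0.03 * sum(a[-sink])
  b[sink] <- a[sink] / 8
  b <- b * (sum(a) / sum(b))  # equal total mRNA in both reference samples
  tibble(universe_id = universe_ids, abund_a = a, abund_b = b,
         is_sink = seq_along(universe_ids) == sink)
}

#' Generate a count matrix under the mixture design
#'
#' Per gene, linear-scale expected abundances in the reference samples A and
#' B are drawn from the baseline distribution (or supplied); expectations in
#' C and D follow by linear mixing; each library's expected counts are the
#' abundance proportions times the configured depth. Counts are
#' negative-binomial (Var = mu + phi mu^2) via quantile coupling — one
#' uniform draw per (gene, library) shared across dispersion values, so
#' dispersion sweeps under a fixed seed are coupled. With `dispersion = 0`
#' counts are deterministic rounded expectations and a designated
#' high-abundance sink gene absorbs rounding residuals so every library
#' contains exactly `depth` fragments.
#'
#' @param config A [synthetic_config].
#' @param annotation An [annotation_set] (generator-made, carrying
#'   `universe_id`; otherwise gene order indexes the abundance draw).
#' @param abundance Optional abundance tibble from an earlier call (for
#'   cross-annotation consistency).
#' @param dispersion Override of `config$dispersion`.
#' @return List with `counts` (a [count_matrix]), `abundance`, and
#'   `true_expr`: gene x sample matrix of true log2 expression on the
#'   per-kilobase (log2FPKM-like) scale.
#' @export
generate_counts <- function(config, annotation, abundance = NULL,
                            dispersion = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  phi <- dispersion %||% config$dispersion
  genes <- annotation$genes
  uid <- genes$universe_id %||% seq_len(nrow(genes))
  if (is.null(abundance)) abundance <- generate_abundance(config, uid)
  ab <- abundance[match(uid, abundance$universe_id), ]
  design <- config$design
  prop <- design$samples
  q <- vapply(seq_len(nrow(prop)), function(i) {
    mix <- prop$prop_a[i] * ab$abund_a + prop$prop_b[i] * ab$abund_b
    mix / sum(mix)
  }, numeric(nrow(ab)))
  colnames(q) <- prop$sample
  libs <- design$libraries
  mu <- q[, libs$sample, drop = FALSE] * config$depth
  colnames(mu) <- libs$library_id
  rownames(mu) <- genes$gene_id

  if (phi == 0) {
    counts <- round(mu)
    sink_row <- if (any(ab$is_sink, na.rm = TRUE)) which(ab$is_sink)[1]
                else which.max(ab$abund_a + ab$abund_b)
    resid <- config$depth - colSums(counts)
    counts[sink_row, ] <- counts[sink_row, ] + resid
    if (any(counts < 0)) abort("depth sink underflow; increase depth")
  } else {
    u <- with_local_seed(child_seed(config$seed, "counts"), {
      matrix(runif(length(mu)), nrow = nrow(mu))
    })
    counts <- stats::qnbinom(u, mu = mu, size = 1 / phi)
    dim(counts) <- dim(mu)
  }
  dimnames(counts) <- dimnames(mu)
  # true expression on the log2FPKM-like scale (per-kilobase concentration),
  # using this annotation's effective gene lengths
  len <- effective_lengths(annotation)
  true_expr <- log2(q * 1e6) -
    log2(len$effective_length[match(genes$gene_id, len$gene_id)] / 1000)
  rownames(true_expr) <- genes$gene_id
  list(
    counts = count_matrix(counts, annotation = annotation_name(annotation)),
    abundance = abundance,
    true_expr = true_expr
  )
}

#' Generate per-library fragment alignments
#'
#' Fragments are placed uniformly within the collapsed exons of genes drawn
#' in proportion to each library's expected abundance; a configured fraction
#' is placed in intergenic deserts (guaranteed no-feature) and a configured
#' fraction of gene-derived fragments receives an extra intergenic candidate
#' location (multi-mapping, resolvable back to the exonic candidate).
#'
#' @param config A [synthetic_config].
#' @param annotation An [annotation_set].
#' @param abundance Optional abundance tibble (see [generate_counts()]).
#' @param libraries Library ids to generate (default: all in the design).
#' @return List with `fragments` (one tibble, all libraries) and
#'   `placed_truth` (per-library per-gene placed fragment counts).
#' @export
generate_fragments <- function(config, annotation, abundance = NULL,
                               libraries = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  genes <- annotation$genes
  uid <- genes$universe_id %||% seq_len(nrow(genes))
  if (is.null(abundance)) abundance <- generate_abundance(config, uid)
  ab <- abundance[match(uid, abundance$universe_id), ]
  col <- collapse_exons(annotation)
  exons <- col$exons |> mutate(len = .data$end - .data$start)
  ex_split <- split(exons, factor(exons$gene_id, levels = genes$gene_id))
  design <- config$design
  libs <- design$libraries
  if (!is.null(libraries)) libs <- filter(libs, .data$library_id %in% libraries)
  prop <- design$samples
  flen <- config$fragment_length
  # intergenic desert per chromosome: far beyond the last exon
  desert <- exons |>
    group_by(.data$chrom) |>
    summarise(desert_start = max(.data$end) + 50000L, .groups = "drop")

  res <- with_local_seed(child_seed(config$seed, "fragments"), {
    purrr::map(seq_len(nrow(libs)), function(li) {
      lib <- libs$library_id[li]
      s <- libs$sample[li]
      pa <- prop$prop_a[prop$sample == s]; pb <- prop$prop_b[prop$sample == s]
      w <- pa * ab$abund_a + pb * ab$abund_b
      n <- config$n_fragments
      n_noise <- round(config$noise_fraction * n)
      n_gene <- n - n_noise
      gene_draw <- sample.int(nrow(genes), n_gene, replace = TRUE,
                              prob = w / sum(w))
      # choose an exon per fragment, weighted by exon length
      frag_rows <- purrr::map(seq_len(nrow(genes)), function(gi) {
        k <- sum(gene_draw == gi)
        if (!k) return(NULL)
        ex <- ex_split[[gi]]
        ei <- sample.int(nrow(ex), k, replace = TRUE, prob = ex$len)
        max_start <- pmax(ex$start[ei], ex$end[ei] - flen)
        st <- ex$start[ei] +
          floor(runif(k) * (max_start - ex$start[ei] + 1))
        en <- pmin(st + flen, ex$end[ei])
        tibble(gene_id = genes$gene_id[gi], chrom = ex$chrom[ei],
               start = as.integer(st), end = as.integer(en))
      }) |> list_rbind()
      noise_rows <- NULL
      if (n_noise > 0) {
        di <- sample.int(nrow(desert), n_noise, replace = TRUE)
        st <- desert$desert_start[di] + as.integer(floor(runif(n_noise) * 100000))
        noise_rows <- tibble(gene_id = NA_character_,
                             chrom = desert$chrom[di],
                             start = st, end = st + flen)
      }
      allrows <- bind_rows(frag_rows, noise_rows)
      allrows <- allrows[sample.int(nrow(allrows)), ]
      allrows$fragment_id <- sprintf("%s_frag%06d", lib, seq_len(nrow(allrows)))
      allrows$candidate <- 1L
      # multimapper extra candidates (intergenic) for gene-derived fragments
      is_gene <- !is.na(allrows$gene_id)
      mm <- which(is_gene & runif(nrow(allrows)) < config$multimapper_fraction)
      extra <- NULL
      if (length(mm)) {
        di <- sample.int(nrow(desert), length(mm), replace = TRUE)
        st <- desert$desert_start[di] + 200000L +
          as.integer(floor(runif(length(mm)) * 100000))
        extra <- tibble(gene_id = allrows$gene_id[mm],
                        chrom = desert$chrom[di], start = st, end = st + flen,
                        fragment_id = allrows$fragment_id[mm], candidate = 2L)
      }
      frags <- bind_rows(allrows, extra) |>
        mutate(library_id = lib, block = 1L) |>
        select("library_id", "fragment_id", "candidate", "block",
               "chrom", "start", "end")
      placed <- tibble(gene_id = allrows$gene_id[is_gene]) |>
        count(.data$gene_id, name = "n_placed") |>
        mutate(library_id = lib)
      list(fragments = frags, placed = placed)
    })
  })
  list(
    fragments = purrr::map(res, "fragments") |> list_rbind(),
    placed_truth = purrr::map(res, "placed") |> list_rbind()
  )
}

#' Write fragments to BED
#'
#' BED4: chrom, start, end, fragment name. Lines sharing a name are the
#' candidate locations of one multi-mapping fragment.
#'
#' @param fragments Fragment tibble (one library).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  write_tsv_det_headerless(
    fragments |> select("chrom", "start", "end", "fragment_id"), path)
}

write_tsv_det_headerless <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(x, path, col_names = FALSE, eol = "\n", progress = FALSE)
  invisible(path)
}

#' Write fragments to a minimal SAM file
#'
#' Single-end records, one per candidate block; candidates beyond the first
#' carry the secondary-alignment flag (0x100). A minimal header with `@SQ`
#' lines is included.
#'
#' @param fragments Fragment tibble (one library).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_sam <- function(fragments, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  sq <- fragments |>
    group_by(.data$chrom) |>
    summarise(len = max(.data$end) + 1000L, .groups = "drop")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", sq$chrom, sq$len))
  body <- fragments |>
    mutate(flag = ifelse(.data$candidate > 1L, 256L, 0L),
           line = sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                          .data$fragment_id, .data$flag, .data$chrom,
                          .data$start + 1L, .data$end - .data$start))
  readr::write_lines(c(header, body$line), path)
  invisible(path)
}

#' Generate truth tables from a log2 expression matrix
#'
#' Covered genes' truth values are the supplied log2 expression plus
#' Gaussian noise of SD `truth_sigma`. The microarray-like table carries one
#' to `max_probes` probes per gene; the best probe measures the truth and
#' additional probes are attenuated (strictly lower mean), so
#' representative-probe selection is exercised and, at `truth_sigma = 0`,
#' recovers the supplied values exactly.
#'
#' @param config A [synthetic_config].
#' @param expr Gene x sample numeric matrix of log2 expression (rownames =
#'   gene ids in the truth id space), or a tibble with `gene_id` and sample
#'   columns.
#' @param sigma Override of `config$truth_sigma`.
#' @return List with `rtpcr` and `microarray` truth tables.
#' @export
generate_truth_tables <- function(config, expr, sigma = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  sigma <- sigma %||% config$truth_sigma
  if (is.data.frame(expr)) {
    ids <- expr$gene_id
    expr <- as.matrix(expr[setdiff(names(expr), "gene_id")])
    rownames(expr) <- ids
  }
  samples <- colnames(expr)
  with_local_seed(child_seed(config$seed, "truth"), {
    n <- nrow(expr)
    cov_r <- sort(sample.int(n, round(config$rtpcr_coverage * n)))
    cov_m <- sort(sample.int(n, round(config$microarray_coverage * n)))
    rt_vals <- expr[cov_r, , drop = FALSE] +
      matrix(rnorm(length(cov_r) * length(samples), 0, sigma),
             ncol = length(samples))
    rtpcr <- bind_cols(tibble(gene_id = rownames(expr)[cov_r]),
                       as_tibble(2^rt_vals, .name_repair = "minimal") |>
                         setNames(samples))
    n_probes <- sample.int(config$max_probes, length(cov_m), replace = TRUE)
    ma <- purrr::map(seq_along(cov_m), function(i) {
      g <- rownames(expr)[cov_m[i]]
      k <- n_probes[i]
      offs <- c(0, if (k > 1) -0.1 - abs(rnorm(k - 1, 0, 0.5)))
      vals <- matrix(rep(expr[cov_m[i], ], each = k), nrow = k) + offs +
        matrix(rnorm(k * length(samples), 0, sigma), nrow = k)
      colnames(vals) <- samples
      bind_cols(tibble(probe_id = sprintf("%s_p%d", g, seq_len(k)),
                       gene_id = g), as_tibble(vals))
    }) |> list_rbind()
    ma <- ma[sample.int(nrow(ma)), ]
    list(
      rtpcr = truth_table(rtpcr, platform = "rtpcr", log2_transform = TRUE,
                          samples = samples),
      microarray = truth_table(ma, platform = "microarray",
                               log2_transform = FALSE, samples = samples)
    )
  })
}

#' Generate a complete synthetic benchmark bundle
#'
#' Orchestrates [generate_annotations()], [generate_counts()] (one count
#' matrix per annotation over a shared abundance draw) and
#' [generate_truth_tables()] (keyed by the shared symbol namespace, from the
#' true expression of the full gene universe). Optionally writes everything
#' to disk as plain-text files plus a JSON manifest.
#'
#' @param config A [synthetic_config].
#' @param dir Optional output directory.
#' @return List with `config`, `annotations`, `maps`, `counts` (named list
#'   of [count_matrix]), `true_expr` (per annotation), `truth` (rtpcr and
#'   microarray tables in symbol space), `abundance`, `bookkeeping`.
#' @export
generate_bundle <- function(config = synthetic_config(), dir = NULL) {
  ann <- generate_annotations(config)
  n_univ <- nrow(ann$bookkeeping$symbols)
  abundance <- generate_abundance(config, seq_len(n_univ))
  counts <- list(); true_expr <- list()
  for (nm in names(ann$annotations)) {
    g <- generate_counts(config, ann$annotations[[nm]], abundance = abundance)
    counts[[nm]] <- g$counts
    true_expr[[nm]] <- g$true_expr
  }
  # truth tables in symbol space, from the universe-wide true expression
  prop <- config$design$samples
  qs <- vapply(seq_len(nrow(prop)), function(i) {
    mix <- prop$prop_a[i] * abundance$abund_a + prop$prop_b[i] * abundance$abund_b
    mix / sum(mix)
  }, numeric(n_univ))
  colnames(qs) <- prop$sample
  # universe truth on the per-kilobase scale, normalized by the baseline
  # (annotation-independent) exonic length of each gene
  univ_expr <- log2(qs * 1e6) -
    log2(ann$bookkeeping$symbols$baseline_length / 1000)
  rownames(univ_expr) <- ann$bookkeeping$symbols$symbol
  truth <- generate_truth_tables(config, univ_expr)
  bundle <- list(config = config, annotations = ann$annotations,
                 maps = ann$maps, counts = counts, true_expr = true_expr,
                 truth = truth, abundance = abundance,
                 bookkeeping = ann$bookkeeping)
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bundle$config
  for (nm in names(bundle$annotations)) {
    write_gtf(bundle$annotations[[nm]], file.path(dir, paste0(nm, ".gtf")))
    write_counts(bundle$counts[[nm]], bundle$annotations[[nm]],
                 file.path(dir, paste0(nm, ".counts.tsv")))
  }
  for (k in names(bundle$maps)) {
    m <- bundle$maps[[k]]
    ns <- attr(m, "namespaces")
    out <- setNames(as_tibble(m), ns)
    write_tsv_det(out, file.path(dir, paste0("map_", gsub(":", "_", k), ".tsv")))
  }
  rt <- as_tibble(bundle$truth$rtpcr)
  samples <- attr(bundle$truth$rtpcr, "samples")
  rt[samples] <- lapply(rt[samples], function(v) 2^v)  # stored linear scale
  write_tsv_det(rt, file.path(dir, "truth_rtpcr.tsv"))
  write_tsv_det(as_tibble(bundle$truth$microarray),
                file.path(dir, "truth_microarray.tsv"))
  manifest <- cfg[setdiff(names(cfg), "design")]
  manifest$biotype_props <- as.list(cfg$biotype_props)
  write_json_det(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}
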