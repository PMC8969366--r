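# CPM/FPKM conversion, TMM, quantile normalization and the expression filter.

toy_counts <- function(m = NULL, seed = 1, n_genes = 150, n_libs = 6) {
  if (is.null(m)) m <- random_nb_counts(n_genes, n_libs, seed)
  count_matrix(m, annotation = "toy")
}

test_that("cpm applies the stated formula and conserves column sums at prior 0", {
  m <- matrix(c(1L, 0L), nrow = 2, dimnames = list(c("g1", "g2"), "L1"))
  cm <- count_matrix(m, annotation = "t")
  expect_equal(cpm(cm, prior = 0, lib_sizes = c(L1 = 1e6))["g1", "L1"], 1.0)
  expect_equal(cpm(cm, prior = 0, lib_sizes = c(L1 = 1e6))["g2", "L1"], 0)
  for (seed in 1:3) {
    cm <- toy_counts(seed = seed)
    expect_equal(unname(colSums(cpm(cm, prior = 0))), rep(1e6, 6))
  }
  zero <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("L1", "L2")))
  expect_error(cpm(count_matrix(zero)), "zero library size")
})

test_that("log2cpm evaluates the voom formula and matches voom numerically", {
  m <- matrix(0L, 1, 1, dimnames = list("g", "L1"))
  em <- log2cpm(m, prior = 0.5, lib_sizes = 1e6 - 1)
  expect_equal(unname(em$values[1, 1]), log2(0.5), tolerance = 1e-12)

  cm <- toy_counts(seed = 4)
  em2 <- log2cpm(cm)
  v <- limma::voom(cm$counts, lib.size = colSums(cm$counts))
  expect_equal(unname(em2$values), unname(v$E), tolerance = 1e-10)

  # doubling counts and library sizes shifts each value by exactly
  # log2((c + 0.25)/(c + 0.5)) - log2((L + 0.5)/(L + 1)) (direct algebra);
  # the shift vanishes as counts and library sizes grow
  cmx <- count_matrix(cm$counts * 2L, annotation = "t")
  L <- colSums(cm$counts)
  em3 <- log2cpm(cmx, lib_sizes = 2 * L)
  shift <- log2((cm$counts + 0.25) / (cm$counts + 0.5)) -
    rep(log2((L + 0.5) / (L + 1)), each = nrow(cm$counts))
  expect_equal(em3$values - em2$values, shift, tolerance = 1e-12)
  big <- count_matrix(matrix(c(2e6L, 1e6L), 1, 2,
                             dimnames = list("g", c("L1", "L2"))))
  em4 <- log2cpm(big, lib_sizes = c(2e6, 2e6))
  em5 <- log2cpm(count_matrix(matrix(c(4e6L, 2e6L), 1, 2,
                                     dimnames = list("g", c("L1", "L2")))),
                 lib_sizes = c(4e6, 4e6))
  expect_lt(max(abs(em4$values - em5$values)), 1e-6)

  # unit factors equal plain library-size normalization
  expect_equal(log2cpm(cm, factors = rep(1, 6))$values, em2$values)
})

test_that("log2fpkm shifts by log2(length/1000) and inverts exactly", {
  cm <- toy_counts(seed = 5, n_genes = 20)
  em <- log2cpm(cm)
  lens <- setNames(rep(1000, 20), rownames(cm$counts))
  expect_equal(log2fpkm(em, lens)$values, em$values)
  lens2 <- setNames(rep(2000, 20), rownames(cm$counts))
  expect_equal(log2fpkm(em, lens2)$values, em$values - 1)
  lens3 <- setNames(sample(200:5000, 20), rownames(cm$counts))
  fp <- log2fpkm(em, lens3)
  back <- fp$values + log2(lens3[rownames(fp$values)] / 1000)
  expect_equal(back, em$values)
  expect_error(log2fpkm(em, lens3[-1]), "no effective length")
})

test_that("TMM factors match the step-by-step oracle and trivial cases", {
  m <- random_nb_counts(300, 4, seed = 6)
  ident <- cbind(m[, 1], m[, 1], m[, 1])
  colnames(ident) <- paste0("L", 1:3)
  f_ident <- tmm_factors(count_matrix(ident))
  expect_equal(unname(f_ident), rep(1, 3), tolerance = 1e-12)

  doubled <- cbind(L1 = m[, 1], L2 = 2L * m[, 1])
  rownames(doubled) <- rownames(m)
  f2 <- tmm_factors(count_matrix(doubled))
  expect_equal(unname(f2), c(1, 1), tolerance = 1e-12)

  for (seed in 7:10) {
    mm <- random_nb_counts(400, 6, seed = seed)
    got <- tmm_factors(count_matrix(mm))
    expect_equal(unname(got), unname(oracle_tmm(mm)), tolerance = 1e-8)
    expect_equal(exp(mean(log(got))), 1, tolerance = 1e-12)
  }
})

test_that("TMM absorbs library scaling into the library sizes", {
  m <- random_nb_counts(400, 4, seed = 11)
  f1 <- tmm_factors(count_matrix(m))
  # scaling every library by the same constant leaves factors unchanged
  f_all <- tmm_factors(count_matrix(m * 3L))
  expect_equal(unname(f1), unname(f_all), tolerance = 1e-10)
  # scaling a single library together with its (implicit) library size leaves
  # the M and A values unchanged; only the precision weights shift, so the
  # factors move a little but the scaling itself is absorbed
  m2 <- m; m2[, 2] <- m2[, 2] * 3L
  f2 <- tmm_factors(count_matrix(m2))
  expect_lt(max(abs(f1 - f2)), 0.1)
})

test_that("quantile normalization reproduces the worked example and its defining property", {
  m <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(c("g1", "g2"), c("L1", "L2")))
  q <- quantile_normalize(m)
  expect_equal(unname(q), matrix(c(2, 3, 2, 3), 2, 2))

  same <- cbind(L1 = c(5, 1, 3), L2 = c(5, 1, 3))
  rownames(same) <- paste0("g", 1:3)
  expect_equal(quantile_normalize(same), same)

  r <- matrix(rnorm(600), 100, 6,
              dimnames = list(paste0("g", 1:100), paste0("L", 1:6)))
  qr <- quantile_normalize(r)
  sorted <- apply(qr, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  # idempotence
  expect_equal(quantile_normalize(qr), qr, tolerance = 1e-12)
  # permutation equivariance in rows
  perm <- sample.int(100)
  expect_equal(quantile_normalize(r[perm, ]), qr[perm, ], tolerance = 1e-12)
})

test_that("the expression filter matches brute force, including boundary cases", {
  # gene at exactly 0.5 CPM in exactly 4 libraries is retained
  lib <- 2e6
  m <- matrix(0L, 3, 6, dimnames = list(c("gBoundary", "gThree", "gZero"),
                                        paste0("L", 1:6)))
  m["gBoundary", 1:4] <- 1L   # 0.5 CPM at lib size 2e6
  m["gThree", 1:3] <- 100L
  filler <- matrix(as.integer(lib / 10), 10, 6,
                   dimnames = list(paste0("f", 1:10), paste0("L", 1:6)))
  filler[1, ] <- as.integer(lib / 10) - colSums(m)
  cm <- count_matrix(rbind(m, filler))
  expect_equal(unname(colSums(cm$counts)), rep(lib, 6))
  kept <- filter_low_expression(cm)
  expect_true("gBoundary" %in% kept)
  expect_false("gThree" %in% kept)
  expect_false("gZero" %in% kept)

  for (seed in 12:14) {
    mm <- random_nb_counts(200, 8, seed = seed, mu_range = c(-2, 4))
    cm <- count_matrix(mm)
    expect_equal(filter_low_expression(cm), oracle_filter_low(mm))
  }
})

test_that("intensity summaries report standard boxplot statistics", {
  v <- matrix(c(1, 2, 3, 4, 5, rep(7, 5)), 5, 2,
              dimnames = list(paste0("g", 1:5), c("L1", "L2")))
  em <- expression_matrix(v, scale = "log2CPM", normalization = "library_size")
  s <- intensity_range_summary(em)
  expect_equal(s$median[s$library_id == "L1"], 3)
  expect_equal(s$iqr[s$library_id == "L1"], 2)
  expect_equal(s$iqr[s$library_id == "L2"], 0)
  # doubling the spread doubles the IQR
  v2 <- cbind(L1 = c(1, 2, 3, 4, 5), L2 = c(-1, 1, 3, 5, 7))
  rownames(v2) <- paste0("g", 1:5)
  s2 <- intensity_range_summary(
    expression_matrix(v2, "log2CPM", "library_size"))
  expect_gt(s2$iqr[2], s2$iqr[1])
})

test_that("normalize_expression tags its output and composes the stages", {
  cm <- toy_counts(seed = 15, n_genes = 120)
  lens <- tibble::tibble(gene_id = rownames(cm$counts),
                         effective_length = sample(200:5000, 120))
  for (method in c("library_size", "quantile", "TMM")) {
    em <- normalize_expression(cm, method, lengths = lens)
    expect_s3_class(em, "expression_matrix")
    expect_equal(attr(em, "scale"), "log2FPKM")
    expect_equal(attr(em, "normalization"),
                 c(library_size = "library_size", quantile = "quantile",
                   TMM = "TMM")[[method]])
  }
})
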