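test_that("expression matrices round-trip through TSV unchanged", {
  spec <- cohort_spec(n_genes = 20, seed = 4)
  coh <- generate_cohort(spec)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(coh$matrix, path)
  back <- read_expression_matrix(path, spec$grid)
  expect_equal(back, coh$matrix, tolerance = 1e-12)
})

test_that("malformed matrices are rejected with the offender named", {
  grid <- sampling_grid(0, 2, 4)
  path <- withr::local_tempfile(fileext = ".tsv")

  write_lines <- function(lines) writeLines(lines, path)
  ## off-grid sample label
  write_lines(c("gene_id\tCT00_r1\tCT02_r1\tCT04_r1\tCT07_r1",
                "g1\t1\t2\t3\t4"))
  expect_error(read_expression_matrix(path, grid), "CT07")
  ## missing timepoint
  write_lines(c("gene_id\tCT00_r1\tCT02_r1\tCT04_r1\tCT04_r2",
                "g1\t1\t2\t3\t4"))
  expect_error(read_expression_matrix(path, grid), "missing|replicate")
  ## duplicate gene ids
  write_lines(c("gene_id\tCT00_r1\tCT02_r1\tCT04_r1\tCT06_r1",
                "g1\t1\t2\t3\t4", "g1\t1\t2\t3\t4"))
  expect_error(read_expression_matrix(path, grid), "duplicate.*g1")
  ## negative value names the row
  write_lines(c("gene_id\tCT00_r1\tCT02_r1\tCT04_r1\tCT06_r1",
                "g1\t1\t2\t3\t4", "g2\t1\t-2\t3\t4"))
  expect_error(read_expression_matrix(path, grid), "negative.*g2")
})

test_that("zero filtering keeps exactly the all-positive rows", {
  m <- matrix(1, 4, 6,
              dimnames = list(paste0("g", 1:4),
                              c("CT00_r1", "CT02_r1", "CT04_r1",
                                "CT00_r2", "CT02_r2", "CT04_r2")))
  m["g3", "CT02_r2"] <- 0
  f <- filter_zero_genes(m)
  expect_identical(rownames(f), c("g1", "g2", "g4"))
  ## all-positive matrix unchanged; idempotent
  expect_identical(filter_zero_genes(f), f)

  ## random binary masks vs brute-force scan
  withr::with_seed(11, {
    for (rep in 1:20) {
      mm <- matrix(stats::rpois(60, 3), 10, 6)
      rownames(mm) <- paste0("g", 1:10)
      colnames(mm) <- colnames(m)
      keep <- vapply(seq_len(10), function(i) all(mm[i, ] > 0), logical(1))
      expect_identical(filter_zero_genes(mm), mm[keep, , drop = FALSE])
    }
  })
})

test_that("size factors follow the median-of-ratios definition", {
  ## identical samples: all 1
  m <- matrix(rep(c(5, 9, 2), 3), 3, 3)
  expect_equal(unname(size_factors(m)), rep(1, 3), tolerance = 1e-12)

  ## one sample at twice another: factors in ratio 2:1
  m2 <- cbind(a = c(5, 9, 2), b = 2 * c(5, 9, 2))
  sf <- size_factors(m2)
  expect_equal(unname(sf["b"] / sf["a"]), 2, tolerance = 1e-12)

  ## 5 x 3 hand matrix against a literal implementation of the definition
  withr::with_seed(2, {
    m3 <- matrix(stats::rlnorm(15, log(50), 1), 5, 3)
  })
  geomean <- exp(rowMeans(log(m3)))
  by_hand <- apply(m3, 2, function(col) stats::median(col / geomean))
  by_hand <- by_hand / exp(mean(log(by_hand)))   # unit geometric mean
  expect_equal(unname(size_factors(m3)), unname(by_hand), tolerance = 1e-12)

  ## no all-positive row -> instructive failure
  m4 <- rbind(c(0, 1, 2), c(1, 0, 2))
  expect_error(size_factors(m4), "filter_zero_genes")
})

test_that("size factors agree with the DESeq2 estimator", {
  withr::with_seed(8, {
    counts <- matrix(stats::rnbinom(300, mu = 100, size = 5) + 1L, 50, 6)
  })
  ours <- unname(size_factors(counts))
  ref <- unname(DESeq2::estimateSizeFactorsForMatrix(counts))
  ## same estimator up to the unit-geometric-mean standardization
  expect_equal(ours, ref / exp(mean(log(ref))), tolerance = 1e-8)
})

test_that("normalization and replicate averaging behave as defined", {
  grid <- sampling_grid(0, 2, 4)
  m <- matrix(c(10, 14, 6, 2, 8, 12, 5, 7), nrow = 1,
              dimnames = list("g1", c("CT00_r1", "CT00_r2", "CT02_r1",
                                      "CT02_r2", "CT04_r1", "CT04_r2",
                                      "CT06_r1", "CT06_r2")))
  ## factors all 1: identity
  expect_equal(normalize_matrix(m, rep(1, 8)), m)
  expect_error(normalize_matrix(m, c(rep(1, 7), 0)), "positive")

  avg <- average_replicates(m, grid)
  expect_equal(unname(avg[1, ]), c(12, 4, 10, 6))

  ## averaged series equals direct recomputation on a seeded cohort
  spec <- cohort_spec(n_genes = 15, seed = 6)
  coh <- generate_cohort(spec)
  avg2 <- average_replicates(coh$matrix, spec$grid)
  direct <- (coh$matrix[, 1:24] + coh$matrix[, 25:48]) / 2
  expect_equal(unname(avg2), unname(direct), tolerance = 1e-12)

  ## averaging commutes with gene subsetting
  sub <- coh$matrix[c(3, 8, 9), , drop = FALSE]
  expect_equal(average_replicates(sub, spec$grid),
               avg2[c(3, 8, 9), , drop = FALSE])
})

test_that("the size-factor estimator is idempotent after normalization", {
  spec <- cohort_spec(n_genes = 100, seed = 12)
  coh <- generate_cohort(spec)
  m <- filter_zero_genes(coh$matrix)
  norm <- normalize_matrix(m, size_factors(m))
  expect_equal(unname(size_factors(norm)), rep(1, ncol(norm)),
               tolerance = 1e-12)
})
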