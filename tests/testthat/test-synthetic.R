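test_that("degenerate no-signal cohort is exactly the baseline everywhere", {
  spec <- cohort_spec(n_genes = 5, fractions = c(flat = 1), seed = 1,
                      noise_cv = 0, baseline_meanlog = log(100),
                      baseline_sdlog = 0)
  coh <- generate_cohort(spec)
  expect_equal(unname(coh$matrix), matrix(100, 5, 48), tolerance = 1e-12)
})

test_that("a noiseless cosine gene matches its closed form", {
  grid <- sampling_grid()
  tr <- gene_truth("g1", baseline = 100,
                   components = list(component_spec(12, 50, 0, 0)),
                   noise_cv = 0, class_label = "twelve_h")
  spec <- cohort_spec(n_genes = 1, seed = 1, noise_cv = 0)
  mat <- rhythmpencil:::truths_to_matrix(list(tr), spec)
  t <- grid_times(grid)
  expected <- 100 + 50 * cos(2 * pi * t / 12)
  expect_equal(unname(mat[1, 1:24]), expected, tolerance = 1e-12)
  expect_equal(unname(mat[1, "CT00_r1"]), 150)
  expect_equal(unname(mat[1, "CT06_r2"]), 50)
})

test_that("identical spec and seed give bit-identical cohorts", {
  spec <- cohort_spec(n_genes = 40, seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truths, b$truths)
  c2 <- generate_cohort(cohort_spec(n_genes = 40, seed = 8))
  expect_false(identical(a$matrix, c2$matrix))
})

test_that("flat-gene sample means sit within 3 sd of their baselines", {
  spec <- cohort_spec(n_genes = 1000, fractions = c(flat = 1), seed = 7,
                      noise_cv = 0.1)
  coh <- generate_cohort(spec)
  baselines <- vapply(coh$truths, `[[`, numeric(1), "baseline")
  n_obs <- ncol(coh$matrix)
  ## multiplicative noise: sd of the gene mean ~ baseline * cv / sqrt(n_obs)
  z <- (rowMeans(coh$matrix) - baselines) / (baselines * 0.1 / sqrt(n_obs))
  expect_true(mean(abs(z) <= 3) > 0.99)
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(10, fractions = c(flat = 0.6, twelve_h = 0.3)),
               "sum to 1")
  expect_error(cohort_spec(10, knockout_abolished_fraction = 1.2), "\\[0, 1\\]")
  expect_error(cohort_spec(10, fractions = c(bogus = 1)), "named")
})

test_that("paired cohort honours the abolished fraction exactly", {
  ## fraction 0 : knockout truths identical to control truths
  spec0 <- cohort_spec(n_genes = 50, seed = 3, knockout_abolished_fraction = 0)
  p0 <- generate_paired_cohort(spec0)
  expect_identical(p0$truths, p0$knockout_truths)
  expect_length(p0$abolished_ids, 0)

  ## fraction 1 : no knockout twelve_h gene retains a 10-14 h component
  spec1 <- cohort_spec(n_genes = 50, seed = 3, knockout_abolished_fraction = 1)
  p1 <- generate_paired_cohort(spec1)
  for (tr in p1$knockout_truths) {
    if (tr$class_label == "twelve_h") {
      pers <- vapply(tr$components, `[[`, numeric(1), "period_h")
      expect_false(any(pers >= 10 & pers <= 14))
    }
  }

  ## fraction 0.8855 with 400 twelve_h genes: round(0.8855 * 400) = 354
  spec <- cohort_spec(n_genes = 2000, seed = 5,
                      knockout_abolished_fraction = 0.8855)
  pc <- generate_paired_cohort(spec)
  n12 <- sum(truth_labels(pc$truths) == "twelve_h")
  expect_equal(n12, 400)
  expect_length(pc$abolished_ids, 354)
  ## abolished genes keep their out-of-band components
  tr <- pc$knockout_truths[[match(pc$abolished_ids[1],
                                  vapply(pc$knockout_truths, `[[`,
                                         character(1), "gene_id"))]]
  pers <- vapply(tr$components, `[[`, numeric(1), "period_h")
  expect_true(all(pers < 10 | pers > 14))
  expect_true(length(pers) >= 1)  # the secondary 24-h component survives
})

test_that("noiseless undamped truths are recovered exactly by the pencil", {
  spec <- cohort_spec(n_genes = 30, seed = 9, noise_cv = 0,
                      decay_range = c(0, 0))
  coh <- generate_cohort(spec)
  avg <- average_replicates(coh$matrix, spec$grid)
  for (i in seq_len(nrow(avg))) {
    tr <- coh$truths[[i]]
    if (length(tr$components) == 0) next
    d <- pencil_decompose(avg[i, ], spec$grid)
    got <- d$components[order(-vapply(d$components, `[[`, numeric(1), "amplitude"))]
    want <- tr$components[order(-vapply(tr$components, `[[`, numeric(1), "amplitude"))]
    for (k in seq_along(want)) {
      expect_equal(got[[k]]$period_h, want[[k]]$period_h,
                   tolerance = 1e-6)
      expect_equal(got[[k]]$amplitude, want[[k]]$amplitude,
                   tolerance = 1e-6)
      dphi <- abs(rhythmpencil:::circular_diff(got[[k]]$phase_h,
                                               want[[k]]$phase_h,
                                               want[[k]]$period_h))
      expect_lt(dphi, 1e-6 * want[[k]]$period_h)
    }
    ## class label consistent with classification of the noiseless signal
    expect_equal(classify_gene(d)$label, tr$class_label)
  }
})

test_that("RER trace generator matches its closed form and seeds", {
  ## constant trace
  tr <- generate_rer_trace(list(), 0.85, n_animals = 2, span_h = 24,
                           step_h = 1, noise_sd = 0, seed = 1)
  expect_equal(tr[[1]]$rer, rep(0.85, 24))

  ## two-cosine closed form
  comps <- list(component_spec(24, 0.05, 18), component_spec(12, 0.02, 2))
  tr <- generate_rer_trace(comps, 0.85, n_animals = 1, span_h = 48,
                           step_h = 0.5, noise_sd = 0, seed = 1)
  t <- tr[[1]]$time_h
  expected <- 0.85 + 0.05 * cos(2 * pi * (t - 18) / 24) +
    0.02 * cos(2 * pi * (t - 2) / 12)
  expect_equal(tr[[1]]$rer, expected, tolerance = 1e-12)

  ## mean across animals approaches the noiseless curve
  noisy <- generate_rer_trace(comps, 0.85, n_animals = 4, span_h = 48,
                              step_h = 0.5, noise_sd = 0.01, seed = 3)
  mean_tr <- rowMeans(vapply(noisy, `[[`, numeric(96), "rer"))
  expect_lt(mean(abs(mean_tr - expected)), 2 * 0.01 / sqrt(4))

  ## determinism and argument validation
  again <- generate_rer_trace(comps, 0.85, n_animals = 4, span_h = 48,
                              step_h = 0.5, noise_sd = 0.01, seed = 3)
  expect_identical(vapply(noisy, `[[`, numeric(96), "rer"),
                   vapply(again, `[[`, numeric(96), "rer"))
  expect_error(generate_rer_trace(comps, 0.85, step_h = 0), "step_h")
})

test_that("component_spec validates its invariants", {
  expect_error(component_spec(0, 1), "period_h > 0")
  expect_error(component_spec(12, -1))
  expect_error(component_spec(12, 1, phase_h = 12))
})
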