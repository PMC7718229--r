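## Independent oracles used across tests. These deliberately take different
## computational routes from the package implementation.

## Prony / linear-prediction pole estimation: solve the forward linear
## prediction y[n+K] = sum_i a_i y[n+i] by least squares and take the roots
## of the characteristic polynomial. Independent of the SVD-pencil route.
prony_poles <- function(y, k) {
  n <- length(y)
  stopifnot(n >= 2 * k)
  a_mat <- matrix(0, n - k, k)
  for (i in seq_len(k)) a_mat[, i] <- y[i:(i + n - k - 1)]
  rhs <- y[(k + 1):n]
  coef <- qr.solve(a_mat, rhs)
  polyroot(c(-coef, 1))
}

## match two complex pole sets greedily and return the max pairwise distance
pole_set_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  worst <- 0
  b_left <- b
  for (z in a) {
    i <- which.min(Mod(b_left - z))
    worst <- max(worst, Mod(b_left[i] - z))
    b_left <- b_left[-i]
  }
  worst
}

## brute-force umbrella statistic for one cyclic peak position: explicit
## loops over group pairs ordered by cyclic distance to the peak, mid-rank
## ties. Independent of the package matrix formulation.
oracle_umbrella_stat <- function(x, groups, m, peak) {
  lt <- function(gi, gj) {
    xi <- x[groups == gi]; xj <- x[groups == gj]
    s <- 0
    for (u in xi) for (v in xj) s <- s + (u < v) + 0.5 * (u == v)
    s
  }
  cyc_dist <- function(i) min((i - peak) %% m, (peak - i) %% m)
  s <- 0
  for (i in 0:(m - 1)) {
    for (j in 0:(m - 1)) {
      if (i != j && cyc_dist(i) > cyc_dist(j)) s <- s + lt(i, j)
    }
  }
  s
}

## full-enumeration p-values for every peak position (distinct permutations
## of x over the observation slots); returns min-p Bonferroni like the test
oracle_umbrella_enum <- function(x, groups, m) {
  n <- length(x)
  perms <- permute_indices(n)
  n_peaks <- m
  obs <- vapply(seq_len(n_peaks), function(p) {
    oracle_umbrella_stat(x, groups, m, p - 1L)
  }, numeric(1))
  counts <- numeric(n_peaks)
  for (r in seq_len(nrow(perms))) {
    xp <- x[perms[r, ]]
    for (p in seq_len(n_peaks)) {
      s <- oracle_umbrella_stat(xp, groups, m, p - 1L)
      if (s >= obs[p] - 1e-9) counts[p] <- counts[p] + 1
    }
  }
  per_peak <- counts / nrow(perms)
  list(per_peak = per_peak, p_value = min(1, min(per_peak) * n_peaks))
}

permute_indices <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permute_indices(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(seq_len(n)[-k][sub], nrow(sub), n - 1L))
  }))
}

## build a bare decomposition object for classifier/differential tests
fake_decomp <- function(gene_id, dc, comps, grid = sampling_grid()) {
  cmp <- lapply(comps, function(cm) {
    list(period_h = cm$period_h, amplitude = cm$amplitude,
         phase_h = cm$phase_h %||% 0, decay_per_h = cm$decay_per_h %||% 0,
         pole = complex(real = 1), residue = complex(real = 1))
  })
  if (length(cmp) > 1) {
    amps <- vapply(cmp, `[[`, numeric(1), "amplitude")
    pers <- vapply(cmp, `[[`, numeric(1), "period_h")
    cmp <- cmp[order(-amps, pers)]
  }
  structure(list(gene_id = gene_id, dc = dc, components = cmp,
                 residual_rms = 0, grid = grid, level = dc),
            class = "gene_decomposition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## preprocess + decompose + classify convenience used by several tests
classify_pipeline <- function(mat, grid, cfg = pencil_config(),
                              bands = period_bands(), filter = osc_filter()) {
  mat <- filter_zero_genes(mat)
  norm <- normalize_matrix(mat, size_factors(mat))
  avg <- average_replicates(norm, grid)
  decomps <- decompose_matrix(avg, grid, cfg)
  list(decomps = decomps, calls = classify_cohort(decomps, bands, filter))
}

## truth labels as a named vector
truth_labels <- function(truths) {
  stats::setNames(vapply(truths, `[[`, character(1), "class_label"),
                  vapply(truths, `[[`, character(1), "gene_id"))
}
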