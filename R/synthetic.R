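#' One damped-sinusoid component specification
#'
#' Ground-truth counterpart of a recovered oscillation: the undamped cosine
#' `amplitude * exp(decay_per_h * t) * cos(2*pi*t/period_h -
#' 2*pi*phase_h/period_h)` peaks at `t = phase_h` (CT hours).
#'
#' @param period_h Period in hours, positive.
#' @param amplitude Non-negative amplitude in expression (or RER) units.
#' @param phase_h Peak time of the undamped cosine in `[0, period_h)`.
#' @param decay_per_h Exponential rate in 1/h; negative values damp.
#' @return An object of class `component_spec`.
#' @export
component_spec <- function(period_h, amplitude, phase_h = 0, decay_per_h = 0) {
  stopifnot(period_h > 0, amplitude >= 0,
            phase_h >= 0, phase_h < period_h, is.finite(decay_per_h))
  structure(list(period_h = period_h, amplitude = amplitude,
                 phase_h = phase_h, decay_per_h = decay_per_h),
            class = "component_spec")
}

eval_component_spec <- function(spec, t) {
  spec$amplitude * exp(spec$decay_per_h * t) *
    cos(2 * pi * t / spec$period_h - 2 * pi * spec$phase_h / spec$period_h)
}

#' Ground truth for one simulated gene
#'
#' @param gene_id Identifier.
#' @param baseline Positive DC expression level.
#' @param components List of [component_spec()] objects.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param class_label One of `"twelve_h"`, `"twentyfour_h"`, `"other"`,
#'   `"flat"`; must agree with the period band of the largest-amplitude
#'   component.
#' @return An object of class `gene_truth`.
#' @export
gene_truth <- function(gene_id, baseline, components = list(), noise_cv = 0,
                       class_label = c("flat", "twelve_h", "twentyfour_h", "other")) {
  class_label <- match.arg(class_label)
  stopifnot(baseline > 0, noise_cv >= 0)
  structure(list(gene_id = gene_id, baseline = baseline,
                 components = components, noise_cv = noise_cv,
                 class_label = class_label),
            class = "gene_truth")
}

## noiseless mean curve for a gene truth at times t
truth_signal <- function(truth, t) {
  out <- rep(truth$baseline, length(t))
  for (spec in truth$components) out <- out + eval_component_spec(spec, t)
  out
}

#' Cohort specification for the synthetic generator
#'
#' Defines the study conditions a simulated cohort emulates: how many genes,
#' the mix of rhythm classes, the sampling design, the replicate count, and —
#' for paired control/knockout cohorts — the fraction of 12-h genes whose
#' 12-h-band components are deleted in the knockout.
#'
#' Class fractions are given over the labels `twelve_h`, `twentyfour_h`,
#' `other`, and `flat`, and must sum to 1.
#'
#' @param n_genes Number of genes.
#' @param fractions Named numeric vector of class proportions summing to 1
#'   (names among `twelve_h`, `twentyfour_h`, `other`, `flat`).
#' @param grid A [sampling_grid()] (default: 24 points, 2 h apart).
#' @param n_replicates Biological replicates per timepoint (default 2).
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @param knockout_abolished_fraction Fraction in `[0, 1]` of `twelve_h`
#'   genes losing their 10-14-h components in the paired knockout
#'   (default 0.8855, the observed proportion of abolished 12-h transcripts).
#' @param rel_amplitude Dominant-component amplitude relative to baseline
#'   (default 0.5).
#' @param secondary_rel_amplitude Amplitude of the secondary (other-band)
#'   component relative to baseline (default 0.2); rhythmic genes carry a
#'   weaker superimposed component in the complementary band, emulating
#'   superimposed 24-h/12-h oscillations.
#' @param noise_cv Coefficient of variation of multiplicative Gaussian noise
#'   (default 0.1).
#' @param decay_range Range of exponential rates (1/h) from which each
#'   component's damping is drawn uniformly (default `c(-0.01, 0)`, mild
#'   damping).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of per-gene
#'   baselines (defaults `log(100)` and `0.5`).
#' @param noise_model `"gaussian"` (multiplicative, truncated at zero;
#'   default) or `"poisson"` (counts with the noiseless curve as mean).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_genes,
                        fractions = c(twelve_h = 0.2, twentyfour_h = 0.3,
                                      other = 0, flat = 0.5),
                        grid = sampling_grid(),
                        n_replicates = 2,
                        seed = 1,
                        knockout_abolished_fraction = 0.8855,
                        rel_amplitude = 0.5,
                        secondary_rel_amplitude = 0.2,
                        noise_cv = 0.1,
                        decay_range = c(-0.01, 0),
                        baseline_meanlog = log(100),
                        baseline_sdlog = 0.5,
                        noise_model = c("gaussian", "poisson")) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_genes >= 1, n_genes == round(n_genes),
            inherits(grid, "sampling_grid"),
            n_replicates >= 1, n_replicates == round(n_replicates),
            noise_cv >= 0, rel_amplitude >= 0, secondary_rel_amplitude >= 0,
            length(decay_range) == 2L, decay_range[1] <= decay_range[2])
  if (knockout_abolished_fraction < 0 || knockout_abolished_fraction > 1) {
    stop("`knockout_abolished_fraction` must lie in [0, 1]", call. = FALSE)
  }
  allowed <- c("twelve_h", "twentyfour_h", "other", "flat")
  if (is.null(names(fractions)) || !all(names(fractions) %in% allowed)) {
    stop("`fractions` must be named with labels among: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must be non-negative and sum to 1 (got sum = ",
         format(sum(fractions), digits = 12), ")", call. = FALSE)
  }
  fr <- stats::setNames(rep(0, length(allowed)), allowed)
  fr[names(fractions)] <- fractions
  structure(
    list(n_genes = as.integer(n_genes), fractions = fr, grid = grid,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed),
         knockout_abolished_fraction = knockout_abolished_fraction,
         rel_amplitude = rel_amplitude,
         secondary_rel_amplitude = secondary_rel_amplitude,
         noise_cv = noise_cv, decay_range = decay_range,
         baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
         noise_model = noise_model),
    class = "cohort_spec"
  )
}

## draw one gene's ground truth (assumes an active seeded RNG stream)
draw_gene_truth <- function(spec, gene_id, label) {
  baseline <- stats::rlnorm(1, spec$baseline_meanlog, spec$baseline_sdlog)
  draw_comp <- function(period_h, rel_amp) {
    component_spec(
      period_h = period_h,
      amplitude = rel_amp * baseline,
      phase_h = stats::runif(1, 0, period_h),
      decay_per_h = stats::runif(1, spec$decay_range[1], spec$decay_range[2])
    )
  }
  comps <- switch(label,
    flat = list(),
    twelve_h = list(draw_comp(stats::runif(1, 11, 13), spec$rel_amplitude),
                    draw_comp(stats::runif(1, 22, 26), spec$secondary_rel_amplitude)),
    twentyfour_h = list(draw_comp(stats::runif(1, 22, 26), spec$rel_amplitude),
                        draw_comp(stats::runif(1, 11, 13), spec$secondary_rel_amplitude)),
    other = list(draw_comp(stats::runif(1, 15.5, 18.5), spec$rel_amplitude))
  )
  gene_truth(gene_id, baseline, comps, spec$noise_cv, label)
}

## expression matrix for a list of truths (assumes active RNG stream)
truths_to_matrix <- function(truths, spec) {
  t <- grid_times(spec$grid)
  n_cols <- spec$grid$n_points * spec$n_replicates
  mat <- matrix(0, nrow = length(truths), ncol = n_cols,
                dimnames = list(vapply(truths, `[[`, character(1), "gene_id"),
                                grid_sample_labels(spec$grid, spec$n_replicates)))
  for (i in seq_along(truths)) {
    mu <- truth_signal(truths[[i]], t)
    row <- numeric(n_cols)
    for (r in seq_len(spec$n_replicates)) {
      idx <- (r - 1L) * spec$grid$n_points + seq_len(spec$grid$n_points)
      row[idx] <- if (spec$noise_model == "poisson") {
        stats::rpois(length(mu), lambda = pmax(mu, 0))
      } else {
        pmax(0, mu * (1 + stats::rnorm(length(mu), 0, truths[[i]]$noise_cv)))
      }
    }
    mat[i, ] <- row
  }
  mat
}

#' Generate a synthetic expression cohort with known rhythm structure
#'
#' Each gene is a positive baseline plus superimposed damped cosines, observed
#' with multiplicative Gaussian noise (truncated at zero) or, optionally,
#' Poisson counts. Columns are labelled `CT{tt}_r{k}` and replicates share
#' the same underlying truth, differing only in noise draws. Identical spec
#' and seed give a bit-identical matrix.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `matrix` (genes x (timepoints * replicates)) and
#'   `truths` (list of [gene_truth()] objects).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_genes = 10, seed = 1))
#' dim(cohort$matrix)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    truths <- draw_cohort_truths(spec)
    mat <- truths_to_matrix(truths, spec)
    list(matrix = mat, truths = truths)
  })
}

## deterministic class assignment + per-gene truth draws
draw_cohort_truths <- function(spec) {
  counts <- round(spec$fractions * spec$n_genes)
  ## fix rounding drift on the largest class
  drift <- spec$n_genes - sum(counts)
  counts[which.max(counts)] <- counts[which.max(counts)] + drift
  labels <- rep(names(counts), counts)
  ids <- sprintf("gene_%05d", seq_len(spec$n_genes))
  lapply(seq_len(spec$n_genes), function(i) {
    draw_gene_truth(spec, ids[i], labels[i])
  })
}

#' Generate a paired control/knockout cohort
#'
#' The control cohort is drawn exactly as in [generate_cohort()]. The
#' knockout shares every gene's truth except that a seeded random subset of
#' the `twelve_h` genes — the fraction given by
#' `spec$knockout_abolished_fraction` — has all components with period in the
#' 10-14 h band deleted, emulating genotype-specific loss of the 12-h
#' rhythm. Noise draws are independent between the two cohorts.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `control` (matrix), `knockout` (matrix), `truths`
#'   (control truths), `knockout_truths`, and `abolished_ids` (character
#'   vector of genes whose 12-h band was deleted).
#' @export
generate_paired_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    truths <- draw_cohort_truths(spec)
    control <- truths_to_matrix(truths, spec)

    twelve_ids <- vapply(
      Filter(function(tr) tr$class_label == "twelve_h", truths),
      `[[`, character(1), "gene_id")
    n_abolish <- round(spec$knockout_abolished_fraction * length(twelve_ids))
    abolished_ids <- if (n_abolish > 0) {
      sort(sample(twelve_ids, n_abolish))
    } else character(0)

    ko_truths <- lapply(truths, function(tr) {
      if (tr$gene_id %in% abolished_ids) {
        keep <- Filter(function(cmp) cmp$period_h < 10 || cmp$period_h > 14,
                       tr$components)
        tr$components <- keep
      }
      tr
    })
    knockout <- truths_to_matrix(ko_truths, spec)
    list(control = control, knockout = knockout, truths = truths,
         knockout_truths = ko_truths, abolished_ids = abolished_ids)
  })
}

#' Generate synthetic respiratory exchange ratio (RER) traces
#'
#' Per-animal traces are a common baseline plus the given oscillatory
#' components, observed with i.i.d. additive Gaussian noise on a uniform
#' grid.
#'
#' @param components List of [component_spec()] objects (RER units).
#' @param baseline Baseline RER level (typically 0.7-1.0).
#' @param n_animals Number of animals.
#' @param span_h Record length in hours.
#' @param step_h Sampling cadence in hours; must satisfy
#'   `0 < step_h < span_h`.
#' @param noise_sd Standard deviation of the additive noise.
#' @param seed Integer seed.
#' @return A list of `rer_trace` objects (see [rer_trace()]).
#' @export
generate_rer_trace <- function(components, baseline, n_animals = 4,
                               span_h = 96, step_h = 0.5, noise_sd = 0.01,
                               seed = 1) {
  if (step_h <= 0 || step_h >= span_h) {
    stop("`step_h` must satisfy 0 < step_h < span_h", call. = FALSE)
  }
  stopifnot(n_animals >= 1, noise_sd >= 0)
  t <- seq(0, span_h - step_h, by = step_h)
  mu <- rep(baseline, length(t))
  for (spec in components) mu <- mu + eval_component_spec(spec, t)
  withr::with_seed(seed, {
    lapply(seq_len(n_animals), function(a) {
      rer_trace(animal_id = sprintf("animal_%02d", a), time_h = t,
                rer = mu + stats::rnorm(length(t), 0, noise_sd))
    })
  })
}

#' Write an expression matrix as TSV
#'
#' Row names are written in a leading `gene_id` column; the header carries
#' the sample labels.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene truths as JSON
#'
#' @param truths List of [gene_truth()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truths_json <- function(truths, path) {
  payload <- lapply(truths, function(tr) {
    list(gene_id = tr$gene_id, baseline = tr$baseline,
         noise_cv = tr$noise_cv, class_label = tr$class_label,
         components = lapply(tr$components, unclass))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
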