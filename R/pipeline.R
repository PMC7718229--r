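#' Resolve a run configuration
#'
#' A run configuration is a named list (or a YAML/JSON file containing one)
#' with optional entries; anything omitted takes the package default:
#'
#' * `grid`: list with `start_ct_h`, `step_h`, `n_points`.
#' * `pencil`: list with `n_oscillations`, `pencil_param`, `include_dc`,
#'   `rank_tolerance`.
#' * `bands`: list with `twelve_h`, `twentyfour_h` (length-2 each).
#' * `filter`: list with `min_rel_amp`, `max_decay`.
#' * `test`: list with `period_h` (default 12) and `alphas`
#'   (default `c(0.005, 0.05)`).
#' * `simulate`: arguments for [cohort_spec()] (e.g. `n_genes`, `fractions`,
#'   `noise_cv`, `knockout_abolished_fraction`) plus `paired = TRUE/FALSE`.
#' * `seed`: master seed; each stage derives its own stream from it.
#'
#' @param config Named list, or path to a YAML or JSON file.
#' @return A list of class `run_config` with every field resolved.
#' @export
resolve_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  g <- config$grid %||% list()
  grid <- sampling_grid(g$start_ct_h %||% 0, g$step_h %||% 2,
                        g$n_points %||% 24)
  pc <- config$pencil %||% list()
  pencil <- pencil_config(pc$n_oscillations %||% 3,
                          pc$pencil_param %||% NULL,
                          pc$include_dc %||% TRUE,
                          pc$rank_tolerance %||% 1e-10)
  bd <- config$bands %||% list()
  bands <- period_bands(unlist(bd$twelve_h %||% c(10, 14)),
                        unlist(bd$twentyfour_h %||% c(20, 28)))
  fl <- config$filter %||% list()
  filter <- osc_filter(fl$min_rel_amp %||% 0.1, fl$max_decay %||% 0.2)
  ts <- config$test %||% list()
  test <- list(period_h = ts$period_h %||% 12,
               alphas = unlist(ts$alphas %||% c(0.005, 0.05)))
  structure(
    list(grid = grid, pencil = pencil, bands = bands, filter = filter,
         test = test, simulate = config$simulate %||% list(),
         seed = config$seed %||% 1L),
    class = "run_config"
  )
}

## serializable view of a resolved config (round-trips unchanged)
config_as_list <- function(cfg) {
  list(
    grid = unclass(cfg$grid),
    pencil = unclass(cfg$pencil),
    bands = unclass(cfg$bands),
    filter = unclass(cfg$filter),
    test = cfg$test,
    simulate = cfg$simulate,
    seed = cfg$seed
  )
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes simulate -> preprocess (zero filter, size factors, normalize,
#' replicate average) -> decompose -> classify -> rhythm test -> genotype
#' comparison on a paired cohort, writing every stage's table plus a
#' machine-readable summary to `out_dir`. Identical config and seed give
#' identical outputs; each stage derives its own seed from the master seed so
#' stages can be re-run in isolation.
#'
#' @param config A [resolve_config()] input (list or file path).
#' @param out_dir Output directory, created if needed; `NULL` runs in memory
#'   only.
#' @return A list with `classification` (control cohort calls),
#'   `rhythm_test` (umbrella-test table), `differential` (when paired),
#'   `summary`, and `config`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- resolve_config(config)
  sim <- cfg$simulate
  paired <- isTRUE(sim$paired %||% TRUE)
  spec <- cohort_spec(
    n_genes = sim$n_genes %||% 500,
    fractions = unlist(sim$fractions %||%
                         c(twelve_h = 0.2, twentyfour_h = 0.3, flat = 0.5)),
    grid = cfg$grid,
    n_replicates = sim$n_replicates %||% 2,
    seed = derive_seed(cfg$seed, "simulate"),
    knockout_abolished_fraction = sim$knockout_abolished_fraction %||% 0.8855,
    rel_amplitude = sim$rel_amplitude %||% 0.5,
    secondary_rel_amplitude = sim$secondary_rel_amplitude %||% 0.2,
    noise_cv = sim$noise_cv %||% 0.1
  )

  prep <- function(mat) {
    mat <- filter_zero_genes(mat)
    norm <- normalize_matrix(mat, size_factors(mat))
    list(raw = mat, norm = norm, avg = average_replicates(norm, cfg$grid))
  }
  decompose_and_classify <- function(avg) {
    decomps <- decompose_matrix(avg, cfg$grid, cfg$pencil)
    list(decomps = decomps,
         calls = classify_cohort(decomps, cfg$bands, cfg$filter))
  }

  if (paired) {
    cohort <- generate_paired_cohort(spec)
    ctrl <- prep(cohort$control)
    ko <- prep(cohort$knockout)
    dc <- decompose_and_classify(ctrl$avg)
    dk <- decompose_and_classify(ko$avg)
    twelve_ids <- intersect(dc$calls$gene_id[dc$calls$label == "twelve_h"],
                            names(dk$decomps))
    diff <- compare_genotypes(dc$decomps[twelve_ids], dk$decomps[twelve_ids],
                              cfg$bands, cfg$filter)
  } else {
    cohort <- generate_cohort(spec)
    ctrl <- prep(cohort$matrix)
    dc <- decompose_and_classify(ctrl$avg)
    diff <- NULL
  }

  rtest <- rhythm_test_matrix(ctrl$norm, cfg$grid, cfg$test$period_h)
  sig_sizes <- vapply(cfg$test$alphas, function(a) sum(rtest$p_value < a),
                      integer(1))
  names(sig_sizes) <- paste0("alpha_", cfg$test$alphas)

  summary <- list(
    n_genes_input = spec$n_genes,
    n_genes_analyzed = nrow(ctrl$avg),
    class_counts = as.list(table(dc$calls$label)),
    umbrella_significant = as.list(sig_sizes),
    differential = if (!is.null(diff)) diff$summary else NULL,
    seed = cfg$seed
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_expression_tsv(ctrl$norm, file.path(out_dir, "control_normalized.tsv"))
    utils::write.table(dc$calls, file.path(out_dir, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rtest, file.path(out_dir, "rhythm_test.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(diff)) {
      utils::write.table(diff$calls, file.path(out_dir, "differential.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(config_as_list(cfg),
                         file.path(out_dir, "config_resolved.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(classification = dc$calls, rhythm_test = rtest, differential = diff,
       summary = summary, config = cfg)
}
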