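#' Compare decompositions between two genotypes
#'
#' For genes rhythmic in the control (callers should restrict the input to
#' control-called 12-h genes), the knockout decomposition is searched for any
#' filter-passing component with period inside the 12-h band. Absence of such
#' a component gives the verdict `abolished`; presence gives `sustained`,
#' together with the circular phase difference (knockout minus control,
#' modulo the control period, in `(-T/2, T/2]`) and the amplitude ratio
#' (knockout / control) of the largest in-band knockout component against the
#' control dominant.
#'
#' Band presence (not retained dominance) is the default criterion, since
#' genes with disrupted amplitude or phase still count as sustained;
#' `require_dominant = TRUE` switches to the stricter rule that the knockout
#' dominant component itself must lie in the band.
#'
#' @param control_decomps,knockout_decomps Lists of `gene_decomposition`
#'   objects covering the same gene ids on the same grid.
#' @param bands A [period_bands()]; the 12-h band drives the verdict.
#' @param filter An [osc_filter()].
#' @param require_dominant Use strict dominance instead of band presence
#'   (default `FALSE`).
#' @return A list of class `differential_result` with `calls` (data.frame:
#'   `gene_id`, `verdict`, `control_period_h`, `control_amplitude`,
#'   `control_phase_h`, `knockout_period_h`, `knockout_amplitude`,
#'   `knockout_phase_h`, `delta_phase_h`, `amplitude_ratio`) and `summary`
#'   (counts and percentages of each verdict).
#' @export
compare_genotypes <- function(control_decomps, knockout_decomps,
                              bands = period_bands(), filter = osc_filter(),
                              require_dominant = FALSE) {
  ctrl_ids <- vapply(control_decomps, `[[`, character(1), "gene_id")
  ko_ids <- vapply(knockout_decomps, `[[`, character(1), "gene_id")
  missing <- setdiff(ctrl_ids, ko_ids)
  if (length(missing) > 0) {
    stop("gene id(s) absent from the knockout cohort: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  names(knockout_decomps) <- ko_ids

  rows <- lapply(control_decomps, function(dc) {
    dk <- knockout_decomps[[dc$gene_id]]
    ctrl_dom <- dominant_component(dc, filter)
    if (is.null(ctrl_dom)) {
      stop("control gene ", dc$gene_id,
           " has no passing component; restrict input to control 12-h calls",
           call. = FALSE)
    }
    ko_comp <- band_component(dk, bands$twelve_h, filter, require_dominant)
    if (is.null(ko_comp)) {
      data.frame(gene_id = dc$gene_id, verdict = "abolished",
                 control_period_h = ctrl_dom$period_h,
                 control_amplitude = ctrl_dom$amplitude,
                 control_phase_h = ctrl_dom$phase_h,
                 knockout_period_h = NA_real_, knockout_amplitude = NA_real_,
                 knockout_phase_h = NA_real_, delta_phase_h = NA_real_,
                 amplitude_ratio = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = dc$gene_id, verdict = "sustained",
                 control_period_h = ctrl_dom$period_h,
                 control_amplitude = ctrl_dom$amplitude,
                 control_phase_h = ctrl_dom$phase_h,
                 knockout_period_h = ko_comp$period_h,
                 knockout_amplitude = ko_comp$amplitude,
                 knockout_phase_h = ko_comp$phase_h,
                 delta_phase_h = circular_diff(ctrl_dom$phase_h,
                                               ko_comp$phase_h,
                                               ctrl_dom$period_h),
                 amplitude_ratio = ko_comp$amplitude / ctrl_dom$amplitude,
                 stringsAsFactors = FALSE)
    }
  })
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  n <- nrow(calls)
  n_abol <- sum(calls$verdict == "abolished")
  summary <- list(
    n_input = n, n_abolished = n_abol, n_sustained = n - n_abol,
    pct_abolished = if (n > 0) 100 * n_abol / n else NA_real_,
    pct_sustained = if (n > 0) 100 * (n - n_abol) / n else NA_real_
  )
  structure(list(calls = calls, summary = summary),
            class = "differential_result")
}

## largest-amplitude filter-passing component inside a band, or the dominant
## component when strict dominance is requested
band_component <- function(d, band, filter, require_dominant) {
  if (require_dominant) {
    dom <- dominant_component(d, filter)
    if (!is.null(dom) && in_band(dom$period_h, band)) return(dom)
    return(NULL)
  }
  passing <- Filter(function(cmp) {
    component_passes(cmp, decomp_level(d), d$grid, filter) && in_band(cmp$period_h, band)
  }, d$components)
  if (length(passing) == 0L) return(NULL)
  amps <- vapply(passing, `[[`, numeric(1), "amplitude")
  pers <- vapply(passing, `[[`, numeric(1), "period_h")
  passing[[order(-amps, pers)[1L]]]
}

#' @export
print.differential_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("differential_result: %d genes; %d abolished (%.2f%%), %d sustained (%.2f%%)\n",
              s$n_input, s$n_abolished, s$pct_abolished,
              s$n_sustained, s$pct_sustained))
  invisible(x)
}

#' Matched-pairs table of sustained genes
#'
#' One row per sustained gene with its phase and amplitude in each genotype
#' (phases in hours on each genotype's own dominant/in-band period), ordered
#' by gene id. Abolished genes are rejected.
#'
#' @param result A `differential_result` from [compare_genotypes()], or its
#'   `calls` data.frame restricted to sustained genes.
#' @return A data.frame with `gene_id`, `control_phase_h`,
#'   `knockout_phase_h`, `control_amplitude`, `knockout_amplitude`.
#' @export
matched_pairs_table <- function(result) {
  calls <- if (inherits(result, "differential_result")) result$calls else result
  stopifnot(is.data.frame(calls))
  if (inherits(result, "differential_result")) {
    calls <- calls[calls$verdict == "sustained", , drop = FALSE]
  } else if (any(calls$verdict != "sustained")) {
    stop("matched_pairs_table() accepts sustained calls only; got abolished gene(s): ",
         paste(utils::head(calls$gene_id[calls$verdict != "sustained"], 5),
               collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    gene_id = calls$gene_id,
    control_phase_h = calls$control_phase_h,
    knockout_phase_h = calls$knockout_phase_h,
    control_amplitude = calls$control_amplitude,
    knockout_amplitude = calls$knockout_amplitude,
    stringsAsFactors = FALSE
  )
  out[order(out$gene_id), , drop = FALSE]
}

#' Overlap between two gene-id sets
#'
#' Duplicates are collapsed before counting.
#'
#' @param a,b Character vectors of gene ids.
#' @return A list of class `concordance_result` with `size_a`, `size_b`,
#'   `size_intersection`, `fraction_of_a` (intersection / size of `a`; 0 when
#'   `a` is empty), and `intersection` (sorted ids).
#' @export
gene_set_overlap <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  inter <- sort(intersect(a, b))
  structure(
    list(size_a = length(a), size_b = length(b),
         size_intersection = length(inter),
         fraction_of_a = if (length(a) == 0) 0 else length(inter) / length(a),
         intersection = inter),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance: |A| = %d, |B| = %d, |A∩B| = %d (%.2f%% of A)\n",
              x$size_a, x$size_b, x$size_intersection, 100 * x$fraction_of_a))
  invisible(x)
}
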