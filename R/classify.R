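#' Period bands for rhythm classes
#'
#' Dominant periods between 10 and 14 h define 12-h (ultradian) genes;
#' periods between 20 and 28 h define 24-h (circadian) genes. Both intervals
#' are closed.
#'
#' @param twelve_h Closed interval (length-2 numeric) for the 12-h class.
#' @param twentyfour_h Closed interval for the 24-h class.
#' @return An object of class `period_bands`.
#' @export
period_bands <- function(twelve_h = c(10, 14), twentyfour_h = c(20, 28)) {
  stopifnot(length(twelve_h) == 2L, length(twentyfour_h) == 2L,
            twelve_h[1] < twelve_h[2], twentyfour_h[1] < twentyfour_h[2])
  if (twelve_h[2] >= twentyfour_h[1]) {
    stop("period bands must be disjoint", call. = FALSE)
  }
  structure(list(twelve_h = twelve_h, twentyfour_h = twentyfour_h),
            class = "period_bands")
}

in_band <- function(period_h, band) {
  period_h >= band[1] & period_h <= band[2]
}

#' Classify one gene from its decomposition
#'
#' The class is decided by the period of the dominant (largest-amplitude,
#' filter-passing) component: inside the 12-h band gives `twelve_h`, inside
#' the 24-h band gives `twentyfour_h`, outside both gives `other`, and no
#' passing component gives `arrhythmic`.
#'
#' @param d A `gene_decomposition`.
#' @param bands A [period_bands()].
#' @param filter An [osc_filter()].
#' @return A list of class `rhythm_call` with `gene_id`, `label`, `dominant`
#'   (component or `NULL`), and `p_value`/`q_value` slots (filled by the
#'   rhythm test, `NA` here).
#' @export
classify_gene <- function(d, bands = period_bands(), filter = osc_filter()) {
  stopifnot(inherits(bands, "period_bands"))
  dom <- dominant_component(d, filter)
  label <- if (is.null(dom)) {
    "arrhythmic"
  } else if (in_band(dom$period_h, bands$twelve_h)) {
    "twelve_h"
  } else if (in_band(dom$period_h, bands$twentyfour_h)) {
    "twentyfour_h"
  } else {
    "other"
  }
  structure(list(gene_id = d$gene_id, label = label, dominant = dom,
                 p_value = NA_real_, q_value = NA_real_),
            class = "rhythm_call")
}

#' Classify every gene of a decomposed cohort
#'
#' @param decomps List of `gene_decomposition` objects (e.g. from
#'   [decompose_matrix()]).
#' @param bands A [period_bands()].
#' @param filter An [osc_filter()].
#' @return A data.frame with one row per gene: `gene_id`, `label`,
#'   `period_h`, `amplitude`, `phase_h`, `decay_per_h` (NA when arrhythmic).
#' @export
classify_cohort <- function(decomps, bands = period_bands(),
                            filter = osc_filter()) {
  rows <- lapply(decomps, function(d) {
    call <- classify_gene(d, bands, filter)
    dom <- call$dominant
    data.frame(
      gene_id = call$gene_id, label = call$label,
      period_h = if (is.null(dom)) NA_real_ else dom$period_h,
      amplitude = if (is.null(dom)) NA_real_ else dom$amplitude,
      phase_h = if (is.null(dom)) NA_real_ else dom$phase_h,
      decay_per_h = if (is.null(dom)) NA_real_ else dom$decay_per_h,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Validated step-up false-discovery-rate adjustment; the mapping back to
#' input positions is order-preserving.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
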