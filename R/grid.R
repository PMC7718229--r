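#' Uniform sampling grid
#'
#' Every decomposition in the package assumes a uniform time axis. A
#' `sampling_grid` records the first circadian time (CT) sampled, the spacing
#' between samples, and the number of samples, so that the timepoints are
#' `t_n = start_ct_h + n * step_h` for `n = 0 .. n_points - 1`.
#'
#' The default grid mirrors a dense circadian design: 24 samples every 2 h
#' covering 48 h (CT0 to CT46, end-exclusive so every 12-h and 24-h cycle is
#' sampled a whole number of times).
#'
#' @param start_ct_h First sampled circadian time in hours (default 0).
#' @param step_h Spacing between samples in hours; must be positive
#'   (default 2).
#' @param n_points Number of samples; must be at least 4 (default 24).
#' @return An object of class `sampling_grid`.
#' @examples
#' g <- sampling_grid()
#' grid_times(g)
#' @export
sampling_grid <- function(start_ct_h = 0, step_h = 2, n_points = 24) {
  stopifnot(is.numeric(start_ct_h), length(start_ct_h) == 1L, is.finite(start_ct_h))
  if (!is.numeric(step_h) || length(step_h) != 1L || !is.finite(step_h) || step_h <= 0) {
    stop("`step_h` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 4 ||
      n_points != round(n_points)) {
    stop("`n_points` must be an integer >= 4", call. = FALSE)
  }
  structure(
    list(start_ct_h = as.numeric(start_ct_h), step_h = as.numeric(step_h),
         n_points = as.integer(n_points)),
    class = "sampling_grid"
  )
}

#' Timepoints of a sampling grid
#'
#' @param grid A [sampling_grid()].
#' @return Numeric vector of length `grid$n_points` with the sampled times in
#'   hours.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "sampling_grid"))
  grid$start_ct_h + grid$step_h * (seq_len(grid$n_points) - 1)
}

#' Total span of a grid in hours
#'
#' The span is end-exclusive: `step_h * n_points`, i.e. the length of signal
#' the grid covers when each sample represents one step.
#'
#' @param grid A [sampling_grid()].
#' @return Span in hours.
#' @export
grid_span <- function(grid) {
  stopifnot(inherits(grid, "sampling_grid"))
  grid$step_h * grid$n_points
}

#' @export
print.sampling_grid <- function(x, ...) {
  cat(sprintf("sampling_grid: %d points, CT%g to CT%g, step %g h\n",
              x$n_points, x$start_ct_h,
              x$start_ct_h + (x$n_points - 1) * x$step_h, x$step_h))
  invisible(x)
}

## sample labels of the form CT{tt}_r{k}, tt zero-padded to 2 digits
grid_sample_labels <- function(grid, n_replicates) {
  tt <- grid_times(grid)
  pad <- max(2L, nchar(as.character(floor(max(tt)))))
  fmt <- paste0("CT%0", pad, "g_r%d")
  as.vector(vapply(seq_len(n_replicates), function(r) {
    sprintf(fmt, tt, r)
  }, character(length(tt))))
}
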