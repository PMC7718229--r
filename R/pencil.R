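#' Configuration for the matrix-pencil decomposition
#'
#' The decomposition models a uniformly sampled series as a constant (DC)
#' level plus `n_oscillations` exponentially damped cosines,
#' \deqn{y(t) = c_0 + \sum_i A_i e^{b_i \tau} \cos(2\pi \tau / T_i + \theta_i),}
#' with \eqn{\tau} the time since the first sample. The model order of the
#' underlying exponential fit is `K = 2 * n_oscillations + include_dc`.
#'
#' @param n_oscillations Number of conjugate-pair (oscillatory) components to
#'   fit, `M`. Default 3, matching the convention of decomposing each liver
#'   transcript into three superimposed oscillations.
#' @param pencil_param The pencil parameter `P`: the Hankel matrix has
#'   `N - P` rows and `P + 1` columns. `NULL` (default) means `floor(N/2)`
#'   (capped at `N - K`): the upper end of the standard `N/3 .. N/2`
#'   noise-robust range, which keeps the signal subspace well determined when
#'   the model order approaches `N/3`. Must satisfy `K <= P <= N - K`.
#' @param include_dc Model a constant level as an extra real pole
#'   (default `TRUE`).
#' @param rank_tolerance Relative singular-value cutoff used to detect rank
#'   deficiency of noiseless or degenerate signals; components are never
#'   fabricated beyond the numerical rank. Default `1e-10`.
#' @return An object of class `pencil_config`.
#' @export
pencil_config <- function(n_oscillations = 3, pencil_param = NULL,
                          include_dc = TRUE, rank_tolerance = 1e-10) {
  stopifnot(n_oscillations >= 1, n_oscillations == round(n_oscillations))
  if (!is.null(pencil_param)) {
    stopifnot(pencil_param >= 1, pencil_param == round(pencil_param))
  }
  stopifnot(is.logical(include_dc), length(include_dc) == 1L)
  stopifnot(rank_tolerance > 0)
  structure(
    list(n_oscillations = as.integer(n_oscillations),
         pencil_param = if (is.null(pencil_param)) NULL else as.integer(pencil_param),
         include_dc = include_dc,
         rank_tolerance = rank_tolerance),
    class = "pencil_config"
  )
}

#' Filter for oscillatory components
#'
#' Components are screened before any call of dominance or band membership:
#' a component counts as a genuine oscillation only if its period is
#' resolvable on the grid (between the Nyquist limit `2 * step_h` and the
#' grid span), it is not over-damped, and its amplitude is non-negligible
#' relative to the gene's level.
#'
#' The relative-amplitude screen uses the decay-adjusted mid-span amplitude
#' `A * exp(b * span/2)` rather than the raw coefficient `A`: noise-fitting
#' components are typically strongly damped, so their coefficient at the
#' first sample overstates how much signal they carry over the record, while
#' genuine mildly damped oscillations are essentially unaffected. The
#' reference level is the DC term, falling back to the series mean when the
#' decomposition assigned no trend content.
#'
#' There is no published amplitude or damping cutoff for calling a transcript
#' "cycling"; these conservative defaults are therefore exposed rather than
#' hard-coded.
#'
#' @param min_rel_amp Minimum amplitude relative to `max(dc, dc_floor)`
#'   (default 0.1).
#' @param max_decay Maximum absolute exponential rate `|b|` in 1/h
#'   (default 0.2).
#' @param min_period_h,max_period_h Optional explicit period limits in hours;
#'   `NULL` (default) uses the grid Nyquist limit and span.
#' @param dc_floor Floor applied to the DC level in the relative-amplitude
#'   denominator so near-zero baselines do not pass everything
#'   (default 1e-8).
#' @return An object of class `osc_filter`.
#' @export
osc_filter <- function(min_rel_amp = 0.1, max_decay = 0.2,
                       min_period_h = NULL, max_period_h = NULL,
                       dc_floor = 1e-8) {
  stopifnot(min_rel_amp >= 0, max_decay >= 0, dc_floor > 0)
  structure(
    list(min_rel_amp = min_rel_amp, max_decay = max_decay,
         min_period_h = min_period_h, max_period_h = max_period_h,
         dc_floor = dc_floor),
    class = "osc_filter"
  )
}

## build one oscillation component record from pole/residue
new_component <- function(period_h, amplitude, phase_h, decay_per_h,
                          pole, residue) {
  list(period_h = period_h, amplitude = amplitude,
       phase_h = wrap_phase(phase_h, period_h), decay_per_h = decay_per_h,
       pole = pole, residue = residue)
}

#' Matrix-pencil decomposition of one uniformly sampled series
#'
#' Recovers the poles and residues of a sum of damped complex exponentials
#' from a single uniformly sampled record, then merges conjugate pole pairs
#' into real damped cosines. The steps are: (1) form the Hankel matrix
#' `H[i, j] = y[i + j]` with `N - P` rows and `P + 1` columns; (2) truncate
#' its SVD to the model order `K` (reduced further if the numerical rank is
#' lower, so degenerate signals never yield fabricated components); (3) take
#' the poles as the eigenvalues of the shifted-versus-unshifted pencil of the
#' truncated right singular vectors; (4) solve the Vandermonde least-squares
#' system for the residues; (5) merge conjugate pairs into damped cosines,
#' assigning real-pole (trend) content to the DC term.
#'
#' For each conjugate pair with pole `z` (positive imaginary part) and
#' residue `r`: period `T = 2*pi*step_h / arg(z)`, decay `b = log|z| /
#' step_h`, amplitude `A = 2|r|`, and phase (peak time of the undamped cosine
#' after the first sample, in `[0, T)`) `((-Arg r) mod 2*pi) * T / (2*pi)`.
#'
#' @param series Numeric vector of finite values sampled on `grid`.
#' @param grid A [sampling_grid()] with `n_points == length(series)`.
#' @param cfg A [pencil_config()].
#' @param gene_id Optional identifier stored in the result.
#' @return An object of class `gene_decomposition`: a list with `gene_id`,
#'   `dc`, `components` (sorted by amplitude, descending), `residual_rms`,
#'   and `grid`. The reconstruction over the grid differs from the input by
#'   exactly `residual_rms` (root mean square).
#' @examples
#' g <- sampling_grid()
#' y <- 10 + 3 * cos(2 * pi * grid_times(g) / 12)
#' d <- pencil_decompose(y, g)
#' d$components[[1]]$period_h
#' @export
pencil_decompose <- function(series, grid, cfg = pencil_config(),
                             gene_id = NA_character_) {
  stopifnot(inherits(grid, "sampling_grid"), inherits(cfg, "pencil_config"))
  y <- as.numeric(series)
  n <- length(y)
  if (n != grid$n_points) {
    stop("`series` length (", n, ") does not match grid n_points (",
         grid$n_points, ")", call. = FALSE)
  }
  if (!all(is.finite(y))) stop("`series` contains non-finite values", call. = FALSE)

  k_max <- 2L * cfg$n_oscillations + as.integer(cfg$include_dc)
  if (n < 2L * k_max) {
    stop("series too short (N = ", n, ") for model order K = ", k_max,
         "; need N >= 2K. Lower `n_oscillations`.", call. = FALSE)
  }
  p <- cfg$pencil_param %||% min(n - k_max, max(k_max, floor(n / 2)))
  if (p < k_max || p > n - k_max) {
    stop("pencil parameter P = ", p, " violates K <= P <= N - K (K = ",
         k_max, ", N = ", n, ")", call. = FALSE)
  }

  ## Hankel matrix, (N - P) x (P + 1)
  h <- matrix(0, nrow = n - p, ncol = p + 1L)
  for (j in seq_len(p + 1L)) h[, j] <- y[j:(j + n - p - 1L)]

  sv <- svd(h)
  ## numerical rank: never fit more exponentials than the data support
  k <- min(k_max, sum(sv$d > cfg$rank_tolerance * sv$d[1] & sv$d > 0))
  if (k == 0L) {
    ## identically (numerically) zero signal
    return(new_gene_decomposition(gene_id, dc = mean(y), components = list(),
                                  residual_rms = rms(y - mean(y)), grid = grid,
                                  level = mean(y)))
  }

  vk <- sv$v[, seq_len(k), drop = FALSE]          # (P + 1) x K
  v1 <- vk[seq_len(p), , drop = FALSE]            # drop last row
  v2 <- vk[2:(p + 1L), , drop = FALSE]            # drop first row
  ## poles: eigenvalues of pinv(V1) %*% V2 (K x K)
  a <- qr.solve(v1, v2)
  poles <- eigen(a, only.values = TRUE)$values

  ## residues: Vandermonde least squares Z r = y
  zmat <- t(vapply(poles, function(z) z^(0:(n - 1L)), complex(n)))
  zmat <- t(zmat)                                  # N x K
  res <- qr.solve(qr(zmat, LAPACK = TRUE), as.complex(y))

  decomp_from_poles(y, poles, res, grid, gene_id)
}

## turn poles/residues into dc + cosine components + residual
decomp_from_poles <- function(y, poles, residues, grid, gene_id) {
  n <- length(y)
  dt <- grid$step_h
  arg_tol <- 1e-6

  args <- Arg(poles)
  is_trend <- abs(args) <= arg_tol                 # (near-)positive-real poles
  is_nyquist <- abs(abs(args) - pi) <= arg_tol     # negative-real poles
  is_osc_pos <- !is_trend & !is_nyquist & args > 0

  ## DC: mean over the grid of the real-pole contributions (exact for z = 1)
  dc <- 0
  if (any(is_trend)) {
    contrib <- rep(0, n)
    for (i in which(is_trend)) {
      contrib <- contrib + Re(residues[i] * poles[i]^(0:(n - 1L)))
    }
    dc <- mean(contrib)
  }

  comps <- list()
  for (i in which(is_osc_pos)) {
    z <- poles[i]; r <- residues[i]
    t_i <- 2 * pi * dt / abs(Arg(z))
    b_i <- log(Mod(z)) / dt
    a_i <- 2 * Mod(r)
    ph <- (-Arg(r)) %% (2 * pi) * t_i / (2 * pi)
    comps[[length(comps) + 1L]] <- new_component(t_i, a_i, ph, b_i, z, r)
  }
  for (i in which(is_nyquist)) {
    ## self-conjugate pole at the Nyquist period 2 * step_h
    z <- poles[i]; r <- residues[i]
    t_i <- 2 * dt
    b_i <- log(Mod(z)) / dt
    a_i <- Mod(r)
    ph <- if (Re(r) >= 0) 0 else t_i / 2
    comps[[length(comps) + 1L]] <- new_component(t_i, a_i, ph, b_i, z, r)
  }

  if (length(comps) > 1L) {
    amps <- vapply(comps, `[[`, numeric(1), "amplitude")
    pers <- vapply(comps, `[[`, numeric(1), "period_h")
    ## amplitude descending; ties toward the shorter period (deterministic)
    comps <- comps[order(-amps, pers)]
  }

  d <- new_gene_decomposition(gene_id, dc = dc, components = comps,
                              residual_rms = 0, grid = grid, level = mean(y))
  d$residual_rms <- rms(y - reconstruct(d))
  d
}

new_gene_decomposition <- function(gene_id, dc, components, residual_rms,
                                   grid, level = dc) {
  structure(
    list(gene_id = gene_id, dc = dc, components = components,
         residual_rms = residual_rms, grid = grid, level = level),
    class = "gene_decomposition"
  )
}

#' @export
print.gene_decomposition <- function(x, ...) {
  cat(sprintf("gene_decomposition%s: dc = %.4g, %d component(s), residual rms = %.3g\n",
              if (is.na(x$gene_id)) "" else paste0(" [", x$gene_id, "]"),
              x$dc, length(x$components), x$residual_rms))
  for (cmp in x$components) {
    cat(sprintf("  T = %7.3f h  A = %9.4g  phase = %6.3f h  decay = %+.4g /h\n",
                cmp$period_h, cmp$amplitude, cmp$phase_h, cmp$decay_per_h))
  }
  invisible(x)
}

#' Evaluate a decomposition on its grid
#'
#' Sums the DC level and every damped-cosine component at the grid
#' timepoints, using time measured from the first sample.
#'
#' @param d A `gene_decomposition` from [pencil_decompose()].
#' @return Numeric vector of length `d$grid$n_points`.
#' @export
reconstruct <- function(d) {
  stopifnot(inherits(d, "gene_decomposition"))
  tau <- grid_times(d$grid) - d$grid$start_ct_h
  out <- rep(d$dc, length(tau))
  for (cmp in d$components) {
    out <- out + eval_component(cmp, tau)
  }
  out
}

## evaluate one damped cosine at times tau (measured from the grid start)
eval_component <- function(cmp, tau) {
  cmp$amplitude * exp(cmp$decay_per_h * tau) *
    cos(2 * pi * tau / cmp$period_h - 2 * pi * cmp$phase_h / cmp$period_h)
}

## does a component pass the oscillation filter?
## `level` is the reference expression level (dc, or series mean fallback)
component_passes <- function(cmp, level, grid, filter) {
  tmin <- filter$min_period_h %||% (2 * grid$step_h)
  tmax <- filter$max_period_h %||% grid_span(grid)
  span <- grid_span(grid)
  eff_amp <- cmp$amplitude * exp(cmp$decay_per_h * span / 2)
  cmp$period_h >= tmin && cmp$period_h <= tmax &&
    abs(cmp$decay_per_h) <= filter$max_decay &&
    eff_amp / max(abs(level), filter$dc_floor) >= filter$min_rel_amp
}

## reference level of a decomposition: the larger of |dc| and the series
## mean magnitude, so baselines absorbed by oscillatory poles still count
decomp_level <- function(d) {
  max(abs(d$dc), abs(d$level %||% 0))
}

#' Dominant oscillatory component of a decomposition
#'
#' Returns the largest-amplitude component among those passing the
#' oscillation filter (period resolvable on the grid, damping and relative
#' amplitude within bounds), or `NULL` when no component passes. Amplitude
#' ties break toward the shorter period, then the earlier component
#' (deterministic).
#'
#' @param d A `gene_decomposition`.
#' @param filter An [osc_filter()].
#' @return A component (list with `period_h`, `amplitude`, `phase_h`,
#'   `decay_per_h`, `pole`, `residue`) or `NULL`.
#' @export
dominant_component <- function(d, filter = osc_filter()) {
  stopifnot(inherits(d, "gene_decomposition"), inherits(filter, "osc_filter"))
  passing <- Filter(function(cmp) component_passes(cmp, decomp_level(d), d$grid, filter),
                    d$components)
  if (length(passing) == 0L) return(NULL)
  amps <- vapply(passing, `[[`, numeric(1), "amplitude")
  pers <- vapply(passing, `[[`, numeric(1), "period_h")
  passing[[order(-amps, pers)[1L]]]
}

#' Decompose every row of an expression matrix
#'
#' Applies [pencil_decompose()] to each gene's replicate-averaged series.
#'
#' @param mat Numeric matrix, genes x timepoints, columns ordered by grid
#'   time (e.g. the output of [average_replicates()]).
#' @param grid A [sampling_grid()] matching `ncol(mat)`.
#' @param cfg A [pencil_config()].
#' @return Named list of `gene_decomposition` objects, one per row.
#' @export
decompose_matrix <- function(mat, grid, cfg = pencil_config()) {
  stopifnot(is.matrix(mat), ncol(mat) == grid$n_points)
  ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  out <- vector("list", nrow(mat))
  names(out) <- ids
  for (i in seq_len(nrow(mat))) {
    out[[i]] <- pencil_decompose(mat[i, ], grid, cfg, gene_id = ids[i])
  }
  out
}
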