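grid24 <- sampling_grid()

test_that("a constant series is pure DC with zero residual", {
  d <- pencil_decompose(rep(5, 24), grid24)
  expect_equal(d$dc, 5, tolerance = 1e-12)
  expect_length(d$components, 0)
  expect_lt(d$residual_rms, 1e-10)
})

test_that("a noiseless cosine is recovered essentially exactly", {
  t <- grid_times(grid24)
  d <- pencil_decompose(cos(2 * pi * t / 12), grid24)
  expect_length(d$components, 1)
  cmp <- d$components[[1]]
  expect_equal(cmp$period_h, 12, tolerance = 1e-8)
  expect_equal(cmp$amplitude, 1, tolerance = 1e-8)
  expect_lt(min(cmp$phase_h, 12 - cmp$phase_h), 1e-8)
  expect_lt(abs(cmp$decay_per_h), 1e-8)
  expect_lt(d$residual_rms, 1e-8)
})

test_that("two damped components plus DC are recovered within 1e-6", {
  t <- grid_times(grid24)
  y <- 10 + 3 * exp(-0.01 * t) * cos(2 * pi * t / 24 - pi / 2) +
    1.5 * cos(2 * pi * t / 12)
  d <- pencil_decompose(y, grid24)
  expect_equal(d$dc, 10, tolerance = 1e-6)
  expect_length(d$components, 2)
  c24 <- d$components[[1]]  # larger amplitude
  c12 <- d$components[[2]]
  expect_equal(c24$period_h, 24, tolerance = 1e-6)
  expect_equal(c24$amplitude, 3, tolerance = 1e-6)
  expect_equal(c24$phase_h, 6, tolerance = 1e-5)   # cos(wt - pi/2) peaks at T/4
  expect_equal(c24$decay_per_h, -0.01, tolerance = 1e-6)
  expect_equal(c12$period_h, 12, tolerance = 1e-6)
  expect_equal(c12$amplitude, 1.5, tolerance = 1e-6)

  ## poles cross-checked against the Prony linear-prediction oracle
  got_poles <- unlist(lapply(d$components, function(cm) {
    c(cm$pole, Conj(cm$pole))
  }))
  got_poles <- c(got_poles, complex(real = 1))  # DC pole
  ref <- prony_poles(y, 5)
  expect_lt(pole_set_distance(got_poles, ref), 1e-8)
})

test_that("random damped-cosine mixtures are recovered exactly (property)", {
  withr::with_seed(21, {
    for (case in 1:50) {
      n_comp <- sample(1:3, 1)
      ## enforce 2-h period separation so components are identifiable
      repeat {
        periods <- sort(stats::runif(n_comp, 6, 30))
        if (n_comp == 1 || min(diff(periods)) >= 2) break
      }
      amps <- stats::runif(n_comp, 0.1, 10)
      phases <- stats::runif(n_comp, 0, periods)
      decays <- stats::runif(n_comp, -0.05, 0.05)
      dc <- stats::runif(1, 0, 20)
      t <- grid_times(grid24)
      y <- rep(dc, 24)
      for (i in seq_len(n_comp)) {
        y <- y + amps[i] * exp(decays[i] * t) *
          cos(2 * pi * (t - phases[i]) / periods[i])
      }
      d <- pencil_decompose(y, grid24)
      expect_length(d$components, n_comp)
      got <- d$components[order(vapply(d$components, `[[`, numeric(1),
                                       "period_h"))]
      ord <- order(periods)
      for (i in seq_len(n_comp)) {
        expect_equal(got[[i]]$period_h, periods[ord][i],
                     tolerance = 1e-6)
        expect_equal(got[[i]]$amplitude, amps[ord][i], tolerance = 1e-6)
        expect_equal(got[[i]]$decay_per_h, decays[ord][i], tolerance = 1e-5)
        dphi <- abs(rhythmpencil:::circular_diff(
          got[[i]]$phase_h, phases[ord][i] %% periods[ord][i],
          periods[ord][i]))
        expect_lt(dphi, 1e-6 * periods[ord][i])
      }
      expect_equal(d$dc, dc, tolerance = max(1e-6, 1e-6 * dc))
      expect_lt(d$residual_rms, 1e-7 * max(abs(y)))
    }
  })
})

test_that("reconstruction is consistent with the stored residual", {
  t <- grid_times(grid24)
  ## noiseless round trip
  y <- 4 + 2 * cos(2 * pi * t / 24) + cos(2 * pi * (t - 3) / 12)
  d <- pencil_decompose(y, grid24)
  expect_equal(reconstruct(d), y, tolerance = 1e-8)

  ## components emptied: constant dc series
  d0 <- d
  d0$components <- list()
  expect_equal(reconstruct(d0), rep(d$dc, 24), tolerance = 1e-12)

  ## noisy input: stored residual equals the direct norm
  withr::with_seed(5, yn <- y + stats::rnorm(24, 0, 0.3))
  dn <- pencil_decompose(yn, grid24)
  expect_equal(dn$residual_rms, sqrt(mean((yn - reconstruct(dn))^2)),
               tolerance = 1e-10)
})

test_that("cosine components agree with their complex pole/residue form", {
  ## for real input the merged damped cosine A e^(b tau) cos(...) must equal
  ## 2 Re(r z^n) of the stored conjugate-pair member at every grid point
  withr::with_seed(31, {
    for (case in 1:10) {
      y <- stats::rnorm(24, 100, 10)
      d <- pencil_decompose(y, grid24)
      tau <- grid_times(grid24)
      for (cmp in d$components) {
        cosine_form <- rhythmpencil:::eval_component(cmp, tau)
        is_nyquist <- abs(abs(Arg(cmp$pole)) - pi) <= 1e-6
        complex_form <- if (is_nyquist) {
          Re(cmp$residue * cmp$pole^(0:23))
        } else {
          2 * Re(cmp$residue * cmp$pole^(0:23))
        }
        expect_equal(cosine_form, complex_form,
                     tolerance = 1e-9 * max(1, max(abs(y))))
      }
    }
  })
})

test_that("adding a constant changes only the DC term", {
  t <- grid_times(grid24)
  y <- 2 * cos(2 * pi * t / 12) + 0.8 * cos(2 * pi * (t - 5) / 24)
  d0 <- pencil_decompose(y, grid24)
  d1 <- pencil_decompose(y + 7, grid24)
  expect_equal(d1$dc - d0$dc, 7, tolerance = 1e-7)
  p0 <- vapply(d0$components, `[[`, numeric(1), "period_h")
  p1 <- vapply(d1$components, `[[`, numeric(1), "period_h")
  a0 <- vapply(d0$components, `[[`, numeric(1), "amplitude")
  a1 <- vapply(d1$components, `[[`, numeric(1), "amplitude")
  expect_equal(sort(p1), sort(p0), tolerance = 1e-6)
  expect_equal(sort(a1), sort(a0), tolerance = 1e-6)
})

test_that("residual rms is non-increasing in the model order", {
  withr::with_seed(41, {
    t <- grid_times(grid24)
    y <- 100 + 20 * cos(2 * pi * t / 12) + stats::rnorm(24, 0, 5)
    res <- vapply(1:3, function(m) {
      pencil_decompose(y, grid24, pencil_config(n_oscillations = m))$residual_rms
    }, numeric(1))
    expect_true(all(diff(res) <= 1e-9))
  })
})

test_that("too-short series and infeasible pencil parameters are rejected", {
  short <- sampling_grid(0, 2, 10)
  expect_error(pencil_decompose(rep(1, 10), short), "Lower `n_oscillations`")
  expect_error(
    pencil_decompose(rep(1, 24), grid24, pencil_config(pencil_param = 20)),
    "P <= N - K")
})

test_that("dominant component selection matches a brute-force scan", {
  ## strict ordering example
  d <- fake_decomp("g", 10, list(list(period_h = 12, amplitude = 5),
                                 list(period_h = 24, amplitude = 3)))
  expect_equal(dominant_component(d)$period_h, 12)

  ## trend-like long period fails the span filter
  d90 <- fake_decomp("g", 10, list(list(period_h = 90, amplitude = 5)))
  expect_null(dominant_component(d90))

  ## random decompositions vs brute force
  filt <- osc_filter()
  grid <- sampling_grid()
  span <- grid_span(grid)
  withr::with_seed(51, {
    for (case in 1:500) {
      n <- sample(0:4, 1)
      comps <- lapply(seq_len(n), function(i) {
        list(period_h = stats::runif(1, 2, 100),
             amplitude = stats::runif(1, 0, 5),
             decay_per_h = stats::runif(1, -0.4, 0.4))
      })
      d <- fake_decomp("g", 1, comps)
      got <- dominant_component(d, filt)
      ## brute force over the filter definition
      pass <- Filter(function(cm) {
        eff <- cm$amplitude * exp(cm$decay_per_h * span / 2)
        cm$period_h >= 4 && cm$period_h <= span &&
          abs(cm$decay_per_h) <= 0.2 && eff / 1 >= 0.1
      }, d$components)
      if (length(pass) == 0) {
        expect_null(got)
      } else {
        amps <- vapply(pass, `[[`, numeric(1), "amplitude")
        pers <- vapply(pass, `[[`, numeric(1), "period_h")
        best <- pass[[order(-amps, pers)[1]]]
        expect_equal(got$period_h, best$period_h)
        expect_equal(got$amplitude, best$amplitude)
      }
    }
  })
})
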