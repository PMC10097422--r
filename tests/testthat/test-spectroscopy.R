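test_that("the reconvolution model matches direct numeric convolution", {
  tau <- 65; fwhm <- 50; t0 <- 150
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  times <- c(80, 120, 150, 200, 400, 900)
  # independent oracle: quadrature of the convolution integral
  oracle <- vapply(times, function(t) {
    # integrand vanishes for s > t, so stop the quadrature at the cut
    integrate(function(s) {
      exp(-((s - t0)^2) / (2 * sigma^2)) / (sigma * sqrt(2 * pi)) *
        exp(-(t - s) / tau)
    }, lower = t0 - 8 * sigma, upper = min(t, t0 + 8 * sigma),
    rel.tol = 1e-12, subdivisions = 2000L)$value
  }, numeric(1))
  got <- convolve_model(times, tau, 1, irf_fwhm = fwhm, t0 = t0)
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("a delta IRF reduces the model to the causal multi-exponential", {
  t <- seq(0, 500, by = 2.44)
  got <- convolve_model(t, c(10, 65), c(2, 1), irf_fwhm = 0, t0 = 50)
  expect_equal(got, ifelse(t >= 50, 2 * exp(-(t - 50) / 10) + exp(-(t - 50) / 65), 0))
  # zero-amplitude second component is inert
  one <- convolve_model(t, 65, 1, irf_fwhm = 50, t0 = 50)
  two <- convolve_model(t, c(10, 65), c(0, 1), irf_fwhm = 50, t0 = 50)
  expect_equal(two, one)
  expect_error(convolve_model(t, -5, 1), class = "pigmentnet_data_error")
})

test_that("the convolution preserves total counts (integral = sum A_i tau_i)", {
  dt <- 0.5
  t <- seq(0, 20000, by = dt)
  A <- c(3, 1); tau <- c(12, 70)
  y <- convolve_model(t, tau, A, irf_fwhm = 50, t0 = 500)
  expect_equal(sum(y) * dt, sum(A * tau), tolerance = 1e-4)
})

test_that("a noiseless single-exponential is recovered to better than 0.1%", {
  d <- make_decay_dataset(lifetimes = 65, amplitudes = matrix(1),
                          wavelengths = 690, peak_counts = Inf)
  fit <- global_fit(d$data, n_components = 1)
  expect_lt(abs(fit$lifetimes - 65) / 65, 1e-3)
  expect_true(fit$converged)
})

test_that("two components under Poisson noise are recovered within 10%", {
  for (seed in c(101, 202, 303)) {
    d <- make_decay_dataset(lifetimes = c(10, 65), seed = seed)
    fit <- global_fit(d$data, n_components = 2)
    expect_lt(max(abs(fit$lifetimes - c(10, 65)) / c(10, 65)), 0.10)
  }
})

test_that("lifetimes are reported ascending with DAS rows aligned", {
  d <- make_decay_dataset(lifetimes = c(10, 65), seed = 9)
  fit <- global_fit(d$data, n_components = 2, init = c(80, 12))
  expect_equal(order(fit$lifetimes), seq_along(fit$lifetimes))
  # fast component carries the negative long-wavelength transfer lobe
  spectra <- fdas(fit)
  fast <- dplyr::filter(spectra, component == 1)
  expect_lt(min(fast$amplitude), 0)
  expect_gt(max(fast$amplitude), 0)
  slow <- dplyr::filter(spectra, component == 2)
  expect_true(all(slow$amplitude > 0))
})

test_that("FDAS are equivariant under wavelength permutation", {
  d <- make_decay_dataset(lifetimes = c(10, 65), seed = 13)
  fit1 <- global_fit(d$data, n_components = 2, init = c(10, 65))
  perm <- d$data[order(-d$data$wavelength, d$data$time), ]
  fit2 <- global_fit(perm, n_components = 2, init = c(10, 65))
  f1 <- fdas(fit1); f2 <- fdas(fit2)
  expect_equal(dplyr::arrange(f2, component, wavelength)$amplitude,
               dplyr::arrange(f1, component, wavelength)$amplitude,
               tolerance = 1e-6)
})

test_that("overparameterised fits surface a degeneracy warning", {
  d <- make_decay_dataset(lifetimes = 65, amplitudes = matrix(rep(1, 6), 1),
                          seed = 3)
  expect_warning(global_fit(d$data, n_components = 3, n_starts = 2),
                 class = "pigmentnet_convergence_warning")
})

test_that("steady-state reconstruction equals the time integral of the model", {
  d <- make_decay_dataset(lifetimes = c(10, 65), seed = 17)
  fit <- global_fit(d$data, n_components = 2)
  ss <- reconstruct_steady_state(fit, components = 1:2)
  # numeric oracle: integrate the fitted noiseless model on a fine grid
  dt <- 0.2
  tfine <- seq(0, 8000, by = dt)
  for (j in seq_along(fit$wavelengths)) {
    num <- sum(convolve_model(tfine, fit$lifetimes, fit$das[, j],
                              fit$irf_fwhm, fit$t0)) * dt
    expect_equal(ss$intensity[j], num, tolerance = 0.01)
  }
  # requesting all components of a 2-component fit changes nothing
  expect_equal(reconstruct_steady_state(fit, 1:2), ss)
  expect_error(reconstruct_steady_state(fit, 3), class = "pigmentnet_data_error")
  # analytic case: constant DAS, single component
  d1 <- make_decay_dataset(lifetimes = 65, amplitudes = matrix(rep(2, 3), 1),
                           wavelengths = c(680, 690, 700), peak_counts = Inf)
  f1 <- global_fit(d1$data, 1)
  s1 <- reconstruct_steady_state(f1, 1)
  expect_equal(s1$intensity, unname(f1$lifetimes * f1$das[1, ]),
               tolerance = 1e-6)
})

test_that("lifetime recovery holds across the nanosecond range", {
  # property sweep: single-component datasets, tau from channel width up
  set.seed(23)
  taus <- exp(seq(log(5), log(500), length.out = 12))
  errs <- vapply(seq_along(taus), function(i) {
    d <- make_decay_dataset(lifetimes = taus[i], amplitudes = matrix(1),
                            wavelengths = 690, seed = 1000 + i,
                            n_channels = 2048)
    fit <- global_fit(d$data, 1, n_starts = 2)
    abs(fit$lifetimes - taus[i]) / taus[i]
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("residuals on model-class data show no lag-1 autocorrelation", {
  sig <- 0
  for (seed in 1:8) {
    d <- make_decay_dataset(lifetimes = c(10, 65), seed = 400 + seed)
    fit <- global_fit(d$data, 2, n_starts = 2)
    r <- as.vector(fit$residuals * sqrt(fit$weights))
    bt <- stats::Box.test(r, lag = 1)
    if (bt$p.value < 0.01) sig <- sig + 1
  }
  expect_lte(sig, 1)
})

test_that("P700 oxidation fits recover the rate and preserve antenna ordering", {
  # noiseless: exact recovery
  clean <- make_p700_trace(tau = 0.1, noise_sd = 0, n_replicates = 1, seed = 1)
  fit <- fit_p700(clean$data)
  expect_equal(fit$rate, 10, tolerance = 1e-6)
  # 2% noise, 8 averaged replicates: within 5%
  noisy <- make_p700_trace(tau = 0.1, noise_sd = 0.02, n_replicates = 8, seed = 5)
  fitn <- fit_p700(noisy$data)
  expect_lt(abs(fitn$rate - 10) / 10, 0.05)
  # larger antenna = faster oxidation: tau_A < tau_B gives rate_A > rate_B
  a <- fit_p700(make_p700_trace(0.05, seed = 8)$data)
  b <- fit_p700(make_p700_trace(0.10, seed = 8)$data)
  expect_gt(a$rate, b$rate)
  expect_equal(a$rate / b$rate, 2, tolerance = 0.1)
  # degenerate inputs
  flat <- tibble::tibble(time = seq(-0.1, 1, 0.01), signal = 1)
  expect_error(fit_p700(flat), class = "pigmentnet_data_error")
  no_base <- dplyr::filter(clean$data, time > 0)
  expect_error(fit_p700(no_base), class = "pigmentnet_data_error")
})

test_that("tidiers and plots expose the fit results", {
  d <- make_decay_dataset(lifetimes = c(10, 65), seed = 29)
  fit <- global_fit(d$data, 2, init = c(10, 65))
  td <- tidy(fit)
  expect_equal(td$lifetime, fit$lifetimes)
  gl <- glance(fit)
  expect_equal(gl$n_components, 2)
  expect_s3_class(autoplot(fit), "ggplot")
  p <- fit_p700(make_p700_trace(0.1, seed = 2)$data)
  expect_equal(tidy(p)$estimate[1], p$rate)
  expect_s3_class(autoplot(p), "ggplot")
})
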