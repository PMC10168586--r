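test_that("Tukey window limits and shape", {
  expect_equal(tukey_window(64, 0), rep(1, 64))
  n <- 64
  hann <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
  expect_equal(tukey_window(n, 1), hann, tolerance = 1e-12)
  w <- tukey_window(101, 0.25)
  expect_equal(w, rev(w))
  expect_equal(w[1], 0)
  expect_equal(max(w), 1)
})

test_that("Welch estimator: tone location, segmentation, white-noise level", {
  fs <- 1000; n <- 10000
  t <- seq_len(n) / fs
  x <- sin(2 * pi * 13 * t)
  sp <- welch_psd(x, fs = fs)
  expect_equal(sp$n_segments, 9) # 10 s at nperseg 2000 / noverlap 1000
  expect_equal(sp$freq[which.max(sp$psd)], 13)
  expect_error(welch_psd(x[1:1500], fs = fs), "shorter")

  # white noise: flat at 2 sigma^2 / fs, and Parseval-consistent
  set.seed(42)
  sigma <- 3
  z <- rnorm(n, sd = sigma)
  sp <- welch_psd(z, fs = fs)
  level <- 2 * sigma^2 / fs
  sel <- sp$freq > 10 & sp$freq < 480
  expect_equal(mean(sp$psd[sel]), level, tolerance = 0.05)
  total <- sum(sp$psd) * (sp$freq[2] - sp$freq[1])
  expect_equal(total, sigma^2, tolerance = 0.05)
})

test_that("band mean frequency follows its defining integral", {
  expect_equal(mean_frequency(flat_spectrum()), 16) # flat -> band midpoint
  # all power in the 13 Hz bin
  f <- seq(0, 500, by = 0.5)
  pk <- flat_spectrum(0, f); pk$psd[f == 13] <- 5
  expect_equal(mean_frequency(pk), 13)
  # P(f) = f on [8, 24]: closed form (M^3-m^3)/3 / ((M^2-m^2)/2)
  ramp <- flat_spectrum(0, f); ramp$psd <- f
  expect_equal(mean_frequency(ramp), (24^3 - 8^3) / 3 / ((24^2 - 8^2) / 2),
               tolerance = 1e-3)
  expect_true(is.na(mean_frequency(flat_spectrum(0))))
  # Eq-4 output always lies inside the band
  set.seed(1)
  for (i in 1:20) {
    s <- flat_spectrum(0, f); s$psd <- runif(length(f))
    mf <- mean_frequency(s)
    expect_gte(mf, 8); expect_lte(mf, 24)
  }
})

test_that("band-averaged power follows its defining integral", {
  expect_equal(mean_beta_psd(flat_spectrum(0)), 0)
  expect_equal(mean_beta_psd(flat_spectrum(2.5)), 2.5)
  # narrow peak of known area: area / (M - m)
  f <- seq(0, 500, by = 0.5)
  s <- flat_spectrum(0, f)
  # boxcar over [12, 14] with 0.5 Hz bins: trapezoid area 4 * (2 + 0.5)
  s$psd[f >= 12 & f <= 14] <- 4
  expect_equal(mean_beta_psd(s), 4 * 2.5 / 16)
})

test_that("binomial null matches the analytic shot-noise level", {
  expect_equal(binomial_null(0, 400)$Q, 0)
  nu0 <- 0.017; N <- 408
  q <- binomial_null(nu0, N, duration = 10000, n_rep = 20, seed = 3)
  analytic <- 2 * nu0 * (1 - nu0) / (N * 1e-3) # density level in (Hz/neuron)^2/Hz
  expect_lt(abs(q$Q - analytic), 3 * q$se + 0.02 * analytic)
})

test_that("corrected beta power of a constant-rate surrogate is zero", {
  nu0 <- 0.05; N <- 390
  set.seed(9)
  vals <- vapply(1:20, function(i) {
    counts <- rbinom(10000, N, nu0)
    series <- structure(list(rate = counts / N / 1e-3, counts = counts,
                             N = N, binwidth = 1, duration = 10000,
                             population = "x"), class = "bg_rate_series")
    corrected_beta_psd(welch_psd(series), Q = binomial_null(nu0, N, seed = i))
  }, numeric(1))
  # statistically indistinguishable from 0 at alpha = 0.01
  expect_gt(stats::t.test(vals, mu = 0)$p.value, 0.01)
})

test_that("time-resolved statistics track a constructed signal", {
  fs <- 1000
  mk_series <- function(x) structure(
    list(rate = x, counts = x, N = 1, binwidth = 1, duration = length(x),
         population = "x"), class = "bg_rate_series")
  t <- seq_len(10000) / fs
  stationary <- mk_series(10 + 3 * sin(2 * pi * 13 * t))
  tr <- time_resolved(stationary)
  expect_lt(max(abs(tr$mean_f - 13)), 0.5)
  # 13 Hz epoch then 19 Hz epoch: windowed mean f switches level
  x2 <- c(10 + 3 * sin(2 * pi * 13 * t[1:5000]),
          10 + 3 * sin(2 * pi * 19 * t[1:5000]))
  tr2 <- time_resolved(mk_series(x2), window = 1000, step = 250)
  early <- tr2$mean_f[tr2$t_mid < 4000]
  late <- tr2$mean_f[tr2$t_mid > 6000]
  expect_lt(max(abs(early - 13)), 1)
  expect_lt(max(abs(late - 19)), 1)
  expect_error(time_resolved(stationary, window = 20000), "longer")
})

test_that("skewness statistic behaves on known distributions", {
  set.seed(7)
  expect_lt(abs(beta_power_skewness(rnorm(3000))), 0.15)
  expect_equal(beta_power_skewness(rexp(20000)), 2, tolerance = 0.15)
  expect_true(is.na(beta_power_skewness(rep(1, 50))))
})

test_that("spectral scalars are invariant to neuron relabelling and time shift", {
  r <- run_simulation(mini_net(), duration = 3000, warmup = 500, seed = 8)
  s0 <- welch_psd(bin_rates(r, "I"))
  # relabel neurons
  r2 <- r
  perm <- sample(100)
  r2$spikes$neuron <- perm[r2$spikes$neuron]
  s2 <- welch_psd(bin_rates(r2, "I"))
  expect_equal(s2$psd, s0$psd)
  # integer-bin time translation shifts the rate series bin-for-bin
  r3 <- r
  r3$spikes$time <- r3$spikes$time + 500
  r3$duration <- r$duration + 500
  shifted <- bin_rates(r3, "I")
  expect_equal(shifted$counts[501:3500], bin_rates(r, "I")$counts)
})
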