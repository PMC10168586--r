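# Spectral pipeline: 1-ms population rate series -> Welch PSD ->
# band-average statistics with a binomial shot-noise correction.

#' Bin a spike raster into a population rate series
#'
#' Computes the population activity as the number of spikes of the
#' observed neurons per 1 ms bin, expressed as an instantaneous
#' population rate in Hz per neuron.  For size-scaled networks the
#' observer subsample (of reference size) recorded in the raster is used,
#' so that series are comparable across scales.
#'
#' @param raster A `bg_raster` from [run_simulation()].
#' @param population Population name.
#' @param neurons Optional integer vector of neuron indices to observe;
#'   defaults to the raster's observer subsample for that population.
#' @param binwidth Bin width in ms (the analysis convention is 1 ms).
#' @return An object of class `bg_rate_series`: list with `rate` (Hz per
#'   neuron, one value per bin), `counts`, `N` (number of observed
#'   neurons), `binwidth`, `duration`, `population`.
#' @export
bin_rates <- function(raster, population, neurons = NULL, binwidth = 1) {
  stopifnot(inherits(raster, "bg_raster"))
  if (!population %in% names(raster$observers))
    stop("unknown population: ", population)
  if (is.null(neurons)) neurons <- raster$observers[[population]]
  sp <- raster$spikes
  keep <- sp$population == population & sp$neuron %in% neurons
  nbin <- floor(raster$duration / binwidth)
  idx <- floor(sp$time[keep] / binwidth) + 1
  idx <- idx[idx >= 1 & idx <= nbin] # spike exactly at t = duration -> last bin
  counts <- tabulate(idx, nbins = nbin)
  N <- length(neurons)
  structure(list(rate = counts / N / (binwidth / 1000), counts = counts,
                 N = N, binwidth = binwidth, duration = nbin * binwidth,
                 population = population),
            class = "bg_rate_series")
}

#' Tukey (tapered cosine) window
#'
#' @param n Window length.
#' @param alpha Taper fraction in `[0, 1]` (0 = rectangular, 1 = Hann).
#' @return Numeric vector of length `n`.
#' @export
tukey_window <- function(n, alpha = 0.25) {
  stopifnot(n >= 1, alpha >= 0, alpha <= 1)
  if (n == 1) return(1)
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  if (alpha > 0) {
    lo <- x < alpha / 2
    hi <- x > 1 - alpha / 2
    w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
    w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - x[hi]) / alpha - 1)))
  }
  w
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: the series is cut into overlapping
#' segments, each segment is constant-detrended, tapered with a Tukey
#' window and Fourier transformed; the one-sided density-normalised
#' periodograms are averaged.  With the default parameters a 10 s series
#' at 1 ms resolution yields 9 segments and a 0.5 Hz frequency grid.
#'
#' @param x A `bg_rate_series` or a plain numeric series.
#' @param fs Sampling frequency in Hz (1000 for 1 ms bins; taken from the
#'   series when `x` is a `bg_rate_series`).
#' @param nperseg Segment length in samples.
#' @param noverlap Overlap between consecutive segments in samples.
#' @param tukey_alpha Taper fraction of the Tukey window.
#' @return An object of class `bg_spectrum`: list with `freq` (Hz), `psd`
#'   (density units, signal-unit^2/Hz), `n_segments`, and when available
#'   `nu0` (mean per-bin spike probability of the underlying series) and
#'   `N` (observed-subsample size) used by the shot-noise correction.
#' @export
welch_psd <- function(x, fs = 1000, nperseg = 2000, noverlap = 1000,
                      tukey_alpha = 0.25) {
  nu0 <- NULL; N <- NULL
  if (inherits(x, "bg_rate_series")) {
    nu0 <- mean(x$counts) / x$N
    N <- x$N
    fs <- 1000 / x$binwidth
    x <- x$rate
  }
  x <- as.numeric(x)
  n <- length(x)
  if (n < nperseg)
    stop("series (", n, " samples) is shorter than one segment (", nperseg, ")")
  stopifnot(noverlap < nperseg)
  step <- nperseg - noverlap
  starts <- seq(1, n - nperseg + 1, by = step)
  w <- tukey_window(nperseg, tukey_alpha)
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nperseg %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2
    acc <- acc + sp
  }
  psd <- acc / length(starts) * scale
  psd[2:(nfreq - 1)] <- 2 * psd[2:(nfreq - 1)] # one-sided (DC/Nyquist once)
  structure(list(freq = seq(0, by = fs / nperseg, length.out = nfreq),
                 psd = psd, n_segments = length(starts),
                 nu0 = nu0, N = N,
                 nperseg = nperseg, noverlap = noverlap,
                 tukey_alpha = tukey_alpha, fs = fs),
            class = "bg_spectrum")
}

#' @export
print.bg_spectrum <- function(x, ...) {
  cat("<bg_spectrum> ", length(x$freq), " bins, df = ",
      signif(x$freq[2] - x$freq[1], 3), " Hz, ", x$n_segments,
      " segments\n", sep = "")
  invisible(x)
}

.band_grid <- function(spec, band) {
  sel <- spec$freq >= band[1] - 1e-9 & spec$freq <= band[2] + 1e-9
  if (sum(sel) < 2) stop("fewer than two frequency bins inside the band")
  sel
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Power-weighted mean frequency over the beta band
#'
#' `Mean f = (int f P(f) df) / (int P(f) df)` over the analysis band
#' (default 8-24 Hz), evaluated by the trapezoid rule on the Welch grid.
#' A spectrally flat signal gives the band midpoint (16 Hz); a pure tone
#' gives the tone frequency.
#'
#' @param spec A `bg_spectrum`.
#' @param band Integration band `c(m, M)` in Hz.
#' @return Mean frequency (Hz), or `NA` if the band carries no power.
#' @export
mean_frequency <- function(spec, band = c(8, 24)) {
  sel <- .band_grid(spec, band)
  f <- spec$freq[sel]; p <- spec$psd[sel]
  tot <- .trapz(f, p)
  if (tot <= 0) return(NA_real_)
  .trapz(f, f * p) / tot
}

#' Band-averaged beta power
#'
#' `Mean PSD = (1/(M-m)) int_m^M P(f) df`: the mean spectral density over
#' the analysis band, a measure of the intensity of beta oscillations.
#'
#' @inheritParams mean_frequency
#' @return Band-averaged PSD (signal-unit^2/Hz).
#' @export
mean_beta_psd <- function(spec, band = c(8, 24)) {
  sel <- .band_grid(spec, band)
  .trapz(spec$freq[sel], spec$psd[sel]) / (band[2] - band[1])
}

#' Shot-noise (binomial) spectral floor
#'
#' Even a population with constant mean activity has a flat, non-zero
#' spectrum: with `N` observed neurons firing independently with per-bin
#' probability `nu0`, the bin counts are Binomial(`N`, `nu0`) and their
#' fluctuations leak into the beta band.  `binomial_null()` estimates
#' this floor `Q(nu0, N)` by Monte Carlo: surrogate count series are
#' drawn i.i.d. from the binomial distribution, passed through the
#' identical Welch + band-average pipeline, and averaged.
#'
#' @param nu0 Per-bin spike probability (mean rate x bin width), in `[0, 1]`.
#' @param N Observed-subsample size.
#' @param duration Surrogate series duration (ms; equals number of 1 ms bins).
#' @param n_rep Number of surrogate repetitions.
#' @param band Analysis band (Hz).
#' @param seed Seed for the surrogate draws.
#' @param ... Passed to [welch_psd()].
#' @return List with `Q` (mean band-averaged surrogate PSD), `se` (its
#'   standard error) and `n_rep`.
#' @export
binomial_null <- function(nu0, N, duration = 10000, n_rep = 20,
                          band = c(8, 24), seed = 1, ...) {
  if (nu0 < 0 || nu0 > 1) stop("nu0 must be a probability in [0,1]")
  if (nu0 == 0) return(list(Q = 0, se = 0, n_rep = n_rep))
  vals <- with_seed(seed, vapply(seq_len(n_rep), function(i) {
    counts <- stats::rbinom(duration, N, nu0)
    series <- structure(list(rate = counts / N / 1e-3, counts = counts,
                             N = N, binwidth = 1, duration = duration,
                             population = "surrogate"),
                        class = "bg_rate_series")
    mean_beta_psd(welch_psd(series, ...), band = band)
  }, numeric(1)))
  list(Q = mean(vals), se = stats::sd(vals) / sqrt(n_rep), n_rep = n_rep)
}

#' Bias-corrected beta power
#'
#' `PSD-dagger = Mean PSD - Q(nu0, N)`: the band-averaged PSD minus the
#' binomial shot-noise floor of a constant-rate population with the same
#' observed size and mean rate.  For pure-noise inputs the result
#' fluctuates around zero and may be slightly negative; it is reported
#' as computed.
#'
#' @param spec A `bg_spectrum` produced from a `bg_rate_series` (so that
#'   `nu0` and `N` are known), or any `bg_spectrum` if `Q` is supplied.
#' @param Q Optional precomputed noise floor (see [binomial_null()]).
#' @param band Analysis band (Hz).
#' @param ... Passed to [binomial_null()] when `Q` is computed here.
#' @return Corrected band-averaged PSD (same units as [mean_beta_psd()]).
#' @export
corrected_beta_psd <- function(spec, Q = NULL, band = c(8, 24), ...) {
  if (is.null(Q)) {
    if (is.null(spec$nu0) || is.null(spec$N))
      stop("spectrum lacks nu0/N; supply Q explicitly")
    Q <- binomial_null(spec$nu0, spec$N, n_rep = 20, band = band, ...)$Q
  } else if (is.list(Q)) {
    Q <- Q$Q
  }
  mean_beta_psd(spec, band = band) - Q
}

#' Time-resolved beta statistics
#'
#' Sliding-window application of the spectral pipeline: for each window
#' the PSD (single Tukey-tapered periodogram when the window equals one
#' Welch segment), the band mean frequency and the band-averaged power
#' are computed.
#'
#' @param series A `bg_rate_series`.
#' @param window Window length (ms).
#' @param step Window step (ms).
#' @param band Analysis band (Hz).
#' @param tukey_alpha Taper fraction.
#' @return Data frame with columns `t_mid` (window centre, ms),
#'   `mean_f` (Hz) and `beta_psd`; attribute `spectra` holds the
#'   per-window `bg_spectrum` objects.
#' @export
time_resolved <- function(series, window = 2000, step = 500, band = c(8, 24),
                          tukey_alpha = 0.25) {
  stopifnot(inherits(series, "bg_rate_series"))
  nbin <- length(series$rate)
  wlen <- round(window / series$binwidth)
  if (wlen > nbin) stop("window longer than the series")
  starts <- seq(1, nbin - wlen + 1, by = round(step / series$binwidth))
  specs <- lapply(starts, function(s) {
    sub <- series
    sub$rate <- series$rate[s:(s + wlen - 1)]
    sub$counts <- series$counts[s:(s + wlen - 1)]
    welch_psd(sub, nperseg = wlen, noverlap = 0, tukey_alpha = tukey_alpha)
  })
  out <- data.frame(
    t_mid = (starts - 1 + wlen / 2) * series$binwidth,
    mean_f = vapply(specs, mean_frequency, numeric(1), band = band),
    beta_psd = vapply(specs, mean_beta_psd, numeric(1), band = band))
  attr(out, "spectra") <- specs
  out
}

#' Skewness of the windowed beta-power distribution
#'
#' Adjusted Fisher-Pearson sample skewness of instantaneous beta-power
#' samples.  Right-skewed distributions indicate transient bursting;
#' near-symmetric distributions indicate sustained oscillation.
#'
#' @param beta_power Numeric vector of windowed beta-power samples.
#' @return Sample skewness, or `NA` for degenerate (constant or too
#'   short) input.
#' @export
beta_power_skewness <- function(beta_power) {
  x <- beta_power[is.finite(beta_power)]
  if (length(x) < 3 || stats::sd(x) == 0) return(NA_real_)
  e1071::skewness(x, type = 2)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so that package internals never disturb user-level
#' reproducibility.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
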