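#' Build the Complete Model
#'
#' Assembles the six-population basal-ganglia network (D1, D2, FSN,
#' GPe-TA, GPe-TI, STN; GPi/SNr are not represented since they send no
#' feedback to the modelled nuclei) with the reference sizes, neuron
#' parameters and connectivity, applies the dopamine-depletion factor
#' `D_d` to the D2 external drive, the population-size multiplier `n`
#' and, optionally, an optogenetic-like perturbation.
#'
#' @param D_d Dopamine-depletion severity: multiplies the external input
#'   rate of the D2 population (reference value at `D_d = 1`).
#' @param n Population-size multiplier (1, 2, 4, 8, ...).  Internal
#'   connection probabilities are divided by `n` so that the expected
#'   number of presynaptic neurons per target is unchanged; spectra are
#'   computed over a fixed subsample of reference size.
#' @param opto Optional [opto_perturbation()].
#' @param opto_seed Seed for the motor/non-motor striatal partition used
#'   by the cortex-inhibition perturbation (drawn once per build).
#' @param config Model configuration, see [bg_config()].
#' @return A [bg_network()].
#' @export
build_complete_model <- function(D_d = 1, n = 1, opto = NULL, opto_seed = 1,
                                 config = bg_config()) {
  stopifnot(D_d > 0, n >= 1)
  pops <- lapply(names(config$populations), function(nm) {
    list(name = nm, N = as.integer(config$populations[[nm]]$size),
         params = neuron_params(population = nm),
         observer_size = as.integer(config$populations[[nm]]$size),
         is_auxiliary = FALSE)
  })
  con <- config$connections
  con <- con[con$source != "ext", ]
  net <- bg_network(pops, con)
  net <- apply_dopamine(net, D_d)
  if (n > 1) net <- scale_size(net, n)
  if (!is.null(opto)) net <- apply_opto(net, opto, seed = opto_seed)
  net
}

#' Apply dopamine depletion to a built network
#'
#' Dopamine depletion is modelled as a multiplicative modulation of the
#' external input rate towards the D2 population (and its auxiliary
#' counterpart `D2*` when present): `nu_ext(D_d) = D_d * nu_ext_1`.  The
#' larger `D_d`, the more severe the depletion.  All other drives are
#' untouched.
#'
#' @param network A [bg_network()].
#' @param D_d Positive depletion factor (`1` = reference dopamine level).
#' @return The modulated network.
#' @export
apply_dopamine <- function(network, D_d) {
  stopifnot(inherits(network, "bg_network"), D_d > 0)
  for (nm in intersect(c("D2", "D2s"), names(network$populations))) {
    p <- network$populations[[nm]]
    p$params$nu_ext <- p$params$nu_ext * D_d
    if (!is.null(p$nu_ext_vec)) p$nu_ext_vec <- p$nu_ext_vec * D_d
    network$populations[[nm]] <- p
  }
  network
}

#' Optogenetic-like perturbation descriptor
#'
#' Encodes the three activity perturbations used to validate the model
#' against in-vivo optogenetic experiments, applied on top of the
#' pathological baseline:
#' \describe{
#'   \item{`cortex_inhibition`}{motor-cortex silencing: the STN external
#'     rate is multiplied by 0.75 and, in a motor fraction (20%) of each
#'     striatal population, the external rate is multiplied by 0.25.}
#'   \item{`stn_modulation`}{STN external rate multiplied by `kappa`;
#'     values in `[0.65, 1.7]` span STN rates of roughly 8-30 Hz.}
#'   \item{`gpe_inhibition`}{constant current reduced by 480 pA in GPe-TA
#'     and by 120 pA in GPe-TI.}
#' }
#'
#' @param kind Perturbation kind (see Description).
#' @param kappa STN drive factor (only for `stn_modulation`).
#' @return An object of class `opto_perturbation`.
#' @export
opto_perturbation <- function(kind = c("cortex_inhibition", "stn_modulation",
                                       "gpe_inhibition"), kappa = 1) {
  kind <- match.arg(kind)
  if (kind == "stn_modulation" && (kappa < 0.65 || kappa > 1.7))
    warning("kappa outside the validated range [0.65, 1.7]")
  structure(list(kind = kind, kappa = kappa,
                 motor_fraction = 0.20, motor_input_factor = 0.25,
                 stn_input_factor = 0.75,
                 gpe_ta_current_delta = -480, gpe_ti_current_delta = -120),
            class = "opto_perturbation")
}

#' Apply an optogenetic-like perturbation to a built network
#'
#' @param network A [bg_network()].
#' @param perturbation An [opto_perturbation()].
#' @param seed Seed for the motor/non-motor striatal partition
#'   (`cortex_inhibition` only); membership is drawn once.
#' @return The perturbed network.
#' @export
apply_opto <- function(network, perturbation, seed = 1) {
  stopifnot(inherits(network, "bg_network"),
            inherits(perturbation, "opto_perturbation"))
  pt <- perturbation
  scale_nu <- function(p, f) {
    p$params$nu_ext <- p$params$nu_ext * f
    if (!is.null(p$nu_ext_vec)) p$nu_ext_vec <- p$nu_ext_vec * f
    p
  }
  if (pt$kind == "cortex_inhibition") {
    network$populations$STN <- scale_nu(network$populations$STN,
                                        pt$stn_input_factor)
    striatal <- intersect(c("D1", "D2", "FSN"), names(network$populations))
    for (i in seq_along(striatal)) {
      p <- network$populations[[striatal[i]]]
      nu <- if (is.null(p$nu_ext_vec)) rep(p$params$nu_ext, p$N) else p$nu_ext_vec
      k <- round(pt$motor_fraction * p$N)
      motor <- .subsample(p$N, k, seed + 20000, i)
      nu[motor] <- nu[motor] * pt$motor_input_factor
      p$nu_ext_vec <- nu
      network$populations[[striatal[i]]] <- p
    }
  } else if (pt$kind == "stn_modulation") {
    network$populations$STN <- scale_nu(network$populations$STN, pt$kappa)
  } else { # gpe_inhibition
    network$populations$GPTA$params$I_e <-
      network$populations$GPTA$params$I_e + pt$gpe_ta_current_delta
    network$populations$GPTI$params$I_e <-
      network$populations$GPTI$params$I_e + pt$gpe_ti_current_delta
  }
  network
}

#' Scale the network size preserving expected in-degrees
#'
#' Multiplies every population size by `n` and divides every internal
#' connection probability by `n`, so that the expected number of
#' presynaptic neurons per target is unchanged.  External drives are
#' per-neuron (probability one) and are not rescaled.  Observer
#' subsamples keep the reference size so that spectra are comparable
#' across `n`.
#'
#' @param network A [bg_network()].
#' @param n Integer size multiplier.
#' @return The rescaled network.
#' @export
scale_size <- function(network, n) {
  stopifnot(inherits(network, "bg_network"), n >= 1)
  if (n == 1) return(network)
  for (nm in names(network$populations)) {
    p <- network$populations[[nm]]
    if (is.null(p$observer_size)) p$observer_size <- p$N
    p$N <- as.integer(round(p$N * n))
    if (!is.null(p$nu_ext_vec))
      stop("scale_size must be applied before per-neuron drive overrides")
    network$populations[[nm]] <- p
  }
  network$connections$p <- network$connections$p / n
  if (any(network$connections$p > 1))
    stop("connection probability exceeds 1 after scaling")
  network
}

#' Calibrate the drive of an externally driven population to a target rate
#'
#' Auxiliary populations receive no recurrent input, so their mean rate
#' is independent of the surrounding network and of the population size.
#' This routine adjusts the constant current `I_e` (or, alternatively,
#' the external Poisson rate `nu_ext`) by bisection until the simulated
#' mean rate of an isolated population matches `target_rate`.
#'
#' @param params A [neuron_params()] describing the population.
#' @param target_rate Target mean rate (Hz).
#' @param tolerance Acceptable absolute rate error (Hz).
#' @param what Which knob to adjust: `"I_e"` or `"nu_ext"`.
#' @param N Size of the probe population used for rate estimation.
#' @param duration Probe simulation length (ms).
#' @param seed Seed of the probe simulations.
#' @param interval Search interval for the knob; widened automatically
#'   from the current value when omitted.
#' @param max_iter Maximum bisection iterations.
#' @return A list with the calibrated `params`, the `value` of the knob
#'   and the `achieved` rate (Hz).
#' @export
calibrate_auxiliary <- function(params, target_rate, tolerance = 0.5,
                                what = c("I_e", "nu_ext"), N = 200,
                                duration = 3000, seed = 1, interval = NULL,
                                max_iter = 40) {
  what <- match.arg(what)
  rate_at <- function(x) {
    p <- params
    p[[what]] <- x
    net <- bg_network(list(list(name = "probe", N = as.integer(N),
                                params = validate_neuron_params(p))),
                      data.frame(source = character(0), target = character(0),
                                 p = numeric(0), delay = numeric(0),
                                 type = character(0), weight = numeric(0)))
    unname(run_simulation(net, duration = duration, warmup = 500,
                          seed = seed)$rates)
  }
  x0 <- params[[what]]
  r0 <- rate_at(x0)
  if (abs(r0 - target_rate) <= tolerance) {
    params[[what]] <- x0
    return(list(params = params, value = x0, achieved = r0))
  }
  if (is.null(interval)) {
    span <- max(abs(x0), if (what == "I_e") 100 else 0.2)
    lo <- x0 - span; hi <- x0 + span
    if (what == "nu_ext") lo <- max(lo, 0)
    for (i in 1:12) {
      if (rate_at(lo) <= target_rate && rate_at(hi) >= target_rate) break
      if (rate_at(lo) > target_rate) lo <- lo - span
      if (rate_at(hi) < target_rate) hi <- hi + span
      if (what == "nu_ext") lo <- max(lo, 0)
      if (i == 12) stop("calibration failure: could not bracket the target ",
                        "rate (", target_rate, " Hz) by varying ", what)
    }
    interval <- c(lo, hi)
  }
  lo <- interval[1]; hi <- interval[2]
  rlo <- rate_at(lo); rhi <- rate_at(hi)
  if ((rlo - target_rate) * (rhi - target_rate) > 0)
    stop("calibration failure: search interval [", lo, ", ", hi,
         "] does not bracket the target rate (rates ", round(rlo, 2), ", ",
         round(rhi, 2), " Hz vs target ", target_rate, " Hz)")
  mid <- x0; rmid <- r0
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    rmid <- rate_at(mid)
    if (abs(rmid - target_rate) <= tolerance) break
    if (rmid < target_rate) lo <- mid else hi <- mid
  }
  params[[what]] <- mid
  list(params = params, value = mid, achieved = rmid)
}
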