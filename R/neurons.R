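#' Neuron parameter record
#'
#' Builds and validates the parameter record of one neuron population for
#' one of the three point-neuron models used in the network:
#' `aeif_cond_exp` (adaptive exponential integrate-and-fire; pallidal and
#' subthalamic populations), `aqif_cond_exp` (adaptive quadratic; medium
#' spiny neurons) and `aqif2_cond_exp` (quadratic with a cubic adaptation
#' nullcline below a pivot voltage; fast-spiking interneurons).
#'
#' Either supply `population` to pull the reference parameters of a named
#' population (Complete Model configuration), or supply the fields
#' explicitly.  Fields given in `...` override the reference values.
#'
#' Units: `C_m` pF; voltages mV; conductances nS; currents pA; times ms;
#' `nu_ext` kHz; `a` in nS for aeif/aqif and nS/mV^2 for aqif2;
#' `k` in nS/mV.
#'
#' @param population Optional reference population name
#'   (`"D1"`, `"D2"`, `"FSN"`, `"GPTI"`, `"GPTA"`, `"STN"`).
#' @param variant Model variant: `"aeif"`, `"aqif"` or `"aqif2"`.
#' @param ... Named parameter overrides (see Details).
#' @return An object of class `neuron_params` (named list).
#' @export
neuron_params <- function(population = NULL, variant = NULL, ...) {
  over <- list(...)
  if (!is.null(population)) {
    cfg <- bg_config()
    if (!population %in% names(cfg$populations))
      stop("unknown reference population: ", population)
    p <- cfg$populations[[population]]
    variant <- sub("_cond_exp$", "", p$model)
    ext <- cfg$connections
    extw <- ext$weight[ext$source == "ext" & ext$target == population]
    p <- p[setdiff(names(p), c("size", "model"))]
    p$ext_weight <- extw
  } else {
    if (is.null(variant)) stop("variant is required when no population is given")
    p <- list()
  }
  p[names(over)] <- over
  p$variant_name <- match.arg(variant, c("aeif", "aqif", "aqif2"))
  p$variant <- match(p$variant_name, c("aeif", "aqif", "aqif2")) - 1L
  validate_neuron_params(p)
}

validate_neuron_params <- function(p) {
  base <- c("C_m", "E_L", "E_ex", "E_in", "tau_ex", "tau_in", "V_th", "I_e",
            "t_ref", "V_reset", "a", "b", "tau_w", "V_peak")
  extra <- switch(p$variant_name,
                  aeif = c("Delta_T", "g_L"),
                  aqif = "k",
                  aqif2 = c("k", "V_b"))
  need <- c(base, extra)
  miss <- need[!need %in% names(p) | vapply(p[need], is.null, logical(1))]
  if (length(miss))
    stop("missing parameter(s) for ", p$variant_name, " model: ",
         paste(miss, collapse = ", "))
  if (is.null(p$nu_ext)) p$nu_ext <- 0
  if (is.null(p$ext_weight)) p$ext_weight <- 0
  if (is.null(p$dev_ext_weight)) p$dev_ext_weight <- 0
  with(p, {
    stopifnot(tau_ex > 0, tau_in > 0, tau_w > 0, C_m > 0,
              V_reset < V_peak, nu_ext >= 0, ext_weight >= 0,
              dev_ext_weight >= 0, t_ref >= 0)
    if (variant_name == "aeif") stopifnot(V_th < V_peak, Delta_T > 0, g_L > 0)
  })
  structure(p, class = "neuron_params")
}

#' Neuron dynamical state
#'
#' @param V Membrane potential (mV).
#' @param w Adaptation current (pA).
#' @param g_ex,g_in Excitatory/inhibitory conductances (nS), non-negative.
#' @param refractory_until Absolute time (ms) until which the neuron is
#'   refractory (`-Inf` when not refractory).
#' @return An object of class `neuron_state`.
#' @export
neuron_state <- function(V, w = 0, g_ex = 0, g_in = 0,
                         refractory_until = -Inf) {
  stopifnot(g_ex >= 0, g_in >= 0)
  structure(list(V = V, w = w, g_ex = g_ex, g_in = g_in,
                 refractory_until = refractory_until),
            class = "neuron_state")
}

# membrane current / adaptation right-hand sides; V is clamped to V_peak
# (the upward blow-up is the spike) and floored at -150 mV.
.v_floor <- -150

#' Time derivatives of the neuron state
#'
#' Evaluates the model right-hand side: the membrane equation of the
#' selected variant, the adaptation-current equation and the exponential
#' conductance decays.  Discrete jumps (spike-triggered `b` increments and
#' synaptic conductance increments) are event handled and do not appear
#' here.
#'
#' @param state A [neuron_state()].
#' @param params A [neuron_params()].
#' @return Named numeric vector `c(V, w, g_ex, g_in)` of time derivatives
#'   (per ms).
#' @export
neuron_derivatives <- function(state, params) {
  p <- params
  Veff <- min(max(state$V, .v_floor), p$V_peak)
  I <- -state$g_ex * (Veff - p$E_ex) - state$g_in * (Veff - p$E_in) -
    state$w + p$I_e
  I <- I + switch(p$variant_name,
    aeif = -p$g_L * (Veff - p$E_L) +
      p$g_L * p$Delta_T * exp(min((Veff - p$V_th) / p$Delta_T, 40)),
    p$k * (Veff - p$E_L) * (Veff - p$V_th))
  dV <- I / p$C_m
  dw <- if (p$variant_name == "aqif2") {
    if (Veff < p$V_b) (-state$w + p$a * (Veff - p$V_b)^3) / p$tau_w
    else -state$w / p$tau_w
  } else {
    (-state$w + p$a * (Veff - p$E_L)) / p$tau_w
  }
  c(V = dV, w = dw, g_ex = -state$g_ex / p$tau_ex,
    g_in = -state$g_in / p$tau_in)
}

#' Advance a neuron one Runge-Kutta step
#'
#' Classical 4th-order Runge-Kutta step of the coupled
#' `(V, w, g_ex, g_in)` system.  A step whose final potential reaches
#' `V_peak` is accepted as emitting a spike at the end of the step: `V` is
#' reset to `V_reset`, `w` is incremented by `b` and the refractory clock
#' is started.  During refractoriness `V` is held at `V_reset` while `w`
#' and the conductances keep evolving.
#'
#' @inheritParams neuron_derivatives
#' @param h Step size (ms), positive.
#' @param t Current time (ms); used only for the refractory bookkeeping.
#' @return The advanced [neuron_state()], with attribute `spike = TRUE`
#'   when a spike was emitted during the step.
#' @export
rk4_step <- function(state, params, h, t = 0) {
  stopifnot(h > 0)
  if (t < state$refractory_until) {
    held <- state
    held$V <- params$V_reset
    k1 <- neuron_derivatives(held, params)
    k2 <- neuron_derivatives(.advance(held, k1, h / 2, freezeV = TRUE), params)
    k3 <- neuron_derivatives(.advance(held, k2, h / 2, freezeV = TRUE), params)
    k4 <- neuron_derivatives(.advance(held, k3, h, freezeV = TRUE), params)
    out <- .advance(held, (k1 + 2 * k2 + 2 * k3 + k4) / 6, h, freezeV = TRUE)
    out$refractory_until <- state$refractory_until
    return(structure(out, spike = FALSE))
  }
  k1 <- neuron_derivatives(state, params)
  k2 <- neuron_derivatives(.advance(state, k1, h / 2), params)
  k3 <- neuron_derivatives(.advance(state, k2, h / 2), params)
  k4 <- neuron_derivatives(.advance(state, k3, h), params)
  out <- .advance(state, (k1 + 2 * k2 + 2 * k3 + k4) / 6, h)
  if (!is.finite(out$V) || !is.finite(out$w))
    stop("numerical divergence in rk4_step at t = ", t + h, " ms")
  spike <- FALSE
  if (out$V >= params$V_peak) {
    out$V <- params$V_reset
    out$w <- out$w + params$b
    out$refractory_until <- t + h + params$t_ref
    spike <- TRUE
  } else if (out$V < .v_floor) {
    out$V <- .v_floor
  }
  structure(out, spike = spike)
}

.advance <- function(state, k, h, freezeV = FALSE) {
  s <- state
  if (!freezeV) s$V <- state$V + h * k[["V"]]
  s$w <- state$w + h * k[["w"]]
  s$g_ex <- state$g_ex + h * k[["g_ex"]]
  s$g_in <- state$g_in + h * k[["g_in"]]
  s
}

#' Apply a presynaptic spike to a neuron
#'
#' Conductance-based exponential synapses respond to an afferent spike
#' with an instantaneous conductance jump equal to the synaptic weight;
#' simultaneous spikes superpose linearly.
#'
#' @inheritParams neuron_derivatives
#' @param weight Synaptic weight (nS), non-negative; the sign of the
#'   interaction is carried by the synapse type, not the weight.
#' @param sign `"E"` (excitatory, increments `g_ex`) or `"I"`
#'   (inhibitory, increments `g_in`).
#' @return The updated [neuron_state()].
#' @export
apply_input_spike <- function(state, weight, sign = c("E", "I")) {
  sign <- match.arg(sign)
  if (weight < 0) stop("synaptic weight must be non-negative")
  if (sign == "E") state$g_ex <- state$g_ex + weight
  else state$g_in <- state$g_in + weight
  state
}
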