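# The Simplified Model: the two beta oscillators (subthalamo-pallidal
# "STN loop" and striato-pallidal "STR loop") extracted from the Complete
# Model, with GPe-TI split into two halves and a coupling parameter
# epsilon scaling the inter-loop connection probabilities.

#' Simplified-Model parameter adaptations
#'
#' Loads the calibrated parameter set of the Simplified Model: external
#' drive adjustments of the real populations (which lose part of their
#' afferents relative to the Complete Model), drives of the auxiliary
#' compensation populations, and intensity scalings of the loop
#' connections.  The calibrated values ship with the package and are
#' produced by [calibrate_simplified()].
#'
#' @param path Path to a simplified-model YAML file.
#' @return A list with elements `targets`, `nu_ext`, `I_e`,
#'   `aux_nu_ext`, `loop_weight_scale` and `gpti_cross`.
#' @export
simplified_config <- function(path = system.file("extdata",
                                                 "simplified_model.yaml",
                                                 package = "bgbeta")) {
  yaml::read_yaml(path)
}

#' Build the Simplified Model
#'
#' The two oscillators identified by the ablation screen are assembled
#' into a dedicated network.  GPe-TI is split into two equal halves:
#' GPTI-A (reciprocally connected with STN, forming the STN loop) and
#' GPTI-B (receiving D2 and projecting to FSN, closing the
#' D2 -> GPe-TI -> FSN -> D2 striatal loop).  Loop-internal connections
#' keep the Complete-Model probabilities; inter-loop connections are
#' scaled by `epsilon` (`p = epsilon * p1`); auxiliary populations D2*,
#' STN*, GPTI* (half the size of their real counterparts, external drive
#' only, rate-matched) compensate the missing input with probability
#' `(1 - epsilon) * p1` (doubled for the halved-size D2* and STN*).  At
#' `epsilon = 0` the loops are fully independent; at `epsilon = 1` the
#' auxiliaries are disconnected and connectivity is realistic.
#'
#' @param epsilon Inter-loop coupling in `[0, 1]`.
#' @param D_d Dopamine-depletion factor applied to the D2 (and D2*)
#'   external rate.
#' @param n Population-size multiplier, see [scale_size()].
#' @param params Simplified-model parameter adaptations, see
#'   [simplified_config()].
#' @param config Complete-Model configuration (source of all shared
#'   parameters), see [bg_config()].
#' @return A [bg_network()].
#' @export
build_simplified_model <- function(epsilon, D_d = 1, n = 1,
                                   params = simplified_config(),
                                   config = bg_config()) {
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]")
  stopifnot(D_d > 0)
  cp <- config$populations
  half_gpti <- as.integer(cp$GPTI$size / 2)

  mk <- function(name, base, N, aux = FALSE) {
    pars <- neuron_params(population = base)
    if (!aux) {
      if (!is.null(params$nu_ext[[name]])) pars$nu_ext <- params$nu_ext[[name]]
      if (!is.null(params$I_e[[name]])) pars$I_e <- params$I_e[[name]]
    } else {
      pars$nu_ext <- params$aux_nu_ext[[name]]
      if (is.null(pars$nu_ext))
        stop("missing auxiliary drive for ", name,
             " in the simplified-model parameter set")
    }
    list(name = name, N = as.integer(N), params = pars,
         observer_size = as.integer(N), is_auxiliary = aux)
  }
  pops <- list(
    mk("D2", "D2", cp$D2$size),
    mk("FSN", "FSN", cp$FSN$size),
    mk("GPTIA", "GPTI", half_gpti),
    mk("GPTIB", "GPTI", half_gpti),
    mk("STN", "STN", cp$STN$size),
    mk("D2s", "D2", cp$D2$size / 2, aux = TRUE),
    mk("STNs", "STN", cp$STN$size / 2, aux = TRUE),
    mk("GPTIs", "GPTI", half_gpti, aux = TRUE))

  p1 <- function(s, t) {
    con <- config$connections
    con[con$source == s & con$target == t, , drop = FALSE]
  }
  wsA <- if (is.null(params$loop_weight_scale$A)) 1 else params$loop_weight_scale$A
  wsB <- if (is.null(params$loop_weight_scale$B)) 1 else params$loop_weight_scale$B
  row <- function(ref, source, target, p_factor, w_scale = 1) {
    data.frame(source = source, target = target, p = ref$p * p_factor,
               delay = ref$delay, type = ref$type,
               weight = ref$weight * w_scale)
  }
  eps <- epsilon
  con <- rbind(
    # STN loop (A), loop-internal at full probability
    row(p1("STN", "GPTI"), "STN", "GPTIA", 1, wsA),
    row(p1("GPTI", "STN"), "GPTIA", "STN", 1, wsA),
    # STR loop (B), loop-internal at full probability
    row(p1("D2", "GPTI"), "D2", "GPTIB", 1, wsB),
    row(p1("GPTI", "FSN"), "GPTIB", "FSN", 1, wsB),
    row(p1("FSN", "D2"), "FSN", "D2", 1, wsB),
    # self-inhibition within each population / half
    row(p1("D2", "D2"), "D2", "D2", 1),
    row(p1("FSN", "FSN"), "FSN", "FSN", 1),
    row(p1("GPTI", "GPTI"), "GPTIA", "GPTIA", 1),
    row(p1("GPTI", "GPTI"), "GPTIB", "GPTIB", 1),
    # inter-loop connections, scaled by epsilon
    row(p1("D2", "GPTI"), "D2", "GPTIA", eps),
    row(p1("STN", "GPTI"), "STN", "GPTIB", eps),
    row(p1("GPTI", "FSN"), "GPTIA", "FSN", eps),
    row(p1("GPTI", "STN"), "GPTIB", "STN", eps),
    # auxiliary compensation, scaled by (1 - epsilon); D2*/STN* are half
    # the source size, so their probabilities are doubled
    row(p1("D2", "GPTI"), "D2s", "GPTIA", 2 * (1 - eps)),
    row(p1("STN", "GPTI"), "STNs", "GPTIB", 2 * (1 - eps)),
    row(p1("GPTI", "FSN"), "GPTIs", "FSN", 1 - eps),
    row(p1("GPTI", "STN"), "GPTIs", "STN", 1 - eps))
  gpti_cross <- if (is.null(params$gpti_cross)) "epsilon" else params$gpti_cross
  if (gpti_cross != "none") {
    f <- if (gpti_cross == "epsilon") eps else 1
    con <- rbind(con,
                 row(p1("GPTI", "GPTI"), "GPTIA", "GPTIB", f),
                 row(p1("GPTI", "GPTI"), "GPTIB", "GPTIA", f))
    if (gpti_cross == "epsilon")
      # keep total pallidal self-inhibition epsilon-invariant
      con <- rbind(con,
                   row(p1("GPTI", "GPTI"), "GPTIs", "GPTIA", 1 - eps),
                   row(p1("GPTI", "GPTI"), "GPTIs", "GPTIB", 1 - eps))
  }
  con <- con[con$p > 0, ]
  net <- bg_network(pops, con)
  net <- apply_dopamine(net, D_d)
  if (n > 1) net <- scale_size(net, n)
  net
}

#' Calibrate the Simplified Model
#'
#' Re-derives the Simplified-Model parameter adaptations from scratch.
#' The populations of the Simplified Model lose part of their
#' Complete-Model afferents (D1 and GPe-TA are absent), so their
#' external drives must be re-tuned; the auxiliary populations need
#' drives that match the target rates; and the two loops' synaptic
#' intensities are scaled so that each isolated loop expresses a robust
#' beta resonance at its natural frequency (~19 Hz for the
#' subthalamo-pallidal loop, ~13 Hz for the striato-pallidal loop, see
#' the methods vignette for how the scalings were selected).
#'
#' The procedure: (1) bisection-calibrate the external rate of each
#' auxiliary population (externally driven, so independent of the rest
#' of the network) to the target rates; (2) iterate damped
#' multiplicative updates of the real populations' external rates in
#' the assembled `epsilon = 0` network until all mean rates match the
#' targets.
#'
#' @param targets Named target rates (Hz) for D2, FSN, GPTI (both
#'   halves) and STN.
#' @param loop_weight_scale List with elements `A` and `B`: intensity
#'   multipliers of the loop connections.
#' @param max_iter Maximum drive-update iterations.
#' @param rel_tol Relative rate tolerance for convergence.
#' @param duration Per-iteration probe duration (ms).
#' @param seed Base seed of the probe simulations.
#' @param path Optional output path; when given, the calibrated
#'   parameter set is written as YAML (the format of
#'   [simplified_config()]).
#' @return The calibrated parameter list (invisibly when `path` is
#'   given).
#' @export
calibrate_simplified <- function(targets = c(D2 = 1.5, FSN = 15,
                                             GPTI = 50, STN = 16),
                                 loop_weight_scale = list(A = 1.4, B = 2.0),
                                 max_iter = 12, rel_tol = 0.06,
                                 duration = 3000, seed = 1, path = NULL) {
  aux <- list()
  for (x in list(c("D2s", "D2"), c("STNs", "STN"), c("GPTIs", "GPTI"))) {
    cal <- calibrate_auxiliary(neuron_params(population = x[2]),
                               target_rate = unname(targets[x[2]]),
                               tolerance = 0.05 * targets[x[2]],
                               what = "nu_ext", seed = seed)
    aux[[x[1]]] <- cal$value
  }
  tg <- c(D2 = unname(targets["D2"]), FSN = unname(targets["FSN"]),
          GPTIA = unname(targets["GPTI"]), GPTIB = unname(targets["GPTI"]),
          STN = unname(targets["STN"]))
  prm <- list(targets = as.list(targets), I_e = list(),
              aux_nu_ext = aux, loop_weight_scale = loop_weight_scale,
              gpti_cross = "epsilon")
  cfg <- bg_config()
  nu <- c(D2 = cfg$populations$D2$nu_ext, FSN = cfg$populations$FSN$nu_ext,
          GPTIA = cfg$populations$GPTI$nu_ext,
          GPTIB = cfg$populations$GPTI$nu_ext,
          STN = cfg$populations$STN$nu_ext)
  best <- nu; best_err <- Inf
  for (it in seq_len(max_iter)) {
    prm$nu_ext <- as.list(nu)
    net <- build_simplified_model(0, params = prm)
    r <- run_simulation(net, duration = duration, warmup = 500,
                        seed = seed + it)
    rates <- r$rates[names(tg)]
    err <- max(abs(rates - tg) / tg)
    if (err < best_err) { best <- nu; best_err <- err }
    if (err < rel_tol) break
    fac <- pmin(pmax((tg / pmax(rates, 0.02))^0.25, 0.9), 1.11)
    nu <- nu * fac
  }
  prm$nu_ext <- as.list(round(best, 4))
  prm$aux_nu_ext <- lapply(prm$aux_nu_ext, round, 4)
  if (!is.null(path)) {
    yaml::write_yaml(prm, path)
    return(invisible(prm))
  }
  prm
}
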