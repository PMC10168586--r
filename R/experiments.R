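# Orchestration of the numbered in-silico experiments: ablation screen,
# coupling/dopamine/size sweeps, optogenetic validation, burst analysis.

.real_pops <- function(network) {
  keep <- !vapply(network$populations, function(p) isTRUE(p$is_auxiliary),
                  logical(1))
  names(network$populations)[keep]
}

.spec_of <- function(raster, population) {
  series <- bin_rates(raster, population)
  nseg <- min(2000, length(series$rate)) # short runs: single segment
  welch_psd(series, nperseg = nseg, noverlap = nseg %/% 2)
}

#' Connection-ablation screen for beta generators
#'
#' Quantifies the relevance of every non-self internal connection
#' `S -> T` for the generation of beta oscillations.  For each
#' connection, a rate-matched auxiliary copy `S*` of the source
#' population (same model and size, external drive only, constant
#' current calibrated so its mean rate matches `S`) replaces the `S -> T`
#' pathway with `S* -> T` at the same probability and weight, severing
#' the feedback carried by the connection while preserving the mean
#' input to `T`.  The relevance ratio is
#' `R(S->T) = sum_p MeanPSD_p(ablated) / sum_p MeanPSD_p(intact)`
#' (band-averaged beta PSD summed over all populations); connections
#' with `R` below the threshold 1/3 are flagged as beta generators.
#' Self-inhibition pathways are excluded (they oscillate at much higher
#' frequencies).
#'
#' @param D_d Dopamine-depletion factor of the screened model.
#' @param duration,warmup Simulation length and warm-up (ms).
#' @param seeds Master seed(s); with several seeds `R` is seed-averaged
#'   and connections whose mean lies within one across-seed SD of the
#'   threshold are flagged as borderline rather than silently
#'   classified.
#' @param threshold Flagging threshold for `R` (default 1/3).
#' @param calibration_tol Rate tolerance (Hz) of the auxiliary
#'   calibration.
#' @param config Complete-Model configuration.
#' @return Data frame with one row per screened connection: `source`,
#'   `target`, `R` (seed mean), `R_sd`, `selected` (`R < threshold`),
#'   `borderline`, `aux_I_e` and `aux_rate` (calibrated auxiliary
#'   current and achieved rate), plus attribute `baseline` (the
#'   intact-model summed beta PSD per seed).
#' @export
ablation_screen <- function(D_d = 1, duration = 5000, warmup = 500,
                            seeds = 1, threshold = 1 / 3,
                            calibration_tol = 1, config = bg_config()) {
  base_net <- build_complete_model(D_d = D_d, config = config)
  pops <- .real_pops(base_net)
  total_power <- function(r)
    sum(vapply(pops, function(p) mean_beta_psd(.spec_of(r, p)), numeric(1)))
  base <- lapply(seeds, function(sd)
    run_simulation(base_net, duration = duration, warmup = warmup, seed = sd))
  base_power <- vapply(base, total_power, numeric(1))
  base_rates <- rowMeans(vapply(base, `[[`, base[[1]]$rates, "rates"))
  con <- base_net$connections
  screened <- con[con$source != con$target, ]
  # one auxiliary calibration per source population (probe rate is
  # independent of population size: auxiliaries have no recurrent input)
  aux_cal <- list()
  for (s in unique(screened$source)) {
    aux_cal[[s]] <- calibrate_auxiliary(
      base_net$populations[[s]]$params,
      target_rate = unname(base_rates[s]), tolerance = calibration_tol,
      what = "I_e", N = min(256L, base_net$populations[[s]]$N),
      duration = max(1500, duration / 3), seed = seeds[1])
  }
  rows <- lapply(seq_len(nrow(screened)), function(i) {
    s <- screened$source[i]; t <- screened$target[i]
    net <- base_net
    aux_name <- paste0(s, "_star")
    aux <- base_net$populations[[s]]
    aux$name <- aux_name
    aux$params <- aux_cal[[s]]$params
    aux$is_auxiliary <- TRUE
    net$populations[[aux_name]] <- aux
    ci <- with(net$connections, which(source == s & target == t))
    net$connections$p[ci] <- 0
    newrow <- screened[i, ]
    newrow$source <- aux_name
    net$connections <- rbind(net$connections, newrow)
    net$connections <- net$connections[net$connections$p > 0, ]
    Rs <- vapply(seq_along(seeds), function(k) {
      r <- run_simulation(net, duration = duration, warmup = warmup,
                          seed = seeds[k])
      total_power(r) / base_power[k]
    }, numeric(1))
    data.frame(source = s, target = t, R = mean(Rs),
               R_sd = if (length(seeds) > 1) stats::sd(Rs) else NA_real_,
               aux_I_e = aux_cal[[s]]$value, aux_rate = aux_cal[[s]]$achieved)
  })
  out <- do.call(rbind, rows)
  out$selected <- out$R < threshold
  out$borderline <- !is.na(out$R_sd) & abs(out$R - threshold) < out$R_sd
  attr(out, "baseline") <- base_power
  out[order(out$R), ]
}

#' Parameter sweep with spectral read-outs
#'
#' Runs the model across a grid of one experimental knob and reports,
#' per value, the mean rates and the beta-band statistics (mean
#' frequency and corrected beta PSD) of the STN and D2 populations,
#' averaged over seeds with across-seed SDs.
#'
#' @param knob One of `"D_d"`, `"epsilon"`, `"n"`, `"kappa"`.
#' @param values Numeric grid of knob values.
#' @param model `"complete"` or `"simplified"` (`epsilon` forces
#'   simplified; `kappa` forces complete).
#' @param D_d,epsilon Fixed values of the knobs not swept.
#' @param seeds Integer vector of master seeds (the analysis convention
#'   is 4 seeds per condition).
#' @param duration,warmup Simulation length and warm-up (ms).
#' @param populations Populations to report (default STN and D2, the
#'   read-outs of the two loops).
#' @return Data frame with one row per knob value: per-population mean
#'   rate, `mean_f` and `psd_dag` columns (`_sd` suffixed across-seed
#'   SDs).
#' @export
bg_sweep <- function(knob = c("D_d", "epsilon", "n", "kappa"), values,
                     model = c("complete", "simplified"),
                     D_d = 1, epsilon = 0.75, seeds = 1:4,
                     duration = 10000, warmup = 500,
                     populations = c("STN", "D2")) {
  knob <- match.arg(knob)
  model <- match.arg(model)
  if (knob == "epsilon") model <- "simplified"
  if (knob == "kappa") model <- "complete"
  one <- function(value, seed) {
    net <- switch(knob,
      D_d = if (model == "complete") build_complete_model(D_d = value)
            else build_simplified_model(epsilon, D_d = value),
      epsilon = build_simplified_model(value, D_d = D_d),
      n = if (model == "complete") build_complete_model(D_d = D_d, n = value)
          else build_simplified_model(epsilon, D_d = D_d, n = value),
      kappa = build_complete_model(D_d = D_d,
        opto = opto_perturbation("stn_modulation", kappa = value)))
    r <- run_simulation(net, duration = duration, warmup = warmup,
                        seed = seed)
    unlist(lapply(populations, function(p) {
      s <- .spec_of(r, p)
      c(rate = unname(r$rates[p]), mean_f = mean_frequency(s),
        psd_dag = corrected_beta_psd(s))
    }))
  }
  rows <- lapply(values, function(v) {
    per_seed <- vapply(seeds, function(sd) one(v, sd),
                       one_template(populations))
    m <- rowMeans(per_seed)
    s <- apply(per_seed, 1, stats::sd)
    names(m) <- paste0(rep(populations, each = 3),
                       c("_rate", "_mean_f", "_psd_dag"))
    names(s) <- paste0(names(m), "_sd")
    c(stats::setNames(v, knob), m, s)
  })
  as.data.frame(do.call(rbind, rows))
}

one_template <- function(populations)
  numeric(3 * length(populations))

#' Population-size limit analysis
#'
#' Repeats a condition at increasing population sizes `n` (with
#' in-degree-preserving connectivity rescaling and fixed reference-size
#' observer subsamples) to test whether beta activity survives the
#' large-population limit: corrected beta power decays towards the noise
#' floor in unsynchronised regimes and is preserved in synchronised
#' ones.
#'
#' @inheritParams bg_sweep
#' @param n_values Size multipliers (reference grid 1, 2, 4, 8).
#' @return A [bg_sweep()] data frame over `n`.
#' @export
size_limit_analysis <- function(n_values = c(1, 2, 4, 8),
                                model = c("simplified", "complete"),
                                D_d = 1, epsilon = 0, seeds = 1:2,
                                duration = 5000, warmup = 500) {
  model <- match.arg(model)
  bg_sweep("n", n_values, model = model, D_d = D_d, epsilon = epsilon,
           seeds = seeds, duration = duration, warmup = warmup)
}

#' Optogenetic validation battery
#'
#' Reproduces the in-silico analogue of the optogenetic experiments on
#' the pathological baseline (Complete Model, `D_d = 1.03`): motor
#' cortex inhibition, a `kappa` sweep of STN drive, and GPe
#' inhibition.  Reports OFF/ON STN rates, rate changes, corrected STN
#' beta power per condition, and the low-dopamine reference beta band
#' against which suppression is judged.
#'
#' @param D_d Pathological baseline depletion factor.
#' @param D_d_low Low-depletion reference level for the healthy beta
#'   band.
#' @param kappa_values STN drive factors for the modulation sweep.
#' @param seeds Master seeds (results averaged).
#' @param duration,warmup Simulation length and warm-up (ms).
#' @return List with data frame `conditions` (rows: off, cortex_inhibition,
#'   gpe_inhibition, stn_modulation at each kappa; columns: STN/GPe rates,
#'   `stn_rate_change_pct`, `stn_psd_dag`) and `low_dd_psd_dag` (reference
#'   band level).
#' @export
opto_battery <- function(D_d = 1.03, D_d_low = 0.85,
                         kappa_values = c(0.65, 1.0, 1.35, 1.7),
                         seeds = 1:2, duration = 10000, warmup = 500) {
  run_cond <- function(opto) {
    per_seed <- vapply(seeds, function(sd) {
      net <- build_complete_model(D_d = D_d, opto = opto, opto_seed = sd)
      r <- run_simulation(net, duration = duration, warmup = warmup,
                          seed = sd)
      c(stn = unname(r$rates["STN"]), gpti = unname(r$rates["GPTI"]),
        gpta = unname(r$rates["GPTA"]),
        dag = corrected_beta_psd(.spec_of(r, "STN")))
    }, numeric(4))
    rowMeans(per_seed)
  }
  off <- run_cond(NULL)
  conds <- list(off = off,
                cortex_inhibition = run_cond(opto_perturbation("cortex_inhibition")),
                gpe_inhibition = run_cond(opto_perturbation("gpe_inhibition")))
  for (k in kappa_values)
    conds[[sprintf("stn_modulation_kappa_%g", k)]] <-
      run_cond(opto_perturbation("stn_modulation", kappa = k))
  low <- vapply(seeds, function(sd) {
    r <- run_simulation(build_complete_model(D_d = D_d_low),
                        duration = duration, warmup = warmup, seed = sd)
    corrected_beta_psd(.spec_of(r, "STN"))
  }, numeric(1))
  tab <- do.call(rbind, lapply(conds, function(x) as.data.frame(as.list(x))))
  tab$condition <- names(conds)
  tab$stn_rate_change_pct <- 100 * (tab$stn - off[["stn"]]) / off[["stn"]]
  rownames(tab) <- NULL
  list(conditions = tab[, c("condition", "stn", "gpti", "gpta",
                            "stn_rate_change_pct", "dag")],
       low_dd_psd_dag = mean(low))
}

#' Beta-burst analysis
#'
#' Characterises the phasic structure of beta activity at a given
#' dopamine-depletion level: sliding-window spectra of the STN activity,
#' the instantaneous frequency difference
#' `delta_f(t) = f_STN(t) - f_D2(t)` between the two loop read-outs, the
#' instantaneous beta power with its median, and the sample skewness of
#' the windowed beta-power distribution (right-skewed = transient
#' bursting; symmetric = sustained oscillation).  Windows are short
#' enough (default 500 ms, stepped by 125 ms) to resolve sub-second
#' bursts.
#'
#' @param D_d Dopamine-depletion factor.
#' @param seeds Master seeds; windows are pooled across seeds for the
#'   skewness.
#' @param duration,warmup Simulation length and warm-up (ms).
#' @param window,step Sliding-window length and step (ms).
#' @return List with `windows` (data frame: seed, t_mid, delta_f,
#'   beta_psd), `median_delta_f`, `median_beta_psd`, `skewness`, and
#'   `anticorrelation` (fraction of windows on the below-median-delta_f /
#'   above-median-power diagonal; > 0.5 indicates that synchronous
#'   epochs carry the beta bursts).
#' @export
burst_analysis <- function(D_d = 0.90, seeds = 1:2, duration = 10000,
                           warmup = 500, window = 500, step = 125) {
  rows <- lapply(seeds, function(sd) {
    r <- run_simulation(build_complete_model(D_d = D_d), duration = duration,
                        warmup = warmup, seed = sd)
    stn <- time_resolved(bin_rates(r, "STN"), window = window, step = step)
    d2 <- time_resolved(bin_rates(r, "D2"), window = window, step = step)
    data.frame(seed = sd, t_mid = stn$t_mid,
               delta_f = stn$mean_f - d2$mean_f, beta_psd = stn$beta_psd)
  })
  w <- do.call(rbind, rows)
  med_df <- stats::median(w$delta_f, na.rm = TRUE)
  med_bp <- stats::median(w$beta_psd, na.rm = TRUE)
  agree <- (w$delta_f < med_df & w$beta_psd > med_bp) |
           (w$delta_f > med_df & w$beta_psd < med_bp)
  list(windows = w, median_delta_f = med_df, median_beta_psd = med_bp,
       skewness = beta_power_skewness(w$beta_psd),
       anticorrelation = mean(agree, na.rm = TRUE))
}
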