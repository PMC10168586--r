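#' Assemble a spiking network
#'
#' A network couples named neuron populations through random (Bernoulli)
#' connections with fixed axonal delays.  Every neuron additionally
#' receives an independent Poisson external drive at its population's
#' `nu_ext`, with a per-neuron synaptic weight drawn once at build time
#' uniformly in `ext_weight +/- dev_ext_weight`.
#'
#' @param populations List of population specifications; each element is a
#'   list with fields `name`, `N` (size), `params` (a [neuron_params()]),
#'   and optionally `is_auxiliary` (logical), `observer_size` (number of
#'   neurons over which rate series and spectra are computed; defaults to
#'   `N`) and `nu_ext_vec` (per-neuron external-rate override, kHz).
#' @param connections Data frame with columns `source`, `target`, `p`
#'   (connection probability per ordered neuron pair), `delay` (ms),
#'   `type` (`"E"`/`"I"`) and `weight` (nS).  External drives are part of
#'   the population records, not of this table.
#' @return An object of class `bg_network`.
#' @export
bg_network <- function(populations, connections) {
  nm <- vapply(populations, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("population names must be unique")
  for (p in populations) {
    stopifnot(p$N >= 1)
    if (!inherits(p$params, "neuron_params"))
      stop("population '", p$name, "': params must be a neuron_params object")
  }
  connections <- as.data.frame(connections)
  bad <- setdiff(unique(c(connections$source, connections$target)), nm)
  if (length(bad))
    stop("connection refers to unknown population(s): ",
         paste(bad, collapse = ", "))
  stopifnot(all(connections$p >= 0 & connections$p <= 1),
            all(connections$delay >= 0), all(connections$weight >= 0),
            all(connections$type %in% c("E", "I")))
  names(populations) <- nm
  structure(list(populations = populations, connections = connections),
            class = "bg_network")
}

#' @export
print.bg_network <- function(x, ...) {
  sizes <- vapply(x$populations, `[[`, numeric(1), "N")
  cat("<bg_network> ", length(sizes), " populations, ",
      sum(sizes), " neurons, ", nrow(x$connections), " pathways\n", sep = "")
  invisible(x)
}

#' Sample the random edges of one connection
#'
#' Draws one independent Bernoulli(`p`) trial per ordered (source, target)
#' neuron pair.  For a population connected to itself, self-connections
#' (autapses) are excluded and multiple edges between the same ordered
#' pair cannot occur.
#'
#' @param p Connection probability in `[0, 1]`.
#' @param N_source,N_target Population sizes.
#' @param self Logical; `TRUE` when source and target are the same
#'   population (excludes the diagonal).
#' @param seed Integer seed for the dedicated connectivity stream.
#' @return Data frame with 1-based columns `source`, `target`.
#' @export
build_connections <- function(p, N_source, N_target, self = FALSE, seed = 1) {
  stopifnot(p >= 0, p <= 1, N_source >= 1, N_target >= 1)
  e <- cpp_build_edges(N_source, N_target, p, self, seed, 0)
  data.frame(source = e$source + 1L, target = e$target + 1L)
}

#' Sample Poisson external-drive spike counts
#'
#' Number of external spikes arriving at each of `n` independently driven
#' neurons within one integration step.
#'
#' @param rate Drive rate (kHz, i.e. expected spikes per ms).
#' @param h Step size (ms).
#' @param n Number of neurons.
#' @return Integer vector of length `n` of Poisson(`rate * h`) counts.
#' @export
sample_poisson_drive <- function(rate, h = 0.1, n = 1) {
  stopifnot(rate >= 0, h > 0)
  stats::rpois(n, rate * h)
}

#' Run a network simulation
#'
#' Integrates all neurons with the classical 4th-order Runge-Kutta scheme
#' at a fixed step, delivering each spike to its postsynaptic conductances
#' after the connection delay (delays are rounded to the nearest multiple
#' of `h`).  The initial `warmup` interval is discarded from the returned
#' raster.  Results are fully determined by `seed`: the master seed spawns
#' independent streams per connection (wiring), per population (initial
#' conditions, external-weight jitter, Poisson drive) so that the run is
#' reproducible bit-for-bit.
#'
#' @param network A [bg_network()].
#' @param duration Analysed duration after warm-up (ms).
#' @param warmup Warm-up interval discarded from the output (ms).
#' @param h Integration step (ms).
#' @param seed Integer master seed.
#' @param record_v Optional character vector of population names whose
#'   first neuron's voltage trace is recorded (diagnostics/testing).
#' @return An object of class `bg_raster`: list with `spikes` (data frame
#'   `time` (ms, in `[0, duration]`, sorted), `population`, `neuron`),
#'   `rates` (named mean rates, Hz), `edge_count` (realised edges per
#'   pathway), `observers` (named list of observed neuron indices),
#'   `duration`, `warmup`, `h`, `seed` and optionally `v_trace`.
#' @export
run_simulation <- function(network, duration = 10000, warmup = 500, h = 0.1,
                           seed = 1, record_v = NULL) {
  stopifnot(inherits(network, "bg_network"), duration > 0, warmup >= 0)
  nm <- names(network$populations)
  pops <- lapply(network$populations, function(p) {
    list(name = p$name, N = as.integer(p$N), params = unclass(p$params),
         nu_ext_vec = p$nu_ext_vec)
  })
  con <- network$connections
  conns <- lapply(seq_len(nrow(con)), function(i) {
    list(source = match(con$source[i], nm) - 1L,
         target = match(con$target[i], nm) - 1L,
         p = con$p[i], delay = con$delay[i],
         sign = if (con$type[i] == "E") 1L else -1L,
         weight = con$weight[i])
  })
  rec <- if (is.null(record_v)) integer(0) else match(record_v, nm) - 1L
  if (anyNA(rec)) stop("record_v names unknown population")
  out <- cpp_simulate(pops, conns, duration, warmup, h, seed, rec)
  ord <- order(out$time, out$population, out$neuron)
  spikes <- data.frame(time = out$time[ord],
                       population = nm[out$population[ord]],
                       neuron = out$neuron[ord])
  observers <- lapply(nm, function(n) {
    p <- network$populations[[n]]
    os <- if (is.null(p$observer_size)) p$N else min(p$observer_size, p$N)
    if (os >= p$N) seq_len(p$N) else .subsample(p$N, os, seed, match(n, nm))
  })
  names(observers) <- nm
  vt <- NULL
  if (length(rec)) {
    vt <- out$v_trace
    names(vt) <- record_v
  }
  structure(list(spikes = spikes, rates = out$rates,
                 edge_count = stats::setNames(out$edge_count,
                   paste(con$source, con$target, sep = "->")),
                 observers = observers, duration = duration, warmup = warmup,
                 h = h, seed = seed, v_trace = vt),
            class = "bg_raster")
}

# deterministic subsample of `k` of `n` neurons, independent of R's RNG state
.subsample <- function(n, k, seed, stream) {
  e <- cpp_build_edges(1L, n, min(1, (k * 4 + 50) / n), FALSE,
                       seed + 10000, stream)
  ids <- unique(e$target + 1L)
  while (length(ids) < k) { # extremely unlikely top-up
    stream <- stream + 1000
    e <- cpp_build_edges(1L, n, 0.5, FALSE, seed + 10000, stream)
    ids <- unique(c(ids, e$target + 1L))
  }
  sort(ids[seq_len(k)])
}

#' @export
print.bg_raster <- function(x, ...) {
  cat("<bg_raster> ", nrow(x$spikes), " spikes over ", x$duration,
      " ms (warm-up ", x$warmup, " ms discarded)\n", sep = "")
  r <- round(x$rates, 2)
  cat("mean rates [Hz]: ", paste(names(r), r, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Serialise a spike raster to TSV
#'
#' @param raster A `bg_raster`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  utils::write.table(raster$spikes[, c("time", "population", "neuron")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
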