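# Shared helpers: R-side reference integration and small test networks.

# integrate a single neuron with the R reference stepper; returns the
# voltage trace sampled at every step (t = 0, h, 2h, ...)
reference_trajectory <- function(params, state, h, n_steps) {
  V <- numeric(n_steps + 1)
  V[1] <- state$V
  t <- 0
  for (i in seq_len(n_steps)) {
    state <- rk4_step(state, params, h, t = t)
    t <- t + h
    V[i + 1] <- state$V
  }
  V
}

# a deterministic single-neuron network: E_L == V_reset so the random
# initial condition collapses to a point, and no external drive
single_neuron_net <- function(params) {
  bg_network(
    list(list(name = "solo", N = 1L, params = params)),
    data.frame(source = character(0), target = character(0), p = numeric(0),
               delay = numeric(0), type = character(0), weight = numeric(0)))
}

# small recurrent network for determinism/stationarity checks
mini_net <- function() {
  exc <- neuron_params(population = "STN", nu_ext = 0.4)
  inh <- neuron_params(population = "GPTI", nu_ext = 1.2)
  bg_network(
    list(list(name = "E", N = 100L, params = exc),
         list(name = "I", N = 100L, params = inh)),
    data.frame(source = c("E", "I", "I"), target = c("I", "E", "I"),
               p = c(0.1, 0.1, 0.05), delay = c(2, 1, 1),
               type = c("E", "I", "I"), weight = c(0.4, 0.1, 1.2)))
}

# manually assembled flat spectrum on a given grid
flat_spectrum <- function(level = 1, freq = seq(0, 500, by = 0.5)) {
  structure(list(freq = freq, psd = rep(level, length(freq)),
                 n_segments = 1, nu0 = NULL, N = NULL),
            class = "bg_spectrum")
}
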