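test_that("model derivatives match their closed forms", {
  # quadratic term vanishes at V = E_L
  aq <- neuron_params(population = "D2", I_e = 0, nu_ext = 0)
  d <- neuron_derivatives(neuron_state(V = aq$E_L), aq)
  expect_equal(unname(d["V"]), 0)

  # aeif with the subthalamic parameter set, at rest with no synapses
  stn <- neuron_params(population = "STN")
  d <- neuron_derivatives(neuron_state(V = stn$E_L), stn)
  expected <- (stn$g_L * stn$Delta_T *
                 exp((stn$E_L - stn$V_th) / stn$Delta_T) + stn$I_e) / stn$C_m
  expect_equal(unname(d["V"]), expected, tolerance = 1e-12)

  # aqif2 adaptation: pure decay above the pivot, cubic below
  fsn <- neuron_params(population = "FSN")
  w0 <- 13
  d_hi <- neuron_derivatives(neuron_state(V = fsn$V_b + 5, w = w0), fsn)
  expect_equal(unname(d_hi["w"]), -w0 / fsn$tau_w)
  d_lo <- neuron_derivatives(neuron_state(V = fsn$V_b - 10, w = w0), fsn)
  expect_equal(unname(d_lo["w"]),
               (-w0 + fsn$a * (-10)^3) / fsn$tau_w)

  # conductances decay exponentially towards zero
  d <- neuron_derivatives(neuron_state(V = -70, g_ex = 3, g_in = 2), stn)
  expect_equal(unname(d["g_ex"]), -3 / stn$tau_ex)
  expect_equal(unname(d["g_in"]), -2 / stn$tau_in)
})

test_that("missing variant-specific parameters are rejected", {
  expect_error(neuron_params(variant = "aeif", C_m = 100, E_L = -70,
                             E_ex = 0, E_in = -80, tau_ex = 5, tau_in = 5,
                             V_th = -50, I_e = 0, t_ref = 0, V_reset = -60,
                             a = 0, b = 10, tau_w = 100, V_peak = 0),
               "Delta_T")
  expect_error(neuron_params(population = "STN", tau_ex = -1))
})

test_that("conductance decay over many RK4 steps matches the analytic exponential", {
  p <- neuron_params(population = "D1", I_e = 0, nu_ext = 0) # tau_ex = 12 ms
  s <- neuron_state(V = p$E_L, g_ex = 1)
  for (i in 1:120) s <- rk4_step(s, p, h = 0.1)
  expect_equal(s$g_ex, exp(-1), tolerance = 1e-6)
  expect_gte(s$g_ex, 0)
})

test_that("the reset contract is exact: V -> V_reset and w += b", {
  p <- neuron_params(population = "GPTI", I_e = 600, nu_ext = 0)
  s <- neuron_state(V = p$E_L, w = 5)
  spiked <- FALSE
  for (i in 1:5000) {
    w_before <- s$w
    s <- rk4_step(s, p, h = 0.1, t = (i - 1) * 0.1)
    if (isTRUE(attr(s, "spike"))) {
      expect_identical(s$V, p$V_reset)
      # Delta w = b on top of the within-step continuous update
      k <- neuron_derivatives(neuron_state(V = p$V_reset, w = w_before), p)
      expect_lt(abs(s$w - w_before - p$b), abs(k[["w"]] * 0.1) + 1)
      spiked <- TRUE
      break
    }
  }
  expect_true(spiked)
})

test_that("RK4 exhibits ~4th-order convergence on a smooth trajectory", {
  p <- neuron_params(population = "STN", I_e = 0, nu_ext = 0)
  make_state <- function() neuron_state(V = p$E_L + 4, w = 30, g_ex = 2,
                                        g_in = 1)
  t_end <- 20
  v_at <- function(h) {
    s <- make_state()
    for (i in seq_len(round(t_end / h))) s <- rk4_step(s, p, h)
    s$V
  }
  ref <- v_at(0.0125)
  hs <- c(0.4, 0.2, 0.1)
  errs <- abs(vapply(hs, v_at, numeric(1)) - ref)
  slope <- stats::coef(stats::lm(log(errs) ~ log(hs)))[2]
  expect_gt(slope, 3)
  expect_lt(slope, 5)
})

test_that("refractoriness holds V at reset and suppresses spiking", {
  p <- neuron_params(population = "GPTI", I_e = 600, nu_ext = 0, t_ref = 3)
  s <- neuron_state(V = p$E_L)
  t <- 0; spike_times <- numeric(0)
  for (i in 1:20000) {
    s <- rk4_step(s, p, h = 0.1, t = t)
    t <- t + 0.1
    if (isTRUE(attr(s, "spike"))) spike_times <- c(spike_times, t)
  }
  expect_gt(length(spike_times), 2)
  expect_true(all(diff(spike_times) > p$t_ref))
  # with t_ref = 0 (the network-wide setting) the ISI can be arbitrary
  p0 <- neuron_params(population = "GPTI", I_e = 600, nu_ext = 0)
  expect_identical(p0$t_ref, 0)
})

test_that("input spikes increment conductances linearly", {
  s <- neuron_state(V = -70)
  s <- apply_input_spike(s, 1.28, "I") # D2 -> GPe-TI synaptic weight
  expect_equal(s$g_in, 1.28)
  expect_equal(s$g_ex, 0)
  s0 <- apply_input_spike(s, 0, "E")
  expect_equal(s0[c("g_ex", "g_in")], s[c("g_ex", "g_in")])
  s2 <- apply_input_spike(apply_input_spike(s, 0.3, "E"), 0.7, "E")
  expect_equal(s2$g_ex, 1.0)
  expect_error(apply_input_spike(s, -0.1, "E"), "non-negative")
})

test_that("the compiled core reproduces the R reference trajectory", {
  # E_L == V_reset makes the random initial condition degenerate, so the
  # two integrators start from the same state
  for (pop in c("STN", "D2", "FSN")) {
    p <- neuron_params(population = pop, nu_ext = 0, dev_ext_weight = 0)
    p$V_reset <- p$E_L
    p$I_e <- switch(pop, STN = 60, D2 = 700, FSN = 620) # above rheobase
    net <- single_neuron_net(p)
    r <- run_simulation(net, duration = 100, warmup = 0, h = 0.1, seed = 1,
                        record_v = "solo")
    ref <- reference_trajectory(p, neuron_state(V = p$E_L), 0.1, 1000)
    expect_lt(max(abs(r$v_trace[["solo"]] - ref)), 1e-5)
    expect_gt(nrow(r$spikes), 0) # the trajectory includes resets
  }
})
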