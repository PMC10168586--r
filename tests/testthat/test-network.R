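test_that("Bernoulli wiring has the right edge statistics", {
  expect_equal(nrow(build_connections(0, 50, 60)), 0)
  # p = 1 external-style rows: every ordered pair connected
  e <- build_connections(1, 3, 4)
  expect_equal(nrow(e), 12)
  # self-connected population: no autapses, single edge per ordered pair
  e <- build_connections(1, 5, 5, self = TRUE)
  expect_equal(nrow(e), 20)
  expect_true(all(e$source != e$target))
  expect_false(any(duplicated(e)))
  # subthalamo-pallidal pathway: count within 4 sigma of Binomial(N_s*N_t, p)
  p <- 0.0735; ns <- 408; nt <- 780
  e <- build_connections(p, ns, nt, seed = 7)
  mu <- p * ns * nt
  sdev <- sqrt(ns * nt * p * (1 - p))
  expect_lt(abs(nrow(e) - mu), 4 * sdev)
  # deterministic given the seed
  expect_identical(e, build_connections(p, ns, nt, seed = 7))
})

test_that("Poisson drive counts have the configured mean", {
  expect_identical(sample_poisson_drive(0, 0.1, 10), rep(0L, 10))
  set.seed(11)
  n <- 1e6
  counts <- sample_poisson_drive(1.083, 0.1, n) # the D2 drive at h = 0.1 ms
  m <- 1.083 * 0.1
  expect_lt(abs(mean(counts) - m), 3 * sqrt(m / n))
})

test_that("spikes arrive exactly after the connection delay", {
  src <- neuron_params(population = "GPTI", I_e = 600, nu_ext = 0,
                       dev_ext_weight = 0)
  src$V_reset <- src$E_L
  tgt <- neuron_params(population = "D2", I_e = 0, nu_ext = 0,
                       dev_ext_weight = 0)
  tgt$V_reset <- tgt$E_L # resting fixed point: V stays at E_L until input
  net <- bg_network(
    list(list(name = "A", N = 1L, params = src),
         list(name = "B", N = 1L, params = tgt)),
    data.frame(source = "A", target = "B", p = 1, delay = 3, type = "E",
               weight = 5))
  r <- run_simulation(net, duration = 200, warmup = 0, h = 0.1, seed = 3,
                      record_v = "B")
  t1 <- min(r$spikes$time[r$spikes$population == "A"])
  vb <- r$v_trace[["B"]]
  dev_idx <- which(abs(vb - tgt$E_L) > 1e-9)
  # trace index i corresponds to time (i-1)*h; first deviation one step
  # after the arrival at t1 + 3 ms, never earlier
  first_dev_t <- (min(dev_idx) - 1) * 0.1
  expect_gte(first_dev_t, t1 + 3)
  expect_lte(first_dev_t, t1 + 3 + 0.1 + 1e-9)
})

test_that("identical seeds give identical rasters, different seeds differ", {
  net <- mini_net()
  r1 <- run_simulation(net, duration = 1000, warmup = 200, seed = 5)
  r2 <- run_simulation(net, duration = 1000, warmup = 200, seed = 5)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$edge_count, r2$edge_count)
  r3 <- run_simulation(net, duration = 1000, warmup = 200, seed = 6)
  expect_false(identical(r1$spikes, r3$spikes))
})

test_that("rates are stationary after warm-up", {
  r <- run_simulation(mini_net(), duration = 4000, warmup = 500, seed = 2)
  for (p in c("E", "I")) {
    s <- bin_rates(r, p)
    half <- length(s$rate) / 2
    r1 <- mean(s$rate[1:half]); r2 <- mean(s$rate[(half + 1):(2 * half)])
    expect_lt(abs(r1 - r2) / max(r1, r2, 1), 0.2)
  }
})

test_that("raster output respects the documented contract", {
  r <- run_simulation(mini_net(), duration = 1000, warmup = 200, seed = 5)
  expect_true(all(r$spikes$time > 0 & r$spikes$time <= 1000))
  expect_false(is.unsorted(r$spikes$time))
  expect_true(all(r$spikes$population %in% c("E", "I")))
  # serialisation round-trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write_raster(r, f)
  back <- utils::read.delim(f)
  expect_equal(nrow(back), nrow(r$spikes))
  expect_equal(back$time, r$spikes$time)
})

test_that("an empty network yields an empty raster", {
  p <- neuron_params(population = "D2", nu_ext = 0, I_e = 0,
                     dev_ext_weight = 0)
  p$V_reset <- p$E_L
  r <- run_simulation(single_neuron_net(p), duration = 500, warmup = 100,
                      seed = 1)
  expect_equal(nrow(r$spikes), 0)
  expect_equal(unname(r$rates), 0)
})
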