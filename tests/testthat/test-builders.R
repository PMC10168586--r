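test_that("the Complete Model matches the reference architecture", {
  net <- build_complete_model()
  sizes <- vapply(net$populations, `[[`, numeric(1), "N")
  expect_equal(sum(sizes), 13872)
  expect_equal(unname(sizes[c("D1", "D2", "FSN", "GPTI", "GPTA", "STN")]),
               c(6000, 6000, 420, 780, 264, 408))
  expect_equal(nrow(net$connections), 19) # internal pathways
  full <- bg_connectivity()
  expect_equal(nrow(full), 25) # + one external-drive row per population
  expect_true(all(full$p[full$source == "ext"] == 1))
  # D2 external drive carries the dopamine factor
  net2 <- build_complete_model(D_d = 1.03)
  expect_equal(net2$populations$D2$params$nu_ext, 1.03 * 1.083)
  expect_equal(net2$populations$D1$params$nu_ext, 1.12)
})

test_that("dopamine depletion modulates only the D2 drive and commutes with build", {
  net <- build_complete_model()
  expect_identical(apply_dopamine(net, 1), net)
  expect_equal(apply_dopamine(net, 1.03)$populations$D2$params$nu_ext,
               1.03 * 1.083)
  expect_identical(apply_dopamine(net, 0.9), build_complete_model(D_d = 0.9))
  expect_error(apply_dopamine(net, -1))
})

test_that("optogenetic perturbations rewrite the intended knobs only", {
  net <- build_complete_model(D_d = 1.03)
  # kappa = 1 is the identity
  k1 <- apply_opto(net, opto_perturbation("stn_modulation", kappa = 1))
  expect_equal(k1, net)
  expect_warning(opto_perturbation("stn_modulation", kappa = 2), "range")
  # cortex inhibition: STN drive x0.75; 20% of each striatal population x0.25
  ctx <- apply_opto(net, opto_perturbation("cortex_inhibition"), seed = 1)
  expect_equal(ctx$populations$STN$params$nu_ext, 0.75 * 0.5)
  for (p in c("D1", "D2", "FSN")) {
    nu <- ctx$populations[[p]]$nu_ext_vec
    base <- net$populations[[p]]$params$nu_ext
    expect_equal(length(nu), net$populations[[p]]$N)
    expect_equal(sum(abs(nu - 0.25 * base) < 1e-12),
                 round(0.2 * net$populations[[p]]$N))
    expect_equal(sum(abs(nu - base) < 1e-12),
                 round(0.8 * net$populations[[p]]$N))
  }
  # GPe inhibition: constant-current deltas on the two pallidal populations
  gpe <- apply_opto(net, opto_perturbation("gpe_inhibition"))
  expect_equal(gpe$populations$GPTA$params$I_e, 1 - 480)
  expect_equal(gpe$populations$GPTI$params$I_e, 12 - 120)
  expect_equal(gpe$populations$STN$params$I_e, net$populations$STN$params$I_e)
})

test_that("size scaling preserves expected in-degrees and observer size", {
  net <- build_complete_model()
  expect_identical(scale_size(net, 1), net)
  for (n in c(2, 8)) {
    sc <- build_complete_model(n = n)
    for (i in seq_len(nrow(net$connections))) {
      src <- net$connections$source[i]
      indeg0 <- net$connections$p[i] * net$populations[[src]]$N
      indeg <- sc$connections$p[i] * sc$populations[[src]]$N
      expect_equal(indeg, indeg0)
    }
    expect_equal(sc$populations$GPTI$observer_size, 780)
    expect_equal(sc$populations$GPTI$N, 780 * n)
  }
  # realised in-degree matches expectation within binomial noise
  p1 <- 0.0833 / 4
  e <- build_connections(p1, 4 * 6000, 780, seed = 5)
  mu <- p1 * 4 * 6000
  expect_lt(abs(nrow(e) / 780 - mu), 4 * sqrt(mu / 780))
})

test_that("the Simplified Model implements the coupling algebra", {
  prm <- simplified_config()
  pr <- function(net, s, t)
    with(net$connections, p[source == s & target == t])
  cfg <- bg_config()
  p1 <- function(s, t)
    with(cfg$connections, p[source == s & target == t])

  half <- build_simplified_model(0.5, params = prm)
  expect_equal(pr(half, "D2", "GPTIA"), 0.5 * p1("D2", "GPTI"))
  expect_equal(pr(half, "D2s", "GPTIA"), 0.5 * 2 * p1("D2", "GPTI"))
  expect_equal(pr(half, "D2", "GPTIB"), p1("D2", "GPTI")) # loop-internal

  # epsilon = 0: loops fully independent (no inter-loop pathways)
  iso <- build_simplified_model(0, params = prm)
  expect_equal(length(pr(iso, "D2", "GPTIA")), 0)
  expect_equal(length(pr(iso, "GPTIB", "STN")), 0)
  # epsilon = 1: auxiliaries play no role
  full <- build_simplified_model(1, params = prm)
  aux_rows <- full$connections$source %in% c("D2s", "STNs", "GPTIs")
  expect_false(any(aux_rows))
  expect_error(build_simplified_model(1.2), "epsilon")

  # input conservation: real + auxiliary expected in-degree is
  # epsilon-invariant for every compensated pathway
  sizes <- function(net) vapply(net$populations, `[[`, numeric(1), "N")
  indeg <- function(net, t) {
    con <- net$connections[net$connections$target == t, ]
    w <- sizes(net)[con$source]
    sum(con$p * w * con$weight)
  }
  ref <- build_simplified_model(1, params = prm)
  for (eps in c(0, 0.3, 0.7)) {
    net <- build_simplified_model(eps, params = prm)
    for (t in c("GPTIA", "GPTIB", "STN", "FSN", "D2"))
      expect_equal(indeg(net, t), indeg(ref, t), tolerance = 1e-12)
  }

  # halved auxiliaries, split pallidal halves
  s <- sizes(iso)
  expect_equal(unname(s[c("GPTIA", "GPTIB", "D2s", "STNs", "GPTIs")]),
               c(390, 390, 3000, 204, 390))
})

test_that("auxiliary calibration finds and holds target rates", {
  p <- neuron_params(population = "STN")
  # fixed point: the target equals the current rate
  probe <- calibrate_auxiliary(p, target_rate = 35, tolerance = 30,
                               what = "I_e", N = 60, duration = 1000,
                               seed = 2)
  expect_equal(probe$value, p$I_e) # within tolerance -> no adjustment
  # rate increases monotonically with I_e in the operating range
  rate_at <- function(Ie) {
    q <- p; q$I_e <- Ie
    net <- bg_network(list(list(name = "x", N = 60L, params = q)),
                      data.frame(source = character(0), target = character(0),
                                 p = numeric(0), delay = numeric(0),
                                 type = character(0), weight = numeric(0)))
    unname(run_simulation(net, duration = 1000, warmup = 300, seed = 2)$rates)
  }
  r0 <- rate_at(5); r1 <- rate_at(105); r2 <- rate_at(205)
  expect_lt(r0, r1); expect_lt(r1, r2)
  # calibration hits an off-current target
  cal <- calibrate_auxiliary(p, target_rate = 30, tolerance = 1.5,
                             what = "I_e", N = 60, duration = 1500, seed = 2)
  expect_lt(abs(cal$achieved - 30), 1.5)
  expect_error(calibrate_auxiliary(p, target_rate = 30, tolerance = 0.1,
                                   what = "I_e", N = 60, duration = 1000,
                                   interval = c(5000, 6000), seed = 2),
               "bracket")
})
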