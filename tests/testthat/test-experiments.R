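test_that("a single-value sweep equals a plain run", {
  sw <- bg_sweep("D_d", 1.03, model = "complete", seeds = 1,
                 duration = 1200)
  r <- run_simulation(build_complete_model(D_d = 1.03), duration = 1200,
                      warmup = 500, seed = 1)
  expect_equal(sw$STN_rate, unname(r$rates["STN"]))
  expect_equal(sw$D2_rate, unname(r$rates["D2"]))
  expect_equal(sw$STN_mean_f,
               mean_frequency(welch_psd(bin_rates(r, "STN"),
                                        nperseg = 1200, noverlap = 600)))
  expect_equal(sw$STN_rate_sd, NA_real_) # single seed: no spread
  expect_equal(sw$D_d, 1.03)
})

test_that("sweep output carries one row per knob value with seed spreads", {
  sw <- bg_sweep("D_d", c(1.0, 1.05), model = "complete", seeds = 1:2,
                 duration = 1200)
  expect_equal(nrow(sw), 2)
  expect_true(all(c("STN_mean_f", "D2_psd_dag", "STN_rate_sd") %in%
                    colnames(sw)))
  expect_true(all(is.finite(sw$STN_rate_sd)))
})

test_that("burst analysis summarises windows and burst asymmetry", {
  res <- burst_analysis(D_d = 0.90, seeds = 1, duration = 2500)
  expect_equal(nrow(res$windows), 17) # (2500 - 500)/125 + 1
  expect_true(is.finite(res$skewness))
  expect_true(res$anticorrelation >= 0 && res$anticorrelation <= 1)
  expect_true(all(c("delta_f", "beta_psd") %in% colnames(res$windows)))
})
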