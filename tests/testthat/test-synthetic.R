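# synthetic dual-echo pCASL generator

test_that("band-limited processes concentrate their power in the declared band", {
  x <- generate_band_limited_process(4096, 0.1, c(0.01, 0.071),
                                     amplitude = 2, seed = 1)
  expect_gte(band_power_fraction(x, 0.1, c(0.01, 0.071)), 0.95)
  expect_equal(mean(x), 0, tolerance = 1e-10)
  # orthogonal in-band sinusoids: sample SD matches the target up to the
  # n-1 denominator of sd()
  expect_equal(sd(x), 2 * sqrt(4096 / 4095), tolerance = 1e-9)
  # property holds across lengths/bands under a fixed seed
  for (k in 1:5) {
    n <- c(64, 90, 128, 200, 45)[k]
    dt <- c(3.5, 3.5, 1, 0.5, 7)[k]
    b <- c(0.01, min(0.065, 0.9 / (2 * dt)))
    y <- generate_band_limited_process(n, dt, b, amplitude = 1, seed = 10 + k)
    expect_gte(band_power_fraction(y, dt, b), 0.95)
  }
})

test_that("zero amplitude gives an all-zero process and seeds are reproducible", {
  expect_equal(max(abs(generate_band_limited_process(128, 1, c(0.05, 0.2),
                                                     amplitude = 0, seed = 1))), 0)
  a <- generate_band_limited_process(128, 1, c(0.05, 0.2), seed = 42)
  b <- generate_band_limited_process(128, 1, c(0.05, 0.2), seed = 42)
  c <- generate_band_limited_process(128, 1, c(0.05, 0.2), seed = 43)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a, c)))
})

test_that("bands outside (0, Nyquist] are rejected", {
  expect_error(generate_band_limited_process(128, 1, c(0.1, 0.6)), "band")
  expect_error(generate_band_limited_process(128, 1, c(0, 0.2)), "band")
  expect_error(bandpass(rnorm(64), dt = 7, band = c(0.01, 0.2)), "Nyquist")
})

test_that("coupled pairs hit the target correlation", {
  c0 <- generate_band_limited_process(10000, 0.5, c(0.01, 0.065), seed = 7)
  # degenerate noise-free case: perfect correlation at zero lag
  b1 <- generate_coupled_pair(c0, 1, lag = 0, dt = 0.5, seed = 8)
  expect_equal(cor(b1, c0), 1, tolerance = 1e-12)
  # independence case: band-limited series have ~ n * 2 * bw * dt effective
  # degrees of freedom (~550 here), not n, so the chance-correlation bound
  # is 2/sqrt(n_eff)
  b0 <- generate_coupled_pair(c0, 0, lag = 0, dt = 0.5, seed = 9)
  n_eff <- 10000 * 2 * (0.065 - 0.01) * 0.5
  expect_lt(abs(cor(b0, c0)), 2 / sqrt(n_eff))
  # intermediate coupling: Fisher CI at n = 10,000
  b5 <- generate_coupled_pair(c0, 0.5, lag = 0, dt = 0.5, seed = 10)
  expect_gt(cor(b5, c0), 0.45)
  expect_lt(cor(b5, c0), 0.55)
  expect_error(generate_coupled_pair(c0, 1.2, 0, dt = 0.5), "target_r")
})

test_that("coupling calibration is unbiased over replicates", {
  rs <- vapply(1:50, function(k) {
    c0 <- generate_band_limited_process(10000, 0.5, c(0.01, 0.065),
                                        seed = 100 + k)
    b <- generate_coupled_pair(c0, 0.5, lag = 0, dt = 0.5, seed = 600 + k)
    cor(b, c0)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.5), 0.01)
})

test_that("a static noise-free run has constant volumes and exact control-label difference", {
  tru <- ground_truth(c(6L, 6L, 2L), coupling = 0, lag = 0, noise_sd = 0,
                      cbf_fluct_amplitude = 0, bold_fluct_amplitude = 0)
  acq <- acq_params(matrix_size = c(6L, 6L, 2L), n_volumes = 20L)
  run <- assemble_dual_echo_run(tru, acq, seed = 1)
  ctl <- run$echo1[, , , run$tags == "control"]
  lab <- run$echo1[, , , run$tags == "label"]
  expect_equal(apply(ctl, 1:3, sd), array(0, dim = c(6, 6, 2)))
  expect_equal(apply(lab, 1:3, sd), array(0, dim = c(6, 6, 2)))
  # control - label equals the difference signal implied by the CBF map
  dm <- ctl[, , , 1] - lab[, , , 1]
  q <- quantify_cbf(ctl[, , , 1], lab[, , , 1], tru$m0_map,
                    quant_params(alpha_inv = 1, label_duration = acq$label_duration,
                                 pld_first = acq$pld_first,
                                 pld_last = acq$pld_first + acq$pld_increment,
                                 n_slices = 2L))
  msk <- as.logical(tru$mask)
  expect_equal(q$cbf[msk], tru$baseline_cbf_map[msk], tolerance = 1e-10)
})

test_that("zero baseline perfusion makes label equal control", {
  tru <- ground_truth(c(6L, 6L, 2L), baseline_cbf = 0, coupling = 0,
                      noise_sd = 0, cbf_fluct_amplitude = 0,
                      bold_fluct_amplitude = 0)
  acq <- acq_params(matrix_size = c(6L, 6L, 2L), n_volumes = 12L)
  run <- assemble_dual_echo_run(tru, acq, seed = 2)
  expect_equal(run$echo1[, , , 1], run$echo1[, , , 2])
  expect_equal(run$echo2[, , , 3], run$echo2[, , , 4])
})

test_that("run assembly is deterministic and rejects mismatched shapes", {
  tru <- small_truth()
  acq <- small_acq()
  r1 <- assemble_dual_echo_run(tru, acq, seed = 5)
  r2 <- assemble_dual_echo_run(tru, acq, seed = 5)
  expect_identical(r1$echo1, r2$echo1)
  expect_identical(r1$echo2, r2$echo2)
  expect_error(assemble_dual_echo_run(tru, acq_params(matrix_size = c(4, 4, 2))),
               "conform")
})

test_that("noise-free baseline runs invert exactly to the injected CBF map", {
  tru <- ground_truth(c(8L, 8L, 4L), noise_sd = 0)
  bl <- assemble_baseline_run(tru, seed = 3)
  q <- quantify_baseline_run(bl$run, bl$m0, quant_params(n_slices = 4L))
  msk <- as.logical(tru$mask)
  expect_lt(max(abs(q$cbf[msk] - tru$baseline_cbf_map[msk]) / 60), 1e-6)
  expect_true(all(bl$m0[msk] > 0))
})

test_that("noisy baseline runs recover the mean CBF within 5 percent", {
  means <- vapply(1:20, function(k) {
    tru <- ground_truth(c(6L, 6L, 2L), baseline_cbf = 60, noise_sd = 0.01)
    bl <- assemble_baseline_run(tru,
      acq = acq_params(tr = 4.269, te1 = 0.01, te2 = NA, n_volumes = 60L,
                       matrix_size = c(6L, 6L, 2L), label_duration = 1.75,
                       pld_first = 1.9, pld_increment = 0.05),
      params = quant_params(n_slices = 2L), seed = 40 + k)
    q <- quantify_baseline_run(bl$run, bl$m0, quant_params(n_slices = 2L))
    mean(q$cbf[as.logical(tru$mask)])
  }, numeric(1))
  expect_lt(abs(mean(means) - 60) / 60, 0.05)
})

test_that("cohorts honor their preset distribution and are reproducible", {
  y <- generate_cohort(15, "young-like", seed = 11)
  expect_equal(nrow(y$truth), 15)
  se <- cohort_preset("young-like")$coupling_sd / sqrt(15)
  expect_lt(abs(mean(y$truth$coupling) - 0.24), 2 * se + 0.01)
  y2 <- generate_cohort(15, "young-like", seed = 11)
  expect_identical(y$truth, y2$truth)
  expect_identical(y$subjects[[3]]$bold, y2$subjects[[3]]$bold)
  # zero between-subject SD: identical truth for all subjects
  pre <- list(coupling_mean = 0.2, coupling_sd = 0, lag_mean = -1, lag_sd = 0,
              baseline_cbf_mean = 60, baseline_cbf_sd = 0)
  z <- generate_cohort(4, pre, seed = 12)
  expect_equal(var(z$truth$coupling), 0)
  expect_equal(var(z$truth$lag), 0)
})
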