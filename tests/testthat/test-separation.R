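# BOLD/CBF signal separation

tr <- 3.5

test_that("the separation cutoff is 1/(4 TR)", {
  expect_equal(separation_cutoff(3.5), 1 / 14)
  expect_equal(separation_cutoff(4.269), 1 / (4 * 4.269))
})

test_that("split/rebuild validates tags and round-trips bit-identically", {
  tru <- small_truth()
  run <- assemble_dual_echo_run(tru, small_acq(n_volumes = 12L), seed = 1)
  s <- split_and_rebuild(run)
  expect_identical(s$te1, run$echo1)
  sp <- split_run(run$echo1, run$tags)
  back <- rebuild_interleaved(sp$control, sp$label, control_first = TRUE)
  expect_identical(back, run$echo1)
  bad <- run
  bad$tags <- rep(c("label", "label", "control", "control"), 3)
  expect_error(split_and_rebuild(bad), "alternate")
})

test_that("constant input yields zero CBF output and is preserved by the BOLD path", {
  x <- rep(7, 40)
  expect_equal(max(abs(separate_cbf(x, tr))), 0, tolerance = 1e-12)
  expect_equal(as.numeric(separate_bold(x, tr)), rep(7, 20), tolerance = 1e-12)
  expect_error(separate_cbf(rep(1, 7), tr), "even")
  expect_error(separate_bold(rep(1, 7), tr), "even")
})

test_that("a constant control-minus-label difference is recovered", {
  n <- 90
  x <- 1000 + rep(c(5, -5), n / 2)    # control first: c - l = 10
  out <- separate_cbf(x, tr)
  expect_equal(as.numeric(out[3:42]), rep(10, 40), tolerance = 1e-6)
  # flipped interleave order flips the sign unless declared
  xf <- 1000 + rep(c(-5, 5), n / 2)
  expect_equal(as.numeric(separate_cbf(xf, tr, control_first = FALSE)[3:42]),
               rep(10, 40), tolerance = 1e-6)
})

test_that("crosstalk between the separated channels is suppressed", {
  n <- 90
  # pure BOLD fluctuation -> CBF channel empty
  b <- generate_band_limited_process(n, tr, c(0.01, 0.065),
                                     amplitude = 0.01, seed = 21)
  cbf_out <- separate_cbf(1000 * (1 + b), tr)
  expect_lt(var(as.numeric(cbf_out)) / var(1000 * b), 1e-3)
  # pure perfusion modulation -> BOLD channel empty
  f <- generate_band_limited_process(n, tr, c(0.01, 0.065),
                                     amplitude = 0.15, seed = 22)
  mod <- 5 * (1 + f) * cos(pi * (seq_len(n) - 1))
  bold_out <- separate_bold(1000 + mod, tr)
  expect_lt(var(as.numeric(bold_out)) / var(mod), 1e-3)
})

test_that("an in-band BOLD sinusoid survives separation with high fidelity", {
  n <- 90
  tv <- (seq_len(n) - 1) * tr
  s <- sin(2 * pi * 0.02 * tv)              # 0.02 Hz, in band
  out <- as.numeric(separate_bold(1000 + 10 * s, tr))
  pair_truth <- (s[seq(1, n, 2)] + s[seq(2, n, 2)]) / 2
  expect_gt(cor(out, pair_truth), 0.99)
})

test_that("both separators are linear and halve the frame count", {
  set.seed(31)
  a <- matrix(rnorm(90 * 5), 90)
  b <- matrix(rnorm(90 * 5), 90)
  expect_equal(separate_cbf(a + b, tr),
               separate_cbf(a, tr) + separate_cbf(b, tr), tolerance = 1e-10)
  expect_equal(separate_bold(a + b, tr),
               separate_bold(a, tr) + separate_bold(b, tr), tolerance = 1e-10)
  expect_equal(nrow(separate_cbf(a, tr)), 45)
  expect_equal(attr(separate_cbf(a, tr), "dt"), 2 * tr)
})

test_that("band-pass removes stop-band and keeps pass-band components", {
  n <- 400; dt <- 5    # 2000 s: 0.005 and 0.03 Hz fall on exact bins
  tv <- (seq_len(n) - 1) * dt
  expect_equal(max(abs(bandpass(rep(4, n), dt))), 0, tolerance = 1e-12)
  slow <- sin(2 * pi * 0.005 * tv)
  expect_lt(sd(bandpass(slow, dt)), 0.05 * sd(slow))
  mid <- sin(2 * pi * 0.03 * tv)
  expect_lt(abs(sd(bandpass(mid, dt)) - sd(mid)) / sd(mid), 0.05)
})

test_that("spatial smoothing preserves constants and matches the Gaussian kernel", {
  v <- array(7, c(6, 6, 4, 2))
  expect_equal(spatial_smooth(v, 6, c(3.6, 3.6, 5)), v, tolerance = 1e-12)
  expect_identical(spatial_smooth(v, 0), v)
  # interior impulse reproduces the separable sampled-Gaussian kernel
  imp <- array(0, c(11, 11, 7, 1)); imp[6, 6, 4, 1] <- 1
  vox <- c(3.6, 3.6, 5)
  sm <- spatial_smooth(imp, 6, vox)
  sig <- (6 / (2 * sqrt(2 * log(2)))) / vox
  k <- lapply(1:3, function(ax) {
    half <- max(1L, ceiling(4 * sig[ax]))
    kk <- exp(-0.5 * (seq(-half, half) / sig[ax])^2)
    kk / sum(kk)
  })
  # along the x-line through the impulse the response is the separable
  # product kx(offset) * ky(0) * kz(0); offsets beyond the kernel are zero
  kern_at <- function(kk, off) {
    c0 <- (length(kk) + 1L) %/% 2L
    i <- c0 + off
    ifelse(i >= 1 & i <= length(kk), kk[pmax(pmin(i, length(kk)), 1)], 0)
  }
  expected <- kern_at(k[[1]], -5:5) * kern_at(k[[2]], 0) * kern_at(k[[3]], 0)
  expect_equal(sm[, 6, 4, 1], expected, tolerance = 1e-6)
})

test_that("RETROICOR removes phase-locked physiological signal and little else", {
  ph <- generate_physio_trace(330, seed = 9)
  tv <- ((0:89) + 0.5) * 3.5
  card <- 3 * boldcbf:::physio_at(ph, "cardiac", tv)
  out <- retroicor_regress(100 + card, ph, tv, order = 2)
  expect_lt(sd(out) / sd(card), 0.05)
  expect_equal(mean(out), mean(100 + card), tolerance = 1e-9)
  # order 0 is the identity
  z <- generate_band_limited_process(90, 3.5, c(0.01, 0.065), seed = 11)
  expect_identical(retroicor_regress(z, ph, tv, order = 0), z)
  # idempotence: a second pass changes nothing
  z1 <- retroicor_regress(z, ph, tv, order = 2)
  z2 <- retroicor_regress(z1, ph, tv, order = 2)
  expect_equal(cor(z1, z2), 1, tolerance = 1e-12)
  # an independent series at long n is nearly untouched (chance projection
  # onto 4 regressors only)
  ph2 <- generate_physio_trace(3.5 * 2000 + 5, seed = 12)
  tv2 <- ((seq_len(2000)) - 0.5) * 3.5
  z3 <- generate_band_limited_process(2000, 3.5, c(0.01, 0.065), seed = 13)
  z4 <- retroicor_regress(z3, ph2, tv2, order = 1)
  expect_gt(cor(z3, z4), 0.995)
  expect_error(retroicor_regress(z, generate_physio_trace(10, seed = 1), tv),
               "cover")
})

test_that("nuisance regression removes supplied confounds exactly", {
  set.seed(41)
  n <- 1000
  r1 <- rnorm(n); r2 <- rnorm(n)
  expect_identical(nuisance_regress(r1, NULL), r1)
  # a series equal to a regressor leaves only its mean
  out <- nuisance_regress(5 + 2 * r1, cbind(r1))
  expect_lt(sd(out), 1e-10)
  # mixture + noise: residual uncorrelated with both regressors
  y <- 0.7 * r1 - 1.2 * r2 + rnorm(n)
  res <- nuisance_regress(y, cbind(r1, r2))
  expect_lt(abs(cor(res, r1)), 0.01)
  expect_lt(abs(cor(res, r2)), 0.01)
  # rank-deficient design is tolerated
  res2 <- nuisance_regress(y, cbind(r1, r1, r2))
  expect_equal(res2, res, tolerance = 1e-9)
  expect_error(nuisance_regress(y, cbind(rnorm(10))), "length")
})

test_that("noise-free synthetic runs separate into the injected fluctuations", {
  tru <- small_truth(coupling = 1, lag = 0)
  acq <- small_acq()
  run <- assemble_dual_echo_run(tru, acq, seed = 51)
  sep <- separate_run(run)
  ms <- masked_series(sep, tru$mask)
  r <- vapply(seq_len(ncol(ms$bold)),
              function(j) cor(ms$bold[, j], ms$cbf[, j]), numeric(1))
  expect_gt(min(r), 0.99)
})
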