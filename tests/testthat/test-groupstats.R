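# group inference: t-tests, FDR, ROI summaries, effect sizes

test_that("one-sample t matches the textbook formula and handles degenerate maps", {
  # hand-computed: values (0.1, 0.2, 0.3, 0.2, 0.2) -> t = 6.3245553, dof 4
  m <- matrix(c(0.1, 0.2, 0.3, 0.2, 0.2), ncol = 1)
  g <- one_sample_t(m)
  expect_equal(g$t, 6.324555320336759, tolerance = 1e-12)
  expect_equal(g$dof, 4)
  expect_equal(g$p, 2 * pt(-6.324555320336759, 4), tolerance = 1e-12)
  # cross-check against stats::t.test as an independent route
  tt <- t.test(m[, 1])
  expect_equal(g$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(g$p, tt$p.value, tolerance = 1e-12)
  # all-zero maps: t = 0, p = 1; nonzero constant maps: undefined
  g0 <- one_sample_t(matrix(0, 4, 3))
  expect_equal(as.numeric(g0$t), rep(0, 3))
  expect_equal(as.numeric(g0$p), rep(1, 3))
  gc <- one_sample_t(matrix(0.3, 4, 1))
  expect_true(is.na(gc$t))
  expect_error(one_sample_t(matrix(1, 1, 2)), "2 subjects")
})

test_that("two-sample t is the pooled-variance unpaired test and is antisymmetric", {
  a <- matrix(c(1.2, 0.8, 1.1, 0.9, 1.3), ncol = 1)
  b <- matrix(c(0.4, 0.6, 0.3, 0.7), ncol = 1)
  g <- two_sample_t(a, b)
  tt <- t.test(a[, 1], b[, 1], var.equal = TRUE)
  expect_equal(g$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(g$p, tt$p.value, tolerance = 1e-12)
  expect_equal(g$dof, 7)
  gs <- two_sample_t(b, a)
  expect_equal(gs$t, -g$t)
  expect_equal(gs$p, g$p)
  gi <- two_sample_t(a, a)
  expect_equal(gi$t, 0)
  # Welch variant agrees with stats::t.test
  gw <- two_sample_t(a, b, var_equal = FALSE)
  tw <- t.test(a[, 1], b[, 1])
  expect_equal(gw$t, unname(tw$statistic), tolerance = 1e-12)
  expect_equal(gw$p, tw$p.value, tolerance = 1e-12)
})

test_that("two-sample t under the null yields uniform p-values", {
  set.seed(81)
  a <- matrix(rnorm(10 * 1000), 10)
  b <- matrix(rnorm(10 * 1000), 10)
  g <- two_sample_t(a, b)
  ks <- suppressWarnings(stats::ks.test(as.numeric(g$p), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH step-up matches the hand-evaluated rule", {
  # all thresholds i*alpha/m: p(4) = 0.04 <= 0.05 -> all 4 rejected
  f <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_equal(sum(f$reject), 4)
  expect_equal(f$q, rep(0.04, 4))
  expect_equal(sum(fdr_bh(rep(1, 10))$reject), 0)
  expect_length(fdr_bh(numeric(0))$q, 0)
  # q >= p elementwise, q <= 1, agrees with the step-up definition
  set.seed(82)
  p <- runif(200)^1.5
  f2 <- fdr_bh(p)
  expect_true(all(f2$q >= p - 1e-12))
  expect_true(all(f2$q <= 1))
  ps <- sort(p)
  k <- suppressWarnings(max(which(ps <= seq_along(ps) * 0.05 / 200)))
  stepup <- if (is.finite(k)) p <= ps[k] else rep(FALSE, 200)
  expect_equal(f2$reject, stepup)
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("ROI extraction averages over the gray-matter-restricted mask", {
  d <- c(6, 6, 2)
  map <- array(5, d)
  mask <- array(TRUE, d)
  expect_equal(as.numeric(roi_extract(map, mask)), 5)
  # checkerboard oracle by direct enumeration
  cb <- array((seq_len(prod(d)) %% 2), d)
  gm <- array(runif(prod(d)), d)
  sel <- as.logical(mask) & gm >= 0.3
  expect_equal(as.numeric(roi_extract(cb, mask, gm, 0.3)), mean(cb[sel]))
  expect_equal(attr(roi_extract(cb, mask, gm, 0.3), "n_voxels"), sum(sel))
  # disjoint support errors
  expect_error(roi_extract(map, mask, array(0, d), 0.3), "empty ROI")
})

test_that("the rmax - r0 contrast reports pooled t and Cohen's d", {
  a <- list(r0 = c(0.2, 0.25, 0.22), rmax = c(0.30, 0.33, 0.31))
  g <- rmax_minus_r0_contrast(a, a)
  expect_equal(g$cohens_d, 0)
  expect_equal(g$t, 0)
  # definition case: difference means 1 vs 0 with pooled SD 1
  set.seed(83)
  x <- rnorm(20); x <- (x - mean(x)) / sd(x)
  y <- rnorm(20); y <- (y - mean(y)) / sd(y)
  expect_equal(cohens_d(x + 1, y), 1, tolerance = 1e-12)
  b <- list(r0 = c(0.2, 0.21, 0.19), rmax = c(0.24, 0.23, 0.25))
  g2 <- rmax_minus_r0_contrast(a, b)
  manual <- t.test(a$rmax - a$r0, b$rmax - b$r0, var.equal = TRUE)
  expect_equal(g2$t, unname(manual$statistic), tolerance = 1e-12)
  expect_equal(g2$p, manual$p.value, tolerance = 1e-12)
})

test_that("group maps restrict FDR to the analysis mask and propagate NA", {
  set.seed(84)
  maps <- lapply(1:5, function(i) array(rnorm(24, mean = 0.5), c(4, 3, 2)))
  mask <- array(rep(c(TRUE, FALSE), 12), c(4, 3, 2))
  g <- one_sample_t(maps, mask = mask)
  expect_true(all(is.na(g$q[!mask])))
  expect_true(all(!g$reject[!mask]))
  expect_true(all(is.finite(g$q[mask])))
  expect_true(all(g$q[mask] >= g$p[mask] - 1e-12))
})
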