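test_that("confound PCA returns centered orthogonal components with ordered variance", {
  set.seed(20)
  mot <- matrix(rnorm(600), 100, 6)
  cm <- build_confound_matrix(mot, rnorm(100), rnorm(100))
  C <- cm$components
  expect_equal(ncol(C), 6L)
  expect_lt(max(abs(colMeans(C))), 1e-10)
  cp <- crossprod(C)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  expect_true(all(diff(cm$explained_variance) <= 1e-10))
})

test_that("duplicate candidate columns reduce the usable rank", {
  set.seed(21)
  base <- matrix(rnorm(300), 100, 3)
  mot <- cbind(base, base)               # rank 3 despite 6 columns
  expect_warning(cm <- build_confound_matrix(mot, csf = NULL, wm = NULL,
                                             n_components = 6),
                 "rank 3")
  expect_equal(ncol(cm$components), 3L)
})

test_that("confound regression removes exactly the confound subspace", {
  set.seed(22)
  mot <- matrix(rnorm(480), 80, 6)
  csf <- rnorm(80); wm <- rnorm(80)
  cm <- build_confound_matrix(mot, csf, wm)
  # a voxel equal to confound + constant is annihilated
  v <- 5 + 2 * cm$components[, 1] - cm$components[, 3]
  noise <- matrix(rnorm(80 * 9), 80, 9)
  run <- matrix_run(cbind(v, noise))
  den <- regress_confounds(run, cm)
  resid <- den$data[1, 1, 1, ]
  expect_lt(sd(resid), 1e-10)
  expect_equal(mean(resid), mean(v), tolerance = 1e-8)   # mean re-added
  # residuals orthogonal to every component
  for (j in 2:10) {
    r <- den$data[j, 1, 1, ] - mean(den$data[j, 1, 1, ])
    dots <- abs(crossprod(cm$components, r))
    norms <- sqrt(colSums(cm$components^2)) * sqrt(sum(r^2))
    expect_lt(max(dots / norms), 1e-8)
  }
})

test_that("an empty confound matrix is the identity transform", {
  set.seed(23)
  run <- matrix_run(matrix(rnorm(200), 50, 4))
  cm <- build_confound_matrix(matrix(rnorm(300), 50, 6), n_components = 0)
  expect_identical(regress_confounds(run, cm)$data, run$data)
})

test_that("ALFF of an in-band sinusoid is its RMS amplitude and scales linearly", {
  n <- 500; tr <- 0.8; A <- 3
  x <- A * sin(2 * pi * 0.05 * (0:(n - 1)) * tr)
  a <- alff_map(series_run(x, tr))$values[1, 1, 1]
  expect_equal(a, A / sqrt(2), tolerance = 1e-6)
  a2 <- alff_map(series_run(2 * x, tr))$values[1, 1, 1]
  expect_equal(a2, 2 * a, tolerance = 1e-12)        # degree-1 homogeneity
  # power scale returns the square
  ap <- alff_map(series_run(x, tr), power_scale = "power")$values[1, 1, 1]
  expect_equal(ap, a^2, tolerance = 1e-10)
})

test_that("spectrum-domain ALFF equals the time-domain band-filtered RMS oracle", {
  set.seed(24)
  for (n in c(120, 241, 541)) {
    tr <- sample(c(0.72, 0.8), 1)
    m <- matrix(rnorm(n * 20), n, 20)
    a <- alff_map(matrix_run(m, tr))$values[, 1, 1]
    o <- apply(m, 2, band_rms_oracle, tr = tr)
    expect_lt(max(abs(a - o) / o), 1e-10)
  }
})

test_that("fALFF is bounded, scale-invariant, and behaves at band extremes", {
  n <- 400; tr <- 0.8
  inband <- sin(2 * pi * (10 / (n * tr)) * (0:(n - 1)) * tr)   # 0.03125 Hz, exact bin
  outband <- sin(2 * pi * 0.3 * (0:(n - 1)) * tr)              # 96th bin, exact
  expect_equal(falff_map(series_run(inband, tr))$values[1, 1, 1], 1,
               tolerance = 1e-9)
  expect_lt(falff_map(series_run(outband, tr))$values[1, 1, 1], 1e-6)
  set.seed(25)
  x <- rnorm(n)
  f1 <- falff_map(series_run(x, tr))$values[1, 1, 1]
  f2 <- falff_map(series_run(7.3 * x, tr))$values[1, 1, 1]
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("white-noise fALFF approaches the flat-spectrum bandwidth fraction", {
  set.seed(26)
  n <- 400; tr <- 0.8
  m <- matrix(rnorm(n * 200), n, 200)
  f <- falff_map(matrix_run(m, tr))$values[, 1, 1]
  expect_equal(mean(f), sqrt(0.092 / 0.625), tolerance = 0.02)
})

test_that("sub-band drift leaves ALFF unchanged and lowers fALFF", {
  set.seed(27)
  n <- 541; tr <- 0.72
  x <- rnorm(n)
  # slowest resolvable component: bin 1 at ~0.0026 Hz, well below the band
  drift <- 3 * sin(2 * pi * (0:(n - 1)) / n)
  a0 <- alff_map(series_run(x, tr))$values[1, 1, 1]
  a1 <- alff_map(series_run(x + drift, tr))$values[1, 1, 1]
  f0 <- falff_map(series_run(x, tr))$values[1, 1, 1]
  f1 <- falff_map(series_run(x + drift, tr))$values[1, 1, 1]
  expect_equal(a1, a0, tolerance = 1e-10)  # drift energy sits entirely below the band
  expect_lt(f1, f0)
})

test_that("tSNR is mean over SD with an infinite sentinel for constant voxels", {
  set.seed(28)
  x <- 100 + 10 * scale(rnorm(200))[, 1]
  expect_equal(tsnr_map(series_run(x))$values[1, 1, 1], 10, tolerance = 1e-9)
  expect_equal(tsnr_map(series_run(rep(5, 50)))$values[1, 1, 1], Inf)
  # Monte-Carlo convergence to c/sigma
  y <- 50 + rnorm(5000, sd = 4)
  expect_equal(tsnr_map(series_run(y))$values[1, 1, 1], 12.5, tolerance = 0.05)
})

test_that("normalization fixes the in-mask mean at 1 and is idempotent", {
  vals <- array(c(rep(1, 32), rep(3, 32)), c(4, 4, 4))
  mask <- array(TRUE, c(4, 4, 4))
  nm <- normalize_map(amplitude_map(vals, "ALFF"), mask)
  expect_true(nm$normalized)
  expect_equal(sort(unique(as.vector(nm$values))), c(0.5, 1.5))
  expect_equal(mean(nm$values[mask]), 1)
  nm2 <- normalize_map(nm, mask)
  expect_equal(nm2$values, nm$values)
  expect_error(normalize_map(amplitude_map(array(0, c(2, 2, 2)), "ALFF"),
                             array(TRUE, c(2, 2, 2))),
               "nonpositive")
})

test_that("global-BOLD beta recovers a planted coupling slope", {
  set.seed(29)
  n <- 300
  g <- as.numeric(arima.sim(list(ar = 0.5), n))
  m <- cbind(2 * g + rnorm(n, sd = 0.5),        # coupled voxel
             rnorm(n),                          # independent voxel
             2 * g + rnorm(n, sd = 0.5) + 100)  # offset changes nothing
  other <- matrix(rep(g, 5), n, 5) + rnorm(5 * n)  # make gbold ~ g
  run <- matrix_run(cbind(m, other))
  bm <- gbold_beta_map(run)
  # the global series is dominated by g; betas are relative to it
  gb <- global_signal(run)
  fit <- coef(lm(m[, 1] ~ gb))[2]
  expect_equal(bm$values[1, 1, 1], unname(fit), tolerance = 1e-6)
  expect_lt(abs(bm$values[2, 1, 1]), 0.15)
  expect_equal(bm$values[3, 1, 1], bm$values[1, 1, 1], tolerance = 0.2)
  cr <- series_run(rep(1, 10))
  expect_error(gbold_beta_map(cr), "constant")
})
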