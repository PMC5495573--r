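make_ds <- function(data, runs = ncol(data)) {
  fmri_dataset(data, tr_s = 2, run_lengths = runs)
}

test_that("trim_initial shortens runs and errors on short runs", {
  ds <- make_ds(matrix(rnorm(3 * 450), 3), runs = c(150, 150, 150))
  tr <- trim_initial(ds, 5)
  expect_equal(tr$run_lengths, c(145, 145, 145))
  expect_equal(tr$data, ds$data[, -c(1:5, 151:155, 301:305)])
  expect_equal(trim_initial(ds, 0)$data, ds$data)
  short <- make_ds(matrix(rnorm(3 * 10), 3), runs = 10)
  expect_error(trim_initial(short, 10), "run\\(s\\) 1")
})

test_that("despike clips only outliers and is identity on clean input", {
  x <- rnorm(200, sd = 1)
  x[50] <- mean(x) + 10 * sd(x)
  ds <- make_ds(rbind(x, rnorm(200, sd = 0.5)))
  out <- despike(ds, 2.5)
  m <- mean(x); s <- sd(x)
  expect_equal(unname(out$data[1, 50]), m + 2.5 * s)
  expect_equal(unname(out$data[1, -50]), unname(x[-50]))  # others untouched
  # uniform noise never exceeds 2.5 SD of its own spread: identity
  clean <- make_ds(matrix(runif(300, -1, 1), 3))
  expect_equal(despike(clean)$data, clean$data)
  const <- make_ds(matrix(5, 2, 100))
  expect_equal(despike(const)$data, const$data)
})

test_that("bandpass passes in-band and rejects out-of-band sinusoids", {
  tt <- (0:299) * 2
  inband <- sin(2 * pi * 0.05 * tt)
  outband <- sin(2 * pi * 0.2 * tt)
  ds <- make_ds(rbind(inband, outband, 0))
  f <- bandpass(ds)
  mid <- 50:250                                # avoid edge transients
  amp_ratio <- sd(f$data[1, mid]) / sd(inband[mid])
  expect_lt(abs(amp_ratio - 1), 0.05)
  expect_lt(sqrt(mean(f$data[2, ]^2)) / sqrt(mean(outband^2)), 0.10)
  expect_equal(f$data[3, ], rep(0, 300))
  expect_error(bandpass(ds, 0.1, 0.01), "f_low")
})

test_that("bandpass frequency response matches the analytic magnitude", {
  # 20 probe frequencies; filtfilt doubles the Butterworth magnitude response
  filt <- signal::butter(4, c(0.01, 0.1) / 0.25, type = "pass")
  # analytic magnitude from the transfer-function polynomials
  Hmag <- function(f_hz, fs = 0.5) {
    z <- exp(-1i * 2 * pi * f_hz / fs)
    abs(sum(filt$b * z^(seq_along(filt$b) - 1)) /
          sum(filt$a * z^(seq_along(filt$a) - 1)))
  }
  probes <- seq(0.015, 0.09, length.out = 20)
  n <- 4000
  tt <- (seq_len(n) - 1) * 2
  for (fr in probes) {
    # round to an exact DFT bin so amplitude is well defined
    k <- round(fr * n * 2)
    fr_bin <- k / (n * 2)
    x <- cos(2 * pi * fr_bin * tt)
    y <- signal::filtfilt(filt, x)
    mid <- 500:3500
    gain <- sqrt(mean(y[mid]^2) / mean(x[mid]^2))
    expect_lt(abs(gain - Hmag(fr_bin)^2), 0.02)  # filtfilt squares |H|
  }
})

test_that("detrend removes quadratics, spares sinusoids, ignores added trends", {
  tt <- seq_len(300)
  quad <- 2 + 0.03 * tt - 1e-4 * tt^2
  sine <- sin(2 * pi * tt / 20)
  ds <- make_ds(rbind(quad, sine))
  out <- detrend(ds)
  expect_lt(max(abs(out$data[1, ])), 1e-8 * max(abs(quad)))
  expect_gt(cor(out$data[2, ], sine), 0.99)
  with_trend <- make_ds(rbind(sine + 5 + 0.1 * tt))
  expect_equal(detrend(with_trend)$data[1, ], out$data[2, ],
               tolerance = 1e-10)
})

test_that("nuisance regression orthogonalizes and handles degenerate input", {
  set.seed(1)
  vent <- rnorm(200)
  y <- 2 * vent + rnorm(200, sd = 0.3)
  ds <- make_ds(rbind(y, vent))
  nuis <- nuisance_set(ventricle = list(vent))
  out <- regress_nuisance(ds, nuis)
  expect_lt(abs(cor(out$data[1, ], vent)), 1e-10)
  expect_lt(max(abs(out$data[2, ])), 1e-10)    # regressor itself wiped out

  # all-zero regressors: identity up to mean removal
  z <- nuisance_set(ventricle = list(rep(0, 200)))
  expect_warning(out2 <- regress_nuisance(ds, z), "rank-deficient")
  expect_equal(out2$data, ds$data - rowMeans(ds$data), tolerance = 1e-10)

  bad <- nuisance_set(ventricle = list(rnorm(150)))
  expect_error(regress_nuisance(ds, bad), "length mismatch")
})

test_that("normalization yields unit means, flags degenerate voxels, and
           leaves correlations untouched", {
  set.seed(2)
  X <- 50 + matrix(rnorm(5 * 200), 5)
  X[5, ] <- X[5, ] - mean(X[5, ])              # zero-mean voxel
  ds <- make_ds(X)
  expect_warning(out <- normalize_to_mean(ds), "flagged")
  expect_equal(rowMeans(out$data[1:4, ]), rep(1, 4))
  expect_equal(attr(out, "flagged_voxels"), 5L)
  # scale invariance
  out7 <- suppressWarnings(normalize_to_mean(make_ds(7 * X)))
  expect_equal(out7$data[1:4, ], out$data[1:4, ], tolerance = 1e-12)
  const <- normalize_to_mean(make_ds(matrix(3, 2, 50)))
  expect_equal(const$data, matrix(1, 2, 50))
})

test_that("full pipeline: order, per-run independence, correlation invariance", {
  parc <- test_parc()
  ds <- simulate_rest(parc, test_spec(), n_runs = 2, run_len = 150, seed = 4)
  pp <- run_preprocess(ds)
  idx <- cumsum(pp$run_lengths)
  expect_equal(pp$run_lengths, c(145, 145))
  for (r in seq_along(pp$run_lengths)) {
    cols <- seq(c(1, idx + 1)[r], idx[r])
    expect_equal(rowMeans(pp$data[, cols]), rep(1, nrow(pp$data)),
                 tolerance = 1e-6)
  }
  steps <- vapply(pp$provenance, `[[`, "", "step")
  expect_equal(steps, c("simulate_rest", "trim_initial", "despike",
                        "bandpass", "detrend", "regress_nuisance",
                        "normalize_to_mean"))

  # permuting run order permutes outputs identically (per-run processing)
  perm <- ds
  perm$data <- ds$data[, c(151:300, 1:150)]
  pperm <- run_preprocess(perm)
  expect_equal(pperm$data[, 1:145], pp$data[, 146:290], tolerance = 1e-10)

  # voxel-level correlations are exactly invariant to the (affine per voxel)
  # normalization; area-level ones only up to the small spread in baselines
  pre <- trim_initial(ds, 5)
  pre <- despike(pre)
  pre <- bandpass(pre)
  pre <- detrend(pre)
  pre <- regress_nuisance(pre, nuisance_set())
  i <- 1; j <- 40
  r1 <- 1:145                                  # within a single run: exact
  expect_equal(cor(pp$data[i, r1], pp$data[j, r1]),
               cor(pre$data[i, r1], pre$data[j, r1]), tolerance = 1e-10)
  # concatenated runs: per-run baselines differ slightly, so only approximate
  M1 <- area_matrix(pp, parc, "across_hemi", n_iter = 3, seed = 1)
  M2 <- area_matrix(pre, parc, "across_hemi", n_iter = 3, seed = 1)
  expect_lt(max(abs(M1$values - M2$values)), 0.01)
})

test_that("pipeline is nearly idempotent at the correlation level", {
  parc <- test_parc()
  ds <- simulate_rest(parc, test_spec(), n_runs = 1, run_len = 500, seed = 6)
  p1 <- run_preprocess(ds)
  p2 <- suppressWarnings(run_preprocess(p1))
  M1 <- area_matrix(p1, parc, "across_hemi", n_iter = 3, seed = 1)
  M2 <- area_matrix(p2, parc, "across_hemi", n_iter = 3, seed = 1)
  dr <- abs(M1$values - M2$values)
  # re-filtering attenuates the band edges a second time, which moves
  # individual pair correlations by a few hundredths at most
  expect_lt(mean(dr), 0.02)
  expect_lt(max(dr), 0.05)
})
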