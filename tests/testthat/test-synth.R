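test_that("parcellation layout: counts, eccentricity tiling, mirror symmetry", {
  parc <- make_parcellation(16, 8, seed = 1)
  expect_equal(nrow(parc), 16 * 16 * 2)
  expect_setequal(unique(parc$area), visual_areas())
  counts <- dplyr::count(parc, hemisphere, area)
  expect_true(all(counts$n == 16))

  # 8 voxels over 8 bands tile 0-10 deg at the centers of 1.25-deg bands
  p8 <- make_parcellation(8, 8, seed = 0)
  v1 <- sort(p8$eccentricity_deg[p8$hemisphere == "left" & p8$area == "V1"])
  expect_equal(v1, seq(0.625, 9.375, by = 1.25))
  expect_equal(unique(diff(v1)), 1.25)

  # hemispheres identical up to the tag and the mirrored x coordinate
  l <- dplyr::arrange(parc[parc$hemisphere == "left", ], area, cortical_distance)
  r <- dplyr::arrange(parc[parc$hemisphere == "right", ], area, cortical_distance)
  expect_equal(l$eccentricity_deg, r$eccentricity_deg)
  expect_equal(l$quadrant, r$quadrant)
  expect_equal(l$x, -r$x)

  # eccentricity monotone in cortical distance within V1
  v1l <- parc[parc$hemisphere == "left" & parc$area == "V1", ]
  o <- order(v1l$cortical_distance)
  expect_true(all(diff(v1l$eccentricity_deg[o]) >= 0))

  # quadrants only on the posterior areas
  expect_true(all(parc$quadrant[parc$area %in% quadrant_areas()] %in%
                    c("dorsal", "ventral")))
  expect_true(all(parc$quadrant[!parc$area %in% quadrant_areas()] == "none"))

  expect_error(make_parcellation(4), "n_voxels_per_area")
  expect_error(make_parcellation(16, 1), "n_ecc_bands")
})

test_that("coupling spec validates and encodes the planted structure", {
  spec <- test_spec()
  ev <- eigen(spec$latent_cov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  expect_equal(max(abs(spec$latent_cov - t(spec$latent_cov))), 0)
  expect_true(all(diag(spec$latent_cov) > 0))

  # homotopic_gain = 0 decouples the hemispheres
  s0 <- coupling_spec(homotopic_gain = 0)
  left <- s0$cells$hemisphere == "left"
  expect_equal(max(abs(s0$latent_cov[left, !left])), 0)

  # non-PSD override rejected
  bad <- diag(nrow(spec$cells)); bad[1, 2] <- bad[2, 1] <- 2
  expect_error(coupling_spec(latent_cov = bad), "positive semi-definite")

  # YAML round trip rebuilds the identical covariance
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_coupling_spec_yaml(spec, tf)
  spec2 <- read_coupling_spec_yaml(tf)
  expect_equal(spec2$latent_cov, spec$latent_cov, tolerance = 1e-12)
})

test_that("simulate_rest is deterministic and converges to the planted coupling", {
  parc <- test_parc()
  spec <- test_spec()
  d1 <- simulate_rest(parc, spec, 1, 100, seed = 11)
  d2 <- simulate_rest(parc, spec, 1, 100, seed = 11)
  expect_identical(d1$data, d2$data)

  # strong homotopic coupling beats a distal pair by a wide margin at long T
  ds <- simulate_rest(parc, spec, 1, 5000, seed = 2)
  mean_area <- function(h, a) {
    colMeans(ds$data[parc$hemisphere == h & parc$area == a, ])
  }
  r_hom <- cor(mean_area("left", "V1"), mean_area("right", "V1"))
  r_dist <- cor(mean_area("left", "V1"), mean_area("right", "MT"))
  expect_gt(r_hom - r_dist, 0.2)

  # identity covariance + no noise: across-area r within sampling error
  id <- coupling_spec(latent_cov = diag(nrow(spec$cells)), noise_sd = 0,
                      ar1 = 0)
  di <- simulate_rest(parc, id, 1, 3000, seed = 3)
  r <- cor(colMeans(di$data[parc$area == "V1" & parc$hemisphere == "left", ]),
           colMeans(di$data[parc$area == "LIP" & parc$hemisphere == "left", ]))
  expect_lt(abs(r), 3 / sqrt(3000))

  expect_error(simulate_rest(parc, spec, 1, 10), "run_len")
})

test_that("hemisphere swap leaves across-hemisphere statistics unchanged", {
  parc <- test_parc()
  ds <- simulate_rest(parc, test_spec(), 1, 400, seed = 5)
  swapped <- parc
  swapped$hemisphere <- ifelse(parc$hemisphere == "left", "right", "left")
  M <- area_matrix(ds, parc, "across_hemi", n_iter = 3, seed = 1)
  Ms <- area_matrix(ds, swapped, "across_hemi", n_iter = 3, seed = 1)
  expect_equal(Ms$values, t(M$values), tolerance = 1e-12)
  g <- group_homotopic_pairs(M)
  gs <- group_homotopic_pairs(Ms)
  expect_equal(gs$r, g$r, tolerance = 1e-12)
})

test_that("phase-encoded simulation plants the phase it claims", {
  parc <- test_parc()
  fwd <- simulate_phase_encoded(parc, 8, "forward", lag_s = 0, snr = 1e8,
                                seed = 1, run_len = 160)
  # voxel response at t maximal where stimulus phase matches planted phase
  phi <- attr(fwd, "planted_phase")
  v <- which.max(parc$eccentricity_deg)
  tt <- (seq_len(160) - 1) * 2
  expected <- 1e8 * cos(2 * pi * tt / 40 - phi[v]) + 100
  expect_equal(unname(fwd$data[v, ]), expected, tolerance = 1e-6)

  rev <- simulate_phase_encoded(parc, 8, "reverse", lag_s = 0, snr = 1e8,
                                seed = 1, run_len = 160)
  pf <- fourier_phase_map(fwd, 8, lag_s = 0)
  pr <- fourier_phase_map(rev, 8, lag_s = 0)
  # reverse negates the phase progression
  expect_equal(Arg(exp(1i * (pf$phase_rad + pr$phase_rad))),
               rep(0, nrow(parc)), tolerance = 1e-6)
  expect_error(simulate_phase_encoded(parc, 8, lag_s = -1), "lag_s")
  expect_error(simulate_phase_encoded(parc, 1), "cycles_per_run")
})

test_that("block design: planted effects, zero effects, degenerate contrast", {
  parc <- test_parc()
  eff <- cbind(curved = 0.5 * (4 - parc$eccentricity_deg) / 4,
               rectilinear = 0)
  ds <- simulate_block_design(parc, c("curved", "rectilinear"), 20, eff,
                              seed = 1, n_runs = 2, run_len = 160,
                              noise_sd = 0.5)
  cr <- glm_contrast(ds, contrast = c(curved = 1, rectilinear = -1))
  # recovered contrast slope against eccentricity matches the plant
  sl <- coef(stats::lm(cr$beta_contrast ~ parc$eccentricity_deg))[2]
  expect_lt(abs(sl - (-0.125)), 0.02)

  z <- simulate_block_design(parc, c("a", "b"), 20, eff * 0, seed = 2,
                             n_runs = 1, run_len = 160)
  cz <- glm_contrast(z, contrast = c(a = 1, b = -1))
  expect_lt(abs(mean(cz$beta_contrast)), 0.05)

  expect_equal(glm_contrast(z, contrast = c(a = 1, b = -1))$beta_contrast -
                 cz$beta_contrast, rep(0, nrow(parc)))
  expect_error(simulate_block_design(parc, c("a", "b"), 19, eff),
               "multiple of tr_s")
  expect_error(simulate_block_design(parc, "a", 20, eff), "2 conditions")
})
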