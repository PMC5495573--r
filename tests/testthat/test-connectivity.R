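test_that("threshold conversions match their closed forms", {
  expect_equal(round(r_to_t(0.15, 1628), 2), 6.12)
  expect_equal(round(r_to_t(0.15, 1394), 2), 5.66)
  expect_equal(r_to_t(0, 50), 0)
  expect_error(r_to_t(1, 10), "\\|r\\|")
  expect_equal(round(t_critical(0.05, 782), 2), 1.96)
  expect_equal(round(t_critical(0.05, 1e6), 2), 1.96)
  dfs <- c(5, 20, 100, 1000)
  expect_true(all(diff(t_critical(0.05, dfs)) < 0))
  expect_error(t_critical(1.2, 10), "alpha")
})

test_that("BH mask: trivial cases and null selection rate", {
  expect_identical(fdr_mask(numeric(0), 0.05), logical(0))
  expect_true(all(fdr_mask(rep(0, 10), 0.05)))
  expect_true(fdr_mask(0.025, 0.05))
  set.seed(1)
  rates <- vapply(seq_len(100), function(i) {
    mean(fdr_mask(runif(1e4), 0.05))
  }, numeric(1))
  expect_lte(mean(rates), 0.05)
})

test_that("balanced subsampling: no-op for equal sizes, reproducible,
           matches exhaustive enumeration on a toy area", {
  parc <- test_parc()
  ds <- simulate_rest(parc, test_spec(), 1, 200, seed = 9)
  a1 <- area_mean_timeseries(ds, parc, "left", n_iter = 1, seed = 1)
  a100 <- area_mean_timeseries(ds, parc, "left", n_iter = 100, seed = 2)
  expect_equal(dim(a1)[3], 1)        # equal sizes: one iteration suffices
  expect_equal(dim(a100)[3], 1)
  expect_equal(a1, a100)

  # toy: area A has 6 voxels, area B has 3; compare the iteration average
  # against the exhaustive average over all C(6,3) = 20 subsamples
  set.seed(3)
  X <- matrix(rnorm(9 * 500), 9)
  X[1:6, ] <- X[1:6, ] + rep(rnorm(500), each = 6)   # shared signal in A
  ds2 <- fmri_dataset(X, run_lengths = 500)
  groups <- list(A = 1:6, B = 7:9)
  combos <- utils::combn(1:6, 3)
  r_exh <- mean(apply(combos, 2, function(ix) {
    cor(colMeans(X[ix, ]), colMeans(X[7:9, ]))
  }))
  mats <- protoconn:::subsample_group_means(ds2, groups, n_iter = 2000,
                                            seed = 4)
  r_iter <- mean(vapply(mats, function(m) cor(m[1, ], m[2, ]), numeric(1)))
  expect_lt(abs(r_iter - r_exh), 0.01)

  expect_error(area_mean_timeseries(ds, parc[0, ], "left"), "empty group")
})

test_that("area matrices: unit diagonal within, planted homotopy across,
           independence bound, NaN warning for constant series", {
  parc <- test_parc()
  ds <- simulate_rest(parc, test_spec(), 1, 600, seed = 10)
  W <- area_matrix(ds, parc, "within_hemi", hemi = "left", n_iter = 3,
                   seed = 1)
  expect_equal(unname(diag(W$values)), rep(1, 16))
  expect_equal(W$values, t(W$values), tolerance = 1e-12)
  expect_equal(W$df, 598L)
  expect_true(all(abs(W$values) <= 1))

  A <- area_matrix(ds, parc, "across_hemi", n_iter = 3, seed = 1)
  offdiag_mean <- (rowSums(A$values) - diag(A$values)) / 15
  expect_true(all(diag(A$values) > offdiag_mean))

  # independent latents stay within the sampling-error bound
  id <- coupling_spec(latent_cov = diag(336), noise_sd = 0, ar1 = 0)
  di <- simulate_rest(parc, id, 1, 5000, seed = 11)
  Ai <- area_matrix(di, parc, "across_hemi", n_iter = 1, seed = 1)
  off <- Ai$values[upper.tri(Ai$values)]
  expect_lt(max(abs(off)), 0.05)

  const <- ds
  const$data[parc$hemisphere == "left" & parc$area == "V1", ] <- 1
  expect_warning(area_matrix(const, parc, "within_hemi", n_iter = 1,
                             seed = 1), "constant")
})

test_that("area-voxel map identifies homotopic peaks and self-correlation", {
  parc <- test_parc()
  ds <- simulate_rest(parc, test_spec(), 1, 2000, seed = 12)
  # a voxel equal to a seed-area mean correlates at 1 with that area
  left_v1 <- which(parc$hemisphere == "left" & parc$area == "V1")
  right1 <- which(parc$hemisphere == "right")[1]
  ds$data[right1, ] <- colMeans(ds$data[left_v1, ])
  AV <- area_voxel_map(ds, parc, "left", n_iter = 1, seed = 1)
  expect_equal(unname(AV$values["V1", 1]), 1, tolerance = 1e-10)

  # planted data: peak column entries lie in the homotopic area
  AV2 <- area_voxel_map(simulate_rest(parc, test_spec(), 1, 2000, seed = 13),
                        parc, "left", n_iter = 3, seed = 1)
  peaks <- rownames(AV2$values)[apply(AV2$values, 2, which.max)]
  truth <- parc$area[match(as.integer(colnames(AV2$values)), parc$voxel_id)]
  expect_gt(mean(peaks == truth), 0.9)

  # white-noise voxel: all correlations small
  ds$data[right1 + 1, ] <- rnorm(ncol(ds$data))
  AV3 <- area_voxel_map(ds, parc, "left", n_iter = 1, seed = 1)
  expect_lt(max(abs(AV3$values[, 2])), 3 / sqrt(ncol(ds$data)))
})

test_that("pair grouping partitions the 136 unordered pairs", {
  parc <- test_parc()
  ds <- simulate_rest(parc, test_spec(), 1, 300, seed = 14)
  M <- area_matrix(ds, parc, "across_hemi", n_iter = 3, seed = 1)
  g <- group_homotopic_pairs(M)
  expect_equal(nrow(g), 136)
  expect_equal(sum(g$group == "homotopic"), 16)
  expect_equal(sum(g$group %in% c("adjacent", "distal")), 120)
  # symmetric matrix: grouping invariant to transposition
  Ms <- M; Ms$values <- (M$values + t(M$values)) / 2
  gs1 <- group_homotopic_pairs(Ms)
  Mt <- Ms; Mt$values <- t(Ms$values)
  gs2 <- group_homotopic_pairs(Mt)
  expect_equal(gs1$r, gs2$r)
})

test_that("relabeling areas permutes profile rows without changing values", {
  parc <- test_parc()
  ds <- simulate_rest(parc, test_spec(), 1, 300, seed = 15)
  W <- area_matrix(ds, parc, "within_hemi", hemi = "left", n_iter = 1,
                   seed = 1)
  A <- area_voxel_map(ds, parc, "left", n_iter = 1, seed = 1)
  pm <- areal_correlation_profile(W, A)
  perm <- sample(16)
  Wp <- W; Wp$values <- W$values[perm, perm]
  Wp$row_ids <- W$row_ids[perm]; Wp$col_ids <- W$col_ids[perm]
  Ap <- A; Ap$values <- A$values[perm, ]; Ap$row_ids <- A$row_ids[perm]
  pmp <- areal_correlation_profile(Wp, Ap)
  expect_equal(pmp$similarity, pm$similarity[perm, ], tolerance = 1e-12)
})

test_that("quadrant matrix shows the planted checkerboard and is 10 x 10", {
  parc <- test_parc()
  ds <- simulate_rest(parc, test_spec(), 1, 600, seed = 16)
  q <- quadrant_matrix(ds, parc, n_iter = 3, seed = 1)
  expect_equal(dim(q$matrix$values), c(10L, 10L))
  means <- tapply(q$groups$r, q$groups$correspondence, mean)
  expect_gt(means["corresponding"], means["non_corresponding"])

  # quadrant-blind latents: no corresponding/non-corresponding difference
  blind <- coupling_spec(quadrant_mismatch = 1)
  db <- simulate_rest(parc, blind, 1, 2000, seed = 17)
  qb <- quadrant_matrix(db, parc, n_iter = 3, seed = 1)
  mb <- tapply(qb$groups$r, qb$groups$correspondence, mean)
  expect_lt(abs(mb["corresponding"] - mb["non_corresponding"]),
            3 / sqrt(2000))

  bad_parc <- parc
  bad_parc$quadrant[bad_parc$area == "V1"] <- "none"
  expect_error(quadrant_matrix(ds, bad_parc), "quadrant")
})
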