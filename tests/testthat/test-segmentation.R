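test_that("nucleus segmentation recovers a noise-free sphere volume within 5%", {
  vox <- c(125, 40, 40)
  R <- 2000
  dims <- c(40L, 116L, 116L)
  ctr <- dims / 2
  ball <- ball_array(dims, ctr, R / vox)
  arr <- array(0, c(1L, dims))
  arr[1, , , ] <- ball * 100
  vol <- mc_volume(arr, "lamin", vox)
  nuc <- segment_nucleus(vol)
  vol_nm3 <- sum(nuc$mask) * prod(vox)
  expect_lt(abs(vol_nm3 - 4 / 3 * pi * R^3) / (4 / 3 * pi * R^3), 0.05)
})

test_that("degenerate channels fail segmentation with clear errors", {
  arr <- array(0, c(1, 8, 16, 16))
  vol <- mc_volume(arr, "lamin")
  expect_error(segment_nucleus(vol), "constant")
})

test_that("the larger of two disjoint nuclei is kept with a warning", {
  dims <- c(20L, 60L, 60L)
  big <- ball_array(dims, c(10, 18, 18), c(6, 12, 12))
  small <- ball_array(dims, c(10, 45, 45), c(3, 6, 6))
  arr <- array(0, c(1L, dims))
  arr[1, , , ] <- (big | small) * 100
  vol <- mc_volume(arr, "lamin", c(125, 40, 40))
  expect_warning(nuc <- segment_nucleus(vol), "discarding")
  # kept component sits where the big sphere is, not the small one
  expect_true(nuc$mask[10, 18, 18])
  expect_false(nuc$mask[10, 45, 45])
})

test_that("lamina surface extraction matches exhaustive small cases", {
  cube <- array(TRUE, c(3, 3, 3))
  s <- extract_lamina_surface(as_nucleus_mask(cube))
  expect_equal(nrow(s$coords), 26L)  # all but the center voxel

  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  s1 <- extract_lamina_surface(as_nucleus_mask(single))
  expect_equal(unname(s1$coords), matrix(c(2L, 2L, 2L), 1))
})

test_that("lamina surface equals the brute-force boundary oracle on random masks", {
  set.seed(42)
  for (i in 1:8) {
    m <- array(runif(16^3) < 0.4, c(16, 16, 16))
    s <- extract_lamina_surface(as_nucleus_mask(m))
    got <- array(FALSE, dim(m))
    got[s$coords] <- TRUE
    expect_identical(got, brute_surface(m))
  }
})

test_that("spot detection returns nothing on a signal-free channel", {
  p <- small_params(seed = 6)
  g <- generate_nucleus_volume(p)
  d <- dim(g$volume$data)
  arr <- array(0, c(2, d[2], d[3], d[4]))
  arr[1, , , ] <- get_channel(g$volume, "lamin")
  vol <- mc_volume(arr, c("lamin", "trf1"), g$volume$voxel_size_nm)
  nuc <- segment_nucleus(vol)
  sp <- detect_spots(vol, "trf1", nuc)
  expect_equal(nrow(sp), 0L)
})

test_that("two spots closer than the minimum radius merge into one detection", {
  vox <- c(125, 40, 40)
  dims <- c(24L, 80L, 80L)
  ctr_nm <- dims * vox / 2
  mk_ball <- function(arr3, ctr, r) {
    b <- ball_array(dims, ctr / vox + 0.5, r / vox)
    arr3[b] <- 100
    arr3
  }
  trf1 <- array(0, dims)
  trf1 <- mk_ball(trf1, ctr_nm + c(0, 0, -40), 150)
  trf1 <- mk_ball(trf1, ctr_nm + c(0, 0, 40), 150)  # 80 nm apart
  lamin <- array(0, dims)
  lamin[ball_array(dims, dims / 2, c(1200, 1400, 1400) / vox)] <- 100
  arr <- array(0, c(2, dims))
  arr[1, , , ] <- lamin; arr[2, , , ] <- trf1
  vol <- mc_volume(arr, c("lamin", "trf1"), vox)
  nuc <- segment_nucleus(vol)
  sp <- detect_spots(vol, "trf1", nuc)
  expect_equal(nrow(sp), 1L)
})

test_that("detected spots respect nucleus containment and geometry invariants", {
  p <- small_params(seed = 12)
  g <- generate_nucleus_volume(p)
  nuc <- segment_nucleus(g$volume)
  sp <- detect_spots(g$volume, "trf1", nuc)
  expect_gt(nrow(sp), 0L)
  voxels <- attr(sp, "voxels")
  for (i in seq_len(nrow(sp))) {
    vc <- voxels[[i]]
    expect_true(all(nuc$mask[vc]))           # member voxels inside nucleus
    ctr_vox <- c(sp$cz_nm[i], sp$cy_nm[i], sp$cx_nm[i]) /
      g$volume$voxel_size_nm + 0.5
    expect_true(all(ctr_vox >= apply(vc, 2, min) - 1e-9) &&
                  all(ctr_vox <= apply(vc, 2, max) + 1e-9))
    expect_gt(sp$equivalent_radius_nm[i], 0)
  }
})

test_that("LAP2 binarization recovers a binary pattern under mild noise", {
  p <- small_params(lap2_target_coverage = 0.15, seed = 13)
  g <- generate_nucleus_volume(p)
  # rebuild the true binary pattern from the recorded focus centers
  vox <- p$voxel_size_nm
  dims <- dim(g$volume$data)[-1]
  zc <- (seq_len(dims[1]) - 0.5) * vox[1]
  yc <- (seq_len(dims[2]) - 0.5) * vox[2]
  xc <- (seq_len(dims[3]) - 0.5) * vox[3]
  truth_bin <- array(FALSE, dims)
  for (i in seq_len(nrow(g$truth$lap2_focus_centers_nm)))
    truth_bin <- telolamina:::stamp_ball(truth_bin,
                                         g$truth$lap2_focus_centers_nm[i, ],
                                         p$lap2_focus_radius_nm, zc, yc, xc)
  arr <- dim(g$volume$data)
  data <- array(0, c(2, dims))
  data[1, , , ] <- get_channel(g$volume, "lamin")
  set.seed(1)
  data[2, , , ] <- pmax(truth_bin * 100 +
                          array(rnorm(prod(dims), 0, 5), dims), 0)
  vol <- mc_volume(data, c("lamin", "lap2a"), vox)
  nuc <- segment_nucleus(vol)
  m <- mask_lap2(vol, "lap2a", nuc)
  inter <- sum(m & truth_bin & nuc$mask)
  union <- sum((m | truth_bin) & nuc$mask)
  expect_gte(inter / union, 0.9)
})

test_that("quantile masking covers the requested fraction; constant channels error", {
  p <- small_params(seed = 14)
  g <- generate_nucleus_volume(p)
  nuc <- segment_nucleus(g$volume)
  m <- mask_lap2(g$volume, "lap2a", nuc, method = "quantile:0.5")
  frac <- sum(m) / sum(nuc$mask)
  expect_lt(abs(frac - 0.5), 0.01)

  d <- dim(g$volume$data)
  flat <- array(1, c(1, d[2], d[3], d[4]))
  vol2 <- mc_volume(flat, "lap2a", g$volume$voxel_size_nm)
  expect_error(mask_lap2(vol2, "lap2a", nuc), "constant")
})
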