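make_flat_section <- function(img, vox = c(125, 40, 40)) {
  # wrap a 2-D intensity image as a one-plane volume and project it
  arr <- array(0, c(1, 1, nrow(img), ncol(img)))
  arr[1, 1, , ] <- img
  vol <- mc_volume(arr, "lap2a", vox)
  project_section(vol, z_center_nm = vox[1] / 2, thickness_nm = vox[1])
}

test_that("section projection selects the planes forced by the slab arithmetic", {
  arr <- array(0, c(1, 20, 8, 8))
  for (z in 1:20) arr[1, z, , ] <- z
  vol <- mc_volume(arr, "trf1", c(125, 40, 40))

  # 544 nm slab centered on the 11th plane: offsets 0, ±125, ±250 nm fit
  s <- project_section(vol, z_center_nm = 10.5 * 125, thickness_nm = 544)
  expect_identical(s$planes, 9:13)
  expect_equal(section_channel(s, "trf1")[1, 1], mean(9:13))

  # 1 nm slab returns the single nearest plane unchanged
  s1 <- project_section(vol, z_center_nm = 10.5 * 125, thickness_nm = 1)
  expect_identical(s1$planes, 11L)
  expect_equal(section_channel(s1, "trf1"), arr[1, 11, , ])

  expect_error(project_section(vol, z_center_nm = 1e6, thickness_nm = 544),
               "outside")
})

test_that("projection of a constant volume is constant", {
  arr <- array(7, c(1, 10, 6, 6))
  vol <- mc_volume(arr, "lap2a")
  s <- project_section(vol, 5 * 125, 544)
  expect_true(all(section_channel(s, "lap2a") == 7))
})

test_that("radial profile of a uniform channel is constant", {
  s <- make_flat_section(matrix(3.5, 64, 64))
  mask <- matrix(TRUE, 64, 64)
  pr <- radial_profile(s, c(32 * 40, 32 * 40), "lap2a", mask)
  expect_equal(pr$distances_nm, seq(0, 400, 40))
  expect_equal(pr$raw_intensity, rep(3.5, 11), tolerance = 1e-12)
})

test_that("radial profile reproduces a centered disc step function", {
  n <- 64; dy <- 40
  ctr <- c(n / 2 * dy, n / 2 * dy)
  yc <- (seq_len(n) - 0.5) * dy
  disc <- outer((yc - ctr[1])^2, (yc - ctr[2])^2, "+") <= 200^2
  s <- make_flat_section(disc * 10)
  pr <- radial_profile(s, ctr, "lap2a", matrix(TRUE, n, n))
  expect_equal(pr$raw_intensity[pr$distances_nm <= 160], rep(10, 5),
               tolerance = 0.05)
  expect_lt(max(pr$raw_intensity[pr$distances_nm >= 280]), 0.5)
})

test_that("the eight-ray profile is invariant under a 90-degree rotation", {
  set.seed(5)
  n <- 64; d <- 40
  img <- matrix(runif(n * n), n, n)
  img <- telolamina:::blur3d(array(img, c(1, n, n)), c(0, 80, 80),
                             c(125, d, d))[1, , ]
  rot <- t(img)[, n:1]  # (y, x) -> (x, n - y + 1): +90 degree rotation
  ctr <- c(n / 2 * d, n / 2 * d)  # rotation fixed point
  mask <- matrix(TRUE, n, n)
  p1 <- radial_profile(make_flat_section(img), ctr, "lap2a", mask)
  p2 <- radial_profile(make_flat_section(rot), ctr, "lap2a", mask)
  expect_equal(p1$raw_intensity, p2$raw_intensity, tolerance = 1e-9)
})

test_that("rays truncate at the nucleus border instead of zero-filling", {
  n <- 64
  img <- matrix(5, n, n)
  mask <- matrix(FALSE, n, n)
  mask[, 1:32] <- TRUE  # nucleus occupies the left half
  ctr <- c(32 * 40, 30 * 40)
  pr <- radial_profile(make_flat_section(img), ctr, "lap2a", mask)
  # samples that survive truncation keep the uniform value
  expect_true(all(abs(pr$raw_intensity - 5) < 1e-9, na.rm = TRUE))
  # the rightward ray is cut: fewer contributing rays at 400 nm than at 0
  expect_lt(sum(!is.na(pr$ray_samples[, 11])), pr$n_rays)
  expect_error(radial_profile(make_flat_section(img), c(32 * 40, 50 * 40),
                              "lap2a", mask), "outside the nucleus")
})

test_that("normalization maps nucleus extremes to 0/1 and is affine-invariant", {
  s <- make_flat_section(matrix(runif(32 * 32), 32, 32))
  mask <- matrix(TRUE, 32, 32)
  pr <- radial_profile(s, c(16 * 40, 16 * 40), "lap2a", mask)

  hi <- normalize_profiles(list(pr), channel_min = min(pr$raw_intensity) - 1,
                           channel_max = max(pr$raw_intensity))[[1]]
  expect_true(all(hi$normalized_intensity <= 1 & hi$normalized_intensity >= 0))

  flat <- pr; flat$raw_intensity[] <- 4
  n0 <- normalize_profiles(list(flat), 4, 9)[[1]]
  expect_equal(n0$normalized_intensity, rep(0, 11))
  n1 <- normalize_profiles(list(flat), -1, 4)[[1]]
  expect_equal(n1$normalized_intensity, rep(1, 11))
  expect_error(normalize_profiles(list(pr), 2, 2), "degenerate")

  # affine transform of the channel leaves normalized profiles unchanged
  img <- section_channel(s, "lap2a")
  s2 <- make_flat_section(3 * img + 2)
  pr2 <- radial_profile(s2, c(16 * 40, 16 * 40), "lap2a", mask)
  rng <- range(img)
  a <- normalize_profiles(list(pr), rng[1], rng[2])[[1]]
  b <- normalize_profiles(list(pr2), 3 * rng[1] + 2, 3 * rng[2] + 2)[[1]]
  expect_equal(a$normalized_intensity, b$normalized_intensity,
               tolerance = 1e-12)
})

test_that("nucleus coverage is the exact section pixel ratio", {
  dims <- c(5L, 20L, 20L)
  nuc <- array(FALSE, dims); nuc[, 5:16, 5:16] <- TRUE
  lap2 <- array(FALSE, dims); lap2[, 5:16, 5:10] <- TRUE  # half the section
  vol <- mc_volume(array(1, c(1, dims)), "lap2a", c(125, 40, 40))
  s <- project_section(vol, 2.5 * 125, 5 * 125)
  nm <- as_nucleus_mask(nuc)
  expect_equal(nucleus_coverage(lap2, nm, s), 50)
  expect_equal(nucleus_coverage(array(FALSE, dims), nm, s), 0)
})

test_that("per-telomere coverage matches brute-force pixel intersection", {
  dims <- c(5L, 16L, 16L)
  vol <- mc_volume(array(1, c(1, dims)), "lap2a", c(125, 40, 40))
  s <- project_section(vol, 2.5 * 125, 5 * 125)

  mk_spot <- function(vox_list) {
    sp <- data.frame(spot_id = 1L, nucleus_id = 1L, cz_nm = 300, cy_nm = 300,
                     cx_nm = 300)
    attr(sp, "voxels") <- list(vox_list)
    class(sp) <- c("telomere_spots", "data.frame")
    sp
  }
  vx <- cbind(z = c(2L, 3L), y = c(4L, 5L), x = c(4L, 4L))
  all_in <- array(TRUE, dims)
  expect_equal(telomere_coverage(mk_spot(vx), all_in, s), 100)
  expect_equal(telomere_coverage(mk_spot(vx), array(FALSE, dims), s), 0)

  set.seed(8)
  for (i in 1:20) {
    lap2 <- array(runif(prod(dims)) < 0.5, dims)
    nvx <- sample(3:10, 1)
    vx <- cbind(z = sample(5, nvx, TRUE), y = sample(16, nvx, TRUE),
                x = sample(16, nvx, TRUE))
    got <- telomere_coverage(mk_spot(vx), lap2, s)
    proj <- apply(lap2, c(2, 3), any)
    pix <- unique(vx[, c("y", "x"), drop = FALSE])
    expect_equal(got, 100 * sum(proj[pix]) / nrow(pix))
  }
})

test_that("category assignment follows the printed worked example and brute force", {
  # worked example: nucleus LAP2c = 15.3%, telomere coverages 12.5/85/36/0
  rec <- categorize_telomeres(c(12.5, 85, 36, 0), lap2c_percent = 15.3,
                              sigma_percent = 10)
  expect_equal(as.character(rec$category), c("average", "high", "high", "low"))
  expect_equal(sum(attr(rec, "histogram")), 4L)

  # boundary values land in "average" (inclusive rule)
  b <- categorize_telomeres(c(8, 24), 16, 8)
  expect_equal(as.character(b$category), c("average", "average"))
  b2 <- categorize_telomeres(c(7.999, 24.001), 16, 8)
  expect_equal(as.character(b2$category), c("low", "high"))

  set.seed(3)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    cov <- runif(n, 0, 100)
    lap2c <- runif(1, 0, 40)
    sig <- runif(1, 0, 25)
    rec <- categorize_telomeres(cov, lap2c, sig)
    lo <- max(0, lap2c - sig); hi <- min(100, lap2c + sig)
    want <- ifelse(cov < lo, "low", ifelse(cov > hi, "high", "average"))
    expect_equal(as.character(rec$category), want)
    expect_equal(sum(attr(rec, "histogram")), n)
  }
})

test_that("lamina distances satisfy self-proximity and spherical geometry", {
  vox <- c(125, 40, 40)
  dims <- c(40L, 116L, 116L)
  R <- 2000
  # voxel index i has its center at (i - 0.5) * vox, so the sphere centered
  # at dims/2 * vox sits at index dims/2 + 0.5
  ball <- ball_array(dims, dims / 2 + 0.5, R / vox)
  nuc <- as_nucleus_mask(ball, vox)
  surf <- extract_lamina_surface(nuc)
  diag_nm <- sqrt(sum(vox^2))

  mk <- function(pt) {
    sp <- data.frame(spot_id = 1L, nucleus_id = 1L, cz_nm = pt[1],
                     cy_nm = pt[2], cx_nm = pt[3])
    class(sp) <- c("telomere_spots", "data.frame")
    sp
  }
  # centroid on a surface voxel center
  sv <- (surf$coords[1, ] - 0.5) * vox
  expect_lte(distance_to_lamina(mk(sv), surf)$distance_nm, diag_nm / 2)

  # sphere center is R from the surface, within a voxel diagonal
  ctr <- dims / 2 * vox
  d <- distance_to_lamina(mk(ctr), surf)$distance_nm
  expect_lt(abs(d - R), diag_nm)

  rec <- distance_to_lamina(mk(ctr), surf, threshold_nm = 250)
  expect_false(rec$within_threshold)
  expect_error(distance_to_lamina(
    mk(ctr), structure(list(coords = surf$coords[0, , drop = FALSE],
                            dim = dims, voxel_size_nm = vox),
                       class = "lamina_surface")), "empty")
})

test_that("profile aggregation reduces identical profiles exactly", {
  s <- make_flat_section(matrix(runif(32 * 32) + 1, 32, 32))
  mask <- matrix(TRUE, 32, 32)
  pr <- radial_profile(s, c(16 * 40, 16 * 40), "lap2a", mask)
  prs <- normalize_profiles(list(pr, pr, pr), 0, 3)
  agg <- aggregate_profiles(prs)
  expect_equal(agg$sem, rep(0, 11))
  expect_equal(agg$mean_norm, prs[[1]]$normalized_intensity)
  expect_equal(agg$n, rep(3L, 11))

  expect_error(aggregate_profiles(prs[1]), "at least 2")
  short <- prs[[1]]; short$distances_nm <- short$distances_nm[1:5]
  expect_error(aggregate_profiles(list(prs[[1]], short)), "mismatched")
})
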