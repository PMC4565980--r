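test_that("identical parameters and seed give bit-identical volumes and truth", {
  p <- small_params(seed = 7)
  g1 <- generate_nucleus_volume(p)
  g2 <- generate_nucleus_volume(p)
  expect_identical(g1$volume$data, g2$volume$data)
  expect_identical(g1$truth$telomere_centers_nm, g2$truth$telomere_centers_nm)
  expect_identical(g1$truth$lap2_focus_centers_nm,
                   g2$truth$lap2_focus_centers_nm)

  g3 <- generate_nucleus_volume(small_params(seed = 8))
  expect_false(identical(g1$volume$data, g3$volume$data))
})

test_that("zero offset puts every associated LAP2 focus on its telomere", {
  p <- small_params(lap2_offset_nm = 0, lap2_association_fraction = 1,
                    seed = 2)
  g <- generate_nucleus_volume(p)
  asg <- g$truth$telomere_to_lap2_assignment
  expect_true(all(!is.na(asg)))
  expect_equal(g$truth$lap2_focus_centers_nm[asg, ],
               unname(g$truth$telomere_centers_nm), ignore_attr = TRUE)
})

test_that("peripheral placement constraint bounds the true lamina distances", {
  p <- small_params(lamina_fraction = 1, lamina_proximity_nm = 250, seed = 4)
  g <- generate_nucleus_volume(p)
  expect_true(all(g$truth$telomere_lamina_distance_nm <= 250))

  # infeasible constraint fails after the attempt cap, naming the constraint
  bad <- small_params(lamina_fraction = 1, lamina_proximity_nm = 0.01,
                      seed = 4)
  expect_error(sample_telomere_centers(bad), "1000 attempts")
})

test_that("recorded lamina distances equal the analytic point-to-surface distance", {
  p <- small_params(seed = 11)
  g <- generate_nucleus_volume(p)
  rel <- sweep(g$truth$telomere_centers_nm, 2, g$truth$nucleus_center_nm)
  d <- point_to_ellipsoid_surface_distance(rel, p$nucleus_radii_nm)
  expect_equal(g$truth$telomere_lamina_distance_nm, d, tolerance = 1e-9)
})

test_that("ellipsoid surface distance matches closed form and optimization oracle", {
  # sphere: closed form R - |p|
  pts <- matrix(rnorm(30), 10, 3) * 800
  expect_equal(point_to_ellipsoid_surface_distance(pts, c(2000, 2000, 2000)),
               abs(2000 - sqrt(rowSums(pts^2))), tolerance = 1e-9)

  # general ellipsoid: minimize distance over a surface parameterization
  radii <- c(1500, 3000, 2200)
  oracle <- function(p) {
    obj <- function(a) {
      s <- c(radii[1] * sin(a[1]),
             radii[2] * cos(a[1]) * sin(a[2]),
             radii[3] * cos(a[1]) * cos(a[2]))
      sqrt(sum((s - p)^2))
    }
    best <- Inf
    for (t0 in seq(-1.2, 1.2, length.out = 5))
      for (f0 in seq(0, 2 * pi, length.out = 7)) {
        r <- optim(c(t0, f0), obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-14, maxit = 5000))
        best <- min(best, r$value)
      }
    best
  }
  set.seed(1)
  pts <- runif_pts <- matrix(rnorm(15), 5, 3)
  pts <- pts / sqrt(rowSums(pts^2)) * runif(5)^(1 / 3)
  pts <- sweep(pts, 2, radii, "*")  # uniform inside the ellipsoid
  d <- point_to_ellipsoid_surface_distance(pts, radii)
  d_oracle <- apply(pts, 1, oracle)
  expect_equal(d, d_oracle, tolerance = 1e-5)
})

test_that("coverage targeting reaches the requested binary section coverage", {
  for (target in c(0.08, 0.157)) {
    p <- small_params(lap2_target_coverage = target,
                      noise = list(poisson_scale = 0, gaussian_sd = 0),
                      seed = 5)
    g <- generate_nucleus_volume(p)
    expect_gte(g$truth$true_nucleus_coverage_fraction, target)
    expect_lte(g$truth$true_nucleus_coverage_fraction, target + 0.02)
  }
})

test_that("mean telomere-to-nearest-LAP2-focus distance increases with the offset", {
  mean_nearest <- function(offset) {
    p <- small_params(lap2_offset_nm = offset, lap2_target_coverage = NA,
                      lap2_background_foci = 10, seed = 9)
    g <- generate_nucleus_volume(p)
    tel <- g$truth$telomere_centers_nm
    foci <- g$truth$lap2_focus_centers_nm
    mean(apply(tel, 1, function(t)
      min(sqrt(rowSums(sweep(foci, 2, t)^2)))))
  }
  d <- vapply(c(0, 100, 200, 300), mean_nearest, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("intensity field hits degenerate and null correlation targets", {
  f1 <- generate_intensity_field(10, target_r = -1, noise_sd = 0, seed = 3)
  expect_equal(cor(f1$truth$mean_a, f1$truth$mean_b), -1, tolerance = 1e-9)

  f0 <- generate_intensity_field(500, target_r = 0, noise_sd = 0, seed = 3)
  expect_lt(abs(cor(f0$truth$mean_a, f0$truth$mean_b)), 3 / sqrt(500))

  expect_error(generate_intensity_field(2, target_r = 0), "n_nuclei >= 3")
  expect_error(generate_intensity_field(50, 0, canvas_px = c(30, 30)),
               "canvas too small")
})
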