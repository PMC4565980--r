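## Synthetic 3D-SIM volume generator with known ground truth.
## Emulates the structures the analysis quantifies: an ellipsoidal nucleus
## wrapped in a thin lamina shell, punctate TRF1 telomere foci, a granular
## nucleoplasmic LAP2alpha texture whose foci sit at a controlled offset from
## telomere centers, Gaussian PSF blur and Poisson+Gaussian noise.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Parameters for the synthetic nucleus generator
#'
#' Defaults describe a modest flattened fibroblast-like nucleus imaged with
#' 3D-SIM-like sampling: 125 nm z-step, 40 nm lateral pitch, PSF sigma
#' (130, 50, 50) nm (about 120 nm lateral / 300 nm axial FWHM).
#'
#' @param nucleus_radii_nm ellipsoid semi-axes \code{(rz, ry, rx)} in nm.
#' @param lamina_thickness_nm thickness of the lamina shell, nm.
#' @param n_telomeres number of TRF1 foci.
#' @param lamina_fraction fraction of telomeres constrained to lie within
#'   \code{lamina_proximity_nm} of the nuclear surface (the rest are placed
#'   farther away). \code{NA} (default) places all telomeres uniformly over
#'   the nucleus volume.
#' @param lamina_proximity_nm proximity criterion for peripheral placement,
#'   nm (default 250, the conventional lamina-association cutoff).
#' @param min_spot_separation_nm minimum pairwise telomere separation, nm.
#' @param lap2_offset_nm distance from a telomere center to its associated
#'   LAP2alpha focus; 0 emulates wild-type-like tight association, 360-400
#'   emulates the HGPS-like displaced association. Applied in-plane (xy)
#'   along one of the eight 45-degree azimuths of the radial-profiling
#'   protocol, chosen uniformly at random, so that the offset is exactly the
#'   displacement the projected profiles measure.
#' @param lap2_association_fraction fraction of telomeres given an associated
#'   LAP2alpha focus.
#' @param lap2_background_foci number of unassociated nucleoplasmic
#'   LAP2alpha foci, used only when \code{lap2_target_coverage} is \code{NA}.
#' @param lap2_target_coverage target fraction of the projected nucleus
#'   section covered by the binary LAP2alpha pattern; background foci are
#'   added until it is reached. \code{NA} disables coverage targeting.
#' @param lap2_focus_radius_nm radius of each LAP2alpha focus, nm (default
#'   80, i.e. ~160 nm diameter, the scale of a SIM-resolved nucleoplasmic
#'   focus; structures much larger than the telomere-LAP2alpha displacement
#'   could not resolve it in a radial profile).
#' @param spot_radius_nm radius of each TRF1 focus, nm.
#' @param psf_sigma_nm Gaussian PSF sigma \code{(sz, sy, sx)}, nm.
#' @param noise list with \code{poisson_scale} (photons per intensity unit;
#'   0 disables shot noise) and \code{gaussian_sd} (additive read noise).
#' @param amplitude peak intensity (arbitrary units) of the binary structures
#'   before blur.
#' @param voxel_size_nm voxel spacing \code{(dz, dy, dx)}, nm.
#' @param section_thickness_nm thickness of the central section used for
#'   coverage targeting (matches the analysis default of 544 nm).
#' @param margin_voxels empty margin around the nucleus, voxels per side.
#' @param seed integer RNG seed; identical parameters and seed give
#'   bit-identical output.
#' @return validated parameter list of class \code{synthetic_params}.
#' @export
synthetic_params <- function(nucleus_radii_nm = c(1500, 3000, 3000),
                             lamina_thickness_nm = 120,
                             n_telomeres = 85,
                             lamina_fraction = NA,
                             lamina_proximity_nm = 250,
                             min_spot_separation_nm = 400,
                             lap2_offset_nm = 0,
                             lap2_association_fraction = 0.6,
                             lap2_background_foci = 40,
                             lap2_target_coverage = 0.157,
                             lap2_focus_radius_nm = 80,
                             spot_radius_nm = 150,
                             psf_sigma_nm = c(130, 50, 50),
                             noise = list(poisson_scale = 1, gaussian_sd = 1),
                             amplitude = 100,
                             voxel_size_nm = c(125, 40, 40),
                             section_thickness_nm = 544,
                             margin_voxels = 4,
                             seed = 1) {
  p <- list(nucleus_radii_nm = as.numeric(nucleus_radii_nm),
            lamina_thickness_nm = lamina_thickness_nm,
            n_telomeres = as.integer(n_telomeres),
            lamina_fraction = lamina_fraction,
            lamina_proximity_nm = lamina_proximity_nm,
            min_spot_separation_nm = min_spot_separation_nm,
            lap2_offset_nm = lap2_offset_nm,
            lap2_association_fraction = lap2_association_fraction,
            lap2_background_foci = as.integer(lap2_background_foci),
            lap2_target_coverage = lap2_target_coverage,
            lap2_focus_radius_nm = lap2_focus_radius_nm,
            spot_radius_nm = spot_radius_nm,
            psf_sigma_nm = as.numeric(psf_sigma_nm),
            noise = noise, amplitude = amplitude,
            voxel_size_nm = as.numeric(voxel_size_nm),
            section_thickness_nm = section_thickness_nm,
            margin_voxels = as.integer(margin_voxels),
            seed = as.integer(seed))
  stopifnot(length(p$nucleus_radii_nm) == 3, all(p$nucleus_radii_nm > 0),
            p$lamina_thickness_nm > 0, p$n_telomeres >= 1,
            p$lamina_proximity_nm > 0, p$min_spot_separation_nm >= 0,
            p$lap2_offset_nm >= 0,
            p$lap2_association_fraction >= 0, p$lap2_association_fraction <= 1,
            p$lap2_background_foci >= 0,
            is.na(p$lap2_target_coverage) ||
              (p$lap2_target_coverage >= 0 && p$lap2_target_coverage <= 1),
            p$lap2_focus_radius_nm > 0, p$spot_radius_nm > 0,
            length(p$psf_sigma_nm) == 3, all(p$psf_sigma_nm >= 0),
            p$noise$poisson_scale >= 0, p$noise$gaussian_sd >= 0,
            length(p$voxel_size_nm) == 3, all(p$voxel_size_nm > 0),
            p$margin_voxels >= 2)
  if (!is.na(p$lamina_fraction) &&
      (p$lamina_fraction < 0 || p$lamina_fraction > 1))
    stop("lamina_fraction must be in [0, 1] or NA")
  class(p) <- "synthetic_params"
  p
}

#' Exact distance from points to the surface of an axis-aligned ellipsoid
#'
#' Computes, for each row of \code{p} (coordinates relative to the ellipsoid
#' center, order \code{(z, y, x)}), the Euclidean distance to the ellipsoid
#' surface with semi-axes \code{radii}. Works for interior and exterior
#' points. Spheres use the closed form; the general case solves the
#' Lagrange-parameter equation by safeguarded root finding (components below
#' 1e-7 nm in magnitude are nudged to 1e-7 to keep the bracket well posed,
#' bounding the error well under 1e-6 nm).
#'
#' @param p numeric matrix (n x 3) or length-3 vector, nm.
#' @param radii semi-axes \code{(rz, ry, rx)}, nm.
#' @return numeric vector of distances, nm.
#' @export
point_to_ellipsoid_surface_distance <- function(p, radii) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  radii <- as.numeric(radii)
  if (diff(range(radii)) < 1e-12 * max(radii)) {
    return(abs(radii[1] - sqrt(rowSums(p^2))))
  }
  a2 <- radii^2
  amin2 <- min(a2)
  one <- function(pi) {
    pi <- ifelse(abs(pi) < 1e-7, 1e-7, pi)
    g <- function(t) sum((radii * pi)^2 / (a2 + t)^2) - 1
    if (g(0) > 0) {            # exterior point: root in (0, inf)
      hi <- max(a2)
      while (g(hi) > 0) hi <- hi * 2
      lo <- 0
    } else {                   # interior: root in (-amin2, 0)
      lo <- NA
      for (k in 3:15) {
        cand <- -amin2 * (1 - 10^(-k))
        if (g(cand) > 0) { lo <- cand; break }
      }
      if (is.na(lo)) lo <- -amin2 * (1 - 1e-15)
      hi <- 0
    }
    t <- uniroot(g, c(lo, hi), tol = 1e-13 * amin2)$root
    sqrt(sum((t * pi / (a2 + t))^2))
  }
  vapply(seq_len(nrow(p)), function(i) one(p[i, ]), numeric(1))
}

# Uniform samples inside an axis-aligned ellipsoid centered at origin,
# returned as n x 3 matrix (z, y, x) in nm.
runif_ellipsoid <- function(n, radii) {
  g <- matrix(rnorm(3 * n), n, 3)
  g <- g / sqrt(rowSums(g^2))
  r <- runif(n)^(1 / 3)
  sweep(g * r, 2, radii, "*")
}

#' Sample telomere center positions for the synthetic generator
#'
#' Rejection-samples telomere centers uniformly inside the nucleus ellipsoid,
#' optionally constraining a fraction to lie within (and the remainder
#' beyond) \code{lamina_proximity_nm} of the nuclear surface, and enforcing a
#' minimum pairwise separation. Positions are relative to the nucleus center.
#'
#' @param params a \code{\link{synthetic_params}} object.
#' @param seed RNG seed; defaults to \code{params$seed}.
#' @return list with \code{centers_nm} (n x 3 matrix, \code{(z, y, x)} nm
#'   relative to the nucleus center) and \code{lamina_distance_nm} (analytic
#'   distance of each center to the nuclear surface).
#' @export
sample_telomere_centers <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "synthetic_params"))
  with_seed(seed, {
    n <- params$n_telomeres
    radii <- params$nucleus_radii_nm
    prox <- params$lamina_proximity_nm
    sep <- params$min_spot_separation_nm
    n_near <- if (is.na(params$lamina_fraction)) 0L
      else as.integer(round(params$lamina_fraction * n))
    centers <- matrix(NA_real_, n, 3)
    dists <- numeric(n)
    for (i in seq_len(n)) {
      constraint <- if (is.na(params$lamina_fraction)) "none"
        else if (i <= n_near) "near" else "far"
      placed <- FALSE
      for (attempt in seq_len(1000L)) {
        cand <- runif_ellipsoid(1, radii)
        d <- point_to_ellipsoid_surface_distance(cand, radii)
        if (constraint == "near" && d > prox) next
        if (constraint == "far" && d <= prox) next
        if (i > 1L && sep > 0) {
          prev <- centers[seq_len(i - 1L), , drop = FALSE]
          if (min(sqrt(rowSums(sweep(prev, 2, cand[1, ])^2))) < sep) next
        }
        centers[i, ] <- cand
        dists[i] <- d
        placed <- TRUE
        break
      }
      if (!placed)
        stop("telomere placement failed after 1000 attempts (constraint: ",
             constraint, " lamina proximity ", prox, " nm, min separation ",
             sep, " nm)")
    }
    colnames(centers) <- c("z", "y", "x")
    list(centers_nm = centers, lamina_distance_nm = dists)
  })
}

# Stamp a solid ball (radius nm) into a logical 3-D array; coords of voxel
# centers given by zc/yc/xc (nm). Returns modified array.
stamp_ball <- function(mask, center, radius, zc, yc, xc) {
  iz <- which(abs(zc - center[1]) <= radius)
  iy <- which(abs(yc - center[2]) <= radius)
  ix <- which(abs(xc - center[3]) <= radius)
  if (!length(iz) || !length(iy) || !length(ix)) return(mask)
  dz2 <- (zc[iz] - center[1])^2
  dy2 <- (yc[iy] - center[2])^2
  dx2 <- (xc[ix] - center[3])^2
  sub <- outer(outer(dz2, dy2, "+"), dx2, "+") <= radius^2
  mask[iz, iy, ix] <- mask[iz, iy, ix, drop = FALSE] | sub
  mask
}

apply_noise <- function(arr, noise) {
  if (noise$poisson_scale > 0) {
    lam <- pmax(arr * noise$poisson_scale, 0)
    arr <- array(rpois(length(lam), lam) / noise$poisson_scale, dim(arr))
  }
  if (noise$gaussian_sd > 0)
    arr <- arr + array(rnorm(length(arr), 0, noise$gaussian_sd), dim(arr))
  pmax(arr, 0)
}

#' Generate a synthetic three-channel nucleus volume with ground truth
#'
#' Builds a calibrated volume with channels \code{lamin} (thin shell on the
#' ellipsoid boundary), \code{trf1} (blurred spheres at telomere centers) and
#' \code{lap2a} (blurred foci: one per associated telomere, displaced by
#' \code{lap2_offset_nm} in a random in-plane direction, plus nucleoplasmic
#' background foci added until the binary LAP2alpha pattern covers
#' approximately \code{lap2_target_coverage} of the projected central
#' nucleus section). PSF blur and Poisson+Gaussian noise are applied last;
#' ground truth records the pre-blur geometry.
#'
#' @param params a \code{\link{synthetic_params}} object.
#' @return list with \code{volume} (an \code{\link{mc_volume}}) and
#'   \code{truth} (class \code{synthetic_truth}: telomere centers in absolute
#'   nm grid coordinates, analytic telomere-to-lamina distances, LAP2alpha
#'   focus centers, the telomere-to-focus assignment, and the achieved
#'   binary coverage fraction).
#' @export
generate_nucleus_volume <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  vox <- params$voxel_size_nm
  radii <- params$nucleus_radii_nm
  m <- params$margin_voxels
  dims <- c(2L * (as.integer(ceiling(radii[1] / vox[1])) + m),
            2L * (as.integer(ceiling(radii[2] / vox[2])) + m),
            2L * (as.integer(ceiling(radii[3] / vox[3])) + m))
  center <- dims * vox / 2
  zc <- (seq_len(dims[1]) - 0.5) * vox[1]
  yc <- (seq_len(dims[2]) - 0.5) * vox[2]
  xc <- (seq_len(dims[3]) - 0.5) * vox[3]

  nz2 <- ((zc - center[1]) / radii[1])^2
  ny2 <- ((yc - center[2]) / radii[2])^2
  nx2 <- ((xc - center[3]) / radii[3])^2
  m2 <- outer(outer(nz2, ny2, "+"), nx2, "+")
  nucleus <- m2 <= 1
  rin <- pmax(radii - params$lamina_thickness_nm, radii * 0.01)
  m2i <- outer(outer(((zc - center[1]) / rin[1])^2,
                     ((yc - center[2]) / rin[2])^2, "+"),
               ((xc - center[3]) / rin[3])^2, "+")
  lamin_bin <- nucleus & (m2i > 1)

  placement <- sample_telomere_centers(params)
  tel <- sweep(placement$centers_nm, 2, center, "+")  # absolute grid nm

  # remaining stochastic choices continue from a generator-derived stream
  res <- with_seed(params$seed + 1L, {
    trf1_bin <- array(FALSE, dims)
    for (i in seq_len(nrow(tel)))
      trf1_bin <- stamp_ball(trf1_bin, tel[i, ], params$spot_radius_nm, zc, yc, xc)

    inside <- function(pt) {
      sum(((pt - center) / radii)^2) <= 1
    }

    sig_vox <- params$psf_sigma_nm / vox
    fr <- params$lap2_focus_radius_nm
    # LAP2 foci render additively: each focus contributes a PSF-blurred ball
    # patch (fluorophore density is additive where foci overlap)
    lap2_channel <- array(0, dims)
    add_focus <- function(channel, pt) {
      ext <- fr + 3 * params$psf_sigma_nm
      iz <- which(abs(zc - pt[1]) <= ext[1])
      iy <- which(abs(yc - pt[2]) <= ext[2])
      ix <- which(abs(xc - pt[3]) <= ext[3])
      if (!length(iz) || !length(iy) || !length(ix)) return(channel)
      sub <- outer(outer((zc[iz] - pt[1])^2, (yc[iy] - pt[2])^2, "+"),
                   (xc[ix] - pt[3])^2, "+") <= fr^2
      patch <- array(as.numeric(sub) * params$amplitude,
                     c(length(iz), length(iy), length(ix)))
      if (any(sig_vox > 0))
        patch <- array(cpp_gauss_blur3d(patch, dim(patch), sig_vox),
                       dim(patch))
      channel[iz, iy, ix] <- channel[iz, iy, ix, drop = FALSE] + patch
      channel
    }

    n <- params$n_telomeres
    n_assoc <- as.integer(round(params$lap2_association_fraction * n))
    assoc_idx <- if (n_assoc > 0) sort(sample.int(n, n_assoc)) else integer(0)
    lap2_centers <- matrix(numeric(0), 0, 3)
    assignment <- rep(NA_integer_, n)
    for (i in assoc_idx) {
      if (params$lap2_offset_nm == 0) {
        pt <- tel[i, ]
      } else {
        pt <- NULL
        for (attempt in seq_len(1000L)) {
          # azimuth drawn from the eight 45-degree directions of the radial
          # profiling protocol, so the offset is measured without angular
          # discretization bias
          phi <- (sample.int(8L, 1L) - 1L) * pi / 4
          cand <- tel[i, ] + params$lap2_offset_nm * c(0, sin(phi), cos(phi))
          if (inside(cand)) { pt <- cand; break }
        }
        if (is.null(pt))
          stop("LAP2a focus placement failed after 1000 attempts ",
               "(offset ", params$lap2_offset_nm, " nm leaves the nucleus)")
      }
      lap2_centers <- rbind(lap2_centers, pt)
      assignment[i] <- nrow(lap2_centers)
      lap2_channel <- add_focus(lap2_channel, pt)
    }

    # central-section geometry used for coverage calibration
    half <- params$section_thickness_nm / 2
    planes <- which(abs(zc - center[1]) <= half)
    if (!length(planes)) planes <- which.min(abs(zc - center[1]))
    nuc_proj <- apply(nucleus[planes, , , drop = FALSE], c(2, 3), any)
    nuc_area <- sum(nuc_proj)
    # the coverage the analysis itself would measure on the noise-free
    # rendering: Otsu binarization inside the nucleus, max-projected over
    # the section planes
    measured_cov <- function(channel) {
      vals <- channel[nucleus]
      if (max(vals) <= min(vals)) return(0)
      thr <- otsu_threshold(vals)
      slab <- channel[planes, , , drop = FALSE]
      dim(slab) <- c(length(planes), dims[2], dims[3])
      proj <- apply(slab, c(2, 3), max)
      sum(proj > thr & nuc_proj) / nuc_area
    }

    if (is.na(params$lap2_target_coverage)) {
      if (params$lap2_background_foci > 0) {
        bg <- sweep(runif_ellipsoid(params$lap2_background_foci, radii), 2,
                    center, "+")
        for (i in seq_len(nrow(bg))) {
          lap2_channel <- add_focus(lap2_channel, bg[i, ])
          lap2_centers <- rbind(lap2_centers, bg[i, ])
        }
      }
      true_cov <- measured_cov(lap2_channel)
    } else {
      target <- params$lap2_target_coverage
      cov <- measured_cov(lap2_channel)
      n_bg <- 0L
      batch <- 10L
      while (cov < target) {
        if (n_bg >= 20000L)
          stop("cannot reach lap2_target_coverage = ", target,
               " (reached ", round(cov, 4), ")")
        snap_channel <- lap2_channel
        snap_centers <- lap2_centers
        snap_n <- n_bg
        pts <- sweep(runif_ellipsoid(batch, radii), 2, center, "+")
        for (i in seq_len(batch)) {
          lap2_channel <- add_focus(lap2_channel, pts[i, ])
          lap2_centers <- rbind(lap2_centers, pts[i, ])
        }
        n_bg <- n_bg + batch
        cov <- measured_cov(lap2_channel)
        if (cov >= target) {
          # roll back and advance focus-by-focus: overshoot is then at most
          # one focus's worth of coverage
          lap2_channel <- snap_channel
          lap2_centers <- snap_centers
          n_bg <- snap_n
          for (i in seq_len(batch)) {
            lap2_channel <- add_focus(lap2_channel, pts[i, ])
            lap2_centers <- rbind(lap2_centers, pts[i, ])
            n_bg <- n_bg + 1L
            cov <- measured_cov(lap2_channel)
            if (cov >= target) break
          }
        }
      }
      true_cov <- cov
    }

    blur <- function(b) {
      arr <- array(as.numeric(b) * params$amplitude, dims)
      if (any(sig_vox > 0))
        arr <- array(cpp_gauss_blur3d(arr, dims, sig_vox), dims)
      arr
    }
    lamin_ch <- apply_noise(blur(lamin_bin), params$noise)
    lap2_ch <- apply_noise(lap2_channel, params$noise)
    trf1_ch <- apply_noise(blur(trf1_bin), params$noise)

    data <- array(0, c(3L, dims))
    data[1, , , ] <- lamin_ch
    data[2, , , ] <- lap2_ch
    data[3, , , ] <- trf1_ch
    rownames(lap2_centers) <- NULL
    list(data = data, lap2_centers = lap2_centers, assignment = assignment,
         true_cov = true_cov, planes = planes)
  })

  volume <- mc_volume(res$data, c("lamin", "lap2a", "trf1"), vox)
  truth <- structure(
    list(telomere_centers_nm = tel,
         telomere_lamina_distance_nm = placement$lamina_distance_nm,
         lap2_focus_centers_nm = res$lap2_centers,
         telomere_to_lap2_assignment = res$assignment,
         true_nucleus_coverage_fraction = res$true_cov,
         nucleus_center_nm = center,
         nucleus_radii_nm = radii,
         section_planes = res$planes),
    class = "synthetic_truth")
  list(volume = volume, truth = truth)
}

#' Generate a 2-D multichannel field of nuclei with programmed intensities
#'
#' Places \code{n_nuclei} non-overlapping elliptical nuclei on a jittered
#' grid and fills two stain channels with per-nucleus mean intensities drawn
#' from a bivariate normal with correlation \code{target_r}; a \code{dapi}
#' channel marks the nuclei for segmentation. A border of one grid cell
#' keeps nuclei away from the image edge.
#'
#' @param n_nuclei number of nuclei (at least 3).
#' @param target_r target Pearson correlation of the per-nucleus mean
#'   intensities, in \code{[-1, 1]}.
#' @param noise_sd per-pixel additive Gaussian noise SD.
#' @param seed RNG seed.
#' @param mean_intensity mean of each stain's per-nucleus intensity.
#' @param sd_intensity SD of each stain's per-nucleus intensity.
#' @param radius_px_range range of ellipse semi-axes in pixels.
#' @param px_size_nm pixel pitch, nm (calibration only).
#' @param canvas_px optional \code{(ny, nx)} canvas size; an error is raised
#'   when the requested nuclei cannot be placed without overlap on it.
#' @return list with \code{field} (an \code{mc_volume} with channels
#'   \code{dapi}, \code{stain_a}, \code{stain_b} and a single z-plane) and
#'   \code{truth} (data.frame of true per-nucleus mean intensities and
#'   geometry).
#' @export
generate_intensity_field <- function(n_nuclei, target_r, noise_sd = 0,
                                     seed = 1, mean_intensity = c(100, 100),
                                     sd_intensity = 15,
                                     radius_px_range = c(6, 10),
                                     px_size_nm = 100, canvas_px = NULL) {
  stopifnot(n_nuclei >= 3, target_r >= -1, target_r <= 1, noise_sd >= 0)
  with_seed(seed, {
    rmax <- radius_px_range[2]
    cell <- 2L * as.integer(ceiling(rmax)) + 4L
    ncol_g <- as.integer(ceiling(sqrt(n_nuclei)))
    nrow_g <- as.integer(ceiling(n_nuclei / ncol_g))
    ny <- (nrow_g + 2L) * cell
    nx <- (ncol_g + 2L) * cell
    if (!is.null(canvas_px)) {
      if (canvas_px[1] < ny || canvas_px[2] < nx)
        stop("canvas too small for non-overlapping placement of ", n_nuclei,
             " nuclei (need at least ", ny, " x ", nx, " px)")
      ny <- canvas_px[1]; nx <- canvas_px[2]
    }

    z1 <- rnorm(n_nuclei); z2 <- rnorm(n_nuclei)
    mean_a <- mean_intensity[1] + sd_intensity * z1
    mean_b <- mean_intensity[2] +
      sd_intensity * (target_r * z1 + sqrt(max(0, 1 - target_r^2)) * z2)

    dapi <- matrix(0, ny, nx)
    sa <- matrix(0, ny, nx)
    sb <- matrix(0, ny, nx)
    truth <- data.frame(nucleus_id = seq_len(n_nuclei), cy_px = NA_real_,
                        cx_px = NA_real_, ry_px = NA_real_, rx_px = NA_real_,
                        mean_a = mean_a, mean_b = mean_b)
    for (i in seq_len(n_nuclei)) {
      gy <- (i - 1L) %/% ncol_g + 1L
      gx <- (i - 1L) %% ncol_g + 1L
      ry <- runif(1, radius_px_range[1], radius_px_range[2])
      rx <- runif(1, radius_px_range[1], radius_px_range[2])
      jy <- runif(1, -(cell / 2 - ry - 1), cell / 2 - ry - 1)
      jx <- runif(1, -(cell / 2 - rx - 1), cell / 2 - rx - 1)
      cy <- (gy + 0.5) * cell + jy
      cx <- (gx + 0.5) * cell + jx
      ys <- max(1L, floor(cy - ry)):min(ny, ceiling(cy + ry))
      xs <- max(1L, floor(cx - rx)):min(nx, ceiling(cx + rx))
      ell <- outer(((ys - cy) / ry)^2, ((xs - cx) / rx)^2, "+") <= 1
      dapi[ys, xs][ell] <- 100
      sa[ys, xs][ell] <- mean_a[i]
      sb[ys, xs][ell] <- mean_b[i]
      truth$cy_px[i] <- cy; truth$cx_px[i] <- cx
      truth$ry_px[i] <- ry; truth$rx_px[i] <- rx
    }
    if (noise_sd > 0) {
      sa <- sa + matrix(rnorm(ny * nx, 0, noise_sd), ny, nx)
      sb <- sb + matrix(rnorm(ny * nx, 0, noise_sd), ny, nx)
      dapi <- dapi + matrix(rnorm(ny * nx, 0, noise_sd), ny, nx)
    }
    data <- array(0, c(3L, 1L, ny, nx))
    data[1, 1, , ] <- pmax(dapi, 0)
    data[2, 1, , ] <- pmax(sa, 0)
    data[3, 1, , ] <- pmax(sb, 0)
    field <- mc_volume(data, c("dapi", "stain_a", "stain_b"),
                       c(1, px_size_nm, px_size_nm))
    list(field = field, truth = truth)
  })
}
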