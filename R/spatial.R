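## Core spatial statistics: projected sections, eight-ray radial LAP2alpha
## profiles around telomeres, surface-coverage statistics with three-category
## classification, and anisotropy-aware telomere-to-lamina distances.
##
## "Surface" quantities (nucleus coverage, per-telomere coverage) are
## computed on projected 2-D sections; lamina distances are computed in full
## 3-D, mirroring the mixed 2-D/3-D methodology of SIM image analysis.

#' Project a slab of z-planes into a 2-D multichannel section
#'
#' Mean-intensity projection of all z-planes whose centers lie within
#' \code{z_center_nm +/- thickness_nm / 2}. With the default 125 nm z-step,
#' the default 544 nm thickness projects 5 planes. If the window contains no
#' plane center but overlaps the volume, the single nearest plane is used.
#'
#' @param vol an \code{\link{mc_volume}}.
#' @param z_center_nm slab center in nm (voxel centers are at
#'   \code{(i - 0.5) * dz}).
#' @param thickness_nm slab thickness in nm.
#' @return object of class \code{section}: projected \code{data}
#'   \code{(channel, y, x)}, channel names, pixel sizes and the projected
#'   plane indices.
#' @export
project_section <- function(vol, z_center_nm, thickness_nm = 544) {
  stopifnot(inherits(vol, "mc_volume"))
  dz <- vol$voxel_size_nm[1]
  nz <- dim(vol$data)[2]
  centers <- (seq_len(nz) - 0.5) * dz
  half <- thickness_nm / 2
  planes <- which(abs(centers - z_center_nm) <= half)
  if (!length(planes)) {
    if (z_center_nm + half < 0 || z_center_nm - half > nz * dz)
      stop("projection window [", z_center_nm - half, ", ", z_center_nm + half,
           "] nm lies outside the volume z-extent [0, ", nz * dz, "] nm")
    planes <- which.min(abs(centers - z_center_nm))
  }
  d <- dim(vol$data)
  proj <- array(0, c(d[1], d[3], d[4]))
  for (ch in seq_len(d[1])) {
    slab <- vol$data[ch, planes, , , drop = FALSE]
    dim(slab) <- c(length(planes), d[3], d[4])
    proj[ch, , ] <- colMeans(slab)
  }
  structure(list(data = proj, channel_names = vol$channel_names,
                 pixel_size_nm = vol$voxel_size_nm[2:3],
                 planes = planes, z_center_nm = z_center_nm,
                 thickness_nm = thickness_nm),
            class = "section")
}

#' Extract one channel of a section as a 2-D matrix
#' @param section a \code{\link{project_section}} result.
#' @param channel channel label.
#' @return numeric matrix \code{(y, x)}.
#' @export
section_channel <- function(section, channel) {
  stopifnot(inherits(section, "section"))
  i <- match(channel, section$channel_names)
  if (is.na(i)) stop("channel '", channel, "' not present in section")
  m <- section$data[i, , , drop = FALSE]
  dim(m) <- dim(section$data)[-1L]
  m
}

#' Project a nucleus mask onto a section
#'
#' By default a pixel belongs to the nucleus section when the nucleus mask is
#' present on any of the section's projected planes at that (y, x) position.
#' With \code{full_thickness = TRUE} only pixels whose column lies inside the
#' nucleus on every projected plane are kept: near the lateral nucleus edge a
#' column is only partially inside the slab, so its mean projection is
#' systematically dimmed, which would imprint a spurious radial trend on
#' intensity profiles; profiling is therefore restricted to the
#' full-thickness region.
#'
#' @param nucleus a \code{\link{segment_nucleus}} result.
#' @param section a \code{\link{project_section}} result.
#' @param full_thickness require the whole slab to be inside the nucleus.
#' @return logical matrix \code{(y, x)}.
#' @export
section_nucleus_mask <- function(nucleus, section, full_thickness = FALSE) {
  stopifnot(inherits(nucleus, "nucleus_mask"), inherits(section, "section"))
  f <- if (full_thickness) all else any
  apply(nucleus$mask[section$planes, , , drop = FALSE], c(2, 3), f)
}

# Bilinear interpolation of matrix `img` (pixel centers at (i - 0.5) * d)
# at physical points (py, px) in nm; NA outside the image.
bilinear_nm <- function(img, py, px, dy, dx) {
  u <- py / dy + 0.5
  v <- px / dx + 0.5
  ny <- nrow(img); nx <- ncol(img)
  u <- pmin(pmax(u, 1), ny)  # clamp to the outermost pixel centers
  v <- pmin(pmax(v, 1), nx)
  i0 <- pmin(floor(u), ny - 1L); i1 <- i0 + 1L
  j0 <- pmin(floor(v), nx - 1L); j1 <- j0 + 1L
  fu <- u - i0; fv <- v - j0
  out <- img[cbind(i0, j0)] * (1 - fu) * (1 - fv) +
    img[cbind(i1, j0)] * fu * (1 - fv) +
    img[cbind(i0, j1)] * (1 - fu) * fv +
    img[cbind(i1, j1)] * fu * fv
  oob <- py < 0 | py > ny * dy | px < 0 | px > nx * dx
  out[oob] <- NA_real_
  out
}

#' Radial intensity profile around one telomere
#'
#' Samples the section intensity along \code{n_rays} rays at equal angular
#' intervals (45 degrees for the default 8 rays) from the telomere center, by
#' bilinear interpolation at distances \code{0, step_nm, ..., max_radius_nm}.
#' A ray is truncated where it leaves the nucleus section mask; truncated
#' samples are excluded from the per-distance mean rather than zero-filled.
#'
#' @param section a \code{\link{project_section}} result.
#' @param spot one row of a \code{\link{detect_spots}} result, or a numeric
#'   \code{c(y, x)} center in nm.
#' @param channel intensity channel to profile (typically \code{lap2a}).
#' @param nucleus_mask_2d logical \code{(y, x)} matrix from
#'   \code{\link{section_nucleus_mask}}.
#' @param n_rays number of rays.
#' @param max_radius_nm profile extent in nm (default 400).
#' @param step_nm sampling step in nm (default 40, the lateral pixel pitch;
#'   finer steps add no information below the pixel size).
#' @param telomere_id identifier stored in the profile.
#' @return object of class \code{radial_profile}: distances, per-distance
#'   mean raw intensity over rays (\code{NA} where every ray is truncated),
#'   a slot for the nucleus-normalized intensity, and the per-ray sample
#'   matrix.
#' @export
radial_profile <- function(section, spot, channel = "lap2a", nucleus_mask_2d,
                           n_rays = 8L, max_radius_nm = 400, step_nm = 40,
                           telomere_id = NULL) {
  stopifnot(inherits(section, "section"), step_nm > 0, n_rays >= 1)
  if (is.data.frame(spot)) {
    ctr <- c(spot$cy_nm[1], spot$cx_nm[1])
    if (is.null(telomere_id)) telomere_id <- spot$spot_id[1]
  } else ctr <- as.numeric(spot)
  img <- section_channel(section, channel)
  dy <- section$pixel_size_nm[1]; dx <- section$pixel_size_nm[2]

  pix <- function(py, px) cbind(pmin(pmax(floor(py / dy) + 1, 1), nrow(img)),
                                pmin(pmax(floor(px / dx) + 1, 1), ncol(img)))
  ctr_pix <- pix(ctr[1], ctr[2])
  if (!nucleus_mask_2d[ctr_pix])
    stop("telomere centroid lies outside the nucleus section")

  distances <- seq(0, max_radius_nm, by = step_nm)
  if (distances[length(distances)] < max_radius_nm)
    distances <- c(distances, max_radius_nm)
  angles <- (seq_len(n_rays) - 1) * 2 * pi / n_rays
  samples <- matrix(NA_real_, n_rays, length(distances))
  for (k in seq_len(n_rays)) {
    py <- ctr[1] + distances * sin(angles[k])
    px <- ctr[2] + distances * cos(angles[k])
    vals <- bilinear_nm(img, py, px, dy, dx)
    pp <- pix(py, px)
    in_mask <- nucleus_mask_2d[pp] &
      py >= 0 & py <= nrow(img) * dy & px >= 0 & px <= ncol(img) * dx
    exit <- which(!in_mask)
    if (length(exit)) vals[min(exit):length(vals)] <- NA_real_
    samples[k, ] <- vals
  }
  raw <- colMeans(samples, na.rm = TRUE)
  raw[!is.finite(raw)] <- NA_real_
  structure(list(telomere_id = telomere_id, distances_nm = distances,
                 raw_intensity = raw, normalized_intensity = NULL,
                 n_rays = n_rays, ray_samples = samples),
            class = "radial_profile")
}

#' Min/max of a section channel inside the nucleus
#'
#' Gives the per-nucleus normalization anchors used by
#' \code{\link{normalize_profiles}}.
#'
#' @inheritParams radial_profile
#' @return list with \code{min} and \code{max}.
#' @export
section_channel_range <- function(section, channel, nucleus_mask_2d) {
  vals <- section_channel(section, channel)[nucleus_mask_2d]
  list(min = min(vals), max = max(vals))
}

#' Normalize radial profiles to the per-nucleus intensity range
#'
#' Applies \code{(raw - min) / (max - min)}, clipped to [0, 1], where min and
#' max are the channel extremes over the nucleus section. This removes
#' between-nucleus differences in absolute staining intensity, making
#' profiles comparable across nuclei and conditions.
#'
#' @param profiles list of \code{\link{radial_profile}} objects from one
#'   nucleus.
#' @param channel_min,channel_max intensity extremes over the nucleus
#'   section (see \code{\link{section_channel_range}}).
#' @return the profiles with \code{normalized_intensity} filled.
#' @export
normalize_profiles <- function(profiles, channel_min, channel_max) {
  if (!(channel_max > channel_min))
    stop("degenerate nucleus: channel max must exceed min for normalization")
  lapply(profiles, function(p) {
    stopifnot(inherits(p, "radial_profile"))
    p$normalized_intensity <-
      pmin(1, pmax(0, (p$raw_intensity - channel_min) /
                     (channel_max - channel_min)))
    p
  })
}

#' Percentage of the nucleus section covered by LAP2alpha
#'
#' The per-nucleus LAP2c statistic: 100 times the LAP2alpha-positive pixels
#' within the projected nucleus section divided by the nucleus section
#' pixels.
#'
#' @param lap2_mask logical 3-D mask from \code{\link{mask_lap2}}.
#' @param nucleus a \code{\link{segment_nucleus}} result.
#' @param section a \code{\link{project_section}} result.
#' @return coverage percentage in [0, 100].
#' @export
nucleus_coverage <- function(lap2_mask, nucleus, section) {
  stopifnot(inherits(section, "section"))
  nuc2 <- section_nucleus_mask(nucleus, section)
  if (!any(nuc2)) stop("empty nucleus section")
  lap2 <- apply(lap2_mask[section$planes, , , drop = FALSE], c(2, 3), any)
  100 * sum(lap2 & nuc2) / sum(nuc2)
}

#' Per-telomere LAP2alpha surface coverage
#'
#' For each spot, the percentage of its member voxels, projected into the
#' section, that overlap the projected LAP2alpha mask. Spots with no voxel
#' in the section give \code{NA} with a warning (the record is skipped, not
#' an error).
#'
#' @param spots a \code{\link{detect_spots}} result.
#' @param lap2_mask logical 3-D mask from \code{\link{mask_lap2}}.
#' @param section a \code{\link{project_section}} result.
#' @return numeric vector of coverage percentages (one per spot, \code{NA}
#'   where the spot misses the section).
#' @export
telomere_coverage <- function(spots, lap2_mask, section) {
  stopifnot(inherits(section, "section"))
  voxels <- attr(spots, "voxels")
  lap2 <- apply(lap2_mask[section$planes, , , drop = FALSE], c(2, 3), any)
  out <- rep(NA_real_, nrow(spots))
  skipped <- 0L
  for (i in seq_len(nrow(spots))) {
    vc <- voxels[[i]]
    vc <- vc[vc[, "z"] %in% section$planes, , drop = FALSE]
    if (nrow(vc) == 0L) { skipped <- skipped + 1L; next }
    pix <- unique(vc[, c("y", "x"), drop = FALSE])
    out[i] <- 100 * sum(lap2[pix]) / nrow(pix)
  }
  if (skipped > 0L)
    warning(skipped, " spot(s) have no voxels in the section; ",
            "coverage recorded as NA")
  out
}

#' Classify telomeres by LAP2alpha surface colocalization
#'
#' Assigns each telomere to one of three categories relative to the nucleus
#' coverage LAP2c and a spread sigma: \code{low} when coverage is below
#' \code{lap2c - sigma}, \code{high} when above \code{lap2c + sigma},
#' \code{average} otherwise (boundaries inclusive into \code{average}).
#' By default sigma is the standard deviation of the per-telomere coverages
#' within the same nucleus.
#'
#' @param coverages per-telomere coverage percentages for one nucleus
#'   (\code{NA} entries are dropped).
#' @param lap2c_percent nucleus LAP2alpha coverage percentage.
#' @param sigma_percent category half-width in percentage points; defaults
#'   to \code{sd(coverages)}.
#' @return data.frame of class \code{coverage_records} with
#'   \code{coverage_percent} and \code{category}; the category histogram
#'   (counts summing to the telomere count) is in attribute
#'   \code{histogram}, and the thresholds used in attribute
#'   \code{thresholds}.
#' @export
categorize_telomeres <- function(coverages, lap2c_percent,
                                 sigma_percent = NULL) {
  ids <- seq_along(coverages)
  keep <- !is.na(coverages)
  coverages <- coverages[keep]
  if (is.null(sigma_percent))
    sigma_percent <- if (length(coverages) > 1) sd(coverages) else 0
  if (sigma_percent < 0) stop("sigma_percent must be non-negative")
  lo <- max(0, lap2c_percent - sigma_percent)
  hi <- min(100, lap2c_percent + sigma_percent)
  category <- ifelse(coverages < lo, "low",
                     ifelse(coverages > hi, "high", "average"))
  out <- data.frame(telomere_id = ids[keep],
                    coverage_percent = coverages,
                    category = factor(category,
                                      levels = c("low", "average", "high")))
  class(out) <- c("coverage_records", "data.frame")
  attr(out, "histogram") <- table(out$category)
  attr(out, "thresholds") <- c(low = lo, high = hi, sigma = sigma_percent,
                               lap2c = lap2c_percent)
  out
}

#' Telomere distance to the nuclear lamina
#'
#' For each spot centroid, the exact minimum anisotropy-aware Euclidean
#' distance (nm) to the set of lamina surface voxel centers, with a boolean
#' proximity flag at \code{threshold_nm} (default 250 nm, the conventional
#' lamina-association criterion). Distances are measured from the spot
#' centroid, matching the rendering of telomeres as center-positioned
#' spheres.
#'
#' @param spots a \code{\link{detect_spots}} result.
#' @param surface an \code{\link{extract_lamina_surface}} result.
#' @param threshold_nm proximity criterion in nm.
#' @return data.frame with \code{telomere_id}, \code{nucleus_id},
#'   \code{distance_nm} and \code{within_threshold}.
#' @export
distance_to_lamina <- function(spots, surface, threshold_nm = 250) {
  stopifnot(inherits(surface, "lamina_surface"))
  if (nrow(surface$coords) == 0L) stop("empty lamina surface")
  vox <- surface$voxel_size_nm
  if (nrow(spots) == 0L)
    return(data.frame(telomere_id = integer(0), nucleus_id = integer(0),
                      distance_nm = numeric(0), within_threshold = logical(0)))
  pts <- cbind(spots$cz_nm, spots$cy_nm, spots$cx_nm)
  surf_nm <- sweep(surface$coords - 0.5, 2, vox, "*")
  d <- cpp_min_dist_nm(pts, surf_nm)
  data.frame(telomere_id = spots$spot_id, nucleus_id = spots$nucleus_id,
             distance_nm = d, within_threshold = d <= threshold_nm)
}

#' Aggregate normalized radial profiles
#'
#' Pointwise mean and SEM of the normalized intensity over telomeres
#' (each telomere contributes its ray-averaged profile), per condition, with
#' the peak distance of the mean curve. Requires at least two profiles per
#' condition and identical distance grids.
#'
#' @param profiles list of normalized \code{\link{radial_profile}} objects.
#' @param condition optional character/factor vector, one entry per profile;
#'   a single condition \code{"all"} is assumed when omitted.
#' @return object of class \code{profile_summary}: data.frame with
#'   \code{condition}, \code{distance_nm}, \code{mean_norm}, \code{sem} and
#'   \code{n}; the per-condition peak distances (nm of the maximum mean
#'   normalized intensity) are in attribute \code{peaks}.
#' @export
aggregate_profiles <- function(profiles, condition = NULL) {
  if (is.null(condition)) condition <- rep("all", length(profiles))
  stopifnot(length(condition) == length(profiles))
  grid <- profiles[[1L]]$distances_nm
  for (p in profiles) {
    stopifnot(inherits(p, "radial_profile"))
    if (!isTRUE(all.equal(p$distances_nm, grid)))
      stop("mismatched distance grids across profiles")
    if (is.null(p$normalized_intensity))
      stop("profiles must be normalized first (see normalize_profiles)")
  }
  out <- NULL
  peaks <- c()
  for (cond in unique(condition)) {
    sel <- profiles[condition == cond]
    if (length(sel) < 2L)
      stop("need at least 2 profiles per condition (condition '", cond, "')")
    mat <- do.call(rbind, lapply(sel, `[[`, "normalized_intensity"))
    n <- colSums(!is.na(mat))
    mu <- colMeans(mat, na.rm = TRUE)
    sem <- apply(mat, 2, sd, na.rm = TRUE) / sqrt(pmax(n, 1))
    mu[n == 0] <- NA_real_
    peaks[cond] <- grid[which.max(mu)]
    out <- rbind(out, data.frame(condition = cond, distance_nm = grid,
                                 mean_norm = mu, sem = sem, n = n))
  }
  class(out) <- c("profile_summary", "data.frame")
  attr(out, "peaks") <- peaks
  out
}
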