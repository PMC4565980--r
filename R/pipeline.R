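## End-to-end per-nucleus analysis: segmentation, spot detection, radial
## profiling, coverage classification and lamina distances in one call.

#' Analyze one multichannel nucleus volume
#'
#' Runs the full measurement chain on a calibrated volume: nucleus
#' segmentation on the lamina channel, lamina surface extraction, 3-D TRF1
#' spot detection, LAP2alpha binarization, projection of a section through
#' the nucleus center, eight-ray radial LAP2alpha profiles around every
#' telomere inside the section (normalized to the per-nucleus intensity
#' range), per-telomere and per-nucleus LAP2alpha surface coverage with
#' three-category classification, and telomere-to-lamina distances.
#'
#' @param vol an \code{\link{mc_volume}} with channels for the lamina,
#'   LAP2alpha and TRF1.
#' @param channels named list mapping roles \code{lamin}, \code{lap2a},
#'   \code{trf1} to channel labels.
#' @param nucleus_id identifier for this nucleus.
#' @param section_thickness_nm projected section thickness (nm).
#' @param z_center_nm section center; defaults to the nucleus mask z-centroid.
#' @param min_radius_nm,max_radius_nm,threshold_factor spot detection
#'   parameters (see \code{\link{detect_spots}}).
#' @param max_radius_profile_nm,step_nm radial profile extent and step (nm).
#' @param lamina_threshold_nm lamina proximity criterion (nm).
#' @param lap2_method LAP2alpha binarization method (see
#'   \code{\link{mask_lap2}}).
#' @return list with components \code{nucleus}, \code{surface},
#'   \code{spots}, \code{section}, \code{profiles} (normalized, one per
#'   in-section telomere), \code{coverage_records}, \code{nucleus_stats}
#'   (LAP2c, sigma, telomere count), and \code{lamina_records}.
#' @export
analyze_volume <- function(vol,
                           channels = list(lamin = "lamin", lap2a = "lap2a",
                                           trf1 = "trf1"),
                           nucleus_id = 1L,
                           section_thickness_nm = 544,
                           z_center_nm = NULL,
                           min_radius_nm = 100, max_radius_nm = 400,
                           threshold_factor = 6,
                           max_radius_profile_nm = 400, step_nm = 40,
                           lamina_threshold_nm = 250,
                           lap2_method = "otsu") {
  nucleus <- segment_nucleus(vol, channels$lamin)
  surface <- extract_lamina_surface(nucleus)
  spots <- detect_spots(vol, channels$trf1, nucleus,
                        min_radius_nm = min_radius_nm,
                        max_radius_nm = max_radius_nm,
                        threshold_factor = threshold_factor,
                        nucleus_id = nucleus_id)
  lap2_mask <- mask_lap2(vol, channels$lap2a, nucleus, method = lap2_method)

  if (is.null(z_center_nm)) {
    zi <- which(apply(nucleus$mask, 1, any))
    zw <- apply(nucleus$mask, 1, sum)[zi]
    z_center_nm <- sum(((zi - 0.5) * vol$voxel_size_nm[1]) * zw) / sum(zw)
  }
  section <- project_section(vol, z_center_nm, section_thickness_nm)
  # profiles use the full-thickness region (partial columns at the lateral
  # edge are dimmed by the projection and would bias the radial trend)
  nuc2d <- section_nucleus_mask(nucleus, section, full_thickness = TRUE)

  dz <- vol$voxel_size_nm[1]
  in_section <- abs(spots$cz_nm - z_center_nm) <= section_thickness_nm / 2
  profiles <- list()
  prof_ids <- integer(0)
  dy <- section$pixel_size_nm[1]; dx <- section$pixel_size_nm[2]
  for (i in which(in_section)) {
    py <- min(max(floor(spots$cy_nm[i] / dy) + 1, 1), nrow(nuc2d))
    px <- min(max(floor(spots$cx_nm[i] / dx) + 1, 1), ncol(nuc2d))
    if (!nuc2d[py, px]) next
    profiles[[length(profiles) + 1L]] <-
      radial_profile(section, c(spots$cy_nm[i], spots$cx_nm[i]),
                     channel = channels$lap2a, nucleus_mask_2d = nuc2d,
                     max_radius_nm = max_radius_profile_nm, step_nm = step_nm,
                     telomere_id = spots$spot_id[i])
    prof_ids <- c(prof_ids, spots$spot_id[i])
  }
  if (length(profiles)) {
    rng <- section_channel_range(section, channels$lap2a, nuc2d)
    profiles <- normalize_profiles(profiles, rng$min, rng$max)
  }

  lap2c <- nucleus_coverage(lap2_mask, nucleus, section)
  cov <- telomere_coverage(spots, lap2_mask, section)
  records <- categorize_telomeres(cov, lap2c)
  records$nucleus_id <- nucleus_id
  thr <- attr(records, "thresholds")
  nucleus_stats <- data.frame(nucleus_id = nucleus_id,
                              lap2c_percent = lap2c,
                              sigma_percent = unname(thr["sigma"]),
                              n_telomeres = nrow(spots))
  lamina_records <- distance_to_lamina(spots, surface, lamina_threshold_nm)

  list(nucleus = nucleus, surface = surface, spots = spots,
       section = section, profiles = profiles, profile_spot_ids = prof_ids,
       coverage_records = records, nucleus_stats = nucleus_stats,
       lamina_records = lamina_records, lap2_mask = lap2_mask)
}
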