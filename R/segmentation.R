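## Nucleus segmentation, lamina surface extraction, 3-D telomere spot
## detection and LAP2alpha binarization.

blur3d <- function(arr, sigma_nm, voxel_size_nm) {
  d <- dim(arr)
  sig_vox <- sigma_nm / voxel_size_nm
  if (all(sig_vox <= 0)) return(arr)
  array(cpp_gauss_blur3d(arr, d, sig_vox), d)
}

# Otsu threshold of a numeric vector via EBImage (256-level histogram).
otsu_threshold <- function(vals) {
  lo <- min(vals); hi <- max(vals)
  if (hi <= lo) stop("cannot threshold a constant signal")
  v <- (vals - lo) / (hi - lo)
  thr01 <- EBImage::otsu(EBImage::Image(matrix(v, ncol = 1L)))
  lo + thr01 * (hi - lo)
}

#' Segment the nucleus from a marker channel
#'
#' Gaussian-smooths the channel, applies an Otsu threshold over the whole
#' volume, fills holes per z-slice (so a hollow lamina shell becomes a solid
#' nucleus) and keeps the largest 6-connected 3-D component.
#'
#' @param vol an \code{\link{mc_volume}}.
#' @param channel channel to segment on (a lamina stain or DAPI).
#' @param smooth_sigma_nm pre-smoothing sigma in nm (isotropic in physical
#'   units, hence anisotropic in voxels).
#' @return object of class \code{nucleus_mask}: list with logical 3-D
#'   \code{mask} and \code{voxel_size_nm}.
#' @export
segment_nucleus <- function(vol, channel = "lamin", smooth_sigma_nm = 100) {
  arr <- get_channel(vol, channel)
  if (max(arr) <= min(arr))
    stop("segmentation failed: channel '", channel, "' is constant")
  sm <- blur3d(arr, rep(smooth_sigma_nm, 3), vol$voxel_size_nm)
  thr <- otsu_threshold(as.vector(sm))
  bin <- sm > thr
  if (!any(bin)) stop("segmentation failed: empty foreground after threshold")
  # fill holes slice-wise (EBImage operates on the last dimension as frames)
  stack <- EBImage::Image(aperm(bin * 1, c(2, 3, 1)))
  filled <- EBImage::fillHull(stack)
  bin <- aperm(filled > 0.5, c(3, 1, 2))
  dim(bin) <- dim(arr)
  lab <- array(cpp_label3d(bin, dim(bin), 6L), dim(bin))
  n_comp <- max(lab)
  if (n_comp == 0L) stop("segmentation failed: no connected component")
  if (n_comp > 1L) {
    sizes <- tabulate(lab[lab > 0L], nbins = n_comp)
    keep <- which.max(sizes)
    warning("discarding ", n_comp - 1L,
            " smaller connected component(s) during nucleus segmentation")
    bin <- lab == keep
  }
  structure(list(mask = bin, voxel_size_nm = vol$voxel_size_nm),
            class = "nucleus_mask")
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat("<nucleus_mask> ", sum(x$mask), " voxels on a ",
      paste(dim(x$mask), collapse = "x"), " grid\n", sep = "")
  invisible(x)
}

shift_logical <- function(a, axis, by) {
  # shift filling with FALSE outside the array
  d <- dim(a)
  out <- array(FALSE, d)
  src <- dst <- lapply(d, seq_len)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) { dst[[axis]] <- (1 + by):n; src[[axis]] <- 1:(n - by) }
  if (by < 0) { dst[[axis]] <- 1:(n + by); src[[axis]] <- (1 - by):n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Extract the lamina surface from a nucleus mask
#'
#' The surface is the morphological inner boundary: every mask voxel that is
#' 6-adjacent to at least one voxel outside the mask (voxels on the array
#' border count as adjacent to outside).
#'
#' @param mask a \code{\link{segment_nucleus}} result.
#' @return object of class \code{lamina_surface}: list with \code{coords}
#'   (n x 3 integer matrix of 1-based \code{(z, y, x)} voxel indices),
#'   \code{dim} and \code{voxel_size_nm}.
#' @export
extract_lamina_surface <- function(mask) {
  stopifnot(inherits(mask, "nucleus_mask"))
  m <- mask$mask
  if (!any(m)) stop("empty nucleus mask")
  all_in <- array(TRUE, dim(m))
  for (axis in 1:3)
    for (by in c(-1L, 1L))
      all_in <- all_in & shift_logical(m, axis, by)
  surf <- m & !all_in
  coords <- which(surf, arr.ind = TRUE)
  colnames(coords) <- c("z", "y", "x")
  structure(list(coords = coords, dim = dim(m),
                 voxel_size_nm = mask$voxel_size_nm),
            class = "lamina_surface")
}

#' @export
print.lamina_surface <- function(x, ...) {
  cat("<lamina_surface> ", nrow(x$coords), " surface voxels\n", sep = "")
  invisible(x)
}

#' Detect telomere (TRF1) spots in 3-D
#'
#' Multiscale Laplacian-of-Gaussian blob detection restricted to the nucleus.
#' Candidate scale-space maxima are kept when (i) the smoothed intensity at
#' the peak exceeds \code{median + threshold_factor * mad} of the channel
#' inside the nucleus and (ii) the scale-normalized LoG response exceeds the
#' same robust statistic of the response at that scale — the response
#' criterion rejects single-voxel shot-noise spikes, which carry almost no
#' blob mass but can cross an intensity-only cut. Overlapping candidates are
#' resolved by keeping the stronger response, where overlap means a center
#' distance not exceeding the sum of the two scale radii. Member voxels are
#' assigned by a seeded watershed on the smoothed channel over
#' above-background voxels.
#'
#' @param vol an \code{\link{mc_volume}}.
#' @param channel spot channel label.
#' @param nucleus a \code{\link{segment_nucleus}} result.
#' @param min_radius_nm,max_radius_nm expected spot radius range in nm
#'   (defaults 100-400 nm, the scale of SIM-resolved telomere foci).
#' @param threshold_factor robust background multiplier (default 6; over a
#'   nucleus of ~1e6 voxels a smaller factor admits noise maxima with
#'   near-certainty by extreme-value statistics).
#' @param n_scales number of logarithmic LoG scales spanning the radius range.
#' @param nucleus_id identifier attached to each spot.
#' @return data.frame of class \code{telomere_spots} with one row per spot:
#'   centroid (\code{cz_nm}, \code{cy_nm}, \code{cx_nm}; intensity-weighted,
#'   nm), voxel count, equivalent radius, detection scale and peak intensity.
#'   The member-voxel coordinate matrices are carried in the \code{voxels}
#'   attribute (a list parallel to the rows).
#' @export
detect_spots <- function(vol, channel = "trf1", nucleus,
                         min_radius_nm = 100, max_radius_nm = 400,
                         threshold_factor = 6, n_scales = 4L,
                         nucleus_id = 1L) {
  stopifnot(inherits(nucleus, "nucleus_mask"))
  if (!(min_radius_nm > 0 && min_radius_nm < max_radius_nm))
    stop("need 0 < min_radius_nm < max_radius_nm")
  if (!any(nucleus$mask)) stop("empty nucleus mask")
  arr <- get_channel(vol, channel)
  d <- dim(arr)
  vox <- vol$voxel_size_nm

  sm <- blur3d(arr, rep(0.5 * min_radius_nm, 3), vox)
  vals <- sm[nucleus$mask]
  thr <- median(vals) + threshold_factor * mad(vals)

  radii <- exp(seq(log(min_radius_nm), log(max_radius_nm),
                   length.out = n_scales))
  cand <- NULL
  for (r in radii) {
    sig <- r / sqrt(3)
    b <- blur3d(arr, rep(sig, 3), vox)
    resp <- -sig^2 * array(cpp_laplacian3d(b, d, vox), d)
    rvals <- resp[nucleus$mask]
    resp_thr <- median(rvals) + threshold_factor * mad(rvals)
    is_max <- array(cpp_local_max3d(resp, nucleus$mask, d), d)
    idx <- which(is_max & resp > resp_thr & sm > thr)
    if (length(idx))
      cand <- rbind(cand, data.frame(idx = idx, radius = r,
                                     resp = resp[idx], peak = sm[idx]))
  }
  empty <- data.frame(spot_id = integer(0), nucleus_id = integer(0),
                      cz_nm = numeric(0), cy_nm = numeric(0),
                      cx_nm = numeric(0), n_voxels = integer(0),
                      equivalent_radius_nm = numeric(0),
                      scale_radius_nm = numeric(0),
                      peak_intensity = numeric(0))
  attr(empty, "voxels") <- list()
  class(empty) <- c("telomere_spots", "data.frame")
  if (is.null(cand) || nrow(cand) == 0L) return(empty)

  cand <- cand[order(-cand$resp, cand$idx), , drop = FALSE]
  coords_of <- function(idx) {
    z <- (idx - 1L) %% d[1] + 1L
    y <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
    x <- (idx - 1L) %/% (d[1] * d[2]) + 1L
    cbind(z, y, x)
  }
  cand_nm <- sweep(coords_of(cand$idx) - 0.5, 2, vox, "*")
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in keep) {
      dist <- sqrt(sum((cand_nm[i, ] - cand_nm[j, ])^2))
      if (dist <= cand$radius[i] + cand$radius[j]) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  cand <- cand[keep, , drop = FALSE]

  allowed <- nucleus$mask & (sm > thr)
  lab <- array(cpp_watershed3d(sm, allowed, cand$idx, d), d)

  n <- nrow(cand)
  voxels <- vector("list", n)
  out <- data.frame(spot_id = seq_len(n), nucleus_id = nucleus_id,
                    cz_nm = NA_real_, cy_nm = NA_real_, cx_nm = NA_real_,
                    n_voxels = NA_integer_, equivalent_radius_nm = NA_real_,
                    scale_radius_nm = cand$radius, peak_intensity = NA_real_)
  for (s in seq_len(n)) {
    vc <- which(lab == s, arr.ind = TRUE)
    colnames(vc) <- c("z", "y", "x")
    voxels[[s]] <- vc
    w <- arr[lab == s]
    ctr_vox <- colSums(vc * w) / sum(w)
    ctr_nm <- (ctr_vox - 0.5) * vox
    out$cz_nm[s] <- ctr_nm[1]; out$cy_nm[s] <- ctr_nm[2]
    out$cx_nm[s] <- ctr_nm[3]
    out$n_voxels[s] <- nrow(vc)
    out$equivalent_radius_nm[s] <-
      (3 * nrow(vc) * prod(vox) / (4 * pi))^(1 / 3)
    out$peak_intensity[s] <- max(w)
  }
  attr(out, "voxels") <- voxels
  class(out) <- c("telomere_spots", "data.frame")
  out
}

#' Binarize the LAP2alpha channel inside the nucleus
#'
#' The threshold is computed from intensities inside the nucleus only, by
#' Otsu's method or a quantile rule (\code{method = "quantile"} with
#' \code{quantile_coverage} the target fraction of nucleus voxels above
#' threshold; the shorthand \code{"quantile:0.5"} is also accepted).
#'
#' @param vol an \code{\link{mc_volume}}.
#' @param channel channel to binarize.
#' @param nucleus a \code{\link{segment_nucleus}} result.
#' @param method \code{"otsu"}, \code{"quantile"} or \code{"quantile:q"}.
#' @param quantile_coverage target covered fraction for the quantile method.
#' @return logical 3-D mask, a subset of the nucleus mask.
#' @export
mask_lap2 <- function(vol, channel = "lap2a", nucleus, method = "otsu",
                      quantile_coverage = 0.5) {
  stopifnot(inherits(nucleus, "nucleus_mask"))
  arr <- get_channel(vol, channel)
  vals <- arr[nucleus$mask]
  if (max(vals) <= min(vals))
    stop("masking failed: channel '", channel, "' is constant inside the nucleus")
  if (grepl("^quantile:", method)) {
    quantile_coverage <- as.numeric(sub("^quantile:", "", method))
    method <- "quantile"
  }
  thr <- switch(method,
                otsu = otsu_threshold(vals),
                quantile = quantile(vals, 1 - quantile_coverage, names = FALSE),
                stop("unknown method: ", method))
  arr > thr & nucleus$mask
}
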