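## Per-nucleus two-channel intensity quantification and correlation
## (the immunofluorescence scatter analysis, e.g. H3K27me3 vs progerin).

#' Quantify per-nucleus mean intensities in a 2-D multichannel field
#'
#' Segments nuclei on a marker channel (Otsu threshold, hole filling,
#' connected components), discards components smaller than
#' \code{min_area_px} or touching the image border, and reports the mean
#' intensity of two measurement channels over each remaining component.
#' Optionally the per-channel median of non-nucleus pixels is subtracted as
#' background (negative background-corrected means are clamped at 0).
#'
#' @param field an \code{\link{mc_volume}} with a single z-plane.
#' @param seg_channel segmentation channel (typically \code{dapi}).
#' @param channels length-2 character vector of measurement channels.
#' @param min_area_px minimum component area in pixels.
#' @param background_subtract subtract the median non-nucleus intensity.
#' @return data.frame with \code{nucleus_id}, \code{mean_a}, \code{mean_b},
#'   \code{area_px} (empty, with a warning, when no nucleus survives).
#' @export
quantify_nuclei_2d <- function(field, seg_channel = "dapi",
                               channels = c("stain_a", "stain_b"),
                               min_area_px = 50L,
                               background_subtract = TRUE) {
  stopifnot(inherits(field, "mc_volume"), length(channels) == 2L)
  seg3 <- get_channel(field, seg_channel)
  if (dim(seg3)[1] != 1L) stop("`field` must have a single z-plane")
  seg <- seg3[1, , ]
  if (max(seg) <= min(seg)) stop("segmentation channel is constant")
  thr <- otsu_threshold(as.vector(seg))
  bin <- seg > thr
  bin <- EBImage::fillHull(EBImage::Image(bin * 1)) > 0.5
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  lab <- EBImage::imageData(lab)
  n_lab <- max(lab)

  a_img <- get_channel(field, channels[1])[1, , ]
  b_img <- get_channel(field, channels[2])[1, , ]
  bg_a <- bg_b <- 0
  if (background_subtract && any(!bin)) {
    bg_a <- median(a_img[!bin])
    bg_b <- median(b_img[!bin])
  }
  ny <- nrow(lab); nx <- ncol(lab)
  border_labels <- setdiff(unique(c(lab[1, ], lab[ny, ], lab[, 1],
                                    lab[, nx])), 0)
  fg <- lab > 0
  labs <- lab[fg]
  areas <- tabulate(labs, nbins = n_lab)
  sum_a <- rowsum(a_img[fg], labs)[, 1]
  sum_b <- rowsum(b_img[fg], labs)[, 1]
  present <- as.integer(names(sum_a))
  keep <- present[areas[present] >= min_area_px &
                    !(present %in% border_labels)]
  if (!length(keep)) {
    warning("no nuclei survive area/border filtering")
    return(data.frame(nucleus_id = integer(0), mean_a = numeric(0),
                      mean_b = numeric(0), area_px = integer(0)))
  }
  ki <- as.character(keep)
  data.frame(nucleus_id = seq_along(keep),
             mean_a = pmax(0, sum_a[ki] / areas[keep] - bg_a),
             mean_b = pmax(0, sum_b[ki] / areas[keep] - bg_b),
             area_px = areas[keep], row.names = NULL)
}

#' Pearson correlation of per-nucleus intensities
#'
#' Product-moment correlation between the two channel means with a two-sided
#' p-value from the t transform and a Fisher-z 95% confidence interval.
#'
#' @param records a \code{\link{quantify_nuclei_2d}} result, or a numeric
#'   vector (then \code{y} must be given).
#' @param y optional second numeric vector.
#' @return object of class \code{correlation_result}: list with \code{r},
#'   \code{n}, \code{p_value}, \code{ci95}.
#' @export
pearson_correlation <- function(records, y = NULL) {
  if (is.data.frame(records)) {
    x <- records$mean_a; y <- records$mean_b
  } else x <- as.numeric(records)
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations, got ", n)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: a channel is constant across nuclei")
  ct <- cor.test(x, y, method = "pearson", conf.level = 0.95)
  structure(list(r = unname(ct$estimate), n = n,
                 p_value = ct$p.value,
                 ci95 = c(ct$conf.int[1], ct$conf.int[2])),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d, p = %.3g, 95%% CI [%.4f, %.4f])\n",
              x$r, x$n, x$p_value, x$ci95[1], x$ci95[2]))
  invisible(x)
}
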