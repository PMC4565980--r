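#' Calibrated multichannel volume
#'
#' Container for a calibrated multichannel image volume. Data are stored as a
#' 4-D array indexed \code{[channel, z, y, x]}; all physical quantities in the
#' package are exchanged in nanometres, with the centre of voxel \code{i}
#' (1-based) along an axis with spacing \code{d} located at \code{(i - 0.5) * d}.
#'
#' @param data 4-D non-negative numeric array, dim \code{(channels, z, y, x)}.
#'   A 3-D array is promoted to a single-channel volume; 2-D fields use
#'   \code{z = 1}.
#' @param channel_names character vector of channel labels (typically from
#'   \code{lamin}, \code{lap2a}, \code{trf1}, \code{dapi}, \code{stain_a},
#'   \code{stain_b}), one per channel.
#' @param voxel_size_nm numeric length-3 \code{(dz, dy, dx)} voxel spacing in
#'   nm; all components must be positive. Anisotropy is permitted and the
#'   default axial spacing of 125 nm matches common 3D-SIM z-stepping.
#' @return An object of class \code{mc_volume}.
#' @export
mc_volume <- function(data, channel_names, voxel_size_nm = c(125, 40, 40)) {
  if (length(dim(data)) == 3L) dim(data) <- c(1L, dim(data))
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4-D array (channel, z, y, x)")
  if (any(data < 0)) stop("intensities must be non-negative")
  if (length(channel_names) != dim(data)[1L])
    stop("length(channel_names) must equal the channel dimension (",
         dim(data)[1L], ")")
  voxel_size_nm <- as.numeric(voxel_size_nm)
  if (length(voxel_size_nm) != 3L || any(!is.finite(voxel_size_nm)) ||
      any(voxel_size_nm <= 0))
    stop("`voxel_size_nm` must be 3 positive numbers (dz, dy, dx)")
  structure(
    list(data = data, channel_names = as.character(channel_names),
         voxel_size_nm = stats::setNames(voxel_size_nm, c("dz", "dy", "dx"))),
    class = "mc_volume")
}

#' @export
print.mc_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<mc_volume> ", d[1], " channel(s) [", paste(x$channel_names, collapse = ", "),
      "], grid z*y*x = ", d[2], "x", d[3], "x", d[4],
      ", voxel (dz,dy,dx) = (", paste(x$voxel_size_nm, collapse = ", "),
      ") nm\n", sep = "")
  invisible(x)
}

#' Extract one channel of a volume as a 3-D array
#'
#' @param vol an \code{mc_volume}.
#' @param channel channel label.
#' @return 3-D array with dim \code{(z, y, x)}.
#' @export
get_channel <- function(vol, channel) {
  stopifnot(inherits(vol, "mc_volume"))
  i <- match(channel, vol$channel_names)
  if (is.na(i)) stop("channel '", channel, "' not present (have: ",
                     paste(vol$channel_names, collapse = ", "), ")")
  arr <- vol$data[i, , , , drop = FALSE]
  dim(arr) <- dim(vol$data)[-1L]
  arr
}

unit_to_nm <- function(u) {
  if (is.null(u) || is.na(u) || !nzchar(u)) return(1000)  # OME default is um
  switch(u,
         "nm" = 1, "um" = 1000, "µm" = 1000, "μm" = 1000,
         "mm" = 1e6,
         stop("unsupported physical-size unit: ", u))
}

#' Parse OME-XML pixel metadata
#'
#' Extracts voxel calibration (converted to nm) and stack geometry from an
#' OME-XML string as found in the ImageDescription tag of an OME-TIFF.
#'
#' @param description character scalar holding OME-XML.
#' @return list with \code{voxel_size_nm} (length-3 \code{(dz,dy,dx)} or
#'   \code{NULL} when absent), \code{size_c} and \code{size_z} (or \code{NA}).
#' @export
parse_ome_metadata <- function(description) {
  out <- list(voxel_size_nm = NULL, size_c = NA_integer_, size_z = NA_integer_)
  if (is.null(description) || !nzchar(description)) return(out)
  doc <- tryCatch(xml2::read_xml(description), error = function(e) NULL)
  if (is.null(doc)) return(out)
  px <- xml2::xml_find_first(doc, "//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) return(out)
  at <- function(a) {
    v <- xml2::xml_attr(px, a)
    if (is.na(v)) NA_real_ else as.numeric(v)
  }
  atc <- function(a) xml2::xml_attr(px, a)
  pz <- at("PhysicalSizeZ"); py <- at("PhysicalSizeY"); px_ <- at("PhysicalSizeX")
  if (!is.na(pz) && !is.na(py) && !is.na(px_)) {
    out$voxel_size_nm <- c(pz * unit_to_nm(atc("PhysicalSizeZUnit")),
                           py * unit_to_nm(atc("PhysicalSizeYUnit")),
                           px_ * unit_to_nm(atc("PhysicalSizeXUnit")))
  }
  sc <- at("SizeC"); sz <- at("SizeZ")
  if (!is.na(sc)) out$size_c <- as.integer(sc)
  if (!is.na(sz)) out$size_z <- as.integer(sz)
  out
}

#' Read a calibrated multichannel volume from TIFF / OME-TIFF
#'
#' Reads a multi-page TIFF stack into an \code{mc_volume}. Calibration
#' precedence is caller argument, then OME metadata, then a JSON sidecar
#' (\code{<path>.json}, written by \code{\link{write_volume}}); if none
#' provides a voxel size the read fails. Page layout is either channel-major
#' (all z-planes of channel 1, then channel 2, ...) or interleaved (all
#' channels of z-plane 1, ...).
#'
#' @param path TIFF file path.
#' @param channel_map named integer vector mapping channel labels to 1-based
#'   channel indices within the stack, e.g. \code{c(lamin = 1, trf1 = 3)}.
#'   Defaults to the sidecar's channel list when available.
#' @param voxel_size_nm optional caller-supplied \code{(dz, dy, dx)} in nm;
#'   overrides file metadata.
#' @param layout page ordering of the stack.
#' @param n_channels total number of channels in the stack; inferred from the
#'   sidecar, OME SizeC, or \code{max(channel_map)} when omitted.
#' @return an \code{mc_volume}.
#' @export
read_volume <- function(path, channel_map = NULL, voxel_size_nm = NULL,
                        layout = c("channel_major", "interleaved"),
                        n_channels = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
                    error = function(e) stop("failed to read TIFF '", path,
                                             "': ", conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  n_pages <- length(pages)
  desc <- attr(pages[[1L]], "description")
  ome <- parse_ome_metadata(desc)

  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL

  if (is.null(channel_map) && !is.null(meta$channel_names))
    channel_map <- stats::setNames(seq_along(meta$channel_names), meta$channel_names)
  if (is.null(channel_map))
    stop("`channel_map` is required when no metadata sidecar is present")
  if (is.null(names(channel_map)) || any(!nzchar(names(channel_map))))
    stop("`channel_map` must be a named integer vector (label -> index)")

  if (is.null(n_channels)) {
    n_channels <- if (!is.null(meta$n_channels)) as.integer(meta$n_channels)
      else if (!is.na(ome$size_c)) ome$size_c
      else max(channel_map)
  }
  if (any(channel_map < 1L) || any(channel_map > n_channels))
    stop("channel_map index out of range: stack has ", n_channels,
         " channel(s), requested ", paste(channel_map, collapse = ","))
  if (n_pages %% n_channels != 0L)
    stop("page count (", n_pages, ") is not a multiple of n_channels (",
         n_channels, ")")
  nz <- n_pages %/% n_channels
  if (!is.null(meta$layout)) layout <- meta$layout

  vox <- if (!is.null(voxel_size_nm)) as.numeric(voxel_size_nm)
    else if (!is.null(ome$voxel_size_nm)) ome$voxel_size_nm
    else if (!is.null(meta$voxel_size_nm)) as.numeric(meta$voxel_size_nm)
    else stop("no voxel calibration: supply `voxel_size_nm` or provide ",
              "OME metadata / a sidecar")

  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  page_of <- function(ch, z) {
    if (layout == "channel_major") (ch - 1L) * nz + z else (z - 1L) * n_channels + ch
  }
  nm <- names(channel_map)
  arr <- array(0, dim = c(length(channel_map), nz, ny, nx))
  for (k in seq_along(channel_map))
    for (z in seq_len(nz))
      arr[k, z, , ] <- pages[[page_of(channel_map[[k]], z)]]
  mc_volume(arr, nm, vox)
}

#' Write a multichannel volume as a 16-bit multi-page TIFF with JSON sidecar
#'
#' Pages are written channel-major; channel names, voxel calibration and
#' layout go into \code{<path>.json} so that \code{\link{read_volume}}
#' restores the volume without further arguments. Intensities are rounded to
#' integers and must fit in \code{[0, 65535]}; integer-valued volumes
#' round-trip bit-exactly.
#'
#' @param vol an \code{mc_volume}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "mc_volume"))
  d <- dim(vol$data)
  vals <- round(vol$data)
  if (max(vals) > 65535) stop("intensities exceed 16-bit range")
  pages <- vector("list", d[1] * d[2])
  p <- 0L
  for (ch in seq_len(d[1]))
    for (z in seq_len(d[2])) {
      p <- p + 1L
      pages[[p]] <- matrix(vals[ch, z, , ] / 65535, d[3], d[4])
    }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(
    list(channel_names = vol$channel_names,
         n_channels = d[1], layout = "channel_major",
         voxel_size_nm = unname(vol$voxel_size_nm)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write measurement records to CSV
#'
#' Accepts a data.frame or a list of named lists sharing one key set; writes
#' a header plus one row per record with stable column order and full float
#' precision.
#'
#' @param records data.frame, or list of named lists with identical names.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_records <- function(records, path) {
  if (is.data.frame(records)) {
    df <- records
  } else if (is.list(records)) {
    if (length(records) == 0L)
      stop("cannot infer columns from an empty record list; pass a data.frame")
    keys <- names(records[[1L]])
    if (is.null(keys)) stop("records must be named lists")
    for (r in records)
      if (!identical(sort(names(r)), sort(keys)))
        stop("heterogeneous record keys: all records must share one key set")
    df <- do.call(rbind, lapply(records, function(r)
      as.data.frame(r[keys], stringsAsFactors = FALSE)))
  } else stop("`records` must be a data.frame or list of named lists")
  df <- df[, setdiff(names(df), "voxels"), drop = FALSE]  # drop list-columns
  ok <- tryCatch({ write.csv(df, path, row.names = FALSE); TRUE },
                 error = function(e) stop("cannot write '", path, "': ",
                                          conditionMessage(e)))
  invisible(path)
}

#' Write run metadata (parameters, seed, software version) as JSON
#'
#' @param path output JSON path.
#' @param params named list of run parameters.
#' @param seed integer seed used for the run, or \code{NULL}.
#' @return \code{path}, invisibly.
#' @export
write_run_metadata <- function(path, params = list(), seed = NULL) {
  jsonlite::write_json(
    list(parameters = params, seed = seed,
         package = "telolamina",
         version = as.character(utils::packageVersion("telolamina"))),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
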