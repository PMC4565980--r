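# Shared fixtures and independent oracles, built in code at test time.

# Small, fast generator settings used throughout the unit tests.
small_params <- function(...) {
  synthetic_params(nucleus_radii_nm = c(1000, 1800, 1800), n_telomeres = 12,
                   ...)
}

# Minimal uncompressed little-endian 16-bit grayscale multi-page TIFF writer
# with an ImageDescription tag on the first page. Used only to fabricate
# OME-TIFF fixtures byte-wise; production writing goes through the package.
write_minimal_ome_tiff <- function(path, planes, description) {
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3) { w2(value); w2(0) } else w4(value)  # SHORT padded
  }
  ny <- nrow(planes[[1]]); nx <- ncol(planes[[1]])
  n <- length(planes)
  bytes_per_page <- ny * nx * 2
  desc_core <- c(charToRaw(description), as.raw(0))
  desc_count <- length(desc_core)
  desc_raw <- if (desc_count %% 2 == 1) c(desc_core, as.raw(0)) else desc_core

  data_off <- 8
  desc_off <- data_off + n * bytes_per_page
  ifd_off <- desc_off + length(desc_raw)
  n_entries <- function(p) if (p == 1) 10 else 9
  ifd_size <- function(p) 2 + 12 * n_entries(p) + 4
  ifd_offs <- cumsum(c(ifd_off, vapply(seq_len(n), ifd_size, numeric(1))))

  writeBin(charToRaw("II"), con); w2(42); w4(ifd_offs[1])
  for (p in seq_len(n))
    writeBin(as.integer(t(planes[[p]])), con, size = 2, endian = "little")
  writeBin(desc_raw, con)
  for (p in seq_len(n)) {
    w2(n_entries(p))
    entry(256, 4, 1, nx)                       # ImageWidth
    entry(257, 4, 1, ny)                       # ImageLength
    entry(258, 3, 1, 16)                       # BitsPerSample
    entry(259, 3, 1, 1)                        # Compression = none
    entry(262, 3, 1, 1)                        # Photometric = min-is-black
    if (p == 1) entry(270, 2, desc_count, desc_off)
    entry(273, 4, 1, data_off + (p - 1) * bytes_per_page)  # StripOffsets
    entry(277, 3, 1, 1)                        # SamplesPerPixel
    entry(278, 4, 1, ny)                       # RowsPerStrip
    entry(279, 4, 1, bytes_per_page)           # StripByteCounts
    w4(if (p < n) ifd_offs[p + 1] else 0)
  }
  invisible(path)
}

# Brute-force oracle: inner 6-connected boundary of a logical 3-D mask.
brute_surface <- function(m) {
  d <- dim(m)
  out <- array(FALSE, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    if (!m[z, y, x]) next
    nb <- list(c(z - 1, y, x), c(z + 1, y, x), c(z, y - 1, x),
               c(z, y + 1, x), c(z, y, x - 1), c(z, y, x + 1))
    for (q in nb) {
      if (any(q < 1) || q[1] > d[1] || q[2] > d[2] || q[3] > d[3] ||
          !m[q[1], q[2], q[3]]) {
        out[z, y, x] <- TRUE
        break
      }
    }
  }
  out
}

# Brute-force oracle: min Euclidean distance (nm) from a point to surface
# voxel centers, anisotropic voxels.
brute_min_dist <- function(pt_nm, coords, vox) {
  centers <- sweep(coords - 0.5, 2, vox, "*")
  sqrt(min(rowSums(sweep(centers, 2, pt_nm)^2)))
}

# Construct a nucleus_mask object directly from a logical array.
as_nucleus_mask <- function(mask, vox = c(125, 40, 40)) {
  structure(list(mask = mask, voxel_size_nm = as.numeric(vox)),
            class = "nucleus_mask")
}

# Solid ellipsoid mask / intensity volume on a given grid.
ball_array <- function(dims, center_vox, radii_vox) {
  zz <- ((seq_len(dims[1]) - center_vox[1]) / radii_vox[1])^2
  yy <- ((seq_len(dims[2]) - center_vox[2]) / radii_vox[2])^2
  xx <- ((seq_len(dims[3]) - center_vox[3]) / radii_vox[3])^2
  outer(outer(zz, yy, "+"), xx, "+") <= 1
}
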