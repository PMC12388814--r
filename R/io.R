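#' Read a micrograph frame from disk
#'
#' Supports 8-bit colour PNG and TIFF via the `png`/`tiff` packages, plus
#' uncompressed 24-bit BMP (the native output of many camera capture stacks)
#' through a small built-in reader. Returns values on the 0-255 scale.
#'
#' @param path Image file path (`.png`, `.tif`/`.tiff`, `.bmp`).
#' @return A rows x cols x 3 numeric array, values 0-255.
#' @export
read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    bmp = return(read_bmp(path)),
    abort(sprintf("Unsupported image format: .%s", ext))
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE] * 255
}

#' Write time-lapse frames (and optionally masks) to disk
#'
#' Frames are written as 8-bit RGB PNG (default) or TIFF; label masks, whose
#' ids can exceed 255, are written as 16-bit grayscale TIFF. The ground-truth
#' volume/event tables go to CSV alongside.
#'
#' @param timelapse A [generate_timelapse()] object.
#' @param dir Output directory (created if needed).
#' @param format `"png"` or `"tiff"` for the frames.
#' @param masks Also write label masks and ground-truth CSVs.
#' @return Invisibly, the directory.
#' @export
write_frames <- function(timelapse, dir, format = c("png", "tiff"),
                         masks = TRUE) {
  format <- arg_match(format)
  stopifnot(inherits(timelapse, "timelapse"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(timelapse$times)) {
    t <- timelapse$times[i]
    img <- timelapse$frames[[i]] / 255
    path <- file.path(dir, sprintf("frame_t%07d.%s", round(t),
                                   if (format == "png") "png" else "tif"))
    if (format == "png") png::writePNG(img, path) else
      tiff::writeTIFF(img, path, bits.per.sample = 8L)
    if (masks) {
      mk <- timelapse$masks[[i]] / 65535
      tiff::writeTIFF(mk, file.path(dir, sprintf("mask_t%07d.tif", round(t))),
                      bits.per.sample = 16L)
    }
  }
  if (masks) {
    readr::write_csv(
      dplyr::rename(timelapse$truth, true_volume_um3 = "true_volume_um3"),
      file.path(dir, "ground_truth.csv"))
    readr::write_csv(timelapse$events, file.path(dir, "events.csv"))
  }
  invisible(dir)
}

#' Read a label mask written by [write_frames()]
#'
#' @param path A 16-bit grayscale TIFF mask path.
#' @return An integer label matrix.
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

# Minimal uncompressed 24-bit BMP reader (BITMAPINFOHEADER, bottom-up rows).
read_bmp <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  if (!identical(rawToChar(magic), "BM")) abort("Not a BMP file.")
  readBin(con, "integer", 2, size = 4, endian = "little")  # file size, reserved
  offset <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (hdr_size < 40) abort("Unsupported BMP header.")
  w <- readBin(con, "integer", 1, size = 4, endian = "little")
  h <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 1, size = 2, endian = "little")  # planes
  bpp <- readBin(con, "integer", 1, size = 2, endian = "little")
  compression <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (bpp != 24L || compression != 0L) {
    abort("Only uncompressed 24-bit BMP is supported.")
  }
  seek(con, offset)
  stride <- ((w * 3 + 3) %/% 4) * 4
  data <- readBin(con, "raw", stride * abs(h))
  hh <- abs(h)
  out <- array(0, c(hh, w, 3L))
  for (row in seq_len(hh)) {
    line <- as.integer(data[(row - 1) * stride + seq_len(w * 3)])
    # BMP stores rows bottom-up and channels as BGR
    r_out <- if (h > 0) hh - row + 1 else row
    px <- matrix(line, ncol = 3, byrow = TRUE)
    out[r_out, , 1] <- px[, 3]
    out[r_out, , 2] <- px[, 2]
    out[r_out, , 3] <- px[, 1]
  }
  out
}

#' Export pipeline tables to CSV
#'
#' Thin wrappers fixing the documented column layouts: detections
#' (`frame_t_min, det_id, centroid_row, centroid_col, area_px2, major_px,
#' minor_px, orientation_rad`), tracks (`cell_id, t_min, volume_um3_raw,
#' volume_um3_smoothed, event`), fits (`cell_id, a, b, c, d, r2, n`) and
#' divisions (`cell_id, division_t_min, volume_at_division_um3,
#' growth_period_min, growth_period_d`).
#'
#' @param x The corresponding tibble.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_detections_csv <- function(x, path) {
  readr::write_csv(select(x, "frame_t_min", "det_id", "centroid_row",
                          "centroid_col", "area_px2", "major_px", "minor_px",
                          "orientation_rad"), path)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
write_tracks_csv <- function(x, path) {
  out <- tibble(cell_id = x$cell_id, t_min = x$frame_t_min,
                volume_um3_raw = x$volume_um3,
                volume_um3_smoothed = if ("volume_um3_smoothed" %in% names(x))
                  x$volume_um3_smoothed else NA_real_,
                event = x$end_event)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
write_fits_csv <- function(x, path) {
  readr::write_csv(select(x, "cell_id", "a", "b", "c", "d", "r2", "n"), path)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
write_divisions_csv <- function(x, path) {
  readr::write_csv(select(x, "cell_id", "division_t_min",
                          "volume_at_division_um3", "growth_period_min",
                          "growth_period_d"), path)
  invisible(path)
}
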