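# Format plumbing: slice matrices and masks on disk as headerless CSV,
# plain-text netpbm (PGM P2/P5, PPM P3) or PNG (via the png package; PNG
# writing is 8-bit only). DICOM and TIFF are not supported in this build and
# are rejected with a clear message.

file_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "txt")) return("csv")
  if (ext == "pgm") return("pgm")
  if (ext == "ppm") return("ppm")
  if (ext == "png") return("png")
  if (ext %in% c("dcm", "dicom", "tif", "tiff"))
    stop(sprintf("unsupported format '%s' for %s: this build reads CSV, PGM and PNG only",
                 ext, path), call. = FALSE)
  stop(sprintf("unrecognized file format for %s", path), call. = FALSE)
}

# headerless CSV matrix; rejects ragged rows naming the offending row
read_csv_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("%s is empty", path), call. = FALSE)
  rows <- strsplit(lines, ",", fixed = TRUE)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged CSV in %s: row %d has %d fields, expected %d",
                 path, bad, widths[bad], widths[1L]), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) stop(sprintf("non-numeric entries in %s", path), call. = FALSE)
  matrix(vals, nrow = length(rows), ncol = widths[1L], byrow = TRUE)
}

write_csv_matrix <- function(m, path) {
  utils::write.table(matrix(as.vector(m), nrow(m), ncol(m)), path,
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# netpbm PGM: P2 (ascii) written by default; P2 and P5 (binary) read
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P5"))
    stop(sprintf("%s is not a PGM file (magic '%s')", path, magic), call. = FALSE)
  tokens <- integer(0)
  # read header tokens (width, height, maxval), skipping comments
  buf <- character(0)
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L)
    if (!length(ch) || !nzchar(ch)) stop(sprintf("truncated PGM header in %s", path), call. = FALSE)
    if (ch == "#") { # comment to end of line
      repeat { ch <- readChar(con, 1L); if (!length(ch) || ch == "\n") break }
    } else if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf)) {
      tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- tokens[1L]; h <- tokens[2L]; maxval <- tokens[3L]
  if (magic == "P5") {
    bytes <- if (maxval > 255L) 2L else 1L
    raw <- readBin(con, "integer", n = h * w, size = bytes, signed = FALSE,
                   endian = "big")
    m <- matrix(raw, h, w, byrow = TRUE)
  } else {
    txt <- readChar(con, file.size(path), useBytes = TRUE)
    vals <- as.integer(strsplit(trimws(txt), "\\s+")[[1L]])
    if (length(vals) < h * w)
      stop(sprintf("truncated PGM data in %s", path), call. = FALSE)
    m <- matrix(vals[seq_len(h * w)], h, w, byrow = TRUE)
  }
  attr(m, "maxval") <- maxval
  m
}

write_pgm <- function(m, path, maxval = 4095L) {
  h <- nrow(m); w <- ncol(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", w, h), as.character(maxval)), con)
  apply_rows <- apply(m, 1L, paste, collapse = " ")
  writeLines(apply_rows, con)
  invisible(path)
}

# 24-bit ascii PPM for the RGB contour overlay
write_ppm <- function(rgb, path) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3L] == 3L)
  h <- dim(rgb)[1L]; w <- dim(rgb)[2L]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", sprintf("%d %d", w, h), "255"), con)
  for (r in seq_len(h)) {
    trip <- as.vector(rbind(rgb[r, , 1L], rgb[r, , 2L], rgb[r, , 3L]))
    writeLines(paste(trip, collapse = " "), con)
  }
  invisible(path)
}

read_png_matrix <- function(path) {
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # grayscale from channel 1
  round(img * (2^depth - 1))
}

#' Read a slice intensity matrix from disk
#'
#' Reads one DIXON channel from headerless CSV, PGM (ascii P2 or binary P5)
#' or grayscale PNG (8- or 16-bit). Values above 4095 are clipped (with a
#' warning giving the count); negative values are rejected.
#'
#' @param path file path; format inferred from the extension.
#' @param expected_channel `"water"` or `"fat"`, tagged onto the result.
#' @return a [raw_image_matrix()].
#' @export
read_image_matrix <- function(path, expected_channel = c("water", "fat")) {
  expected_channel <- match.arg(expected_channel)
  fmt <- file_format(path)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  m <- switch(fmt,
              csv = read_csv_matrix(path),
              pgm = read_pgm(path),
              ppm = stop(sprintf("%s is an RGB overlay, not a slice matrix", path), call. = FALSE),
              png = read_png_matrix(path))
  if (any(m < 0))
    stop(sprintf("negative intensities in %s", path), call. = FALSE)
  n_clip <- sum(m > 4095)
  if (n_clip > 0L) {
    warning(sprintf("%d value(s) above 4095 clipped in %s", n_clip, path),
            call. = FALSE)
    m <- pmin(m, 4095)
  }
  raw_image_matrix(matrix(as.integer(round(m)), nrow(m), ncol(m)),
                   expected_channel)
}

#' Write a slice intensity matrix
#'
#' @param matrix_in integer matrix (e.g. a [raw_image_matrix()]).
#' @param path output path; `.csv` or `.pgm` (12-bit capable). 8-bit PNG is
#'   available only for display images via [write_display_image()].
#' @export
write_image_matrix <- function(matrix_in, path) {
  fmt <- file_format(path)
  m <- matrix(as.integer(matrix_in), nrow(matrix_in), ncol(matrix_in))
  switch(fmt,
         csv = write_csv_matrix(m, path),
         pgm = write_pgm(m, path, maxval = max(4095L, max(m))),
         stop(sprintf("cannot write a 12-bit matrix to %s; use .csv or .pgm", path),
              call. = FALSE))
  invisible(path)
}

#' Write an 8-bit display image (PNG, PGM or CSV)
#'
#' @param image an [eight_bit_image()].
#' @param path output path ending in `.png`, `.pgm` or `.csv`.
#' @export
write_display_image <- function(image, path) {
  stopifnot(inherits(image, "EightBitImage"))
  fmt <- file_format(path)
  m <- matrix(as.integer(image), nrow(image), ncol(image))
  switch(fmt,
         png = png::writePNG(m / 255, path),
         pgm = write_pgm(m, path, maxval = 255L),
         csv = write_csv_matrix(m, path),
         stop(sprintf("cannot write a display image to %s", path), call. = FALSE))
  invisible(path)
}

#' Read an ROI mask
#'
#' Any nonzero pixel counts as in-ROI. Accepts CSV, PGM or PNG. Contours are
#' traced from the mask ([roi_mask()]); a mask with several connected ROI
#' components is accepted with a warning, an empty mask is rejected.
#'
#' @param path file path.
#' @return an [roi_mask()].
#' @export
read_mask <- function(path) {
  fmt <- file_format(path)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  m <- switch(fmt,
              csv = read_csv_matrix(path),
              pgm = read_pgm(path),
              png = read_png_matrix(path),
              stop(sprintf("cannot read a mask from %s", path), call. = FALSE))
  if (!any(m != 0)) stop(sprintf("empty mask in %s", path), call. = FALSE)
  roi_mask(matrix(m != 0, nrow(m), ncol(m)))
}

#' Write an ROI mask (255 = in ROI)
#'
#' @param mask an [roi_mask()].
#' @param path output path ending in `.png`, `.pgm` or `.csv`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "RoiMask"))
  m <- matrix(ifelse(mask$in_roi, 255L, 0L), nrow(mask$in_roi), ncol(mask$in_roi))
  fmt <- file_format(path)
  switch(fmt,
         png = png::writePNG(m / 255, path),
         pgm = write_pgm(m, path, maxval = 255L),
         csv = write_csv_matrix(m, path),
         stop(sprintf("cannot write a mask to %s", path), call. = FALSE))
  invisible(path)
}
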