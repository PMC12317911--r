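#' Construct a raw intensity matrix for one DIXON channel
#'
#' A `RawImageMatrix` is an integer H x W grid of 12-bit MR intensities
#' (levels 0--4095) for either the water-only or the fat-only signal of one
#' slice. It is the unit of input for the ratio pipeline.
#'
#' @param values numeric matrix; coerced to integer. All values must lie in
#'   \[0, 4095\].
#' @param channel `"water"` or `"fat"`.
#' @return an integer matrix of class `RawImageMatrix` with a `channel`
#'   attribute.
#' @examples
#' m <- raw_image_matrix(matrix(0:3, 2, 2), "water")
#' channel(m)
#' @export
raw_image_matrix <- function(values, channel = c("water", "fat")) {
  channel <- match.arg(channel)
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (anyNA(values)) stop("image contains NA values", call. = FALSE)
  v <- as.numeric(values)
  if (any(v != floor(v)))
    stop("intensities must be whole numbers", call. = FALSE)
  if (any(v < 0) || any(v > 4095))
    stop("intensities must lie in [0, 4095]", call. = FALSE)
  m <- matrix(as.integer(v), nrow(values), ncol(values))
  structure(m, channel = channel, class = c("RawImageMatrix", "matrix", "array"))
}

#' @rdname raw_image_matrix
#' @param x a `RawImageMatrix`
#' @export
channel <- function(x) attr(x, "channel", exact = TRUE)

#' @export
print.RawImageMatrix <- function(x, ...) {
  cat(sprintf("<RawImageMatrix %dx%d, channel=%s, range=[%d, %d]>\n",
              nrow(x), ncol(x), channel(x), min(x), max(x)))
  invisible(x)
}

#' Construct an 8-bit display image
#'
#' Holds a grid of integers in \[0, 255\], the output of the 4096-to-256 level
#' affine conversion used for display renderings (IWO, IFO, IRWO, IBPRWO).
#'
#' @param values integer matrix with all values in \[0, 255\].
#' @return an integer matrix of class `EightBitImage`.
#' @export
eight_bit_image <- function(values) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  v <- as.numeric(values)
  if (anyNA(v) || any(v != floor(v)) || any(v < 0) || any(v > 255))
    stop("8-bit image values must be integers in [0, 255]", call. = FALSE)
  structure(matrix(as.integer(v), nrow(values), ncol(values)),
            class = c("EightBitImage", "matrix", "array"))
}

#' @export
print.EightBitImage <- function(x, ...) {
  cat(sprintf("<EightBitImage %dx%d, range=[%d, %d]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Construct a water-to-oil ratio matrix
#'
#' A `RatioMatrix` holds nonnegative reals: the full per-voxel water/fat
#' ratio map, its ROI-masked version (out-of-ROI voxels exactly zero), or the
#' brown-fat extraction (only the top-fraction voxels nonzero). The
#' `provenance` attribute records which stage produced it and is checked by
#' downstream operations so stages cannot be skipped or repeated out of order.
#'
#' @param values nonnegative numeric matrix, all finite.
#' @param provenance one of `"full"`, `"roi_masked"`, `"brown_extracted"`.
#' @return a numeric matrix of class `RatioMatrix`.
#' @export
ratio_matrix <- function(values,
                         provenance = c("full", "roi_masked", "brown_extracted")) {
  provenance <- match.arg(provenance)
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("ratio values must all be finite", call. = FALSE)
  if (any(values < 0)) stop("ratio values must be nonnegative", call. = FALSE)
  structure(matrix(as.numeric(values), nrow(values), ncol(values)),
            provenance = provenance,
            class = c("RatioMatrix", "matrix", "array"))
}

#' @rdname ratio_matrix
#' @param x a `RatioMatrix`
#' @export
provenance <- function(x) attr(x, "provenance", exact = TRUE)

#' @export
print.RatioMatrix <- function(x, ...) {
  cat(sprintf("<RatioMatrix %dx%d, provenance=%s, range=[%.4g, %.4g]>\n",
              nrow(x), ncol(x), provenance(x), min(x), max(x)))
  invisible(x)
}

#' Specification for the 12-bit to 8-bit intensity conversion
#'
#' Parameters of the affine level conversion
#' `x_new = round((x - x_min) / (x_max - x_min) * out_max)`.
#' Defaults map the full 12-bit range 0..4095 onto 0..255.
#'
#' @param x_min,x_max input intensity bounds; `x_max` must exceed `x_min`.
#' @param out_max top output level (255 for 8-bit display).
#' @return a list of class `ConversionSpec`.
#' @export
conversion_spec <- function(x_min = 0, x_max = 4095, out_max = 255) {
  if (!is.numeric(x_min) || !is.numeric(x_max) || length(x_min) != 1L ||
      length(x_max) != 1L)
    stop("x_min and x_max must be single numbers", call. = FALSE)
  if (x_max <= x_min)
    stop(sprintf("degenerate conversion range: x_max (%g) must exceed x_min (%g)",
                 x_max, x_min), call. = FALSE)
  if (out_max < 1) stop("out_max must be at least 1", call. = FALSE)
  structure(list(x_min = x_min, x_max = x_max, out_max = out_max),
            class = "ConversionSpec")
}

#' Specification for the top-fraction brown-fat extraction
#'
#' Controls how the highest-ratio voxels are retained from the ROI-masked
#' ratio map. The retained count is `count_rounding(retain_fraction * N)`
#' where `N` counts ROI voxels (`denominator = "roi_elements"`, the default)
#' or all voxels of the grid (`"all_elements"`). Ties at the cutoff value are
#' broken by ascending row-major voxel index so extraction is deterministic.
#'
#' @param retain_fraction fraction of elements to keep, in (0, 1\]. Default
#'   0.01 (the top 1%).
#' @param denominator what `N` counts.
#' @param count_rounding how `retain_fraction * N` is rounded to an integer
#'   count; `"ceil"` (default) guarantees at least one voxel is kept for a
#'   nonempty ROI.
#' @param tie_break tie policy; only `"value_then_row_major"` is defined.
#' @return a list of class `ExtractionSpec`.
#' @export
extraction_spec <- function(retain_fraction = 0.01,
                            denominator = c("roi_elements", "all_elements"),
                            count_rounding = c("ceil", "floor", "round"),
                            tie_break = "value_then_row_major") {
  denominator <- match.arg(denominator)
  count_rounding <- match.arg(count_rounding)
  tie_break <- match.arg(tie_break)
  if (!is.numeric(retain_fraction) || length(retain_fraction) != 1L ||
      is.na(retain_fraction) || retain_fraction <= 0 || retain_fraction > 1)
    stop("retain_fraction must lie in (0, 1]", call. = FALSE)
  structure(list(retain_fraction = retain_fraction, denominator = denominator,
                 count_rounding = count_rounding, tie_break = tie_break),
            class = "ExtractionSpec")
}

#' Policy for ratio computation where the fat signal vanishes
#'
#' The per-voxel quotient water/fat is undefined where the fat signal is 0.
#' Voxels with zero fat but positive water are assigned the finite ceiling
#' `zero_fat_cap` (they are exactly the high water-to-fat voxels the method
#' looks for, so they must not be dropped); voxels with both signals zero are
#' assigned 0 (no tissue signal).
#'
#' @param zero_fat_cap positive ratio ceiling, default 1000.
#' @return a list of class `RatioPolicy`.
#' @export
ratio_policy <- function(zero_fat_cap = 1000) {
  if (!is.numeric(zero_fat_cap) || length(zero_fat_cap) != 1L ||
      is.na(zero_fat_cap) || zero_fat_cap <= 0)
    stop("zero_fat_cap must be a single positive number", call. = FALSE)
  structure(list(zero_fat_cap = as.numeric(zero_fat_cap), zero_zero_value = 0),
            class = "RatioPolicy")
}
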