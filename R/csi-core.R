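# Core chemical-shift image computations: level conversion for display,
# per-voxel water-to-oil ratio, ROI masking, and top-fraction brown-fat
# extraction.

# round-half-up on nonnegative operands; base round() is round-half-even,
# which would make integer edge cases (e.g. x*255/4095 landing on .5)
# platform-surprising for a reproducibility-focused pipeline
round_half_up <- function(x) floor(x + 0.5)

# row-major linear index of every cell of an H x W matrix (R stores
# column-major); used for the deterministic extraction tie-break
row_major_index <- function(h, w) {
  (as.vector(row(matrix(0, h, w))) - 1L) * w + as.vector(col(matrix(0, h, w)))
}

#' Convert intensities to 8-bit display levels
#'
#' Applies the affine level conversion
#' `x_new = round((x - x_min) / (x_max - x_min) * out_max)`, mapping the
#' 12-bit range 0..4095 onto 0..255 under the default spec. Values outside
#' `[x_min, x_max]` are clipped first and the clip count is reported as a
#' warning. Rounding is half-up so every edge case is reproducible.
#'
#' @param matrix_in numeric or integer matrix.
#' @param spec a [conversion_spec()].
#' @return an [eight_bit_image()] of the same dimensions, with attribute
#'   `n_clipped` (number of input values that fell outside the spec range).
#' @examples
#' rescale_intensity(matrix(c(0, 2048, 4095), 1, 3))[1, ]
#' @export
rescale_intensity <- function(matrix_in, spec = conversion_spec()) {
  stopifnot(inherits(spec, "ConversionSpec"))
  if (!is.matrix(matrix_in)) stop("input must be a matrix", call. = FALSE)
  if (anyNA(matrix_in)) stop("input contains NA", call. = FALSE)
  v <- as.numeric(matrix_in)
  n_clip <- sum(v < spec$x_min | v > spec$x_max)
  if (n_clip > 0L) {
    warning(sprintf("%d value(s) outside [%g, %g] clipped before conversion",
                    n_clip, spec$x_min, spec$x_max), call. = FALSE)
    v <- pmin(pmax(v, spec$x_min), spec$x_max)
  }
  out <- round_half_up((v - spec$x_min) / (spec$x_max - spec$x_min) * spec$out_max)
  img <- eight_bit_image(matrix(out, nrow(matrix_in), ncol(matrix_in)))
  attr(img, "n_clipped") <- n_clip
  img
}

#' Per-voxel water-to-oil ratio map
#'
#' Divides the water-only matrix by the fat-only matrix elementwise to obtain
#' the ratio map at the heart of the brown-fat analysis: brown adipose tissue
#' carries more water relative to fat than white adipose tissue, so its
#' voxels show elevated ratios. Division by a zero fat signal is resolved by
#' `policy`: zero fat with positive water gets the finite cap
#' `policy$zero_fat_cap` (these voxels are the extreme of the very signal the
#' method targets and must not be discarded), zero fat with zero water gets 0.
#'
#' @param water,fat [raw_image_matrix()] objects of identical dimensions with
#'   channels `"water"` and `"fat"` respectively.
#' @param policy a [ratio_policy()].
#' @return a [ratio_matrix()] with provenance `"full"` and attribute
#'   `n_capped`, the number of zero-fat/positive-water voxels that received
#'   the cap.
#' @export
water_oil_ratio <- function(water, fat, policy = ratio_policy()) {
  stopifnot(inherits(policy, "RatioPolicy"))
  if (!inherits(water, "RawImageMatrix") || !inherits(fat, "RawImageMatrix"))
    stop("water and fat must be RawImageMatrix objects", call. = FALSE)
  if (!identical(dim(water), dim(fat)))
    stop(sprintf("shape mismatch: water is %dx%d, fat is %dx%d",
                 nrow(water), ncol(water), nrow(fat), ncol(fat)), call. = FALSE)
  if (!identical(channel(water), "water") || !identical(channel(fat), "fat"))
    stop(sprintf("channel mismatch: expected (water, fat), got (%s, %s)",
                 channel(water), channel(fat)), call. = FALSE)
  wv <- as.numeric(water); fv <- as.numeric(fat)
  r <- numeric(length(wv))
  pos_fat <- fv > 0
  r[pos_fat] <- wv[pos_fat] / fv[pos_fat]
  capped <- !pos_fat & wv > 0
  r[capped] <- policy$zero_fat_cap
  # remaining (fat 0, water 0) stay 0
  out <- ratio_matrix(matrix(r, nrow(water), ncol(water)), "full")
  attr(out, "n_capped") <- sum(capped)
  out
}

#' Restrict a ratio map to the periprostatic-fat ROI
#'
#' Sets every voxel outside the ROI to exactly zero, producing the masked
#' ratio map from which brown fat is extracted. In-ROI voxels pass through
#' unchanged.
#'
#' @param ratio a [ratio_matrix()] with provenance `"full"`.
#' @param mask an [roi_mask()] of matching dimensions.
#' @return a [ratio_matrix()] with provenance `"roi_masked"`.
#' @export
apply_roi <- function(ratio, mask) {
  stopifnot(inherits(ratio, "RatioMatrix"), inherits(mask, "RoiMask"))
  if (!identical(provenance(ratio), "full"))
    stop("apply_roi expects a full (unmasked) ratio map; got provenance ",
         provenance(ratio), call. = FALSE)
  if (!identical(dim(ratio), dim(mask$in_roi)))
    stop(sprintf("shape mismatch: ratio is %dx%d, mask is %dx%d",
                 nrow(ratio), ncol(ratio),
                 nrow(mask$in_roi), ncol(mask$in_roi)), call. = FALSE)
  v <- unclass(ratio)
  attributes(v) <- list(dim = dim(ratio))
  v[!mask$in_roi] <- 0
  ratio_matrix(v, "roi_masked")
}

#' Extract the top-fraction brown-fat voxels
#'
#' Sorts all ROI voxels of the masked ratio map from large to small and
#' retains the first `retain_fraction` of them (default the top 1%, chosen
#' because brown fat is scarce within the fat compartment); every other voxel
#' is set to zero. The retained count is
#' `count_rounding(retain_fraction * N)` with `N` the ROI voxel count under
#' the default denominator, and at least 1 under `"ceil"` rounding. Ties at
#' the cutoff value are kept in ascending row-major order so the retained set
#' is deterministic.
#'
#' @param prwo a [ratio_matrix()] with provenance `"roi_masked"`.
#' @param mask the [roi_mask()] that produced it.
#' @param spec an [extraction_spec()].
#' @return a list with `bprwo` (a [ratio_matrix()], provenance
#'   `"brown_extracted"`), `retained_indices` (k x 2 matrix of (row, col) in
#'   retention order: descending value, row-major ascending within ties), and
#'   `k` (the retained count).
#' @export
extract_brown_fat <- function(prwo, mask, spec = extraction_spec()) {
  stopifnot(inherits(prwo, "RatioMatrix"), inherits(mask, "RoiMask"),
            inherits(spec, "ExtractionSpec"))
  if (!identical(provenance(prwo), "roi_masked"))
    stop("extract_brown_fat expects a roi_masked ratio map; got provenance ",
         provenance(prwo), call. = FALSE)
  if (!identical(dim(prwo), dim(mask$in_roi)))
    stop("shape mismatch between ratio map and mask", call. = FALSE)
  in_roi <- as.vector(mask$in_roi)
  n_roi <- sum(in_roi)
  if (n_roi == 0L) stop("empty ROI: nothing to extract", call. = FALSE)

  h <- nrow(prwo); w <- ncol(prwo)
  n_total <- if (spec$denominator == "roi_elements") n_roi else h * w
  k <- switch(spec$count_rounding,
              ceil = ceiling(spec$retain_fraction * n_total),
              floor = floor(spec$retain_fraction * n_total),
              round = round(spec$retain_fraction * n_total))
  k <- as.integer(max(min(k, n_roi), if (spec$count_rounding == "ceil") 1L else 0L))

  vals <- as.numeric(prwo)
  rm_idx <- row_major_index(h, w)
  cand <- which(in_roi)
  ord <- cand[order(-vals[cand], rm_idx[cand])]
  keep <- ord[seq_len(k)]

  out <- numeric(h * w)
  out[keep] <- vals[keep]
  rows <- ((keep - 1L) %% h) + 1L
  cols <- ((keep - 1L) %/% h) + 1L
  res <- ratio_matrix(matrix(out, h, w), "brown_extracted")
  list(bprwo = res,
       retained_indices = cbind(row = rows, col = cols),
       k = k)
}

#' Render a ratio map as an 8-bit image
#'
#' Applies the affine level conversion with the map's own minimum and maximum
#' as input bounds, so the full dynamic range of the ratio map spans 0..255.
#' A constant map has no dynamic range; by convention it renders all-zero
#' (with a warning).
#'
#' @param ratio a [ratio_matrix()] (any provenance).
#' @return an [eight_bit_image()].
#' @export
render_ratio_image <- function(ratio) {
  stopifnot(inherits(ratio, "RatioMatrix"))
  lo <- min(ratio); hi <- max(ratio)
  if (hi == lo) {
    warning("constant ratio map: degenerate display range, rendering all-zero",
            call. = FALSE)
    return(eight_bit_image(matrix(0L, nrow(ratio), ncol(ratio))))
  }
  rescale_intensity(matrix(as.numeric(ratio), nrow(ratio), ncol(ratio)),
                    conversion_spec(x_min = lo, x_max = hi))
}

#' Overlay ROI contours on a grayscale image
#'
#' Replicates an 8-bit grayscale image to RGB and paints the outer ROI
#' contour pure green and the inner contour pure red, reproducing the
#' conventional display where the periprostatic fat lies inside the green
#' contour and outside the red one.
#'
#' @param image an [eight_bit_image()].
#' @param mask an [roi_mask()] of matching dimensions.
#' @return an H x W x 3 integer array with values in \[0, 255\].
#' @export
overlay_contours <- function(image, mask) {
  stopifnot(inherits(image, "EightBitImage"), inherits(mask, "RoiMask"))
  if (!identical(dim(image), dim(mask$in_roi)))
    stop("shape mismatch between image and mask", call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  rgb <- array(rep(as.integer(image), 3L), dim = c(h, w, 3L))
  oc <- mask$outer_contour
  if (nrow(oc)) {
    rgb[cbind(oc[, 1L], oc[, 2L], 1L)] <- 0L
    rgb[cbind(oc[, 1L], oc[, 2L], 2L)] <- 255L
    rgb[cbind(oc[, 1L], oc[, 2L], 3L)] <- 0L
  }
  ic <- mask$inner_contour
  if (nrow(ic)) {
    rgb[cbind(ic[, 1L], ic[, 2L], 1L)] <- 255L
    rgb[cbind(ic[, 1L], ic[, 2L], 2L)] <- 0L
    rgb[cbind(ic[, 1L], ic[, 2L], 3L)] <- 0L
  }
  rgb
}
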