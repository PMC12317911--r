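# Synthetic DIXON phantom generator. Emulates the inputs the analysis
# assumes: paired 12-bit water/fat slice matrices containing an elliptical
# prostate, an annular periprostatic-fat ROI of mostly white adipose tissue
# (high fat fraction), sparse brown-fat blobs with elevated water fraction,
# additive Gaussian channel noise, and group-conditional log-normal iPSA.

#' Parameters of a synthetic DIXON slice phantom
#'
#' Describes one slice's geometry and signal model. The prostate is an
#' ellipse at `prostate_center` with semi-axes `prostate_radii`; the
#' periprostatic-fat ROI is the annulus between that ellipse and the ellipse
#' grown by `annulus_width`. Annulus voxels carry a total (water + fat)
#' signal of `signal_peak`, split by fat fraction: `wat_fat_fraction` for
#' white fat, `bat_fat_fraction` for voxels inside brown-fat blobs. Brown fat
#' must have the lower fat fraction (i.e. higher water-to-fat ratio) --- that
#' contrast is the premise of the whole method.
#'
#' @param image_height,image_width slice dimensions in pixels.
#' @param prostate_center (row, col) of the prostate ellipse centre.
#' @param prostate_radii (row, col) semi-axes in pixels.
#' @param annulus_width radial width of the fat annulus in pixels.
#' @param wat_fat_fraction fat fraction of white adipose voxels, in (0, 1).
#' @param bat_fat_fraction fat fraction inside brown-fat blobs, in (0, 1);
#'   must be strictly below `wat_fat_fraction`.
#' @param bat_blob_count number of circular brown-fat blobs seeded in the
#'   annulus (centres drawn uniformly over annulus voxels; overlap allowed).
#' @param bat_blob_radius blob radius in pixels.
#' @param signal_peak total in-tissue signal level, at most 4095.
#' @param noise_sd standard deviation of the additive Gaussian noise applied
#'   per channel before clipping and integer quantization.
#' @param seed integer seed making the slice reproducible.
#' @return a list of class `PhantomParams`.
#' @export
phantom_params <- function(image_height = 96, image_width = 96,
                           prostate_center = c(48, 48),
                           prostate_radii = c(16, 20),
                           annulus_width = 10,
                           wat_fat_fraction = 0.85,
                           bat_fat_fraction = 0.5,
                           bat_blob_count = 3,
                           bat_blob_radius = 3,
                           signal_peak = 3000,
                           noise_sd = 40,
                           seed = 1L) {
  p <- list(image_height = as.integer(image_height),
            image_width = as.integer(image_width),
            prostate_center = as.numeric(prostate_center),
            prostate_radii = as.numeric(prostate_radii),
            annulus_width = as.numeric(annulus_width),
            wat_fat_fraction = wat_fat_fraction,
            bat_fat_fraction = bat_fat_fraction,
            bat_blob_count = as.integer(bat_blob_count),
            bat_blob_radius = as.numeric(bat_blob_radius),
            signal_peak = as.numeric(signal_peak),
            noise_sd = as.numeric(noise_sd),
            seed = as.integer(seed))
  validate_phantom_params(p)
  structure(p, class = "PhantomParams")
}

validate_phantom_params <- function(p) {
  if (!(p$bat_fat_fraction > 0 && p$bat_fat_fraction < p$wat_fat_fraction &&
        p$wat_fat_fraction < 1))
    stop("need 0 < bat_fat_fraction < wat_fat_fraction < 1 (brown fat must have the higher water-to-fat ratio)",
         call. = FALSE)
  if (p$signal_peak > 4095 || p$signal_peak <= 0)
    stop("signal_peak must lie in (0, 4095]", call. = FALSE)
  if (p$noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  if (p$bat_blob_count < 0) stop("bat_blob_count must be >= 0", call. = FALSE)
  outer_r <- p$prostate_radii + p$annulus_width
  if (p$prostate_center[1] - outer_r[1] < 1 ||
      p$prostate_center[1] + outer_r[1] > p$image_height ||
      p$prostate_center[2] - outer_r[2] < 1 ||
      p$prostate_center[2] + outer_r[2] > p$image_width)
    stop(sprintf(
      "phantom geometry does not fit: outer ellipse (semi-axes %.1f x %.1f at centre %.0f,%.0f) exceeds the %dx%d image",
      outer_r[1], outer_r[2], p$prostate_center[1], p$prostate_center[2],
      p$image_height, p$image_width), call. = FALSE)
  invisible(p)
}

#' Clinical profile of one risk group
#'
#' Holds the group label, cohort size, iPSA moments (mean and SD in ng/ml),
#' and the range from which each patient's brown-fat blob count is drawn.
#' Default profiles via [default_group_profiles()] mirror a 21-patient
#' localized prostate-cancer cohort: 4 low / 4 intermediate / 13 high risk
#' with iPSA 6.7 (2.3) / 10.4 (3.6) / 51.9 (50.6) ng/ml.
#'
#' @param group_label `"low"`, `"intermediate"` or `"high"` (NCCN strata).
#' @param n_patients nonnegative integer.
#' @param ipsa_mean,ipsa_sd iPSA moments, ng/ml; mean > 0, sd >= 0.
#' @param bat_blob_count_range length-2 integer range (inclusive) of per-
#'   patient brown-fat blob counts.
#' @return a list of class `GroupProfile`.
#' @export
group_profile <- function(group_label = c("low", "intermediate", "high"),
                          n_patients, ipsa_mean, ipsa_sd,
                          bat_blob_count_range = c(0L, 2L)) {
  group_label <- match.arg(group_label)
  if (n_patients < 0) stop("n_patients must be >= 0", call. = FALSE)
  if (ipsa_mean <= 0) stop("ipsa_mean must be > 0", call. = FALSE)
  if (ipsa_sd < 0) stop("ipsa_sd must be >= 0", call. = FALSE)
  if (length(bat_blob_count_range) != 2L ||
      bat_blob_count_range[1] > bat_blob_count_range[2] ||
      bat_blob_count_range[1] < 0)
    stop("bat_blob_count_range must be a nondecreasing nonnegative pair",
         call. = FALSE)
  structure(list(group_label = group_label,
                 n_patients = as.integer(n_patients),
                 ipsa_mean = ipsa_mean, ipsa_sd = ipsa_sd,
                 bat_blob_count_range = as.integer(bat_blob_count_range)),
            class = "GroupProfile")
}

#' @rdname group_profile
#' @export
default_group_profiles <- function() {
  list(
    group_profile("low", 4, 6.7, 2.3, c(0L, 2L)),
    group_profile("intermediate", 4, 10.4, 3.6, c(3L, 6L)),
    group_profile("high", 13, 51.9, 50.6, c(4L, 8L))
  )
}

# squared normalized elliptical radius of every pixel
ellipse_dist2 <- function(h, w, center, radii) {
  rr <- (row(matrix(0, h, w)) - center[1]) / radii[1]
  cc <- (col(matrix(0, h, w)) - center[2]) / radii[2]
  rr^2 + cc^2
}

#' Generate one synthetic DIXON slice pair with its ROI mask
#'
#' Builds paired water-only and fat-only 12-bit matrices plus the annular
#' periprostatic-fat mask. Compartments: background (no signal), prostate
#' interior (water-dominant soft tissue at 30% fat fraction, a fixed
#' cosmetic choice --- the prostate is excluded from all statistics), white
#' adipose annulus, and circular brown-fat blobs whose centres are drawn
#' uniformly over annulus voxels. Gaussian noise of `params$noise_sd` is
#' added per channel, then values are clipped to \[0, 4095\] and quantized
#' half-up to integers. Fully deterministic given `params$seed`.
#'
#' @param params a [phantom_params()].
#' @return a list with `water` and `fat` ([raw_image_matrix()]), `mask`
#'   (an [roi_mask()]), and `truth` (per-compartment bookkeeping: logical
#'   matrices `bat` and `annulus`, and `n_roi`).
#' @export
generate_phantom_slice <- function(params) {
  stopifnot(inherits(params, "PhantomParams"))
  validate_phantom_params(params)
  h <- params$image_height; w <- params$image_width

  inner <- ellipse_dist2(h, w, params$prostate_center, params$prostate_radii) <= 1
  outer <- ellipse_dist2(h, w, params$prostate_center,
                         params$prostate_radii + params$annulus_width) <= 1
  annulus <- outer & !inner

  set.seed(params$seed)
  bat <- matrix(FALSE, h, w)
  ann_idx <- which(annulus)
  if (params$bat_blob_count > 0L && length(ann_idx)) {
    centers <- sample(ann_idx, params$bat_blob_count, replace = TRUE)
    for (ci in centers) {
      cr <- ((ci - 1L) %% h) + 1L
      cc <- ((ci - 1L) %/% h) + 1L
      d2 <- (row(bat) - cr)^2 + (col(bat) - cc)^2
      bat <- bat | (d2 <= params$bat_blob_radius^2)
    }
    bat <- bat & annulus  # blobs are clipped to the annulus
  }

  fat_frac <- matrix(0, h, w)
  fat_frac[annulus] <- params$wat_fat_fraction
  fat_frac[bat] <- params$bat_fat_fraction
  fat_frac[inner] <- 0.30  # prostate soft tissue, outside the ROI
  signal <- matrix(0, h, w)
  signal[annulus | inner] <- params$signal_peak

  fat_sig <- signal * fat_frac
  wat_sig <- signal * (1 - fat_frac)
  wat_sig[!(annulus | inner)] <- 0
  if (params$noise_sd > 0) {
    wat_sig <- wat_sig + stats::rnorm(h * w, 0, params$noise_sd)
    fat_sig <- fat_sig + stats::rnorm(h * w, 0, params$noise_sd)
  }
  quantize <- function(x) {
    matrix(as.integer(pmin(pmax(floor(x + 0.5), 0), 4095)), h, w)
  }
  list(water = raw_image_matrix(quantize(wat_sig), "water"),
       fat = raw_image_matrix(quantize(fat_sig), "fat"),
       mask = roi_mask(annulus),
       truth = list(bat = bat, annulus = annulus, n_roi = sum(annulus)))
}

#' Draw an iPSA value for a risk group
#'
#' Samples from a log-normal distribution moment-matched to the group's
#' (mean, SD): `sigma^2 = log(1 + sd^2/mean^2)`, `mu = log(mean) - sigma^2/2`.
#' The log-normal family is a deliberate choice for a strictly positive
#' serum marker whose high-risk dispersion is as large as its mean (heavy
#' right skew). A zero SD degenerates to the point mass at the mean.
#'
#' @param profile a [group_profile()].
#' @param seed integer seed; draws are reproducible.
#' @param n number of draws.
#' @return numeric vector of `n` strictly positive iPSA values (ng/ml).
#' @export
sample_ipsa <- function(profile, seed, n = 1L) {
  stopifnot(inherits(profile, "GroupProfile"))
  if (profile$ipsa_sd < 0) stop("ipsa_sd must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  if (profile$ipsa_sd == 0) return(rep(profile$ipsa_mean, n))
  sigma2 <- log(1 + (profile$ipsa_sd / profile$ipsa_mean)^2)
  mu <- log(profile$ipsa_mean) - sigma2 / 2
  stats::rlnorm(n, meanlog = mu, sdlog = sqrt(sigma2))
}

# deterministic per-patient sub-seed: a counter scheme off the master seed,
# independent of iteration order, kept below 2^31
derive_seed <- function(master_seed, index, stream = 0L) {
  as.integer((as.double(master_seed) * 48271 + index * 10007 + stream * 97 + 12345) %%
               2147483647)
}

#' Generate a synthetic patient cohort
#'
#' Produces one record per patient across the supplied group profiles. Each
#' patient gets a seeded iPSA draw, a brown-fat blob count drawn uniformly
#' from the group's range, and `slices_per_patient` phantom slices. All
#' randomness flows from per-patient sub-seeds derived deterministically
#' from `seed`, so cohorts are reproducible record-by-record.
#'
#' @param profiles list of [group_profile()] objects; must be nonempty.
#' @param params a [phantom_params()] template (its `bat_blob_count` and
#'   `seed` are overridden per patient/slice).
#' @param slices_per_patient integer >= 1.
#' @param seed master seed.
#' @return a list of `PatientRecord` lists, each with `patient_id`,
#'   `risk_group`, `ipsa`, `bat_blob_count` and `slices` (each slice a list
#'   with `water`, `fat`, `mask`, `truth`).
#' @examples
#' \donttest{
#' cohort <- generate_cohort(seed = 7)
#' table(vapply(cohort, `[[`, "", "risk_group"))
#' }
#' @export
generate_cohort <- function(profiles = default_group_profiles(),
                            params = phantom_params(),
                            slices_per_patient = 1L, seed = 1L) {
  if (!length(profiles)) stop("empty profile list", call. = FALSE)
  if (slices_per_patient < 1L) stop("slices_per_patient must be >= 1", call. = FALSE)
  lapply(profiles, function(p) stopifnot(inherits(p, "GroupProfile")))

  records <- list()
  patient_index <- 0L
  for (prof in profiles) {
    for (j in seq_len(prof$n_patients)) {
      patient_index <- patient_index + 1L
      ipsa <- sample_ipsa(prof, derive_seed(seed, patient_index, 1L))
      set.seed(derive_seed(seed, patient_index, 2L))
      n_blobs <- sample(prof$bat_blob_count_range[1]:prof$bat_blob_count_range[2], 1L)
      slices <- lapply(seq_len(slices_per_patient), function(s) {
        sp <- params
        sp$bat_blob_count <- n_blobs
        sp$seed <- derive_seed(seed, patient_index, 2L + s)
        generate_phantom_slice(sp)
      })
      records[[patient_index]] <- structure(
        list(patient_id = sprintf("P%03d", patient_index),
             risk_group = prof$group_label,
             ipsa = ipsa,
             bat_blob_count = n_blobs,
             slices = slices),
        class = "PatientRecord")
    }
  }
  records
}
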