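# End-to-end driver: simulate a phantom cohort to disk, analyze a manifest
# of slice files plus a clinical table, and write the report artifacts.
# Reruns with the same config and seed reproduce every numeric CSV bitwise.

#' Pipeline configuration
#'
#' Bundles every tunable of a run. Can be loaded from a JSON or YAML file
#' whose top-level keys match the argument names (nested `conversion`,
#' `extraction`, `policy` lists configure the respective specs).
#'
#' @param manifest path to the slice manifest CSV with columns
#'   `patient_id,slice_index,water_path,fat_path,mask_path`.
#' @param clinical path to the clinical CSV with columns
#'   `patient_id,risk_group,ipsa_ng_ml`.
#' @param out_dir output directory (created if absent).
#' @param conversion a [conversion_spec()].
#' @param extraction an [extraction_spec()].
#' @param policy a [ratio_policy()].
#' @param n_boot bootstrap replicates for AUC uncertainty.
#' @param seed master seed.
#' @param image_format `"pgm"`, `"png"` or `"csv"` for display images.
#' @return a list of class `PipelineConfig`.
#' @export
pipeline_config <- function(manifest = NULL, clinical = NULL, out_dir = ".",
                            conversion = conversion_spec(),
                            extraction = extraction_spec(),
                            policy = ratio_policy(),
                            n_boot = 2000L, seed = 1L,
                            image_format = c("pgm", "png", "csv")) {
  image_format <- match.arg(image_format)
  stopifnot(inherits(conversion, "ConversionSpec"),
            inherits(extraction, "ExtractionSpec"),
            inherits(policy, "RatioPolicy"))
  structure(list(manifest = manifest, clinical = clinical, out_dir = out_dir,
                 conversion = conversion, extraction = extraction,
                 policy = policy, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), image_format = image_format),
            class = "PipelineConfig")
}

#' @rdname pipeline_config
#' @param path JSON (`.json`) or YAML (`.yml`/`.yaml`) config file.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else stop(sprintf("config must be .json or .yaml, got %s", path),
                   call. = FALSE)
  conv <- do.call(conversion_spec, as.list(raw$conversion %||% list()))
  extr <- do.call(extraction_spec, as.list(raw$extraction %||% list()))
  pol <- do.call(ratio_policy, as.list(raw$policy %||% list()))
  pipeline_config(manifest = raw$manifest, clinical = raw$clinical,
                  out_dir = raw$out_dir %||% ".", conversion = conv,
                  extraction = extr, policy = pol,
                  n_boot = raw$n_boot %||% 2000L, seed = raw$seed %||% 1L,
                  image_format = raw$image_format %||% "pgm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable config fingerprint for the run manifest (FNV-1a over the JSON form;
# no cryptographic need, just change detection)
config_hash <- function(config) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  s <- jsonlite::toJSON(strip(config), auto_unbox = TRUE, null = "null")
  bytes <- utf8ToInt(as.character(s))
  hash <- 2166136261
  for (b in bytes) hash <- (bitwXor(as.integer(hash %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(hash))
}

#' Write a phantom cohort to disk
#'
#' Materializes a synthetic cohort as per-slice water/fat/mask files, a
#' clinical table and a slice manifest, in the layout [run_pipeline()]
#' consumes.
#'
#' @param out_dir output directory.
#' @param profiles,params,slices_per_patient,seed see [generate_cohort()].
#' @param image_format `"pgm"`, `"csv"` or `"png"` (PNG only for masks; slice
#'   matrices are 12-bit and use PGM/CSV).
#' @return invisibly, a list with the manifest and clinical table paths.
#' @export
simulate_cohort_to_disk <- function(out_dir,
                                    profiles = default_group_profiles(),
                                    params = phantom_params(),
                                    slices_per_patient = 1L, seed = 1L,
                                    image_format = c("pgm", "csv")) {
  image_format <- match.arg(image_format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  slice_dir <- file.path(out_dir, "slices")
  dir.create(slice_dir, showWarnings = FALSE)
  cohort <- generate_cohort(profiles, params, slices_per_patient, seed)

  rows <- list()
  for (rec in cohort) {
    for (s in seq_along(rec$slices)) {
      sl <- rec$slices[[s]]
      base <- file.path(slice_dir, sprintf("%s_s%02d", rec$patient_id, s))
      wp <- paste0(base, "_water.", image_format)
      fp <- paste0(base, "_fat.", image_format)
      mp <- paste0(base, "_mask.", image_format)
      write_image_matrix(sl$water, wp)
      write_image_matrix(sl$fat, fp)
      write_mask(sl$mask, mp)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = rec$patient_id, slice_index = s,
        water_path = wp, fat_path = fp, mask_path = mp,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)

  clinical <- data.frame(
    patient_id = vapply(cohort, `[[`, "", "patient_id"),
    risk_group = vapply(cohort, `[[`, "", "risk_group"),
    ipsa_ng_ml = vapply(cohort, `[[`, 0, "ipsa"),
    stringsAsFactors = FALSE)
  clinical_path <- file.path(out_dir, "clinical.csv")
  utils::write.csv(clinical, clinical_path, row.names = FALSE)
  invisible(list(manifest = manifest_path, clinical = clinical_path,
                 cohort = cohort))
}

# load one patient's slices off disk per the manifest rows
load_patient_record <- function(pid, clin_row, mrows) {
  slices <- lapply(seq_len(nrow(mrows)), function(i) {
    list(water = read_image_matrix(mrows$water_path[i], "water"),
         fat = read_image_matrix(mrows$fat_path[i], "fat"),
         mask = read_mask(mrows$mask_path[i]))
  })
  structure(list(patient_id = pid, risk_group = clin_row$risk_group,
                 ipsa = clin_row$ipsa_ng_ml, slices = slices),
            class = "PatientRecord")
}

#' Run the full analysis pipeline from files on disk
#'
#' Loads the manifest and clinical table, runs the per-slice image pipeline
#' for every patient (writing the four display renderings and the RGB
#' contour overlay per slice plus per-slice counters), then the cohort
#' report (`patient_summaries.csv`, `group_comparison.csv`,
#' `roc_results.csv`, `roc_curves.csv`, `summary.txt`) and a
#' `run_manifest.json` recording the config hash, seed and package version.
#' A failure in one patient is recorded and the others still complete; the
#' returned status is nonzero if any patient failed.
#'
#' @param config a [pipeline_config()] with `manifest` and `clinical` set.
#' @return invisibly, a list with `status` (0 on full success), `report`
#'   (the `CohortReport`, or NULL if too few patients survived), and
#'   `failures` (named character vector of per-patient error messages).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(config$manifest) || is.null(config$clinical))
    stop("config must name manifest and clinical files", call. = FALSE)
  manifest <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
  clinical <- utils::read.csv(config$clinical, stringsAsFactors = FALSE)
  need <- c("patient_id", "slice_index", "water_path", "fat_path", "mask_path")
  if (!all(need %in% names(manifest)))
    stop("manifest is missing columns: ",
         paste(setdiff(need, names(manifest)), collapse = ", "), call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(config$out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)

  cohort <- list()
  failures <- character(0)
  slice_stats <- list()
  ifmt <- config$image_format
  for (pid in unique(manifest$patient_id)) {
    res <- tryCatch({
      mrows <- manifest[manifest$patient_id == pid, , drop = FALSE]
      crow <- clinical[clinical$patient_id == pid, , drop = FALSE]
      if (nrow(crow) != 1L)
        stop(sprintf("patient %s has %d clinical rows", pid, nrow(crow)))
      rec <- load_patient_record(pid, crow, mrows)
      for (s in seq_along(rec$slices)) {
        sl <- rec$slices[[s]]
        r <- water_oil_ratio(sl$water, sl$fat, config$policy)
        pr <- apply_roi(r, sl$mask)
        ex <- extract_brown_fat(pr, sl$mask, config$extraction)
        base <- file.path(img_dir, sprintf("%s_s%02d", pid, s))
        write_display_image(rescale_intensity(unclass_matrix(sl$water), config$conversion),
                            paste0(base, "_IWO.", ifmt))
        write_display_image(rescale_intensity(unclass_matrix(sl$fat), config$conversion),
                            paste0(base, "_IFO.", ifmt))
        write_display_image(suppressWarnings(render_ratio_image(r)),
                            paste0(base, "_IRWO.", ifmt))
        ibpr <- suppressWarnings(render_ratio_image(ex$bprwo))
        write_display_image(ibpr, paste0(base, "_IBPRWO.", ifmt))
        write_ppm(overlay_contours(ibpr, sl$mask), paste0(base, "_overlay.ppm"))
        slice_stats[[length(slice_stats) + 1L]] <- data.frame(
          patient_id = pid, slice_index = s,
          n_roi = sum(sl$mask$in_roi), k_retained = ex$k,
          n_capped = attr(r, "n_capped"),
          retained_mean = mean(ex$bprwo[ex$retained_indices]),
          stringsAsFactors = FALSE)
      }
      rec
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[pid] <- conditionMessage(res)
      message(sprintf("patient %s failed: %s", pid, conditionMessage(res)))
    } else {
      cohort[[length(cohort) + 1L]] <- res
    }
  }

  if (length(slice_stats))
    utils::write.csv(do.call(rbind, slice_stats),
                     file.path(config$out_dir, "slice_stats.csv"),
                     row.names = FALSE)

  report <- NULL
  groups <- vapply(cohort, `[[`, "", "risk_group")
  if (length(cohort) >= 2L && length(unique(groups)) >= 2L) {
    report <- cohort_report(cohort, config$extraction, config$policy,
                            n_boot = config$n_boot, seed = config$seed)
    write_cohort_report(report, config$out_dir)
  } else {
    failures["cohort"] <- "too few patients or groups for a cohort report"
  }

  jsonlite::write_json(
    list(config_hash = config_hash(config), seed = config$seed,
         package_version = as.character(utils::packageVersion("batcsi")),
         n_patients = length(cohort), n_failures = length(failures)),
    file.path(config$out_dir, "run_manifest.json"), auto_unbox = TRUE)

  invisible(list(status = if (length(failures)) 1L else 0L,
                 report = report, failures = failures))
}

unclass_matrix <- function(x) matrix(as.numeric(x), nrow(x), ncol(x))

#' Write the cohort report CSVs and text summary
#'
#' @param report a `CohortReport` from [cohort_report()].
#' @param out_dir output directory.
#' @export
write_cohort_report <- function(report, out_dir) {
  stopifnot(inherits(report, "CohortReport"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$summaries,
                   file.path(out_dir, "patient_summaries.csv"), row.names = FALSE)
  cmp <- report$comparison
  utils::write.csv(data.frame(
    comparison = "clinically_significant_vs_low",
    mean_a = cmp$mean_a, mean_b = cmp$mean_b, sd_a = cmp$sd_a, sd_b = cmp$sd_b,
    difference = cmp$difference,
    ci_low = cmp$difference_ci_low, ci_high = cmp$difference_ci_high,
    t_p_value = cmp$t_p_value,
    mannwhitney_p_value = cmp$mannwhitney_p_value),
    file.path(out_dir, "group_comparison.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, lapply(report$roc, function(r)
    data.frame(feature = r$feature_label, auc = r$auc, auc_sd = r$auc_sd,
               n_pos = r$n_pos, n_neg = r$n_neg))),
    file.path(out_dir, "roc_results.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, lapply(report$roc, function(r)
    cbind(feature = r$feature_label, r$curve))),
    file.path(out_dir, "roc_curves.csv"), row.names = FALSE)
  con <- file(file.path(out_dir, "summary.txt"), "w")
  sink(con); print(report); sink(); close(con)
  invisible(out_dir)
}
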