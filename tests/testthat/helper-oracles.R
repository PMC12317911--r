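# Independent brute-force oracles and small fixture builders. Oracles are
# written as naive loops/enumerations on purpose: they must not share code
# paths with the implementation they check.

# elementwise ROI masking by explicit double loop
oracle_apply_roi <- function(values, in_roi) {
  out <- values
  for (r in seq_len(nrow(values)))
    for (c in seq_len(ncol(values)))
      if (!in_roi[r, c]) out[r, c] <- 0
  out
}

# stable sort on (-value, row-major index), take k: the retained index set
oracle_extract_indices <- function(values, in_roi, k) {
  recs <- NULL
  w <- ncol(values)
  for (r in seq_len(nrow(values)))
    for (c in seq_len(w))
      if (in_roi[r, c])
        recs <- rbind(recs, c(values[r, c], (r - 1) * w + c, r, c))
  ord <- order(-recs[, 1], recs[, 2])
  recs[ord[seq_len(k)], 3:4, drop = FALSE]
}

# O(n^2) pairwise concordance AUC with half credit for ties
oracle_auc_concordance <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos)
    for (n in neg)
      tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# naive double-loop water/fat ratio with the zero-fat policy
oracle_ratio <- function(water, fat, cap) {
  out <- matrix(0, nrow(water), ncol(water))
  for (r in seq_len(nrow(water)))
    for (c in seq_len(ncol(water))) {
      wv <- water[r, c]; fv <- fat[r, c]
      out[r, c] <- if (fv > 0) wv / fv else if (wv > 0) cap else 0
    }
  out
}

# small fast phantom geometry for tests
tiny_params <- function(...) {
  phantom_params(image_height = 48, image_width = 48,
                 prostate_center = c(24, 24), prostate_radii = c(8, 10),
                 annulus_width = 5, ...)
}

# a patient record built directly from matrices (no phantom randomness)
manual_record <- function(water_list, fat_list, mask, id = "T001",
                          risk = "low", ipsa = 5) {
  slices <- Map(function(w, f) list(
    water = raw_image_matrix(w, "water"),
    fat = raw_image_matrix(f, "fat"),
    mask = mask), water_list, fat_list)
  structure(list(patient_id = id, risk_group = risk, ipsa = ipsa,
                 slices = unname(slices)),
            class = "PatientRecord")
}
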