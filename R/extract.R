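#' Feature name registry
#'
#' The fixed, documented feature order used by [extract_all()] and by the
#' POE+ACC tie-break: histogram (HIS, 9), co-occurrence (COM, 220 for the
#' default distance grid), run-length (RUN, 20), gradient (GRA, 5),
#' autoregressive (ARM, 5), then wavelet energies (WAV, `4 * wav_scales`).
#'
#' @param com_distances interpixel distances of the co-occurrence grid.
#' @param wav_scales number of Haar wavelet scales.
#' @return data.frame with columns `name` and `category`.
#' @export
feature_registry <- function(com_distances = 1:5, wav_scales = 3L) {
  his <- c("Mean", "Variance", "Skewness", "Kurtosis",
           "Perc.01%", "Perc.10%", "Perc.50%", "Perc.90%", "Perc.99%")
  com <- unlist(lapply(com_offsets(com_distances), function(o)
    sprintf("S(%d,%d)%s", o[1], o[2], com_stat_names)))
  rlm <- as.vector(vapply(rlm_dir_prefix,
                          function(d) paste0(d, "_", rlm_stat_names),
                          character(5)))
  gra <- c("GrMean", "GrVariance", "GrSkewness", "GrKurtosis", "GrNonZeros")
  arm <- c("Teta1", "Teta2", "Teta3", "Teta4", "Sigma")
  wav <- as.vector(t(outer(seq_len(wav_scales), c("LL", "LH", "HL", "HH"),
                           function(s, b) sprintf("WavEn%s_s-%d", b, s))))
  data.frame(
    name = c(his, com, rlm, gra, arm, wav),
    category = rep(c("HIS", "COM", "RUN", "GRA", "ARM", "WAV"),
                   c(length(his), length(com), length(rlm),
                     length(gra), length(arm), length(wav))),
    stringsAsFactors = FALSE)
}

#' Extract the full feature vector of an ROI
#'
#' Concatenates all six families in the fixed registry order (HIS, COM, RUN,
#' GRA, ARM, WAV). Features that are infeasible for the ROI (e.g. large
#' co-occurrence offsets on a tiny mask) carry explicit `NA` markers; the
#' name set is always complete. The result is deterministic for a fixed
#' input and configuration.
#'
#' @param roi a `quantized_roi`.
#' @param com_distances interpixel distances for the co-occurrence grid.
#' @param wav_scales number of Haar wavelet scales.
#' @return named numeric vector with a `category` attribute (one of HIS,
#'   COM, RUN, GRA, ARM, WAV per feature).
#' @export
extract_all <- function(roi, com_distances = 1:5, wav_scales = 3L) {
  stopifnot(inherits(roi, "quantized_roi"))
  roi <- roi_crop(roi)
  reg <- feature_registry(com_distances, wav_scales)
  out <- c(histogram_features(roi),
           com_grid(roi, com_distances),
           rlm_features(roi),
           gradient_features(roi),
           arm_features(roi),
           wavelet_features(roi, wav_scales))
  stopifnot(identical(names(out), reg$name))
  attr(out, "category") <- reg$category
  out
}

#' Extract the feature table of a cohort
#'
#' Runs ROI construction, gray-level normalization/quantization and
#' [extract_all()] on every case and assembles the cases-by-features table
#' that all downstream steps (harmonization, selection, classification)
#' operate on.
#'
#' @param cohort list of `image_study` objects.
#' @param bits quantization depth for [normalize_quantize()].
#' @param com_distances,wav_scales passed to [extract_all()].
#' @return data.frame (with `check.names = FALSE`) holding `case_id`,
#'   `center_id`, `class_label` and one column per registered feature.
#' @export
extract_cohort <- function(cohort, bits = 6L, com_distances = 1:5,
                           wav_scales = 3L) {
  stopifnot(length(cohort) > 0)
  rows <- lapply(cohort, function(img) {
    mask <- make_roi_mask(img)
    roi <- normalize_quantize(img, mask, bits = bits)
    extract_all(roi, com_distances, wav_scales)
  })
  feats <- do.call(rbind, rows)
  meta <- data.frame(
    case_id = vapply(cohort, `[[`, character(1), "case_id"),
    center_id = vapply(cohort, `[[`, character(1), "center_id"),
    class_label = vapply(cohort, `[[`, character(1), "class_label"),
    stringsAsFactors = FALSE)
  out <- cbind(meta, as.data.frame(feats, check.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Split a feature table into metadata and feature matrix
#'
#' @param table a feature table from [extract_cohort()].
#' @return list with `meta` (data.frame of the id/label columns) and `X`
#'   (numeric matrix of feature values, columns named).
#' @export
feature_matrix <- function(table) {
  meta_cols <- intersect(c("case_id", "center_id", "class_label"),
                         names(table))
  X <- as.matrix(table[, setdiff(names(table), meta_cols), drop = FALSE])
  storage.mode(X) <- "double"
  list(meta = table[, meta_cols, drop = FALSE], X = X)
}
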