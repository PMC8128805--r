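#' Write a cohort to disk as 16-bit grayscale images plus a manifest
#'
#' Each case is stored as a single-channel 16-bit TIFF (intensities affinely
#' mapped onto the full 16-bit range; the per-case mapping is recorded in
#' the manifest so [read_cohort()] can undo it, up to 16-bit rounding) and
#' a manifest CSV with one row per case: `case_id`, `center_id`,
#' `class_label`, `roi_center_x`, `roi_center_y`, `roi_radius_mm`,
#' `pixel_spacing_mm`, `intensity_min`, `intensity_max`, `file`.
#'
#' @param cohort list of `image_study` objects.
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(s) {
    rng <- range(s$pixels)
    scaled <- if (diff(rng) > 0) (s$pixels - rng[1]) / diff(rng)
              else s$pixels * 0
    file <- paste0(s$case_id, ".tif")
    tiff::writeTIFF(scaled, file.path(dir, file), bits.per.sample = 16L)
    data.frame(case_id = s$case_id, center_id = s$center_id,
               class_label = s$class_label,
               roi_center_x = s$roi_center[1], roi_center_y = s$roi_center[2],
               roi_radius_mm = s$roi_radius_mm,
               pixel_spacing_mm = s$pixel_spacing_mm,
               intensity_min = rng[1], intensity_max = rng[2],
               file = file, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param manifest path to the manifest CSV; image paths are resolved
#'   relative to its directory.
#' @return list of `image_study` objects.
#' @export
read_cohort <- function(manifest) {
  m <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  lapply(seq_len(nrow(m)), function(i) {
    r <- m[i, ]
    img <- tiff::readTIFF(file.path(dir, r$file))
    if (length(dim(img)) == 3) img <- img[, , 1]
    pixels <- img * (r$intensity_max - r$intensity_min) + r$intensity_min
    new_image_study(pixels = pixels, pixel_spacing_mm = r$pixel_spacing_mm,
                    center_id = r$center_id, class_label = r$class_label,
                    case_id = r$case_id,
                    roi_center = c(r$roi_center_x, r$roi_center_y),
                    roi_radius_mm = r$roi_radius_mm)
  })
}
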