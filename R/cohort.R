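#' Configuration for a synthetic dual-center cohort
#'
#' Defines the study conditions for [generate_cohort()]: two centers (A, B)
#' imaging the same physical field of view at different matrix sizes, and two
#' lesion classes (cholesteatoma, MEI) that differ only in the second-order
#' spatial structure of their texture. The defaults mirror a dual-center
#' temporal-bone HRCT setting: 50 cases per center with a 23/27 (A) and 25/25
#' (B) cholesteatoma/MEI split, a 512x512 matrix at center A versus 768x768 at
#' center B over a common 102.4 mm field of view (pixel spacing 0.2 mm vs
#' 0.1333 mm), and center-specific intensity shift, noise level and
#' reconstruction blur.
#'
#' Lesion texture is a stationary Gaussian random field; the two classes get
#' different spatial correlation lengths and anisotropy, so they differ in
#' co-occurrence / run-length / wavelet structure but not in mean intensity.
#' Intensities are arbitrary HU-like units; no calibration is claimed.
#'
#' @param n_per_center named integer vector, cases per center (names "A","B").
#' @param chol_fraction named numeric vector in \[0,1\]: per-center fraction of
#'   cholesteatoma cases (the remainder are MEI).
#' @param matrix_size named integer vector: reconstruction matrix per center.
#' @param fov_mm physical field of view (mm), identical for both centers, so
#'   pixel spacing is `fov_mm / matrix_size`.
#' @param class_texture list with one entry per class, each holding
#'   `corr_mm` (Gaussian correlation length, mm) and `anisotropy` (ratio of
#'   x to y correlation lengths; 1 = isotropic).
#' @param texture_amplitude standard deviation of the lesion field (HU-like).
#' @param base_intensity mean lesion intensity common to both classes.
#' @param center_effect list with one entry per center, each holding `shift`
#'   (additive intensity offset), `noise_sd` (iid acquisition noise sd) and
#'   `blur_mm` (Gaussian reconstruction-kernel surrogate, sd in mm).
#' @param roi_radius_mm circular ROI radius (mm); area must exceed 4 mm^2.
#' @param seed integer RNG seed; fully determines the cohort.
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
#' @examples
#' cfg <- cohort_config(n_per_center = c(A = 4, B = 4),
#'                      matrix_size = c(A = 64, B = 96), fov_mm = 12.8)
#' cohort <- generate_cohort(cfg)
cohort_config <- function(n_per_center = c(A = 50, B = 50),
                          chol_fraction = c(A = 23 / 50, B = 25 / 50),
                          matrix_size = c(A = 512, B = 768),
                          fov_mm = 102.4,
                          class_texture = list(
                            cholesteatoma = list(corr_mm = 0.30, anisotropy = 1.0),
                            MEI           = list(corr_mm = 0.52, anisotropy = 1.0)),
                          texture_amplitude = 25,
                          base_intensity = 60,
                          center_effect = list(
                            A = list(shift = 0,  noise_sd = 4, blur_mm = 0.30),
                            B = list(shift = 30, noise_sd = 4, blur_mm = 0.30)),
                          roi_radius_mm = 2,
                          seed = 1L) {
  cfg <- list(n_per_center = n_per_center, chol_fraction = chol_fraction,
              matrix_size = matrix_size, fov_mm = fov_mm,
              class_texture = class_texture,
              texture_amplitude = texture_amplitude,
              base_intensity = base_intensity,
              center_effect = center_effect,
              roi_radius_mm = roi_radius_mm, seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  centers <- c("A", "B")
  for (nm in c("n_per_center", "chol_fraction", "matrix_size"))
    if (!all(centers %in% names(cfg[[nm]])))
      stop("`", nm, "` must be named with centers A and B", call. = FALSE)
  if (any(cfg$matrix_size <= 0) || any(cfg$matrix_size != round(cfg$matrix_size)))
    stop("matrix sizes must be positive integers", call. = FALSE)
  if (any(cfg$chol_fraction < 0) || any(cfg$chol_fraction > 1))
    stop("class fraction outside [0, 1]", call. = FALSE)
  if (cfg$fov_mm <= 0) stop("fov_mm must be positive", call. = FALSE)
  if (pi * cfg$roi_radius_mm^2 <= 4)
    stop("ROI area pi*r^2 must exceed 4 mm^2 (got ",
         signif(pi * cfg$roi_radius_mm^2, 3), " mm^2)", call. = FALSE)
  for (cc in centers) {
    n <- cfg$matrix_size[[cc]]
    spacing <- cfg$fov_mm / n
    r_px <- cfg$roi_radius_mm / spacing
    if ((n - 1) / 2 - r_px < 2)
      stop("ROI does not fit inside the ", cc,
           " image with a 2-pixel margin", call. = FALSE)
  }
  classes <- c("cholesteatoma", "MEI")
  if (!all(classes %in% names(cfg$class_texture)))
    stop("class_texture must define cholesteatoma and MEI", call. = FALSE)
  p1 <- cfg$class_texture$cholesteatoma; p2 <- cfg$class_texture$MEI
  if (isTRUE(all.equal(unlist(p1), unlist(p2))))
    stop("class texture parameters must differ between classes", call. = FALSE)
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic dual-center cohort configuration\n")
  for (cc in c("A", "B"))
    cat(sprintf("  center %s: n=%d, matrix %dx%d (spacing %.4f mm), shift %+g, noise sd %g, blur %g mm\n",
                cc, x$n_per_center[[cc]], x$matrix_size[[cc]], x$matrix_size[[cc]],
                x$fov_mm / x$matrix_size[[cc]], x$center_effect[[cc]]$shift,
                x$center_effect[[cc]]$noise_sd, x$center_effect[[cc]]$blur_mm))
  for (cl in names(x$class_texture))
    cat(sprintf("  class %s: correlation length %g mm, anisotropy %g\n",
                cl, x$class_texture[[cl]]$corr_mm, x$class_texture[[cl]]$anisotropy))
  cat(sprintf("  ROI radius %g mm, seed %d\n", x$roi_radius_mm, x$seed))
  invisible(x)
}

## DFT frequencies in cycles/mm for an n-point grid with spacing dx
fft_freq <- function(n, dx) {
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]
  k / (n * dx)
}

## Gaussian transfer function exp(-2 pi^2 (kx^2 lx^2 + ky^2 ly^2)) on the
## DFT frequency grid; lx/ly are kernel standard deviations in mm.
gaussian_transfer <- function(n, dx, lx, ly) {
  k <- fft_freq(n, dx)
  gx <- exp(-2 * pi^2 * (k * lx)^2)
  gy <- exp(-2 * pi^2 * (k * ly)^2)
  outer(gy, gx)  # rows = y frequency, cols = x frequency
}

## Spectral synthesis of stationary Gaussian random fields: each inverse FFT
## of complex white noise shaped by `transfer` yields two independent real
## fields (real and imaginary parts). `norm` scales to unit variance.
synth_fields <- function(n_fields, transfer, norm) {
  n <- nrow(transfer)
  out <- vector("list", n_fields)
  for (p in seq_len(ceiling(n_fields / 2))) {
    w <- matrix(complex(real = stats::rnorm(n * n),
                        imaginary = stats::rnorm(n * n)), n, n)
    z <- stats::fft(w * transfer, inverse = TRUE) / (n * n) / norm
    i <- 2 * p - 1
    out[[i]] <- Re(z)
    if (i + 1 <= n_fields) out[[i + 1]] <- Im(z)
  }
  out
}

## Fractional-area-average downsampling operator from n_src to n_tgt pixels
## along one axis (rows of the returned matrix sum to 1).
area_average_operator <- function(n_tgt, n_src) {
  ratio <- n_src / n_tgt
  D <- matrix(0, n_tgt, n_src)
  for (i in seq_len(n_tgt)) {
    lo <- (i - 1) * ratio
    hi <- i * ratio
    j0 <- floor(lo) + 1
    j1 <- ceiling(hi)
    for (j in j0:min(j1, n_src)) {
      w <- min(hi, j) - max(lo, j - 1)
      if (w > 0) D[i, j] <- w / ratio
    }
  }
  D
}

#' Generate a synthetic dual-center cohort
#'
#' Simulates every case on a common physical grid at the finest center
#' resolution, then samples it at each center's matrix size by exact
#' fractional-area averaging, so that within a class the only systematic
#' between-center differences are acquisition effects: matrix size / pixel
#' spacing, reconstruction blur, additive intensity shift and iid noise.
#' Class-specific texture is a unit-variance stationary Gaussian random field
#' with the class's correlation length and anisotropy (spectral synthesis with
#' a Gaussian kernel), scaled by `texture_amplitude` and offset by
#' `base_intensity`. The seed in `config` fully determines the output.
#'
#' @param config a [cohort_config()].
#' @return list of `image_study` objects, each with elements `pixels`
#'   (matrix, rows = y), `pixel_spacing_mm`, `center_id`, `class_label`,
#'   `case_id`, `roi_center` (0-based `c(x, y)` pixel coordinates) and
#'   `roi_radius_mm`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  set.seed(config$seed)

  n_fine <- max(config$matrix_size)
  dx_fine <- config$fov_mm / n_fine
  classes <- c("cholesteatoma", "MEI")

  ## per-class spectral transfer, normalized so the unblurred field has sd 1
  class_spec <- lapply(classes, function(cl) {
    p <- config$class_texture[[cl]]
    lx <- p$corr_mm * sqrt(p$anisotropy)
    ly <- p$corr_mm / sqrt(p$anisotropy)
    A <- gaussian_transfer(n_fine, dx_fine, lx, ly)
    list(A = A, norm = sqrt(sum(A^2)) / (n_fine * n_fine))
  })
  names(class_spec) <- classes

  downsamplers <- lapply(config$matrix_size, function(m)
    if (m < n_fine) area_average_operator(m, n_fine) else NULL)

  cohort <- list()
  for (cc in c("A", "B")) {
    n_c <- config$n_per_center[[cc]]
    n_chol <- round(config$chol_fraction[[cc]] * n_c)
    counts <- c(cholesteatoma = n_chol, MEI = n_c - n_chol)
    eff <- config$center_effect[[cc]]
    m_c <- config$matrix_size[[cc]]
    spacing <- config$fov_mm / m_c
    blur <- gaussian_transfer(n_fine, dx_fine, eff$blur_mm, eff$blur_mm)
    D <- downsamplers[[cc]]
    idx <- 0L
    for (cl in classes) {
      m <- counts[[cl]]
      if (m == 0) next
      cs <- class_spec[[cl]]
      fields <- synth_fields(m, cs$A * blur, cs$norm)
      for (f in fields) {
        idx <- idx + 1L
        img <- if (is.null(D)) f else D %*% f %*% t(D)
        img <- config$base_intensity + eff$shift +
          config$texture_amplitude * img +
          matrix(stats::rnorm(m_c * m_c, sd = eff$noise_sd), m_c, m_c)
        cohort[[length(cohort) + 1L]] <- new_image_study(
          pixels = img, pixel_spacing_mm = spacing, center_id = cc,
          class_label = cl, case_id = sprintf("%s%03d", cc, idx),
          roi_center = c((m_c - 1) / 2, (m_c - 1) / 2),
          roi_radius_mm = config$roi_radius_mm)
      }
    }
  }
  cohort
}

#' Construct an image study record
#'
#' Carrier for one case: a 2D intensity grid with spacing metadata, center and
#' class labels, and a circular ROI definition.
#'
#' @param pixels numeric matrix (rows index y, columns x).
#' @param pixel_spacing_mm square pixel spacing in mm.
#' @param center_id center/batch label.
#' @param class_label lesion class label.
#' @param case_id unique case identifier.
#' @param roi_center 0-based `c(x, y)` pixel coordinates of the ROI center
#'   (pixel-center convention).
#' @param roi_radius_mm ROI radius in mm.
#' @return an `image_study` object.
#' @export
new_image_study <- function(pixels, pixel_spacing_mm, center_id, class_label,
                            case_id, roi_center, roi_radius_mm) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)), pixel_spacing_mm > 0,
            length(roi_center) == 2, roi_radius_mm > 0)
  r_px <- roi_radius_mm / pixel_spacing_mm
  if (roi_center[1] - r_px < 2 || roi_center[2] - r_px < 2 ||
      roi_center[1] + r_px > ncol(pixels) - 3 ||
      roi_center[2] + r_px > nrow(pixels) - 3)
    stop("ROI circle must lie inside the image with a 2-pixel margin",
         call. = FALSE)
  structure(list(pixels = pixels, pixel_spacing_mm = pixel_spacing_mm,
                 center_id = center_id, class_label = class_label,
                 case_id = case_id, roi_center = as.numeric(roi_center),
                 roi_radius_mm = roi_radius_mm),
            class = "image_study")
}

#' @export
print.image_study <- function(x, ...) {
  cat(sprintf("<image_study %s> %dx%d @ %.4f mm, center %s, class %s, ROI r=%g mm\n",
              x$case_id, nrow(x$pixels), ncol(x$pixels), x$pixel_spacing_mm,
              x$center_id, x$class_label, x$roi_radius_mm))
  invisible(x)
}
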