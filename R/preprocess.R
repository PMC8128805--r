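#' Build the circular ROI mask for a case
#'
#' A pixel belongs to the ROI iff the distance from its center to the ROI
#' center is at most the ROI radius, measured in physical units (pixel-center
#' convention, 0-based coordinates). The physical ROI area must exceed
#' 4 mm^2 and the mask must hold at least 16 pixels.
#'
#' @param image an `image_study`.
#' @return a `roi_mask`: list with `mask` (logical matrix congruent with the
#'   image), `roi_center`, `roi_radius_mm`, `pixel_spacing_mm`, `n_pixels`
#'   and `area_mm2`.
#' @export
make_roi_mask <- function(image) {
  stopifnot(inherits(image, "image_study"))
  sp <- image$pixel_spacing_mm
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  x <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  y <- matrix(0:(nr - 1), nr, nc)
  r_px <- image$roi_radius_mm / sp
  mask <- (x - image$roi_center[1])^2 + (y - image$roi_center[2])^2 <= r_px^2
  n_pix <- sum(mask)
  area <- n_pix * sp^2
  if (area <= 4)
    stop("ROI area ", signif(area, 4), " mm^2 does not exceed the 4 mm^2 minimum",
         call. = FALSE)
  if (n_pix < 16)
    stop("ROI mask has fewer than 16 pixels", call. = FALSE)
  structure(list(mask = mask, roi_center = image$roi_center,
                 roi_radius_mm = image$roi_radius_mm, pixel_spacing_mm = sp,
                 n_pixels = n_pix, area_mm2 = area),
            class = "roi_mask")
}

#' Normalize and quantize the gray levels of an ROI
#'
#' Computes the ROI mean `mu` and standard deviation `sigma`, clips
#' intensities to `[mu - 3 sigma, mu + 3 sigma]` ("limiting the dynamics";
#' out-of-range values are saturated, not discarded), and linearly maps that
#' interval onto the integer levels `1..2^bits` (the lower endpoint maps to
#' level 1, the upper endpoint to level `2^bits`). Co-occurrence and
#' run-length features are computed on the quantized levels; the remaining
#' families use the clipped, unquantized values. This makes every feature
#' invariant to a positive affine rescaling of the raw intensities (exactly
#' for quantized features, up to the clipping map otherwise).
#'
#' A constant ROI (`sigma = 0`) is a documented degenerate case: all pixels
#' map to the mid-scale level with a warning.
#'
#' @param image an `image_study`.
#' @param mask the corresponding [make_roi_mask()] result.
#' @param bits quantization depth; `2^bits` gray levels (default 6, i.e. 64).
#' @return a `quantized_roi`: list with `levels` (integer matrix, `NA`
#'   outside the mask), `clipped` (clipped intensities, `NA` outside),
#'   `mask`, `n_levels`, `pixel_spacing_mm`, `params` (`mu`, `sigma`,
#'   `n_levels`) and `case_id`.
#' @export
normalize_quantize <- function(image, mask, bits = 6L) {
  stopifnot(inherits(image, "image_study"), inherits(mask, "roi_mask"),
            bits >= 1, sum(mask$mask) > 0)
  n_levels <- as.integer(2^bits)
  v <- image$pixels[mask$mask]
  mu <- mean(v)
  sigma <- stats::sd(v)
  clipped <- matrix(NA_real_, nrow(image$pixels), ncol(image$pixels))
  levels <- matrix(NA_integer_, nrow(image$pixels), ncol(image$pixels))
  if (sigma == 0) {
    warning("constant ROI (sigma = 0): all pixels map to the mid-scale level")
    clipped[mask$mask] <- v
    levels[mask$mask] <- as.integer(n_levels / 2)
  } else {
    lo <- mu - 3 * sigma
    hi <- mu + 3 * sigma
    cv <- pmin(pmax(v, lo), hi)
    clipped[mask$mask] <- cv
    lev <- floor((cv - lo) / (hi - lo) * n_levels) + 1
    levels[mask$mask] <- as.integer(pmin(lev, n_levels))
  }
  structure(list(levels = levels, clipped = clipped, mask = mask$mask,
                 n_levels = n_levels, pixel_spacing_mm = mask$pixel_spacing_mm,
                 params = list(mu = mu, sigma = sigma, n_levels = n_levels),
                 case_id = image$case_id),
            class = "quantized_roi")
}

#' Resample an image to a smaller square matrix
#'
#' Bilinear interpolation onto a `target x target` grid covering the same
#' physical field of view (pixel-center convention). Pixel spacing is scaled
#' by `source/target`; the ROI center is mapped to the new grid and the
#' physical ROI radius is unchanged. This is the image-domain ("preimage")
#' center-effect correction: resampling the larger-matrix center onto the
#' smaller matrix used by the other center.
#'
#' @param image an `image_study` with a square pixel grid.
#' @param target_matrix target matrix size (must not exceed the source size).
#' @return a new `image_study`.
#' @export
resample_image <- function(image, target_matrix) {
  stopifnot(inherits(image, "image_study"))
  n_src <- nrow(image$pixels)
  if (ncol(image$pixels) != n_src)
    stop("resampling requires a square image", call. = FALSE)
  n_tgt <- as.integer(target_matrix)
  if (n_tgt > n_src) stop("target matrix exceeds source matrix", call. = FALSE)
  if (n_tgt == n_src) return(image)
  ratio <- n_src / n_tgt
  W <- bilinear_operator(n_tgt, n_src)
  out <- W %*% image$pixels %*% t(W)
  new_image_study(pixels = out,
                  pixel_spacing_mm = image$pixel_spacing_mm * ratio,
                  center_id = image$center_id, class_label = image$class_label,
                  case_id = image$case_id,
                  roi_center = (image$roi_center + 0.5) / ratio - 0.5,
                  roi_radius_mm = image$roi_radius_mm)
}

## 1D bilinear interpolation operator (n_tgt x n_src), pixel-center aligned:
## target pixel i sits at source coordinate (i + .5) * ratio - .5.
bilinear_operator <- function(n_tgt, n_src) {
  ratio <- n_src / n_tgt
  s <- (seq_len(n_tgt) - 0.5) * ratio - 0.5
  s <- pmin(pmax(s, 0), n_src - 1)
  j0 <- pmin(floor(s), n_src - 2)
  w1 <- s - j0
  W <- matrix(0, n_tgt, n_src)
  W[cbind(seq_len(n_tgt), j0 + 1)] <- 1 - w1
  W[cbind(seq_len(n_tgt), j0 + 2)] <- w1
  W
}
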