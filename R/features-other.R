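## Gradient, autoregressive-model, Haar-wavelet and histogram features.
## All four families operate on the clipped (mu +/- 3 sigma) but unquantized
## intensities, mirroring common texture-analysis practice where integer
## quantization is a co-occurrence / run-length construct.

## population central moments
central_moments <- function(v) {
  m <- mean(v)
  d <- v - m
  list(mean = m, m2 = mean(d^2), m3 = mean(d^3), m4 = mean(d^4))
}

#' Absolute gradient features
#'
#' Central-difference gradient magnitude
#' `g = sqrt((I(x+1,y) - I(x-1,y))^2 + (I(x,y+1) - I(x,y-1))^2) / 2` on
#' interior ROI pixels (those whose four axial neighbours are in-mask),
#' computed on the clipped intensities. Emits the mean, variance, skewness
#' and excess kurtosis of `g` plus the fraction of interior pixels with
#' nonzero gradient. Variance, skewness and kurtosis use population moments;
#' skewness and kurtosis are `NA` when the gradient is constant.
#'
#' @param roi a `quantized_roi`.
#' @return named numeric vector: `GrMean`, `GrVariance`, `GrSkewness`,
#'   `GrKurtosis`, `GrNonZeros`.
#' @export
gradient_features <- function(roi) {
  stopifnot(inherits(roi, "quantized_roi"))
  roi <- roi_crop(roi)
  M <- roi$clipped
  msk <- roi$mask
  nr <- nrow(M); nc <- ncol(M)
  nm <- c(GrMean = NA_real_, GrVariance = NA_real_, GrSkewness = NA_real_,
          GrKurtosis = NA_real_, GrNonZeros = NA_real_)
  if (nr < 3 || nc < 3) return(nm)
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  interior <- msk[ri, ci, drop = FALSE] &
    msk[ri, ci - 1, drop = FALSE] & msk[ri, ci + 1, drop = FALSE] &
    msk[ri - 1, ci, drop = FALSE] & msk[ri + 1, ci, drop = FALSE]
  if (!any(interior)) return(nm)
  gx <- (M[ri, ci + 1, drop = FALSE] - M[ri, ci - 1, drop = FALSE])
  gy <- (M[ri + 1, ci, drop = FALSE] - M[ri - 1, ci, drop = FALSE])
  g <- sqrt(gx^2 + gy^2)[interior] / 2
  mom <- central_moments(g)
  c(GrMean = mom$mean,
    GrVariance = mom$m2,
    GrSkewness = if (mom$m2 > 0) mom$m3 / mom$m2^1.5 else NA_real_,
    GrKurtosis = if (mom$m2 > 0) mom$m4 / mom$m2^2 - 3 else NA_real_,
    GrNonZeros = mean(g > 0))
}

#' Causal autoregressive model features
#'
#' Least-squares fit of the first-order causal autoregressive image model
#' `I(x,y) = th1 I(x-1,y) + th2 I(x-1,y-1) + th3 I(x,y-1) + th4 I(x+1,y-1) + e`
#' on mean-centered clipped intensities, using every ROI pixel whose causal
#' neighbourhood lies inside the mask. Emits the four coefficients
#' (`Teta1`..`Teta4`) and the residual standard deviation (`Sigma`, root mean
#' square residual). Requires at least 20 usable pixels (otherwise all `NA`
#' with a warning); for a rank-deficient design (e.g. constant ROI) the
#' coefficients are set to 0 with a warning.
#'
#' @param roi a `quantized_roi`.
#' @return named numeric vector: `Teta1`..`Teta4`, `Sigma`.
#' @export
arm_features <- function(roi) {
  stopifnot(inherits(roi, "quantized_roi"))
  roi <- roi_crop(roi)
  msk <- roi$mask
  nr <- nrow(msk); nc <- ncol(msk)
  nm <- c(Teta1 = NA_real_, Teta2 = NA_real_, Teta3 = NA_real_,
          Teta4 = NA_real_, Sigma = NA_real_)
  if (nr < 2 || nc < 3) return(nm)
  M <- roi$clipped - mean(roi$clipped[msk])
  ri <- 2:nr; ci <- 2:(nc - 1)
  ok <- msk[ri, ci, drop = FALSE] &
    msk[ri, ci - 1, drop = FALSE] & msk[ri - 1, ci - 1, drop = FALSE] &
    msk[ri - 1, ci, drop = FALSE] & msk[ri - 1, ci + 1, drop = FALSE]
  n_ok <- sum(ok)
  if (n_ok < 20) {
    warning("fewer than 20 pixels with a full causal neighbourhood; ARM features missing")
    return(nm)
  }
  y <- M[ri, ci, drop = FALSE][ok]
  X <- cbind(M[ri, ci - 1, drop = FALSE][ok],
             M[ri - 1, ci - 1, drop = FALSE][ok],
             M[ri - 1, ci, drop = FALSE][ok],
             M[ri - 1, ci + 1, drop = FALSE][ok])
  fit <- stats::lm.fit(X, y)
  theta <- fit$coefficients
  if (anyNA(theta)) {
    warning("rank-deficient autoregressive design; undetermined coefficients set to 0")
    theta[is.na(theta)] <- 0
  }
  res <- y - X %*% theta
  c(Teta1 = unname(theta[1]), Teta2 = unname(theta[2]),
    Teta3 = unname(theta[3]), Teta4 = unname(theta[4]),
    Sigma = sqrt(mean(res^2)))
}

## One level of the non-standard 2D Haar transform (orthonormal pairs).
## Returns LL, HL (high-pass along x), LH (high-pass along y), HH.
haar_step <- function(M) {
  nc <- ncol(M); nr <- nrow(M)
  o <- seq(1, nc, by = 2); e <- o + 1
  Lx <- (M[, o, drop = FALSE] + M[, e, drop = FALSE]) / sqrt(2)
  Hx <- (M[, o, drop = FALSE] - M[, e, drop = FALSE]) / sqrt(2)
  o <- seq(1, nr, by = 2); e <- o + 1
  list(LL = (Lx[o, , drop = FALSE] + Lx[e, , drop = FALSE]) / sqrt(2),
       LH = (Lx[o, , drop = FALSE] - Lx[e, , drop = FALSE]) / sqrt(2),
       HL = (Hx[o, , drop = FALSE] + Hx[e, , drop = FALSE]) / sqrt(2),
       HH = (Hx[o, , drop = FALSE] - Hx[e, , drop = FALSE]) / sqrt(2))
}

## Full decomposition on a padded bounding box; also reduces the mask so
## that a coefficient is flagged when its spatial support intersects the ROI.
haar_decompose <- function(M, msk, n_scales) {
  out <- vector("list", n_scales)
  cur <- M; curmask <- msk
  for (s in seq_len(n_scales)) {
    bands <- haar_step(cur)
    o_r <- seq(1, nrow(curmask), by = 2); o_c <- seq(1, ncol(curmask), by = 2)
    curmask <- curmask[o_r, , drop = FALSE] | curmask[o_r + 1, , drop = FALSE]
    curmask <- curmask[, o_c, drop = FALSE] | curmask[, o_c + 1, drop = FALSE]
    out[[s]] <- list(bands = bands, support = curmask)
    cur <- bands$LL
  }
  out
}

#' Haar wavelet subband energies
#'
#' Non-standard (Mallat) 2D Haar decomposition of the ROI bounding box,
#' padded to a multiple of `2^n_scales` with the ROI mean (mask-exterior
#' pixels are likewise filled with the ROI mean). At each scale the energy
#' of the LL, LH, HL and HH subbands is the mean of squared coefficients
#' whose spatial support intersects the mask. In the subband names the first
#' letter is the filter along x (horizontal) and the second along y, so `HL`
#' responds to vertical edges and `LH` to horizontal ones; `WavEnLL_s-2` is
#' the energy after bi-directional low-pass filtering at scale 2.
#'
#' Scales that do not fit in the bounding box are truncated with a warning
#' and reported as `NA`.
#'
#' @param roi a `quantized_roi`.
#' @param n_scales number of dyadic scales (default 3, i.e. 12 features).
#' @return named numeric vector `WavEnLL_s-1`, `WavEnLH_s-1`, ... of length
#'   `4 * n_scales`.
#' @export
wavelet_features <- function(roi, n_scales = 3L) {
  stopifnot(inherits(roi, "quantized_roi"), n_scales >= 1)
  roi <- roi_crop(roi)
  nms <- as.vector(t(outer(seq_len(n_scales), c("LL", "LH", "HL", "HH"),
                           function(s, b) sprintf("WavEn%s_s-%d", b, s))))
  out <- stats::setNames(rep(NA_real_, 4 * n_scales), nms)
  dims <- dim(roi$mask)
  feasible <- min(n_scales, floor(log2(min(dims))))
  if (feasible < n_scales)
    warning("ROI bounding box supports only ", feasible, " of ", n_scales,
            " wavelet scales; remaining energies are missing")
  if (feasible < 1) return(out)
  block <- 2^feasible
  pr <- ceiling(dims[1] / block) * block
  pc <- ceiling(dims[2] / block) * block
  fill <- mean(roi$clipped[roi$mask])
  M <- matrix(fill, pr, pc)
  M[seq_len(dims[1]), seq_len(dims[2])] <- ifelse(roi$mask, roi$clipped, fill)
  msk <- matrix(FALSE, pr, pc)
  msk[seq_len(dims[1]), seq_len(dims[2])] <- roi$mask
  dec <- haar_decompose(M, msk, feasible)
  for (s in seq_len(feasible)) {
    sup <- dec[[s]]$support
    for (b in c("LL", "LH", "HL", "HH")) {
      coefs <- dec[[s]]$bands[[b]][sup]
      out[sprintf("WavEn%s_s-%d", b, s)] <- mean(coefs^2)
    }
  }
  out
}

#' First-order histogram features
#'
#' Gray-level statistics of the clipped ROI intensities: mean, variance
#' (sample, `n - 1` denominator), skewness and excess kurtosis (population
#' moments), and the 1st, 10th, 50th, 90th and 99th percentiles
#' (type-7 quantiles). Skewness and kurtosis are `NA` for a constant ROI.
#'
#' @param roi a `quantized_roi`.
#' @return named numeric vector of length 9: `Mean`, `Variance`, `Skewness`,
#'   `Kurtosis`, `Perc.01%`, `Perc.10%`, `Perc.50%`, `Perc.90%`, `Perc.99%`.
#' @export
histogram_features <- function(roi) {
  stopifnot(inherits(roi, "quantized_roi"))
  v <- roi$clipped[roi$mask]
  mom <- central_moments(v)
  q <- stats::quantile(v, c(.01, .10, .50, .90, .99), names = FALSE, type = 7)
  c(Mean = mom$mean,
    Variance = stats::var(v),
    Skewness = if (mom$m2 > 0) mom$m3 / mom$m2^1.5 else NA_real_,
    Kurtosis = if (mom$m2 > 0) mom$m4 / mom$m2^2 - 3 else NA_real_,
    "Perc.01%" = q[1], "Perc.10%" = q[2], "Perc.50%" = q[3],
    "Perc.90%" = q[4], "Perc.99%" = q[5])
}
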