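## Gray-level co-occurrence features (Haralick family, MaZda naming).
##
## Conventions: offset (dx, dy) pairs pixel (x, y) with (x + dx, y + dy),
## x = column, y = row (y grows downward). Matrices are symmetrized (each
## pair counted in both directions) so the marginals coincide and the
## correlation is well-defined. Entropies use the natural logarithm with
## 0 log 0 = 0.

com_stat_names <- c("AngScMom", "Contrast", "Correlat", "SumOfSqs",
                    "InvDfMom", "SumAverg", "SumVarnc", "SumEntrp",
                    "Entropy", "DifVarnc", "DifEntrp")

## Offsets of the standard 4-direction x 5-distance grid, in grid order.
com_offsets <- function(distances = 1:5) {
  out <- list()
  for (d in distances)
    out <- c(out, list(c(d, 0), c(0, d), c(d, d), c(d, -d)))
  out
}

## Restrict a quantized_roi to the bounding box of its mask (idempotent);
## feature code works on the cropped grids for speed.
roi_crop <- function(roi) {
  if (isTRUE(attr(roi, "cropped"))) return(roi)
  rr <- range(which(rowSums(roi$mask) > 0))
  cr <- range(which(colSums(roi$mask) > 0))
  roi$levels <- roi$levels[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  roi$clipped <- roi$clipped[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  roi$mask <- roi$mask[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  attr(roi, "cropped") <- TRUE
  roi
}

#' Co-occurrence features for one pixel offset
#'
#' Builds the symmetrized gray-level co-occurrence matrix for offset
#' `(dx, dy)` restricted to pixel pairs that lie entirely inside the ROI
#' mask, and returns the 11 Haralick-family statistics with MaZda-style
#' names `S(dx,dy)<Stat>`: angular second moment, contrast, correlation, sum
#' of squares (marginal variance), inverse difference moment, sum average,
#' sum variance, sum entropy, entropy, difference variance and difference
#' entropy.
#'
#' If the ROI admits no valid pair for the offset, all 11 values are `NA`
#' (explicit missing markers). For a single-level matrix the correlation is
#' undefined (0/0) and returned as `NA`.
#'
#' @param roi a `quantized_roi` from [normalize_quantize()].
#' @param dx,dy integer pixel offset (x = column, y = row, y downward).
#' @return named numeric vector of length 11.
#' @export
com_features <- function(roi, dx, dy) {
  stopifnot(inherits(roi, "quantized_roi"))
  roi <- roi_crop(roi)
  P <- com_matrix(roi$levels, dx, dy, roi$n_levels)
  stats <- com_statistics(P)
  names(stats) <- sprintf("S(%d,%d)%s", dx, dy, com_stat_names)
  stats
}

## Symmetrized, normalized co-occurrence matrix (n_levels x n_levels) or NULL
## when no valid pair exists. `levels` is an integer matrix with NA outside
## the mask.
com_matrix <- function(levels, dx, dy, n_levels) {
  nr <- nrow(levels); nc <- ncol(levels)
  r0 <- max(1, 1 - dy); r1 <- min(nr, nr - dy)
  c0 <- max(1, 1 - dx); c1 <- min(nc, nc - dx)
  if (r0 > r1 || c0 > c1) return(NULL)
  a <- levels[r0:r1, c0:c1, drop = FALSE]
  b <- levels[(r0 + dy):(r1 + dy), (c0 + dx):(c1 + dx), drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  i <- a[ok]; j <- b[ok]
  counts <- tabulate((i - 1L) * n_levels + j, nbins = n_levels * n_levels) +
            tabulate((j - 1L) * n_levels + i, nbins = n_levels * n_levels)
  P <- matrix(counts, n_levels, n_levels, byrow = TRUE)  # row = i, col = j
  P / sum(P)
}

## The 11 Haralick statistics of a normalized symmetric co-occurrence matrix.
com_statistics <- function(P) {
  if (is.null(P)) return(rep(NA_real_, 11L))
  K <- nrow(P)
  lev <- seq_len(K)
  px <- rowSums(P)
  mu_x <- sum(lev * px)
  var_x <- sum((lev - mu_x)^2 * px)
  ii <- matrix(lev, K, K)
  jj <- t(ii)
  ## sum (i+j) and absolute-difference |i-j| distributions via rowsum
  p_sum <- as.vector(rowsum(as.vector(P), as.vector(ii + jj)))
  ks <- 2:(2 * K)
  p_dif <- as.vector(rowsum(as.vector(P), as.vector(abs(ii - jj))))
  ds <- 0:(K - 1)
  sum_avg <- sum(ks * p_sum)
  mu_d <- sum(ds * p_dif)
  nz <- P > 0
  corr <- if (var_x > 0)
    (sum(ii * jj * P) - mu_x * mu_x) / var_x else NA_real_
  c(AngScMom = sum(P^2),
    Contrast = sum((ii - jj)^2 * P),
    Correlat = corr,
    SumOfSqs = var_x,
    InvDfMom = sum(P / (1 + (ii - jj)^2)),
    SumAverg = sum_avg,
    SumVarnc = sum((ks - sum_avg)^2 * p_sum),
    SumEntrp = -sum(p_sum[p_sum > 0] * log(p_sum[p_sum > 0])),
    Entropy  = -sum(P[nz] * log(P[nz])),
    DifVarnc = sum((ds - mu_d)^2 * p_dif),
    DifEntrp = -sum(p_dif[p_dif > 0] * log(p_dif[p_dif > 0])))
}

#' The full 220-feature co-occurrence grid
#'
#' Evaluates [com_features()] over the standard offset grid
#' `(d,0), (0,d), (d,d), (d,-d)` for distances `d = 1..5` (11 statistics x 4
#' directions x 5 distances = 220 features), in that fixed order. Offsets
#' infeasible for the ROI yield explicit `NA` markers; the name set is always
#' complete.
#'
#' @param roi a `quantized_roi`.
#' @param distances integer vector of interpixel distances (default `1:5`).
#' @return named numeric vector of length `11 * 4 * length(distances)`.
#' @export
com_grid <- function(roi, distances = 1:5) {
  roi <- roi_crop(roi)
  offs <- com_offsets(distances)
  unlist(lapply(offs, function(o) com_features(roi, o[1], o[2])))
}
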