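## Independent brute-force oracles and fixture builders. The oracles
## deliberately use plain loops and direct formula transcriptions, separate
## from the package's vectorized implementations.

## build a quantized_roi directly from an integer level matrix (NA = off-mask)
roi_from_levels <- function(levels, n_levels = max(levels, na.rm = TRUE),
                            clipped = levels, spacing = 1) {
  levels <- as.matrix(levels)
  storage.mode(levels) <- "integer"
  structure(list(levels = levels, clipped = as.matrix(clipped) * 1.0,
                 mask = !is.na(levels), n_levels = as.integer(n_levels),
                 pixel_spacing_mm = spacing,
                 params = list(mu = NA_real_, sigma = NA_real_,
                               n_levels = as.integer(n_levels)),
                 case_id = "fixture"),
            class = "quantized_roi")
}

## build an image_study around a pixel matrix, ROI centered
image_from_matrix <- function(pixels, spacing = 0.2, radius_mm = 2,
                              center = "A", class = "cholesteatoma",
                              id = "T001") {
  n <- nrow(pixels)
  new_image_study(pixels = pixels, pixel_spacing_mm = spacing,
                  center_id = center, class_label = class, case_id = id,
                  roi_center = c((ncol(pixels) - 1) / 2, (n - 1) / 2),
                  roi_radius_mm = radius_mm)
}

## a small cohort config for fast tests (same physical FOV logic, tiny grids)
small_config <- function(...) {
  cohort_config(n_per_center = c(A = 6, B = 6),
                matrix_size = c(A = 64, B = 96), fov_mm = 12.8, ...)
}

## brute-force co-occurrence oracle: enumerate every pixel pair for offset
## (dx, dy) in both directions, then evaluate the eleven statistics by
## direct summation loops.
oracle_com <- function(levels, dx, dy, n_levels) {
  nr <- nrow(levels); nc <- ncol(levels)
  counts <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + dy; c2 <- c + dx
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
        !is.na(levels[r, c]) && !is.na(levels[r2, c2])) {
      a <- levels[r, c]; b <- levels[r2, c2]
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  if (sum(counts) == 0) return(rep(NA_real_, 11))
  P <- counts / sum(counts)
  K <- n_levels
  mu_x <- 0; for (i in 1:K) mu_x <- mu_x + i * sum(P[i, ])
  var_x <- 0; for (i in 1:K) var_x <- var_x + (i - mu_x)^2 * sum(P[i, ])
  asm <- 0; contrast <- 0; idm <- 0; ent <- 0; cross <- 0
  p_sum <- numeric(2 * K); p_dif <- numeric(K)
  for (i in 1:K) for (j in 1:K) {
    p <- P[i, j]
    asm <- asm + p^2
    contrast <- contrast + (i - j)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    if (p > 0) ent <- ent - p * log(p)
    cross <- cross + i * j * p
    p_sum[i + j] <- p_sum[i + j] + p
    p_dif[abs(i - j) + 1] <- p_dif[abs(i - j) + 1] + p
  }
  sum_avg <- 0; for (k in 2:(2 * K)) sum_avg <- sum_avg + k * p_sum[k]
  sum_var <- 0; sum_ent <- 0
  for (k in 2:(2 * K)) {
    sum_var <- sum_var + (k - sum_avg)^2 * p_sum[k]
    if (p_sum[k] > 0) sum_ent <- sum_ent - p_sum[k] * log(p_sum[k])
  }
  mu_d <- 0; for (d in 0:(K - 1)) mu_d <- mu_d + d * p_dif[d + 1]
  dif_var <- 0; dif_ent <- 0
  for (d in 0:(K - 1)) {
    dif_var <- dif_var + (d - mu_d)^2 * p_dif[d + 1]
    if (p_dif[d + 1] > 0) dif_ent <- dif_ent - p_dif[d + 1] * log(p_dif[d + 1])
  }
  correlat <- if (var_x > 0) (cross - mu_x^2) / var_x else NA_real_
  c(asm, contrast, correlat, var_x, idm, sum_avg, sum_var, sum_ent, ent,
    dif_var, dif_ent)
}

## exhaustive threshold-and-polarity probability-of-error oracle
oracle_poe <- function(values, labels) {
  ok <- !is.na(values)
  values <- values[ok]; labels <- factor(labels[ok])
  lev <- levels(labels)
  cuts <- c(-Inf, sort(unique(values))[-1] -
              diff(sort(unique(values))) / 2, Inf)
  n <- length(values)
  best <- Inf
  for (t in cuts) {
    below <- values < t
    e1 <- sum(below & labels != lev[1]) + sum(!below & labels != lev[2])
    e2 <- sum(below & labels != lev[2]) + sum(!below & labels != lev[1])
    best <- min(best, e1, e2)
  }
  best / n
}

## pair-counting AUC oracle
oracle_auc <- function(scores, labels, positive = levels(factor(labels))[2]) {
  labels <- factor(labels)
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

## exhaustive-distance leave-one-out k-NN oracle
oracle_knn <- function(X, labels, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  pred <- character(n)
  for (i in seq_len(n)) {
    d <- rep(Inf, n)
    for (j in seq_len(n)) if (j != i) d[j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    nb <- order(d)[seq_len(k)]
    votes <- table(factor(labels[nb], levels = levels(factor(labels))))
    pred[i] <- names(votes)[which.max(votes)]
  }
  mean(pred == as.character(labels))
}

## synthesize one stationary isotropic Gaussian-field ROI matrix (quantized)
sim_field_roi <- function(n = 32, corr_px = 2, bits = 4) {
  A <- otoradiomics:::gaussian_transfer(n, 1, corr_px, corr_px)
  f <- otoradiomics:::synth_fields(1, A, sqrt(sum(A^2)) / n^2)[[1]]
  lev <- as.integer(cut(f, breaks = 2^bits))
  roi_from_levels(matrix(lev, n, n), n_levels = 2^bits, clipped = matrix(f, n, n))
}
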