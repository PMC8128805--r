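test_that("gradient features: constant ROI and linear ramp behave analytically", {
  roi <- roi_from_levels(matrix(4L, 10, 10), n_levels = 8,
                         clipped = matrix(5, 10, 10))
  f <- gradient_features(roi)
  expect_equal(unname(f["GrMean"]), 0)
  expect_equal(unname(f["GrNonZeros"]), 0)

  ramp <- outer(rep(1, 12), 1:12, function(r, c) 2.5 * c)  # I = c * x
  roi2 <- roi_from_levels(matrix(1L, 12, 12), n_levels = 2, clipped = ramp)
  f2 <- gradient_features(roi2)
  expect_equal(unname(f2["GrMean"]), 2.5)
  expect_equal(unname(f2["GrVariance"]), 0)
  expect_equal(unname(f2["GrNonZeros"]), 1)

  set.seed(30)
  roi3 <- sim_field_roi(n = 16)
  f3 <- gradient_features(roi3)
  expect_gte(unname(f3["GrNonZeros"]), 0)
  expect_lte(unname(f3["GrNonZeros"]), 1)
})

test_that("autoregressive coefficients are recovered on a simulated causal field", {
  set.seed(31)
  theta <- c(0.45, 0.05, 0.30, 0.08)
  n <- 48
  M <- matrix(0, n, n)
  M[1, ] <- rnorm(n, sd = 0.5)
  M[, 1] <- rnorm(n, sd = 0.5)
  M[, n] <- rnorm(n, sd = 0.5)
  for (r in 2:n) for (c in 2:(n - 1))
    M[r, c] <- theta[1] * M[r, c - 1] + theta[2] * M[r - 1, c - 1] +
      theta[3] * M[r - 1, c] + theta[4] * M[r - 1, c + 1] + rnorm(1, sd = 0.3)
  roi <- roi_from_levels(matrix(1L, n, n), n_levels = 2, clipped = M)
  f <- arm_features(roi)
  ## standard errors of the least-squares fit
  ok <- cbind(M[2:n, 1:(n - 2)], M[1:(n - 1), 1:(n - 2)],
              M[1:(n - 1), 2:(n - 1)], M[1:(n - 1), 3:n])
  X <- cbind(as.vector(M[2:n, 1:(n - 2)]), as.vector(M[1:(n - 1), 1:(n - 2)]),
             as.vector(M[1:(n - 1), 2:(n - 1)]), as.vector(M[1:(n - 1), 3:n]))
  se <- sqrt(diag(solve(crossprod(X))) * f["Sigma"]^2)
  for (i in 1:4)
    expect_lt(abs(f[[paste0("Teta", i)]] - theta[i]), 3 * se[i] + 0.02)
  expect_lt(abs(f[["Sigma"]] - 0.3), 0.05)
})

test_that("white noise yields near-zero autoregressive coefficients", {
  set.seed(32)
  hits <- 0
  for (i in 1:20) {
    M <- matrix(rnorm(30 * 30), 30, 30)
    f <- arm_features(roi_from_levels(matrix(1L, 30, 30), 2, clipped = M))
    if (all(abs(f[paste0("Teta", 1:4)]) < 0.12)) hits <- hits + 1
  }
  expect_gte(hits, 19)  # 3 SE of theta-hat is about 0.10 at n ~ 800
})

test_that("a constant ROI gives zero autoregressive residual scale", {
  roi <- roi_from_levels(matrix(2L, 10, 10), 4, clipped = matrix(9, 10, 10))
  f <- suppressWarnings(arm_features(roi))
  expect_equal(unname(f["Sigma"]), 0)
  expect_equal(unname(f["Teta1"]), 0)
})

test_that("Haar details vanish on constants and localize stripe energy", {
  roi <- roi_from_levels(matrix(1L, 16, 16), 2, clipped = matrix(3, 16, 16))
  f <- wavelet_features(roi, n_scales = 3)
  expect_length(f, 12)
  detail <- f[!grepl("LL", names(f))]
  expect_true(all(detail == 0))
  expect_gt(unname(f["WavEnLL_s-1"]), 0)

  ## horizontal stripes of period 2 vary along y -> scale-1 LH dominates
  stripes <- matrix(rep(c(0, 4), each = 1, length.out = 16), 16, 16)  # rows alternate
  roi2 <- roi_from_levels(matrix(1L, 16, 16), 2, clipped = stripes)
  f2 <- wavelet_features(roi2, n_scales = 3)
  expect_gt(unname(f2["WavEnLH_s-1"]), unname(f2["WavEnHL_s-1"]))
  expect_gt(unname(f2["WavEnLH_s-1"]), unname(f2["WavEnHH_s-1"]))
})

test_that("the Haar transform is orthonormal on full boxes (Parseval)", {
  set.seed(33)
  M <- matrix(rnorm(32 * 32), 32, 32)
  msk <- matrix(TRUE, 32, 32)
  dec <- otoradiomics:::haar_decompose(M, msk, 3)
  total <- sum(dec[[3]]$bands$LL^2)
  for (s in 1:3)
    total <- total + sum(dec[[s]]$bands$LH^2) + sum(dec[[s]]$bands$HL^2) +
      sum(dec[[s]]$bands$HH^2)
  expect_equal(total, sum(M^2), tolerance = 1e-8)
})

test_that("scales beyond the bounding box are truncated with missing markers", {
  roi <- sim_field_roi(n = 8)
  expect_warning(f <- wavelet_features(roi, n_scales = 4), "scales")
  expect_length(f, 16)
  expect_true(all(is.na(f[grepl("s-4", names(f))])))
  expect_false(anyNA(f[grepl("s-1|s-2|s-3", names(f))]))
})

test_that("histogram features: constants, median oracle, symmetric null", {
  roi <- roi_from_levels(matrix(1L, 8, 8), 2, clipped = matrix(42, 8, 8))
  f <- histogram_features(roi)
  expect_equal(unname(f["Mean"]), 42)
  expect_equal(unname(f["Variance"]), 0)
  expect_true(all(f[grepl("^Perc", names(f))] == 42))

  set.seed(34)
  v <- rnorm(400)
  roi2 <- roi_from_levels(matrix(1L, 20, 20), 2, clipped = matrix(v, 20, 20))
  f2 <- histogram_features(roi2)
  sorted <- sort(v)  # sort-based median oracle
  expect_equal(unname(f2["Perc.50%"]), (sorted[200] + sorted[201]) / 2)
  ## symmetric distribution: skewness within 3 standard errors (~sqrt(6/n))
  expect_lt(abs(f2[["Skewness"]]), 3 * sqrt(6 / 400))
})

test_that("extract_all concatenates all families with the registered counts and order", {
  set.seed(35)
  img <- image_from_matrix(matrix(rnorm(64 * 64, 60, 10), 64, 64))
  roi <- normalize_quantize(img, make_roi_mask(img))
  fv <- extract_all(roi)
  cats <- attr(fv, "category")
  expect_equal(as.vector(table(cats)[c("HIS", "COM", "RUN", "GRA", "ARM", "WAV")]),
               c(9L, 220L, 20L, 5L, 5L, 12L))
  expect_identical(names(fv), feature_registry()$name)
  ## determinism
  expect_identical(unname(fv), unname(extract_all(roi)))
})

test_that("direction-pooled co-occurrence statistics are invariant to 90-degree rotation", {
  set.seed(36)
  lv <- matrix(sample.int(8, 16 * 16, replace = TRUE), 16, 16)
  roi <- roi_from_levels(lv, 8)
  roi_rot <- roi_from_levels(t(lv[nrow(lv):1, ]), 8)  # 90-degree rotation
  g1 <- com_grid(roi)
  g2 <- com_grid(roi_rot)
  for (d in 1:5) for (stat in otoradiomics:::com_stat_names) {
    dirs <- sprintf("S(%s)%s",
                    c(paste0(d, ",0"), paste0("0,", d),
                      paste0(d, ",", d), paste0(d, ",-", d)), stat)
    expect_equal(mean(g1[dirs]), mean(g2[dirs]), tolerance = 1e-8,
                 info = paste("d =", d, stat))
  }
})
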