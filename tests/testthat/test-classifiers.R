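test_that("the discriminant axis matches the hand-computed 2-feature solution", {
  ## two features, the same within-class shape in both classes, class means
  ## offset by (1, 1): w is proportional to Sw^-1 (m1 - m2), a 2x2 solve
  X1 <- rbind(c(2, 0.5), c(-2, -0.5), c(0, 1), c(0, -1)) / sqrt(2)
  X <- rbind(X1 + 0.5, X1 - 0.5)
  labels <- rep(c("p", "q"), each = 4)
  Sw <- (crossprod(scale(X[1:4, ], scale = FALSE)) +
         crossprod(scale(X[5:8, ], scale = FALSE))) / (8 - 2)
  w_hand <- solve(Sw, c(1, 1))
  proj <- lda_project(X, labels)
  cosang <- sum(proj$w * w_hand) / sqrt(sum(w_hand^2))
  expect_equal(abs(cosang), 1, tolerance = 1e-10)
})

test_that("the discriminant direction agrees with the reference LDA implementation", {
  set.seed(50)
  X <- matrix(rnorm(60 * 4), 60, 4)
  labels <- rep(c("a", "b"), each = 30)
  X[labels == "b", 1] <- X[labels == "b", 1] + 2
  proj <- lda_project(X, labels)
  ref <- MASS::lda(X, grouping = labels)$scaling[, 1]
  cosang <- abs(sum(proj$w * ref)) / sqrt(sum(ref^2))
  expect_equal(cosang, 1, tolerance = 1e-8)
})

test_that("well-separated clouds project far apart; null means project nowhere", {
  set.seed(51)
  n <- 60
  labels <- rep(c("a", "b"), each = n / 2)
  Xsep <- matrix(rnorm(n * 5), n, 5)
  Xsep[labels == "b", ] <- Xsep[labels == "b", ] + 6 / sqrt(5)
  p <- lda_project(Xsep, labels)$projected
  gap <- abs(mean(p[labels == "a"]) - mean(p[labels == "b"]))
  pooled_sd <- sqrt((var(p[labels == "a"]) + var(p[labels == "b"])) / 2)
  expect_gt(gap, 5 * pooled_sd)

  Xnull <- matrix(rnorm(n * 5), n, 5)
  pn <- lda_project(Xnull, labels)$projected
  tstat <- stats::t.test(pn ~ labels)$statistic
  ## LDA overfits the training direction, but the separation stays modest
  expect_lt(abs(tstat), 6)
})

test_that("LDA projection is sign-invariant to affine feature rescaling", {
  set.seed(52)
  X <- matrix(rnorm(40 * 3), 40, 3)
  labels <- rep(c("a", "b"), each = 20)
  X[labels == "b", 2] <- X[labels == "b", 2] + 1
  p1 <- lda_project(X, labels)$projected
  X2 <- X
  X2[, 2] <- -5 * X2[, 2] + 7
  p2 <- lda_project(X2, labels)$projected
  expect_equal(abs(cor(p1, p2)), 1, tolerance = 1e-8)
})

test_that("leave-one-out k-NN matches the exhaustive-distance oracle", {
  ## printed 5-case toy set
  X <- cbind(c(0, 0.1, 0.2, 5, 5.1), c(0, 0, 0.1, 5, 5))
  labels <- c("a", "a", "a", "b", "b")
  res <- knn_loo(X, labels, k = 1)
  expect_equal(res$accuracy, oracle_knn(X, labels, 1))
  expect_equal(res$accuracy, 1)

  set.seed(53)
  for (k in c(1, 3)) {
    Xr <- matrix(rnorm(30 * 3), 30, 3)
    lr <- sample(c("a", "b"), 30, replace = TRUE)
    expect_equal(knn_loo(Xr, lr, k = k)$accuracy, oracle_knn(Xr, lr, k),
                 info = paste("k =", k))
  }
})

test_that("duplicate-point clusters classify perfectly with k = 1", {
  X <- matrix(rep(c(0, 0, 10, 10), each = 3), ncol = 1)
  labels <- rep(c("a", "b"), each = 6)
  expect_equal(knn_loo(X, labels, k = 1)$accuracy, 1)
})

test_that("random labels give chance-level leave-one-out accuracy", {
  set.seed(54)
  acc <- replicate(60, {
    X <- matrix(rnorm(100), 100, 1)
    l <- rep(c("a", "b"), each = 50)[sample(100)]
    knn_loo(X, l, k = 1)$accuracy
  })
  se <- sd(acc) / sqrt(length(acc))
  expect_lt(abs(mean(acc) - 0.5), 3 * se + 0.02)
})

test_that("k-NN input contracts are enforced", {
  X <- matrix(rnorm(10), 10, 1)
  l <- rep(c("a", "b"), 5)
  expect_error(knn_loo(X, l, k = 2), "odd")
  expect_error(knn_loo(X, l, k = 11), "smaller")
})

test_that("AUC equals the pair-counting oracle and handles ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c("n", "n", "p", "p")), 1)
  expect_equal(roc_auc(rep(1, 8), rep(c("n", "p"), 4)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  set.seed(55)
  for (i in 1:20) {
    s <- sample(round(rnorm(15), 1))  # ties likely
    l <- sample(c("n", "p"), 15, replace = TRUE)
    if (length(unique(l)) < 2) next
    expect_equal(roc_auc(s, l), oracle_auc(s, l), info = paste("case", i))
  }
})

test_that("AUC is invariant to strictly monotone score transforms", {
  set.seed(56)
  s <- rnorm(40)
  l <- rep(c("n", "p"), 20)
  expect_equal(roc_auc(exp(s), l), roc_auc(s, l))
  expect_equal(roc_auc(rank(s), l), roc_auc(s, l))
})

test_that("the MLP separates separable classes and is seed-deterministic", {
  set.seed(57)
  n <- 160
  labels <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 10), n, 10)
  X[labels == "b", ] <- X[labels == "b", ] + 4 / sqrt(10)
  good <- 0
  for (s in 1:20)
    if (mlp_train_eval(X, labels, split_seed = s)$auc > 0.95) good <- good + 1
  expect_gte(good, 19)
  r1 <- mlp_train_eval(X, labels, split_seed = 11)
  r2 <- mlp_train_eval(X, labels, split_seed = 11)
  expect_identical(r1$auc, r2$auc)
  expect_identical(r1$acc_val_pct, r2$acc_val_pct)
})

test_that("permuted labels put the MLP near chance", {
  set.seed(58)
  n <- 80
  X <- matrix(rnorm(n * 10), n, 10)
  labels <- rep(c("a", "b"), each = n / 2)[sample(n)]
  aucs <- vapply(1:20, function(s) mlp_train_eval(X, labels, s)$auc, numeric(1))
  expect_gte(stats::median(aucs), 0.35)
  expect_lte(stats::median(aucs), 0.65)
})

test_that("repeated runs summarize as median and range over the split seeds", {
  set.seed(59)
  n <- 50
  labels <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 5), n, 5)
  X[labels == "b", 1] <- X[labels == "b", 1] + 1.5
  rr <- repeat_runs(X, labels, n_reps = 5, master_seed = 4)
  aucs <- vapply(rr$runs, `[[`, numeric(1), "auc")
  s <- rr$summary
  expect_equal(s$median[s$metric == "auc"], stats::median(aucs))
  expect_equal(s$min[s$metric == "auc"], min(aucs))
  expect_equal(s$max[s$metric == "auc"], max(aucs))
  expect_match(rr$formatted["auc"], "^\\d\\.\\d\\d \\(\\d\\.\\d\\d-\\d\\.\\d\\d\\)$")
  ## reproducible five-tuple; single repetition equals the single run
  rr2 <- repeat_runs(X, labels, n_reps = 5, master_seed = 4)
  expect_identical(aucs, vapply(rr2$runs, `[[`, numeric(1), "auc"))
  r1 <- repeat_runs(X, labels, n_reps = 1, master_seed = 9)
  expect_equal(r1$summary$median[1], r1$runs[[1]]$auc)
})
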