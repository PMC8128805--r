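make_batch_table <- function(seed = 42, n = 50, G = 200, shift = 1.5,
                             scale = 1.8, feat_means = TRUE) {
  set.seed(seed)
  batch <- rep(c("A", "B"), each = n)
  Y <- matrix(rnorm(2 * n * G), 2 * n, G) * rep(c(1, scale), each = n) +
    rep(c(0, shift), each = n)
  if (feat_means)
    Y <- Y + matrix(rnorm(G, sd = 3), 2 * n, G, byrow = TRUE)
  colnames(Y) <- paste0("f", seq_len(G))
  list(Y = Y, batch = batch)
}

test_that("a single batch fits to the identity model", {
  d <- make_batch_table()
  one <- d$batch == "A"
  m <- fit_combat(d$Y[one, ], batch = d$batch[one])
  expect_true(all(m$gamma_star == 0))
  expect_true(all(m$delta2_star == 1))
  h <- apply_combat(m, d$Y[one, ], batch = d$batch[one])
  expect_equal(h, d$Y[one, ], tolerance = 1e-12)
})

test_that("the unshrunk location/scale fit equalizes batch moments exactly", {
  d <- make_batch_table()
  m <- fit_combat(d$Y, batch = d$batch, eb = FALSE)
  h <- apply_combat(m, d$Y, batch = d$batch)
  mean_gap <- abs(colMeans(h[d$batch == "A", ]) - colMeans(h[d$batch == "B", ]))
  expect_lt(max(mean_gap), 1e-6)
  var_ratio <- apply(h[d$batch == "A", ], 2, var) /
    apply(h[d$batch == "B", ], 2, var)
  expect_equal(unname(var_ratio), rep(1, ncol(h)), tolerance = 1e-6)
  ## refitting on harmonized data finds no batch effect left (idempotence)
  m2 <- fit_combat(h, batch = d$batch, eb = FALSE)
  expect_lt(max(abs(m2$gamma_hat)), 1e-6)
})

test_that("empirical-Bayes harmonization equalizes batch means up to shrinkage noise", {
  d <- make_batch_table()
  m <- fit_combat(d$Y, batch = d$batch)
  h <- apply_combat(m, d$Y, batch = d$batch)
  gap_before <- colMeans(d$Y[d$batch == "B", ]) - colMeans(d$Y[d$batch == "A", ])
  gap_after <- colMeans(h[d$batch == "B", ]) - colMeans(h[d$batch == "A", ])
  ## shrinkage leaves a residual, but the injected shift is largely removed
  expect_gt(stats::median(abs(gap_before)), 1)
  expect_lt(stats::median(abs(gap_after)),
            stats::median(abs(gap_before)) / 5)
})

test_that("injected per-batch shift and scale are recovered on simulation", {
  d <- make_batch_table(seed = 7, shift = 1.5, scale = 1.8)
  m <- fit_combat(d$Y, batch = d$batch)
  h <- apply_combat(m, d$Y, batch = d$batch)
  nA <- sum(d$batch == "A"); nB <- sum(d$batch == "B")
  se <- sqrt(apply(h[d$batch == "A", ], 2, var) / nA +
             apply(h[d$batch == "B", ], 2, var) / nB)
  gap <- abs(colMeans(h[d$batch == "A", ]) - colMeans(h[d$batch == "B", ]))
  expect_gte(mean(gap <= 3 * se), 0.95)
})

test_that("results agree with the independent reference implementation", {
  d <- make_batch_table(seed = 99)
  m <- fit_combat(d$Y, batch = d$batch, tol = 1e-4)  # reference stops at 1e-4
  h <- apply_combat(m, d$Y, batch = d$batch)
  ref <- t(suppressMessages(
    sva::ComBat(dat = t(d$Y), batch = d$batch, par.prior = TRUE,
                prior.plots = FALSE)))
  expect_lt(max(abs(h - ref)), 1e-6)
})

test_that("class-protected harmonization preserves the class effect", {
  set.seed(8)
  n <- 40; G <- 150
  batch <- rep(c("A", "B"), each = n)
  cls <- rep(rep(c(0, 1), each = n / 2), 2)
  effect <- 1.0
  Y <- matrix(rnorm(2 * n * G), 2 * n, G) + rep(c(0, 2), each = n) +
    cls * effect
  colnames(Y) <- paste0("f", 1:G)
  design <- cbind(class = cls)
  m <- fit_combat(Y, batch = batch, covariates = design)
  h <- apply_combat(m, Y, batch = batch, covariates = design)
  d_before <- colMeans(Y[cls == 1, ]) - colMeans(Y[cls == 0, ])
  d_after <- colMeans(h[cls == 1, ]) - colMeans(h[cls == 0, ])
  se <- sqrt(apply(h[cls == 1, ], 2, var) / n + apply(h[cls == 0, ], 2, var) / n)
  expect_gte(mean(abs(d_after - d_before) <= 3 * se), 0.95)
  ## the sign of the within-batch class difference survives
  dA <- colMeans(h[cls == 1 & batch == "A", ]) -
    colMeans(h[cls == 0 & batch == "A", ])
  expect_gt(mean(dA > 0), 0.9)
})

test_that("row permutation only permutes the harmonized output", {
  d <- make_batch_table(seed = 5, n = 20, G = 30)
  m <- fit_combat(d$Y, batch = d$batch)
  h <- apply_combat(m, d$Y, batch = d$batch)
  p <- sample(nrow(d$Y))
  hp <- apply_combat(m, d$Y[p, ], batch = d$batch[p])
  expect_equal(hp, h[p, ], tolerance = 1e-12)
})

test_that("degenerate inputs are rejected or passed through", {
  d <- make_batch_table(seed = 6, n = 10, G = 20)
  expect_error(fit_combat(d$Y[c(1, 11:20), ], batch = d$batch[c(1, 11:20)]),
               "at least 2")
  Yz <- d$Y; Yz[, 3] <- 7
  expect_warning(m <- fit_combat(Yz, batch = d$batch), "zero-variance")
  h <- apply_combat(m, Yz, batch = d$batch)
  expect_equal(unname(h[, 3]), rep(7, nrow(Yz)))
  expect_error(apply_combat(m, Yz, batch = rep("C", nrow(Yz))), "unknown batch")
})
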