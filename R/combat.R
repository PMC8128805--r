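#' Fit an empirical-Bayes location/scale harmonization model
#'
#' Removes additive and multiplicative batch (center/scanner) effects from a
#' feature table, following the standard parametric empirical-Bayes
#' ("ComBat") construction: per feature, a grand mean and pooled variance
#' are estimated by least squares across all cases (optionally adjusting for
#' protected covariates), values are standardized, per-batch location
#' (`gamma`) and scale (`delta^2`) estimates are shrunk towards
#' across-feature priors (normal for `gamma`, inverse-gamma for `delta^2`,
#' hyperparameters by method of moments), and the conditional posterior
#' updates are iterated to convergence.
#'
#' With a single batch the model is the identity (`gamma* = 0`,
#' `delta*^2 = 1`). Zero-variance features are passed through unharmonized
#' with a warning. Convergence uses the maximum relative change of the
#' shrunk estimates between iterations.
#'
#' @param table feature table from [extract_cohort()], or any data.frame /
#'   matrix of cases x features.
#' @param batch batch label per case; defaults to the table's `center_id`.
#' @param covariates optional numeric design matrix of protected biological
#'   covariates (cases x q), e.g. a class indicator; must not be confounded
#'   with batch.
#' @param tol relative-change convergence tolerance (default `1e-6`).
#' @param max_iter maximum empirical-Bayes iterations per batch.
#' @param eb if `TRUE` (default) shrink the batch parameters by empirical
#'   Bayes; if `FALSE` use the raw per-batch location/scale estimates, which
#'   equalizes per-batch feature means and variances exactly (the shrunk
#'   adjustment equalizes them only approximately, the price of stabilizing
#'   small batches).
#' @return a `combat_model` with the per-feature estimates (`alpha`,
#'   `beta`, `var_pooled`), per-batch raw and shrunk batch parameters
#'   (`gamma_hat`, `gamma_star`, `delta2_hat`, `delta2_star`), the prior
#'   hyperparameters and fit metadata.
#' @references Johnson WE, Li C, Rabinovic A (2007) Adjusting batch effects
#'   in microarray expression data using empirical Bayes methods.
#'   Biostatistics 8(1):118-127.
#' @export
fit_combat <- function(table, batch = NULL, covariates = NULL,
                       tol = 1e-6, max_iter = 200L, eb = TRUE) {
  parts <- combat_inputs(table, batch)
  Y <- parts$X
  batch <- parts$batch
  batches <- levels(batch)
  n_i <- as.vector(table(batch))
  N <- nrow(Y)
  if (any(n_i < 2)) stop("every batch needs at least 2 cases", call. = FALSE)

  keep <- apply(Y, 2, function(v) stats::var(v, na.rm = TRUE) > 0 &&
                  sum(!is.na(v)) > 0)
  if (!all(keep))
    warning(sum(!keep), " zero-variance feature(s) passed through unharmonized")
  Yk <- Y[, keep, drop = FALSE]
  G <- ncol(Yk)

  B <- vapply(batches, function(b) as.numeric(batch == b), numeric(N))
  X <- if (is.null(covariates)) B else {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == N)
    cbind(B, covariates)
  }
  if (qr(X)$rank < ncol(X))
    stop("covariate design is confounded with batch", call. = FALSE)

  Bhat <- solve(crossprod(X), crossprod(X, Yk))
  grand_mean <- as.vector(crossprod(n_i / N, Bhat[seq_along(batches), , drop = FALSE]))
  resid <- Yk - X %*% Bhat
  var_pooled <- colSums(resid^2, na.rm = TRUE) / N

  stand_mean <- matrix(grand_mean, N, G, byrow = TRUE)
  beta <- NULL
  if (!is.null(covariates)) {
    beta <- Bhat[-seq_along(batches), , drop = FALSE]
    stand_mean <- stand_mean + covariates %*% beta
  }
  Z <- (Yk - stand_mean) / matrix(sqrt(var_pooled), N, G, byrow = TRUE)

  gamma_hat <- delta2_hat <- gamma_star <- delta2_star <-
    matrix(NA_real_, length(batches), G,
           dimnames = list(batches, colnames(Yk)))
  priors <- list()
  iters <- integer(length(batches))

  single <- length(batches) == 1L
  for (b in seq_along(batches)) {
    Zi <- Z[batch == batches[b], , drop = FALSE]
    g_hat <- colMeans(Zi, na.rm = TRUE)
    d_hat <- apply(Zi, 2, stats::var, na.rm = TRUE)
    gamma_hat[b, ] <- g_hat
    delta2_hat[b, ] <- d_hat
    if (single) {
      gamma_star[b, ] <- 0
      delta2_star[b, ] <- 1
      priors[[b]] <- list(gamma_bar = NA_real_, t2 = NA_real_,
                          a_prior = NA_real_, b_prior = NA_real_)
      next
    }
    if (!eb) {
      gamma_star[b, ] <- g_hat
      delta2_star[b, ] <- d_hat
      priors[[b]] <- list(gamma_bar = NA_real_, t2 = NA_real_,
                          a_prior = NA_real_, b_prior = NA_real_)
      next
    }
    g_bar <- mean(g_hat)
    t2 <- stats::var(g_hat)
    m <- mean(d_hat); s2 <- stats::var(d_hat)
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    sol <- combat_it_sol(Zi, g_hat, d_hat, g_bar, t2, a_prior, b_prior,
                         tol, max_iter)
    gamma_star[b, ] <- sol$g_new
    delta2_star[b, ] <- sol$d_new
    iters[b] <- sol$iterations
    priors[[b]] <- list(gamma_bar = g_bar, t2 = t2,
                        a_prior = a_prior, b_prior = b_prior)
  }
  names(priors) <- batches

  structure(list(alpha = grand_mean, beta = beta, var_pooled = var_pooled,
                 gamma_hat = gamma_hat, gamma_star = gamma_star,
                 delta2_hat = delta2_hat, delta2_star = delta2_star,
                 priors = priors, batches = batches, n_per_batch = n_i,
                 features = colnames(Y), harmonized = colnames(Yk),
                 parametric = TRUE, eb = eb, tol = tol, iterations = iters,
                 has_covariates = !is.null(covariates)),
            class = "combat_model")
}

## Standard conditional empirical-Bayes updates for one batch, iterated to a
## relative-change fixed point. The stopping rule replicates the canonical
## implementation exactly (including its signed denominator) so that results
## are bit-comparable with the reference at a matched tolerance.
combat_it_sol <- function(Zi, g_hat, d_hat, g_bar, t2, a_prior, b_prior,
                          tol, max_iter) {
  n <- colSums(!is.na(Zi))
  g_old <- g_hat
  d_old <- d_hat
  change <- 1
  count <- 0L
  while (change > tol) {
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- colSums((Zi - matrix(g_new, nrow(Zi), ncol(Zi), byrow = TRUE))^2,
                    na.rm = TRUE)
    d_new <- (0.5 * sum2 + b_prior) / (n / 2 + a_prior - 1)
    change <- max((abs(g_new - g_old) / g_old), (abs(d_new - d_old) / d_old))
    g_old <- g_new
    d_old <- d_new
    count <- count + 1L
    if (count >= max_iter)
      stop("empirical-Bayes updates did not converge in ", max_iter,
           " iterations (last relative change ", signif(change, 3), ")",
           call. = FALSE)
  }
  list(g_new = g_new, d_new = d_new, iterations = count)
}

#' Apply a harmonization model to a feature table
#'
#' Adjusts each value by
#' `y* = sqrt(var_pooled) / sqrt(delta*^2) * (z - gamma*) + alpha (+ X beta)`,
#' i.e. removes the shrunk per-batch location/scale effect and restores the
#' grand mean (and covariate contribution, if fitted). Case metadata and
#' class labels are untouched; missing values stay missing; features the
#' model passed through (zero variance at fit time) are returned unchanged.
#'
#' @param model a `combat_model` from [fit_combat()].
#' @param table feature table whose batches and features are known to the
#'   model (no out-of-batch extrapolation).
#' @param batch batch label per case; defaults to the table's `center_id`.
#' @param covariates covariate design matching the one used at fit time.
#' @return the harmonized table, same shape and class as the input.
#' @export
apply_combat <- function(model, table, batch = NULL, covariates = NULL) {
  stopifnot(inherits(model, "combat_model"))
  parts <- combat_inputs(table, batch)
  Y <- parts$X
  batch <- as.character(parts$batch)
  if (!all(batch %in% model$batches))
    stop("unknown batch label(s): ",
         paste(setdiff(unique(batch), model$batches), collapse = ", "),
         call. = FALSE)
  if (model$has_covariates && is.null(covariates))
    stop("model was fitted with covariates; supply the matching design",
         call. = FALSE)
  if (!all(model$harmonized %in% colnames(Y)))
    stop("table lacks features known to the model", call. = FALSE)

  cols <- model$harmonized
  Yh <- Y[, cols, drop = FALSE]
  N <- nrow(Yh); G <- ncol(Yh)
  stand_mean <- matrix(model$alpha, N, G, byrow = TRUE)
  if (model$has_covariates)
    stand_mean <- stand_mean + as.matrix(covariates) %*% model$beta
  sdp <- matrix(sqrt(model$var_pooled), N, G, byrow = TRUE)
  Z <- (Yh - stand_mean) / sdp
  bi <- match(batch, model$batches)
  Zadj <- (Z - model$gamma_star[bi, , drop = FALSE]) /
    sqrt(model$delta2_star)[bi, , drop = FALSE]
  out_vals <- Zadj * sdp + stand_mean

  out <- table
  if (is.data.frame(table)) {
    out[, cols] <- as.data.frame(out_vals, check.names = FALSE)
  } else {
    out[, cols] <- out_vals
  }
  out
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("<combat_model> %d feature(s), %d batch(es): %s\n",
              length(x$features), length(x$batches),
              paste(sprintf("%s (n=%d)", x$batches, x$n_per_batch),
                    collapse = ", ")))
  cat(sprintf("  parametric empirical Bayes, tol %g, iterations: %s\n",
              x$tol, paste(x$iterations, collapse = "/")))
  if (x$has_covariates) cat("  protected covariates: yes\n")
  invisible(x)
}

## Accepts a feature table (data.frame with metadata columns) or a bare
## matrix plus explicit batch labels.
combat_inputs <- function(table, batch) {
  if (is.data.frame(table)) {
    fm <- feature_matrix(table)
    X <- fm$X
    if (is.null(batch)) {
      if (!"center_id" %in% names(fm$meta))
        stop("no `batch` given and table has no center_id column", call. = FALSE)
      batch <- fm$meta$center_id
    }
  } else {
    X <- as.matrix(table)
    if (is.null(batch)) stop("`batch` is required for matrix input", call. = FALSE)
  }
  stopifnot(length(batch) == nrow(X))
  list(X = X, batch = factor(batch))
}
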