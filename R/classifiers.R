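#' Fisher linear discriminant projection
#'
#' Computes the two-class Fisher discriminant axis
#' `w` proportional to `Sw^-1 (m1 - m2)` from the pooled within-class
#' covariance `Sw` of the (typically standardized) selected features, and
#' projects the cases onto it — the "most discriminating feature"
#' coordinate. If the pooled covariance is numerically singular, a ridge
#' `epsilon * I` (default `1e-6`) is added; if it is still singular an error
#' is raised. The axis is deterministic given the data, up to sign.
#'
#' @param X numeric matrix of cases x features.
#' @param labels two-class labels.
#' @param ridge ridge added to the pooled scatter when inversion fails.
#' @return an `lda_projection`: list with `w` (unit-norm axis),
#'   `projected` (numeric vector), `class_means` and `levels`.
#' @export
lda_project <- function(X, labels, ridge = 1e-6) {
  X <- as.matrix(X)
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2, all(table(labels) >= 2))
  lev <- levels(labels)
  X1 <- X[labels == lev[1], , drop = FALSE]
  X2 <- X[labels == lev[2], , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  S1 <- crossprod(sweep(X1, 2, m1))
  S2 <- crossprod(sweep(X2, 2, m2))
  Sw <- (S1 + S2) / (nrow(X) - 2)
  w <- tryCatch(solve(Sw, m1 - m2), error = function(e) {
    tryCatch(solve(Sw + diag(ridge, ncol(X)), m1 - m2),
             error = function(e2)
               stop("pooled within-class scatter is singular even after ridge",
                    call. = FALSE))
  })
  w <- w / sqrt(sum(w^2))
  structure(list(w = w, projected = as.vector(X %*% w),
                 class_means = rbind(m1, m2), levels = lev),
            class = "lda_projection")
}

#' Leave-one-out k-nearest-neighbour classification
#'
#' Classifies each case by the majority vote of its `k` nearest Euclidean
#' neighbours among the remaining `n - 1` cases. `k` must be odd (two-class
#' vote ties are thereby impossible) and smaller than `n`. Distance ties are
#' broken by case order, which makes the result fully deterministic.
#'
#' @param X numeric matrix (cases x features) or a vector of projected
#'   coordinates.
#' @param labels two-class labels.
#' @param k neighbourhood size (default 1).
#' @return a `knn_loo_result`: list with `accuracy` (fraction correct),
#'   `predicted`, `misclassified` (named per-class counts) and `n`.
#' @export
knn_loo <- function(X, labels, k = 1L) {
  X <- as.matrix(X)
  labels <- factor(labels)
  n <- nrow(X)
  if (k >= n) stop("k must be smaller than the number of cases", call. = FALSE)
  if (k %% 2 == 0) stop("k must be odd for a two-class majority vote",
                        call. = FALSE)
  D <- as.matrix(stats::dist(X))
  pred <- character(n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    nb <- others[order(D[i, others])[seq_len(k)]]   # stable: ties by case order
    votes <- table(labels[nb])
    pred[i] <- names(votes)[which.max(votes)]
  }
  correct <- pred == as.character(labels)
  mis <- tapply(!correct, labels, sum)
  structure(list(accuracy = mean(correct), predicted = pred,
                 misclassified = mis, n = n, k = k),
            class = "knn_loo_result")
}

#' Area under the ROC curve
#'
#' Mann-Whitney form of the AUC: the probability that a random positive
#' case scores above a random negative one, counting ties as one half —
#' identical to trapezoidal integration of the ROC curve and invariant to
#' any strictly monotone transform of the scores.
#'
#' @param scores continuous classifier scores.
#' @param labels two-class labels; `positive` selects the positive class
#'   (default: the second factor level).
#' @param positive label of the positive class.
#' @return the AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("both classes must be present", call. = FALSE)
  if (is.null(positive)) positive <- levels(labels)[2]
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Train and evaluate the MLP on one stratified 70/30 split
#'
#' Draws a stratified random split (70% training / 30% validation by
#' default), z-scores the selected features using training-set statistics
#' only, trains a single-hidden-layer feed-forward perceptron with logistic
#' units (via [nnet::nnet()]; 4 hidden neurons, weight decay 0.1,
#' cross-entropy loss, at most 500 optimizer iterations by default) and
#' evaluates it on the held-out cases. Identical seed and data give an
#' identical result.
#'
#' @param X numeric matrix of cases x selected features.
#' @param labels two-class labels; the second factor level is the positive
#'   class.
#' @param split_seed integer seed for the split and the weight
#'   initialization.
#' @param train_frac training fraction (default 0.7).
#' @param hidden hidden-layer size (default 4; at least 3 per protocol).
#' @param decay weight decay (default 0.1, sized for 10 standardized inputs
#'   and ~70 training cases).
#' @param maxit maximum optimizer iterations (default 500).
#' @return a `run_result`: list with `auc` (validation), `acc_train_pct`,
#'   `acc_val_pct` (accuracies in percent at the 0.5 threshold),
#'   `misclassified_val` (named per-class counts), `split_seed` and the
#'   architecture settings.
#' @export
mlp_train_eval <- function(X, labels, split_seed, train_frac = 0.7,
                           hidden = 4L, decay = 0.1, maxit = 500L) {
  X <- as.matrix(X)
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2, nrow(X) == length(labels))
  set.seed(split_seed)
  idx_train <- unlist(lapply(levels(labels), function(lv) {
    ids <- which(labels == lv)
    sample(ids, max(1, round(train_frac * length(ids))))
  }))
  idx_val <- setdiff(seq_along(labels), idx_train)
  if (length(unique(labels[idx_val])) < 2 || length(unique(labels[idx_train])) < 2)
    stop("split left a class empty; need >= 2 cases per class", call. = FALSE)

  mu <- colMeans(X[idx_train, , drop = FALSE])
  sdv <- apply(X[idx_train, , drop = FALSE], 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  y <- as.numeric(labels == levels(labels)[2])

  fit <- nnet::nnet(Z[idx_train, , drop = FALSE], y[idx_train],
                    size = hidden, decay = decay, maxit = maxit,
                    entropy = TRUE, trace = FALSE)
  score_train <- as.vector(stats::predict(fit, Z[idx_train, , drop = FALSE]))
  score_val <- as.vector(stats::predict(fit, Z[idx_val, , drop = FALSE]))
  pred_val <- ifelse(score_val > 0.5, levels(labels)[2], levels(labels)[1])
  correct_val <- pred_val == as.character(labels[idx_val])
  mis <- tapply(!correct_val, labels[idx_val], sum)
  structure(list(
    auc = roc_auc(score_val, labels[idx_val]),
    acc_train_pct = 100 * mean((score_train > 0.5) == (y[idx_train] == 1)),
    acc_val_pct = 100 * mean(correct_val),
    misclassified_val = mis,
    n_train = length(idx_train), n_val = length(idx_val),
    split_seed = split_seed,
    settings = list(hidden = hidden, decay = decay, maxit = maxit,
                    train_frac = train_frac)),
    class = "run_result")
}

#' Repeat the MLP protocol over independent random splits
#'
#' Runs [mlp_train_eval()] `n_reps` times with independent stratified
#' splits (split seeds derived deterministically from `master_seed`) and
#' summarises validation AUC and the two accuracies as
#' `median (min - max)`, the reporting convention of repeated-split
#' radiomics studies.
#'
#' @param X numeric matrix of cases x selected features.
#' @param labels two-class labels.
#' @param n_reps number of repetitions (default 5).
#' @param master_seed seed from which the per-repetition split seeds are
#'   derived.
#' @param ... further arguments passed to [mlp_train_eval()].
#' @return a `repeat_runs_result`: list with `runs` (list of `run_result`),
#'   `summary` (data.frame with median/min/max for `auc`, `acc_train_pct`,
#'   `acc_val_pct`) and `formatted` (named character, "median (min-max)").
#' @export
repeat_runs <- function(X, labels, n_reps = 5L, master_seed = 1L, ...) {
  stopifnot(n_reps >= 1)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1, n_reps)
  runs <- lapply(seq_len(n_reps), function(r) {
    out <- mlp_train_eval(X, labels, split_seed = seeds[r], ...)
    out$repetition <- r
    out
  })
  metrics <- c("auc", "acc_train_pct", "acc_val_pct")
  vals <- sapply(metrics, function(m) vapply(runs, `[[`, numeric(1), m))
  vals <- matrix(vals, nrow = n_reps, dimnames = list(NULL, metrics))
  summary <- data.frame(metric = metrics,
                        median = apply(vals, 2, stats::median),
                        min = apply(vals, 2, min),
                        max = apply(vals, 2, max),
                        row.names = NULL)
  digits <- c(auc = 2, acc_train_pct = 1, acc_val_pct = 1)
  formatted <- stats::setNames(sprintf(
    "%.*f (%.*f-%.*f)", digits[metrics], summary$median,
    digits[metrics], summary$min, digits[metrics], summary$max), metrics)
  structure(list(runs = runs, summary = summary, formatted = formatted,
                 n_reps = n_reps, master_seed = master_seed),
            class = "repeat_runs_result")
}

#' @export
print.repeat_runs_result <- function(x, ...) {
  cat(sprintf("MLP over %d stratified splits (master seed %d):\n",
              x$n_reps, x$master_seed))
  cat(sprintf("  validation AUC       %s\n", x$formatted["auc"]))
  cat(sprintf("  training accuracy %%  %s\n", x$formatted["acc_train_pct"]))
  cat(sprintf("  validation accuracy %% %s\n", x$formatted["acc_val_pct"]))
  invisible(x)
}
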