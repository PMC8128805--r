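#' Probability of classification error of a single feature
#'
#' Minimal class-prior-weighted misclassification rate of a one-dimensional
#' threshold classifier, over all cut points between sorted distinct values
#' and both polarities (the classical single-feature error estimate used in
#' POE+ACC selection; priors are the empirical class frequencies, so this is
#' the resubstitution error of the best threshold). Cases with a missing
#' value are excluded. The result lies in `[0, 0.5]`; the degenerate
#' thresholds at the extremes always admit `min(n1, n2) / n`.
#'
#' @param values numeric feature values, one per case.
#' @param labels two-class labels, same length.
#' @return the probability of error.
#' @export
poe <- function(values, labels) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]
  labels <- factor(labels[ok])
  if (nlevels(labels) != 2)
    stop("exactly two classes with observed values are required", call. = FALSE)
  n <- length(values)
  ord <- order(values)
  v <- values[ord]
  is1 <- labels[ord] == levels(labels)[1]
  n1 <- sum(is1); n2 <- n - n1
  ## cuts are allowed after position k only where the value changes
  cum1 <- cumsum(is1)
  cum2 <- seq_len(n) - cum1
  cut_ok <- c(v[-n] < v[-1], TRUE)          # position n = cut above everything
  c1 <- c(0, cum1[cut_ok])                  # class-1 cases below the cut
  c2 <- c(0, cum2[cut_ok])
  ## polarity 1: class 1 below the cut; polarity 2: class 2 below
  err1 <- (n1 - c1) + c2
  err2 <- (n2 - c2) + c1
  min(err1, err2) / n
}

#' POE + ACC sequential feature selection
#'
#' Greedy forward selection minimizing the sum of the single-feature
#' probability of error (POE) and the average absolute correlation (ACC)
#' with the features already selected: the first feature is the global POE
#' minimizer; each later step picks `argmin POE(f) + mean_j |r(f, s_j)|`
#' over the remaining features. Ties break deterministically towards the
#' earlier column (registry order). Zero-variance and all-missing features
#' are excluded; features with sporadic missing values participate through
#' pairwise-complete correlations.
#'
#' @param table feature table from [extract_cohort()] (or a plain
#'   data.frame/matrix of cases x features).
#' @param labels two-class labels; defaults to the table's `class_label`.
#' @param n_select number of features to select (default 10).
#' @param method correlation type, `"pearson"` (default) or `"spearman"`.
#' @param poe_weight,acc_weight weights of the two criterion terms
#'   (default 1 and 1, i.e. the plain sum).
#' @return a `selection_result`: data.frame with one row per selection step
#'   (`feature`, `poe`, `acc`, `criterion`) plus configuration attributes.
#' @export
select_features <- function(table, labels = NULL, n_select = 10L,
                            method = c("pearson", "spearman"),
                            poe_weight = 1, acc_weight = 1) {
  method <- match.arg(method)
  if (is.data.frame(table) && "class_label" %in% names(table)) {
    fm <- feature_matrix(table)
    X <- fm$X
    if (is.null(labels)) labels <- fm$meta$class_label
  } else {
    X <- as.matrix(table)
  }
  stopifnot(!is.null(labels), length(labels) == nrow(X))

  usable <- apply(X, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) >= 2 && stats::var(v) > 0
  })
  if (sum(usable) < n_select) {
    warning("only ", sum(usable), " usable features; returning a shorter list")
    n_select <- sum(usable)
  }
  Xu <- X[, usable, drop = FALSE]
  poe_all <- apply(Xu, 2, poe, labels = labels)

  selected <- integer(0)
  rows <- vector("list", n_select)
  remaining <- seq_len(ncol(Xu))
  for (step in seq_len(n_select)) {
    if (step == 1) {
      acc <- rep(0, length(remaining))
    } else {
      R <- suppressWarnings(
        stats::cor(Xu[, remaining, drop = FALSE],
                   Xu[, selected, drop = FALSE],
                   use = "pairwise.complete.obs", method = method))
      acc <- rowMeans(abs(R))
      acc[is.na(acc)] <- 1      # uncorrelatable against selected: worst case
    }
    crit <- poe_weight * poe_all[remaining] + acc_weight * acc
    best <- which.min(crit)     # first minimum = registry-order tie-break
    pick <- remaining[best]
    rows[[step]] <- data.frame(feature = colnames(Xu)[pick],
                               poe = unname(poe_all[pick]),
                               acc = unname(acc[best]),
                               criterion = unname(crit[best]),
                               stringsAsFactors = FALSE)
    selected <- c(selected, pick)
    remaining <- remaining[-best]
  }
  out <- do.call(rbind, rows)
  attr(out, "n_select") <- n_select
  attr(out, "method") <- method
  attr(out, "weights") <- c(poe = poe_weight, acc = acc_weight)
  class(out) <- c("selection_result", "data.frame")
  out
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("POE+ACC selection (%s correlation), %d feature(s):\n",
              attr(x, "method"), nrow(x)))
  print.data.frame(x, row.names = TRUE, digits = 4)
  invisible(x)
}
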