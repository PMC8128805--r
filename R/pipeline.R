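## The four-condition dual-center experiment:
##   (a) per-center LDA + k-NN leave-one-out on unmodified data,
##   (b) pooled unmodified data -> MLP,
##   (c) pooled data with center B resampled to center A's matrix -> MLP,
##   (d) pooled data harmonized at the feature level -> MLP.
## Conditions (b)-(d) share the cohort and master seed and differ only in
## the correction applied.

## z-score columns; zero-variance columns are left centered only
standardize_columns <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  sweep(sweep(X, 2, mu), 2, sdv, "/")
}

## drop feature columns with any missing value (selection keeps them, but
## the classifiers need complete inputs)
complete_feature_columns <- function(X) {
  X[, colSums(is.na(X)) == 0, drop = FALSE]
}

#' Single-center protocol: POE+ACC, LDA projection, k-NN leave-one-out
#'
#' For the cases of one center: extract features, select the `n_select`
#' best by POE+ACC, z-score them, project onto the Fisher discriminant axis
#' and classify by k-NN with leave-one-out cross-validation. Feature
#' selection and standardization use all cases of the center (the
#' resubstitution-flavoured protocol of small single-center radiomics
#' analyses; see the methods vignette for the leakage discussion).
#'
#' @param cohort list of `image_study` objects (may contain both centers).
#' @param center_id which center to evaluate.
#' @param n_select number of features to select (default 10).
#' @param k k-NN neighbourhood size (default 1).
#' @param bits quantization depth for feature extraction.
#' @param features optional precomputed feature table (skips extraction).
#' @return list with `center_id`, `n`, `correct`, `accuracy_pct`,
#'   `misclassified` (per-class counts), `selected` (feature names) and
#'   `settings`.
#' @export
run_single_center <- function(cohort, center_id, n_select = 10L, k = 1L,
                              bits = 6L, features = NULL) {
  if (is.null(features)) {
    sub <- Filter(function(s) s$center_id == center_id, cohort)
    if (length(sub) == 0) stop("no cases for center ", center_id, call. = FALSE)
    features <- extract_cohort(sub, bits = bits)
  } else {
    features <- features[features$center_id == center_id, , drop = FALSE]
  }
  if (length(unique(features$class_label)) < 2)
    stop("center ", center_id, " does not contain both classes", call. = FALSE)
  sel <- select_features(features, n_select = n_select)
  fm <- feature_matrix(features)
  Xs <- complete_feature_columns(fm$X[, sel$feature, drop = FALSE])
  Z <- standardize_columns(Xs)
  proj <- lda_project(Z, features$class_label)
  res <- knn_loo(proj$projected, features$class_label, k = k)
  n <- nrow(features)
  list(center_id = center_id, n = n,
       correct = round(res$accuracy * n),
       accuracy_pct = 100 * res$accuracy,
       misclassified = res$misclassified,
       selected = sel$feature,
       settings = list(n_select = n_select, k = k, bits = bits))
}

#' Pooled dual-center protocol with an optional center-effect correction
#'
#' Applies the requested correction, selects features by POE+ACC on the
#' corrected pooled table, and runs the repeated stratified MLP protocol:
#' \describe{
#'   \item{`none`}{pooled features as extracted.}
#'   \item{`resample`}{images with a matrix larger than the smallest matrix
#'     in the cohort are bilinearly resampled to it, ROIs are re-derived on
#'     the resampled images, features re-extracted, and selection repeated.}
#'   \item{`combat`}{empirical-Bayes feature harmonization across centers
#'     ([fit_combat()] on the pooled table, fitted before the
#'     train/validation splits; see the vignette for the implied leakage).}
#' }
#'
#' @param cohort list of `image_study` objects from both centers.
#' @param correction one of `"none"`, `"resample"`, `"combat"`.
#' @param master_seed seed driving the repeated splits.
#' @param n_select,n_reps,bits protocol settings.
#' @param features optional precomputed uncorrected feature table (used by
#'   `none` and `combat`).
#' @param combat_covariates optional protected covariate design for the
#'   `combat` arm (default none).
#' @param ... further arguments passed to [mlp_train_eval()].
#' @return list with `correction`, `selected`, `runs`
#'   (a `repeat_runs_result`), `median_auc` and `settings`.
#' @export
run_pooled <- function(cohort, correction = c("none", "resample", "combat"),
                       master_seed = 1L, n_select = 10L, n_reps = 5L,
                       bits = 6L, features = NULL, combat_covariates = NULL,
                       ...) {
  correction <- match.arg(correction)
  if (correction == "resample") {
    target <- min(vapply(cohort, function(s) nrow(s$pixels), numeric(1)))
    cohort <- lapply(cohort, function(s)
      if (nrow(s$pixels) > target) resample_image(s, target) else s)
    features <- extract_cohort(cohort, bits = bits)
  } else if (is.null(features)) {
    features <- extract_cohort(cohort, bits = bits)
  }
  if (length(unique(features$center_id)) < 2)
    stop("pooled analysis needs both centers", call. = FALSE)
  if (correction == "combat") {
    model <- fit_combat(features, covariates = combat_covariates)
    features <- apply_combat(model, features, covariates = combat_covariates)
  }
  sel <- select_features(features, n_select = n_select)
  fm <- feature_matrix(features)
  Xs <- complete_feature_columns(fm$X[, sel$feature, drop = FALSE])
  runs <- repeat_runs(Xs, features$class_label, n_reps = n_reps,
                      master_seed = master_seed, ...)
  list(correction = correction, selected = sel$feature, runs = runs,
       median_auc = runs$summary$median[runs$summary$metric == "auc"],
       settings = list(n_select = n_select, n_reps = n_reps, bits = bits,
                       master_seed = master_seed))
}

#' Run the full four-condition dual-center study
#'
#' Generates the cohort with `master_seed`, evaluates the single-center
#' LDA + k-NN protocol for each center, and the pooled MLP protocol under
#' the three corrections (none, matrix resampling, feature harmonization).
#' The three pooled arms share the identical cohort and master seed and
#' differ only in the correction stage. The result is deterministic for a
#' fixed configuration and seed.
#'
#' @param config a [cohort_config()]; its seed is replaced by `master_seed`
#'   so that one integer controls the whole experiment.
#' @param master_seed integer seed for cohort generation and the repeated
#'   splits.
#' @param n_select,n_reps,k,bits protocol settings.
#' @return a `study_report`: list with `single_center` (per-center blocks),
#'   `pooled` (blocks for `none`, `resample`, `combat`), `config`,
#'   `master_seed` and `version`.
#' @export
run_study <- function(config = cohort_config(), master_seed = 1L,
                      n_select = 10L, n_reps = 5L, k = 1L, bits = 6L) {
  stopifnot(inherits(config, "cohort_config"))
  config$seed <- as.integer(master_seed)
  cohort <- generate_cohort(config)
  features <- extract_cohort(cohort, bits = bits)

  single <- lapply(c("A", "B"), function(cc)
    run_single_center(cohort, cc, n_select = n_select, k = k, bits = bits,
                      features = features))
  names(single) <- c("A", "B")

  pooled <- lapply(c("none", "resample", "combat"), function(corr)
    run_pooled(cohort, correction = corr, master_seed = master_seed,
               n_select = n_select, n_reps = n_reps, bits = bits,
               features = if (corr == "resample") NULL else features))
  names(pooled) <- c("none", "resample", "combat")

  structure(list(single_center = single, pooled = pooled,
                 config = unclass(config), master_seed = master_seed,
                 settings = list(n_select = n_select, n_reps = n_reps,
                                 k = k, bits = bits),
                 version = as.character(utils::packageVersion("otoradiomics"))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Dual-center radiomics study report (seed %d)\n", x$master_seed))
  for (cc in names(x$single_center)) {
    b <- x$single_center[[cc]]
    cat(sprintf("  center %s: %d/%d cases (accuracy, %.0f%%; misclassified: %s)\n",
                cc, b$correct, b$n, b$accuracy_pct,
                paste(b$misclassified, names(b$misclassified), collapse = ", ")))
  }
  lab <- c(none = "pooled unmodified", resample = "pooled resampled",
           combat = "pooled harmonized")
  for (corr in names(x$pooled)) {
    b <- x$pooled[[corr]]
    cat(sprintf("  %-18s AUC %s, train acc %s, val acc %s\n", lab[corr],
                b$runs$formatted["auc"], b$runs$formatted["acc_train_pct"],
                b$runs$formatted["acc_val_pct"]))
  }
  invisible(x)
}

#' Serialize a study report to JSON
#'
#' Writes the complete report (all blocks, per-repetition results, selected
#' feature lists, configuration, seeds and package version) as JSON.
#'
#' @param report a `study_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_study_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  ser <- rapply(unclass(report), unclass, how = "replace")
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
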