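# k-nearest-neighbour species classification with group-aware validation.
#
# Patches from the same source image (or leaf, or tree) are highly
# correlated; folds therefore never split a grouping-key value, so accuracy
# estimates reflect generalization to unseen images rather than to
# neighbouring patches of an image already trained on.

#' Columns of the feature table used as kNN predictors
#' @keywords internal
#' @noRd
CLASSIFIER_FEATURES <- c("glcm_asm", "glcm_contrast", "glcm_entropy",
                         "glcm_homogeneity", "glcm_correlation",
                         "grad_mean", "grad_std", "compression_bpp")

classifier_feature_cols <- function(df) {
  c(CLASSIFIER_FEATURES[CLASSIFIER_FEATURES %in% names(df)],
    grep("^sp_[0-9]+$", names(df), value = TRUE))
}

#' Build a grouped, species-stratified cross-validation plan
#'
#' Assigns every patch to a fold such that all patches sharing a grouping
#' key (source image by default) land in the same fold, and each species
#' spreads its groups as evenly as possible across folds.
#'
#' @param patch_manifest data frame with `patch_id`, `species` and the
#'   grouping columns (`image_id`, `leaf_id`, `tree_id`).
#' @param grouping `"source_image"`, `"leaf"` or `"tree"`.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return a `leaftex_split`: data frame `patch_id`, `fold` with the
#'   grouping and fold count as attributes.
#' @export
make_split <- function(patch_manifest, grouping = c("source_image", "leaf",
                                                    "tree"),
                       n_folds = 5, seed = 1) {
  grouping <- match.arg(grouping)
  key_col <- switch(grouping, source_image = "image_id", leaf = "leaf_id",
                    tree = "tree_id")
  stopifnot_cols(patch_manifest, c("patch_id", "species", key_col),
                 "patch manifest")
  key <- paste(patch_manifest$species, patch_manifest[[key_col]], sep = "\r")
  fold_of_key <- with_seed(seed, {
    res <- character(0)
    for (sp in sort(unique(patch_manifest$species))) {
      keys <- unique(key[patch_manifest$species == sp])
      if (length(keys) < n_folds)
        ltx_validation_error(
          "species '%s' has %d distinct %s group(s), fewer than %d folds",
          sp, length(keys), grouping, n_folds)
      keys <- sample(keys)
      res[keys] <- rep_len(seq_len(n_folds), length(keys))
    }
    res
  })
  out <- data.frame(patch_id = patch_manifest$patch_id,
                    fold = as.integer(fold_of_key[key]),
                    stringsAsFactors = FALSE)
  structure(out, grouping = grouping, n_folds = as.integer(n_folds),
            class = c("leaftex_split", "data.frame"))
}

# Standardize by training-set mean/sd; zero-variance columns are dropped
# with a warning. Returns list(train, test, cols).
standardize_features <- function(train, test, cols) {
  mu <- colMeans(train[, cols, drop = FALSE])
  sd_ <- apply(train[, cols, drop = FALSE], 2, stats::sd)
  zero <- sd_ == 0 | !is.finite(sd_)
  if (any(zero)) {
    warning(sprintf("dropping zero-variance feature(s): %s",
                    paste(cols[zero], collapse = ", ")))
    cols <- cols[!zero]
    mu <- mu[!zero]; sd_ <- sd_[!zero]
  }
  scale_mat <- function(df) {
    m <- as.matrix(df[, cols, drop = FALSE])
    sweep(sweep(m, 2, mu), 2, sd_, "/")
  }
  list(train = scale_mat(train), test = scale_mat(test), cols = cols)
}

# Deterministic kNN vote: majority among the k nearest; ties broken by the
# summed inverse distance of each candidate label's neighbours, then by the
# lexicographically smallest label.
knn_predict <- function(Xtr, ytr, Xte, k) {
  d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
  d2[d2 < 0] <- 0
  apply(d2, 1, function(row) {
    nn <- order(row)[seq_len(k)]
    labs <- ytr[nn]
    dists <- sqrt(row[nn])
    votes <- table(labs)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      invd <- vapply(top, function(l)
        sum(1 / pmax(dists[labs == l], 1e-12)), 0)
      top <- top[invd == max(invd)]
    }
    sort(top)[1]
  })
}

classification_report <- function(truth, pred, species_levels,
                                  per_fold_accuracy = NULL) {
  confusion <- table(factor(truth, levels = species_levels),
                     factor(pred, levels = species_levels),
                     dnn = c("truth", "predicted"))
  structure(list(
    accuracy = sum(diag(confusion)) / sum(confusion),
    confusion = confusion,
    per_fold_accuracy = per_fold_accuracy,
    n_test = length(truth)
  ), class = "leaftex_classification_report")
}

#' @export
print.leaftex_classification_report <- function(x, ...) {
  cat(sprintf("<leaftex_classification_report> accuracy %.4f on %d patches\n",
              x$accuracy, x$n_test))
  if (!is.null(x$per_fold_accuracy))
    cat("  per-fold:", paste(sprintf("%.3f", x$per_fold_accuracy),
                             collapse = " "), "\n")
  invisible(x)
}

#' Classify patches by k-nearest neighbours
#'
#' Features are z-scored by the training mean and standard deviation
#' (zero-variance columns dropped with a warning), distances are Euclidean
#' and the vote is a deterministic majority with the tie rules documented in
#' the package (summed inverse distance, then lexicographic label order).
#'
#' @param train_features,test_features feature tables sharing the same
#'   feature columns plus a `species` column in `train_features` (and in
#'   `test_features` for the report).
#' @param k neighbourhood size.
#' @return a `leaftex_classification_report` with `accuracy`, a
#'   species-by-species `confusion` table (rows = truth) and the predicted
#'   labels as attribute `"predictions"`.
#' @export
knn_classify <- function(train_features, test_features, k = 3) {
  cols <- classifier_feature_cols(train_features)
  if (!setequal(cols, classifier_feature_cols(test_features)))
    ltx_validation_error("train and test feature columns differ")
  if (nrow(train_features) < k)
    ltx_validation_error("k = %d exceeds the %d training rows", k,
                         nrow(train_features))
  std <- standardize_features(train_features, test_features, cols)
  pred <- knn_predict(std$train, as.character(train_features$species),
                      std$test, k)
  species_levels <- sort(unique(c(train_features$species,
                                  test_features$species)))
  rep <- classification_report(as.character(test_features$species), pred,
                               species_levels)
  attr(rep, "predictions") <- pred
  rep
}

#' Grouped cross-validated kNN accuracy
#'
#' For each fold of the plan, refits the spectral PCA model on the training
#' patches' radial spectra (`spec_bin_*` columns), projects both partitions,
#' standardizes by training statistics and classifies the held-out patches.
#' No statistic ever crosses from a test fold into its training data.
#'
#' @param features feature table from [extract_features()] (must contain the
#'   `spec_bin_*` columns so the spectral model can be refitted per fold).
#' @param plan a `leaftex_split` covering all patches.
#' @param k neighbourhood size.
#' @param n_components spectral components per fold model.
#' @return a `leaftex_classification_report` with the pooled confusion
#'   matrix, pooled accuracy and `per_fold_accuracy`.
#' @export
cross_validated_accuracy <- function(features, plan, k = 3,
                                     n_components = 25) {
  stopifnot(inherits(plan, "leaftex_split"))
  idx <- match(features$patch_id, plan$patch_id)
  if (anyNA(idx))
    ltx_validation_error("split plan does not cover all patches")
  fold <- plan$fold[idx]
  spec_cols <- grep("^spec_bin_", names(features), value = TRUE)
  truths <- character(0); preds <- character(0); pids <- character(0)
  folds <- integer(0)
  per_fold <- numeric(0)
  for (f in sort(unique(fold))) {
    tr <- features[fold != f, , drop = FALSE]
    te <- features[fold == f, , drop = FALSE]
    absent <- setdiff(unique(te$species), unique(tr$species))
    if (length(absent)) {
      warning(sprintf(
        "fold %d: species %s absent from training, excluded from its test set",
        f, paste(absent, collapse = ", ")))
      te <- te[!te$species %in% absent, , drop = FALSE]
    }
    if (nrow(te) == 0) next
    model <- fit_spectral_model(as.matrix(tr[, spec_cols]),
                                n_components = n_components)
    tr2 <- add_spectral_scores(tr, model)
    te2 <- add_spectral_scores(te, model)
    rep_f <- knn_classify(tr2, te2, k = k)
    pred <- attr(rep_f, "predictions")
    truths <- c(truths, as.character(te$species))
    preds <- c(preds, pred)
    pids <- c(pids, te$patch_id)
    folds <- c(folds, rep(f, nrow(te)))
    per_fold <- c(per_fold, mean(pred == te$species))
  }
  out <- classification_report(truths, preds, sort(unique(features$species)),
                               per_fold_accuracy = per_fold)
  out$predictions <- data.frame(patch_id = pids, fold = folds,
                                truth = truths, predicted = preds,
                                stringsAsFactors = FALSE)
  out
}
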