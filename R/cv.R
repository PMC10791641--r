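# Lake-level (spatial) cross-validation: folds are partitions of lakes, not
# rows, so held-out lakes are never seen during training.

#' Assign lakes to spatial cross-validation folds
#'
#' Randomly partitions the distinct lakes of a table into `k` folds of
#' near-equal lake counts (sizes differ by at most one); every row of a lake
#' shares its lake's fold.
#'
#' @param table Data.frame with a `lake_id` column.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold indices (1..k), one per row of `table`.
#' @export
make_spatial_folds <- function(table, k = 5L, seed = 1L) {
  require_columns(table, "lake_id", "table")
  lakes <- unique(table$lake_id)
  if (length(lakes) < k) {
    stop(sprintf("need at least k = %d distinct lakes, got %d", k, length(lakes)),
         call. = FALSE)
  }
  set.seed(seed)
  shuffled <- sample(lakes)
  fold_of <- stats::setNames(rep(seq_len(k), length.out = length(shuffled)),
                             shuffled)
  unname(fold_of[as.character(table$lake_id)])
}

#' Class-stratified holdout split
#'
#' Sets aside `frac` of each trophic class (rounded, at least one row) for
#' validation; the remainder is the training part. The two parts are disjoint
#' and exhaustive.
#'
#' @param table Data.frame with a `trophic_state` column.
#' @param frac Fraction of each class held out.
#' @param seed Integer seed.
#' @return List with `train` and `validation` data.frames.
#' @export
stratified_holdout <- function(table, frac, seed = 1L) {
  require_columns(table, "trophic_state", "table")
  set.seed(seed)
  cls <- as.character(table$trophic_state)
  val_idx <- integer(0)
  for (cc in unique(cls)) {
    rows <- which(cls == cc)
    if (length(rows) < 2L) {
      stop(sprintf("class '%s' has fewer than 2 rows; cannot split", cc),
           call. = FALSE)
    }
    n_val <- max(1L, round(frac * length(rows)))
    val_idx <- c(val_idx, sample(rows, n_val))
  }
  list(train = table[-val_idx, , drop = FALSE],
       validation = table[val_idx, , drop = FALSE])
}

#' Spatially cross-validate one classifier family
#'
#' Runs the lake-level k-fold routine: within each fold's training part a
#' 90:10 class-stratified inner split supplies the early-stopping validation
#' set; the early-stopped model predicts class probabilities for the held-out
#' fold. Pooled predictions cover every row exactly once, and the absence of
#' lake-level leakage is asserted for every fold. Per-fold best epoch/round
#' counts are recorded for the final-model budget.
#'
#' @param family Family code or alias.
#' @param hyperparams Named hyperparameter list (`NULL` = tuned defaults).
#' @param table Training table from [build_training_table()].
#' @param k Number of spatial folds.
#' @param seed Integer seed.
#' @param patience Early-stopping patience.
#' @param inner_frac Fraction of each class held out inside each fold.
#' @param max_iter Cap on epochs/rounds.
#' @return Object of class `"lts_cv"`: `predictions` (one row per table row:
#'   `lake_id`, `year`, `fold`, `true_state`, `prob_dys`, `prob_eumixo`,
#'   `prob_oligo`, `pred_state`, `family`), `best_iters`, `metrics` (pooled
#'   [confusion_and_accuracy()] plus [roc_auc_ovr()]), `k`, `family`.
#' @export
cross_validate <- function(family, hyperparams = NULL, table, k = 5L, seed = 1L,
                           patience = 20L, inner_frac = 0.1, max_iter = 300L) {
  family <- canonical_family(family)
  require_columns(table, c("lake_id", "year", "trophic_state"), "table")
  fold <- make_spatial_folds(table, k = k, seed = derive_seed(seed, 5))
  preds <- vector("list", k)
  best_iters <- rep(NA_integer_, k)
  for (i in seq_len(k)) {
    test <- table[fold == i, , drop = FALSE]
    rest <- table[fold != i, , drop = FALSE]
    leak <- intersect(unique(test$lake_id), unique(rest$lake_id))
    if (length(leak)) {
      stop(sprintf("spatial leakage in fold %d: lake(s) %s on both sides",
                   i, paste(utils::head(leak, 3), collapse = ", ")), call. = FALSE)
    }
    split <- stratified_holdout(rest, frac = inner_frac,
                                seed = derive_seed(seed, 100 + i))
    fit <- tryCatch(
      train_model(family, hyperparams, split$train, split$validation,
                  patience = patience, seed = derive_seed(seed, 200 + i),
                  max_iter = max_iter),
      error = function(e) stop(sprintf("fold %d: %s", i, conditionMessage(e)),
                               call. = FALSE))
    best_iters[i] <- fit$best_iter
    p <- predict_proba(fit, test)
    preds[[i]] <- data.frame(
      lake_id = test$lake_id, year = test$year, fold = i,
      true_state = as.character(test$trophic_state),
      prob_dys = p[, "dys"], prob_eumixo = p[, "eu/mixo"],
      prob_oligo = p[, "oligo"],
      pred_state = colnames(p)[max.col(p, ties.method = "first")],
      family = family, stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  if (nrow(predictions) != nrow(table)) {
    stop("pooled CV predictions do not cover the table exactly once", call. = FALSE)
  }
  metrics <- confusion_and_accuracy(predictions$true_state, predictions$pred_state)
  metrics$auc <- roc_auc_ovr(
    predictions$true_state,
    as.matrix(stats::setNames(
      predictions[, c("prob_dys", "prob_eumixo", "prob_oligo")],
      lts_classes())))
  structure(list(predictions = predictions, best_iters = best_iters,
                 metrics = metrics, k = k, family = family),
            class = "lts_cv")
}

#' @export
print.lts_cv <- function(x, ...) {
  cat(sprintf("Spatial %d-fold cross-validation (%s): %d rows, %d lakes\n",
              x$k, x$family, nrow(x$predictions), length(unique(x$predictions$lake_id))))
  cat(sprintf("  overall accuracy: %.3f   balanced (macro): %.3f   macro AUC: %.3f\n",
              x$metrics$overall_accuracy, x$metrics$balanced_accuracy_macro,
              x$metrics$auc$macro))
  invisible(x)
}

#' Train the final full-data model
#'
#' Trains one model on the whole table for a fixed iteration budget (the
#' rounded median of the per-fold best epochs/rounds from cross-validation),
#' without early stopping. The multinomial logit ignores the budget and is fit
#' to convergence.
#'
#' @inheritParams cross_validate
#' @param best_iters Integer vector of per-fold best epochs/rounds.
#' @return An `"lts_model"`.
#' @export
finalize_model <- function(family, hyperparams = NULL, table, best_iters = NULL,
                           seed = 1L) {
  family <- canonical_family(family)
  if (family == "mlr") {
    return(train_model("mlr", hyperparams, table, seed = seed))
  }
  if (is.null(best_iters) || all(is.na(best_iters))) {
    stop("finalize_model needs per-fold best iteration counts", call. = FALSE)
  }
  budget <- max(1L, as.integer(round(stats::median(best_iters, na.rm = TRUE))))
  train_model(family, hyperparams, table, seed = seed, n_iter = budget)
}
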