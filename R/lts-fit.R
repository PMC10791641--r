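# The central modelling object: a spatially cross-validated three-family
# ensemble classifier for lake trophic state.

#' Fit the lake trophic-state ensemble
#'
#' Fits the requested classifier families (multinomial logistic regression,
#' multilayer perceptron, gradient boosted trees) on z-scored relative-band
#' predictors under lake-level 5-fold spatial cross-validation, then trains
#' final full-data models with the epoch/round budget taken as the median of
#' the per-fold best iterations. Hyperparameters default to the tuned grid
#' winners; set `tune = TRUE` to rerun the coarse grid search first.
#'
#' @param data Training table from [build_training_table()] (columns
#'   `lake_id`, `year`, `z_red`..`z_nir`, `trophic_state`; the `"scaler"`
#'   attribute, when present, is stored for prediction-time standardization).
#' @param families Character vector of family codes (`"mlr"`, `"mlp"`,
#'   `"xgb"`; aliases accepted).
#' @param k Number of spatial folds.
#' @param seed Integer seed controlling folds, splits and fits.
#' @param hyperparams Named list of per-family hyperparameter lists; defaults
#'   to [lts_tuned_hyperparams()].
#' @param tune If `TRUE`, run [grid_search()] per family (mlp, xgb) and use
#'   its winners.
#' @param patience Early-stopping patience (epochs/rounds).
#' @param max_iter Cap on training epochs/rounds.
#' @param scaler Optional `"lts_scaler"` overriding the one attached to
#'   `data`.
#' @return Object of class `"lts"` with elements `cv` (per-family
#'   [cross_validate()] results), `models` (per-family final `"lts_model"`s),
#'   `grid` (per-family grid-search tables when tuned), `scaler`, `families`,
#'   `k`, `seed`, `call`.
#' @examples
#' \donttest{
#' cfg <- lts_sim_config(n_lakes = 60, years = c(2007L, 2012L), seed = 3)
#' sim <- simulate_lts_dataset(cfg, campaigns = c(2007L, 2012L))
#' tab <- build_training_table(sim$insitu, aggregate_overpasses(sim$overpasses),
#'                             lakes = sim$lakes)
#' fit <- lts(tab, families = "mlr", k = 3, seed = 1)
#' summary(fit)
#' }
#' @export
lts <- function(data, families = c("mlr", "mlp", "xgb"), k = 5L, seed = 1L,
                hyperparams = lts_tuned_hyperparams(), tune = FALSE,
                patience = 20L, max_iter = 300L, scaler = NULL) {
  cl <- match.call()
  families <- vapply(families, canonical_family, character(1))
  if (anyDuplicated(families)) stop("duplicate families", call. = FALSE)
  scaler <- scaler %||% attr(data, "scaler")
  cv <- list(); models <- list(); grids <- list()
  for (fam in families) {
    hp <- hyperparams[[fam]] %||% lts_tuned_hyperparams()[[fam]]
    if (tune && fam %in% c("mlp", "xgb")) {
      gs <- grid_search(fam, NULL, data, seed = derive_seed(seed, 400),
                        patience = patience, max_iter = max_iter)
      hp <- gs$best
      grids[[fam]] <- gs$table
    }
    cv[[fam]] <- cross_validate(fam, hp, data, k = k, seed = seed,
                                patience = patience, max_iter = max_iter)
    models[[fam]] <- finalize_model(fam, hp, data,
                                    best_iters = cv[[fam]]$best_iters,
                                    seed = derive_seed(seed, 500))
  }
  structure(list(cv = cv, models = models, grid = if (length(grids)) grids,
                 scaler = scaler, families = unname(families), k = k,
                 seed = seed, n_rows = nrow(data),
                 n_lakes = length(unique(data$lake_id)), call = cl),
            class = "lts")
}

#' @export
print.lts <- function(x, ...) {
  cat("Lake trophic-state ensemble classifier\n")
  cat(sprintf("  training rows: %d (%d lakes)   spatial folds: %d   seed: %s\n",
              x$n_rows, x$n_lakes, x$k, format(x$seed)))
  for (fam in x$families) {
    m <- x$cv[[fam]]$metrics
    cat(sprintf("  %-3s  CV accuracy %.3f   balanced %.3f   macro AUC %.3f\n",
                fam, m$overall_accuracy, m$balanced_accuracy_macro, m$auc$macro))
  }
  invisible(x)
}

#' @export
summary.lts <- function(object, ...) {
  rows <- lapply(object$families, function(fam) {
    m <- object$cv[[fam]]$metrics
    data.frame(family = fam,
               overall_accuracy = m$overall_accuracy,
               balanced_accuracy_macro = m$balanced_accuracy_macro,
               macro_auc = m$auc$macro,
               dys_balanced_accuracy =
                 m$per_class$balanced_accuracy[m$per_class$class == "dys"],
               stringsAsFactors = FALSE)
  })
  out <- list(metrics = do.call(rbind, c(rows, make.row.names = FALSE)),
              confusion = lapply(object$cv, function(cv) cv$metrics$confusion),
              per_class = lapply(object$cv, function(cv) cv$metrics$per_class),
              k = object$k)
  class(out) <- "summary.lts"
  out
}

#' @export
print.summary.lts <- function(x, ...) {
  cat(sprintf("Pooled spatial %d-fold cross-validation metrics\n", x$k))
  print(x$metrics, row.names = FALSE, digits = 4)
  for (fam in names(x$confusion)) {
    cat(sprintf("\nConfusion matrix (%s), rows = reference:\n", fam))
    print(x$confusion[[fam]])
  }
  invisible(x)
}

#' @export
coef.lts <- function(object, ...) {
  if (!"mlr" %in% object$families) {
    stop("coefficients are defined for the multinomial logit; 'mlr' was not fit",
         call. = FALSE)
  }
  stats::coef(object$models$mlr$fit)
}

#' Predict trophic state for new lake-years
#'
#' Applies the final models to a feature table. When `z_*` columns are absent
#' they are computed from the `rel_*` columns with the training-time scaler.
#'
#' @param object An `"lts"` fit.
#' @param newdata Feature table (from [aggregate_overpasses()] or
#'   [build_training_table()]).
#' @param type `"ensemble"` for the averaged table (see
#'   [ensemble_predictions()]), `"individual"` for the per-model nine-column
#'   probability table, `"class"` for the ensemble categorical call only.
#' @param ... Unused.
#' @return A data.frame (see `type`).
#' @export
predict.lts <- function(object, newdata, type = c("ensemble", "individual", "class"),
                        ...) {
  type <- match.arg(type)
  if (!all(lts_predictors() %in% names(newdata))) {
    if (is.null(object$scaler)) {
      stop("newdata lacks z_* columns and the fit carries no scaler", call. = FALSE)
    }
    newdata <- zscore_apply(object$scaler, newdata)
  }
  individual <- predict_all(object$models, newdata)
  if (type == "individual") return(individual)
  ens <- ensemble_predictions(individual)
  if (type == "class") {
    return(ens[, c("Hylak_id", "year", "categorical_ts")])
  }
  ens
}

#' Per-model probability table
#'
#' Applies each final model to all feature rows and assembles the nine-column
#' individual-model probability table keyed by (`Hylak_id`, `year`). Rows with
#' missing predictor values are skipped; the count is attached as attribute
#' `"n_skipped"`.
#'
#' @param models Named list with `"lts_model"`s for `mlr`, `mlp`, `xgb`.
#' @param features Feature table with `lake_id`, `year` and `z_*` columns.
#' @return Data.frame with `Hylak_id`, `year` and
#'   `prob_{dys,eumixo,oligo}_{mlr,mlp,xgb}`.
#' @export
predict_all <- function(models, features) {
  need <- c("mlr", "mlp", "xgb")
  if (!all(need %in% names(models))) {
    stop(sprintf("need one final model per family (%s)", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  require_columns(features, c("lake_id", "year", lts_predictors()), "features")
  ok <- stats::complete.cases(features[, lts_predictors()])
  skipped <- sum(!ok)
  features <- features[ok, , drop = FALSE]
  out <- data.frame(Hylak_id = features$lake_id, year = features$year)
  suffix <- c(dys = "dys", `eu/mixo` = "eumixo", oligo = "oligo")
  for (fam in need) {
    p <- predict_proba(models[[fam]], features)
    for (cc in lts_classes()) {
      out[[sprintf("prob_%s_%s", suffix[[cc]], fam)]] <- p[, cc]
    }
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Plot cross-validated confusion matrices
#'
#' Draws one bubble-style confusion matrix per fitted family from the pooled
#' spatial cross-validation predictions, circle area scaled by count.
#'
#' @param x An `"lts"` fit.
#' @param ... Passed to [graphics::symbols()].
#' @export
plot.lts <- function(x, ...) {
  fams <- x$families
  old <- graphics::par(mfrow = c(1, length(fams)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  classes <- lts_classes()
  for (fam in fams) {
    cm <- x$cv[[fam]]$metrics$confusion
    grid <- expand.grid(ref = seq_along(classes), pred = seq_along(classes))
    cnt <- cm[cbind(grid$ref, grid$pred)]
    graphics::plot(NA, xlim = c(0.5, 3.5), ylim = c(3.5, 0.5), axes = FALSE,
                   xlab = "predicted", ylab = "reference", main = fam)
    graphics::axis(1, at = 1:3, labels = classes)
    graphics::axis(2, at = 1:3, labels = classes, las = 1)
    graphics::symbols(grid$pred, grid$ref, circles = sqrt(cnt / max(cnt, 1)) / 2.2,
                      inches = FALSE, add = TRUE, bg = "grey80", ...)
    graphics::text(grid$pred, grid$ref, cnt, cex = 0.8)
  }
  invisible(x)
}
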