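# The three classifier families behind a single train/predict surface.
# Families are identified by the short codes used in the published prediction
# schema: "mlr" (multinomial logistic regression), "mlp" (single-hidden-layer
# perceptron), "xgb" (gradient boosted trees).

LTS_FAMILIES <- c("mlr", "mlp", "xgb")

canonical_family <- function(family) {
  alias <- c(mlr = "mlr", multinomial_logit = "mlr", logit = "mlr",
             mlp = "mlp", gbt = "xgb", xgb = "xgb")
  family <- as.character(family)
  if (!family %in% names(alias)) {
    stop(sprintf("unknown model family '%s' (use %s)", family,
                 paste(LTS_FAMILIES, collapse = ", ")), call. = FALSE)
  }
  unname(alias[[family]])
}

lts_predictors <- function() paste0("z_", lts_bands())

model_matrix_xy <- function(table) {
  require_columns(table, c(lts_predictors(), "trophic_state"), "model table")
  x <- as.matrix(table[, lts_predictors()])
  y <- factor(table$trophic_state, levels = lts_classes())
  if (anyNA(y)) stop("trophic_state contains values outside the class vocabulary",
                     call. = FALSE)
  list(x = x, y = y)
}

#' Hyperparameter grids and tuned defaults
#'
#' `lts_default_grid()` returns the coarse grid searched for a family:
#' hidden units \{5, 10, 20\} by learning rate \{0.01, 0.001, 0.0005\} for the
#' perceptron; maximum depth \{2, 3, 4\}, subsample and column sample
#' \{0.5, 0.8\}, step size \{0.01, 0.1\} and minimum child weight \{1, 3\} for
#' the boosted trees. `lts_tuned_hyperparams()` returns the grid winners used
#' as defaults (perceptron: 20 units, learning rate 0.001; boosted trees:
#' depth 4, subsample 0.5, column sample 0.5, step size 0.01, minimum child
#' weight 1). The multinomial logit has no tunable hyperparameters.
#'
#' @param family One of `"mlr"`, `"mlp"`, `"xgb"` (aliases
#'   `"multinomial_logit"`, `"gbt"` accepted).
#' @return `lts_default_grid()`: a data.frame (or `NULL` for `"mlr"`);
#'   `lts_tuned_hyperparams()`: a named list of per-family hyperparameter lists.
#' @export
lts_default_grid <- function(family) {
  switch(canonical_family(family),
    mlr = NULL,
    mlp = expand.grid(hidden_units = c(5L, 10L, 20L),
                      learning_rate = c(0.01, 0.001, 0.0005),
                      KEEP.OUT.ATTRS = FALSE),
    xgb = expand.grid(max_depth = c(2L, 3L, 4L),
                      subsample = c(0.5, 0.8),
                      colsample = c(0.5, 0.8),
                      step_size = c(0.01, 0.1),
                      min_child_weight = c(1, 3),
                      KEEP.OUT.ATTRS = FALSE)
  )
}

#' @rdname lts_default_grid
#' @export
lts_tuned_hyperparams <- function() {
  list(mlr = list(),
       mlp = list(hidden_units = 20L, learning_rate = 0.001),
       xgb = list(max_depth = 4L, subsample = 0.5, colsample = 0.5,
                  step_size = 0.01, min_child_weight = 1))
}

## ---- multilayer perceptron engine -----------------------------------------
## One ReLU hidden layer, softmax output, categorical cross-entropy loss,
## Adam updates on shuffled mini-batches of 32, optional early stopping on
## validation loss with a fixed patience. Weights from the best validation
## epoch are kept.

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

cross_entropy <- function(p, y_idx) {
  -mean(log(pmax(p[cbind(seq_along(y_idx), y_idx)], 1e-12)))
}

mlp_forward <- function(w, x) {
  h <- x %*% w$W1
  h <- sweep(h, 2L, w$b1, `+`)
  h[h < 0] <- 0
  z <- h %*% w$W2
  z <- sweep(z, 2L, w$b2, `+`)
  list(h = h, p = softmax_rows(z))
}

mlp_train <- function(x, y_idx, n_class, hidden = 20L, lr = 0.001,
                      batch_size = 32L, patience = 20L, max_epochs = 300L,
                      n_epochs = NULL, xval = NULL, yval_idx = NULL, seed = 1L) {
  set.seed(seed)
  n <- nrow(x); p <- ncol(x)
  w <- list(W1 = matrix(stats::rnorm(p * hidden, 0, sqrt(2 / p)), p, hidden),
            b1 = numeric(hidden),
            W2 = matrix(stats::rnorm(hidden * n_class, 0, sqrt(2 / hidden)),
                        hidden, n_class),
            b2 = numeric(n_class))
  m <- lapply(w, function(z) z * 0)   # Adam first moments
  v <- lapply(w, function(z) z * 0)   # Adam second moments
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0L
  onehot <- diag(n_class)
  early <- is.null(n_epochs)
  if (early && (is.null(xval) || is.null(yval_idx))) {
    stop("mlp training with early stopping requires validation data", call. = FALSE)
  }
  total_epochs <- if (early) max_epochs else n_epochs
  trace <- numeric(0)
  best_loss <- Inf; best_epoch <- 0L; best_w <- w; stall <- 0L
  for (epoch in seq_len(total_epochs)) {
    idx <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      b <- idx[start:min(start + batch_size - 1L, n)]
      xb <- x[b, , drop = FALSE]
      fwd <- mlp_forward(w, xb)
      dz <- (fwd$p - onehot[y_idx[b], , drop = FALSE]) / length(b)
      g <- list(W1 = NULL, b1 = NULL,
                W2 = crossprod(fwd$h, dz), b2 = colSums(dz))
      dh <- dz %*% t(w$W2)
      dh[fwd$h <= 0] <- 0
      g$W1 <- crossprod(xb, dh)
      g$b1 <- colSums(dh)
      t <- t + 1L
      for (nm in names(w)) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
        mhat <- m[[nm]] / (1 - beta1^t)
        vhat <- v[[nm]] / (1 - beta2^t)
        w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    loss <- if (early) {
      cross_entropy(mlp_forward(w, xval)$p, yval_idx)
    } else {
      cross_entropy(mlp_forward(w, x)$p, y_idx)
    }
    if (!is.finite(loss)) {
      stop(sprintf("mlp training failure: non-finite loss at epoch %d (trace: %s)",
                   epoch, paste(signif(utils::tail(trace, 5), 4), collapse = ", ")),
           call. = FALSE)
    }
    trace <- c(trace, loss)
    if (early) {
      if (loss < best_loss - 1e-12) {
        best_loss <- loss; best_epoch <- epoch; best_w <- w; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
  }
  if (!early) { best_w <- w; best_epoch <- total_epochs; best_loss <- utils::tail(trace, 1L) }
  list(weights = best_w, trace = trace, best_iter = best_epoch, best_loss = best_loss)
}

## ---- unified training surface ---------------------------------------------

#' Train one classifier family
#'
#' Fits a single model of the requested family on z-scored relative-band
#' predictors. The multinomial logit is fit to convergence; the perceptron and
#' the boosted trees train with early stopping on validation categorical
#' cross-entropy (patience in epochs/rounds) unless a fixed iteration budget
#' `n_iter` is supplied, in which case no early stopping is used.
#'
#' @param family Family code or alias (see [lts_default_grid()]).
#' @param hyperparams Named list of family hyperparameters; `NULL` uses the
#'   tuned defaults from [lts_tuned_hyperparams()].
#' @param train Training data.frame with `z_*` predictors and `trophic_state`.
#' @param validation Validation data.frame (required for early stopping).
#' @param patience Early-stopping patience in epochs/boosting rounds.
#' @param seed Integer seed.
#' @param n_iter Optional fixed epoch/round budget (disables early stopping;
#'   ignored by the multinomial logit).
#' @param max_iter Cap on epochs/rounds when early stopping.
#' @return An object of class `"lts_model"` with elements `family`,
#'   `hyperparams`, `fit`, `classes`, `best_iter` and `trace` (validation loss
#'   per epoch/round where applicable).
#' @export
train_model <- function(family, hyperparams = NULL, train, validation = NULL,
                        patience = 20L, seed = 1L, n_iter = NULL,
                        max_iter = 300L) {
  family <- canonical_family(family)
  hp <- utils::modifyList(lts_tuned_hyperparams()[[family]],
                          hyperparams %||% list())
  tr <- model_matrix_xy(train)
  val <- if (!is.null(validation)) model_matrix_xy(validation)
  fit <- NULL; best_iter <- NA_integer_; trace <- NULL
  if (family == "mlr") {
    dat <- data.frame(.y = tr$y, tr$x, check.names = FALSE)
    fit <- suppressWarnings(nnet::multinom(
      stats::as.formula(paste(".y ~", paste(lts_predictors(), collapse = "+"))),
      data = dat, trace = FALSE, maxit = 1000, reltol = 1e-12))
    trace <- fit$deviance
  } else if (family == "mlp") {
    res <- mlp_train(tr$x, as.integer(tr$y), n_class = 3L,
                     hidden = hp$hidden_units, lr = hp$learning_rate,
                     patience = patience, max_epochs = max_iter,
                     n_epochs = n_iter,
                     xval = val$x, yval_idx = if (!is.null(val)) as.integer(val$y),
                     seed = seed)
    fit <- res$weights
    best_iter <- res$best_iter
    trace <- res$trace
  } else {
    if (is.null(n_iter) && is.null(validation)) {
      stop("xgb training with early stopping requires validation data", call. = FALSE)
    }
    params <- list(objective = "multi:softprob", num_class = 3L,
                   max_depth = hp$max_depth, eta = hp$step_size,
                   subsample = hp$subsample, colsample_bytree = hp$colsample,
                   min_child_weight = hp$min_child_weight,
                   nthread = 1L, seed = seed)
    dtr <- xgboost::xgb.DMatrix(tr$x, label = as.integer(tr$y) - 1L)
    if (is.null(n_iter)) {
      dva <- xgboost::xgb.DMatrix(val$x, label = as.integer(val$y) - 1L)
      fit <- xgboost::xgb.train(params = params, data = dtr,
                                nrounds = max_iter,
                                evals = list(val = dva),
                                early_stopping_rounds = patience, verbose = 0)
      best_iter <- as.integer(xgboost::xgb.attributes(fit)$best_iteration)
      el <- attributes(fit)$evaluation_log
      trace <- as.numeric(el$val_mlogloss)
    } else {
      fit <- xgboost::xgb.train(params = params, data = dtr,
                                nrounds = n_iter, verbose = 0)
      best_iter <- as.integer(n_iter)
    }
    if (!is.null(trace) && any(!is.finite(trace))) {
      stop("xgb training failure: non-finite validation loss", call. = FALSE)
    }
  }
  structure(list(family = family, hyperparams = hp, fit = fit,
                 classes = lts_classes(), best_iter = best_iter, trace = trace),
            class = "lts_model")
}

#' Class-probability predictions from a fitted family model
#'
#' @param model An `"lts_model"` from [train_model()] or [finalize_model()].
#' @param newdata Data.frame with the `z_*` predictor columns.
#' @return Numeric matrix, one row per input row, columns `lts_classes()`;
#'   rows sum to 1.
#' @export
predict_proba <- function(model, newdata) {
  stopifnot(inherits(model, "lts_model"))
  require_columns(newdata, lts_predictors(), "newdata")
  x <- as.matrix(newdata[, lts_predictors()])
  p <- switch(model$family,
    mlr = {
      probs <- stats::predict(model$fit,
                              newdata = data.frame(x, check.names = FALSE),
                              type = "probs")
      if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L,
                                               dimnames = list(NULL, names(probs)))
      probs[, lts_classes(), drop = FALSE]
    },
    mlp = {
      out <- mlp_forward(model$fit, x)$p
      colnames(out) <- lts_classes()
      out
    },
    xgb = {
      out <- stats::predict(model$fit, xgboost::xgb.DMatrix(x),
                            iterationrange = c(1L, model$best_iter))
      if (is.null(dim(out))) out <- matrix(out, ncol = 3L, byrow = TRUE)
      colnames(out) <- lts_classes()
      out
    })
  unname_rows <- p
  rownames(unname_rows) <- NULL
  unname_rows
}

#' @export
print.lts_model <- function(x, ...) {
  desc <- c(mlr = "multinomial logistic regression",
            mlp = "multilayer perceptron",
            xgb = "gradient boosted trees")[[x$family]]
  cat(sprintf("Trophic-state classifier: %s\n", desc))
  if (length(x$hyperparams)) {
    cat("  hyperparameters:",
        paste(sprintf("%s=%s", names(x$hyperparams), x$hyperparams), collapse = ", "),
        "\n")
  }
  if (!is.na(x$best_iter)) cat(sprintf("  iterations used: %d\n", x$best_iter))
  invisible(x)
}

#' Coarse grid search with a stratified validation split
#'
#' Splits the training table 80:20 stratified by class, trains every unique
#' grid combination with early stopping, and returns the combination with the
#' lowest best validation loss along with the full loss table.
#'
#' @param family Family code (grid search applies to `"mlp"` and `"xgb"`).
#' @param grid Data.frame of hyperparameter combinations; `NULL` uses
#'   [lts_default_grid()]. Duplicate rows are removed before fitting.
#' @param train Training table.
#' @param seed Integer seed for the split and the fits.
#' @param patience Early-stopping patience.
#' @param max_iter Cap on epochs/rounds.
#' @return List with `best` (named hyperparameter list) and `table`
#'   (grid with a `val_loss` column).
#' @export
grid_search <- function(family, grid = NULL, train, seed = 1L, patience = 20L,
                        max_iter = 300L) {
  family <- canonical_family(family)
  grid <- grid %||% lts_default_grid(family)
  if (is.null(grid) || nrow(grid) == 0L) stop("empty hyperparameter grid", call. = FALSE)
  grid <- unique(grid)
  split <- stratified_holdout(train, frac = 0.2, seed = derive_seed(seed, 11))
  losses <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    hp <- as.list(grid[i, , drop = FALSE])
    fit <- train_model(family, hp, split$train, split$validation,
                       patience = patience, seed = derive_seed(seed, 23 + i),
                       max_iter = max_iter)
    losses[i] <- min(fit$trace)
  }
  grid$val_loss <- losses
  best <- as.list(grid[which.min(losses), setdiff(names(grid), "val_loss"),
                       drop = FALSE])
  list(best = best, table = grid)
}
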