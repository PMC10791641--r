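# Evaluation and diagnostic battery: confusion/accuracy metrics, one-vs-rest
# ROC AUC, exact Shapley attribution, Type II ANOVA on lake properties,
# NCP-position misclassification profiles, and group-wise state proportions.

#' Confusion matrix and accuracy metrics
#'
#' Builds the reference-by-predicted confusion matrix and derives overall
#' accuracy (trace over total), one-vs-rest true positive rate (recall) and
#' true negative rate (specificity) per class, per-class balanced accuracy
#' ((TPR + TNR) / 2) and the unweighted macro balanced accuracy.
#'
#' @param truth,predicted Character/factor vectors over a shared class
#'   vocabulary.
#' @param classes Class vocabulary (default `lts_classes()`).
#' @return List with `confusion` (rows = reference), `overall_accuracy`,
#'   `per_class` (data.frame of tpr, tnr, balanced_accuracy) and
#'   `balanced_accuracy_macro`.
#' @export
confusion_and_accuracy <- function(truth, predicted, classes = lts_classes()) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) == 0L) stop("empty input", call. = FALSE)
  if (length(truth) != length(predicted)) stop("length mismatch", call. = FALSE)
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad)) stop(sprintf("labels outside class vocabulary: %s",
                                paste(bad, collapse = ", ")), call. = FALSE)
  cm <- table(factor(truth, classes), factor(predicted, classes))
  dimnames(cm) <- list(reference = classes, predicted = classes)
  total <- sum(cm)
  per <- lapply(classes, function(cc) {
    tp <- cm[cc, cc]
    fn <- sum(cm[cc, ]) - tp
    fp <- sum(cm[, cc]) - tp
    tn <- total - tp - fn - fp
    tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    data.frame(class = cc, tpr = tpr, tnr = tnr,
               balanced_accuracy = (tpr + tnr) / 2)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  list(confusion = cm,
       overall_accuracy = sum(diag(cm)) / total,
       per_class = per,
       balanced_accuracy_macro = mean(per$balanced_accuracy))
}

# midrank one-vs-rest AUC for a single class
auc_midrank <- function(pos, score) {
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest ROC AUC
#'
#' Per-class area under the ROC curve computed with the rank (Mann-Whitney)
#' statistic using midranks for ties, plus the unweighted macro average over
#' classes. A class with no positive or no negative example gets `NA`.
#'
#' @param truth Character/factor vector of reference labels.
#' @param probs Numeric matrix of class probabilities (or scores) with class
#'   column names.
#' @return List with `per_class` (named numeric) and `macro`.
#' @export
roc_auc_ovr <- function(truth, probs) {
  truth <- as.character(truth)
  probs <- as.matrix(probs)
  if (is.null(colnames(probs))) stop("'probs' needs class column names", call. = FALSE)
  per <- vapply(colnames(probs), function(cc) {
    auc_midrank(truth == cc, probs[, cc])
  }, numeric(1))
  list(per_class = per, macro = mean(per, na.rm = TRUE))
}

#' Exact Shapley attribution for a low-dimensional model
#'
#' Computes exact Shapley values for one prediction by enumerating all
#' 2^p feature coalitions (p = 4 here, so 16). Features absent from a
#' coalition are marginalized interventionally: the model is averaged over
#' background rows with the absent coordinates substituted. Efficiency
#' (sum of attributions = f(x) - E_background[f]) holds by construction.
#'
#' @param f Function taking a numeric matrix (rows = inputs) and returning a
#'   numeric vector of model outputs (e.g. one class probability).
#' @param x Numeric vector, the instance to explain.
#' @param background Numeric matrix of background rows (same column order as
#'   `x`).
#' @return List with `phi` (named attribution per feature), `baseline`
#'   (E_background[f]) and `fx` (model output at `x`).
#' @examples
#' f <- function(m) m %*% c(1, 2, 0, -1)
#' bg <- matrix(rnorm(40), ncol = 4)
#' shap_exact(f, c(1, 1, 1, 1), bg)
#' @export
shap_exact <- function(f, x, background) {
  background <- as.matrix(background)
  if (nrow(background) == 0L) stop("empty background sample", call. = FALSE)
  p <- length(x)
  stopifnot(ncol(background) == p)
  n_coal <- 2^p
  # value of every coalition: mean model output with coalition coords set to x
  vals <- numeric(n_coal)
  members <- vector("list", n_coal)
  for (s in seq_len(n_coal) - 1L) {
    mem <- which(bitwAnd(s, 2^(seq_len(p) - 1L)) > 0L)
    members[[s + 1L]] <- mem
    m <- background
    if (length(mem)) m[, mem] <- matrix(x[mem], nrow(background), length(mem),
                                        byrow = TRUE)
    vals[s + 1L] <- mean(f(m))
  }
  fact <- factorial(0:p)
  phi <- numeric(p)
  for (i in seq_len(p)) {
    for (s in seq_len(n_coal) - 1L) {
      if (bitwAnd(s, 2^(i - 1L)) > 0L) next
      sz <- length(members[[s + 1L]])
      wt <- fact[sz + 1L] * fact[p - sz] / fact[p + 1L]
      phi[i] <- phi[i] + wt * (vals[s + 2^(i - 1L) + 1L] - vals[s + 1L])
    }
  }
  names(phi) <- colnames(background) %||% paste0("x", seq_len(p))
  list(phi = phi, baseline = vals[1L], fx = vals[n_coal])
}

#' Shapley attribution table for a fitted trophic-state model
#'
#' Runs [shap_exact()] for each requested row and each class of an
#' `"lts_model"`, using a seeded background subsample of the training table.
#'
#' @param model An `"lts_model"`.
#' @param table Data.frame with the `z_*` predictors (rows to explain).
#' @param background Background data.frame; defaults to `table`.
#' @param n_background Maximum background rows (seeded subsample).
#' @param classes Classes to attribute (default all three).
#' @param seed Seed for the background subsample.
#' @return Data.frame with `row`, `class`, `phi_red`, `phi_green`, `phi_blue`,
#'   `phi_nir`, `baseline`, `fx`.
#' @export
shap_values <- function(model, table, background = table, n_background = 200L,
                        classes = lts_classes(), seed = 1L) {
  stopifnot(inherits(model, "lts_model"))
  require_columns(table, lts_predictors(), "table")
  bg <- as.matrix(background[, lts_predictors()])
  if (nrow(bg) > n_background) {
    set.seed(seed)
    bg <- bg[sample.int(nrow(bg), n_background), , drop = FALSE]
  }
  xs <- as.matrix(table[, lts_predictors()])
  out <- vector("list", nrow(xs) * length(classes))
  kk <- 0L
  for (cc in classes) {
    f <- function(m) {
      colnames(m) <- lts_predictors()
      predict_proba(model, as.data.frame(m))[, cc]
    }
    for (r in seq_len(nrow(xs))) {
      sv <- shap_exact(f, xs[r, ], bg)
      kk <- kk + 1L
      out[[kk]] <- data.frame(row = r, class = cc,
                              phi_red = sv$phi[[1L]], phi_green = sv$phi[[2L]],
                              phi_blue = sv$phi[[3L]], phi_nir = sv$phi[[4L]],
                              baseline = sv$baseline, fx = sv$fx,
                              stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize Shapley attributions
#'
#' Per class, ranks features by mean absolute attribution; per feature and
#' class, reports the Spearman rank correlation between the feature's value
#' and its attribution (the sign-vs-value association).
#'
#' @param shap Data.frame from [shap_values()] (needs `row`, `class`,
#'   `phi_*` columns).
#' @param features Data.frame with the `z_*` predictor columns, indexed by
#'   `shap$row`.
#' @return List with `importance` (data.frame class, feature, mean_abs_phi,
#'   rank) and `association` (data.frame class, feature, spearman_rho).
#' @export
shap_summary <- function(shap, features) {
  require_columns(shap, c("row", "class", paste0("phi_", lts_bands())), "shap")
  require_columns(features, lts_predictors(), "features")
  imp <- list(); assoc <- list()
  for (cc in unique(shap$class)) {
    sub <- shap[shap$class == cc, , drop = FALSE]
    mabs <- vapply(lts_bands(), function(b) mean(abs(sub[[paste0("phi_", b)]])),
                   numeric(1))
    imp[[cc]] <- data.frame(class = cc, feature = paste0("z_", lts_bands()),
                            mean_abs_phi = unname(mabs),
                            rank = rank(-mabs, ties.method = "first"))
    rho <- vapply(lts_bands(), function(b) {
      phi <- sub[[paste0("phi_", b)]]
      val <- features[[paste0("z_", b)]][sub$row]
      if (stats::sd(phi) == 0 || stats::sd(val) == 0) return(NA_real_)
      stats::cor(val, phi, method = "spearman")
    }, numeric(1))
    assoc[[cc]] <- data.frame(class = cc, feature = paste0("z_", lts_bands()),
                              spearman_rho = unname(rho))
  }
  list(importance = do.call(rbind, c(imp, make.row.names = FALSE)),
       association = do.call(rbind, c(assoc, make.row.names = FALSE)))
}

#' Type II sum-of-squares ANOVA on a lake property
#'
#' Fits the additive (no-interaction) linear model of a (optionally
#' log-transformed) response on dummy-coded factors and reports each factor's
#' Type II sum of squares (the residual-sum-of-squares increase when that
#' factor is dropped from the full additive model), F statistic and unadjusted
#' p value. Type II is appropriate for the unbalanced designs that arise when
#' crossing model family, correctness and trophic state.
#'
#' @param data Data.frame holding response and factors.
#' @param response Name of the response column (positive when
#'   `log_transform`).
#' @param factors Character vector of factor column names.
#' @param log_transform Natural-log transform the response (default `TRUE`);
#'   non-positive responses are an error, not offset.
#' @return Data.frame of class `"lts_anova"`: one row per factor plus a
#'   `Residuals` row, with `sum_sq`, `df`, `F_value`, `p_value`.
#' @export
anova_type2 <- function(data, response, factors, log_transform = TRUE) {
  require_columns(data, c(response, factors), "data")
  y <- data[[response]]
  check_numeric_finite(y, response)
  if (log_transform) {
    if (any(y <= 0)) stop(sprintf("log transform requires strictly positive '%s'",
                                  response), call. = FALSE)
    y <- log(y)
  }
  fd <- data.frame(.y = y)
  for (f in factors) {
    fv <- factor(data[[f]])
    if (nlevels(droplevels(fv)) < 2L) {
      stop(sprintf("factor '%s' has fewer than 2 observed levels", f), call. = FALSE)
    }
    fd[[f]] <- droplevels(fv)
  }
  full <- stats::lm(stats::as.formula(paste(".y ~", paste(factors, collapse = "+"))),
                    data = fd)
  if (anyNA(stats::coef(full))) {
    aliased <- names(which(is.na(stats::coef(full))))
    stop(sprintf("rank-deficient design; aliased terms: %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  a2 <- car::Anova(full, type = 2)
  out <- data.frame(term = rownames(a2), sum_sq = a2[["Sum Sq"]],
                    df = as.integer(a2[["Df"]]), F_value = a2[["F value"]],
                    p_value = a2[["Pr(>F)"]], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("lts_anova", "data.frame")
  out
}

#' NCP-position misclassification profile
#'
#' Summarizes where correctly and incorrectly classified lake-years sit on the
#' Nutrient-Color Paradigm axes: per correctness stratum, the median and range
#' of total phosphorus and true color and the median absolute distance to each
#' threshold, plus the fraction of each stratum falling inside configurable
#' boundary bands around the thresholds.
#'
#' @param data Data.frame with `tp_ugL`, `color_pcu` and logical/character
#'   `correct` flag.
#' @param thresholds An [ncp_thresholds()] object.
#' @param tp_band,color_band Length-2 boundary bands (defaults 15-45 ug/L and
#'   11-29 PCU).
#' @return List with `summary` (one row per correctness stratum) and
#'   `band_fraction` (fraction of each stratum inside both-axis boundary
#'   bands on either axis).
#' @export
ncp_misclassification_profile <- function(data, thresholds = ncp_thresholds(),
                                          tp_band = c(15, 45),
                                          color_band = c(11, 29)) {
  require_columns(data, c("tp_ugL", "color_pcu", "correct"), "data")
  if (nrow(data) == 0L) stop("empty input", call. = FALSE)
  correct <- as.logical(data$correct)
  strata <- list(correct = correct, misclassified = !correct)
  rows <- list(); band <- list()
  for (nm in names(strata)) {
    d <- data[strata[[nm]], , drop = FALSE]
    if (nrow(d) == 0L) next
    rows[[nm]] <- data.frame(
      stratum = nm, n = nrow(d),
      tp_median = stats::median(d$tp_ugL),
      tp_min = min(d$tp_ugL), tp_max = max(d$tp_ugL),
      color_median = stats::median(d$color_pcu),
      color_min = min(d$color_pcu), color_max = max(d$color_pcu),
      tp_dist_median = stats::median(abs(d$tp_ugL - thresholds$tp_thresh)),
      color_dist_median = stats::median(abs(d$color_pcu - thresholds$color_thresh)))
    in_band <- (d$tp_ugL >= tp_band[1] & d$tp_ugL <= tp_band[2]) |
      (d$color_pcu >= color_band[1] & d$color_pcu <= color_band[2])
    band[[nm]] <- data.frame(stratum = nm, frac_near_boundary = mean(in_band))
  }
  list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
       band_fraction = do.call(rbind, c(band, make.row.names = FALSE)))
}

#' Group-wise trophic-state proportions
#'
#' Compares predicted and reference trophic-state composition within groups
#' (ecoregion stand-ins): per (group, year, state) the proportion of lakes in
#' that state from each source and their signed and absolute differences, and
#' per state the mean and sd of the signed differences, with and without a
#' minimum-lake-count filter on groups.
#'
#' @param predicted,reference Data.frames with `group`, `year`, `state`
#'   columns (one row per lake-year).
#' @param min_lakes Minimum lakes per (group, year) for the filtered summary.
#' @param classes State vocabulary.
#' @return List with `table` (per group/year/state proportions and
#'   differences), `by_state` and `by_state_filtered` (mean and sd of signed
#'   differences per state).
#' @export
group_proportions <- function(predicted, reference, min_lakes = 10L,
                              classes = lts_classes()) {
  for (nm in list(list(predicted, "predicted"), list(reference, "reference"))) {
    require_columns(nm[[1]], c("group", "year", "state"), nm[[2]])
  }
  prop_table <- function(df) {
    key <- paste(df$group, df$year, sep = "\r")
    out <- list()
    for (k in unique(key)) {
      d <- df[key == k, , drop = FALSE]
      counts <- table(factor(d$state, classes))
      out[[k]] <- data.frame(group = d$group[1L], year = d$year[1L],
                             state = classes,
                             prop = as.numeric(counts) / nrow(d),
                             n = nrow(d), stringsAsFactors = FALSE)
    }
    do.call(rbind, c(out, make.row.names = FALSE))
  }
  p <- prop_table(predicted); r <- prop_table(reference)
  m <- merge(p, r, by = c("group", "year", "state"),
             suffixes = c("_pred", "_ref"))
  m$diff <- m$prop_pred - m$prop_ref
  m$abs_diff <- abs(m$diff)
  by_state <- function(d) {
    out <- lapply(classes, function(cc) {
      dd <- d[d$state == cc, , drop = FALSE]
      data.frame(state = cc, mean_diff = mean(dd$diff), sd_diff = stats::sd(dd$diff),
                 mean_abs_diff = mean(dd$abs_diff), n_groups = nrow(dd))
    })
    do.call(rbind, c(out, make.row.names = FALSE))
  }
  filt <- m[m$n_pred >= min_lakes & m$n_ref >= min_lakes, , drop = FALSE]
  list(table = m, by_state = by_state(m),
       by_state_filtered = if (nrow(filt)) by_state(filt) else NULL)
}
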