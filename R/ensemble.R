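# Ensemble averaging of the three models' class probabilities and the
# published-schema output writers.

ENSEMBLE_COLUMNS <- c("Hylak_id", "year", "categorical_ts",
                      "mean_prob_dys", "mean_prob_eumixo", "mean_prob_oligo",
                      "var_prob_dys", "var_prob_eumixo", "var_prob_oligo")

INDIVIDUAL_COLUMNS <- c("Hylak_id", "year",
                        "prob_dys_mlr", "prob_eumixo_mlr", "prob_oligo_mlr",
                        "prob_dys_mlp", "prob_eumixo_mlp", "prob_oligo_mlp",
                        "prob_dys_xgb", "prob_eumixo_xgb", "prob_oligo_xgb")

#' Ensemble the three models' probabilities
#'
#' For each lake-year and class, averages the three models' probabilities and
#' takes their sample variance (divisor n - 1 = 2). The categorical call is
#' the class with the highest mean probability; exact ties are broken by the
#' fixed precedence eu/mixo > oligo > dys.
#'
#' @param individual Data.frame from [predict_all()] with the nine per-model
#'   probability columns keyed by (`Hylak_id`, `year`).
#' @return Data.frame with the published ensemble columns: `Hylak_id`, `year`,
#'   `categorical_ts`, `mean_prob_*`, `var_prob_*`.
#' @export
ensemble_predictions <- function(individual) {
  require_columns(individual, INDIVIDUAL_COLUMNS, "individual predictions")
  out <- data.frame(Hylak_id = individual$Hylak_id, year = individual$year)
  suffixes <- c("dys", "eumixo", "oligo")
  means <- matrix(NA_real_, nrow(individual), 3L,
                  dimnames = list(NULL, c("dys", "eu/mixo", "oligo")))
  for (i in seq_along(suffixes)) {
    cols <- sprintf("prob_%s_%s", suffixes[i], c("mlr", "mlp", "xgb"))
    m <- as.matrix(individual[, cols])
    mu <- rowMeans(m)
    va <- rowSums((m - mu)^2) / (ncol(m) - 1L)
    out[[paste0("mean_prob_", suffixes[i])]] <- mu
    out[[paste0("var_prob_", suffixes[i])]] <- va
    means[, i] <- mu
  }
  out$categorical_ts <- argmax_with_precedence(means, c("eu/mixo", "oligo", "dys"))
  out[, ENSEMBLE_COLUMNS]
}

#' Write the published prediction tables
#'
#' Writes `ensemble_predictions.csv` and `individual_predictions.csv` with the
#' published column names and order (comma-separated, UTF-8, header row, no
#' quoting). The (`Hylak_id`, `year`) key must be unique in both tables and
#' join 1:1 between them.
#'
#' @param ensemble Data.frame from [ensemble_predictions()].
#' @param individual Data.frame from [predict_all()].
#' @param dir Output directory (created if missing).
#' @return Invisible character vector of the two file paths.
#' @export
write_lts_outputs <- function(ensemble, individual, dir) {
  require_columns(ensemble, ENSEMBLE_COLUMNS, "ensemble")
  require_columns(individual, INDIVIDUAL_COLUMNS, "individual")
  ek <- paste(ensemble$Hylak_id, ensemble$year)
  ik <- paste(individual$Hylak_id, individual$year)
  if (anyDuplicated(ek) || anyDuplicated(ik)) {
    stop("duplicate (Hylak_id, year) key in prediction table", call. = FALSE)
  }
  if (!setequal(ek, ik)) {
    stop("(Hylak_id, year) keys do not join 1:1 between the two tables",
         call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(file.path(dir, "ensemble_predictions.csv"),
             file.path(dir, "individual_predictions.csv"))
  utils::write.csv(ensemble[, ENSEMBLE_COLUMNS], paths[1L],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(individual[, INDIVIDUAL_COLUMNS], paths[2L],
                   row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read back published prediction tables
#'
#' @param dir Directory holding the two CSV files.
#' @return List with `ensemble` and `individual` data.frames.
#' @export
read_lts_outputs <- function(dir) {
  list(ensemble = utils::read.csv(file.path(dir, "ensemble_predictions.csv"),
                                  check.names = FALSE),
       individual = utils::read.csv(file.path(dir, "individual_predictions.csv"),
                                    check.names = FALSE))
}
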