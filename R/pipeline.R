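# Orchestrated simulate -> aggregate -> train -> predict -> qc runs with a
# JSON manifest recording seeds, hashes and the row-count ledger.

LTS_STAGES <- c("simulate", "aggregate", "train", "predict", "qc")

#' Assemble a pipeline configuration
#'
#' Builds (and lightly validates) the configuration for [lts_run()]. Can also
#' be supplied as a YAML file path to `lts_run()` with the same field names.
#' One global seed derives per-stage seeds by fixed offsets unless a stage
#' seed is given explicitly.
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Global integer seed.
#' @param sim Named list of [lts_sim_config()] arguments (used by the
#'   simulate stage).
#' @param campaigns In situ campaign years.
#' @param tp_thresh,color_thresh NCP thresholds.
#' @param summer_months Months defining summer.
#' @param families Model families to fit.
#' @param k Spatial folds.
#' @param n_shap_rows Rows per class explained in the qc stage.
#' @param min_area_km2 Minimum lake area for training lakes.
#' @return List of class `"lts_pipeline_config"`.
#' @export
lts_pipeline_config <- function(out_dir, seed = 1L, sim = list(),
                                campaigns = c(2007L, 2012L, 2017L),
                                tp_thresh = 30, color_thresh = 20,
                                summer_months = 6:8,
                                families = c("mlr", "mlp", "xgb"), k = 5L,
                                n_shap_rows = 10L, min_area_km2 = 0.1) {
  structure(list(out_dir = out_dir, seed = seed, sim = sim,
                 campaigns = as.integer(campaigns),
                 tp_thresh = tp_thresh, color_thresh = color_thresh,
                 summer_months = as.integer(summer_months),
                 families = families, k = as.integer(k),
                 n_shap_rows = as.integer(n_shap_rows),
                 min_area_km2 = min_area_km2),
            class = "lts_pipeline_config")
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "lts_pipeline_config")) {
    config <- do.call(lts_pipeline_config, config)
  }
  config
}

require_artifact <- function(path, producing_stage) {
  if (!file.exists(path)) {
    stop(sprintf("missing upstream artifact '%s'; run stage '%s' first",
                 basename(path), producing_stage), call. = FALSE)
  }
  path
}

file_hashes <- function(paths) {
  h <- tools::md5sum(paths[file.exists(paths)])
  stats::setNames(as.vector(h), basename(names(h)))
}

#' Run the trophic-state pipeline
#'
#' Executes the requested stages in order: `simulate` writes the synthetic
#' lake registry, in situ and overpass tables; `aggregate` turns them into
#' per lake-year features, the labeled training table and the scaler;
#' `train` fits the cross-validated ensemble and writes pooled CV
#' predictions; `predict` applies the final models to all lake-years and
#' writes the two published-schema tables; `qc` writes metrics, confusion
#' matrices, Shapley values, ANOVA tables, the NCP misclassification profile
#' and group proportions. A JSON manifest records configuration and file
#' hashes, per-stage seeds, row counts and dropped-row tallies.
#'
#' @param config An [lts_pipeline_config()], a plain named list of its
#'   arguments, or a YAML file path.
#' @param stages Subset of `c("simulate", "aggregate", "train", "predict",
#'   "qc")`.
#' @return Invisible manifest list (also written to `manifest.json`).
#' @export
lts_run <- function(config, stages = LTS_STAGES) {
  config <- read_pipeline_config(config)
  stages <- match.arg(stages, LTS_STAGES, several.ok = TRUE)
  stages <- LTS_STAGES[LTS_STAGES %in% stages]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  manifest_path <- out("manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else list()
  cfg_plain <- unclass(config)
  manifest$config <- cfg_plain
  manifest$config_hash <- config_hash(cfg_plain)
  manifest$package_version <- as.character(utils::packageVersion("trophicstate"))
  manifest$stages <- manifest$stages %||% list()
  thresholds <- ncp_thresholds(config$tp_thresh, config$color_thresh)

  for (stage in stages) {
    stage_seed <- derive_seed(config$seed, match(stage, LTS_STAGES))
    entry <- list(seed = stage_seed)
    if (stage == "simulate") {
      sim_cfg <- do.call(lts_sim_config, utils::modifyList(
        list(seed = stage_seed), config$sim))
      sim <- simulate_lts_dataset(sim_cfg, config$campaigns, dir = config$out_dir)
      entry$rows <- list(lakes = nrow(sim$lakes), insitu = nrow(sim$insitu),
                         overpasses = nrow(sim$overpasses))
      entry$files <- file_hashes(out(c("lakes.csv", "insitu.csv", "overpasses.csv")))
    } else if (stage == "aggregate") {
      insitu <- utils::read.csv(require_artifact(out("insitu.csv"), "simulate"))
      overpasses <- utils::read.csv(require_artifact(out("overpasses.csv"), "simulate"))
      lakes <- utils::read.csv(require_artifact(out("lakes.csv"), "simulate"))
      features <- aggregate_overpasses(overpasses, config$summer_months)
      tab <- build_training_table(insitu, features, lakes = lakes,
                                  thresholds = thresholds,
                                  min_area_km2 = config$min_area_km2)
      scaler <- attr(tab, "scaler")
      trans <- transition_summary(insitu, thresholds)
      utils::write.csv(features, out("features.csv"), row.names = FALSE, quote = FALSE)
      utils::write.csv(tab, out("training_table.csv"), row.names = FALSE, quote = FALSE)
      utils::write.csv(data.frame(column = scaler$cols, mean = unname(scaler$mean),
                                  sd = unname(scaler$sd)),
                       out("scaler.csv"), row.names = FALSE, quote = FALSE)
      n_lake_years <- nrow(features) + attr(features, "n_no_summer") +
        attr(features, "n_degenerate")
      entry$rows <- list(lake_years = n_lake_years, features = nrow(features),
                         training = nrow(tab))
      entry$dropped <- c(list(no_summer = attr(features, "n_no_summer"),
                              degenerate_spectrum = attr(features, "n_degenerate")),
                         as.list(attr(tab, "dropped")))
      entry$transitions <- list(n_multi = trans$n_multi,
                                frac_stable = trans$frac_stable)
      entry$files <- file_hashes(out(c("features.csv", "training_table.csv",
                                       "scaler.csv")))
    } else if (stage == "train") {
      tab <- read_training_table(require_artifact(out("training_table.csv"),
                                                  "aggregate"))
      scaler <- read_scaler(require_artifact(out("scaler.csv"), "aggregate"))
      fit <- lts(tab, families = config$families, k = config$k,
                 seed = stage_seed, scaler = scaler)
      cvp <- do.call(rbind, lapply(fit$cv, `[[`, "predictions"))
      rownames(cvp) <- NULL
      utils::write.csv(cvp, out("cv_predictions.csv"), row.names = FALSE, quote = FALSE)
      saveRDS(fit, out("lts_fit.rds"))
      entry$rows <- list(cv_predictions = nrow(cvp))
      entry$metrics <- lapply(fit$cv, function(cv) {
        list(overall_accuracy = cv$metrics$overall_accuracy,
             balanced_accuracy_macro = cv$metrics$balanced_accuracy_macro,
             macro_auc = cv$metrics$auc$macro)
      })
      entry$files <- file_hashes(out("cv_predictions.csv"))
    } else if (stage == "predict") {
      fit <- readRDS(require_artifact(out("lts_fit.rds"), "train"))
      features <- utils::read.csv(require_artifact(out("features.csv"), "aggregate"))
      individual <- predict.lts(fit, features, type = "individual")
      ens <- ensemble_predictions(individual)
      write_lts_outputs(ens, individual, config$out_dir)
      entry$rows <- list(features = nrow(features), predicted = nrow(individual))
      entry$dropped <- list(missing_features = attr(individual, "n_skipped"))
      entry$files <- file_hashes(out(c("ensemble_predictions.csv",
                                       "individual_predictions.csv")))
    } else if (stage == "qc") {
      cvp <- utils::read.csv(require_artifact(out("cv_predictions.csv"), "train"),
                             check.names = FALSE)
      insitu <- utils::read.csv(require_artifact(out("insitu.csv"), "simulate"))
      lakes <- utils::read.csv(require_artifact(out("lakes.csv"), "simulate"))
      tab <- read_training_table(require_artifact(out("training_table.csv"),
                                                  "aggregate"))
      fit <- readRDS(require_artifact(out("lts_fit.rds"), "train"))
      files <- run_qc_stage(cvp, insitu, lakes, tab, fit, config, thresholds,
                            stage_seed)
      entry$files <- file_hashes(files)
    }
    manifest$stages[[stage]] <- entry
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  invisible(manifest)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(cfg[order(names(cfg))]), collapse = ""), tmp)
  as.vector(tools::md5sum(tmp))
}

read_training_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  tab$trophic_state <- factor(tab$trophic_state, levels = lts_classes())
  tab
}

read_scaler <- function(path) {
  s <- utils::read.csv(path)
  structure(list(cols = s$column, mean = stats::setNames(s$mean, s$column),
                 sd = stats::setNames(s$sd, s$column)), class = "lts_scaler")
}

run_qc_stage <- function(cvp, insitu, lakes, tab, fit, config, thresholds,
                         seed) {
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  # per-family metrics and confusion matrices
  metric_rows <- list()
  for (fam in unique(cvp$family)) {
    sub <- cvp[cvp$family == fam, , drop = FALSE]
    met <- confusion_and_accuracy(sub$true_state, sub$pred_state)
    auc <- roc_auc_ovr(sub$true_state,
                       as.matrix(stats::setNames(
                         sub[, c("prob_dys", "prob_eumixo", "prob_oligo")],
                         lts_classes())))
    metric_rows[[fam]] <- data.frame(
      family = fam, overall_accuracy = met$overall_accuracy,
      balanced_accuracy_macro = met$balanced_accuracy_macro,
      macro_auc = auc$macro,
      dys_balanced_accuracy =
        met$per_class$balanced_accuracy[met$per_class$class == "dys"])
    cpath <- out(sprintf("confusion_%s.csv", sub("/", "", fam)))
    utils::write.csv(as.data.frame.matrix(met$confusion), cpath, quote = FALSE)
    files <- c(files, cpath)
  }
  mpath <- out("metrics.csv")
  utils::write.csv(do.call(rbind, c(metric_rows, make.row.names = FALSE)),
                   mpath, row.names = FALSE, quote = FALSE)
  files <- c(files, mpath)

  # NCP-position profile: join CV predictions back to averaged chemistry
  chem <- average_duplicates(insitu)
  joined <- merge(cvp, chem[, c("lake_id", "year", "tp_ugL", "color_pcu")],
                  by = c("lake_id", "year"))
  joined$correct <- joined$true_state == joined$pred_state
  prof <- ncp_misclassification_profile(joined, thresholds)
  ppath <- out("ncp_profile.csv")
  utils::write.csv(merge(prof$summary, prof$band_fraction, by = "stratum"),
                   ppath, row.names = FALSE, quote = FALSE)
  files <- c(files, ppath)

  # Type II ANOVA of each positive lake property on family/correctness/state
  ajoined <- merge(joined, lakes[, setdiff(names(lakes), "true_state")],
                   by = "lake_id")
  for (prop in c("area_km2", "mean_depth_m", "max_depth_m",
                 "shoreline_development")) {
    ad <- data.frame(y = ajoined[[prop]], model_family = ajoined$family,
                     correct = ajoined$correct,
                     trophic_state = ajoined$true_state)
    tabout <- tryCatch(
      anova_type2(ad, "y", c("model_family", "correct", "trophic_state")),
      error = function(e) NULL)
    if (is.null(tabout)) next
    apath <- out(sprintf("anova_%s.csv", prop))
    utils::write.csv(tabout, apath, row.names = FALSE, quote = FALSE)
    files <- c(files, apath)
  }

  # group-wise proportions: ensemble categorical vs in situ labels
  ens_path <- file.path(config$out_dir, "ensemble_predictions.csv")
  if (file.exists(ens_path)) {
    ens <- utils::read.csv(ens_path, check.names = FALSE)
    glab <- lakes[, c("lake_id", "group_label")]
    pred <- merge(ens, glab, by.x = "Hylak_id", by.y = "lake_id")
    pred <- data.frame(group = pred$group_label, year = pred$year,
                       state = pred$categorical_ts)
    chem$state <- merge_eumixo(classify_ncp(chem$tp_ugL, chem$color_pcu,
                                            thresholds))
    ref <- merge(chem, glab, by = "lake_id")
    ref <- data.frame(group = ref$group_label, year = ref$year, state = ref$state)
    pred <- pred[pred$year %in% unique(ref$year), , drop = FALSE]
    gp <- group_proportions(pred, ref)
    gpath <- out("group_proportions.csv")
    utils::write.csv(gp$table, gpath, row.names = FALSE, quote = FALSE)
    files <- c(files, gpath)
  }

  # exact Shapley values for a seeded per-class sample of training rows
  set.seed(seed)
  rows <- unlist(lapply(lts_classes(), function(cc) {
    idx <- which(as.character(tab$trophic_state) == cc)
    if (length(idx)) sample(idx, min(config$n_shap_rows, length(idx)))
  }))
  sh <- lapply(fit$families, function(fam) {
    s <- shap_values(fit$models[[fam]], tab[rows, , drop = FALSE],
                     background = tab, seed = seed)
    s$family <- fam
    s$lake_id <- tab$lake_id[rows][s$row]
    s$year <- tab$year[rows][s$row]
    s
  })
  spath <- out("shap_values.csv")
  utils::write.csv(do.call(rbind, c(sh, make.row.names = FALSE)), spath,
                   row.names = FALSE, quote = FALSE)
  c(files, spath)
}
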