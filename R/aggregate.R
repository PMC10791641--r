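# From in situ chemistry to NCP trophic labels, and from overpass records to
# per lake-year z-scored relative-band feature vectors.

#' Nutrient-Color Paradigm thresholds
#'
#' Total phosphorus and true color cutoffs separating the four NCP quadrants.
#' Defaults are the established 30 ug/L phosphorus and 20 PCU color cutoffs.
#'
#' @param tp_thresh Total phosphorus threshold, ug/L.
#' @param color_thresh True color threshold, PCU.
#' @return List of class `"ncp_thresholds"`.
#' @export
ncp_thresholds <- function(tp_thresh = 30, color_thresh = 20) {
  if (!is.numeric(tp_thresh) || tp_thresh <= 0) {
    stop("'tp_thresh' must be positive", call. = FALSE)
  }
  if (!is.numeric(color_thresh) || color_thresh <= 0) {
    stop("'color_thresh' must be positive", call. = FALSE)
  }
  structure(list(tp_thresh = tp_thresh, color_thresh = color_thresh),
            class = "ncp_thresholds")
}

#' Classify a lake visit into an NCP quadrant
#'
#' Assigns one of the four Nutrient-Color Paradigm states from total phosphorus
#' and true color. A lake is "low" on an axis strictly below the threshold and
#' "high" at or above it (the boundary value counts as high, making the rule
#' total and deterministic): (low, low) is oligotrophic, (high, low) eutrophic,
#' (low, high) dystrophic, (high, high) mixotrophic.
#'
#' @param tp Total phosphorus, ug/L (vectorized).
#' @param color True color, PCU (vectorized).
#' @param thresholds An [ncp_thresholds()] object.
#' @return Character vector of four-state labels.
#' @examples
#' classify_ncp(c(10, 50, 10, 50), c(5, 5, 50, 50))
#' @export
classify_ncp <- function(tp, color, thresholds = ncp_thresholds()) {
  check_numeric_finite(tp, "tp")
  check_numeric_finite(color, "color")
  if (any(tp < 0) || any(color < 0)) {
    stop("'tp' and 'color' must be nonnegative", call. = FALSE)
  }
  high_tp <- tp >= thresholds$tp_thresh
  high_color <- color >= thresholds$color_thresh
  out <- character(length(tp))
  out[!high_tp & !high_color] <- "oligotrophic"
  out[high_tp & !high_color] <- "eutrophic"
  out[!high_tp & high_color] <- "dystrophic"
  out[high_tp & high_color] <- "mixotrophic"
  out
}

#' Merge eutrophic and mixotrophic states
#'
#' Maps the four NCP quadrant states to the merged three-state vocabulary used
#' for modeling: eutrophic and mixotrophic collapse to `"eu/mixo"` (their
#' spectral signatures are nearly identical), oligotrophic maps to `"oligo"`
#' and dystrophic to `"dys"`.
#'
#' @param label4 Character vector of four-state labels.
#' @return Character vector over `lts_classes()`.
#' @export
merge_eumixo <- function(label4) {
  map <- c(oligotrophic = "oligo", eutrophic = "eu/mixo",
           dystrophic = "dys", mixotrophic = "eu/mixo")
  bad <- setdiff(unique(label4), names(map))
  if (length(bad)) {
    stop(sprintf("unknown trophic label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  unname(map[label4])
}

#' Average repeated within-campaign visits
#'
#' For lakes sampled more than once within a campaign year, replaces the visits
#' by their unweighted arithmetic mean of total phosphorus and true color; the
#' record keeps the earliest visit date.
#'
#' @param insitu Data.frame with `lake_id`, `date`, `tp_ugL`, `color_pcu`.
#' @return Data.frame with one row per (lake, campaign year).
#' @export
average_duplicates <- function(insitu) {
  require_columns(insitu, c("lake_id", "date", "tp_ugL", "color_pcu"), "insitu")
  if (nrow(insitu) == 0L) stop("empty in situ table", call. = FALSE)
  insitu$date <- as.Date(insitu$date)
  yr <- as.integer(format(insitu$date, "%Y"))
  key <- paste(insitu$lake_id, yr, sep = "\r")
  out <- data.frame(
    lake_id = as.integer(tapply(insitu$lake_id, key, `[`, 1L)),
    year = as.integer(tapply(yr, key, `[`, 1L)),
    date = as.Date(tapply(insitu$date, key, min), origin = "1970-01-01"),
    tp_ugL = as.numeric(tapply(insitu$tp_ugL, key, mean)),
    color_pcu = as.numeric(tapply(insitu$color_pcu, key, mean))
  )
  out <- out[order(out$lake_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Median summer spectrum for one lake-year
#'
#' Filters one lake-year's overpass records to the summer months and returns
#' the per-band medians together with the number of summer images used.
#' Lake-years with no summer record yield `NULL`.
#'
#' @param overpasses Data.frame of overpass records for a single lake-year.
#' @param summer_months Integer months defining summer (default June-August).
#' @return List with `medians` (named length-4 vector) and `n_images`, or
#'   `NULL` when no summer record exists.
#' @export
summer_median_spectrum <- function(overpasses, summer_months = 6:8) {
  require_columns(overpasses, c("date", lts_bands()), "overpasses")
  mo <- as.integer(format(as.Date(overpasses$date), "%m"))
  s <- overpasses[mo %in% summer_months, , drop = FALSE]
  if (nrow(s) == 0L) return(NULL)
  med <- vapply(lts_bands(), function(b) stats::median(s[[b]]), numeric(1))
  list(medians = med, n_images = nrow(s))
}

#' Normalize a median spectrum to relative band fractions
#'
#' Divides each band's median summer reflectance by the sum over the four
#' bands, so the output vector sums to 1.
#'
#' @param medians Named (or band-ordered) nonnegative length-4 vector.
#' @return Named length-4 vector summing to 1.
#' @export
relative_normalize <- function(medians) {
  if (length(medians) != 4L) stop("'medians' must have length 4", call. = FALSE)
  check_numeric_finite(medians, "medians")
  if (any(medians < 0)) stop("'medians' must be nonnegative", call. = FALSE)
  s <- sum(medians)
  if (s <= 0) stop("degenerate spectrum: all four bands are zero", call. = FALSE)
  out <- medians / s
  names(out) <- lts_bands()
  out
}

#' Per lake-year relative-band features from an overpass table
#'
#' Table-level driver: filters to summer months, takes per-band medians within
#' each (lake, year), normalizes them to relative fractions and counts the
#' images used. Lake-years with no summer image, or with an all-zero median
#' spectrum, are dropped; their counts are attached as attributes
#' `"n_no_summer"` and `"n_degenerate"`.
#'
#' @param overpasses Data.frame with `lake_id`, `date` and the four bands.
#' @param summer_months Integer months defining summer.
#' @return Data.frame with `lake_id`, `year`, `rel_red`, `rel_green`,
#'   `rel_blue`, `rel_nir`, `n_images`.
#' @export
aggregate_overpasses <- function(overpasses, summer_months = 6:8) {
  require_columns(overpasses, c("lake_id", "date", lts_bands()), "overpasses")
  overpasses$date <- as.Date(overpasses$date)
  yr <- as.integer(format(overpasses$date, "%Y"))
  mo <- as.integer(format(overpasses$date, "%m"))
  in_summer <- mo %in% summer_months
  all_years <- unique(paste(overpasses$lake_id, yr, sep = "\r"))
  s <- overpasses[in_summer, , drop = FALSE]
  syr <- yr[in_summer]
  if (nrow(s) == 0L) {
    out <- data.frame(lake_id = integer(), year = integer(),
                      rel_red = numeric(), rel_green = numeric(),
                      rel_blue = numeric(), rel_nir = numeric(),
                      n_images = integer())
    attr(out, "n_no_summer") <- length(all_years)
    attr(out, "n_degenerate") <- 0L
    return(out)
  }
  key <- paste(s$lake_id, syr, sep = "\r")
  med <- vapply(lts_bands(), function(b) {
    as.numeric(tapply(s[[b]], key, stats::median))
  }, numeric(length(unique(key))))
  if (is.null(dim(med))) med <- matrix(med, nrow = 1L, dimnames = list(NULL, lts_bands()))
  ids <- do.call(rbind, strsplit(sort(unique(key)), "\r", fixed = TRUE))
  n_img <- as.integer(tapply(syr, key, length))
  sums <- rowSums(med)
  degen <- sums <= 0
  rel <- med / ifelse(sums > 0, sums, 1)
  out <- data.frame(lake_id = as.integer(ids[, 1L]), year = as.integer(ids[, 2L]),
                    rel_red = rel[, "red"], rel_green = rel[, "green"],
                    rel_blue = rel[, "blue"], rel_nir = rel[, "nir"],
                    n_images = n_img)
  out <- out[!degen, , drop = FALSE]
  out <- out[order(out$lake_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_no_summer") <- length(all_years) - length(unique(key))
  attr(out, "n_degenerate") <- sum(degen)
  out
}

#' Fit and apply a per-band z-score scaler
#'
#' `zscore_fit()` estimates per-band means and sample standard deviations from
#' a training table; `zscore_apply()` standardizes a table with those fit-time
#' statistics, adding `z_*` columns. Applying a scaler to its own fit table
#' yields columns with mean 0 and sample sd 1.
#'
#' @param table Data.frame containing the columns in `cols`.
#' @param cols Columns to standardize (default the four relative bands).
#' @return `zscore_fit()`: an object of class `"lts_scaler"`;
#'   `zscore_apply()`: the table with `z_*` columns appended.
#' @export
zscore_fit <- function(table, cols = paste0("rel_", lts_bands())) {
  require_columns(table, cols, "training table")
  if (nrow(table) < 2L) stop("z-scaler fit requires at least 2 rows", call. = FALSE)
  mean_ <- vapply(cols, function(cc) mean(table[[cc]]), numeric(1))
  sd_ <- vapply(cols, function(cc) stats::sd(table[[cc]]), numeric(1))
  zero <- sd_ == 0 | !is.finite(sd_)
  if (any(zero)) {
    stop(sprintf("zero variance in band column(s): %s",
                 paste(cols[zero], collapse = ", ")), call. = FALSE)
  }
  structure(list(cols = cols, mean = mean_, sd = sd_), class = "lts_scaler")
}

#' @rdname zscore_fit
#' @param scaler An `"lts_scaler"` from `zscore_fit()`.
#' @export
zscore_apply <- function(scaler, table) {
  stopifnot(inherits(scaler, "lts_scaler"))
  require_columns(table, scaler$cols, "table")
  for (cc in scaler$cols) {
    zname <- sub("^rel_", "z_", cc)
    if (zname == cc) zname <- paste0("z_", cc)
    table[[zname]] <- (table[[cc]] - scaler$mean[[cc]]) / scaler$sd[[cc]]
  }
  table
}

#' @export
print.lts_scaler <- function(x, ...) {
  cat("Per-band z-score scaler (fit-time statistics)\n")
  print(data.frame(column = x$cols, mean = unname(x$mean), sd = unname(x$sd)),
        row.names = FALSE)
  invisible(x)
}

#' Build the labeled training table
#'
#' Joins labeled in situ lake-campaigns with per lake-year spectral features:
#' duplicates are averaged, NCP labels computed and merged to the three-state
#' vocabulary, lakes smaller than `min_area_km2` dropped when a lake attribute
#' table is supplied, and the result inner-joined to the features on
#' (`lake_id`, `year`). Unless a scaler is supplied, per-band z-scoring
#' statistics are fit on the resulting table and stored in the `"scaler"`
#' attribute for reuse on prediction data.
#'
#' @param insitu In situ table (`lake_id`, `date`, `tp_ugL`, `color_pcu`).
#' @param features Output of [aggregate_overpasses()].
#' @param lakes Optional lake attribute table with `lake_id` and `area_km2`.
#' @param thresholds An [ncp_thresholds()] object.
#' @param min_area_km2 Minimum lake area retained when `lakes` is given
#'   (default 0.1 km2, i.e. 10 ha).
#' @param scaler Optional pre-fit `"lts_scaler"`; fit on this table when `NULL`.
#' @return Data.frame with `lake_id`, `year`, `tp_ugL`, `color_pcu`, the
#'   `rel_*` and `z_*` band columns, `n_images` and factor `trophic_state`;
#'   attributes `"scaler"` and `"dropped"` (named counts).
#' @export
build_training_table <- function(insitu, features, lakes = NULL,
                                 thresholds = ncp_thresholds(),
                                 min_area_km2 = 0.1, scaler = NULL) {
  labeled <- average_duplicates(insitu)
  labeled$trophic_state <- merge_eumixo(
    classify_ncp(labeled$tp_ugL, labeled$color_pcu, thresholds))
  dropped <- c(small_lake = 0L, unmatched_insitu = 0L, unmatched_features = 0L)
  if (!is.null(lakes)) {
    require_columns(lakes, c("lake_id", "area_km2"), "lakes")
    keep <- labeled$lake_id %in% lakes$lake_id[lakes$area_km2 >= min_area_km2]
    dropped[["small_lake"]] <- sum(!keep)
    labeled <- labeled[keep, , drop = FALSE]
  }
  require_columns(features, c("lake_id", "year", paste0("rel_", lts_bands()),
                              "n_images"), "features")
  for (side in list(list(labeled, "insitu"), list(features, "features"))) {
    key <- paste(side[[1]]$lake_id, side[[1]]$year)
    if (anyDuplicated(key)) {
      stop(sprintf("duplicate (lake_id, year) key in %s table: %s",
                   side[[2]], key[duplicated(key)][1L]), call. = FALSE)
    }
  }
  merged <- merge(labeled[, c("lake_id", "year", "tp_ugL", "color_pcu", "trophic_state")],
                  features, by = c("lake_id", "year"))
  if (nrow(merged) == 0L) stop("empty join: no (lake_id, year) overlap between in situ and features",
                               call. = FALSE)
  dropped[["unmatched_insitu"]] <- nrow(labeled) - nrow(merged)
  dropped[["unmatched_features"]] <- nrow(features) - nrow(merged)
  if (is.null(scaler)) scaler <- zscore_fit(merged)
  merged <- zscore_apply(scaler, merged)
  merged$trophic_state <- factor(merged$trophic_state, levels = lts_classes())
  merged <- merged[order(merged$lake_id, merged$year), , drop = FALSE]
  rownames(merged) <- NULL
  attr(merged, "scaler") <- scaler
  attr(merged, "dropped") <- dropped
  merged
}

#' Within-summer trophic-state transition summary
#'
#' For lakes visited at least twice within one campaign year, classifies each
#' visit (NCP rule then eu/mixo merge) and summarizes state stability: the
#' fraction of lake-campaigns keeping one state, the first-to-last visit
#' transition matrix, and per-path proportions among changing lakes and among
#' all multiply-sampled lakes.
#'
#' @param insitu In situ table with repeated visits.
#' @param thresholds An [ncp_thresholds()] object.
#' @return List of class `"lts_transitions"`: `n_multi`, `frac_stable`,
#'   `transition_matrix` (3x3 counts, rows = first visit), `paths`
#'   (data.frame of off-diagonal paths with proportions among changing and
#'   among all multiply-sampled lakes).
#' @export
transition_summary <- function(insitu, thresholds = ncp_thresholds()) {
  require_columns(insitu, c("lake_id", "date", "tp_ugL", "color_pcu"), "insitu")
  insitu$date <- as.Date(insitu$date)
  yr <- as.integer(format(insitu$date, "%Y"))
  key <- paste(insitu$lake_id, yr, sep = "\r")
  multi <- names(which(table(key) >= 2L))
  classes <- lts_classes()
  mat <- matrix(0L, 3L, 3L, dimnames = list(first = classes, last = classes))
  for (k in multi) {
    rows <- insitu[key == k, , drop = FALSE]
    rows <- rows[order(rows$date), , drop = FALSE]
    st <- merge_eumixo(classify_ncp(rows$tp_ugL, rows$color_pcu, thresholds))
    mat[st[1L], st[length(st)]] <- mat[st[1L], st[length(st)]] + 1L
  }
  total <- sum(mat)
  frac_stable <- if (total > 0) sum(diag(mat)) / total else NA_real_
  n_change <- total - sum(diag(mat))
  paths <- expand.grid(from = classes, to = classes, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  paths <- paths[paths$from != paths$to, , drop = FALSE]
  paths$count <- mat[cbind(paths$from, paths$to)]
  paths$frac_of_changing <- if (n_change > 0) paths$count / n_change else NA_real_
  paths$frac_of_all <- if (total > 0) paths$count / total else NA_real_
  rownames(paths) <- NULL
  structure(list(n_multi = total, frac_stable = frac_stable,
                 transition_matrix = mat, paths = paths),
            class = "lts_transitions")
}

#' @export
print.lts_transitions <- function(x, ...) {
  cat(sprintf("Within-summer trophic state transitions (%d multiply-sampled lake-campaigns)\n",
              x$n_multi))
  cat(sprintf("  stable: %.1f%%\n", 100 * x$frac_stable))
  print(x$transition_matrix)
  chg <- x$paths[x$paths$count > 0, , drop = FALSE]
  if (nrow(chg)) {
    cat("Changing-lake paths:\n")
    print(chg, row.names = FALSE)
  }
  invisible(x)
}
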