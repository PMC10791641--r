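# Synthetic data generator: lake registry, in situ chemistry campaigns,
# and per-overpass four-band reflectance records with known ground truth.

#' Simulate a lake registry with known trophic states
#'
#' Draws `n_lakes` lakes with true Nutrient-Color Paradigm quadrant states from
#' the configured class mix, plus morphological and locational attributes
#' (lognormal area and depths, normal elevation, shoreline development >= 1)
#' and a generic group label standing in for an ecoregion.
#'
#' @param config An [lts_sim_config()] object.
#' @return A data.frame with one row per lake: `lake_id`, `true_state`,
#'   `area_km2`, `mean_depth_m`, `max_depth_m`, `elevation_m`,
#'   `shoreline_development`, `group_label`.
#' @examples
#' lakes <- simulate_lakes(lts_sim_config(n_lakes = 20, seed = 1))
#' table(lakes$true_state)
#' @export
simulate_lakes <- function(config) {
  stopifnot(inherits(config, "lts_sim_config"))
  n <- config$n_lakes
  if (n == 0L) {
    return(data.frame(lake_id = integer(), true_state = character(),
                      area_km2 = numeric(), mean_depth_m = numeric(),
                      max_depth_m = numeric(), elevation_m = numeric(),
                      shoreline_development = numeric(), group_label = character(),
                      stringsAsFactors = FALSE))
  }
  set.seed(derive_seed(config$seed, 1))
  true_state <- sample(lts_states4(), n, replace = TRUE, prob = config$class_mix)
  mean_depth <- stats::rlnorm(n, log(5), 0.7)
  depth_ratio <- pmax(exp(stats::rnorm(n, log(2.2), 0.35)), 1)
  data.frame(
    lake_id = seq_len(n),
    true_state = true_state,
    area_km2 = stats::rlnorm(n, log(0.6), 1.0),
    mean_depth_m = mean_depth,
    max_depth_m = mean_depth * depth_ratio,
    elevation_m = stats::rnorm(n, 400, 300),
    shoreline_development = 1 + stats::rlnorm(n, log(0.8), 0.6),
    group_label = sample(paste0("G", seq_len(config$n_groups)), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# destination state for a within-summer transition, conditional on source.
# Changing lakes predominantly move toward eutrophic/mixotrophic; the merged
# eu/mixo class only ever transitions to oligotrophic.
transition_destination <- function(state) {
  switch(state,
    oligotrophic = sample(c("eutrophic", "dystrophic"), 1L, prob = c(0.8, 0.2)),
    dystrophic   = sample(c("eutrophic", "oligotrophic"), 1L, prob = c(0.8, 0.2)),
    eutrophic    = "oligotrophic",
    mixotrophic  = "oligotrophic"
  )
}

draw_chemistry <- function(states, config) {
  tp <- stats::rlnorm(length(states),
                      log(config$tp_median[states]),
                      config$tp_sdlog[states])
  color <- stats::rlnorm(length(states),
                         log(config$color_median[states]),
                         config$color_sdlog[states])
  data.frame(tp_ugL = tp, color_pcu = color)
}

#' Simulate in situ chemistry campaigns
#'
#' One visit per lake per campaign year, with total phosphorus and true color
#' drawn from the lake's true-state lognormal distributions; a configurable
#' fraction of lakes receives a second same-summer visit, and a configurable
#' fraction of those revisited lakes transitions to a neighbouring trophic
#' state before the second visit (its chemistry is then drawn from the
#' transitioned state). Visit dates fall in June-September.
#'
#' @param lakes Registry from [simulate_lakes()].
#' @param campaigns Integer vector of campaign years; must lie within the
#'   configured year range.
#' @param config An [lts_sim_config()] object.
#' @return Data.frame with columns `lake_id`, `date`, `tp_ugL`, `color_pcu`.
#' @export
simulate_insitu <- function(lakes, campaigns, config) {
  stopifnot(inherits(config, "lts_sim_config"))
  if (nrow(lakes) == 0L) stop("'lakes' must be nonempty", call. = FALSE)
  campaigns <- as.integer(campaigns)
  bad <- setdiff(campaigns, config$years)
  if (length(bad)) {
    stop(sprintf("unknown campaign year(s): %s (outside configured years %d-%d)",
                 paste(bad, collapse = ", "), min(config$years), max(config$years)),
         call. = FALSE)
  }
  set.seed(derive_seed(config$seed, 2))
  n <- nrow(lakes)
  out <- vector("list", length(campaigns))
  for (ci in seq_along(campaigns)) {
    yr <- campaigns[ci]
    season_start <- as.Date(sprintf("%d-06-01", yr))
    # first visit for every lake, June 1 - Sept 30 (122 days)
    d1 <- season_start + sample.int(122L, n, replace = TRUE) - 1L
    chem1 <- draw_chemistry(lakes$true_state, config)
    first <- data.frame(lake_id = lakes$lake_id, date = d1, chem1)
    n_dup <- round(config$duplicate_frac * n)
    if (n_dup > 0L) {
      dup_idx <- sample.int(n, n_dup)
      dup_states <- lakes$true_state[dup_idx]
      moved <- stats::runif(n_dup) < config$transition_prob
      for (j in which(moved)) {
        dup_states[j] <- transition_destination(dup_states[j])
      }
      d2 <- season_start + sample.int(122L, n_dup, replace = TRUE) - 1L
      chem2 <- draw_chemistry(dup_states, config)
      second <- data.frame(lake_id = lakes$lake_id[dup_idx], date = d2, chem2)
      out[[ci]] <- rbind(first, second)
    } else {
      out[[ci]] <- first
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$lake_id, res$date), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Simulate per-overpass reflectance records
#'
#' For every lake-year a Poisson number of summer (June-August) overpasses is
#' drawn with the era-specific mean, plus Poisson off-summer records. Raw band
#' values are `raw_scale` times the lake state's relative signature plus
#' Gaussian noise, truncated at zero.
#'
#' @inheritParams simulate_insitu
#' @return Data.frame with columns `lake_id`, `date`, `red`, `green`, `blue`, `nir`.
#' @export
simulate_overpasses <- function(lakes, config) {
  stopifnot(inherits(config, "lts_sim_config"))
  if (length(config$years) == 0L) stop("year range is empty", call. = FALSE)
  set.seed(derive_seed(config$seed, 3))
  grid <- expand.grid(lake = seq_len(nrow(lakes)), year = config$years,
                      KEEP.OUT.ATTRS = FALSE)
  era <- year_era(grid$year, config$eras)
  rate <- ifelse(is.na(era), 0, unname(config$overpass_rate[era]))
  n_sum <- stats::rpois(nrow(grid), rate)
  n_off <- stats::rpois(nrow(grid), config$offseason_rate)

  lake_rep <- c(rep(grid$lake, n_sum), rep(grid$lake, n_off))
  year_rep <- c(rep(grid$year, n_sum), rep(grid$year, n_off))
  is_summer <- rep(c(TRUE, FALSE), c(sum(n_sum), sum(n_off)))
  m <- length(lake_rep)
  if (m == 0L) {
    return(data.frame(lake_id = integer(), date = as.Date(character()),
                      red = numeric(), green = numeric(), blue = numeric(),
                      nir = numeric()))
  }
  # summer: uniform over Jun 1 - Aug 31 (92 days); off-summer: uniform over
  # the remaining days of the year
  jan1 <- as.Date(sprintf("%d-01-01", year_rep))
  jun1_off <- as.integer(as.Date(sprintf("%d-06-01", year_rep)) - jan1)
  year_len <- as.integer(as.Date(sprintf("%d-12-31", year_rep)) - jan1) + 1L
  doy <- integer(m)
  doy[is_summer] <- jun1_off[is_summer] + sample.int(92L, sum(is_summer), replace = TRUE) - 1L
  if (any(!is_summer)) {
    off_len <- year_len[!is_summer] - 92L
    u <- floor(stats::runif(sum(!is_summer)) * off_len)   # 0 .. off_len-1
    off_start <- jun1_off[!is_summer]
    doy[!is_summer] <- ifelse(u < off_start, u, u + 92L)
  }
  dates <- jan1 + doy

  states <- lakes$true_state[lake_rep]
  sig <- config$spectra_means[states, , drop = FALSE]
  raw <- config$raw_scale * sig +
    matrix(stats::rnorm(m * 4L, 0, config$spectra_noise_sd), nrow = m)
  raw <- pmax(raw, 0)
  colnames(raw) <- lts_bands()
  res <- data.frame(lake_id = lakes$lake_id[lake_rep], date = dates, raw)
  res <- res[order(res$lake_id, res$date), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Simulate a full synthetic dataset
#'
#' Convenience wrapper producing the lake registry, in situ campaign table and
#' overpass table in one call, optionally writing the three delimited files
#' (`lakes.csv`, `insitu.csv`, `overpasses.csv`).
#'
#' @param config An [lts_sim_config()] object.
#' @param campaigns Campaign years for the in situ table.
#' @param dir Optional output directory; created if missing.
#' @return Invisible list with `lakes`, `insitu`, `overpasses` data.frames.
#' @export
simulate_lts_dataset <- function(config, campaigns, dir = NULL) {
  lakes <- simulate_lakes(config)
  insitu <- simulate_insitu(lakes, campaigns, config)
  overpasses <- simulate_overpasses(lakes, config)
  out <- list(lakes = lakes, insitu = insitu, overpasses = overpasses)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(lakes, file.path(dir, "lakes.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(insitu, file.path(dir, "insitu.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(overpasses, file.path(dir, "overpasses.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(out)
}
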