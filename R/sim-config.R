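# Configuration object for the synthetic lake / chemistry / overpass generator.

default_spectra_means <- function() {
  # qualitative class signatures: oligo blue > green > red >= nir;
  # eu/mixo green > red > blue > nir; dys nir > red > green > blue.
  m <- rbind(
    oligotrophic = c(red = 0.20, green = 0.28, blue = 0.42, nir = 0.10),
    eutrophic    = c(red = 0.28, green = 0.38, blue = 0.24, nir = 0.10),
    dystrophic   = c(red = 0.28, green = 0.22, blue = 0.14, nir = 0.36),
    mixotrophic  = c(red = 0.30, green = 0.36, blue = 0.22, nir = 0.12)
  )
  m[lts_states4(), ]
}

expand_state_param <- function(x, name) {
  states <- lts_states4()
  if (length(x) == 1L) x <- stats::setNames(rep(x, 4L), states)
  if (is.null(names(x))) names(x) <- states
  if (!all(states %in% names(x))) {
    stop_config(name, sprintf("must be named over states %s", paste(states, collapse = ", ")))
  }
  x[states]
}

#' Configuration for the synthetic lake trophic-state generator
#'
#' Assembles and validates the parameters governing simulated lake registries,
#' in situ chemistry campaigns, and satellite overpass spectra. Defaults encode
#' the study conditions the generator emulates: class-conditional lognormal
#' total phosphorus and true color, per-state relative reflectance signatures,
#' Poisson summer overpass counts with era-specific means (3.04 images per
#' summer for 1984-1998, 5.64 for 1999-2012, 5.42 for 2013-2020), 10% of lakes
#' revisited within a campaign, and a 14.9% within-summer transition rate for
#' revisited lakes.
#'
#' @param n_lakes Number of lakes to simulate.
#' @param years Inclusive range of overpass years.
#' @param seed Integer seed; all generator functions derive their streams from it.
#' @param class_mix Probabilities over the four quadrant states, summing to 1.
#' @param tp_median,tp_sdlog Per-state lognormal total phosphorus (median ug/L,
#'   log-scale sd). Scalars are recycled across states.
#' @param color_median,color_sdlog Per-state lognormal true color (median PCU,
#'   log-scale sd).
#' @param spectra_means 4x4 matrix (state x band) of mean relative reflectance
#'   signatures; every row must sum to 1.
#' @param spectra_noise_sd Additive Gaussian noise sd on raw reflectance, per band.
#' @param raw_scale Multiplier from relative signature to raw reflectance units.
#' @param overpass_rate Named per-era mean summer images per lake-year.
#' @param offseason_rate Mean off-summer images per lake-year (exercises the
#'   summer filter downstream).
#' @param transition_prob Probability that a revisited lake changes trophic
#'   state between its two within-summer visits.
#' @param duplicate_frac Fraction of lakes sampled twice per campaign.
#' @param n_groups Number of generic group labels (ecoregion stand-ins).
#'
#' @return A validated list of class `"lts_sim_config"`.
#' @examples
#' cfg <- lts_sim_config(n_lakes = 50, seed = 7)
#' lakes <- simulate_lakes(cfg)
#' @export
lts_sim_config <- function(n_lakes = 200,
                           years = 1984:2020,
                           seed = 1,
                           class_mix = c(oligotrophic = 0.35, eutrophic = 0.40,
                                         dystrophic = 0.10, mixotrophic = 0.15),
                           tp_median = c(oligotrophic = 12, eutrophic = 80,
                                         dystrophic = 15, mixotrophic = 90),
                           tp_sdlog = 0.30,
                           color_median = c(oligotrophic = 8, eutrophic = 10,
                                            dystrophic = 60, mixotrophic = 55),
                           color_sdlog = 0.30,
                           spectra_means = default_spectra_means(),
                           spectra_noise_sd = 25,
                           raw_scale = 1000,
                           overpass_rate = c("1984-1998" = 3.04,
                                             "1999-2012" = 5.64,
                                             "2013-2020" = 5.42),
                           offseason_rate = 1.0,
                           transition_prob = 0.149,
                           duplicate_frac = 0.10,
                           n_groups = 9) {
  if (!is.numeric(n_lakes) || length(n_lakes) != 1L || n_lakes < 0 || n_lakes != round(n_lakes)) {
    stop_config("n_lakes", "must be a single nonnegative integer")
  }
  if (length(years) < 1L || any(years != round(years))) {
    stop_config("years", "must be a nonempty integer vector")
  }
  class_mix <- expand_state_param(class_mix, "class_mix")
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-12) {
    stop_config("class_mix", "must be nonnegative and sum to 1")
  }
  tp_median <- expand_state_param(tp_median, "tp_median")
  tp_sdlog <- expand_state_param(tp_sdlog, "tp_sdlog")
  color_median <- expand_state_param(color_median, "color_median")
  color_sdlog <- expand_state_param(color_sdlog, "color_sdlog")
  for (nm in c("tp_median", "color_median")) {
    if (any(get(nm) <= 0)) stop_config(nm, "must be positive")
  }
  for (nm in c("tp_sdlog", "color_sdlog")) {
    if (any(get(nm) < 0)) stop_config(nm, "must be nonnegative")
  }
  spectra_means <- as.matrix(spectra_means)
  if (!all(lts_states4() %in% rownames(spectra_means)) ||
      !all(lts_bands() %in% colnames(spectra_means))) {
    stop_config("spectra_means", "must have state rownames and band colnames")
  }
  spectra_means <- spectra_means[lts_states4(), lts_bands()]
  if (any(spectra_means < 0) || any(abs(rowSums(spectra_means) - 1) > 1e-12)) {
    stop_config("spectra_means", "rows must be nonnegative and sum to 1")
  }
  if (length(spectra_noise_sd) != 1L || spectra_noise_sd < 0) {
    stop_config("spectra_noise_sd", "must be a single nonnegative number")
  }
  if (raw_scale <= 0) stop_config("raw_scale", "must be positive")
  if (any(overpass_rate < 0)) stop_config("overpass_rate", "must be nonnegative")
  if (offseason_rate < 0) stop_config("offseason_rate", "must be nonnegative")
  if (transition_prob < 0 || transition_prob > 1) {
    stop_config("transition_prob", "must be in [0, 1]")
  }
  if (duplicate_frac < 0 || duplicate_frac > 1) {
    stop_config("duplicate_frac", "must be in [0, 1]")
  }
  eras <- parse_eras(names(overpass_rate))
  structure(list(
    n_lakes = as.integer(n_lakes), years = as.integer(years), seed = seed,
    class_mix = class_mix, tp_median = tp_median, tp_sdlog = tp_sdlog,
    color_median = color_median, color_sdlog = color_sdlog,
    spectra_means = spectra_means, spectra_noise_sd = spectra_noise_sd,
    raw_scale = raw_scale, overpass_rate = overpass_rate, eras = eras,
    offseason_rate = offseason_rate, transition_prob = transition_prob,
    duplicate_frac = duplicate_frac, n_groups = as.integer(n_groups)
  ), class = "lts_sim_config")
}

parse_eras <- function(labels) {
  if (is.null(labels)) stop_config("overpass_rate", "must be named 'start-end'")
  parts <- strsplit(labels, "-", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop_config("overpass_rate", "names must be 'start-end'")
  data.frame(label = labels,
             start = as.integer(vapply(parts, `[`, "", 1L)),
             end = as.integer(vapply(parts, `[`, "", 2L)))
}

# era label for each year (NA when outside all eras)
year_era <- function(years, eras) {
  out <- rep(NA_character_, length(years))
  for (i in seq_len(nrow(eras))) {
    out[years >= eras$start[i] & years <= eras$end[i]] <- eras$label[i]
  }
  out
}

#' @export
print.lts_sim_config <- function(x, ...) {
  cat("Synthetic lake trophic-state generator configuration\n")
  cat(sprintf("  lakes: %d   years: %d-%d   seed: %s\n",
              x$n_lakes, min(x$years), max(x$years), format(x$seed)))
  cat("  class mix:", paste(sprintf("%s=%.2f", names(x$class_mix), x$class_mix),
                            collapse = " "), "\n")
  cat(sprintf("  overpass rates: %s\n",
              paste(sprintf("%s=%.2f", names(x$overpass_rate), x$overpass_rate),
                    collapse = " ")))
  cat(sprintf("  duplicate_frac: %.2f   transition_prob: %.3f   spectra noise sd: %g\n",
              x$duplicate_frac, x$transition_prob, x$spectra_noise_sd))
  invisible(x)
}
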