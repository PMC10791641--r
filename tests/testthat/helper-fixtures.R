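# Shared fixtures and independent oracles. Expensive fixtures are built once
# per test run and cached in an environment.

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# generator with every noise source off: spectra exactly the class signature,
# chemistry exactly the class median, no within-summer transitions
zero_noise_config <- function(n_lakes, years = c(2007L, 2012L, 2017L), seed = 1) {
  lts_sim_config(n_lakes = n_lakes, years = years, seed = seed,
                 spectra_noise_sd = 0, tp_sdlog = 0, color_sdlog = 0,
                 transition_prob = 0)
}

# small default-condition dataset reused across modules
small_sim <- function() {
  get_fixture("small_sim", {
    cfg <- lts_sim_config(n_lakes = 80, years = c(2007L, 2012L, 2017L), seed = 42)
    simulate_lts_dataset(cfg, campaigns = c(2007L, 2012L, 2017L))
  })
}

small_training <- function() {
  get_fixture("small_training", {
    sim <- small_sim()
    build_training_table(sim$insitu, aggregate_overpasses(sim$overpasses),
                         lakes = sim$lakes)
  })
}

# three well-separated Gaussian blobs in the 4-D predictor space, one synthetic
# lake per row
make_blobs <- function(n = 300, sep = 3, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(sep, 0, 0, 0), c(0, sep, 0, 0), c(0, 0, sep, 0))
  cls <- sample(rep(lts_classes(), length.out = n))
  idx <- match(cls, lts_classes())
  x <- centers[idx, ] + matrix(rnorm(n * 4), n, 4)
  out <- data.frame(lake_id = seq_len(n), year = 2000L, x)
  names(out)[3:6] <- paste0("z_", c("red", "green", "blue", "nir"))
  out$trophic_state <- factor(cls, levels = lts_classes())
  out
}

# O(n^2) pairwise AUC oracle with ties counted 1/2
pairwise_auc <- function(pos, score) {
  sp <- score[pos]; sn <- score[!pos]
  if (!length(sp) || !length(sn)) return(NA_real_)
  tot <- 0
  for (s in sp) tot <- tot + sum(s > sn) + 0.5 * sum(s == sn)
  tot / (length(sp) * length(sn))
}

# brute-force Type II sums of squares: RSS(model without factor) minus
# RSS(full additive model), fit with lm directly
type2_ss_oracle <- function(data, response, factors, log_transform = TRUE) {
  y <- data[[response]]
  if (log_transform) y <- log(y)
  fd <- data.frame(.y = y)
  for (f in factors) fd[[f]] <- factor(data[[f]])
  full <- lm(as.formula(paste(".y ~", paste(factors, collapse = "+"))), data = fd)
  rss_full <- deviance(full)
  out <- data.frame(term = factors, sum_sq = NA_real_, df = NA_integer_)
  for (i in seq_along(factors)) {
    rest <- setdiff(factors, factors[i])
    red <- if (length(rest)) {
      lm(as.formula(paste(".y ~", paste(rest, collapse = "+"))), data = fd)
    } else {
      lm(.y ~ 1, data = fd)
    }
    out$sum_sq[i] <- deviance(red) - rss_full
    out$df[i] <- df.residual(red) - df.residual(full)
  }
  out$rss_full <- rss_full
  out$df_resid <- df.residual(full)
  out
}
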