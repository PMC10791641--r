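# Shared constants and small helpers.

#' Trophic state vocabularies
#'
#' `lts_classes()` returns the merged three-state vocabulary used for modeling,
#' in the fixed (alphabetical) order every probability matrix in the package
#' follows. `lts_states4()` returns the four Nutrient-Color Paradigm quadrant
#' names.
#'
#' @return Character vector of state names.
#' @export
lts_classes <- function() c("dys", "eu/mixo", "oligo")

#' @rdname lts_classes
#' @export
lts_states4 <- function() c("oligotrophic", "eutrophic", "dystrophic", "mixotrophic")

# band order used everywhere: Landsat visible + near-infrared
lts_bands <- function() c("red", "green", "blue", "nir")

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic per-stage seed derivation from one global seed; stays < 2^31
derive_seed <- function(seed, offset) {
  (as.numeric(seed) %% 1000003) * 2011 + offset
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_numeric_finite <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' must be finite numeric", name), call. = FALSE)
  }
  invisible(x)
}

# stable column reorder/check
require_columns <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# argmax over a numeric matrix with an explicit tie precedence over colnames
argmax_with_precedence <- function(m, precedence) {
  stopifnot(all(precedence %in% colnames(m)))
  rowmax <- do.call(pmax, as.data.frame(m))
  out <- rep(NA_character_, nrow(m))
  for (cls in precedence) {
    hit <- is.na(out) & m[, cls] >= rowmax - 0 & m[, cls] == rowmax
    out[hit] <- cls
  }
  out
}
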