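# Shared helpers: validation, rounding, severity bands.

validate_items <- function(items, n, lo, hi, scale) {
  if (length(items) != n) {
    abort(sprintf("%s requires exactly %d items, got %d", scale, n, length(items)),
          class = "mhtriage_validation_error")
  }
  items <- as.numeric(items)
  bad <- which(is.na(items) | items != floor(items) | items < lo | items > hi)
  if (length(bad) > 0) {
    abort(sprintf("%s item %d is out of range [%d, %d] (value: %s)",
                  scale, bad[1], lo, hi, format(items[bad[1]])),
          class = "mhtriage_validation_error")
  }
  as.integer(items)
}

#' Round half up
#'
#' Rounds half away from zero at a fixed number of decimal digits, the
#' convention used for reported percentages and summary statistics (base R's
#' `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.35), 0)
#' round_half_up(23.529, 1)
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a fraction as a reported percentage
#'
#' @param x Fraction in \[0, 1\].
#' @param digits Decimal digits of the percentage (default 0, whole percent).
#' @return Numeric percentage rounded half-up.
#' @examples
#' pct(8 / 34)  # 24
#' pct(34 / 130, 1)  # 26.2
#' @export
pct <- function(x, digits = 0) {
  round_half_up(100 * x, digits)
}

band_levels <- c("none", "mild", "moderate", "severe")
grouped_band_levels <- c("none", "mild_to_moderate", "severe")

# 4-band severity on a 0-3-per-item scale total: 0-4 none, 5-9 mild,
# 10-14 moderate, >= 15 severe. Same cutoffs for GAD-7 and PHQ-9.
severity_band <- function(total) {
  b <- ifelse(total >= 15, "severe",
       ifelse(total >= 10, "moderate",
       ifelse(total >= 5, "mild", "none")))
  factor(b, levels = band_levels, ordered = TRUE)
}

# 3-way coarsening: mild and moderate collapse to mild_to_moderate (5-14).
collapse_band <- function(band) {
  b <- as.character(band)
  b[b %in% c("mild", "moderate")] <- "mild_to_moderate"
  factor(b, levels = grouped_band_levels, ordered = TRUE)
}

`%na%` <- function(x, y) ifelse(is.na(x), y, x)
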