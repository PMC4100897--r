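# Internal helpers shared across the package.

# round half away from zero (printed MPL tables use this convention,
# whereas base round() rounds halves to even); the 1e-9 guard keeps decimal
# halves such as 0.495 from falling just below the threshold in binary
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  out <- sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
  out[!is.finite(x)] <- x[!is.finite(x)]
  out
}

# clip probabilities away from 0/1 before taking logs
clip_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

`%||%` <- function(a, b) if (is.null(a)) b else a

# keep the RRA coefficient out of the 1e-6 band around r = 1 where the
# literal CRRA form x^(1-r)/(1-r) degenerates; the MLE search region
# excludes that band
clamp_r_band <- function(r, band = 1e-6) {
  ifelse(abs(1 - r) < band, ifelse(r >= 1, 1 + band, 1 - band), r)
}
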