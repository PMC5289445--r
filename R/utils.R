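#' Abundance transform used throughout the pipeline
#'
#' Applies the `log + 1` transform to a positive quantity (a copy number or
#' an S/H ratio): `ln(x) + 1`. Note the convention: the natural logarithm is
#' taken first and 1 is added to the result (so `log_plus_one(1) == 1`);
#' this reproduces, e.g., 183 copies -> 6.21 to two decimals. It is not
#' `ln(x + 1)`.
#'
#' @param x Numeric vector of positive quantities.
#' @return Numeric vector `log(x) + 1`; non-positive or missing inputs
#'   return `NA` (absent clades are never transformed).
#' @examples
#' log_plus_one(c(1, 26, 183))
#' @export
log_plus_one <- function(x) {
  out <- ifelse(is.finite(x) & x > 0, log(x) + 1, NA_real_)
  as.numeric(out)
}

#' Convert between exponential-decay and Ct-per-decade curve parameterizations
#'
#' Standard curves are sometimes reported as an exponential fit of template
#' quantity against Ct, `q = A * exp(-k * Ct)`. The equivalent log-linear
#' regression of Ct on log10(q) has slope `-ln(10) / k` (Ct per decade) and
#' intercept `ln(A) / k` (Ct at one copy).
#'
#' @param decay Positive decay constant `k` (per Ct).
#' @param amplitude Prefactor `A` (template quantity at Ct 0). Only needed
#'   for the intercept.
#' @return `decay_to_slope()`: the Ct-per-decade slope (negative).
#'   `decay_to_intercept()`: the Ct at quantity 1.
#' @examples
#' decay_to_slope(0.681)    # ~ -3.381 Ct per decade
#' decay_to_intercept(0.681, 1e11)
#' @export
decay_to_slope <- function(decay) {
  stopifnot(is.numeric(decay), all(decay > 0))
  -log(10) / decay
}

#' @rdname decay_to_slope
#' @export
decay_to_intercept <- function(decay, amplitude) {
  stopifnot(is.numeric(decay), all(decay > 0), all(amplitude > 0))
  log(amplitude) / decay
}

#' Percent rounding policy
#'
#' Whole-sample summaries (e.g., the fraction of mono-clade colonies in a
#' species) are printed as integer percentages; pattern-group percentages
#' are printed to one decimal.
#'
#' @param x Percentage values.
#' @param kind `"summary"` (integer) or `"group"` (one decimal).
#' @return Rounded percentages.
#' @export
round_percent <- function(x, kind = c("summary", "group")) {
  kind <- match.arg(kind)
  round(x, digits = if (kind == "summary") 0 else 1)
}

# Canonical clade labels handled by the assay panel.
CLADE_LEVELS <- c("A", "B", "C", "D", "E", "F")
HOST_ASSAY <- "host"
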