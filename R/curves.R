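#' Fit a qPCR standard curve
#'
#' Ordinary least-squares regression of Ct on log10(template quantity) over
#' a dilution series. Replicate Cts enter as independent observations (they
#' are not averaged first). The fitted slope gives the amplification
#' efficiency; together with the limit of quantification (LOQ) it defines
#' the Ct ceiling above which a well is not quantifiable.
#'
#' @param data Data frame with one row per replicate observation and
#'   columns `quantity` (known template amount, strictly positive) and
#'   `ct` (observed cycle threshold).
#' @param assay Assay label stored on the curve (e.g., `"A"` for the clade-A
#'   28S primer set, `"host"` for the coral 18S set).
#' @param loq Limit of quantification in the units of `quantity`. The
#'   default 200 copies applies to the clade-specific 28S assays.
#' @param quantity_kind What `quantity` measures: `"copies"`, `"cells"`, or
#'   `"mass"` (ng of DNA).
#' @return An object of class `standard_curve`: slope (Ct per decade,
#'   negative for a valid curve), intercept (Ct at quantity 1), R squared,
#'   efficiency in percent, LOQ and the corresponding Ct upper limit, plus
#'   the underlying `lm` fit for downstream coefficient tests.
#' @examples
#' dil <- tibble::tibble(quantity = 10^(1:7), ct = 40 - 3.322 * (1:7))
#' fit_standard_curve(dil, assay = "A")
#' @export
fit_standard_curve <- function(data, assay = NA_character_, loq = 200,
                               quantity_kind = c("copies", "cells", "mass")) {
  quantity_kind <- match.arg(quantity_kind)
  if (!all(c("quantity", "ct") %in% names(data))) {
    abort("`data` must have columns `quantity` and `ct`.")
  }
  data <- dplyr::filter(data, is.finite(.data$quantity), is.finite(.data$ct))
  if (any(data$quantity <= 0)) {
    abort("All template quantities must be strictly positive.")
  }
  if (dplyr::n_distinct(data$quantity) < 3) {
    abort("A standard curve needs at least 3 distinct template quantities.")
  }
  data <- dplyr::mutate(data, log_q = log10(.data$quantity))
  fit <- lm(ct ~ log_q, data = data)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (!is.finite(slope) || slope >= 0) {
    warn(paste0("Fitted slope ", signif(slope, 4),
                " is non-negative: invalid standard curve."))
    valid <- FALSE
  } else {
    valid <- TRUE
  }
  r2 <- summary(fit)$r.squared
  curve <- new_standard_curve(
    assay = assay, slope = slope, intercept = intercept, r_squared = r2,
    loq = loq, quantity_kind = quantity_kind, valid = valid,
    fit = fit, n = nrow(data)
  )
  curve
}

#' Construct a standard curve from known coefficients
#'
#' Builds a `standard_curve` directly from a slope and intercept, e.g. taken
#' from a published curve equation, without underlying fit data. Curves
#' reported in the exponential form `q = A * exp(-k * Ct)` can be converted
#' with [decay_to_slope()] and [decay_to_intercept()].
#'
#' @param slope Ct per decade of template (negative).
#' @param intercept Ct at a template quantity of 1.
#' @param assay,loq,quantity_kind,r_squared See [fit_standard_curve()].
#' @return A `standard_curve` object (without fit data; it cannot be used
#'   in [compare_coefficients()]).
#' @examples
#' standard_curve(slope = -3.322, intercept = 40, assay = "A")
#' @export
standard_curve <- function(slope, intercept, assay = NA_character_,
                           loq = 200, r_squared = NA_real_,
                           quantity_kind = "copies") {
  stopifnot(is.numeric(slope), is.numeric(intercept), length(slope) == 1,
            length(intercept) == 1)
  if (!is.finite(slope) || slope >= 0) {
    abort("A standard curve requires a finite negative slope.")
  }
  new_standard_curve(
    assay = assay, slope = slope, intercept = intercept,
    r_squared = r_squared, loq = loq, quantity_kind = quantity_kind,
    valid = TRUE, fit = NULL, n = NA_integer_
  )
}

new_standard_curve <- function(assay, slope, intercept, r_squared, loq,
                               quantity_kind, valid, fit, n) {
  structure(
    list(
      assay = assay,
      slope = slope,
      intercept = intercept,
      r_squared = r_squared,
      efficiency_pct = if (valid) efficiency_percent(slope) else NA_real_,
      loq = loq,
      ct_upper_limit = if (valid) slope * log10(loq) + intercept else NA_real_,
      quantity_kind = quantity_kind,
      valid = valid,
      fit = fit,
      n = n
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve>", if (!is.na(x$assay)) paste0("assay ", x$assay), "\n")
  cat(sprintf("  Ct = %.4f %+.4f * log10(%s)\n",
              x$intercept, x$slope, x$quantity_kind))
  cat(sprintf("  R^2 = %s   efficiency = %s%%\n",
              format(x$r_squared, digits = 4),
              format(x$efficiency_pct, digits = 4)))
  cat(sprintf("  LOQ = %g %s  ->  Ct upper limit = %s\n",
              x$loq, x$quantity_kind, format(x$ct_upper_limit, digits = 5)))
  if (!x$valid) cat("  ** flagged invalid (non-negative slope) **\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.standard_curve <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(
      term = c("(Intercept)", "log10(quantity)"),
      estimate = c(x$intercept, x$slope),
      std.error = NA_real_, statistic = NA_real_, p.value = NA_real_
    ))
  }
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("(Intercept)", "log10(quantity)"),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' @exportS3Method generics::glance
glance.standard_curve <- function(x, ...) {
  tibble::tibble(
    assay = x$assay,
    slope = x$slope,
    intercept = x$intercept,
    r.squared = x$r_squared,
    efficiency_pct = x$efficiency_pct,
    loq = x$loq,
    ct_upper_limit = x$ct_upper_limit,
    quantity_kind = x$quantity_kind,
    n = x$n,
    valid = x$valid
  )
}

#' Amplification efficiency of a standard curve
#'
#' Efficiency is the ratio of the expected slope of a perfectly efficient
#' reaction (-3.322 Ct per decade, i.e. exact doubling every cycle) to the
#' observed slope, in percent: `100 * (-3.322) / slope`. A slope of exactly
#' -3.322 gives 100%; shallower slopes (|m| < 3.322) exceed 100%.
#'
#' @param curve A `standard_curve`, or a numeric slope in Ct per decade.
#' @return Efficiency in percent.
#' @examples
#' efficiency_percent(-3.322)              # 100
#' efficiency_percent(decay_to_slope(0.681)) # clade-A printed fit, ~98.2
#' @export
efficiency_percent <- function(curve) {
  slope <- if (inherits(curve, "standard_curve")) curve$slope else curve
  stopifnot(is.numeric(slope))
  if (any(!is.finite(slope)) || any(slope == 0)) {
    abort("Efficiency is undefined for a zero or non-finite slope.")
  }
  100 * EXPECTED_SLOPE / slope
}

#' Ct ceiling of the quantifiable range
#'
#' The Ct at which a standard curve predicts its limit of quantification;
#' observed Cts beyond this threshold are not quantifiable (the template
#' amount falls below the LOQ). Raising the LOQ lowers the threshold.
#'
#' @param curve A `standard_curve`.
#' @param loq Limit of quantification; defaults to the curve's own.
#' @return The threshold Ct.
#' @examples
#' cv <- standard_curve(-3.322, 40)
#' quantifiable_ct_threshold(cv, loq = 200)  # 40 - 3.322*log10(200)
#' @export
quantifiable_ct_threshold <- function(curve, loq = curve$loq) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!curve$valid) abort("Cannot compute a Ct threshold for an invalid curve.")
  if (!is.finite(loq) || loq <= 0) abort("`loq` must be a positive quantity.")
  curve$slope * log10(loq) + curve$intercept
}

#' Pairwise comparison of standard-curve coefficients
#'
#' Student's t-test for the difference between the slopes (or intercepts) of
#' two independently fitted standard curves, using the pooled residual
#' variance of the two regressions; degrees of freedom are
#' `n_a + n_b - 4`. Used to compare assay sensitivities (intercepts) and to
#' check that clade-specific assays share a common efficiency (slopes).
#'
#' @param curve_a,curve_b `standard_curve` objects carrying fit data
#'   (from [fit_standard_curve()]).
#' @param which Which coefficient to compare: `"slope"` or `"intercept"`.
#' @return A one-row tibble: `coefficient`, `estimate_a`, `estimate_b`,
#'   `statistic` (t), `df`, `p.value` (two-sided).
#' @export
compare_coefficients <- function(curve_a, curve_b,
                                 which = c("slope", "intercept")) {
  which <- match.arg(which)
  for (cv in list(curve_a, curve_b)) {
    if (!inherits(cv, "standard_curve") || is.null(cv$fit)) {
      abort("Both curves must come from fit_standard_curve() (fit data needed).")
    }
    if (cv$n < 3) abort("Each fit needs at least 3 observations.")
  }
  part <- function(cv) {
    x <- cv$fit$model$log_q
    n <- length(x)
    sxx <- sum((x - mean(x))^2)
    rss <- sum(stats::residuals(cv$fit)^2)
    est <- if (which == "slope") cv$slope else cv$intercept
    cvar <- if (which == "slope") 1 / sxx else 1 / n + mean(x)^2 / sxx
    list(n = n, rss = rss, est = est, cvar = cvar)
  }
  a <- part(curve_a)
  b <- part(curve_b)
  df <- a$n + b$n - 4
  s2 <- (a$rss + b$rss) / df
  se <- sqrt(s2 * (a$cvar + b$cvar))
  diff <- a$est - b$est
  # noise-free fits leave only floating-point residue; floor both the SE
  # and the difference at the scale of double rounding
  floor_scale <- 1e-10 * max(abs(a$est), abs(b$est), 1)
  tstat <- if (se < floor_scale) {
    if (abs(diff) < floor_scale) 0 else sign(diff) * Inf
  } else {
    diff / se
  }
  tibble::tibble(
    coefficient = which,
    estimate_a = a$est,
    estimate_b = b$est,
    statistic = tstat,
    df = df,
    p.value = 2 * pt(-abs(tstat), df)
  )
}

#' Invert a standard curve: Ct to template quantity
#'
#' `quantity = 10^((ct - intercept) / slope)`; strictly decreasing in Ct.
#' Cts beyond the curve's quantifiable ceiling are rejected — such wells
#' should be handled by the positive-call rules (see [call_positive()])
#' rather than quantified.
#'
#' @param ct Numeric vector of (calibrated) Ct values.
#' @param curve A `standard_curve`.
#' @param enforce_loq Reject Cts beyond the quantifiable range (default
#'   TRUE).
#' @return Template quantities in the curve's units.
#' @examples
#' cv <- standard_curve(-3.322, 40)
#' ct_to_quantity(26.712, cv)  # ~1e4 copies
#' @export
ct_to_quantity <- function(ct, curve, enforce_loq = TRUE) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!curve$valid) abort("Cannot invert an invalid standard curve.")
  if (enforce_loq) {
    bad <- is.finite(ct) & ct > curve$ct_upper_limit + 1e-9
    if (any(bad)) {
      abort(paste0(
        sum(bad), " Ct value(s) exceed the quantifiable ceiling (",
        format(curve$ct_upper_limit, digits = 5),
        "); apply call_positive() first and quantify only positive wells."
      ))
    }
  }
  10^((ct - curve$intercept) / curve$slope)
}
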