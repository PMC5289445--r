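#' Cross-amplification specificity score (Sp)
#'
#' Scores how specific a primer set is for its target template. Each
#' off-target primer set that amplifies the same DNA sample contributes a
#' penalty of `100 * 2^-(Ctx - Cti)` percentage points, where `Cti` is the
#' Ct of the matched primer set and `Ctx` the Ct of the off-target set:
#'
#'   `Sp(%) = 100 * (1 - sum over amplifying off-targets of 2^-(Ctx - Cti))`
#'
#' An off-target amplifying one cycle late costs 50 points; eight cycles
#' late costs ~0.4 points. Off-target sets that never amplify (encoded as
#' `NA`) contribute nothing, so a perfectly specific assay scores 100%.
#'
#' @param cti Ct of the matched (target) primer set on the DNA sample.
#' @param ctx Numeric vector of off-target Cts on the same sample; `NA`
#'   means no amplification. May be empty.
#' @return Sp in percent (a scalar). An off-target amplifying at or before
#'   the target (`Ctx <= Cti`) is allowed but anomalous — it drives Sp
#'   towards or below zero and triggers a warning.
#' @examples
#' specificity_score(20, c(NA, NA, NA, NA, NA))  # 100
#' specificity_score(20, c(26, NA, NA, NA, NA))  # 100 - 100/2^6 = 98.4375
#' @export
specificity_score <- function(cti, ctx = numeric()) {
  stopifnot(is.numeric(cti), length(cti) == 1, is.finite(cti))
  ctx <- as.numeric(ctx)
  amp <- ctx[is.finite(ctx)]
  if (any(amp <= cti)) {
    warn(paste0(
      "Off-target amplification at or before the target Ct (delta Ct <= 0): ",
      "anomalous panel, Sp may be negative."
    ))
  }
  100 * (1 - sum(2^(-(amp - cti))))
}

#' Score a panel of specificity assays
#'
#' Tidy interface over [specificity_score()]: one row per (target DNA,
#' off-target primer set) observation.
#'
#' @param data Data frame with columns `target` (DNA sample / matched
#'   primer label), `cti` (Ct of the matched set, constant within target),
#'   and `ctx` (off-target Ct, `NA` for no amplification).
#' @return A tibble with one row per target: `target`, `cti`, `sp_pct`,
#'   `n_offtarget`, `n_amplifying`, and `anomalous` (TRUE if any off-target
#'   amplified at or before the target).
#' @export
specificity_panel <- function(data) {
  req <- c("target", "cti", "ctx")
  if (!all(req %in% names(data))) {
    abort("`data` must have columns `target`, `cti`, and `ctx`.")
  }
  data |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(
      cti = {
        ci <- unique(.data$cti)
        if (length(ci) != 1) abort("`cti` must be constant within a target.")
        ci
      },
      sp_pct = specificity_score(.data$cti[1], .data$ctx),
      n_offtarget = dplyr::n(),
      n_amplifying = sum(is.finite(.data$ctx)),
      anomalous = any(is.finite(.data$ctx) & .data$ctx <= .data$cti[1]),
      .groups = "drop"
    )
}
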