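#' Technical-replicate quality control
#'
#' Each sample is assayed twice on the same plate; the two Cts are averaged
#' only when they differ by at most 1 cycle (boundary inclusive). Wells
#' whose replicates disagree by more than 1 Ct — or where one replicate
#' amplified and the other did not — cannot be resolved in silico and are
#' flagged for reprocessing; wells where neither replicate amplified are
#' censored.
#'
#' @param ct_rep1,ct_rep2 Numeric vectors of replicate Cts (`NA` = no
#'   amplification).
#' @param max_delta Maximum tolerated |Ct1 - Ct2| (default 1, inclusive).
#' @return A tibble with columns `mean_ct` (arithmetic mean where accepted,
#'   `NA` otherwise) and `qc_status` (`"accepted"`, `"reprocess"`,
#'   `"censored"`).
#' @examples
#' replicate_qc(c(20, 20, 20, NA), c(20, 21, 21.2, NA))
#' @export
replicate_qc <- function(ct_rep1, ct_rep2, max_delta = 1) {
  stopifnot(length(ct_rep1) == length(ct_rep2), max_delta > 0)
  both_na <- is.na(ct_rep1) & is.na(ct_rep2)
  one_na <- xor(is.na(ct_rep1), is.na(ct_rep2))
  delta_ok <- !is.na(ct_rep1) & !is.na(ct_rep2) &
    abs(ct_rep1 - ct_rep2) <= max_delta
  status <- dplyr::case_when(
    both_na ~ "censored",
    one_na ~ "reprocess",
    delta_ok ~ "accepted",
    .default = "reprocess"
  )
  tibble::tibble(
    mean_ct = ifelse(status == "accepted", (ct_rep1 + ct_rep2) / 2, NA_real_),
    qc_status = status
  )
}

#' Remove plate-to-plate Ct offsets with the interplate calibrator
#'
#' Every plate carries the same calibrator template in triplicate for each
#' assay. The per-plate, per-assay offset is the difference between the
#' plate's mean calibrator Ct and a reference Ct for that assay; the offset
#' is subtracted from every Ct on the plate (calibrators included, so
#' calibrating an already-calibrated set of plates is a no-op). By default the
#' reference is the calibrator mean of the first plate (so calibrating
#' twice is a no-op); an explicit reference table can be supplied instead.
#'
#' @param wells Well table in the [simulate_plates()] dialect.
#' @param reference Optional tibble with columns `assay`, `reference_ct`.
#'   `NULL` (default) uses the first plate's calibrator means.
#' @return The well table with sample Cts offset-corrected, plus an
#'   `offsets` attribute (tibble `plate_id`, `assay`, `offset`). Plates
#'   missing a calibrator triplicate for an assay they use are an error.
#' @export
calibrate_plates <- function(wells, reference = NULL) {
  check_wells(wells)
  cal <- wells |>
    dplyr::filter(.data$role == "calibrator", !is.na(.data$ct_rep1)) |>
    dplyr::group_by(.data$plate_id, .data$assay) |>
    dplyr::summarise(cal_ct = mean(.data$ct_rep1), n_cal = dplyr::n(),
                     .groups = "drop")
  used <- dplyr::distinct(wells[wells$role == "sample", ],
                          .data$plate_id, .data$assay)
  missing <- dplyr::anti_join(used, cal, by = c("plate_id", "assay"))
  if (nrow(missing) > 0) {
    abort(paste0(
      "Plate(s) missing an interplate calibrator for assay(s) in use: ",
      paste(unique(paste0(missing$plate_id, "/", missing$assay)),
            collapse = ", ")
    ))
  }
  if (is.null(reference)) {
    first_plate <- sort(unique(cal$plate_id))[1]
    reference <- cal |>
      dplyr::filter(.data$plate_id == first_plate) |>
      dplyr::transmute(.data$assay, reference_ct = .data$cal_ct)
  }
  offsets <- cal |>
    dplyr::inner_join(reference, by = "assay") |>
    dplyr::transmute(.data$plate_id, .data$assay,
                     offset = .data$cal_ct - .data$reference_ct)
  out <- wells |>
    dplyr::left_join(offsets, by = c("plate_id", "assay")) |>
    dplyr::mutate(
      corr = ifelse(is.na(.data$offset), 0, .data$offset),
      ct_rep1 = .data$ct_rep1 - .data$corr,
      ct_rep2 = .data$ct_rep2 - .data$corr
    ) |>
    dplyr::select(-"offset", -"corr")
  attr(out, "offsets") <- offsets
  out
}

#' Positive-call rule for a quantified well
#'
#' A well counts as a positive, quantifiable amplification only when (i)
#' its technical replicates passed QC, (ii) both replicate Cts lie at or
#' below the assay's quantifiable Ct ceiling (the Ct of the LOQ), and
#' (iii) the observed melting temperature matches the expected amplicon Tm
#' within tolerance. All failure modes are statuses, not errors.
#'
#' @param mean_ct,qc_status From [replicate_qc()].
#' @param ct_rep1,ct_rep2 The replicate Cts (both are checked against the
#'   ceiling, not just their mean).
#' @param curve The assay's `standard_curve` (supplies `ct_upper_limit`).
#' @param tm Observed melting temperature (`NA` = untested).
#' @param expected_tm Expected amplicon Tm for the assay.
#' @param tm_tol Tm tolerance in degC (default 0.3, chosen so that the
#'   C1-type (~82.95 degC) and C15-type (~83.5 degC) amplicons are
#'   distinguished).
#' @return Character vector of statuses: `"positive"`, `"below_loq"`,
#'   `"tm_mismatch"`, `"reprocess"`, or `"censored"`.
#' @export
call_positive <- function(mean_ct, qc_status, ct_rep1, ct_rep2, curve,
                          tm = NA_real_, expected_tm = NA_real_,
                          tm_tol = 0.3) {
  stopifnot(inherits(curve, "standard_curve"))
  limit <- curve$ct_upper_limit
  quantifiable <- !is.na(ct_rep1) & !is.na(ct_rep2) &
    ct_rep1 <= limit & ct_rep2 <= limit
  tm_ok <- is.na(tm) | is.na(expected_tm) | abs(tm - expected_tm) <= tm_tol
  dplyr::case_when(
    qc_status == "censored" ~ "censored",
    qc_status == "reprocess" ~ "reprocess",
    !quantifiable ~ "below_loq",
    !tm_ok ~ "tm_mismatch",
    .default = "positive"
  )
}

#' Symbiont-to-host ratio
#'
#' Normalizes a clade's 28S copy number by the colony's host 18S units
#' ("polyp units"), making symbiont densities comparable across samples of
#' differing biomass.
#'
#' @param clade_copies Clade 28S copies.
#' @param host_units Host 18S units (must be positive; non-positive hosts
#'   mark the sample unquantifiable, returned as `NA`).
#' @return `clade_copies / host_units`.
#' @examples
#' sh_ratio(26, 1e6)
#' @export
sh_ratio <- function(clade_copies, host_units) {
  ifelse(is.finite(host_units) & host_units > 0,
         clade_copies / host_units, NA_real_)
}

#' Quantify symbiont communities from calibrated plates
#'
#' The full per-colony quantification: replicate QC, positive calls
#' against each assay's quantifiable range and expected Tm, inversion of
#' the standard curves to 28S copy numbers (and optionally cell numbers),
#' host normalization to S/H ratios, and the `ln(x) + 1` abundance
#' transform. Input wells should already be offset-corrected with
#' [calibrate_plates()].
#'
#' @param wells Calibrated well table.
#' @param curves Named list of `standard_curve` objects, one per assay
#'   (clade labels plus `"host"`), in copy units.
#' @param assay_info Optional tibble with columns `assay`, `expected_tm`
#'   giving the expected amplicon Tm per assay; defaults to no Tm check.
#' @param cell_curves Optional named list of `standard_curve`s in cell
#'   units; clades with a cell curve get a `cells` column.
#' @param tm_tol Tm tolerance in degC (default 0.3).
#' @param max_delta Replicate QC tolerance in Ct (default 1).
#' @return A tidy tibble, one row per (sample, clade assay): `sample_id`,
#'   `clade`, `mean_ct`, `qc_status`, `status`, `copies`, `cells`,
#'   `host_units`, `sh_ratio`, `transformed` (`ln(copies) + 1`). Copies and
#'   ratios are `NA` unless the well is positive and the host quantified.
#'   A `qc` attribute tabulates every non-positive well with its reason.
#' @export
quantify_samples <- function(wells, curves, assay_info = NULL,
                             cell_curves = NULL, tm_tol = 0.3,
                             max_delta = 1) {
  check_wells(wells)
  assays_present <- setdiff(unique(wells$assay[wells$role == "sample"]), NULL)
  uncovered <- setdiff(assays_present, names(curves))
  if (length(uncovered) > 0) {
    abort(paste0("No standard curve supplied for assay(s): ",
                 paste(uncovered, collapse = ", ")))
  }
  if (is.null(assay_info)) {
    assay_info <- tibble::tibble(assay = assays_present,
                                 expected_tm = NA_real_)
  }

  if (!"tm" %in% names(wells)) wells$tm <- NA_real_
  sw <- wells |>
    dplyr::filter(.data$role == "sample") |>
    dplyr::left_join(assay_info, by = "assay")
  qc <- replicate_qc(sw$ct_rep1, sw$ct_rep2, max_delta = max_delta)
  sw <- dplyr::bind_cols(sw, qc)

  sw <- sw |>
    dplyr::group_by(.data$assay) |>
    dplyr::group_modify(function(df, key) {
      curve <- curves[[key$assay]]
      df$status <- call_positive(df$mean_ct, df$qc_status,
                                 df$ct_rep1, df$ct_rep2, curve,
                                 tm = df$tm, expected_tm = df$expected_tm,
                                 tm_tol = tm_tol)
      df$quantity <- NA_real_
      pos <- df$status == "positive"
      df$quantity[pos] <- ct_to_quantity(df$mean_ct[pos], curve)
      df$cells <- NA_real_
      if (!is.null(cell_curves) && key$assay %in% names(cell_curves)) {
        ccv <- cell_curves[[key$assay]]
        ok <- pos & df$mean_ct <= ccv$ct_upper_limit
        df$cells[ok] <- ct_to_quantity(df$mean_ct[ok], ccv)
      }
      df
    }) |>
    dplyr::ungroup()

  hosts <- sw |>
    dplyr::filter(.data$assay == HOST_ASSAY) |>
    dplyr::transmute(.data$sample_id, host_units = .data$quantity,
                     host_status = .data$status)

  out <- sw |>
    dplyr::filter(.data$assay != HOST_ASSAY) |>
    dplyr::left_join(hosts, by = "sample_id") |>
    dplyr::mutate(
      copies = .data$quantity,
      sh_ratio = sh_ratio(.data$copies, .data$host_units),
      transformed = log_plus_one(.data$copies)
    ) |>
    dplyr::select(dplyr::any_of(c("sample_id", "species", "site")),
                  clade = "assay", "plate_id", "mean_ct", "qc_status",
                  "status", "copies", "cells", "host_units", "host_status",
                  "sh_ratio", "transformed") |>
    dplyr::arrange(.data$sample_id, .data$clade)

  attr(out, "qc") <- sw |>
    dplyr::filter(.data$status != "positive") |>
    dplyr::select(dplyr::any_of(c("plate_id", "well_id", "sample_id",
                                  "assay", "qc_status", "status")))
  out
}

check_wells <- function(wells) {
  req <- c("plate_id", "sample_id", "role", "assay", "ct_rep1", "ct_rep2")
  if (!is.data.frame(wells) || !all(req %in% names(wells))) {
    abort(paste0("Well table must have columns: ",
                 paste(req, collapse = ", ")))
  }
  invisible(wells)
}
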