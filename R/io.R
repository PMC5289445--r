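PLATE_COLS <- c("plate_id", "well_id", "sample_id", "role", "assay",
                "ct_rep1", "ct_rep2", "tm", "censored")

#' Read and write plate CSV files
#'
#' The flat plate dialect: one row per well with columns `plate_id`,
#' `well_id`, `sample_id`, `role` (`sample` / `calibrator` / `standard`),
#' `assay`, `ct_rep1`, `ct_rep2`, `tm`, `censored`. Censored replicates
#' are empty cells. The header is checked, duplicate well IDs and rows
#' carrying more than the two replicate Cts of the dialect are rejected.
#'
#' @param path File path.
#' @param wells Well tibble (from [simulate_plates()] or [read_plates()]).
#' @return `read_plates()`: the well tibble. `write_plates()`: the path,
#'   invisibly.
#' @export
read_plates <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    plate_id = readr::col_character(),
    well_id = readr::col_character(),
    sample_id = readr::col_character(),
    role = readr::col_character(),
    assay = readr::col_character(),
    ct_rep1 = readr::col_double(),
    ct_rep2 = readr::col_double(),
    tm = readr::col_double(),
    censored = readr::col_logical()
  ), progress = FALSE)
  if (nrow(raw) == 0) abort("Empty plate file: no wells.")
  missing_cols <- setdiff(PLATE_COLS, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Plate file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  extra_ct <- grep("^ct_rep[0-9]+$", names(raw), value = TRUE)
  if (length(setdiff(extra_ct, c("ct_rep1", "ct_rep2"))) > 0) {
    abort("Sample wells carry exactly two replicate Cts (ct_rep1, ct_rep2).")
  }
  dup <- raw$well_id[duplicated(paste(raw$plate_id, raw$well_id))]
  if (length(dup) > 0) {
    abort(paste0("Duplicate well ID(s): ", paste(unique(dup), collapse = ", ")))
  }
  bad_role <- setdiff(unique(raw$role), c("sample", "calibrator", "standard"))
  if (length(bad_role) > 0) {
    abort(paste0("Unknown well role(s): ", paste(bad_role, collapse = ", ")))
  }
  bad_assay <- setdiff(unique(raw$assay), c(CLADE_LEVELS, HOST_ASSAY))
  if (length(bad_assay) > 0) {
    abort(paste0("Unknown assay label(s): ",
                 paste(bad_assay, collapse = ", ")))
  }
  raw[, PLATE_COLS]
}

#' @rdname read_plates
#' @export
write_plates <- function(wells, path) {
  check_wells(wells)
  readr::write_csv(as.data.frame(wells)[, PLATE_COLS], path)
  invisible(path)
}

#' Read and write community truth tables
#'
#' @param truth Truth tibble from [design_communities()].
#' @param path File path.
#' @return `read_truth()`: the truth tibble; `write_truth()`: the path,
#'   invisibly.
#' @export
read_truth <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    species = readr::col_character(),
    site = readr::col_character(),
    clade = readr::col_character(),
    true_copies = readr::col_double()
  ), progress = FALSE)
}

#' @rdname read_truth
#' @export
write_truth <- function(truth, path) {
  readr::write_csv(truth, path)
  invisible(path)
}

#' Serialize standard curves to a structured config file
#'
#' Curves are written as a YAML map keyed by assay, carrying slope,
#' intercept, R squared, efficiency, LOQ, the quantifiable Ct ceiling and
#' the quantity kind — the interface between assay validation and
#' quantification.
#'
#' @param curves Named list of `standard_curve` objects.
#' @param path File path.
#' @return `write_curves()`: the path, invisibly. `read_curves()`: a named
#'   list of `standard_curve` objects (coefficients only; fit data is not
#'   serialized).
#' @export
write_curves <- function(curves, path) {
  stopifnot(is.list(curves), length(curves) > 0,
            !is.null(names(curves)), all(names(curves) != ""))
  payload <- purrr::map(curves, function(cv) {
    stopifnot(inherits(cv, "standard_curve"))
    list(slope = cv$slope, intercept = cv$intercept,
         r_squared = cv$r_squared, efficiency_pct = cv$efficiency_pct,
         loq = cv$loq, ct_upper_limit = cv$ct_upper_limit,
         quantity_kind = cv$quantity_kind)
  })
  yaml::write_yaml(payload, path, precision = 15)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  payload <- yaml::read_yaml(path)
  if (length(payload) == 0) abort("Curve file defines no assays.")
  purrr::imap(payload, function(p, assay) {
    standard_curve(
      slope = p$slope, intercept = p$intercept, assay = assay,
      loq = p$loq %||% 200, r_squared = p$r_squared %||% NA_real_,
      quantity_kind = p$quantity_kind %||% "copies"
    )
  })
}

#' Pipeline configuration
#'
#' Defaults for every tunable threshold of the pipeline: the replicate
#' acceptance rule (|delta Ct| <= 1), the dominance cut (5%), the Tm
#' tolerance (0.3 degC), the near-boundary flag band, the LOQ (200 copies
#' for 28S assays), and the per-assay expected Tm table.
#'
#' @param ... Named overrides of the defaults.
#' @return A `pipeline_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    max_delta_ct = 1,
    dominant_threshold_pct = 5,
    tm_tolerance = 0.3,
    near_boundary_pct = 0.1,
    loq = 200,
    abundance = "sh_ratio",
    dapc_features = "transformed",
    expected_tm = NULL,   # tibble(assay, expected_tm), NULL = no Tm check
    calibrator_reference = NULL,
    seed = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  bad <- c("max_delta_ct", "dominant_threshold_pct", "tm_tolerance", "loq")
  if (any(purrr::map_lgl(cfg[bad], function(v) !is.numeric(v) || v <= 0))) {
    abort("All thresholds must be positive numbers.")
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname default_config
#' @param path File path for the YAML round trip.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- unclass(cfg)
  if (!is.null(out$expected_tm)) out$expected_tm <- as.list(out$expected_tm)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname default_config
#' @param cfg A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$expected_tm)) {
    raw$expected_tm <- tibble::as_tibble(raw$expected_tm)
  }
  do.call(default_config, raw)
}
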