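#' Run the full quantification pipeline
#'
#' Chains the analysis stages on a well table: interplate calibration,
#' replicate QC and positive calls, standard-curve inversion to copy
#' numbers, S/H normalization, community profiling with dominant/background
#' classification, species-level pattern summaries, and (when at least two
#' species are present) the DAPC ordination. Deterministic given its
#' inputs; every rejected well, plate offset and near-boundary call is
#' collected in the run log.
#'
#' @param wells Well table ([read_plates()] / [simulate_plates()]).
#' @param curves Named list of `standard_curve`s covering every assay in
#'   `wells` ([read_curves()] or fitted).
#' @param metadata Optional tibble mapping `sample_id` to `species`/`site`
#'   (e.g., a truth table's distinct colony rows); required for species
#'   summaries and the ordination.
#' @param config A [default_config()] list.
#' @return A list: `quant` (per sample x clade quantification),
#'   `profiles` (community profiles), `summary` (per-species pattern
#'   summary, `NULL` without metadata), `ordination` (`dapc_fit` or
#'   `NULL`), and `log` (tibbles of rejected wells, plate offsets, and
#'   near-boundary classifications).
#' @export
run_pipeline <- function(wells, curves, metadata = NULL,
                         config = default_config()) {
  stopifnot(inherits(config, "pipeline_config"))

  calibrated <- calibrate_plates(wells, reference = config$calibrator_reference)
  quant <- quantify_samples(
    calibrated, curves,
    assay_info = config$expected_tm,
    tm_tol = config$tm_tolerance,
    max_delta = config$max_delta_ct
  )
  profiles <- community_profiles(
    quant, metadata = metadata,
    abundance = config$abundance,
    threshold_pct = config$dominant_threshold_pct,
    near = config$near_boundary_pct
  )

  summary_tbl <- NULL
  ordination <- NULL
  if ("species" %in% names(profiles) &&
      !all(is.na(profiles$species))) {
    summary_tbl <- species_summary(profiles)
    if (dplyr::n_distinct(profiles$species) >= 2) {
      feats <- dapc_features(quant, feature = config$dapc_features)
      meta <- dplyr::distinct(profiles, .data$sample_id, .data$species)
      feats <- dplyr::inner_join(feats, meta, by = "sample_id")
      ordination <- dapc(
        dplyr::select(feats, -"sample_id", -"species"),
        groups = feats$species
      )
    }
  }

  log <- list(
    rejected_wells = attr(quant, "qc"),
    plate_offsets = attr(calibrated, "offsets"),
    near_boundary = dplyr::filter(profiles, .data$near_boundary),
    undetected_samples = attr(profiles, "undetected") %||% character()
  )
  list(quant = quant, profiles = profiles, summary = summary_tbl,
       ordination = ordination, log = log)
}

#' Per-sample feature matrix for the ordination
#'
#' Wide per-sample matrix of a quantification column across clades, for
#' use as DAPC features. Absent or non-positive clades enter as 0 (the
#' `ln(x) + 1` transform is undefined at 0, so absence is encoded as a 0
#' feature value by convention).
#'
#' @param quant Quantification table from [quantify_samples()].
#' @param feature Column to spread (default `"transformed"`, the
#'   transformed 28S copy numbers).
#' @return A tibble with `sample_id` and one numeric column per clade.
#' @export
dapc_features <- function(quant, feature = "transformed") {
  stopifnot(feature %in% names(quant))
  quant |>
    dplyr::select("sample_id", "clade", value = dplyr::all_of(feature)) |>
    dplyr::mutate(value = tidyr::replace_na(.data$value, 0)) |>
    tidyr::pivot_wider(names_from = "clade", values_from = "value",
                       values_fill = 0) |>
    dplyr::arrange(.data$sample_id)
}
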