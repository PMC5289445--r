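test_that("replicate QC averages concordant pairs and flags the rest", {
  qc <- replicate_qc(c(20.0, 20.0, 20.0, NA, 33, NA),
                     c(20.0, 21.0, 21.2, 20, NA, NA))
  expect_equal(qc$qc_status,
               c("accepted", "accepted", "reprocess", "reprocess",
                 "reprocess", "censored"))
  # boundary inclusive: |delta Ct| = 1 is still averaged
  expect_equal(qc$mean_ct[1:2], c(20.0, 20.5))
  expect_true(all(is.na(qc$mean_ct[3:6])))
})

make_manual_wells <- function(plate_id, sample_ct, cal_ct, assay = "A",
                              sample_id = "s1") {
  dplyr::bind_rows(
    tibble::tibble(
      plate_id = plate_id, well_id = paste0(plate_id, "_W1"),
      sample_id = sample_id, role = "sample", assay = assay,
      ct_rep1 = sample_ct, ct_rep2 = sample_ct, tm = NA_real_,
      censored = FALSE
    ),
    tibble::tibble(
      plate_id = plate_id, well_id = paste0(plate_id, "_C", 1:3),
      sample_id = "calibrator", role = "calibrator", assay = assay,
      ct_rep1 = cal_ct, ct_rep2 = NA_real_, tm = NA_real_, censored = FALSE
    )
  )
}

test_that("interplate calibration removes per-plate offsets", {
  ref <- tibble::tibble(assay = "A", reference_ct = 25)

  # calibrator on the reference: no change
  w0 <- make_manual_wells("P01", sample_ct = 30, cal_ct = 25)
  c0 <- calibrate_plates(w0, reference = ref)
  expect_equal(dplyr::filter(c0, role == "sample")$ct_rep1, 30)

  # calibrator 0.5 above the reference: every sample Ct reduced by 0.5
  w1 <- make_manual_wells("P01", sample_ct = 30, cal_ct = 25.5)
  c1 <- calibrate_plates(w1, reference = ref)
  expect_equal(dplyr::filter(c1, role == "sample")$ct_rep1, 29.5)

  # two plates with opposite offsets measuring the same template agree
  w2 <- dplyr::bind_rows(
    make_manual_wells("P01", sample_ct = 30.4, cal_ct = 25.4),
    make_manual_wells("P02", sample_ct = 29.7, cal_ct = 24.7,
                      sample_id = "s2")
  )
  c2 <- calibrate_plates(w2, reference = ref)
  s <- dplyr::filter(c2, role == "sample")
  expect_equal(s$ct_rep1, c(30, 30))
})

test_that("calibration with the first plate as reference is idempotent", {
  truth <- design_communities(species_profiles(), seed = 4)
  wells <- simulate_plates(truth, seed = 5)
  once <- calibrate_plates(wells)
  twice <- calibrate_plates(once)
  expect_equal(
    dplyr::filter(twice, role == "sample")$ct_rep1,
    dplyr::filter(once, role == "sample")$ct_rep1,
    tolerance = 1e-12
  )
})

test_that("plates without calibrators are rejected by name", {
  w <- make_manual_wells("P07", sample_ct = 30, cal_ct = 25)
  w <- dplyr::filter(w, role == "sample")
  expect_error(calibrate_plates(w), "P07")
})

test_that("positive calls require QC, the Ct ceiling, and a matching Tm", {
  cv <- standard_curve(-3.322, 40, loq = 200)   # ceiling 32.356
  expect_equal(
    call_positive(25, "accepted", 25, 25, cv, tm = NA),
    "positive"
  )
  # one replicate beyond the ceiling: not quantifiable even if the mean is
  expect_equal(
    call_positive(32.2, "accepted", 31.4, 33.0, cv),
    "below_loq"
  )
  expect_equal(call_positive(NA, "reprocess", 20, 22, cv), "reprocess")
  expect_equal(call_positive(NA, "censored", NA, NA, cv), "censored")
  # the C1-type (82.95) vs C15-type (83.5) melting profiles are distinct
  # at the default 0.3 degC tolerance
  expect_equal(
    call_positive(25, "accepted", 25, 25, cv, tm = 82.95,
                  expected_tm = 83.5),
    "tm_mismatch"
  )
  expect_equal(
    call_positive(25, "accepted", 25, 25, cv, tm = 83.4,
                  expected_tm = 83.5),
    "positive"
  )
})

test_that("S/H ratios divide clade copies by host units", {
  expect_equal(sh_ratio(100, 100), 1)
  expect_equal(sh_ratio(26, 1e6), 2.6e-5)
  expect_true(is.na(sh_ratio(100, 0)))
  # halving the host units doubles every ratio
  expect_equal(sh_ratio(c(10, 50), 500), sh_ratio(c(10, 50), 1000) * 2)
})

test_that("zero-noise simulation is recovered to within 0.1%", {
  truth <- design_communities(species_profiles(), seed = 10)
  assays <- default_assay_params(ct_noise_sd = 0)
  wells <- simulate_plates(truth, assays, plate_offset_sd = 0.4, seed = 11)
  cal <- calibrate_plates(wells,
                          reference = attr(wells, "calibrator_reference"))
  quant <- quantify_samples(cal, true_curves(assays),
                            assay_info = true_tm(assays))
  cmp <- quant |>
    dplyr::filter(status == "positive") |>
    dplyr::inner_join(truth, by = c("sample_id", "clade"))
  expect_gt(nrow(cmp), 50)
  expect_lt(max(abs(cmp$copies / cmp$true_copies - 1)), 1e-3)
  # host units recovered too
  host <- truth |>
    dplyr::filter(clade == "host") |>
    dplyr::inner_join(dplyr::distinct(quant, sample_id, host_units),
                      by = "sample_id")
  expect_lt(max(abs(host$host_units / host$true_copies - 1)), 1e-3)
  # and every true clade above the LOQ was called positive
  above <- truth |>
    dplyr::filter(clade != "host", true_copies > 200 * 1.001) |>
    dplyr::left_join(quant, by = c("sample_id", "clade"))
  expect_true(all(above$status == "positive"))
})

test_that("with 0.15 Ct noise, >=95% of above-LOQ quantifications are within 25%", {
  truth <- design_communities(species_profiles(), seed = 12)
  assays <- default_assay_params(ct_noise_sd = 0.15)
  wells <- simulate_plates(truth, assays, seed = 13)
  cal <- calibrate_plates(wells,
                          reference = attr(wells, "calibrator_reference"))
  quant <- quantify_samples(cal, true_curves(assays),
                            assay_info = true_tm(assays))
  cmp <- quant |>
    dplyr::filter(status == "positive") |>
    dplyr::inner_join(truth, by = c("sample_id", "clade")) |>
    dplyr::filter(true_copies > 200)
  expect_gt(nrow(cmp), 50)
  within <- abs(cmp$copies / cmp$true_copies - 1) <= 0.25
  expect_gte(mean(within), 0.95)
})

test_that("missing standard curves are reported per assay", {
  truth <- manual_truth(c(A = 1e4))
  wells <- simulate_plates(truth, default_assay_params(), seed = 1)
  curves <- true_curves()
  curves$A <- NULL
  expect_error(quantify_samples(calibrate_plates(wells), curves), "A")
})

test_that("reprocess wells are excluded and logged with a reason", {
  cv <- list(A = standard_curve(-3.322, 40),
             host = standard_curve(-3.322, 40, loq = 1))
  wells <- tibble::tibble(
    plate_id = "P01", well_id = paste0("W", 1:2),
    sample_id = "s1", role = "sample", assay = c("A", "host"),
    ct_rep1 = c(20, 20), ct_rep2 = c(21.5, 20),  # A replicates discordant
    tm = NA_real_, censored = FALSE
  )
  quant <- quantify_samples(wells, cv)
  a <- dplyr::filter(quant, clade == "A")
  expect_equal(a$status, "reprocess")
  expect_true(is.na(a$copies))
  qc <- attr(quant, "qc")
  expect_true("reprocess" %in% qc$status)
})
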