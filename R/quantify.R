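#' Plate normalization factors from calibrator Ct values
#'
#' Every plate carries replicate wells of a common calibrator DNA (K562).
#' The normalization factor for an assay on a plate is the ratio of the
#' calibrator's across-plate mean Ct to its mean Ct on that plate, so a
#' plate running systematically high or low is pulled back to the study-wide
#' calibrator level.
#'
#' @param plate_mean_ct Named list or vector with elements `telomere` and
#'   `albumin`: the calibrator's mean Ct on this plate.
#' @param global_mean_ct Same shape: the calibrator's mean Ct across all
#'   plates.
#' @param plate_id Optional plate identifier carried into the output.
#' @return One-row tibble with the four calibrator means and `factor_tel`,
#'   `factor_alb`.
#' @export
plate_normalization <- function(plate_mean_ct, global_mean_ct,
                                plate_id = NA_character_) {
  p_tel <- as.numeric(plate_mean_ct[["telomere"]])
  p_alb <- as.numeric(plate_mean_ct[["albumin"]])
  g_tel <- as.numeric(global_mean_ct[["telomere"]])
  g_alb <- as.numeric(global_mean_ct[["albumin"]])
  vals <- c(p_tel, p_alb, g_tel, g_alb)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("invalid calibrator Ct: means must be finite and positive")
  }
  tibble(
    plate_id = plate_id,
    ct_cal_tel_plate = p_tel, ct_cal_alb_plate = p_alb,
    ct_cal_tel_global = g_tel, ct_cal_alb_global = g_alb,
    factor_tel = g_tel / p_tel,
    factor_alb = g_alb / p_alb
  )
}

#' Calibrate a mean Ct with a plate normalization factor
#'
#' Multiplicative on the Ct scale: `raw_mean_ct * factor`.
#'
#' @param raw_mean_ct Mean Ct after replicate QC (cycles).
#' @param factor Plate normalization factor (> 0).
#' @return Calibrated Ct (cycles).
#' @export
calibrate_ct <- function(raw_mean_ct, factor) {
  if (any(!is.finite(factor)) || any(factor <= 0)) {
    abort("normalization factor must be positive")
  }
  raw_mean_ct * factor
}

#' Absolute telomere length of one sample from calibrated Ct values
#'
#' The delta-delta-Ct calculation: `delta_ct = ct_alb_cal - ct_tel_cal`,
#' `delta_delta_ct = delta_ct - calibrator_delta_ct`, T/S ratio
#' `2^delta_delta_ct`, and absolute telomere length `ts_ratio * anchor_bp`.
#' The anchor is the calibrator's externally determined absolute telomere
#' length, 5,290 bp for the K562 line used here.
#'
#' @param ct_tel_cal,ct_alb_cal Calibrated mean Ct of the telomere and
#'   albumin assays (cycles). Vectorised.
#' @param calibrator_delta_ct The calibrator's own `ct_alb - ct_tel`.
#' @param anchor_bp Absolute telomere length assigned to the calibrator
#'   (basepairs, default 5290).
#' @param sample_id Optional identifier column.
#' @return Tibble with `delta_ct`, `delta_delta_ct`, `ts_ratio`, `abs_tl_bp`.
#' @examples
#' # a sample with the calibrator's own Ct values comes back at the anchor
#' quantify_sample(13.0, 15.0, calibrator_delta_ct = 2.0)$abs_tl_bp
#' @export
quantify_sample <- function(ct_tel_cal, ct_alb_cal, calibrator_delta_ct,
                            anchor_bp = 5290, sample_id = NA_character_) {
  if (!is.finite(anchor_bp) || anchor_bp <= 0) abort("anchor_bp must be > 0")
  delta_ct <- ct_alb_cal - ct_tel_cal
  ddct <- delta_ct - calibrator_delta_ct
  ts <- 2^ddct
  tibble(
    sample_id = sample_id,
    ct_tel_calibrated = ct_tel_cal,
    ct_alb_calibrated = ct_alb_cal,
    delta_ct = delta_ct,
    delta_delta_ct = ddct,
    ts_ratio = ts,
    abs_tl_bp = ts * anchor_bp
  )
}

#' Quantify a full set of qPCR plates
#'
#' End-to-end composition of the well-level pipeline: primer-dimer wells are
#' dropped, replicates pass QC ([qc_replicates()]), per-plate calibrator
#' means give normalization factors ([plate_normalization()]), participant
#' and internal-control Cts are calibrated ([calibrate_ct()]), and each
#' sample is quantified against the across-plate calibrator delta-Ct
#' ([quantify_sample()]).
#'
#' A sample may appear on several plates (failed samples are rerun on later
#' plates); the latest non-failed result wins. Plates missing calibrator
#' wells for either assay have all their samples marked `failed`.
#'
#' @param wells Tibble of well measurements: `plate_id`, `sample_id`,
#'   `role` (`participant`, `calibrator`, `internal_control`), `assay`
#'   (`telomere`, `albumin`), `ct`, `primer_dimer` (logical).
#' @param qc_policy,min_valid Passed to [qc_replicates()].
#' @param anchor_bp Calibrator absolute telomere length in basepairs.
#' @return Object of class `telo_quant`: a list with `results` (one row per
#'   participant sample: calibrated Cts, delta-delta-Ct, T/S ratio,
#'   `abs_tl_bp`, `qc_status`), `controls` (per-plate internal-control
#'   quantifications), `precision` (inter-/intra-assay CVs), and
#'   `calibration` (per-plate normalization factors).
#' @export
quantify_plate_set <- function(wells,
                               qc_policy = c("leave_one_out_2sd", "literal_2sd"),
                               min_valid = 2,
                               anchor_bp = 5290) {
  qc_policy <- match.arg(qc_policy)
  needed <- c("plate_id", "sample_id", "role", "assay", "ct", "primer_dimer")
  missing_cols <- setdiff(needed, names(wells))
  if (length(missing_cols)) {
    abort(paste("wells table missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (any(!wells$role %in% c("participant", "calibrator", "internal_control"))) {
    abort("role must be participant, calibrator or internal_control")
  }
  if (any(!wells$assay %in% c("telomere", "albumin"))) {
    abort("assay must be telomere or albumin")
  }
  if (any(!is.finite(wells$ct) | wells$ct <= 0)) {
    abort("Ct values must be finite and positive")
  }

  plate_order <- tibble(
    plate_id = unique(wells$plate_id),
    plate_rank = seq_along(unique(wells$plate_id))
  )

  wells <- dplyr::filter(wells, !.data$primer_dimer)

  reps <- wells |>
    group_by(.data$plate_id, .data$sample_id, .data$role, .data$assay) |>
    summarise(
      qc = list(qc_replicates(.data$ct, policy = qc_policy, min_valid = min_valid)),
      .groups = "drop"
    ) |>
    tidyr::unnest("qc")

  # intra-assay precision across each sample's replicate wells (raw Ct scale)
  intra <- reps |>
    dplyr::filter(.data$role == "participant", .data$n_valid >= 2) |>
    mutate(cv_ct = purrr::map_dbl(.data$valid_cts, function(v) {
      if (mean(v) == 0) return(NA_real_)
      100 * sd(v) / mean(v)
    }))

  cal <- reps |>
    dplyr::filter(.data$role == "calibrator") |>
    select("plate_id", "assay", "mean_ct") |>
    tidyr::pivot_wider(names_from = "assay", values_from = "mean_ct")
  for (col in c("telomere", "albumin")) {
    if (!col %in% names(cal)) cal[[col]] <- NA_real_
  }
  cal_ok <- dplyr::filter(cal, is.finite(.data$telomere), is.finite(.data$albumin))
  if (nrow(cal_ok) == 0) abort("no plate carries complete calibrator wells")

  global <- list(
    telomere = mean(cal_ok$telomere),
    albumin = mean(cal_ok$albumin)
  )
  calibrator_delta_ct <- global$albumin - global$telomere

  calibration <- purrr::pmap_dfr(
    cal_ok,
    function(plate_id, telomere, albumin) {
      plate_normalization(
        list(telomere = telomere, albumin = albumin), global, plate_id = plate_id
      )
    }
  )

  per_assay <- reps |>
    dplyr::filter(.data$role != "calibrator") |>
    left_join(select(calibration, "plate_id", "factor_tel", "factor_alb"),
      by = "plate_id"
    ) |>
    mutate(
      plate_has_calibrator = is.finite(.data$factor_tel) & is.finite(.data$factor_alb),
      factor = if_else(.data$assay == "telomere", .data$factor_tel, .data$factor_alb),
      ct_calibrated = if_else(.data$plate_has_calibrator,
        calibrate_ct(.data$mean_ct, if_else(.data$plate_has_calibrator, .data$factor, 1)),
        NA_real_
      )
    )

  by_sample <- per_assay |>
    select(
      "plate_id", "sample_id", "role", "assay",
      "ct_calibrated", "mean_ct", "rerun", "plate_has_calibrator"
    ) |>
    tidyr::pivot_wider(
      names_from = "assay",
      values_from = c("ct_calibrated", "mean_ct", "rerun"),
      names_sep = "."
    )
  for (col in c(
    "ct_calibrated.telomere", "ct_calibrated.albumin",
    "mean_ct.telomere", "mean_ct.albumin"
  )) {
    if (!col %in% names(by_sample)) by_sample[[col]] <- NA_real_
  }
  for (col in c("rerun.telomere", "rerun.albumin")) {
    if (!col %in% names(by_sample)) by_sample[[col]] <- NA
  }

  by_sample <- by_sample |>
    mutate(
      qc_status = dplyr::case_when(
        !.data$plate_has_calibrator ~ "failed",
        is.na(.data$ct_calibrated.telomere) | is.na(.data$ct_calibrated.albumin) ~ "rerun_needed",
        dplyr::coalesce(.data$rerun.telomere, FALSE) |
          dplyr::coalesce(.data$rerun.albumin, FALSE) ~ "rerun_needed",
        TRUE ~ "ok"
      )
    )

  quant <- quantify_sample(
    ct_tel_cal = by_sample$ct_calibrated.telomere,
    ct_alb_cal = by_sample$ct_calibrated.albumin,
    calibrator_delta_ct = calibrator_delta_ct,
    anchor_bp = anchor_bp,
    sample_id = by_sample$sample_id
  ) |>
    mutate(
      plate_id = by_sample$plate_id,
      role = by_sample$role,
      qc_status = by_sample$qc_status
    )

  controls <- dplyr::filter(quant, .data$role == "internal_control")

  # rerun resolution: the latest non-failed measurement of a participant wins
  results <- quant |>
    dplyr::filter(.data$role == "participant") |>
    left_join(plate_order, by = "plate_id") |>
    arrange(.data$sample_id, .data$plate_rank) |>
    group_by(.data$sample_id) |>
    dplyr::group_modify(function(d, key) {
      ok <- dplyr::filter(d, .data$qc_status == "ok")
      if (nrow(ok)) return(slice(ok, dplyr::n()))
      nf <- dplyr::filter(d, .data$qc_status != "failed")
      if (nrow(nf)) return(slice(nf, dplyr::n()))
      slice(d, dplyr::n())
    }) |>
    ungroup() |>
    select(-"plate_rank", -"role")

  controls_ok <- dplyr::filter(controls, .data$qc_status == "ok")
  precision <- dplyr::bind_rows(
    if (nrow(controls_ok) >= 2) {
      ic_raw_tel <- reps |>
        dplyr::filter(
          .data$role == "internal_control", .data$assay == "telomere",
          .data$plate_id %in% controls_ok$plate_id
        )
      dplyr::bind_rows(
        assay_cv(ic_raw_tel$mean_ct, label = "inter_assay_ct_tel_control"),
        assay_cv(controls_ok$abs_tl_bp, label = "inter_assay_abs_tl_control")
      )
    },
    if (nrow(intra)) {
      intra |>
        group_by(.data$assay) |>
        summarise(
          label = paste0("intra_assay_ct_", first(.data$assay), "_max"),
          mean_value = mean(.data$cv_ct, na.rm = TRUE),
          sd_value = sd(.data$cv_ct),
          cv_percent = max(.data$cv_ct, na.rm = TRUE),
          .groups = "drop"
        ) |>
        select(-"assay")
    }
  )

  structure(
    list(
      results = results,
      controls = controls,
      precision = precision %||% tibble(),
      calibration = calibration,
      anchor_bp = anchor_bp,
      calibrator_delta_ct = calibrator_delta_ct
    ),
    class = "telo_quant"
  )
}

#' @export
print.telo_quant <- function(x, ...) {
  cat("<telo_quant> ", nrow(x$results), " participant samples on ",
    nrow(x$calibration), " plates; anchor ", x$anchor_bp, " bp\n",
    sep = ""
  )
  print(dplyr::count(x$results, .data$qc_status))
  invisible(x)
}

#' @rdname quantify_plate_set
#' @param x A `telo_quant` object.
#' @param ... Unused.
#' @method tidy telo_quant
#' @export
tidy.telo_quant <- function(x, ...) {
  select(
    x$results, "sample_id", "ct_tel_calibrated", "ct_alb_calibrated",
    "delta_delta_ct", "ts_ratio", "abs_tl_bp", "qc_status"
  )
}

#' @rdname quantify_plate_set
#' @method glance telo_quant
#' @export
glance.telo_quant <- function(x, ...) {
  tibble(
    n_samples = nrow(x$results),
    n_ok = sum(x$results$qc_status == "ok"),
    n_rerun_needed = sum(x$results$qc_status == "rerun_needed"),
    n_failed = sum(x$results$qc_status == "failed"),
    n_plates = nrow(x$calibration),
    anchor_bp = x$anchor_bp
  )
}
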