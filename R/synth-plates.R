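#' Synthesize well-level qPCR plates from telomere lengths
#'
#' Inverse of [quantify_plate_set()]: given per-sample telomere lengths,
#' emits the well table a plate reader would produce. Per sample the albumin
#' Ct is drawn around 15 cycles, and the ideal telomere Ct follows from the
#' delta-delta-Ct identity `ct_tel = ct_alb - log2(tl / anchor_bp) -
#' calibrator_delta_ct`. Participants get quadruplicate wells; the
#' calibrator (at `anchor_bp`) and the internal control get triplicates on
#' every plate. Plate batch effects are multiplicative Ct shifts by default,
#' the form the plate normalization cancels exactly; an additive variant is
#' available for sensitivity checks.
#'
#' @param samples Tibble with columns `sample_id` and `tl_bp` (> 0).
#' @param seed Integer seed.
#' @param well_sd Per-well Ct noise SD in cycles (default 0).
#' @param plate_shift_sd SD of the per-plate batch effect: on the log scale
#'   of the multiplicative Ct factor, or in cycles when
#'   `plate_shift = "additive"` (default 0).
#' @param plate_shift `"multiplicative"` (default) or `"additive"`.
#' @param plate_capacity Participants per 384-well plate (default 90:
#'   90 x 4 + 2 controls x 3 = 366 wells).
#' @param anchor_bp Calibrator absolute telomere length (bp).
#' @param calibrator_delta_ct Calibrator `ct_alb - ct_tel` (cycles).
#' @param control_tl_bp Internal-control telomere length (bp, default 2577).
#' @param mu_alb Mean albumin Ct (cycles).
#' @return Well table: `plate_id`, `sample_id`, `role`, `assay`, `ct`,
#'   `primer_dimer` — the input schema of [quantify_plate_set()].
#' @examples
#' w <- synthesize_plate_cts(tibble::tibble(sample_id = "s1", tl_bp = 5290))
#' @export
synthesize_plate_cts <- function(samples,
                                 seed = 1L,
                                 well_sd = 0,
                                 plate_shift_sd = 0,
                                 plate_shift = c("multiplicative", "additive"),
                                 plate_capacity = 90,
                                 anchor_bp = 5290,
                                 calibrator_delta_ct = 2,
                                 control_tl_bp = 2577,
                                 mu_alb = 15) {
  plate_shift <- match.arg(plate_shift)
  if (!all(c("sample_id", "tl_bp") %in% names(samples))) {
    abort("samples needs columns sample_id and tl_bp")
  }
  if (any(!is.finite(samples$tl_bp) | samples$tl_bp <= 0)) {
    abort("telomere lengths must be finite and positive")
  }
  set.seed(seed)

  n <- nrow(samples)
  n_plates <- ceiling(n / plate_capacity)
  plate_of <- rep(seq_len(n_plates), each = plate_capacity)[seq_len(n)]

  layout <- dplyr::bind_rows(
    tibble(
      plate = plate_of,
      sample_id = samples$sample_id,
      role = "participant",
      tl_bp = samples$tl_bp,
      n_wells = 4L
    ),
    tidyr::crossing(
      plate = seq_len(n_plates),
      tibble(
        sample_id = c("K562", "NTERA2"),
        role = c("calibrator", "internal_control"),
        tl_bp = c(anchor_bp, control_tl_bp),
        n_wells = 3L
      )
    )
  ) |>
    tidyr::uncount(.data$n_wells)

  m <- nrow(layout)
  # each well carries independent noise on both reads
  ct_alb <- mu_alb + rnorm(m, 0, well_sd)
  ct_tel <- mu_alb - log2(layout$tl_bp / anchor_bp) - calibrator_delta_ct +
    rnorm(m, 0, well_sd)

  shift <- rnorm(n_plates, 0, plate_shift_sd)
  if (plate_shift == "multiplicative") {
    fac <- exp(shift)[layout$plate]
    ct_tel <- ct_tel * fac
    ct_alb <- ct_alb * fac
  } else {
    ct_tel <- ct_tel + shift[layout$plate]
    ct_alb <- ct_alb + shift[layout$plate]
  }

  out <- dplyr::bind_rows(
    layout |> mutate(assay = "telomere", ct = ct_tel),
    layout |> mutate(assay = "albumin", ct = ct_alb)
  ) |>
    mutate(
      plate_id = sprintf("plate%03d", .data$plate),
      primer_dimer = FALSE
    ) |>
    select("plate_id", "sample_id", "role", "assay", "ct", "primer_dimer") |>
    arrange(.data$plate_id, .data$sample_id, .data$assay)
  out
}
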