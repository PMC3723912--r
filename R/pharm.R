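#' Dose-response curve of free-running period versus inhibitor dose
#'
#' Summarises fitted periods per dose and reports the lengthening relative to
#' the paired vehicle plate. Pairing follows the plate-layout convention of
#' comparing each treated well to the identical well position on a different
#' plate: within each dose, treated and control fits are matched on `pair_by`
#' (default `well`). Unmatched wells are dropped with a warning; a dose with
#' no matched control pairs is an error.
#'
#' @param treated Fit tibble from [fit_rhythms()] for treated wells; must
#'   contain `dose_uM`, `period_h`, `rhythmic`, and the `pair_by` column.
#' @param controls Fit tibble for the paired vehicle wells (same schema).
#' @param pair_by Column matching treated wells to control wells (default
#'   `"well"`).
#' @return Tibble with one row per dose: `dose_uM`, `mean_period`,
#'   `sd_period`, `n`, `control_mean_period`, `delta_period` (treated minus
#'   paired vehicle mean, hours), plus carried `line`/`treatment` labels.
#' @export
dose_response <- function(treated, controls, pair_by = "well") {
  for (tb in list(treated, controls)) {
    assert_that(all(c("dose_uM", "period_h", "rhythmic", pair_by) %in% names(tb)),
                "fit tables need dose_uM, period_h, rhythmic and the pairing column")
  }
  treated <- dplyr::filter(treated, .data$rhythmic, is.finite(.data$period_h))
  controls <- dplyr::filter(controls, .data$rhythmic, is.finite(.data$period_h))
  doses <- sort(unique(treated$dose_uM))
  rows <- purrr::map(doses, function(d) {
    tr <- dplyr::filter(treated, .data$dose_uM == d)
    ct <- dplyr::filter(controls, .data$dose_uM == d)
    matched <- intersect(tr[[pair_by]], ct[[pair_by]])
    unmatched <- setdiff(union(tr[[pair_by]], ct[[pair_by]]), matched)
    if (length(matched) < 2) {
      stop("pairing error at dose ", d, " uM: no matched control pairs",
           if (length(unmatched)) paste0(" (unmatched wells: ",
                                         paste(unmatched, collapse = ", "), ")"),
           call. = FALSE)
    }
    if (length(unmatched) > 0) {
      warning("dose ", d, " uM: dropping unmatched wells: ",
              paste(unmatched, collapse = ", "), call. = FALSE)
    }
    tr <- tr[match(matched, tr[[pair_by]]), ]
    ct <- ct[match(matched, ct[[pair_by]]), ]
    tibble::tibble(
      dose_uM = d,
      mean_period = mean(tr$period_h),
      sd_period = sd(tr$period_h),
      n = nrow(tr),
      control_mean_period = mean(ct$period_h),
      delta_period = mean(tr$period_h) - mean(ct$period_h),
      line = if ("line" %in% names(tr)) tr$line[1] else NA_character_,
      compound = if ("treatment" %in% names(tr)) tr$treatment[1] else NA_character_
    )
  })
  dplyr::bind_rows(rows)
}

# Per-pair wrapped phase differences in hours, delays negative.
paired_phase_diffs <- function(treated, vehicle, period_ref, pair_by = "well") {
  matched <- intersect(treated[[pair_by]], vehicle[[pair_by]])
  if (length(matched) < length(union(treated[[pair_by]], vehicle[[pair_by]]))) {
    warning("dropping unmatched wells: ",
            paste(setdiff(union(treated[[pair_by]], vehicle[[pair_by]]), matched),
                  collapse = ", "), call. = FALSE)
  }
  tr <- treated[match(matched, treated[[pair_by]]), ]
  ve <- vehicle[match(matched, vehicle[[pair_by]]), ]
  # a later treated peak is a phase delay, reported negative by convention
  wrap_half_period(-(tr$phase_h - ve$phase_h), period_ref)
}

#' Phase change between treated and vehicle rhythms
#'
#' Computes the phase change after a perturbing pulse as the circular mean of
#' per-pair differences in the peak time of the fitted fundamental component,
#' converted to minutes and wrapped into `(-T*30, T*30]` minutes. Phase
#' delays (treated peak later than vehicle) are negative by consensus; a
#' shift of exactly half a cycle reports as an advance (+T/2).
#'
#' @param treated,vehicle Fit tibbles (schema of [fit_rhythms()]); all wells
#'   must be rhythmic.
#' @param period_ref Reference period T in hours used for wrapping and
#'   angle conversion.
#' @param pair_by Pairing column (default `"well"`).
#' @return List: `delta_phi_min` (circular mean, minutes), `sd_min` (circular
#'   SD, minutes), `n` (pairs), `p_value` (two-tailed t-test of the per-pair
#'   wrapped differences against zero), `pair_diffs_min`.
#' @export
phase_change <- function(treated, vehicle, period_ref, pair_by = "well") {
  assert_that(period_ref > 0, "`period_ref` must be > 0")
  for (tb in list(treated, vehicle)) {
    assert_that(all(c("phase_h", "rhythmic", pair_by) %in% names(tb)),
                "fit tables need phase_h, rhythmic and the pairing column")
  }
  # wells failing the rhythmicity gate are dropped with their pairs; a group
  # that is arrhythmic as a whole leaves < 2 pairs and errors below
  treated <- dplyr::filter(treated, .data$rhythmic)
  vehicle <- dplyr::filter(vehicle, .data$rhythmic)
  if (nrow(treated) < 2 || nrow(vehicle) < 2) {
    stop("arrhythmic post-washout group: phase change is undefined", call. = FALSE)
  }
  d_h <- paired_phase_diffs(treated, vehicle, period_ref, pair_by)
  n <- length(d_h)
  if (n < 2) {
    stop("arrhythmic post-washout group: fewer than 2 rhythmic pairs remain",
         call. = FALSE)
  }
  theta <- 2 * pi * d_h / period_ref
  C <- mean(cos(theta)); S <- mean(sin(theta))
  mean_h <- wrap_half_period(atan2(S, C) * period_ref / (2 * pi), period_ref)
  Rbar <- min(1, sqrt(C^2 + S^2))
  sd_h <- sqrt(pmax(0, -2 * log(Rbar))) * period_ref / (2 * pi)
  p <- if (sd(d_h) == 0) {
    if (mean(d_h) == 0) 1 else 0
  } else {
    t.test(d_h, mu = 0)$p.value
  }
  list(delta_phi_min = 60 * mean_h, sd_min = 60 * sd_h, n = n,
       p_value = p, pair_diffs_min = 60 * d_h)
}

#' Build a phase-response curve from pulse experiments
#'
#' One [phase_change()] per pulse start time, assembled into a curve sorted
#' by pulse start. Points whose phase change cannot be computed (e.g.
#' arrhythmic wells) are flagged in the `note` column rather than aborting
#' the curve. Per-point raw p-values are Holm-corrected across the curve to
#' control the familywise error rate when asking which pulse times shift
#' phase; `significant` refers to the corrected values.
#'
#' @param fits Fit tibble covering all pulse experiments, with columns
#'   `pulse_start_zt`, `treatment`, `phase_h`, `rhythmic` and the pairing
#'   column.
#' @param vehicle_label Value of `treatment` identifying vehicle wells.
#' @param period_ref Reference period in hours (default 24).
#' @param pair_by Pairing column (default `"well"`).
#' @return Tibble with one row per pulse start: `pulse_start_zt`,
#'   `delta_phi_min`, `sd_min`, `n`, `p_value`, `p_holm`, `significant`,
#'   `note`.
#' @export
build_prc <- function(fits, vehicle_label = "vehicle", period_ref = 24,
                      pair_by = "well") {
  assert_that(all(c("pulse_start_zt", "treatment", "phase_h", "rhythmic",
                    pair_by) %in% names(fits)),
              "fits need pulse_start_zt, treatment, phase_h, rhythmic and the pairing column")
  starts <- sort(unique(fits$pulse_start_zt))
  assert_that(length(starts) >= 1, "no pulse experiments found")
  rows <- purrr::map(starts, function(zt) {
    sub <- dplyr::filter(fits, .data$pulse_start_zt == zt)
    tr <- dplyr::filter(sub, .data$treatment != vehicle_label)
    ve <- dplyr::filter(sub, .data$treatment == vehicle_label)
    out <- tryCatch(
      phase_change(tr, ve, period_ref, pair_by),
      error = function(e) e
    )
    if (inherits(out, "error")) {
      tibble::tibble(pulse_start_zt = zt, delta_phi_min = NA_real_,
                     sd_min = NA_real_, n = NA_integer_, p_value = NA_real_,
                     note = conditionMessage(out))
    } else {
      tibble::tibble(pulse_start_zt = zt, delta_phi_min = out$delta_phi_min,
                     sd_min = out$sd_min, n = out$n, p_value = out$p_value,
                     note = NA_character_)
    }
  })
  prc <- dplyr::bind_rows(rows)
  prc$p_holm <- p.adjust(prc$p_value, method = "holm")
  prc$significant <- !is.na(prc$p_holm) & prc$p_holm < 0.05
  dplyr::relocate(prc, "note", .after = "significant")
}
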