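test_that("vehicle-vs-vehicle dose response shows no period difference", {
  base <- trace_params(noise_sd = 60)
  sim <- simulate_dose_response(base, doses = 0,
                                effect_fun = function(d) 0,
                                n_replicates = 8, seed = 21)
  fits <- fit_rhythms(sim$traces)
  dr <- dose_response(dplyr::filter(fits, treatment != "vehicle"),
                      dplyr::filter(fits, treatment == "vehicle"))
  expect_equal(dr$delta_period, 0, tolerance = 0.3)
})

test_that("dose_response errors when control pairing is missing", {
  tr <- fits_tbl(phase_h = c(5, 5, 5), dose_uM = 1)
  ct <- fits_tbl(phase_h = c(5, 5), well = c("W8", "W9"), dose_uM = 1,
                 treatment = "vehicle")
  expect_error(dose_response(tr, ct), "pairing error.*unmatched")
})

test_that("a Hill-shaped period effect is recovered at the top dose", {
  base <- trace_params(noise_sd = 100)   # noise 20% of amplitude
  sim <- simulate_dose_response(base, doses = c(0, 1, 4, 16),
                                n_replicates = 8, seed = 31)
  fits <- fit_rhythms(sim$traces)
  dr <- dose_response(dplyr::filter(fits, treatment != "vehicle"),
                      dplyr::filter(fits, treatment == "vehicle"))
  truth <- sim$truth$true_period_treated - sim$truth$true_period_vehicle
  top <- which.max(dr$dose_uM)
  expect_equal(dr$delta_period[top], truth[length(truth)], tolerance = 0.3)
  # monotone generated effect -> recovered means non-decreasing within noise
  expect_true(all(diff(dr$mean_period) > -0.3))
})

test_that("phase_change reproduces hand-computed shifts and wrap rules", {
  ve <- fits_tbl(phase_h = rep(12, 4), treatment = "vehicle")
  tr <- fits_tbl(phase_h = rep(14.5, 4))
  pc <- phase_change(tr, ve, period_ref = 24)
  expect_equal(pc$delta_phi_min, -150)
  expect_equal(pc$sd_min, 0)

  # identical groups: exactly zero
  pc0 <- phase_change(ve, ve, period_ref = 24)
  expect_equal(pc0$delta_phi_min, 0)

  # a 23 h apparent delay wraps to a 60 min advance
  tr23 <- fits_tbl(phase_h = rep(12 + 23, 4) %% 24)
  pc23 <- phase_change(tr23, ve, period_ref = 24)
  expect_equal(pc23$delta_phi_min, 60)
})

test_that("phase_change sign flips when groups swap and is shift-invariant", {
  set.seed(7)
  ph_v <- (10 + rnorm(6, 0, 0.3)) %% 24
  ph_t <- (ph_v + 1.5) %% 24
  ve <- fits_tbl(ph_v, treatment = "vehicle")
  tr <- fits_tbl(ph_t)
  fwd <- phase_change(tr, ve, 24)
  rev <- phase_change(ve, tr, 24)
  expect_equal(fwd$delta_phi_min, -rev$delta_phi_min, tolerance = 1e-9)
  # adding a constant to both groups' phases changes nothing
  ve2 <- fits_tbl((ph_v + 5) %% 24, treatment = "vehicle")
  tr2 <- fits_tbl((ph_t + 5) %% 24)
  expect_equal(phase_change(tr2, ve2, 24)$delta_phi_min, fwd$delta_phi_min,
               tolerance = 1e-9)
})

test_that("delta-phi maps shifts differing by a full cycle to one value", {
  ve <- fits_tbl(phase_h = rep(6, 4), treatment = "vehicle")
  tr_a <- fits_tbl(phase_h = rep(8, 4))         # 2 h delay
  tr_b <- fits_tbl(phase_h = rep((8 + 24) %% 24, 4))
  expect_equal(phase_change(tr_a, ve, 24)$delta_phi_min,
               phase_change(tr_b, ve, 24)$delta_phi_min)
})

test_that("phase_change demands rhythmic pairs", {
  ve <- fits_tbl(phase_h = rep(12, 4), treatment = "vehicle")
  tr <- fits_tbl(phase_h = rep(13, 4))
  tr$rhythmic <- FALSE
  expect_error(phase_change(tr, ve, 24), "arrhythmic")
})

test_that("build_prc flags failing points instead of aborting", {
  good <- dplyr::bind_rows(
    fits_tbl(rep(12, 4), treatment = "vehicle", pulse_start_zt = 0),
    fits_tbl(rep(13, 4), pulse_start_zt = 0))
  bad <- dplyr::bind_rows(
    fits_tbl(rep(12, 4), treatment = "vehicle", pulse_start_zt = 12),
    dplyr::mutate(fits_tbl(rep(13, 4), pulse_start_zt = 12), rhythmic = FALSE))
  prc <- build_prc(dplyr::bind_rows(good, bad))
  expect_equal(nrow(prc), 2)
  expect_true(is.na(prc$delta_phi_min[prc$pulse_start_zt == 12]))
  expect_match(prc$note[prc$pulse_start_zt == 12], "arrhythmic")
  expect_false(is.na(prc$delta_phi_min[prc$pulse_start_zt == 0]))
})

test_that("treated == vehicle data gives a curve of zeros", {
  fits <- dplyr::bind_rows(purrr::map(c(0, 6, 12, 18), function(zt) {
    ph <- rep(c(4, 9, 15, 21), length.out = 4)
    dplyr::bind_rows(fits_tbl(ph, treatment = "vehicle", pulse_start_zt = zt),
                     fits_tbl(ph, pulse_start_zt = zt))
  }))
  prc <- build_prc(fits)
  expect_equal(prc$delta_phi_min, rep(0, 4))
  expect_false(any(prc$significant))
})

test_that("a generated delay-only PRC is recovered with correct shape", {
  base <- trace_params(noise_sd = 100)
  sim <- simulate_prc_experiment(base, pulse_starts = seq(0, 22, 2),
                                 true_shift_fun = delay_prc_shift(peak_zt = 12,
                                                                  max_delay_min = -150),
                                 n_replicates = 8, seed = 17)
  fits <- fit_rhythms(sim$traces)
  prc <- build_prc(fits)
  # extremum position within +/- 2 h of the generated ZT12 peak
  ext <- prc$pulse_start_zt[which.min(prc$delta_phi_min)]
  expect_lte(abs(ext - 12), 2)
  # every truly delayed phase recovered with negative sign
  delayed <- sim$truth$pulse_start_zt[sim$truth$true_shift_min < -30]
  expect_true(all(prc$delta_phi_min[prc$pulse_start_zt %in% delayed] < 0))
  # magnitude at the peak close to the constructed -150 min
  expect_equal(min(prc$delta_phi_min), -150, tolerance = 45)
})
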