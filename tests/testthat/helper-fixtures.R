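# Shared fixture builders; everything is generated in code at test time.

noiseless_params <- function(period = 24, phase = 6, duration = 96,
                             damping_rate = 0, amplitude = 500, drift = 0) {
  trace_params(noise_sd = 0, drift = drift, damping_rate = damping_rate,
               period = period, phase = phase, amplitude = amplitude,
               duration = duration)
}

# small fit tibble for pharm-level tests, bypassing trace fitting
fits_tbl <- function(phase_h, period_h = 24, well = paste0("W", seq_along(phase_h)),
                     treatment = "treated", pulse_start_zt = NA_real_,
                     dose_uM = NA_real_) {
  tibble::tibble(plate = "P", well = well, period_h = period_h,
                 phase_h = phase_h, amplitude = 100, rss = 1,
                 rhythmic = TRUE, treatment = treatment,
                 pulse_start_zt = pulse_start_zt, dose_uM = dose_uM)
}

# minimal occurrence table: one row per (site, occurrence)
peptide_tbl <- function(protein_id, pos, residues = "S", ab) {
  stopifnot(is.list(ab))
  tibble::tibble(protein_id = protein_id, peptide_seq = "PEPTIDE",
                 site_positions = as.character(pos), residues = residues,
                 charge = 2L, missed_cuts = 0L, other_mods = "",
                 !!!ab)
}
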