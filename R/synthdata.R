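#' Parameters for a synthetic bioluminescence trace
#'
#' Defines the generative model for one reporter trace recorded after
#' transfer to constant light:
#' \deqn{x(t) = baseline + drift \cdot t +
#'   amplitude \cdot e^{-damping\_rate \cdot t}
#'   \cos\!\big(2\pi (t - phase)/period\big) + \epsilon_t,}
#' with \eqn{\epsilon_t \sim N(0, noise\_sd^2)} i.i.d. The damped cosine plus
#' linear drift is the minimal model matching the morphology of reporter
#' rhythms damping out under constant light.
#'
#' @param baseline Mean luminescence level (counts).
#' @param drift Linear drift (counts/hour).
#' @param amplitude Initial amplitude of the rhythmic component (counts).
#' @param damping_rate Exponential damping rate (1/hour, >= 0).
#' @param period Free-running period (hours, > 0).
#' @param phase Time of the first peak of the rhythmic component (hours).
#' @param noise_sd SD of additive Gaussian noise (counts, >= 0).
#' @param sampling_interval Sampling cadence (hours); must be <= period/8.
#' @param duration Recording length (hours); must cover >= 2 periods.
#' @return A validated `trace_params` list.
#' @export
trace_params <- function(baseline = 1000, drift = 0, amplitude = 500,
                         damping_rate = 0.005, period = 24, phase = 6,
                         noise_sd = 0, sampling_interval = 1, duration = 120) {
  p <- list(
    baseline = baseline, drift = drift, amplitude = amplitude,
    damping_rate = damping_rate, period = period, phase = phase,
    noise_sd = noise_sd, sampling_interval = sampling_interval,
    duration = duration
  )
  for (nm in names(p)) {
    assert_that(is.numeric(p[[nm]]) && length(p[[nm]]) == 1L && is.finite(p[[nm]]),
                paste0("trace_params: `", nm, "` must be a single finite number"))
  }
  assert_that(p$period > 0, "trace_params: `period` must be > 0")
  assert_that(p$amplitude >= 0, "trace_params: `amplitude` must be >= 0")
  assert_that(p$damping_rate >= 0, "trace_params: `damping_rate` must be >= 0")
  assert_that(p$noise_sd >= 0, "trace_params: `noise_sd` must be >= 0")
  assert_that(p$duration >= 2 * p$period,
              "trace_params: `duration` must cover at least two periods (duration >= 2*period)")
  assert_that(p$sampling_interval > 0 && p$sampling_interval <= p$period / 8,
              "trace_params: `sampling_interval` must be positive and <= period/8")
  structure(p, class = "trace_params")
}

# Noiseless expectation of the trace model on a time grid.
trace_mean <- function(params, times) {
  params$baseline + params$drift * times +
    params$amplitude * exp(-params$damping_rate * times) *
      cos(2 * pi * (times - params$phase) / params$period)
}

#' Simulate one luminescence trace
#'
#' Deterministic in `(params, seed)`. Ground truth (period, phase, amplitude)
#' is attached as the `"truth"` attribute.
#'
#' @param params A [trace_params()] object.
#' @param seed Integer seed.
#' @param metadata Named list of metadata columns to attach (e.g. `well`,
#'   `plate`, `line`, `treatment`, `dose_uM`, `pulse_start_zt`, `replicate`).
#' @param t_start First sampled time (hours since transfer to constant light).
#' @return A tibble with columns `time_h`, `lum`, plus metadata columns.
#' @export
simulate_trace <- function(params, seed, metadata = list(), t_start = 0) {
  if (!inherits(params, "trace_params")) params <- do.call(trace_params, params)
  times <- seq(t_start, t_start + params$duration, by = params$sampling_interval)
  mu <- trace_mean(params, times)
  eps <- if (params$noise_sd > 0) {
    with_seed(seed, rnorm(length(times), 0, params$noise_sd))
  } else {
    numeric(length(times))
  }
  out <- tibble::tibble(time_h = times, lum = mu + eps)
  for (nm in names(metadata)) out[[nm]] <- metadata[[nm]]
  attr(out, "truth") <- tibble::tibble(
    period = params$period, phase = params$phase, amplitude = params$amplitude
  )
  out
}

# Default metadata schema used by the plate-level generators.
default_meta <- function(well, plate, line, treatment, dose_uM, pulse_start_zt,
                         replicate) {
  list(well = well, plate = plate, line = line, treatment = treatment,
       dose_uM = dose_uM, pulse_start_zt = pulse_start_zt, replicate = replicate)
}

#' Simulate a plate of replicate traces for one condition
#'
#' Replicate wells share the generative parameters; each well gets an
#' independent noise stream derived from `seed`. Wells are named `W1..Wn` so
#' that a treated plate and its control plate pair by identical well position.
#'
#' @inheritParams simulate_trace
#' @param n_replicates Wells per condition (>= 2).
#' @param plate Plate identifier.
#' @param line,treatment,dose_uM,pulse_start_zt Metadata applied to all wells.
#' @return Long tibble of all wells; truth attached as attribute (one row per well).
#' @export
simulate_plate <- function(params, seed, n_replicates = 8, plate = "P1",
                           line = "CCA1-LUC", treatment = "vehicle",
                           dose_uM = 0, pulse_start_zt = NA_real_, t_start = 0) {
  assert_that(n_replicates >= 2, "simulate_plate: `n_replicates` must be >= 2")
  wells <- purrr::map(seq_len(n_replicates), function(i) {
    simulate_trace(params, seed = seed + i,
                   metadata = default_meta(
                     well = paste0("W", i), plate = plate, line = line,
                     treatment = treatment, dose_uM = dose_uM,
                     pulse_start_zt = pulse_start_zt, replicate = i),
                   t_start = t_start)
  })
  truth <- purrr::map_dfr(seq_along(wells), function(i) {
    dplyr::mutate(attr(wells[[i]], "truth"), well = paste0("W", i),
                  plate = plate, .before = 1)
  })
  out <- dplyr::bind_rows(wells)
  attr(out, "truth") <- truth
  out
}

#' Hill-shaped period lengthening used by the dose-response generator
#'
#' \eqn{\Delta T(d) = E_{max} d^{h} / (EC_{50}^{h} + d^{h})} hours.
#'
#' @param dose Dose (uM).
#' @param emax Maximal period lengthening (hours); default 7.7 h, the scale of
#'   a strong CK1 inhibitor at saturating dose.
#' @param ec50 Half-maximal dose (uM).
#' @param hill Hill coefficient.
#' @export
hill_period_effect <- function(dose, emax = 7.7, ec50 = 1, hill = 2) {
  emax * dose^hill / (ec50^hill + dose^hill)
}

#' Simulate a paired dose-response experiment
#'
#' For each dose, one treated plate (period lengthened by `effect_fun(dose)`)
#' and one paired vehicle plate with identical well positions are generated,
#' emulating the convention of comparing treated wells to the identical well
#' position on a different plate.
#'
#' @param base Base [trace_params()] for vehicle wells.
#' @param doses Numeric vector of doses (uM), typically including 0.
#' @param effect_fun Function dose -> period lengthening in hours.
#' @param n_replicates Wells per plate.
#' @param compound Compound label.
#' @param seed Integer seed.
#' @return List with `traces` (long tibble over all plates) and `truth`
#'   (per-dose true treated period).
#' @export
simulate_dose_response <- function(base, doses, effect_fun = hill_period_effect,
                                   n_replicates = 8, compound = "PF-670462",
                                   seed = 1) {
  plates <- purrr::imap(doses, function(d, i) {
    treated_par <- base
    treated_par$period <- base$period + effect_fun(d)
    treated_par <- do.call(trace_params, unclass(treated_par)[names(formals(trace_params))])
    tr <- simulate_plate(treated_par, seed = seed + 1000L * i,
                         plate = paste0("T", i), treatment = compound, dose_uM = d,
                         n_replicates = n_replicates)
    ve <- simulate_plate(base, seed = seed + 1000L * i + 500L,
                         plate = paste0("V", i), treatment = "vehicle", dose_uM = d,
                         n_replicates = n_replicates)
    dplyr::bind_rows(tr, ve)
  })
  truth <- tibble::tibble(
    dose_uM = doses,
    true_period_treated = base$period + effect_fun(doses),
    true_period_vehicle = base$period
  )
  list(traces = dplyr::bind_rows(plates), truth = truth)
}

#' Simulate a phase-response-curve experiment
#'
#' Emulates pulse-and-washout designs: for each pulse start time, treated and
#' vehicle plates of reinitiated rhythms are generated, sampled from washout
#' (`pulse_start + pulse_duration`) onwards. The treated rhythmic component is
#' phase-shifted by `true_shift_fun(pulse_start)` in minutes, delays negative
#' (a delay moves the peak later).
#'
#' @param base Base [trace_params()] (phase = vehicle peak time).
#' @param pulse_starts Pulse onset times (hours after transfer to constant light).
#' @param true_shift_fun Function pulse_start (h) -> phase shift in minutes
#'   (delays negative).
#' @param pulse_duration Pulse length in hours (default 4).
#' @param n_replicates Wells per plate.
#' @param seed Integer seed.
#' @param compound Compound label for treated wells.
#' @return List with `traces` and `truth` (per pulse start, true shift in minutes).
#' @export
simulate_prc_experiment <- function(base, pulse_starts,
                                    true_shift_fun = function(zt) 0,
                                    pulse_duration = 4, n_replicates = 8,
                                    seed = 1, compound = "PF-670462") {
  assert_that(all(pulse_starts >= 0 & pulse_starts <= base$period),
              "simulate_prc_experiment: pulse starts must lie within one circadian cycle of release")
  plates <- purrr::imap(pulse_starts, function(zt, i) {
    shift_min <- true_shift_fun(zt)
    treated_par <- base
    # delta-phi = -(phase_treated - phase_vehicle) * 60, so a negative
    # (delay) shift moves the treated peak later.
    treated_par$phase <- base$phase - shift_min / 60
    treated_par <- do.call(trace_params, unclass(treated_par)[names(formals(trace_params))])
    t0 <- zt + pulse_duration
    tr <- simulate_plate(treated_par, seed = seed + 2000L * i,
                         plate = paste0("T", i), treatment = compound,
                         pulse_start_zt = zt, n_replicates = n_replicates,
                         t_start = t0)
    ve <- simulate_plate(base, seed = seed + 2000L * i + 997L,
                         plate = paste0("V", i), treatment = "vehicle",
                         pulse_start_zt = zt, n_replicates = n_replicates,
                         t_start = t0)
    dplyr::bind_rows(tr, ve)
  })
  truth <- tibble::tibble(
    pulse_start_zt = pulse_starts,
    true_shift_min = vapply(pulse_starts, true_shift_fun, numeric(1))
  )
  list(traces = dplyr::bind_rows(plates), truth = truth)
}

#' Parameters for the synthetic phospho-proteomics generator
#'
#' Emulates a label-free phospho-site quantification table: sites with
#' log-normal replicate abundances in two groups, a spiked fraction carrying a
#' true fold change in group B, each site emitted as one or more peptide
#' occurrence rows (charge states / missed cleavages) whose abundances sum to
#' the site abundance, and CK1-motif labels enriched among up-spiked sites.
#'
#' @param n_proteins Number of proteins.
#' @param sites_per_protein Function `n -> integer vector` of site counts per
#'   protein (default 1-3 uniform).
#' @param n_replicates_per_group Replicates per group (default 5).
#' @param abundance_log_mean,abundance_log_sd Mean log abundance across sites
#'   and within-site replicate log-SD.
#' @param site_log_sd Between-site SD of log baseline abundance.
#' @param spike_fraction Fraction of sites given a true effect in group B.
#' @param spike_fc_fun Function `n -> fold changes` for spiked sites (default:
#'   85% up-spikes with FC ~ logN(log 3, 0.25), 15% down-spikes reciprocal).
#' @param motif_label_rate_spiked_up P(CK1 target | up-spiked site).
#' @param motif_label_rate_background P(CK1 target | other site).
#' @param peptide_multiplicity Function `n -> integer vector` of occurrence
#'   rows per site (default 1 + Poisson(0.6)).
#' @param missing_rate Missing-at-random rate for abundances (default 0).
#' @export
phospho_sim_params <- function(n_proteins = 200,
                               sites_per_protein = function(n) sample(1:3, n, replace = TRUE),
                               n_replicates_per_group = 5,
                               abundance_log_mean = log(5e4),
                               abundance_log_sd = 0.25,
                               site_log_sd = 1,
                               spike_fraction = 0.1,
                               spike_fc_fun = default_spike_fc,
                               motif_label_rate_spiked_up = 0.6,
                               motif_label_rate_background = 0.25,
                               peptide_multiplicity = function(n) 1L + rpois(n, 0.6),
                               missing_rate = 0) {
  p <- as.list(environment())
  assert_that(p$n_proteins >= 1, "phospho_sim_params: `n_proteins` must be >= 1")
  assert_that(p$n_replicates_per_group >= 2,
              "phospho_sim_params: `n_replicates_per_group` must be >= 2")
  assert_that(p$spike_fraction >= 0 && p$spike_fraction <= 1,
              "phospho_sim_params: `spike_fraction` must be in [0, 1]")
  for (nm in c("motif_label_rate_spiked_up", "motif_label_rate_background",
               "missing_rate")) {
    assert_that(p[[nm]] >= 0 && p[[nm]] <= 1,
                paste0("phospho_sim_params: `", nm, "` must be in [0, 1]"))
  }
  assert_that(is.function(p$sites_per_protein) && is.function(p$spike_fc_fun) &&
                is.function(p$peptide_multiplicity),
              "phospho_sim_params: distribution specs must be functions of n")
  structure(p, class = "phospho_sim_params")
}

#' @rdname phospho_sim_params
#' @param n Number of fold changes to draw.
#' @export
default_spike_fc <- function(n) {
  up <- runif(n) < 0.85
  fc <- exp(rnorm(n, log(3), 0.25))
  ifelse(up, fc, 1 / fc)
}

aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Random protein with S/T planted at `positions`; position - 3 is set to a
# CK1-consensus determinant (S/T/D/E) when the site is a motif target and to
# a non-determinant residue otherwise, so motif truth is encoded in sequence.
random_protein <- function(len, positions, residues, is_target) {
  s <- sample(aa_alphabet, len, replace = TRUE)
  s[positions] <- residues
  for (j in seq_along(positions)) {
    pm3 <- positions[j] - 3
    if (pm3 >= 1) {
      s[pm3] <- if (is_target[j]) sample(c("S", "T", "D", "E"), 1)
                else sample(setdiff(aa_alphabet, c("S", "T", "D", "E")), 1)
    }
  }
  paste(s, collapse = "")
}

#' Simulate a phospho-peptide quantification table with ground truth
#'
#' Per-replicate site abundances are log-normal; spiked sites have their
#' group-B mean multiplied by the true fold change. Each site is split over
#' `peptide_multiplicity` occurrence rows with fixed per-occurrence
#' proportions, so occurrence abundances sum exactly to the site abundance in
#' every replicate. Protein sequences are generated alongside with the CK1
#' consensus determinant planted (or not) at each site per its true label, so
#' motif scanning can recover the labels.
#'
#' @param params A [phospho_sim_params()] object.
#' @param seed Integer seed.
#' @param group_names Names of the two sample groups (control first).
#' @return List with `peptides` (occurrence-level tibble in the standard
#'   schema), `truth` (per-site tibble: `site_key`, `is_spiked`,
#'   `true_fc`, `is_ck1_target`, `protein_id`, `position`), and `proteins`
#'   (a named [Biostrings::AAStringSet] of generated protein sequences).
#' @export
simulate_phospho_table <- function(params, seed, group_names = c("parent", "ox")) {
  if (!inherits(params, "phospho_sim_params")) {
    stop("`params` must come from phospho_sim_params()", call. = FALSE)
  }
  assert_that(length(group_names) == 2, "exactly two group names required")
  with_seed(seed, {
    nrep <- params$n_replicates_per_group
    n_sites_per <- params$sites_per_protein(params$n_proteins)
    protein_id <- rep(paste0("PROT", sprintf("%04d", seq_len(params$n_proteins))),
                      n_sites_per)
    n_sites <- length(protein_id)

    # site positions: spread sites along each protein, 8 residues apart so
    # motif windows never overlap
    position <- unlist(purrr::map(n_sites_per, function(k) 10 + 8 * (seq_len(k) - 1)))
    residue <- sample(c("S", "T"), n_sites, replace = TRUE, prob = c(0.7, 0.3))
    site_key <- paste0(protein_id, "_", residue, position)

    is_spiked <- runif(n_sites) < params$spike_fraction
    true_fc <- rep(1, n_sites)
    if (any(is_spiked)) true_fc[is_spiked] <- params$spike_fc_fun(sum(is_spiked))
    spiked_up <- is_spiked & true_fc > 1
    p_target <- ifelse(spiked_up, params$motif_label_rate_spiked_up,
                       params$motif_label_rate_background)
    is_target <- runif(n_sites) < p_target

    # per-site baseline, then per-replicate log-normal abundances
    site_logmean <- rnorm(n_sites, params$abundance_log_mean, params$site_log_sd)
    ab_a <- matrix(rlnorm(n_sites * nrep, rep(site_logmean, nrep),
                          params$abundance_log_sd), nrow = n_sites)
    ab_b <- matrix(rlnorm(n_sites * nrep, rep(site_logmean + log(true_fc), nrep),
                          params$abundance_log_sd), nrow = n_sites)
    site_ab <- cbind(ab_a, ab_b)
    sample_names <- c(paste0(group_names[1], "_", seq_len(nrep)),
                      paste0(group_names[2], "_", seq_len(nrep)))
    colnames(site_ab) <- sample_names

    # occurrence rows: fixed per-site proportions across replicates
    mult <- pmax(1L, as.integer(params$peptide_multiplicity(n_sites)))
    rows <- purrr::map(seq_len(n_sites), function(i) {
      m <- mult[i]
      w <- rgamma(m, shape = 2)
      w <- w / sum(w)
      occ <- outer(w, site_ab[i, ])     # m x samples, columns sum to site abundance
      # peptide context around the site (placeholder sequence; real context
      # lives in the protein FASTA)
      tibble::tibble(
        protein_id = protein_id[i],
        peptide_seq = NA_character_,
        site_positions = as.character(position[i]),
        residues = residue[i],
        charge = sample(2:4, m, replace = TRUE),
        missed_cuts = sample(0:2, m, replace = TRUE),
        other_mods = "",
        tibble::as_tibble(occ)
      )
    })
    peptides <- dplyr::bind_rows(rows)

    if (params$missing_rate > 0) {
      for (sn in sample_names) {
        drop <- runif(nrow(peptides)) < params$missing_rate
        peptides[[sn]][drop] <- NA_real_
      }
    }

    # protein sequences with motif truth planted
    prot_len <- 10 + 8 * (n_sites_per - 1) + 15
    uprot <- unique(protein_id)
    seqs <- vapply(seq_along(uprot), function(k) {
      idx <- which(protein_id == uprot[k])
      random_protein(prot_len[k], position[idx], residue[idx], is_target[idx])
    }, character(1))
    proteins <- Biostrings::AAStringSet(setNames(seqs, uprot))

    # fill peptide_seq with a tryptic-like window from the protein
    pep_window <- function(pid, pos) {
      s <- as.character(proteins[[pid]])
      substr(s, max(1, pos - 7), min(nchar(s), pos + 7))
    }
    peptides$peptide_seq <- mapply(pep_window, peptides$protein_id,
                                   as.integer(peptides$site_positions))

    truth <- tibble::tibble(
      site_key = site_key, protein_id = protein_id, position = position,
      residue = residue, is_spiked = is_spiked, true_fc = true_fc,
      is_ck1_target = is_target
    )
    list(peptides = peptides, truth = truth, proteins = proteins)
  })
}
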