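trace_schema <- c("time_h", "lum", "well", "plate")

#' Read a long-format luminescence trace table
#'
#' Validates the schema, drops rows with non-finite luminescence (counting
#' them in a message), and returns the table sorted by plate, well and time
#' so each well forms a valid trace.
#'
#' @param path CSV path with at least columns `time_h`, `lum`, `well`,
#'   `plate` (plus any metadata).
#' @return Tibble of traces.
#' @export
read_traces <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(trace_schema, names(tbl))
  if (length(missing_cols) > 0) {
    stop("trace file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- !is.finite(tbl$lum)
  if (any(bad)) {
    message("read_traces: dropped ", sum(bad), " row(s) with non-finite luminescence")
    tbl <- tbl[!bad, ]
  }
  dplyr::arrange(tbl, .data$plate, .data$well, .data$time_h)
}

#' Write a trace table to CSV
#' @param traces Trace tibble.
#' @param path Output CSV path.
#' @export
write_traces <- function(traces, path) {
  readr::write_csv(traces, path)
  invisible(path)
}

#' Read an occurrence-level phospho-peptide table
#'
#' Reads the standard schema produced by [simulate_phospho_table()] or, via
#' `mapping`, an exported supplementary spreadsheet whose columns are named
#' differently. `mapping` declares which input columns hold the identifiers
#' and which are per-sample abundances, isolating spreadsheet-layout
#' differences from the analysis code.
#'
#' @param path CSV path.
#' @param mapping Optional named list with entries `protein_id`,
#'   `site_positions`, `residues` (input column names) and `abundance_cols`
#'   (named character vector: output sample name -> input column name).
#' @return Tibble in the standard occurrence schema with an
#'   `"abundance_cols"` attribute.
#' @export
read_phospho_table <- function(path, mapping = NULL) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(mapping)) {
    for (nm in c("protein_id", "site_positions", "residues")) {
      src <- mapping[[nm]] %||% nm
      assert_that(src %in% names(tbl),
                  paste0("mapped column `", src, "` not found in ", path))
      tbl[[nm]] <- tbl[[src]]
    }
    ac <- mapping$abundance_cols
    assert_that(!is.null(ac) && all(ac %in% names(tbl)),
                "mapping$abundance_cols must name existing columns")
    for (j in seq_along(ac)) tbl[[names(ac)[j] %||% ac[j]]] <- tbl[[ac[j]]]
    abundance_cols <- if (is.null(names(ac))) ac else names(ac)
  } else {
    req <- c("protein_id", "site_positions", "residues")
    missing_cols <- setdiff(req, names(tbl))
    if (length(missing_cols) > 0) {
      stop("phospho table ", path, " is missing required column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    numcols <- names(tbl)[vapply(tbl, is.numeric, logical(1))]
    abundance_cols <- setdiff(numcols, c("charge", "missed_cuts"))
  }
  attr(tbl, "abundance_cols") <- abundance_cols
  tbl
}

#' Read a site-label table (imported kinase-target predictions)
#'
#' @param path CSV with columns `site_key` and `is_target` (logical or 0/1).
#' @return Tibble with `site_key`, `is_target`, `source = "imported"`.
#' @export
read_site_labels <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("site_key", "is_target"), names(tbl))
  if (length(missing_cols) > 0) {
    stop("label file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(site_key = tbl$site_key,
                 is_target = as.logical(tbl$is_target),
                 source = "imported")
}

#' Default pipeline configuration
#'
#' All stage parameters and every seed used by a [run_pipeline()] run, as a
#' validated nested list that round-trips through YAML. Unknown keys are
#' rejected so a typo cannot silently fall back to a default.
#'
#' @param ... Overrides for top-level sections (`rhythm`, `pharm`,
#'   `phospho`, `motif`, `synth`, `seed`), each a named list merged over the
#'   defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    synth = list(
      n_replicates = 8L, doses = c(0, 0.25, 0.5, 1, 2, 4, 8, 16),
      prc_pulse_starts = seq(0, 22, by = 2), prc_peak_zt = 12,
      prc_max_delay_min = -150, n_proteins = 200L, spike_fraction = 0.1
    ),
    rhythm = list(window = c(16, 40), grid_step = 0.05, n_harmonics = 3L,
                  burn_in = 24, rhythm_gate = 2),
    pharm = list(period_ref = 24, pair_by = "well"),
    phospho = list(group_a = "parent", group_b = "ox",
                   p_threshold = 0.05, fc_threshold = 1.5),
    motif = list(n_permutations = 1e5, background = "all")
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  assert_that(length(unknown) == 0,
              paste0("unknown config section(s): ", paste(unknown, collapse = ", ")))
  cfg <- defaults
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]])) {
      bad <- setdiff(names(overrides[[nm]]), names(defaults[[nm]]))
      assert_that(length(bad) == 0,
                  paste0("unknown key(s) in config section `", nm, "`: ",
                         paste(bad, collapse = ", ")))
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full synthetic pipeline end to end
#'
#' Generates the synthetic experiments, fits rhythms, assembles the
#' dose-response and phase-response curves, collates and tests the
#' phospho table, summarises overlaps against a second comparison, runs the
#' motif-enrichment permutation test, and writes every output table plus a
#' JSON run manifest (parameters, seeds, session versions) to `out_dir`.
#' Identical config gives identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisible list with all stage results (`dose_response`, `prc`,
#'   `differential`, `overlap`, `enrichment`, `manifest`, ...).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  assert_that(inherits(config, "pipeline_config"),
              "`config` must come from pipeline_config()")
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline failed in stage `", name, "`: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  seed <- config$seed
  base <- trace_params(noise_sd = 100, amplitude = 500)

  dr_sim <- stage("simulate dose-response", simulate_dose_response(
    base, doses = config$synth$doses, n_replicates = config$synth$n_replicates,
    seed = seed))
  prc_shift <- delay_prc_shift(config$synth$prc_peak_zt,
                               config$synth$prc_max_delay_min)
  prc_sim <- stage("simulate PRC", simulate_prc_experiment(
    base, pulse_starts = config$synth$prc_pulse_starts,
    true_shift_fun = prc_shift, n_replicates = config$synth$n_replicates,
    seed = seed + 10000L))
  ph_sim <- stage("simulate phospho table", simulate_phospho_table(
    phospho_sim_params(n_proteins = config$synth$n_proteins,
                       spike_fraction = config$synth$spike_fraction),
    seed = seed + 20000L,
    group_names = c(config$phospho$group_a, config$phospho$group_b)))

  fit_with <- function(traces) {
    do.call(fit_rhythms, c(list(traces = traces),
                           config$rhythm[c("window", "grid_step", "n_harmonics",
                                           "burn_in", "rhythm_gate")]))
  }
  dr_fits <- stage("fit dose-response rhythms", fit_with(dr_sim$traces))
  prc_fits <- stage("fit PRC rhythms", fit_with(prc_sim$traces))

  dr <- stage("dose-response", dose_response(
    dplyr::filter(dr_fits, .data$treatment != "vehicle"),
    dplyr::filter(dr_fits, .data$treatment == "vehicle"),
    pair_by = config$pharm$pair_by))
  prc <- stage("phase-response curve", build_prc(
    prc_fits, period_ref = config$pharm$period_ref,
    pair_by = config$pharm$pair_by))

  sites <- stage("collate sites", collate_sites(ph_sim$peptides))
  diff <- stage("differential sites", differential_sites(
    sites, config$phospho$group_a, config$phospho$group_b,
    p_threshold = config$phospho$p_threshold,
    fc_threshold = config$phospho$fc_threshold))
  overlap <- stage("overlap counts", overlap_counts(list(main = diff)))

  labels <- stage("motif scan", scan_ck1_consensus(
    ph_sim$proteins,
    dplyr::transmute(ph_sim$truth, site_key = .data$site_key,
                     protein_id = .data$protein_id, position = .data$position)))
  enr_input <- stage("motif enrichment", {
    joined <- dplyr::inner_join(
      dplyr::filter(diff, .data$testable, is.finite(.data$fold_change)),
      labels, by = "site_key")
    if (config$motif$background == "non_differential") {
      joined <- dplyr::filter(joined, .data$is_target | .data$direction == "ns")
    }
    permutation_enrichment(joined$fold_change, joined$is_target,
                           n_permutations = config$motif$n_permutations,
                           seed = seed + 30000L)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("ck1clock")),
    r_version = R.version.string,
    config = unclass(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  out <- list(dose_response = dr, prc = prc, differential = diff,
              overlap = overlap, enrichment = enr_input,
              dr_truth = dr_sim$truth, prc_truth = prc_sim$truth,
              phospho_truth = ph_sim$truth, fits_dr = dr_fits,
              fits_prc = prc_fits, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(dr, file.path(out_dir, "dose_response.csv"))
    readr::write_csv(prc, file.path(out_dir, "prc.csv"))
    readr::write_csv(diff, file.path(out_dir, "differential_sites.csv"))
    readr::write_csv(overlap$per_comparison, file.path(out_dir, "overlap.csv"))
    jsonlite::write_json(
      list(observed_statistic = enr_input$observed_statistic,
           p_two_tailed = enr_input$p_two_tailed,
           n_permutations = enr_input$n_permutations,
           group_sizes = as.list(enr_input$group_sizes)),
      file.path(out_dir, "enrichment.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    say("outputs written to ", out_dir)
  }
  invisible(out)
}

#' Delay-only phase-response shape
#'
#' A smooth delay-only curve peaking (most negative) at `peak_zt`, used by
#' the synthetic PRC experiment: shifts are zero away from the sensitive
#' window and reach `max_delay_min` minutes at the peak.
#'
#' @param peak_zt Pulse time of maximal delay (hours).
#' @param max_delay_min Delay at the peak (minutes, negative).
#' @param width Half-width of the sensitive window (hours).
#' @return Function pulse_start (h) -> shift (minutes).
#' @export
delay_prc_shift <- function(peak_zt = 12, max_delay_min = -150, width = 6) {
  function(zt) {
    d <- abs(wrap_half_period(zt - peak_zt, 24))
    ifelse(d >= width, 0, max_delay_min * cos(pi * d / (2 * width))^2)
  }
}
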