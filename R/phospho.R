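#' Collate phospho-peptide occurrences to unique phospho-sites
#'
#' Multiple quantified occurrences of the same phosphorylation event (charge
#' states, missed cleavages, further modifications) are summed per sample
#' into one site-level profile, keyed by protein accession plus the
#' phosphorylated residue position(s). Total abundance is conserved: each
#' sample's site abundance equals the sum over its contributing records.
#'
#' @param records Occurrence-level tibble with columns `protein_id`,
#'   `site_positions` (semicolon-separated 1-based residue indices),
#'   `residues` (S/T/Y per site, semicolon-separated in register with
#'   positions), and one numeric abundance column per sample. Additional
#'   identification columns (`peptide_seq`, `charge`, `missed_cuts`,
#'   `other_mods`) are allowed and ignored.
#' @param abundance_cols Character vector of abundance column names; by
#'   default all numeric columns except `charge` and `missed_cuts`.
#' @return Site-level tibble: `site_key`, `protein_id`, `site_positions`,
#'   `residues`, `n_records`, then one summed abundance column per sample.
#'   Missing occurrence abundances are treated as absent (summed with
#'   `na.rm`); a site unobserved in a sample gets `NA`.
#' @export
collate_sites <- function(records, abundance_cols = NULL) {
  req <- c("protein_id", "site_positions", "residues")
  assert_that(all(req %in% names(records)),
              paste0("records need columns: ", paste(req, collapse = ", ")))
  if (is.null(abundance_cols)) {
    numcols <- names(records)[vapply(records, is.numeric, logical(1))]
    abundance_cols <- setdiff(numcols, c("charge", "missed_cuts"))
  }
  assert_that(length(abundance_cols) >= 1, "no abundance columns found")

  # normalise multi-site keys: sort positions, keep residues in register
  key_parts <- purrr::map2(
    strsplit(as.character(records$site_positions), ";"),
    strsplit(as.character(records$residues), ";"),
    function(pos, res) {
      pos <- as.integer(pos)
      assert_that(length(res) == length(pos) || length(res) == 1,
                  "residues must be in register with site_positions")
      if (length(res) == 1 && length(pos) > 1) res <- rep(res, length(pos))
      o <- order(pos)
      list(pos = pos[o], res = res[o])
    })
  records$site_key <- paste0(
    records$protein_id, "_",
    vapply(key_parts, function(kp) paste0(kp$res, kp$pos, collapse = ";"),
           character(1)))

  # conflicting residue annotation at the same position is a data error
  ann <- tibble::tibble(
    protein_id = rep(records$protein_id, lengths(purrr::map(key_parts, "pos"))),
    pos = unlist(purrr::map(key_parts, "pos")),
    res = unlist(purrr::map(key_parts, "res"))
  )
  conflict <- dplyr::summarise(
    dplyr::group_by(ann, .data$protein_id, .data$pos),
    n_res = dplyr::n_distinct(.data$res), .groups = "drop")
  conflict <- dplyr::filter(conflict, .data$n_res > 1)
  if (nrow(conflict) > 0) {
    stop("conflicting residue annotation at ",
         paste(paste0(conflict$protein_id, ":", conflict$pos), collapse = ", "),
         call. = FALSE)
  }

  sum_or_na <- function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
  grouped <- dplyr::group_by(records, .data$site_key)
  out <- dplyr::summarise(
    grouped,
    protein_id = dplyr::first(.data$protein_id),
    site_positions = dplyr::first(.data$site_positions),
    residues = dplyr::first(.data$residues),
    n_records = dplyr::n(),
    dplyr::across(dplyr::all_of(abundance_cols), sum_or_na),
    .groups = "drop")
  attr(out, "abundance_cols") <- abundance_cols
  out
}

#' Identify significantly differential phospho-sites
#'
#' Implements the standard label-free testing procedure for site-level
#' abundances: the two-tailed independent-samples t-test is run on
#' arcsinh-transformed abundances (the transform symmetrises right-skewed
#' label-free intensities), while the fold change is the ratio of raw
#' within-group means (group B over group A, untransformed). A site is
#' significant when `p < p_threshold` and the fold change is beyond
#' `fc_threshold` in either direction (> 1.5 or < 1/1.5 by default).
#' No multiple-testing correction enters the gate; a Benjamini-Hochberg
#' column is emitted for information only.
#'
#' @param sites Site-level tibble from [collate_sites()] (or any tibble with
#'   `site_key` and the abundance columns).
#' @param group_a,group_b Character vectors of abundance column names, or a
#'   single group prefix matched against columns named `<prefix>_<rep>`.
#'   Group A is the control; fold change is B over A.
#' @param p_threshold,fc_threshold Significance gates (defaults 0.05, 1.5).
#' @param var_equal Use the pooled-variance t-test instead of Welch
#'   (default `FALSE`).
#' @return Tibble: `site_key`, `mean_a`, `mean_b`, `fold_change`, `p_value`,
#'   `p_bh`, `significant`, `direction` (`up`/`down`/`ns`), `testable`,
#'   `note`. Sites with fewer than two finite abundances in either group, or
#'   a zero group-A mean, are reported untestable and never significant.
#' @export
differential_sites <- function(sites, group_a, group_b, p_threshold = 0.05,
                               fc_threshold = 1.5, var_equal = FALSE) {
  cols_a <- resolve_group_cols(sites, group_a)
  cols_b <- resolve_group_cols(sites, group_b)
  assert_that(length(cols_a) >= 2 && length(cols_b) >= 2,
              "each group needs >= 2 sample columns")
  key <- if ("site_key" %in% names(sites)) sites$site_key else as.character(seq_len(nrow(sites)))

  A <- as.matrix(sites[, cols_a])
  B <- as.matrix(sites[, cols_b])
  n <- nrow(sites)
  res <- tibble::tibble(
    site_key = key,
    mean_a = NA_real_, mean_b = NA_real_, fold_change = NA_real_,
    p_value = NA_real_, p_bh = NA_real_, significant = FALSE,
    direction = "ns", testable = FALSE, note = NA_character_
  )
  for (i in seq_len(n)) {
    a <- A[i, ][is.finite(A[i, ])]
    b <- B[i, ][is.finite(B[i, ])]
    if (length(a) < 2 || length(b) < 2) {
      res$note[i] <- "fewer than 2 finite abundances in a group"
      next
    }
    ma <- mean(a); mb <- mean(b)
    res$mean_a[i] <- ma; res$mean_b[i] <- mb
    if (ma == 0) {
      res$note[i] <- "zero control-group mean: fold change undefined"
      next
    }
    res$fold_change[i] <- mb / ma
    ta <- asinh(a); tb <- asinh(b)
    res$p_value[i] <- if (sd(ta) == 0 && sd(tb) == 0) {
      if (isTRUE(all.equal(mean(ta), mean(tb)))) 1 else 0
    } else {
      t.test(tb, ta, var.equal = var_equal)$p.value
    }
    res$testable[i] <- TRUE
  }
  res$p_bh <- p.adjust(res$p_value, method = "BH")
  pass_fc <- res$fold_change > fc_threshold | res$fold_change < 1 / fc_threshold
  res$significant <- res$testable & !is.na(res$p_value) &
    res$p_value < p_threshold & !is.na(pass_fc) & pass_fc
  res$direction <- dplyr::case_when(
    res$significant & res$fold_change > 1 ~ "up",
    res$significant & res$fold_change < 1 ~ "down",
    TRUE ~ "ns"
  )
  res
}

resolve_group_cols <- function(sites, group) {
  if (all(group %in% names(sites))) return(group)
  if (length(group) == 1) {
    hits <- grep(paste0("^", group, "_"), names(sites), value = TRUE)
    if (length(hits) >= 1) return(hits)
  }
  stop("cannot resolve group columns: ", paste(group, collapse = ", "),
       call. = FALSE)
}

#' Summarise direction counts and overlaps across comparisons
#'
#' Counts up- and down-regulated significant sites per comparison and the
#' pairwise intersections of significant site sets by direction — the table
#' behind a chord diagram of shared differential sites across treatments.
#'
#' @param results Named list of [differential_sites()] result tibbles.
#' @return List with `per_comparison` (comparison, up, down, total) and
#'   `pairwise` (comparison_1, comparison_2, direction, n_shared).
#' @export
overlap_counts <- function(results) {
  assert_that(is.list(results) && length(results) >= 1 && !is.null(names(results)),
              "`results` must be a named list of differential result tibbles")
  sig_sets <- purrr::map(results, function(r) {
    list(up = r$site_key[r$direction == "up"],
         down = r$site_key[r$direction == "down"])
  })
  per_comparison <- purrr::imap_dfr(sig_sets, function(s, nm) {
    tibble::tibble(comparison = nm, up = length(s$up), down = length(s$down),
                   total = length(s$up) + length(s$down))
  })
  nms <- names(results)
  pairwise <- NULL
  if (length(nms) >= 2) {
    pairs <- combn(nms, 2, simplify = FALSE)
    pairwise <- purrr::map_dfr(pairs, function(pr) {
      tibble::tibble(
        comparison_1 = pr[1], comparison_2 = pr[2],
        direction = c("up", "down"),
        n_shared = c(length(intersect(sig_sets[[pr[1]]]$up, sig_sets[[pr[2]]]$up)),
                     length(intersect(sig_sets[[pr[1]]]$down, sig_sets[[pr[2]]]$down)))
      )
    })
  }
  list(per_comparison = per_comparison, pairwise = pairwise)
}
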