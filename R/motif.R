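#' Annotate phospho-sites as CK1 targets by consensus scanning
#'
#' A deliberately simple consensus scorer for CK1 substrate context, provided
#' as a documented stand-in for trained kinase-substrate classifiers (whose
#' predictions can instead be imported as a label table). CK1 prefers an
#' acidic or phospho-primed determinant three residues upstream of the
#' acceptor: a site is called a target when position p-3 holds S, T, D or E.
#' The score counts acidic residues (D/E) in the p-7..p-1 window plus a +1
#' bonus for an S/T (primed) determinant at p-3. This is a sequence-rule
#' heuristic, not a reimplementation of any trained classifier.
#'
#' @param proteins A [Biostrings::AAStringSet] (or path to a protein FASTA).
#' @param sites Tibble with `site_key`, `protein_id` and `position` (1-based
#'   acceptor residue index).
#' @return Tibble: `site_key`, `is_target`, `score`, `source = "consensus"`.
#' @export
scan_ck1_consensus <- function(proteins, sites) {
  if (is.character(proteins)) proteins <- Biostrings::readAAStringSet(proteins)
  assert_that(methods::is(proteins, "AAStringSet"),
              "`proteins` must be an AAStringSet or FASTA path")
  # FASTA headers may carry descriptions; key on the first word
  names(proteins) <- sub("\\s.*$", "", names(proteins))
  assert_that(all(c("site_key", "protein_id", "position") %in% names(sites)),
              "`sites` needs site_key, protein_id and position columns")
  missing_prot <- setdiff(unique(sites$protein_id), names(proteins))
  assert_that(length(missing_prot) == 0,
              paste0("proteins absent from FASTA: ",
                     paste(head(missing_prot, 5), collapse = ", ")))
  seqs <- as.character(proteins)
  n <- nrow(sites)
  is_target <- logical(n); score <- numeric(n)
  for (i in seq_len(n)) {
    s <- seqs[[sites$protein_id[i]]]
    pos <- sites$position[i]
    if (pos < 1 || pos > nchar(s)) {
      stop("site position out of range: ", sites$protein_id[i], " position ",
           pos, " (protein length ", nchar(s), ")", call. = FALSE)
    }
    win <- substr(s, max(1, pos - 7), pos - 1)      # p-7..p-1, empty at pos 1
    chars <- strsplit(win, "")[[1]]
    pm3 <- if (pos - 3 >= 1) substr(s, pos - 3, pos - 3) else ""
    primed <- pm3 %in% c("S", "T")
    acidic_pm3 <- pm3 %in% c("D", "E")
    is_target[i] <- primed || acidic_pm3
    score[i] <- sum(chars %in% c("D", "E")) + as.numeric(primed)
  }
  tibble::tibble(site_key = sites$site_key, is_target = is_target,
                 score = score, source = "consensus")
}

enrichment_statistic <- function(fold_changes, labels) {
  mean(fold_changes[labels]) - mean(fold_changes[!labels])
}

check_partition <- function(fold_changes, labels) {
  assert_that(length(fold_changes) == length(labels),
              "fold_changes and labels must have equal length")
  assert_that(all(is.finite(fold_changes)), "fold changes must be finite")
  assert_that(is.logical(labels) && !anyNA(labels), "labels must be TRUE/FALSE")
  k <- sum(labels)
  if (k == 0 || k == length(labels)) {
    stop("degenerate partition: need at least one target and one non-target",
         call. = FALSE)
  }
  k
}

#' Monte-Carlo permutation test for motif enrichment in fold change
#'
#' Tests whether the mean fold change of motif-target sites differs from the
#' remaining sites. The observed statistic is
#' `mean(fc | target) - mean(fc | non-target)`. Labels are re-sampled
#' preserving the observed partition dimensions (group sizes), and the
#' two-tailed p-value is the frequency with which the absolute permuted
#' statistic equals or exceeds the absolute observed statistic (ties count
#' toward the tail). Deterministic given `seed`.
#'
#' @param fold_changes Per-site fold changes (finite reals, raw ratio scale).
#' @param labels Logical per-site target labels.
#' @param n_permutations Number of label permutations (default 1e5; raise to
#'   1e7 for publication-grade resolution of very small p-values).
#' @param seed Integer seed.
#' @param plus_one Use the (b+1)/(n+1) small-sample estimator instead of the
#'   raw tail frequency (default `FALSE`).
#' @return List of class `enrichment_result`: `observed_statistic`,
#'   `p_two_tailed`, `n_permutations`, `seed`, `group_sizes`.
#' @export
permutation_enrichment <- function(fold_changes, labels, n_permutations = 1e5,
                                   seed = 1, plus_one = FALSE) {
  k <- check_partition(fold_changes, labels)
  n <- length(fold_changes)
  obs <- enrichment_statistic(fold_changes, labels)
  total <- sum(fold_changes)
  # statistic is a function of the target-group sum alone:
  # stat = s/k - (total - s)/(n - k)
  thr <- abs(obs) * (1 - 1e-12) - 1e-12   # tolerate FP error so ties count
  n_exceed <- with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      s <- sum(fold_changes[sample.int(n, k)])
      stat <- s / k - (total - s) / (n - k)
      if (abs(stat) >= thr) hits <- hits + 1L
    }
    hits
  })
  p <- if (plus_one) (n_exceed + 1) / (n_permutations + 1) else n_exceed / n_permutations
  structure(list(observed_statistic = obs, p_two_tailed = p,
                 n_permutations = as.integer(n_permutations), seed = seed,
                 group_sizes = c(target = k, non_target = n - k)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(paste0("<enrichment_result> mean fold-change difference ",
                     "(target - non-target): %.4f\n  two-tailed p = %s ",
                     "(%d permutations, groups %d/%d, seed %s)\n"),
              x$observed_statistic,
              format(x$p_two_tailed, digits = 3), x$n_permutations,
              x$group_sizes[1], x$group_sizes[2], format(x$seed)))
  invisible(x)
}

#' Exact permutation p-value by exhaustive enumeration
#'
#' Enumerates every placement of the target labels (all `choose(n, k)`
#' subsets), computing the same statistic and two-tailed tie-inclusive tail
#' rule as [permutation_enrichment()]. Serves as the exact oracle for small
#' problems.
#'
#' @inheritParams permutation_enrichment
#' @return Exact two-tailed p-value.
#' @export
exhaustive_enrichment <- function(fold_changes, labels) {
  k <- check_partition(fold_changes, labels)
  n <- length(fold_changes)
  assert_that(choose(n, k) <= 1e6,
              "combinatorial bound exceeded: choose(n, k) must be <= 1e6")
  obs <- enrichment_statistic(fold_changes, labels)
  total <- sum(fold_changes)
  thr <- abs(obs) * (1 - 1e-12) - 1e-12
  sums <- combn(fold_changes, k, FUN = sum)
  stats <- sums / k - (total - sums) / (n - k)
  mean(abs(stats) >= thr)
}
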