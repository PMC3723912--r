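test_that("collation sums occurrences of the same site", {
  recs <- peptide_tbl(protein_id = c("P1", "P1"), pos = c("12", "12"),
                      ab = list(s1 = c(100, 50), s2 = c(10, 20)))
  sites <- collate_sites(recs)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$s1, 150)
  expect_equal(sites$s2, 30)
  expect_equal(sites$n_records, 2)
})

test_that("distinct sites pass through unchanged", {
  recs <- peptide_tbl(protein_id = c("P1", "P2"), pos = c("12", "12"),
                      ab = list(s1 = c(100, 50)))
  sites <- collate_sites(recs)
  expect_equal(nrow(sites), 2)
  expect_setequal(sites$s1, c(100, 50))
})

test_that("multi-site keys are order-normalised and residues kept in register", {
  recs <- peptide_tbl(protein_id = c("P1", "P1"),
                      pos = c("12;15", "15;12"),
                      residues = c("S;T", "T;S"),
                      ab = list(s1 = c(10, 20)))
  sites <- collate_sites(recs)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$site_key, "P1_S12;T15")
  expect_equal(sites$s1, 30)
})

test_that("conflicting residue annotation is a named data error", {
  recs <- peptide_tbl(protein_id = c("P1", "P1"), pos = c("12", "12"),
                      residues = c("S", "T"), ab = list(s1 = c(1, 2)))
  expect_error(collate_sites(recs), "conflicting residue.*P1:12")
})

test_that("collation conserves total abundance on randomised tables", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 60
    recs <- peptide_tbl(
      protein_id = sample(paste0("P", 1:12), n, replace = TRUE),
      pos = as.character(sample(c(5, 9, 14, 22), n, replace = TRUE)),
      ab = list(a1 = rlnorm(n, 8), a2 = rlnorm(n, 8), b1 = rlnorm(n, 8)))
    recs <- recs[sample(n), ]
    sites <- collate_sites(recs)
    for (cl in c("a1", "a2", "b1")) {
      expect_equal(sum(sites[[cl]]), sum(recs[[cl]]))
    }
  }
})

test_that("differential_sites applies the transform/test/gate procedure", {
  # clear up-regulation: raw means 300 vs 100
  sites <- tibble::tibble(
    site_key = c("up", "flat"),
    a_1 = c(98, 200), a_2 = c(102, 201), a_3 = c(100, 199),
    a_4 = c(99, 200), a_5 = c(101, 200),
    b_1 = c(297, 200), b_2 = c(305, 199), b_3 = c(300, 201),
    b_4 = c(295, 200), b_5 = c(303, 200))
  res <- differential_sites(sites, "a", "b")
  up <- res[res$site_key == "up", ]
  expect_true(up$significant)
  expect_equal(up$direction, "up")
  expect_equal(up$fold_change, 3, tolerance = 0.01)
  expect_equal(res$direction[res$site_key == "flat"], "ns")
})

test_that("small fold changes fail the gate regardless of p-value", {
  # fc = 1.2 with tiny within-group spread: p well below 0.05, still ns
  sites <- tibble::tibble(
    site_key = "s",
    a_1 = 100.0, a_2 = 100.1, a_3 = 99.9, a_4 = 100.05, a_5 = 99.95,
    b_1 = 120.0, b_2 = 120.1, b_3 = 119.9, b_4 = 120.05, b_5 = 119.95)
  res <- differential_sites(sites, "a", "b")
  expect_lt(res$p_value, 0.001)
  expect_equal(res$fold_change, 1.2, tolerance = 1e-6)
  expect_false(res$significant)
  expect_equal(res$direction, "ns")
})

test_that("identical groups give fc 1 and p ~ 1", {
  v <- c(100, 110, 90, 105, 95)
  sites <- tibble::tibble(site_key = "s",
                          !!!setNames(as.list(v), paste0("a_", 1:5)),
                          !!!setNames(as.list(v), paste0("b_", 1:5)))
  res <- differential_sites(sites, "a", "b")
  expect_equal(res$fold_change, 1)
  expect_equal(res$p_value, 1, tolerance = 1e-9)
  expect_false(res$significant)
})

test_that("t-test p-values match the closed-form Welch oracle to 1e-10", {
  a <- c(120.3, 98.7, 111.2, 105.9, 131.4)
  b <- c(260.1, 231.8, 301.2, 244.4, 287.3)
  sites <- tibble::tibble(site_key = "s",
                          !!!setNames(as.list(a), paste0("g1_", 1:5)),
                          !!!setNames(as.list(b), paste0("g2_", 1:5)))
  res <- differential_sites(sites, "g1", "g2")
  # closed-form Welch on arcsinh-transformed vectors
  x <- asinh(a); y <- asinh(b)
  se2 <- var(x) / 5 + var(y) / 5
  tstat <- (mean(y) - mean(x)) / sqrt(se2)
  df <- se2^2 / ((var(x) / 5)^2 / 4 + (var(y) / 5)^2 / 4)
  p_ref <- 2 * pt(-abs(tstat), df)
  expect_equal(res$p_value, p_ref, tolerance = 1e-10)
  # fold change comes from raw means, never the transform
  expect_equal(res$fold_change, mean(b) / mean(a), tolerance = 1e-12)
})

test_that("sample order within a group does not matter", {
  set.seed(12)
  a <- rlnorm(5, 5); b <- rlnorm(5, 5.5)
  s1 <- tibble::tibble(site_key = "s",
                       !!!setNames(as.list(a), paste0("a_", 1:5)),
                       !!!setNames(as.list(b), paste0("b_", 1:5)))
  s2 <- tibble::tibble(site_key = "s",
                       !!!setNames(as.list(a[c(3, 1, 5, 2, 4)]), paste0("a_", 1:5)),
                       !!!setNames(as.list(b[c(2, 5, 1, 4, 3)]), paste0("b_", 1:5)))
  r1 <- differential_sites(s1, "a", "b")
  r2 <- differential_sites(s2, "a", "b")
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$fold_change, r2$fold_change)
})

test_that("untestable and zero-mean sites are flagged, not dropped", {
  sites <- tibble::tibble(
    site_key = c("sparse", "zeroA"),
    a_1 = c(10, 0), a_2 = c(NA, 0), a_3 = c(NA, 0), a_4 = c(NA, 0), a_5 = c(NA, 0),
    b_1 = c(20, 50), b_2 = c(21, 60), b_3 = c(19, 55), b_4 = c(20, 52), b_5 = c(22, 58))
  res <- differential_sites(sites, "a", "b")
  expect_equal(nrow(res), 2)
  expect_false(any(res$testable))
  expect_false(any(res$significant))
  expect_match(res$note[res$site_key == "sparse"], "finite")
  expect_match(res$note[res$site_key == "zeroA"], "zero")
})

test_that("overlap_counts handles identical, disjoint and random sets", {
  mk <- function(keys_up, keys_down = character()) {
    tibble::tibble(site_key = c(keys_up, keys_down),
                   direction = c(rep("up", length(keys_up)),
                                 rep("down", length(keys_down))),
                   significant = TRUE)
  }
  a <- mk(c("s1", "s2"), "s3")
  oc_same <- overlap_counts(list(x = a, y = a))
  expect_equal(oc_same$per_comparison$total, c(3, 3))
  expect_equal(oc_same$pairwise$n_shared, c(2, 1))

  b <- mk(c("t1"), c("t2", "t3"))
  oc_disj <- overlap_counts(list(x = a, y = b))
  expect_equal(oc_disj$pairwise$n_shared, c(0, 0))

  # inclusion-exclusion on random sets
  set.seed(5)
  u <- paste0("s", 1:40)
  A <- mk(sample(u, 15))
  B <- mk(sample(u, 20))
  oc <- overlap_counts(list(A = A, B = B))
  inter <- oc$pairwise$n_shared[oc$pairwise$direction == "up"]
  union_size <- length(union(A$site_key, B$site_key))
  expect_equal(union_size, 15 + 20 - inter)
})
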