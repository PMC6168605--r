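simple_callset <- function(pos, gt = "0/1", qual = 50) {
  tibble::tibble(contig = "c1", pos = as.integer(pos), ref = "A",
                 alt = "T", qual = qual, filter = "PASS", gt = gt)
}

test_that("identical callsets are fully concordant", {
  a <- random_small_callset(80)
  cmp <- compare_callsets(a, a)
  g <- glance(cmp)
  expect_equal(g$fn, 0L)
  expect_equal(g$fp, 0L)
  expect_equal(g$tp, nrow(a))
  expect_equal(g$discordance, 0)
  expect_equal(g$concordance, 1)
})

test_that("private keys become fn and fp by side", {
  a <- simple_callset(c(1, 2, 3))
  b <- simple_callset(c(2, 3, 4))
  g <- glance(compare_callsets(a, b))
  expect_equal(unlist(g[c("tp", "fn", "fp")]),
               c(tp = 2L, fn = 1L, fp = 1L))
})

test_that("genotype mismatches use double-entry accounting", {
  a <- simple_callset(c(1, 2), gt = c("0/1", "0/1"))
  b <- simple_callset(c(1, 2), gt = c("0/1", "1/1"))
  site_level <- glance(compare_callsets(a, b))
  expect_equal(site_level$discordance, 0)
  gt_level <- compare_callsets(a, b, require_genotype_match = TRUE)
  g <- glance(gt_level)
  expect_equal(unlist(g[c("tp", "fn", "fp")]),
               c(tp = 1L, fn = 1L, fp = 1L))
  expect_equal(sort(gt_level$status$status), c("concordant", "gt_mismatch"))
  # partition: each mismatch key adds one to both fn and fp
  expect_equal(g$tp + g$fn, nrow(gt_level$status))
})

test_that("randomized comparisons equal the exhaustive double-loop oracle", {
  withr::local_seed(13)
  for (rep in 1:8) {
    a <- random_small_callset(300, n_pos = 500L)
    b <- random_small_callset(300, n_pos = 500L)
    for (gm in c(FALSE, TRUE)) {
      got <- glance(compare_callsets(a, b, require_genotype_match = gm))
      want <- oracle_compare_counts(a, b, require_genotype_match = gm)
      expect_equal(got$tp, want$tp)
      expect_equal(got$fn, want$fn)
      expect_equal(got$fp, want$fp)
    }
  }
})

test_that("comparison is symmetric and partitions the union", {
  withr::local_seed(5)
  a <- random_small_callset(200)
  b <- random_small_callset(200)
  ab <- glance(compare_callsets(a, b))
  ba <- glance(compare_callsets(b, a))
  expect_equal(ab$tp, ba$tp)
  expect_equal(ab$fn, ba$fp)
  expect_equal(ab$fp, ba$fn)
  expect_equal(ab$discordance, ba$discordance)
  expect_equal(ab$tp + ab$fn + ab$fp, ab$n_keys)
})

test_that("duplicate keys collapse to the highest-QUAL record", {
  a <- simple_callset(c(7, 7), qual = c(10, 99))
  expect_message(cmp <- compare_callsets(a, simple_callset(7)),
                 "duplicate")
  expect_equal(cmp$status$qual_a, 99)
  expect_equal(glance(cmp)$tp, 1L)
})

test_that("rate formulas match direct substitution and are complementary", {
  expect_equal(discordance_rate(99, 1, 0), 0.01)
  expect_equal(concordance_rate(997, 2, 1), 0.997)
  expect_true(is.na(discordance_rate(0, 0, 0)))
  expect_equal(concordance_rate(0, 3, 4), 0)
  withr::local_seed(3)
  tp <- sample(0:1000, 200, replace = TRUE)
  fn <- sample(0:50, 200, replace = TRUE)
  fp <- sample(0:50, 200, replace = TRUE)
  keep <- tp + fn + fp > 0
  expect_equal(discordance_rate(tp, fn, fp)[keep] +
                 concordance_rate(tp, fn, fp)[keep],
               rep(1, sum(keep)))
})

test_that("k-way sharing classes match the membership-bitmap oracle", {
  withr::local_seed(23)
  sets <- purrr::map(1:5, function(i) random_small_callset(150, n_pos = 300L))
  got <- sharing_classes(sets)
  want <- oracle_sharing(purrr::map(sets, key_of))
  expect_equal(setNames(got$n, got$sharing), want[got$sharing])
  expect_equal(sum(got$fraction), 1)
  # identical callsets: everything is shared by all
  same <- sharing_classes(list(sets[[1]], sets[[1]], sets[[1]]))
  expect_equal(same$n[same$sharing == "all"], nrow(sets[[1]]))
  expect_equal(sum(same$n[same$sharing != "all"]), 0L)
  # a key in 2 of 3 sets is partial
  three <- list(simple_callset(1:2), simple_callset(2:3), simple_callset(4))
  cls <- sharing_classes(three)
  expect_equal(cls$n[cls$sharing == "partial"], 1L)
  expect_equal(cls$n[cls$sharing == "unique"], 3L)
})

test_that("filter modes keep PASS or drop LowQual as documented", {
  cs <- tibble::tibble(
    contig = "c1", pos = 1:4, ref = "A", alt = "T", qual = 1,
    filter = c("PASS", "LowQual", "VQSRTrancheSNP99", "PASS;LowQual"),
    gt = "0/1"
  )
  expect_equal(filter_pass(cs, "pass-only")$pos, 1L)
  expect_equal(filter_pass(cs, "drop-lowqual")$pos, c(1L, 3L))
  expect_error(filter_pass(cs, "bogus"))
  all_pass <- dplyr::mutate(cs, filter = "PASS")
  expect_identical(filter_pass(all_pass, "pass-only"), all_pass)
})
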