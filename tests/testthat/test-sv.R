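test_that("breakpoint overlap needs both padded intervals to intersect", {
  x <- tibble::tibble(contig1 = "c1", start1 = 99L, end1 = 102L,
                      contig2 = "c1", start2 = 499L, end2 = 502L)
  expect_true(breakpoints_overlap(x, x))
  # abutting half-open intervals share no base
  y <- dplyr::mutate(x, start1 = 102L, end1 = 105L)
  expect_false(breakpoints_overlap(x, y))
  # one breakpoint overlapping is not enough
  z <- dplyr::mutate(x, start2 = 600L, end2 = 603L)
  expect_false(breakpoints_overlap(x, z))
  w <- dplyr::mutate(x, contig2 = "c2")
  expect_false(breakpoints_overlap(x, w))
})

test_that("identical SV callsets all match", {
  withr::local_seed(2)
  a <- random_sv_callset(40)
  cmp <- classify_sv_pair(a, a)
  expect_equal(cmp$counts$match, 40L)
  expect_equal(sum(unlist(cmp$counts[, -1])), 0L)
  expect_equal(sv_discordance_rate(cmp$counts), 0)
  expect_equal(sv_shared_rate(cmp$counts), 1)
})

test_that("strand and type disagreement land in the 2x2 grid", {
  del <- tibble::tibble(
    contig1 = "c1", start1 = 99L, end1 = 102L,
    contig2 = "c1", start2 = 499L, end2 = 502L,
    name = "a", score = 1, strand1 = "+", strand2 = "-",
    svtype = "DEL", msq = 100
  )
  dup_flipped <- dplyr::mutate(del, strand1 = "-", strand2 = "+",
                               svtype = "DUP")
  cmp <- classify_sv_pair(del, dup_flipped)
  expect_equal(cmp$counts$discordant_discordant_type, 1L)
  same_strand_other_type <- dplyr::mutate(del, svtype = "DUP")
  expect_equal(classify_sv_pair(del, same_strand_other_type)$counts$
                 match_discordant_type, 1L)
  flipped_same_type <- dplyr::mutate(del, strand1 = "-", strand2 = "+")
  expect_equal(classify_sv_pair(del, flipped_same_type)$counts$discordant,
               1L)
})

test_that("random jittered sets equal the all-pairs oracle", {
  withr::local_seed(17)
  for (rep in 1:6) {
    a <- random_sv_callset(60, span = 20000L)
    # b: jittered copy of a subset of a, plus private calls
    keep <- sample.int(60, 45)
    b <- a[keep, ]
    j1 <- sample(-2:2, 45, replace = TRUE)
    j2 <- sample(-2:2, 45, replace = TRUE)
    b$start1 <- b$start1 + j1; b$end1 <- b$end1 + j1
    b$start2 <- b$start2 + j2; b$end2 <- b$end2 + j2
    flip <- sample.int(45, 5)
    b$strand1[flip] <- ifelse(b$strand1[flip] == "+", "-", "+")
    b <- dplyr::bind_rows(b, random_sv_callset(10, span = 20000L))
    got <- classify_sv_pair(a, b)$counts
    want <- oracle_sv_counts(a, b)
    expect_equal(as.data.frame(got), as.data.frame(want),
                 info = sprintf("rep %d", rep))
  }
})

test_that("swapping the callsets swaps only the private categories", {
  withr::local_seed(29)
  a <- random_sv_callset(50, span = 15000L)
  b <- random_sv_callset(50, span = 15000L)
  ab <- classify_sv_pair(a, b)$counts
  ba <- classify_sv_pair(b, a)$counts
  expect_equal(ab$match, ba$match)
  expect_equal(ab$discordant, ba$discordant)
  expect_equal(ab$match_discordant_type, ba$match_discordant_type)
  expect_equal(ab$discordant_discordant_type,
               ba$discordant_discordant_type)
  expect_equal(ab$zero_only, ba$one_only)
  expect_equal(ab$one_only, ba$zero_only)
  expect_equal(sv_discordance_rate(ab), sv_discordance_rate(ba))
})

test_that("SV rate formulas match independent arithmetic", {
  counts <- tibble::tibble(match = 99L, discordant = 0L,
                           match_discordant_type = 0L,
                           discordant_discordant_type = 0L,
                           zero_only = 0L, one_only = 1L)
  expect_equal(sv_discordance_rate(counts), 0.01)
  expect_equal(sv_shared_rate(counts), 0.99)
  empty <- dplyr::mutate(counts, match = 0L, one_only = 0L)
  expect_true(is.na(sv_discordance_rate(empty)))
  withr::local_seed(31)
  rand <- tibble::tibble(
    match = sample(0:100, 50, replace = TRUE),
    discordant = sample(0:20, 50, replace = TRUE),
    match_discordant_type = sample(0:20, 50, replace = TRUE),
    discordant_discordant_type = sample(0:20, 50, replace = TRUE),
    zero_only = sample(0:20, 50, replace = TRUE),
    one_only = sample(0:20, 50, replace = TRUE)
  )
  num <- rand$discordant + rand$zero_only + rand$one_only +
    rand$discordant_discordant_type
  den <- rowSums(rand)
  expect_equal(sv_discordance_rate(rand), ifelse(den > 0, num / den, NA))
  expect_equal(sv_shared_rate(rand),
               ifelse(rand$match + rand$zero_only + rand$one_only > 0,
                      rand$match /
                        (rand$match + rand$zero_only + rand$one_only),
                      NA))
})

test_that("padding expands intervals and never goes negative", {
  sv <- tibble::tibble(contig1 = "c1", start1 = 0L, end1 = 1L,
                       contig2 = "c1", start2 = 10L, end2 = 11L)
  padded <- pad_breakpoints(sv, 2L)
  expect_equal(padded$start1, 0L)
  expect_equal(padded$end1, 3L)
  expect_equal(padded$start2, 8L)
})
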