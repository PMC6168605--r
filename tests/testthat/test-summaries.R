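test_that("lower-median convention is used for even-sized cells", {
  expect_equal(median_lower(c(10, 20, 30, 40)), 20)
  expect_equal(median_lower(c(30, 10, 20)), 20)
  expect_equal(median_lower(7), 7)
  expect_true(is.na(median_lower(numeric())))
  withr::local_seed(4)
  for (i in 1:20) {
    x <- runif(sample(1:30, 1))
    expect_equal(median_lower(x), sort(x)[floor((length(x) + 1) / 2)])
  }
})

test_that("quality summaries report exact medians and means per cell", {
  tbl <- tibble::tibble(
    status = c("concordant", "concordant", "discordant", "concordant",
               "discordant"),
    class = c("snv", "snv", "snv", "indel", "snv"),
    qual = c(10, 30, 5, 42, 7)
  )
  out <- quality_by_status(tbl, qual_col = "qual")
  conc_snv <- dplyr::filter(out, status == "concordant", class == "snv")
  expect_equal(conc_snv$median_qual, 10) # lower median of {10, 30}
  expect_equal(conc_snv$mean_qual, 20)
  disc_snv <- dplyr::filter(out, status == "discordant", class == "snv")
  expect_equal(disc_snv$n, 2L)
  expect_equal(disc_snv$median_qual, 5)
  single <- dplyr::filter(out, class == "indel")
  expect_equal(single$median_qual, single$mean_qual)
})

test_that("pair aggregation reproduces means and boxplot hinges", {
  withr::local_seed(9)
  per_sample <- tidyr::crossing(pair = c("p1 vs p2", "p1 vs p3"),
                                sample = sprintf("s%02d", 1:20)) |>
    dplyr::mutate(value = runif(dplyr::n()))
  agg <- aggregate_pairs(per_sample)
  expect_equal(nrow(agg), 2L)
  for (p in agg$pair) {
    x <- per_sample$value[per_sample$pair == p]
    row <- agg[agg$pair == p, ]
    expect_equal(row$mean, mean(x))
    expect_equal(row$n_samples, 20L)
    fn <- stats::fivenum(x)
    expect_equal(c(row$hinge_lo, row$median, row$hinge_hi), fn[2:4])
    iqr <- fn[4] - fn[2]
    expect_equal(row$whisker_lo, min(x[x >= fn[2] - 1.5 * iqr]))
    expect_equal(row$whisker_hi, max(x[x <= fn[4] + 1.5 * iqr]))
  }
  one <- aggregate_pairs(tibble::tibble(pair = "p", value = 0.25))
  expect_equal(one$mean, 0.25)
  expect_equal(one$median, 0.25)
})

small_report <- function(seed = 5) {
  cfg <- sim_config(
    seed = seed, contigs = c(t1 = 6e5, t2 = 3e5), n_truth_snv = 1200L,
    n_truth_indel = 150L, n_truth_sv = 30L,
    pipelines = c("pA", "pB", "pC"), n_trios = 1L
  )
  sim <- simulate_study(cfg)
  fe_evaluate(sim$callsets, regions = sim$truth$regions,
              pedigree = sim$truth$pedigree)
}

test_that("report tables have the expected shape and internal consistency", {
  rep <- small_report()
  k <- length(rep$pipelines)
  expect_equal(length(unique(rep$small_pairwise$pair)), k * (k - 1) / 2)
  # counts table covers every pair x sample x class x region cell
  expect_equal(nrow(rep$small_pairwise),
               k * (k - 1) / 2 * length(rep$samples) * 2 * 3)
  # aggregated means equal the mean of per-sample values
  agg_all <- rep$small_aggregate |>
    dplyr::filter(class == "snv", region == "all")
  manual <- rep$small_pairwise |>
    dplyr::filter(class == "snv") |>
    dplyr::group_by(pair, sample) |>
    dplyr::summarize(v = discordance_rate(sum(tp), sum(fn), sum(fp)),
                     .groups = "drop") |>
    dplyr::group_by(pair) |>
    dplyr::summarize(m = mean(v))
  expect_equal(agg_all$discordance_mean[order(agg_all$pair)],
               manual$m[order(manual$pair)])
  # sharing fractions sum to one per sample
  sums <- rep$sharing |>
    dplyr::group_by(sample) |>
    dplyr::summarize(s = sum(fraction))
  expect_equal(sums$s, rep(1, length(rep$samples)))
})

test_that("discordant sites have lower quality than concordant ones", {
  rep <- small_report()
  q <- rep$quality |>
    dplyr::filter(class == "snv") |>
    dplyr::group_by(concordance) |>
    dplyr::summarize(med = mean(median_qual))
  expect_lt(q$med[q$concordance == "discordant"],
            q$med[q$concordance == "concordant"])
})

test_that("rendered reports are deterministic and re-render identically", {
  rep <- small_report(seed = 6)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  render_report(rep, d1)
  render_report(small_report(seed = 6), d2)
  files <- list.files(d1, pattern = "\\.tsv$")
  expect_true(length(files) >= 7L)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("tidiers and plots expose the report components", {
  rep <- small_report()
  expect_s3_class(tidy(rep), "tbl_df")
  g <- glance(rep)
  expect_equal(sort(g$class), c("indel", "snv"))
  expect_true(all(g$discordance >= 0 & g$discordance <= 1))
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(autoplot(rep, "mendelian"), "ggplot")
  expect_s3_class(plot_quality(rep), "ggplot")
})
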