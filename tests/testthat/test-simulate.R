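tiny_cfg <- function(...) {
  sim_config(
    seed = 101, contigs = c(t1 = 8e5, t2 = 4e5),
    n_truth_snv = 1500L, n_truth_indel = 200L, n_truth_sv = 40L,
    pipelines = c("pA", "pB", "pC"), n_trios = 1L, ...
  )
}

test_that("configuration is validated", {
  expect_error(sim_config(region_fractions = c(easy = 0.5, medium = 0.4,
                                               hard = 0.2)),
               "sum to 1")
  expect_error(sim_config(dropout = c(easy = -0.1, medium = 0, hard = 0)),
               "probabilities")
  expect_error(sim_config(n_truth_snv = -5), "non-negative")
  expect_error(
    simulate_truth(sim_config(contigs = c(c1 = 2000),
                              n_truth_snv = 1900L, n_truth_indel = 0L,
                              n_truth_sv = 0L)),
    "too short"
  )
})

test_that("regions partition every contig and follow the fractions", {
  truth <- simulate_truth(tiny_cfg())
  reg <- tibble::as_tibble(truth$regions)
  by_contig <- reg |>
    dplyr::group_by(contig) |>
    dplyr::arrange(start, .by_group = TRUE) |>
    dplyr::summarize(covered = sum(end - start),
                     gapless = all(start == dplyr::lag(end, default = 0L)))
  expect_equal(setNames(by_contig$covered, by_contig$contig),
               c(t1 = 8e5, t2 = 4e5))
  expect_true(all(by_contig$gapless))
  frac <- reg |>
    dplyr::group_by(region) |>
    dplyr::summarize(bp = sum(end - start)) |>
    dplyr::mutate(f = bp / sum(bp))
  expect_equal(frac$f[frac$region == "easy"], 0.72, tolerance = 0.1)
})

test_that("degenerate region fractions label every variant easy", {
  cfg <- tiny_cfg(region_fractions = c(easy = 1, medium = 0, hard = 0))
  truth <- simulate_truth(cfg)
  expect_true(all(truth$variants$region == "easy"))
  expect_true(all(truth$sv$region == "easy"))
})

test_that("the simulation is byte-identical under a fixed seed", {
  cfg <- tiny_cfg()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(simulate_study(cfg), d1)
  write_study(simulate_study(cfg), d2)
  files <- list.files(d1)
  expect_true(length(files) >= 8L)
  expect_equal(sort(files), sort(list.files(d2)))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("uncorrupted transmission yields zero Mendelian errors", {
  cfg <- tiny_cfg(mendelian_error_rate_discordant = 0)
  truth <- simulate_truth(cfg)
  trio <- trios_from_ped(truth$pedigree)[1, ]
  gt_wide <- truth$genotypes |>
    dplyr::filter(sample %in% c(trio$child, trio$father, trio$mother)) |>
    tidyr::pivot_wider(id_cols = variant_id, names_from = sample,
                       values_from = gt)
  cls <- mapply(oracle_trio, gt_wide[[trio$child]], gt_wide[[trio$father]],
                gt_wide[[trio$mother]])
  expect_equal(sum(cls == "informative_error"), 0L)
})

test_that("noise-free pipelines emit identical callsets", {
  cfg <- tiny_cfg(
    dropout = c(easy = 0, medium = 0, hard = 0),
    spurious_per_mb = c(easy = 0, medium = 0, hard = 0),
    genotype_error = c(easy = 0, medium = 0, hard = 0),
    sv_type_flip_prob = 0, sv_strand_flip_prob = 0, sv_jitter_bp = 0,
    mendelian_error_rate_discordant = 0
  )
  sim <- simulate_study(cfg)
  a <- sample_callset(sim$callsets, "pA", sim$callsets$samples[1])
  b <- sample_callset(sim$callsets, "pB", sim$callsets$samples[1])
  expect_equal(glance(compare_callsets(a, b))$discordance, 0)
  sv_a <- dplyr::filter(sim$callsets$sv, pipeline == "pA")
  sv_b <- dplyr::filter(sim$callsets$sv, pipeline == "pB")
  cmp <- classify_sv_pair(sv_a, sv_b)
  expect_equal(sv_shared_rate(cmp$counts), 1)
  expect_equal(sv_discordance_rate(cmp$counts), 0)
})

test_that("jitter within the padded window keeps the shared rate at 1", {
  cfg <- tiny_cfg(
    dropout = c(easy = 0.01, medium = 0.01, hard = 0.01),
    sv_dropout = c(easy = 0, medium = 0, hard = 0),
    sv_type_flip_prob = 0, sv_strand_flip_prob = 0, sv_jitter_bp = 1
  )
  sim <- simulate_study(cfg)
  sv_a <- dplyr::filter(sim$callsets$sv, pipeline == "pA")
  sv_b <- dplyr::filter(sim$callsets$sv, pipeline == "pB")
  expect_equal(sv_shared_rate(classify_sv_pair(sv_a, sv_b)$counts), 1)
})

test_that("pairwise discordance follows the dropout-model expectation", {
  d <- 0.004
  cfg <- sim_config(
    seed = 77, contigs = c(t1 = 2e6), n_truth_snv = 12000L,
    n_truth_indel = 0L, n_truth_sv = 0L, pipelines = c("pA", "pB"),
    n_trios = 2L,
    dropout = c(easy = d, medium = d, hard = d),
    spurious_per_mb = c(easy = 0, medium = 0, hard = 0),
    genotype_error = c(easy = 0, medium = 0, hard = 0),
    mendelian_error_rate_discordant = 0
  )
  sim <- simulate_study(cfg)
  counts <- purrr::map(sim$callsets$samples, function(s) {
    glance(compare_callsets(sample_callset(sim$callsets, "pA", s),
                            sample_callset(sim$callsets, "pB", s)))
  }) |> purrr::list_rbind()
  p_exp <- 2 * d / (1 + d)
  n_union <- sum(counts$tp + counts$fn + counts$fp)
  p_obs <- sum(counts$fn + counts$fp) / n_union
  se <- sqrt(p_exp * (1 - p_exp) / n_union)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("spurious calls never collide with truth keys", {
  cfg <- tiny_cfg(spurious_per_mb = c(easy = 20, medium = 20, hard = 20))
  sim <- simulate_study(cfg)
  truth_keys <- paste0(sim$truth$variants$contig, ":",
                       sim$truth$variants$pos)
  spur <- sim$callsets$small |>
    dplyr::anti_join(sim$truth$variants,
                     by = c("contig", "pos", "ref", "alt"))
  expect_gt(nrow(spur), 0L)
  expect_false(any(paste0(spur$contig, ":", spur$pos) %in% truth_keys))
})
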