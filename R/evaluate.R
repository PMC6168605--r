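# End-to-end evaluation: all pairwise comparisons, k-way sharing,
# Mendelian analysis and quality summaries over a set of per-pipeline
# callsets.

#' One pipeline's callset for one sample
#'
#' The sample's own calls under one pipeline: carrier records with a
#' non-missing genotype.
#'
#' @param callsets An `fe_callsets` (or its `small` tibble).
#' @param pipeline,sample Labels to extract.
#' @return Callset tibble suitable for [compare_callsets()].
#' @export
sample_callset <- function(callsets, pipeline, sample) {
  small <- if (inherits(callsets, "fe_callsets")) callsets$small else callsets
  small |>
    filter(.data$pipeline == .env$pipeline, .data$sample == .env$sample,
           !is.na(.data$gt), .data$gt != "0/0") |>
    select(-"pipeline")
}

#' Cohort genotype table of one pipeline
#'
#' Expands one pipeline's records to a complete genotype table over all
#' samples at every site the pipeline called in any sample: explicit
#' records keep their genotype (`NA` = missing, e.g. a dropped call),
#' samples without a record at a called site are hom-ref `0/0`.
#'
#' @param callsets An `fe_callsets` (or its `small` tibble).
#' @param pipeline Pipeline label.
#' @return Tibble with `contig`, `pos`, `ref`, `alt`, `sample`, `gt`.
#' @export
cohort_genotypes <- function(callsets, pipeline) {
  small <- if (inherits(callsets, "fe_callsets")) callsets$small else callsets
  recs <- filter(small, .data$pipeline == .env$pipeline)
  samples <- unique(small$sample)
  sites <- distinct(recs, dplyr::pick(dplyr::all_of(variant_key_cols)))
  tidyr::crossing(sites, sample = samples) |>
    left_join(
      recs |>
        select(dplyr::all_of(variant_key_cols), "sample", "gt") |>
        mutate(.present = TRUE),
      by = c(variant_key_cols, "sample")
    ) |>
    mutate(gt = ifelse(is.na(.data$.present), "0/0", .data$gt)) |>
    select(-".present")
}

pipeline_pairs <- function(pipelines) {
  if (length(pipelines) < 2L) {
    abort("at least two pipelines are required")
  }
  cmb <- combn(pipelines, 2L)
  tibble(a = cmb[1L, ], b = cmb[2L, ],
         pair = paste(cmb[1L, ], cmb[2L, ], sep = " vs "))
}

#' Evaluate functional equivalence across a set of pipeline callsets
#'
#' Runs the full comparison battery on an `fe_callsets` object: pairwise
#' small-variant comparisons per sample (stratified by variant class and
#' region), k-way sharing classes per sample, pairwise SV classification,
#' Mendelian-error rates by concordance status per trio, and
#' quality-by-concordance summaries, then aggregates rates across samples
#' (mean plus box summaries) per pipeline pair.
#'
#' @param callsets An `fe_callsets`, e.g. from [simulate_study()].
#' @param regions An `fe_regions` index, or `NULL` for a single `all`
#'   stratum.
#' @param pedigree Pedigree tibble (see [read_ped()]); `NULL` skips the
#'   Mendelian analysis.
#' @param require_genotype_match Score genotype mismatches at shared keys
#'   as discordant (see [compare_callsets()]).
#' @return An object of class `fe_report`: a list of tibbles
#'   `small_pairwise` (per pair x sample x class x region counts and
#'   rates), `small_aggregate` (across-sample aggregation),
#'   `sharing` (per sample), `sharing_aggregate`, `sv_pairwise`
#'   (per pair counts and rates), `mendelian` (per pair x trio),
#'   `mendelian_aggregate`, and `quality` (per pair, by concordance
#'   status).
#' @export
fe_evaluate <- function(callsets, regions = NULL, pedigree = NULL,
                        require_genotype_match = FALSE) {
  stopifnot(inherits(callsets, "fe_callsets"))
  pairs <- pipeline_pairs(callsets$pipelines)
  samples <- callsets$samples

  per_sample_cs <- purrr::map(
    rlang::set_names(callsets$pipelines),
    function(p) purrr::map(
      rlang::set_names(samples),
      function(s) sample_callset(callsets, p, s)
    )
  )

  comparisons <- list()
  small_rows <- list()
  quality_rows <- list()
  for (i in seq_len(nrow(pairs))) {
    for (s in samples) {
      cmp <- compare_callsets(
        per_sample_cs[[pairs$a[i]]][[s]], per_sample_cs[[pairs$b[i]]][[s]],
        require_genotype_match = require_genotype_match, regions = regions
      )
      comparisons[[paste(pairs$pair[i], s, sep = " / ")]] <- cmp
      small_rows[[length(small_rows) + 1L]] <- cmp$counts |>
        mutate(pair = pairs$pair[i], a = pairs$a[i], b = pairs$b[i],
               sample = s)
      quality_rows[[length(quality_rows) + 1L]] <- cmp$status |>
        mutate(concordance = ifelse(.data$status == "concordant",
                                    "concordant", "discordant"),
               pair = pairs$pair[i], sample = s)
    }
  }
  small_pairwise <- list_rbind(small_rows) |>
    mutate(discordance = discordance_rate(.data$tp, .data$fn, .data$fp),
           concordance = concordance_rate(.data$tp, .data$fn, .data$fp)) |>
    select("pair", "a", "b", "sample", "class", "region", "tp", "fn",
           "fp", "discordance", "concordance")

  small_aggregate <- small_pairwise |>
    group_by(.data$pair, .data$sample, .data$class) |>
    summarize(tp = sum(.data$tp), fn = sum(.data$fn), fp = sum(.data$fp),
              .groups = "drop") |>
    mutate(region = "all") |>
    bind_rows(small_pairwise |> select("pair", "sample", "class",
                                       "region", "tp", "fn", "fp")) |>
    mutate(value = discordance_rate(.data$tp, .data$fn, .data$fp)) |>
    aggregate_pairs(.data$class, .data$region) |>
    rename(discordance_mean = "mean")

  sharing <- purrr::map(rlang::set_names(samples), function(s) {
    sharing_classes(purrr::map(per_sample_cs, function(bysmp) bysmp[[s]])) |>
      mutate(sample = s)
  }) |> list_rbind()
  sharing_aggregate <- sharing |>
    group_by(.data$sharing) |>
    summarize(n = sum(.data$n), mean_fraction = mean(.data$fraction),
              .groups = "drop")

  quality <- list_rbind(quality_rows) |>
    mutate(qual = dplyr::coalesce(.data$qual_a, .data$qual_b)) |>
    group_by(.data$pair) |>
    group_modify(function(df, key) {
      quality_by_status(
        df |> select(status = "concordance", "class", "qual"),
        qual_col = "qual"
      )
    }) |>
    ungroup() |>
    rename(concordance = "status")

  sv_pairwise <- sv_quality <- NULL
  if (!is.null(callsets$sv) && nrow(callsets$sv) > 0L) {
    sv_sets <- purrr::map(rlang::set_names(callsets$pipelines),
                          function(p) filter(callsets$sv,
                                             .data$pipeline == p))
    sv_rows <- purrr::pmap(pairs, function(a, b, pair) {
      cls <- classify_sv_pair(sv_sets[[a]], sv_sets[[b]])
      cls$counts |> mutate(pair = pair, a = a, b = b)
    })
    sv_pairwise <- list_rbind(sv_rows) |>
      mutate(discordance = sv_discordance_rate(dplyr::pick(everything())),
             shared_rate = sv_shared_rate(dplyr::pick(everything()))) |>
      select("pair", "a", "b", dplyr::all_of(SV_CATEGORIES),
             "discordance", "shared_rate")
    sv_quality <- purrr::pmap(pairs, function(a, b, pair) {
      cls <- classify_sv_pair(sv_sets[[a]], sv_sets[[b]])
      calls_a <- cls$calls |> filter(.data$set == "a")
      tibble(
        status = ifelse(calls_a$outcome == "match", "concordant",
                        "discordant"),
        class = "sv",
        qual = sv_sets[[a]]$msq[calls_a$idx]
      ) |>
        quality_by_status(qual_col = "qual") |>
        mutate(pair = pair)
    }) |> list_rbind() |> rename(concordance = "status")
  }

  mendelian <- mendelian_aggregate <- NULL
  if (!is.null(pedigree)) {
    trios <- trios_from_ped(pedigree)
    cohorts <- purrr::map(rlang::set_names(callsets$pipelines),
                          function(p) cohort_genotypes(callsets, p))
    me_rows <- list()
    for (i in seq_len(nrow(pairs))) {
      for (t in seq_len(nrow(trios))) {
        trio <- trios[t, ]
        if (!all(c(trio$child, trio$father, trio$mother) %in% samples)) {
          inform(sprintf("skipping trio %s: member absent from callsets",
                         trio$family))
          next
        }
        cmp <- comparisons[[paste(pairs$pair[i], trio$child,
                                  sep = " / ")]]
        me_rows[[length(me_rows) + 1L]] <-
          me_by_concordance(cmp, cohorts[[pairs$a[i]]], trio) |>
          mutate(pair = pairs$pair[i], family = trio$family)
      }
    }
    mendelian <- list_rbind(me_rows)
    mendelian_aggregate <- mendelian |>
      group_by(.data$pair, .data$concordance, .data$region) |>
      summarize(
        informative = sum(.data$informative),
        errors = sum(.data$errors),
        mean_me_rate = mean(.data$me_rate, na.rm = TRUE),
        pooled_me_rate = ifelse(sum(.data$informative) > 0,
                                sum(.data$errors) / sum(.data$informative),
                                NA_real_),
        .groups = "drop"
      )
  }

  structure(
    list(
      small_pairwise = small_pairwise, small_aggregate = small_aggregate,
      sharing = sharing, sharing_aggregate = sharing_aggregate,
      quality = quality, sv_pairwise = sv_pairwise,
      sv_quality = sv_quality, mendelian = mendelian,
      mendelian_aggregate = mendelian_aggregate,
      pipelines = callsets$pipelines, samples = samples
    ),
    class = "fe_report"
  )
}

#' @export
print.fe_report <- function(x, ...) {
  cat("<fe_report> ", length(x$pipelines), " pipelines, ",
      length(x$samples), " samples\n", sep = "")
  cat("mean pairwise discordance by class (all regions):\n")
  print(
    x$small_aggregate |>
      filter(.data$region == "all") |>
      group_by(.data$class) |>
      summarize(discordance = mean(.data$discordance_mean),
                .groups = "drop")
  )
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits deterministic tab-delimited tables (and, optionally, box-plot
#' figures) for every component of an `fe_report`.
#'
#' @param report An `fe_report` from [fe_evaluate()].
#' @param dir Output directory (created if needed).
#' @param figures Also write PNG figures (default `FALSE`).
#' @return `dir`, invisibly.
#' @export
render_report <- function(report, dir, figures = FALSE) {
  stopifnot(inherits(report, "fe_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(
    small_pairwise = report$small_pairwise |>
      arrange(.data$pair, .data$sample, .data$class, .data$region),
    small_aggregate = report$small_aggregate |>
      arrange(.data$pair, .data$class, .data$region),
    sharing = arrange(report$sharing, .data$sample, .data$sharing),
    sharing_aggregate = arrange(report$sharing_aggregate, .data$sharing),
    quality = arrange(report$quality, .data$pair, .data$class,
                      .data$concordance),
    sv_pairwise = report$sv_pairwise,
    sv_quality = report$sv_quality,
    mendelian = report$mendelian,
    mendelian_aggregate = report$mendelian_aggregate
  )
  for (nm in names(tables)) {
    if (!is.null(tables[[nm]])) {
      readr::write_tsv(tables[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       progress = FALSE)
    }
  }
  if (figures) {
    ggplot2::ggsave(file.path(dir, "discordance.png"),
                    plot_discordance(report), width = 8, height = 4,
                    dpi = 150)
    if (!is.null(report$mendelian)) {
      ggplot2::ggsave(file.path(dir, "mendelian.png"),
                      plot_me_rates(report), width = 6, height = 4,
                      dpi = 150)
    }
  }
  invisible(dir)
}
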