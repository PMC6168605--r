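# Pairwise and k-way concordance of small-variant callsets.
#
# Matching is normalized exact allele matching on the key
# (contig, pos, ref, alt): pipelines sharing one variant caller diverge
# mainly in which borderline sites they call, not in representation, so a
# haplotype-level comparator is not reconstructed here. The comparator is
# isolated behind compare_callsets() so an alternative matcher is a
# one-point change.

variant_key_cols <- c("contig", "pos", "ref", "alt")

# Collapse duplicate identical keys within one callset, keeping the
# highest-QUAL record. Deterministic and conservative.
collapse_duplicates <- function(callset, label) {
  n0 <- nrow(callset)
  out <- callset |>
    arrange(.data$contig, .data$pos, .data$ref, .data$alt,
            dplyr::desc(.data$qual)) |>
    distinct(dplyr::pick(dplyr::all_of(variant_key_cols)), .keep_all = TRUE)
  if (nrow(out) < n0) {
    inform(sprintf("collapsed %d duplicate key(s) in callset %s",
                   n0 - nrow(out), label))
  }
  out
}

#' Compare two small-variant callsets of the same sample
#'
#' Both callsets must already be normalized (see [normalize_variants()])
#' and belong to the same sample. Keys present in both callsets are
#' concordant; keys private to either side are discordant. With
#' `require_genotype_match = TRUE`, a shared key whose genotype multisets
#' differ is counted once as a false negative and once as a false positive
#' (double-entry accounting, as when a truth/query comparison scores the
#' genotype), and labeled `gt_mismatch` in the per-key status.
#'
#' @param a,b Callset tibbles with columns `contig`, `pos`, `ref`, `alt`,
#'   `qual`, `gt`.
#' @param require_genotype_match Score genotype mismatches at shared keys
#'   as discordant (default `FALSE`: site-level matching only).
#' @param regions Optional `fe_regions` index; when supplied, counts are
#'   stratified by region label, otherwise a single `"all"` stratum is
#'   used.
#' @return An object of class `fe_comparison`: a list with
#'   * `status`: one row per union key with `class` (`snv`/`indel`),
#'     `region`, `status` (`concordant`, `a_only`, `b_only`,
#'     `gt_mismatch`), and the per-side `qual`/`gt`;
#'   * `counts`: per `(class, region)` counts `tp`, `fn`, `fp`.
#' @export
compare_callsets <- function(a, b, require_genotype_match = FALSE,
                             regions = NULL) {
  a <- collapse_duplicates(a, "a")
  b <- collapse_duplicates(b, "b")
  joined <- full_join(
    a |> select(dplyr::all_of(variant_key_cols), qual_a = "qual",
                gt_a = "gt") |> mutate(in_a = TRUE),
    b |> select(dplyr::all_of(variant_key_cols), qual_b = "qual",
                gt_b = "gt") |> mutate(in_b = TRUE),
    by = variant_key_cols
  )
  status <- joined |>
    mutate(
      in_a = dplyr::coalesce(.data$in_a, FALSE),
      in_b = dplyr::coalesce(.data$in_b, FALSE),
      status = dplyr::case_when(
        .data$in_a & !.data$in_b ~ "a_only",
        !.data$in_a & .data$in_b ~ "b_only",
        require_genotype_match &
          dplyr::coalesce(.data$gt_a, ".") !=
            dplyr::coalesce(.data$gt_b, ".") ~ "gt_mismatch",
        .default = "concordant"
      ),
      class = variant_class(.data$ref, .data$alt)
    ) |>
    select(-"in_a", -"in_b")
  if (!is.null(regions)) {
    status$region <- classify_position(regions, status$contig, status$pos)
    region_lvls <- REGION_LEVELS
  } else {
    status$region <- "all"
    region_lvls <- "all"
  }
  counts <- status |>
    count(.data$class, .data$region, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L)
  for (col in c("concordant", "a_only", "b_only", "gt_mismatch")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  counts <- counts |>
    transmute(
      class = .data$class, region = .data$region,
      tp = .data$concordant,
      fn = .data$a_only + .data$gt_mismatch,
      fp = .data$b_only + .data$gt_mismatch
    ) |>
    tidyr::complete(
      class = c("snv", "indel"), region = region_lvls,
      fill = list(tp = 0L, fn = 0L, fp = 0L)
    ) |>
    arrange(.data$class, .data$region)
  structure(
    list(status = status, counts = counts,
         require_genotype_match = require_genotype_match),
    class = "fe_comparison"
  )
}

#' @export
print.fe_comparison <- function(x, ...) {
  cat("<fe_comparison> ", nrow(x$status), " union keys\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Pairwise discordance rate
#'
#' The fraction of the union of two callsets not matched between them:
#' `(fn + fp) / (tp + fn + fp)`. Symmetric under swapping the callsets.
#'
#' @param tp,fn,fp Non-negative count vectors (matched, a-only, b-only;
#'   genotype mismatches, when scored, contribute to both `fn` and `fp`).
#' @return Numeric vector of rates; `NA` where the denominator is zero.
#' @export
#' @examples
#' discordance_rate(99, 1, 0)
discordance_rate <- function(tp, fn, fp) {
  den <- tp + fn + fp
  ifelse(den > 0, (fn + fp) / den, NA_real_)
}

#' Pairwise concordance rate
#'
#' `tp / (tp + fn + fp)`; the complement of [discordance_rate()].
#'
#' @inheritParams discordance_rate
#' @return Numeric vector of rates; `NA` where the denominator is zero.
#' @export
concordance_rate <- function(tp, fn, fp) {
  den <- tp + fn + fp
  ifelse(den > 0, tp / den, NA_real_)
}

#' k-way sharing classes over callsets
#'
#' Each key in the union of `k >= 2` callsets is classed `all` (present in
#' every callset), `unique` (present in exactly one) or `partial`
#' (anything in between).
#'
#' @param callsets Either a named list of callset tibbles or one long
#'   tibble with a `pipeline` column.
#' @return Tibble with columns `sharing`, `n`, `fraction` (fractions sum
#'   to 1 over a non-empty union).
#' @export
sharing_classes <- function(callsets) {
  if (is.data.frame(callsets)) {
    stopifnot("pipeline" %in% names(callsets))
    callsets <- split(callsets, callsets$pipeline)
  }
  k <- length(callsets)
  if (k < 2L) {
    abort("at least two callsets are required")
  }
  membership <- purrr::imap(callsets, function(cs, nm) {
    cs |>
      distinct(dplyr::pick(dplyr::all_of(variant_key_cols))) |>
      mutate(.n = 1L)
  }) |>
    list_rbind() |>
    count(dplyr::pick(dplyr::all_of(variant_key_cols)), name = "n_sets")
  tallies <- membership |>
    mutate(sharing = dplyr::case_when(
      .data$n_sets == k ~ "all",
      .data$n_sets == 1L ~ "unique",
      .default = "partial"
    )) |>
    count(.data$sharing)
  out <- tibble(sharing = c("all", "unique", "partial")) |>
    left_join(tallies, by = "sharing") |>
    mutate(n = dplyr::coalesce(.data$n, 0L),
           fraction = if (sum(.data$n) > 0) .data$n / sum(.data$n)
                      else NA_real_)
  out
}

#' Filter a callset on its FILTER field
#'
#' Two documented modes mirror the two analysis designs: `"pass-only"`
#' keeps only records whose FILTER is `PASS`; `"drop-lowqual"` keeps all
#' records except those flagged `LowQual`.
#'
#' @param callset Callset tibble with a `filter` column.
#' @param mode `"pass-only"` or `"drop-lowqual"`.
#' @return The filtered callset.
#' @export
filter_pass <- function(callset, mode = c("pass-only", "drop-lowqual")) {
  mode <- rlang::arg_match(mode)
  has_label <- function(field, label) {
    purrr::map_lgl(stringr::str_split(field, ";"), function(x) label %in% x)
  }
  if (mode == "pass-only") {
    filter(callset, .data$filter == "PASS")
  } else {
    filter(callset, !has_label(.data$filter, "LowQual"))
  }
}
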