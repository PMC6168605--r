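# Quality-by-concordance summaries and cross-sample aggregation.

#' Lower median
#'
#' Exact median using the lower-median convention for even-sized samples:
#' the `floor((n + 1) / 2)`-th order statistic.
#'
#' @param x Numeric vector (NAs removed).
#' @return Scalar; `NA` for an empty vector.
#' @export
median_lower <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) NA_real_ else as.numeric(x[floor((n + 1) / 2)])
}

#' Variant quality summarized by concordance status
#'
#' For each (status, class) cell, reports the exact lower-convention
#' median and the arithmetic mean of the per-variant quality. For small
#' variants the quality is QUAL; for SV calls pass `msq` as the quality
#' column. Empty cells are absent from the output.
#'
#' @param status_tbl Tibble with columns `status`, `class` and the quality
#'   column; the `status` slot of an `fe_comparison` works directly (the
#'   quality of the first callset is used, falling back to the second for
#'   keys private to it).
#' @param qual_col Name of the quality column (default picks `qual_a`
#'   completed by `qual_b`, or `qual` if present).
#' @return Tibble with `status`, `class`, `n`, `median_qual`, `mean_qual`.
#' @export
quality_by_status <- function(status_tbl, qual_col = NULL) {
  df <- as_tibble(status_tbl)
  if (is.null(qual_col)) {
    if (all(c("qual_a", "qual_b") %in% names(df))) {
      df$.qual <- dplyr::coalesce(df$qual_a, df$qual_b)
    } else if ("qual" %in% names(df)) {
      df$.qual <- df$qual
    } else {
      abort("no quality column found; pass qual_col")
    }
  } else {
    df$.qual <- df[[qual_col]]
  }
  if (!"class" %in% names(df)) {
    df$class <- "all"
  }
  df |>
    filter(!is.na(.data$.qual)) |>
    group_by(.data$status, .data$class) |>
    summarize(
      n = dplyr::n(),
      median_qual = median_lower(.data$.qual),
      mean_qual = mean(.data$.qual),
      .groups = "drop"
    ) |>
    arrange(.data$class, .data$status)
}

#' Aggregate per-sample rates over samples, per pipeline pair
#'
#' Computes, for every `(pair, ...)` group, the mean of the per-sample
#' values together with the five-number box summary used for plotting:
#' lower-median hinge quartiles and whiskers extending to the most extreme
#' values within 1.5 inter-quartile ranges of the hinges.
#'
#' @param per_sample Tibble with columns `pair`, a `value` column, and any
#'   further grouping columns.
#' @param value Name of the value column (default `"value"`).
#' @param ... Additional grouping columns (tidyselect), e.g. `class`,
#'   `region`.
#' @return Tibble with per-group `n_samples`, `mean`, `median`, `hinge_lo`,
#'   `hinge_hi`, `whisker_lo`, `whisker_hi`.
#' @export
aggregate_pairs <- function(per_sample, ..., value = "value") {
  per_sample |>
    group_by(.data$pair, ...) |>
    summarize(
      n_samples = sum(!is.na(.data[[value]])),
      mean = mean(.data[[value]], na.rm = TRUE),
      box = list(grDevices::boxplot.stats(
        .data[[value]][!is.na(.data[[value]])], do.conf = FALSE,
        do.out = FALSE
      )$stats),
      .groups = "drop"
    ) |>
    mutate(
      whisker_lo = purrr::map_dbl(.data$box, 1L),
      hinge_lo = purrr::map_dbl(.data$box, 2L),
      median = purrr::map_dbl(.data$box, 3L),
      hinge_hi = purrr::map_dbl(.data$box, 4L),
      whisker_hi = purrr::map_dbl(.data$box, 5L)
    ) |>
    select(-"box")
}
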