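# broom-style tidiers and ggplot2 views of comparison results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pairwise small-variant comparison
#'
#' @param x An `fe_comparison`.
#' @param ... Unused.
#' @return The per-`(class, region)` count tibble with discordance and
#'   concordance rates.
#' @method tidy fe_comparison
#' @export
tidy.fe_comparison <- function(x, ...) {
  x$counts |>
    mutate(discordance = discordance_rate(.data$tp, .data$fn, .data$fp),
           concordance = concordance_rate(.data$tp, .data$fn, .data$fp))
}

#' Glance at a pairwise small-variant comparison
#'
#' @param x An `fe_comparison`.
#' @param ... Unused.
#' @return One-row tibble with overall `tp`, `fn`, `fp`, `discordance`,
#'   `concordance` and `n_keys`.
#' @method glance fe_comparison
#' @export
glance.fe_comparison <- function(x, ...) {
  tot <- summarize(x$counts, tp = sum(.data$tp), fn = sum(.data$fn),
                   fp = sum(.data$fp))
  tibble(
    tp = tot$tp, fn = tot$fn, fp = tot$fp,
    discordance = discordance_rate(tot$tp, tot$fn, tot$fp),
    concordance = concordance_rate(tot$tp, tot$fn, tot$fp),
    n_keys = nrow(x$status)
  )
}

#' Tidy a pairwise SV comparison
#'
#' @param x An `fe_sv_comparison`.
#' @param ... Unused.
#' @return Per-call outcome tibble (`set`, `idx`, `outcome`).
#' @method tidy fe_sv_comparison
#' @export
tidy.fe_sv_comparison <- function(x, ...) {
  x$calls
}

#' Glance at a pairwise SV comparison
#'
#' @param x An `fe_sv_comparison`.
#' @param ... Unused.
#' @return One-row tibble with the six category counts plus
#'   `discordance` and `shared_rate`.
#' @method glance fe_sv_comparison
#' @export
glance.fe_sv_comparison <- function(x, ...) {
  x$counts |>
    mutate(discordance = sv_discordance_rate(x$counts),
           shared_rate = sv_shared_rate(x$counts))
}

#' Tidy an evaluation report
#'
#' @param x An `fe_report`.
#' @param ... Unused.
#' @return The per-pair, per-sample small-variant rate table.
#' @method tidy fe_report
#' @export
tidy.fe_report <- function(x, ...) {
  x$small_pairwise
}

#' Glance at an evaluation report
#'
#' @param x An `fe_report`.
#' @param ... Unused.
#' @return One row per variant class with the mean pairwise discordance
#'   and concordance over all pipeline pairs and samples.
#' @method glance fe_report
#' @export
glance.fe_report <- function(x, ...) {
  x$small_aggregate |>
    filter(.data$region == "all") |>
    group_by(.data$class) |>
    summarize(discordance = mean(.data$discordance_mean),
              concordance = 1 - mean(.data$discordance_mean),
              .groups = "drop")
}

#' Box plot of pairwise discordance rates
#'
#' One panel per variant class; boxes summarize the per-sample pairwise
#' discordance rates of each pipeline pair per region stratum (hinges at
#' the quartiles, whiskers at 1.5 IQR).
#'
#' @param report An `fe_report`.
#' @return A ggplot object.
#' @export
plot_discordance <- function(report) {
  df <- report$small_pairwise |>
    mutate(region = region_factor(.data$region))
  if (all(is.na(df$region))) {
    df$region <- factor("all")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region,
                                   y = .data$discordance,
                                   fill = .data$region)) +
    ggplot2::geom_boxplot(coef = 1.5, outlier.size = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$class)) +
    ggplot2::labs(x = "genomic region stratum",
                  y = "pairwise discordance rate", fill = NULL) +
    ggplot2::theme_bw()
}

#' Box plot of Mendelian error rates by concordance status
#'
#' @param report An `fe_report` with a Mendelian component.
#' @return A ggplot object.
#' @export
plot_me_rates <- function(report) {
  stopifnot(!is.null(report$mendelian))
  ggplot2::ggplot(report$mendelian,
                  ggplot2::aes(x = .data$concordance, y = .data$me_rate,
                               fill = .data$concordance)) +
    ggplot2::geom_boxplot(coef = 1.5, outlier.size = 0.5) +
    ggplot2::labs(x = "pairwise concordance status",
                  y = "Mendelian error rate", fill = NULL) +
    ggplot2::theme_bw()
}

#' Box plot of variant quality by concordance status
#'
#' @param report An `fe_report`.
#' @return A ggplot object.
#' @export
plot_quality <- function(report) {
  ggplot2::ggplot(report$quality,
                  ggplot2::aes(x = .data$class, y = .data$median_qual,
                               fill = .data$concordance)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "variant class", y = "median quality (log scale)",
                  fill = NULL) +
    ggplot2::theme_bw()
}

#' Plot an evaluation report
#'
#' @param object An `fe_report`.
#' @param which Which view: `"discordance"`, `"mendelian"` or
#'   `"quality"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export autoplot
#' @method autoplot fe_report
#' @export
autoplot.fe_report <- function(object, which = c("discordance",
                                                 "mendelian", "quality"),
                               ...) {
  which <- rlang::arg_match(which)
  switch(which,
         discordance = plot_discordance(object),
         mendelian = plot_me_rates(object),
         quality = plot_quality(object))
}
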