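# Padded-breakpoint SV matching with a six-category classification.
#
# Two calls overlap when both of their padded breakpoint intervals
# intersect (half-open, same contigs) — the paired-interval intersection
# used by bedtools pairtopair. Overlapping pairs are classed on a
# 2x2 strand-pair-by-type grid:
#   strands equal,  type equal  -> match
#   strands equal,  type differs -> match_discordant_type
#   strands differ, type equal  -> discordant
#   strands differ, type differs -> discordant_discordant_type
# This grid is a declared reconstruction of the category names' semantics;
# it is isolated in sv_pair_category() so an alternative rule is a
# one-point change.

SV_CATEGORIES <- c("match", "discordant", "match_discordant_type",
                   "discordant_discordant_type", "zero_only", "one_only")

# best-partner precedence for multi-overlap resolution
SV_PRECEDENCE <- c(match = 1L, match_discordant_type = 2L,
                   discordant = 3L, discordant_discordant_type = 4L)

sv_pair_category <- function(strand_equal, type_equal) {
  dplyr::case_when(
    strand_equal & type_equal ~ "match",
    strand_equal & !type_equal ~ "match_discordant_type",
    !strand_equal & type_equal ~ "discordant",
    .default = "discordant_discordant_type"
  )
}

#' Do two SV calls' breakpoints overlap?
#'
#' True iff the breakpoint-1 intervals intersect and the breakpoint-2
#' intervals intersect, on matching contigs, with at least one shared base
#' of the 0-based half-open (already padded) intervals. Vectorized over
#' rows; single-row inputs are recycled.
#'
#' @param x,y SV call tibbles with `contig1/start1/end1`,
#'   `contig2/start2/end2`.
#' @return Logical vector.
#' @export
breakpoints_overlap <- function(x, y) {
  n <- max(nrow(x), nrow(y))
  ix <- rep_len(seq_len(nrow(x)), n)
  iy <- rep_len(seq_len(nrow(y)), n)
  x <- x[ix, ]; y <- y[iy, ]
  x$contig1 == y$contig1 & x$contig2 == y$contig2 &
    x$start1 < y$end1 & y$start1 < x$end1 &
    x$start2 < y$end2 & y$start2 < x$end2
}

#' Classify a pairwise SV comparison
#'
#' Every call in either callset receives exactly one outcome. Calls with no
#' overlapping partner in the other set are `zero_only` (first set) or
#' `one_only` (second set). Overlapping calls are paired greedily by best
#' category under the precedence match > match_discordant_type >
#' discordant > discordant_discordant_type, ties broken by smallest
#' breakpoint distance and then by coordinate order; each matched pair
#' contributes one count to its category.
#'
#' @param a,b SV call tibbles (padded intervals, see [read_bedpe()]).
#' @param extra_slop Extra matching slop in bp added to each interval end
#'   beyond the built-in 1 bp padding (default 0).
#' @return Object of class `fe_sv_comparison`: list with `calls` (per-call
#'   set, row index and outcome) and `counts` (one-row tibble of the six
#'   category counts).
#' @export
classify_sv_pair <- function(a, b, extra_slop = 0L) {
  a <- mutate(a, .idx = dplyr::row_number())
  b <- mutate(b, .idx = dplyr::row_number())
  if (extra_slop > 0L) {
    slop <- as.integer(extra_slop)
    a <- mutate(a, start1 = .data$start1 - slop, end1 = .data$end1 + slop,
                start2 = .data$start2 - slop, end2 = .data$end2 + slop)
    b <- mutate(b, start1 = .data$start1 - slop, end1 = .data$end1 + slop,
                start2 = .data$start2 - slop, end2 = .data$end2 + slop)
  }
  pairs <- inner_join(
    a |> select(a_idx = ".idx", contig1 = "contig1", contig2 = "contig2",
                a_s1 = "start1", a_e1 = "end1", a_s2 = "start2",
                a_e2 = "end2", a_strand1 = "strand1", a_strand2 = "strand2",
                a_type = "svtype"),
    b |> select(b_idx = ".idx", contig1 = "contig1", contig2 = "contig2",
                b_s1 = "start1", b_e1 = "end1", b_s2 = "start2",
                b_e2 = "end2", b_strand1 = "strand1", b_strand2 = "strand2",
                b_type = "svtype"),
    by = c("contig1", "contig2"), relationship = "many-to-many"
  ) |>
    filter(.data$a_s1 < .data$b_e1, .data$b_s1 < .data$a_e1,
           .data$a_s2 < .data$b_e2, .data$b_s2 < .data$a_e2) |>
    mutate(
      category = sv_pair_category(
        .data$a_strand1 == .data$b_strand1 &
          .data$a_strand2 == .data$b_strand2,
        .data$a_type == .data$b_type
      ),
      rank = SV_PRECEDENCE[.data$category],
      dist = abs(.data$a_s1 - .data$b_s1) + abs(.data$a_s2 - .data$b_s2)
    ) |>
    # order-symmetric tie-breaks so that swapping the callsets swaps only
    # zero_only/one_only, never the shared categories
    arrange(.data$rank, .data$dist,
            pmin(.data$a_s1, .data$b_s1), pmax(.data$a_s1, .data$b_s1),
            pmin(.data$a_s2, .data$b_s2), pmax(.data$a_s2, .data$b_s2),
            pmin(.data$a_idx, .data$b_idx), pmax(.data$a_idx, .data$b_idx))
  a_out <- rep(NA_character_, nrow(a))
  b_out <- rep(NA_character_, nrow(b))
  if (nrow(pairs) > 0L) {
    for (i in seq_len(nrow(pairs))) {
      ai <- pairs$a_idx[i]; bi <- pairs$b_idx[i]
      if (is.na(a_out[ai]) && is.na(b_out[bi])) {
        a_out[ai] <- pairs$category[i]
        b_out[bi] <- pairs$category[i]
      }
    }
  }
  paired_categories <- a_out[!is.na(a_out)]
  a_out[is.na(a_out)] <- "zero_only"
  b_out[is.na(b_out)] <- "one_only"
  counts <- tibble(
    match = sum(paired_categories == "match"),
    discordant = sum(paired_categories == "discordant"),
    match_discordant_type =
      sum(paired_categories == "match_discordant_type"),
    discordant_discordant_type =
      sum(paired_categories == "discordant_discordant_type"),
    zero_only = sum(a_out == "zero_only"),
    one_only = sum(b_out == "one_only")
  )
  calls <- bind_rows(
    tibble(set = "a", idx = seq_len(nrow(a)), outcome = a_out),
    tibble(set = "b", idx = seq_len(nrow(b)), outcome = b_out)
  )
  structure(list(calls = calls, counts = counts),
            class = "fe_sv_comparison")
}

#' @export
print.fe_sv_comparison <- function(x, ...) {
  cat("<fe_sv_comparison>\n")
  print(x$counts)
  invisible(x)
}

sv_count_cols <- function(counts) {
  stopifnot(all(SV_CATEGORIES %in% names(counts)))
  counts
}

#' SV pairwise discordance rate
#'
#' `(discordant + zero_only + one_only + discordant_discordant_type) /
#' (match + discordant + match_discordant_type +
#' discordant_discordant_type + zero_only + one_only)`. Calls matched with
#' a discordant type but concordant strands count as concordant
#' (denominator only).
#'
#' @param counts Data frame (or one-row tibble) with the six category
#'   count columns; vectorized over rows.
#' @return Numeric vector; `NA` where the denominator is zero.
#' @export
sv_discordance_rate <- function(counts) {
  counts <- sv_count_cols(counts)
  num <- counts$discordant + counts$zero_only + counts$one_only +
    counts$discordant_discordant_type
  den <- counts$match + counts$discordant + counts$match_discordant_type +
    counts$discordant_discordant_type + counts$zero_only + counts$one_only
  ifelse(den > 0, num / den, NA_real_)
}

#' SV shared rate
#'
#' `match / (match + zero_only + one_only)`.
#'
#' @inheritParams sv_discordance_rate
#' @return Numeric vector; `NA` where the denominator is zero.
#' @export
sv_shared_rate <- function(counts) {
  counts <- sv_count_cols(counts)
  den <- counts$match + counts$zero_only + counts$one_only
  ifelse(den > 0, counts$match / den, NA_real_)
}

#' Pad breakpoint intervals
#'
#' Expands both breakpoint intervals by `pad` bp on each side, the padding
#' convention required before paired-interval matching.
#'
#' @param sv SV call tibble.
#' @param pad Padding in bp (default 1).
#' @return The tibble with expanded intervals (clamped at 0).
#' @export
pad_breakpoints <- function(sv, pad = 1L) {
  pad <- as.integer(pad)
  mutate(sv,
         start1 = pmax(.data$start1 - pad, 0L), end1 = .data$end1 + pad,
         start2 = pmax(.data$start2 - pad, 0L), end2 = .data$end2 + pad)
}
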