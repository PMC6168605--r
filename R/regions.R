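# Easy / medium / hard genome stratification.
#
# The easy stratum is the externally curated high-confidence region set;
# the hard stratum is the union of difficult-sequence components
# (centromeres, satellites, low-complexity, high-copy windows) minus any
# portion overlapping the easy set; everything else is medium. Within each
# contig the three strata are disjoint and cover every base.

iranges_of <- function(df) {
  IRanges::reduce(IRanges::IRanges(start = df$start + 1L, end = df$end))
}

ranges_to_tibble <- function(contig, ir, region) {
  if (length(ir) == 0L) {
    return(tibble(contig = character(), start = integer(),
                  end = integer(), region = character()))
  }
  tibble(
    contig = contig,
    start = IRanges::start(ir) - 1L,
    end = IRanges::end(ir),
    region = region
  )
}

#' Build the easy/medium/hard region index
#'
#' @param easy Tibble of high-confidence intervals (`contig`, `start`,
#'   `end`; 0-based half-open), e.g. from [read_bed()].
#' @param hard_components List of tibbles of difficult-region components;
#'   their union, minus any portion overlapping `easy`, becomes the hard
#'   stratum. Overlap subtraction is at interval granularity: the
#'   non-overlapping remainder of a partially overlapping hard interval
#'   stays hard.
#' @param contig_lengths Named vector of contig lengths in bp.
#' @return A `fe_regions` tibble with columns `contig`, `start`, `end`
#'   (0-based half-open) and `region`, forming an exact partition of every
#'   contig.
#' @export
build_region_index <- function(easy, hard_components = list(),
                               contig_lengths) {
  stopifnot(!is.null(names(contig_lengths)))
  if (is.data.frame(hard_components)) {
    hard_components <- list(hard_components)
  }
  hard_all <- if (length(hard_components) > 0L) {
    bind_rows(hard_components)
  } else {
    tibble(contig = character(), start = integer(), end = integer())
  }
  for (df in c(list(easy), list(hard_all))) {
    unknown <- setdiff(unique(df$contig), names(contig_lengths))
    if (length(unknown) > 0L) {
      abort(sprintf("unknown contig in region input: %s",
                    paste(unknown, collapse = ", ")))
    }
    over <- df$end > contig_lengths[df$contig]
    if (any(over)) {
      abort(sprintf("region interval extends past the end of contig %s",
                    df$contig[which(over)[1L]]))
    }
  }
  out <- purrr::map(names(contig_lengths), function(ctg) {
    len <- as.integer(contig_lengths[[ctg]])
    genome <- IRanges::IRanges(start = 1L, end = len)
    ez <- iranges_of(filter(easy, .data$contig == ctg))
    hd_raw <- iranges_of(filter(hard_all, .data$contig == ctg))
    hd <- IRanges::setdiff(hd_raw, ez)
    md <- IRanges::setdiff(IRanges::setdiff(genome, ez), hd)
    bind_rows(
      ranges_to_tibble(ctg, ez, "easy"),
      ranges_to_tibble(ctg, hd, "hard"),
      ranges_to_tibble(ctg, md, "medium")
    )
  }) |>
    list_rbind() |>
    arrange(.data$contig, .data$start)
  attr(out, "contig_lengths") <- contig_lengths
  class(out) <- c("fe_regions", class(out))
  out
}

assert_partition <- function(regions) {
  lens <- attr(regions, "contig_lengths")
  ok <- regions |>
    group_by(.data$contig) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarize(
      covered = sum(.data$end - .data$start),
      gapless = all(.data$start == lag(.data$end, default = 0L)),
      .groups = "drop"
    )
  identical(sort(ok$contig), sort(names(lens))) &&
    all(ok$gapless) &&
    all(ok$covered == lens[ok$contig])
}

#' Region label of a genomic position
#'
#' @param regions A `fe_regions` index from [build_region_index()].
#' @param contig Character vector of contig names.
#' @param pos Integer vector of 1-based positions.
#' @return Character vector of region labels, one per position.
#' @export
classify_position <- function(regions, contig, pos) {
  lens <- attr(regions, "contig_lengths")
  unknown <- setdiff(unique(contig), names(lens))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown contig: %s", paste(unknown, collapse = ", ")))
  }
  if (any(pos < 1L | pos > lens[contig])) {
    abort("position outside contig bounds")
  }
  out <- rep(NA_character_, length(contig))
  for (ctg in unique(contig)) {
    sel <- contig == ctg
    reg <- filter(regions, .data$contig == ctg) |> arrange(.data$start)
    # position pos (1-based) lies in [start, end) when start < pos <= end
    idx <- findInterval(pos[sel] - 1L, reg$start)
    out[sel] <- reg$region[idx]
  }
  out
}

#' Region label of a structural variant
#'
#' An SV is assigned the most difficult label among all regions that either
#' of its (padded) breakpoint intervals overlaps.
#'
#' @param regions A `fe_regions` index.
#' @param sv Tibble of SV calls with `contig1`, `start1`, `end1`,
#'   `contig2`, `start2`, `end2` (0-based half-open).
#' @return Character vector of region labels, one per call.
#' @export
classify_sv_region <- function(regions, sv) {
  if (nrow(sv) == 0L) {
    return(character())
  }
  lab1 <- interval_labels(regions, sv$contig1, sv$start1, sv$end1)
  lab2 <- interval_labels(regions, sv$contig2, sv$start2, sv$end2)
  purrr::map2_chr(lab1, lab2, function(a, b) hardest_region(c(a, b)))
}

# Labels of all region intervals overlapping [start, end) on each contig.
interval_labels <- function(regions, contig, start, end) {
  lens <- attr(regions, "contig_lengths")
  unknown <- setdiff(unique(contig), names(lens))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown contig: %s", paste(unknown, collapse = ", ")))
  }
  out <- vector("list", length(contig))
  for (ctg in unique(contig)) {
    sel <- which(contig == ctg)
    reg <- filter(regions, .data$contig == ctg)
    reg_ir <- IRanges::IRanges(start = reg$start + 1L, end = reg$end)
    q_ir <- IRanges::IRanges(start = start[sel] + 1L, end = end[sel])
    hits <- IRanges::findOverlaps(q_ir, reg_ir)
    lab <- split(reg$region[S4Vectors::subjectHits(hits)],
                 factor(S4Vectors::queryHits(hits), levels = seq_along(sel)))
    for (i in seq_along(sel)) out[[sel[i]]] <- lab[[i]]
  }
  out
}
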