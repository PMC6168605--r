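# BED / BEDPE / PED readers and writers.
#
# BED and BEDPE coordinates are 0-based half-open, as in the formats
# themselves; no conversion is applied on read or write.

read_text_rows <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!stringr::str_starts(lines, "#") & lines != ""]
  stringr::str_split(lines, "\t")
}

check_columns <- function(fields, min_cols, path, what) {
  bad <- which(lengths(fields) < min_cols)
  if (length(bad) > 0L) {
    abort(sprintf("%s record with fewer than %d columns in %s at line %d",
                  what, min_cols, path, bad[1L]))
  }
}

#' Read a BED file
#'
#' @param path Path to a BED file (3+ tab-separated columns, 0-based
#'   half-open intervals). A fourth column, when present, is kept as `name`.
#' @return Tibble with columns `contig`, `start`, `end` (and `name`).
#' @export
read_bed <- function(path) {
  fields <- read_text_rows(path)
  if (length(fields) == 0L) {
    return(tibble(contig = character(), start = integer(), end = integer()))
  }
  check_columns(fields, 3L, path, "BED")
  out <- tibble(
    contig = map_chr(fields, 1L),
    start = as.integer(map_chr(fields, 2L)),
    end = as.integer(map_chr(fields, 3L))
  )
  if (anyNA(out$start) || anyNA(out$end)) {
    abort(sprintf("non-integer BED coordinate in %s at line %d",
                  path, which(is.na(out$start) | is.na(out$end))[1L]))
  }
  if (any(out$end <= out$start)) {
    abort(sprintf("empty or inverted BED interval in %s at line %d",
                  path, which(out$end <= out$start)[1L]))
  }
  if (any(lengths(fields) >= 4L)) {
    out$name <- map_chr(fields, function(f) {
      if (length(f) >= 4L) f[[4L]] else NA_character_
    })
  }
  out
}

#' Write a BED file
#'
#' Rows are written sorted by contig, start, end.
#'
#' @param x Tibble with columns `contig`, `start`, `end` and optionally
#'   `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- arrange(x, .data$contig, .data$start, .data$end)
  cols <- list(x$contig, as.integer(x$start), as.integer(x$end))
  if ("name" %in% names(x)) cols <- c(cols, list(x$name))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

valid_strands <- c("+", "-", ".")

#' Read a BEDPE file of paired SV breakpoints
#'
#' Reads the 10+-column BEDPE dialect used for structural variants: two
#' 0-based half-open breakpoint intervals, name, score, two strands, then a
#' `TYPE` column and a mean-sample-quality (`MSQ`) column. The intervals
#' are taken as already padded for matching.
#'
#' @param path Path to a BEDPE file.
#' @return Tibble with columns `contig1`, `start1`, `end1`, `contig2`,
#'   `start2`, `end2`, `name`, `score`, `strand1`, `strand2`, `svtype`,
#'   `msq`.
#' @export
read_bedpe <- function(path) {
  fields <- read_text_rows(path)
  if (length(fields) == 0L) {
    return(empty_sv_calls())
  }
  check_columns(fields, 10L, path, "BEDPE")
  col <- function(i) map_chr(fields, function(f) {
    if (length(f) >= i) f[[i]] else NA_character_
  })
  out <- tibble(
    contig1 = col(1L), start1 = as.integer(col(2L)), end1 = as.integer(col(3L)),
    contig2 = col(4L), start2 = as.integer(col(5L)), end2 = as.integer(col(6L)),
    name = col(7L), score = suppressWarnings(as.numeric(col(8L))),
    strand1 = col(9L), strand2 = col(10L),
    svtype = col(11L),
    msq = suppressWarnings(as.numeric(col(12L)))
  )
  bad <- which(out$strand1 %not_in% valid_strands |
                 out$strand2 %not_in% valid_strands)
  if (length(bad) > 0L) {
    abort(sprintf("invalid strand in %s at line %d (must be +, - or .)",
                  path, bad[1L]))
  }
  bad <- which(out$end1 <= out$start1 | out$end2 <= out$start2)
  if (length(bad) > 0L) {
    abort(sprintf("empty or inverted breakpoint interval in %s at line %d",
                  path, bad[1L]))
  }
  out
}

empty_sv_calls <- function() {
  tibble(
    contig1 = character(), start1 = integer(), end1 = integer(),
    contig2 = character(), start2 = integer(), end2 = integer(),
    name = character(), score = numeric(),
    strand1 = character(), strand2 = character(),
    svtype = character(), msq = numeric()
  )
}

#' Write a BEDPE file
#'
#' Rows are written sorted by the first, then second, breakpoint.
#'
#' @param x Tibble of SV calls as returned by [read_bedpe()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(x, path) {
  if (any(x$strand1 %not_in% valid_strands |
            x$strand2 %not_in% valid_strands)) {
    abort("invalid strand (must be +, - or .)")
  }
  x <- arrange(x, .data$contig1, .data$start1, .data$end1,
               .data$contig2, .data$start2, .data$end2)
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%d\t%d\t%s\t%s\t%s\t%s\t%s\t%s",
    x$contig1, x$start1, x$end1, x$contig2, x$start2, x$end2,
    x$name, format(x$score, trim = TRUE),
    x$strand1, x$strand2, x$svtype, format(x$msq, trim = TRUE)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a PED pedigree file
#'
#' @param path Path to a 6-column PED file (family, sample, father, mother,
#'   sex, phenotype); `0` denotes a missing parent.
#' @return Tibble with columns `family`, `sample`, `father`, `mother`,
#'   `sex`, `phenotype`; missing parents are `NA`.
#' @export
read_ped <- function(path) {
  fields <- read_text_rows(path)
  if (length(fields) == 0L) {
    return(tibble(family = character(), sample = character(),
                  father = character(), mother = character(),
                  sex = integer(), phenotype = integer()))
  }
  check_columns(fields, 6L, path, "PED")
  out <- tibble(
    family = map_chr(fields, 1L),
    sample = map_chr(fields, 2L),
    father = dplyr::na_if(map_chr(fields, 3L), "0"),
    mother = dplyr::na_if(map_chr(fields, 4L), "0"),
    sex = as.integer(map_chr(fields, 5L)),
    phenotype = as.integer(map_chr(fields, 6L))
  )
  if (any(out$sample == out$father | out$sample == out$mother, na.rm = TRUE)) {
    abort(sprintf("sample listed as its own parent in %s", path))
  }
  out
}

#' Write a PED pedigree file
#'
#' @param ped Tibble as returned by [read_ped()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  lines <- sprintf(
    "%s\t%s\t%s\t%s\t%d\t%d",
    ped$family, ped$sample,
    dplyr::coalesce(ped$father, "0"), dplyr::coalesce(ped$mother, "0"),
    ped$sex, ped$phenotype
  )
  writeLines(lines, path)
  invisible(path)
}

#' Extract parent-offspring trios from a pedigree
#'
#' @param ped Pedigree tibble from [read_ped()].
#' @return Tibble with one row per offspring having both parents present:
#'   columns `family`, `child`, `father`, `mother`.
#' @export
trios_from_ped <- function(ped) {
  ped |>
    filter(!is.na(.data$father), !is.na(.data$mother)) |>
    transmute(family = .data$family, child = .data$sample,
              father = .data$father, mother = .data$mother)
}
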