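# VCF reading/writing for small variants and SV callsets.
#
# VCF positions stay 1-based; interval arithmetic elsewhere in the package
# is 0-based half-open, with conversion only at I/O boundaries.

# Canonicalize a diploid GT string to an unordered "a/b" multiset with
# a <= b; phase separators are ignored. Any missing allele gives NA.
canonical_gt <- function(gt) {
  gt <- stringr::str_replace_all(gt, stringr::fixed("|"), "/")
  parts <- stringr::str_split(gt, stringr::fixed("/"))
  map_chr(parts, function(p) {
    if (length(p) != 2L || any(p == ".") || anyNA(p)) {
      return(NA_character_)
    }
    a <- sort(as.integer(p))
    paste0(a[1L], "/", a[2L])
  })
}

# Per-alt genotype after multiallelic decomposition: alleles equal to the
# alt index become 1, all other called alleles become 0.
decompose_gt <- function(gt, alt_index) {
  out <- rep(NA_character_, length(gt))
  ok <- !is.na(gt)
  if (any(ok)) {
    parts <- stringr::str_split(gt[ok], stringr::fixed("/"))
    out[ok] <- purrr::map2_chr(parts, alt_index[ok], function(p, k) {
      a <- sort(as.integer(as.integer(p) == k))
      paste0(a[1L], "/", a[2L])
    })
  }
  out
}

#' Read one sample's small variants from a VCF
#'
#' Reads a (possibly multi-sample) VCF and returns the decomposed,
#' allele-level small-variant records for one sample. Multiallelic records
#' are split into one row per alternate allele, each carrying the sample's
#' allele presence for that alternate (other alternates collapse to the
#' reference). Records whose only allele is a symbolic deletion placeholder
#' (`*`) or any other symbolic allele are dropped.
#'
#' @param path Path to a VCF (plain text or gzipped).
#' @param sample Sample identifier; must be a genotype column of the VCF.
#' @param drop_uncalled Drop rows where the sample's genotype is missing or
#'   carries no copy of the alternate allele (default `TRUE`), so the result
#'   is the sample's own callset as produced by a per-sample split.
#' @return A tibble with columns `contig`, `pos` (1-based), `ref`, `alt`,
#'   `qual`, `filter`, `gt` (unordered `"a/b"` multiset, `NA` when missing)
#'   and `sample`.
#' @export
read_small_variants <- function(path, sample, drop_uncalled = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) { # single-record VCFs collapse to a vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  if (nrow(fix) == 0L) {
    return(empty_small_variants(sample))
  }
  gt_mat <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt_mat))) {
    gt_mat <- matrix(gt_mat, nrow = nrow(fix),
                     dimnames = list(NULL, names(gt_mat)))
  }
  if (!sample %in% colnames(gt_mat)) {
    abort(sprintf(
      "sample '%s' not present in %s; available samples: %s",
      sample, path, paste(colnames(gt_mat), collapse = ", ")
    ))
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1L]
    abort(sprintf("malformed POS in %s at record %d", path, bad))
  }
  rec <- tibble(
    contig = fix[, "CHROM"],
    pos = pos,
    ref = fix[, "REF"],
    alt_field = fix[, "ALT"],
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    filter = fix[, "FILTER"],
    gt_raw = canonical_gt(unname(gt_mat[, sample]))
  )
  out <- rec |>
    mutate(.record = dplyr::row_number()) |>
    mutate(alt = stringr::str_split(.data$alt_field, ",")) |>
    tidyr::unnest("alt") |>
    group_by(.data$.record) |>
    mutate(alt_index = dplyr::row_number()) |>
    ungroup() |>
    filter(!is_symbolic_allele(.data$alt)) |>
    mutate(gt = decompose_gt(.data$gt_raw, .data$alt_index)) |>
    select("contig", "pos", "ref", "alt", "qual", "filter", "gt") |>
    mutate(sample = .env$sample)
  if (drop_uncalled) {
    out <- filter(out, !is.na(.data$gt) & .data$gt != "0/0")
  }
  out
}

is_symbolic_allele <- function(alt) {
  alt == "*" | stringr::str_starts(alt, stringr::fixed("<"))
}

empty_small_variants <- function(sample = character()) {
  tibble(
    contig = character(), pos = integer(), ref = character(),
    alt = character(), qual = numeric(), filter = character(),
    gt = character(), sample = character()
  )
}

#' Write small variants to a multi-sample VCF
#'
#' Writes a long tibble of per-sample small-variant records (as produced by
#' the synthetic generator) to a VCF 4.2 file with one genotype column per
#' sample. Samples without a row at a site are written as `0/0`.
#'
#' @param variants Tibble with columns `contig`, `pos`, `ref`, `alt`,
#'   `qual`, `filter`, `gt`, `sample`.
#' @param path Output path.
#' @param contig_lengths Named numeric vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, path, contig_lengths = NULL) {
  stopifnot(all(c("contig", "pos", "ref", "alt", "qual", "filter",
                  "gt", "sample") %in% names(variants)))
  samples <- sort(unique(variants$sample))
  wide <- variants |>
    mutate(gt = dplyr::coalesce(.data$gt, "./.")) |>
    tidyr::pivot_wider(
      id_cols = c("contig", "pos", "ref", "alt", "qual", "filter"),
      names_from = "sample", values_from = "gt", values_fill = "0/0"
    ) |>
    arrange(.data$contig, .data$pos, .data$ref, .data$alt)
  for (s in samples) {
    if (!s %in% names(wide)) wide[[s]] <- "0/0"
  }
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(contig_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>",
              names(contig_lengths), as.integer(contig_lengths))
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t")
  )
  gts <- do.call(paste, c(unname(as.list(wide[samples])), sep = "\t"))
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t%s\t%s\t.\tGT\t%s",
    wide$contig, wide$pos, wide$ref, wide$alt,
    ifelse(is.na(wide$qual), ".", format(round(wide$qual, 2),
                                         trim = TRUE, scientific = FALSE)),
    wide$filter, gts
  )
  writeLines(c(header, body), path)
  invisible(path)
}
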