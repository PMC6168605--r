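# Variant normalization: shared-base trimming and reference left-alignment.
#
# Two callsets from different pipelines can encode the same allelic event
# with different (pos, ref, alt) triples; exact-key matching is only
# well-defined after every record is reduced to its canonical, left-aligned
# minimal representation.

normalize_one <- function(pos, ref, alt, contig_seq = NULL) {
  if (nchar(ref) == 0L || nchar(alt) == 0L) {
    abort("ref and alt alleles must be non-empty")
  }
  if (!is.null(contig_seq)) {
    obs <- substr(contig_seq, pos, pos + nchar(ref) - 1L)
    if (!identical(obs, ref)) {
      abort(sprintf(
        "ref allele '%s' at pos %d does not match reference ('%s')",
        ref, pos, obs
      ))
    }
  }
  repeat {
    rn <- nchar(ref); an <- nchar(alt)
    last_eq <- substr(ref, rn, rn) == substr(alt, an, an)
    if (last_eq && rn > 1L && an > 1L) {
      ref <- substr(ref, 1L, rn - 1L)
      alt <- substr(alt, 1L, an - 1L)
    } else if (last_eq && !is.null(contig_seq) && pos > 1L) {
      # extend left with the reference base, then retry trimming
      base <- substr(contig_seq, pos - 1L, pos - 1L)
      ref <- paste0(base, substr(ref, 1L, rn - 1L))
      alt <- paste0(base, substr(alt, 1L, an - 1L))
      pos <- pos - 1L
    } else {
      break
    }
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize small-variant records
#'
#' Trims shared trailing, then leading, bases from each ref/alt pair and,
#' when reference sequence is supplied, left-aligns indels to their minimal
#' position (trailing shared bases are repeatedly replaced by extending the
#' alleles leftwards along the reference). The operation is idempotent, so
#' any two encodings of the same allelic event map to the same
#' `(contig, pos, ref, alt)` key.
#'
#' Without a reference only the trimming step is applied; this is
#' sufficient when all callsets come from one variant caller that already
#' left-aligns, and is the mode used on synthetic callsets.
#'
#' @param variants Tibble with columns `contig`, `pos`, `ref`, `alt`
#'   (other columns pass through).
#' @param reference Optional named character vector of contig sequences.
#' @return The tibble with normalized `pos`, `ref`, `alt`.
#' @export
#' @examples
#' v <- tibble::tibble(contig = "c1", pos = 100L, ref = "CT", alt = "CA")
#' normalize_variants(v)
normalize_variants <- function(variants, reference = NULL) {
  if (nrow(variants) == 0L) {
    return(variants)
  }
  bad <- !grepl("^[ACGTN]+$", variants$ref) | !grepl("^[ACGTN]+$", variants$alt)
  if (any(bad)) {
    abort(sprintf("ref/alt alleles must be non-empty strings over ACGTN (row %d)",
                  which(bad)[1L]))
  }
  if (any(variants$ref == variants$alt)) {
    abort("ref and alt must differ")
  }
  norm <- pmap(
    list(variants$pos, variants$ref, variants$alt, variants$contig),
    function(pos, ref, alt, contig) {
      seq <- if (is.null(reference)) NULL else reference[[contig]]
      normalize_one(as.integer(pos), ref, alt, seq)
    }
  )
  variants$pos <- map_int(norm, "pos")
  variants$ref <- map_chr(norm, "ref")
  variants$alt <- map_chr(norm, "alt")
  variants
}

#' Variant class from allele lengths
#'
#' @param ref,alt Character vectors of normalized alleles.
#' @return `"snv"` where both alleles have length 1, `"indel"` otherwise.
#' @export
variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "snv", "indel")
}
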