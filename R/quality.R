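#' Parse a base-quality binning scheme string
#'
#' A binning scheme maps raw Phred base qualities onto a small set of
#' representative values so that recalibrated alignments compress well.
#' The scheme is written as ascending `threshold:value` pairs separated by
#' commas (the `binQualS` dialect used by bamUtil): a quality `q` is mapped
#' to the value of the largest threshold that is `<= q`.
#'
#' @param scheme A scheme string such as
#'   `"0:2,3:3,4:4,5:5,6:6,7:10,13:20,23:30,33:40"`.
#' @return A tibble with integer columns `threshold` and `value`, one row
#'   per bin, thresholds strictly increasing and values non-decreasing.
#' @export
#' @examples
#' parse_bin_scheme(four_bin_scheme())
parse_bin_scheme <- function(scheme) {
  if (is.data.frame(scheme)) {
    stopifnot(all(c("threshold", "value") %in% names(scheme)))
    out <- tibble(
      threshold = as.integer(scheme$threshold),
      value = as.integer(scheme$value)
    )
  } else {
    stopifnot(is.character(scheme), length(scheme) == 1L)
    pairs <- stringr::str_split_1(scheme, ",")
    parts <- stringr::str_split(pairs, ":")
    if (any(lengths(parts) != 2L)) {
      abort("each bin must be written as 'threshold:value'")
    }
    out <- tibble(
      threshold = as.integer(map_chr(parts, 1L)),
      value = as.integer(map_chr(parts, 2L))
    )
  }
  if (anyNA(out$threshold) || anyNA(out$value)) {
    abort("bin thresholds and values must be integers")
  }
  if (any(diff(out$threshold) <= 0L)) {
    abort("bin thresholds must be strictly increasing")
  }
  if (any(diff(out$value) < 0L)) {
    abort("binned values must be non-decreasing")
  }
  out
}

#' The four-bin quality scheme
#'
#' The binning scheme adopted by the harmonized pipelines: qualities below 7
#' are kept (sub-Phred-7 scores are preserved verbatim by recalibration),
#' and higher qualities collapse to the four representative values
#' 10, 20, 30 and 40.
#'
#' @return The scheme string `"0:2,3:3,4:4,5:5,6:6,7:10,13:20,23:30,33:40"`.
#' @export
four_bin_scheme <- function() {
  "0:2,3:3,4:4,5:5,6:6,7:10,13:20,23:30,33:40"
}

#' Bin Phred quality scores
#'
#' Maps each quality to the binned value of the largest scheme threshold
#' `<= q`. The map is a monotone non-decreasing step function and is
#' idempotent: binning an already binned value returns it unchanged.
#'
#' @param q Integer vector of Phred qualities, all `>= 0`.
#' @param scheme A scheme string or parsed scheme tibble
#'   (default [four_bin_scheme()]).
#' @return Integer vector of binned qualities, same length as `q`.
#' @export
#' @examples
#' bin_quality(c(0, 6, 25, 40))
bin_quality <- function(q, scheme = four_bin_scheme()) {
  sch <- parse_bin_scheme(scheme)
  q <- as.integer(q)
  if (anyNA(q) || any(q < 0L)) {
    abort("qualities must be non-negative integers")
  }
  if (any(q < sch$threshold[1L])) {
    abort("quality below the first bin threshold")
  }
  idx <- findInterval(q, sch$threshold)
  sch$value[idx]
}

#' Downsampling probability for coverage matching
#'
#' When comparing sequencing replicates of one individual, coverage
#' differences are removed by randomly downsampling every replicate to the
#' coverage of the shallowest one. The retention probability is the target
#' (lowest) coverage divided by the replicate's own coverage.
#'
#' @param target_cov Target mean coverage (the lowest among replicates).
#' @param sample_cov The replicate's own mean coverage.
#' @return Fraction in `(0, 1]`, vectorized over its arguments.
#' @export
#' @examples
#' downsample_probability(20, 40)
downsample_probability <- function(target_cov, sample_cov) {
  if (any(!is.finite(target_cov)) || any(!is.finite(sample_cov))) {
    abort("coverages must be finite numbers")
  }
  if (any(target_cov <= 0)) {
    abort("target coverage must be positive")
  }
  if (any(target_cov > sample_cov)) {
    abort("target coverage must not exceed the sample's coverage")
  }
  target_cov / sample_cov
}
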