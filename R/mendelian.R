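# Trio Mendelian-error classification and ME rates by concordance status.
#
# A site-trio is informative when a Mendelian error would be detectable
# given the parental genotypes; het x het parents admit every child
# genotype, so such sites are uninformative. The ME rate is
# errors / informative sites.

gt_alleles <- function(gt) {
  parts <- stringr::str_split(gt, stringr::fixed("/"))
  purrr::map(parts, function(p) {
    if (length(p) != 2L || anyNA(suppressWarnings(as.integer(p)))) {
      abort("genotypes must be diploid 'a/b' multisets")
    }
    as.integer(p)
  })
}

is_het <- function(gt) {
  !is.na(gt) & stringr::str_detect(gt, "^(\\d+)/(\\d+)$") &
    purrr::map_lgl(stringr::str_split(gt, "/"),
                   function(p) p[1L] != p[2L])
}

#' Prefilter a trio site
#'
#' A site-trio enters the Mendelian analysis only when no genotype is
#' missing and at least one of the three genotypes is heterozygous
#' (uniformly homozygous sites carry no transmission information worth
#' scoring and are excluded).
#'
#' @param child,father,mother Character vectors of `"a/b"` genotype
#'   multisets; `NA` (or any genotype containing `.`) is missing.
#' @return Logical vector: keep the site-trio?
#' @export
trio_site_keep <- function(child, father, mother) {
  missing_gt <- function(gt) {
    is.na(gt) | stringr::str_detect(gt, stringr::fixed("."))
  }
  any_missing <- missing_gt(child) | missing_gt(father) | missing_gt(mother)
  keep <- !any_missing
  keep[keep] <- is_het(child[keep]) | is_het(father[keep]) |
    is_het(mother[keep])
  keep
}

#' Classify a trio genotype combination
#'
#' For each biallelic site-trio (after [trio_site_keep()]):
#' `informative_error` when no choice of one allele from the father and
#' one from the mother reproduces the child's genotype multiset;
#' `uninformative` when both parents are heterozygous (every child
#' genotype is transmission-consistent, so no error is detectable);
#' `informative_consistent` otherwise.
#'
#' @inheritParams trio_site_keep
#' @return Character vector over
#'   `{uninformative, informative_consistent, informative_error}`.
#' @export
#' @examples
#' classify_trio("1/1", "0/0", "0/1")
classify_trio <- function(child, father, mother) {
  c_al <- gt_alleles(child)
  f_al <- gt_alleles(father)
  m_al <- gt_alleles(mother)
  purrr::pmap_chr(list(c_al, f_al, m_al), function(ch, fa, mo) {
    ch <- sort(ch)
    consistent <- FALSE
    for (x in fa) {
      for (y in mo) {
        if (identical(sort(c(x, y)), ch)) consistent <- TRUE
      }
    }
    if (!consistent) {
      "informative_error"
    } else if (fa[1L] != fa[2L] && mo[1L] != mo[2L]) {
      "uninformative"
    } else {
      "informative_consistent"
    }
  })
}

#' Mendelian error rate
#'
#' Number of informative-error sites divided by the total number of
#' informative sites.
#'
#' @param classification Character vector of [classify_trio()] outcomes.
#' @return Scalar rate; `NA` when there are no informative sites.
#' @export
me_rate <- function(classification) {
  err <- sum(classification == "informative_error")
  inf <- err + sum(classification == "informative_consistent")
  if (inf == 0L) NA_real_ else err / inf
}

#' Mendelian error rates stratified by concordance status
#'
#' Joins the per-key concordance status of a pairwise comparison (for the
#' offspring sample) with the trio's genotypes as seen by the *first*
#' pipeline of the pair, prefilters, classifies each site-trio, and
#' returns informative/error counts and ME rates per
#' (concordance class, region). Keys whose status is `concordant` form the
#' concordant class; `a_only`, `b_only` and `gt_mismatch` keys form the
#' discordant class.
#'
#' @param comparison An `fe_comparison` for the offspring sample
#'   (pipeline a = the first pipeline, whose genotypes are used).
#' @param genotypes Long genotype tibble of the first pipeline with
#'   columns `contig`, `pos`, `ref`, `alt`, `gt`, `sample`, including
#'   hom-ref rows for non-carriers (e.g. a cohort VCF read with
#'   `drop_uncalled = FALSE`); sites absent for a sample are missing.
#' @param trio One-row tibble (or list) with `child`, `father`, `mother`
#'   sample ids.
#' @return Tibble with columns `concordance`, `region`, `informative`,
#'   `errors`, `me_rate`, plus an `uninformative` count.
#' @export
me_by_concordance <- function(comparison, genotypes, trio) {
  stopifnot(inherits(comparison, "fe_comparison"))
  members <- c(child = trio$child[[1L]], father = trio$father[[1L]],
               mother = trio$mother[[1L]])
  missing_members <- setdiff(members, unique(genotypes$sample))
  if (length(missing_members) > 0L) {
    abort(sprintf("trio member(s) absent from genotype table: %s",
                  paste(missing_members, collapse = ", ")))
  }
  gt_of <- function(who) {
    genotypes |>
      filter(.data$sample == members[[who]]) |>
      select(dplyr::all_of(variant_key_cols), "gt") |>
      rlang::set_names(c(variant_key_cols, paste0("gt_", who)))
  }
  sites <- comparison$status |>
    select(dplyr::all_of(variant_key_cols), "region", "status") |>
    left_join(gt_of("child"), by = variant_key_cols) |>
    left_join(gt_of("father"), by = variant_key_cols) |>
    left_join(gt_of("mother"), by = variant_key_cols) |>
    mutate(concordance = ifelse(.data$status == "concordant",
                                "concordant", "discordant")) |>
    filter(trio_site_keep(.data$gt_child, .data$gt_father, .data$gt_mother)) |>
    mutate(classification = classify_trio(.data$gt_child, .data$gt_father,
                                          .data$gt_mother))
  region_lvls <- if (all(sites$region == "all") || nrow(sites) == 0L) {
    unique(c(comparison$counts$region))
  } else {
    REGION_LEVELS
  }
  sites |>
    count(.data$concordance, .data$region, .data$classification) |>
    tidyr::pivot_wider(names_from = "classification", values_from = "n",
                       values_fill = 0L) |>
    (\(df) {
      for (col in c("uninformative", "informative_consistent",
                    "informative_error")) {
        if (!col %in% names(df)) df[[col]] <- 0L
      }
      df
    })() |>
    tidyr::complete(
      concordance = c("concordant", "discordant"), region = region_lvls,
      fill = list(uninformative = 0L, informative_consistent = 0L,
                  informative_error = 0L)
    ) |>
    transmute(
      concordance = .data$concordance, region = .data$region,
      informative = .data$informative_consistent + .data$informative_error,
      errors = .data$informative_error,
      uninformative = .data$uninformative,
      me_rate = ifelse(.data$informative > 0,
                       .data$errors / .data$informative, NA_real_)
    ) |>
    arrange(.data$concordance, .data$region)
}
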