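# Seeded synthetic multi-pipeline study generator.
#
# The generator emulates the analytic structure of a multi-center
# harmonization study: one truth callset per sample, several pipelines
# that each miss a small region-dependent fraction of true calls and add
# a few spurious ones, lower variant quality at sites any pipeline
# misses, trio genotypes with Mendelian-inconsistent child calls injected
# only at those borderline sites, and SV breakpoints reproduced with
# small bounded jitter. It does not model reads, coverage, duplication
# or caller internals.

GT_LEVELS <- c("0/0", "0/1", "1/1")

#' Simulation configuration
#'
#' Defaults describe a desk-scale version of a five-pipeline
#' post-harmonization study: a 10 Mb two-contig genome split
#' 72% / 19.5% / 8.5% into easy/medium/hard strata, 50,000 true small
#' variants (90% SNVs), 500 SVs, three parent-offspring trios, per-region
#' dropout rates that put most discordance in the hard stratum, a
#' rare-skewed allele-frequency spectrum, a 23% Mendelian-inconsistency
#' injection rate at discordant sites, and concordant-site variant
#' qualities roughly two hundred times the discordant-site ones.
#'
#' @param seed Integer seed; every simulated quantity derives from it.
#' @param contigs Named vector of contig lengths in bp.
#' @param region_fractions Named fractions of the genome assigned to
#'   `easy`, `medium`, `hard` (must sum to 1).
#' @param n_truth_snv,n_truth_indel,n_truth_sv Truth counts.
#' @param pipelines Character vector of pipeline labels.
#' @param n_trios Number of parent-offspring trios (3 samples each).
#' @param dropout Named per-region probability that a pipeline misses a
#'   true call in one sample.
#' @param spurious_per_mb Named per-region rate of spurious calls per
#'   pipeline per sample per Mb.
#' @param genotype_error Named per-region probability that a retained
#'   carrier genotype is mis-genotyped (het/hom-alt flip).
#' @param af_beta Beta(shape1, shape2) allele-frequency spectrum for
#'   truth sites.
#' @param mendelian_error_rate_discordant Probability that a trio
#'   offspring's genotype is replaced by a transmission-inconsistent one
#'   at a site some pipeline misses.
#' @param qual_concordant,qual_discordant `c(mean, sd)` of the (0-truncated
#'   normal) QUAL distributions for sites kept by every pipeline versus
#'   the rest.
#' @param sv_jitter_bp Maximum per-breakpoint displacement (uniform
#'   integer in `[-j, j]`) applied per pipeline.
#' @param sv_type_flip_prob,sv_strand_flip_prob Per-pipeline probabilities
#'   of mistyping an SV / reporting it with inverted strands.
#' @param sv_dropout Optional named per-region SV dropout probabilities;
#'   defaults to `dropout`.
#' @return A validated list of class `fe_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       contigs = c(sim1 = 6e6, sim2 = 4e6),
                       region_fractions = c(easy = 0.72, medium = 0.195,
                                            hard = 0.085),
                       n_truth_snv = 45000L,
                       n_truth_indel = 5000L,
                       n_truth_sv = 500L,
                       pipelines = paste0("center", 1:5),
                       n_trios = 3L,
                       dropout = c(easy = 0.001, medium = 0.005,
                                   hard = 0.03),
                       spurious_per_mb = c(easy = 0.2, medium = 1,
                                           hard = 5),
                       genotype_error = c(easy = 5e-4, medium = 2e-3,
                                          hard = 1e-2),
                       af_beta = c(1, 9),
                       mendelian_error_rate_discordant = 0.23,
                       qual_concordant = c(mean = 2000, sd = 600),
                       qual_discordant = c(mean = 10, sd = 6),
                       sv_jitter_bp = 1L,
                       sv_type_flip_prob = 0.01,
                       sv_strand_flip_prob = 0.01,
                       sv_dropout = NULL) {
  cfg <- list(
    seed = as.integer(seed), contigs = contigs,
    region_fractions = region_fractions[REGION_LEVELS],
    n_truth_snv = as.integer(n_truth_snv),
    n_truth_indel = as.integer(n_truth_indel),
    n_truth_sv = as.integer(n_truth_sv),
    pipelines = pipelines, n_trios = as.integer(n_trios),
    dropout = dropout[REGION_LEVELS],
    spurious_per_mb = spurious_per_mb[REGION_LEVELS],
    genotype_error = genotype_error[REGION_LEVELS],
    af_beta = af_beta,
    mendelian_error_rate_discordant = mendelian_error_rate_discordant,
    qual_concordant = qual_concordant, qual_discordant = qual_discordant,
    sv_jitter_bp = as.integer(sv_jitter_bp),
    sv_type_flip_prob = sv_type_flip_prob,
    sv_strand_flip_prob = sv_strand_flip_prob,
    sv_dropout = (sv_dropout %||% dropout)[REGION_LEVELS]
  )
  names(cfg$region_fractions) <- REGION_LEVELS
  names(cfg$dropout) <- REGION_LEVELS
  names(cfg$spurious_per_mb) <- REGION_LEVELS
  names(cfg$genotype_error) <- REGION_LEVELS
  names(cfg$sv_dropout) <- REGION_LEVELS
  probs <- c(cfg$dropout, cfg$genotype_error, cfg$sv_dropout,
             cfg$mendelian_error_rate_discordant,
             cfg$sv_type_flip_prob, cfg$sv_strand_flip_prob)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1)) {
    abort("all probabilities must lie in [0, 1]")
  }
  if (abs(sum(cfg$region_fractions) - 1) > 1e-9) {
    abort("region fractions must sum to 1")
  }
  if (any(c(cfg$n_truth_snv, cfg$n_truth_indel, cfg$n_truth_sv) < 0)) {
    abort("truth counts must be non-negative")
  }
  if (is.null(names(cfg$contigs)) || any(cfg$contigs <= 0)) {
    abort("contigs must be a named vector of positive lengths")
  }
  structure(cfg, class = "fe_sim_config")
}

# Partition each contig into labeled windows matching the genome-wide
# fractions; windows are shuffled so strata interleave along the contig.
simulate_regions <- function(cfg, n_windows = 20L) {
  purrr::map(names(cfg$contigs), function(ctg) {
    len <- as.integer(cfg$contigs[[ctg]])
    bounds <- unique(round(seq(0L, len, length.out = n_windows + 1L)))
    nw <- length(bounds) - 1L
    quota <- floor(cfg$region_fractions * nw)
    rem <- nw - sum(quota)
    if (rem > 0L) {
      extra <- order(cfg$region_fractions * nw - quota,
                     decreasing = TRUE)[seq_len(rem)]
      quota[extra] <- quota[extra] + 1L
    }
    labels <- sample(rep(REGION_LEVELS, times = quota))
    tibble(contig = ctg, start = as.integer(bounds[-length(bounds)]),
           end = as.integer(bounds[-1L]), region = labels)
  }) |>
    list_rbind() |>
    arrange(.data$contig, .data$start)
}

random_alleles <- function(class_vec) {
  n <- length(class_vec)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- purrr::map_chr(ref, function(r) sample(setdiff(bases, r), 1L))
  indel <- which(class_vec == "indel")
  if (length(indel) > 0L) {
    k <- sample(1:6, length(indel), replace = TRUE)
    tail_seq <- purrr::map_chr(k, function(m) {
      paste(sample(bases, m, replace = TRUE), collapse = "")
    })
    is_del <- runif(length(indel)) < 0.5
    ref[indel] <- ifelse(is_del, paste0(ref[indel], tail_seq), ref[indel])
    alt[indel] <- ifelse(is_del, substr(ref[indel], 1L, 1L),
                         paste0(ref[indel], tail_seq))
  }
  list(ref = ref, alt = alt)
}

mendelian_children <- function(father, mother) {
  fa <- stringr::str_split(father, "/")
  mo <- stringr::str_split(mother, "/")
  purrr::map2(fa, mo, function(f, m) {
    f <- as.integer(f); m <- as.integer(m)
    kids <- character()
    for (x in f) {
      for (y in m) {
        kids <- c(kids, paste(sort(c(x, y)), collapse = "/"))
      }
    }
    unique(kids)
  })
}

#' Simulate the truth layer of a multi-pipeline study
#'
#' Generates the region partition, truth small variants and SVs, the
#' pedigree, per-sample truth genotypes (children by Mendelian
#' transmission), the per-(variant, sample, pipeline) dropout mask, and —
#' at carrier sites flagged as discordant by that mask — injected
#' transmission-inconsistent offspring genotypes. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `fe_truth` with elements `config`, `regions`
#'   (an `fe_regions` partition), `variants`, `genotypes`, `dropout`,
#'   `sv`, `pedigree`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "fe_sim_config"))
  set.seed(config$seed)
  regions <- simulate_regions(config)
  attr(regions, "contig_lengths") <- config$contigs
  class(regions) <- c("fe_regions", class(regions))

  n_small <- config$n_truth_snv + config$n_truth_indel
  if (n_small > 0.5 * sum(config$contigs)) {
    abort("contigs too short for the requested variant count")
  }
  contig_of <- sample(names(config$contigs), n_small, replace = TRUE,
                      prob = config$contigs / sum(config$contigs))
  pos <- purrr::map_int(contig_of, function(ctg) {
    # leave headroom so multi-base deletion alleles stay on the contig
    sample.int(as.integer(config$contigs[[ctg]]) - 10L, 1L)
  })
  dup <- duplicated(paste0(contig_of, ":", pos))
  while (any(dup)) {
    pos[dup] <- purrr::map_int(contig_of[dup], function(ctg) {
      sample.int(as.integer(config$contigs[[ctg]]) - 10L, 1L)
    })
    dup <- duplicated(paste0(contig_of, ":", pos))
  }
  class_vec <- rep(c("snv", "indel"),
                   times = c(config$n_truth_snv, config$n_truth_indel))
  alleles <- random_alleles(class_vec)
  variants <- tibble(
    variant_id = seq_len(n_small),
    contig = contig_of, pos = pos,
    ref = alleles$ref, alt = alleles$alt, class = class_vec,
    af = rbeta(n_small, config$af_beta[1L], config$af_beta[2L])
  ) |>
    mutate(region = classify_position(regions, .data$contig, .data$pos)) |>
    arrange(.data$contig, .data$pos)

  pedigree <- tibble(
    family = rep(sprintf("fam%02d", seq_len(config$n_trios)), each = 3L),
    member = rep(c("father", "mother", "child"), config$n_trios)
  ) |>
    mutate(
      sample = paste0(.data$family, "_", .data$member),
      father = ifelse(.data$member == "child",
                      paste0(.data$family, "_father"), NA_character_),
      mother = ifelse(.data$member == "child",
                      paste0(.data$family, "_mother"), NA_character_),
      sex = dplyr::case_when(.data$member == "father" ~ 1L,
                             .data$member == "mother" ~ 2L,
                             .default = sample(1:2, dplyr::n(),
                                               replace = TRUE)),
      phenotype = 0L
    ) |>
    select("family", "sample", "father", "mother", "sex", "phenotype")

  founders <- filter(pedigree, is.na(.data$father))$sample
  trios <- trios_from_ped(pedigree)

  founder_gt <- purrr::map(founders, function(s) {
    g <- rbinom(n_small, 2L, variants$af)
    tibble(variant_id = variants$variant_id, sample = s,
           gt = GT_LEVELS[g + 1L])
  }) |> list_rbind()

  transmit <- function(gt) {
    g <- match(gt, GT_LEVELS) - 1L
    ifelse(g == 1L, rbinom(length(g), 1L, 0.5), as.integer(g == 2L))
  }
  child_gt <- purrr::pmap(trios, function(family, child, father, mother) {
    fa <- filter(founder_gt, .data$sample == father)$gt
    mo <- filter(founder_gt, .data$sample == mother)$gt
    g <- transmit(fa) + transmit(mo)
    tibble(variant_id = variants$variant_id, sample = child,
           gt = GT_LEVELS[g + 1L])
  }) |> list_rbind()

  genotypes <- bind_rows(founder_gt, child_gt) |>
    mutate(carrier = .data$gt != "0/0", corrupted = FALSE)

  # per-(variant, sample, pipeline) dropout mask over carrier records
  carriers <- genotypes |>
    filter(.data$carrier) |>
    select("variant_id", "sample") |>
    left_join(select(variants, "variant_id", "region"), by = "variant_id")
  dropout <- tidyr::crossing(carriers, pipeline = config$pipelines) |>
    mutate(dropped = runif(dplyr::n()) <
             unname(config$dropout[.data$region]))

  discordant_any <- dropout |>
    group_by(.data$variant_id, .data$sample) |>
    summarize(discordant = any(.data$dropped), .groups = "drop")

  # Inject transmission-inconsistent offspring genotypes at flagged
  # (discordant) sites. Downstream trio analysis only sees sites where no
  # genotype is missing and some trio member is heterozygous, and only
  # alt-carrying child genotypes survive in callsets; the one parental
  # combination where an injected error stays analyzable is
  # het x hom-ref (child flips to 1/1). The per-site injection
  # probability at those sites is calibrated against the flagged-site
  # combination counts so that the measured ME rate among analyzable
  # informative discordant sites is an unbiased estimate of the
  # configured rate.
  m <- config$mendelian_error_rate_discordant
  injection <- NULL
  if (m > 0 && nrow(trios) > 0L) {
    parent_gt <- genotypes |>
      select("variant_id", "sample", "gt")
    flagged <- discordant_any |>
      filter(.data$discordant, .data$sample %in% trios$child) |>
      left_join(trios, by = c(sample = "child")) |>
      left_join(parent_gt |> rlang::set_names(c("variant_id", "father",
                                                "gt_father")),
                by = c("variant_id", "father")) |>
      left_join(parent_gt |> rlang::set_names(c("variant_id", "mother",
                                                "gt_mother")),
                by = c("variant_id", "mother")) |>
      mutate(
        combo = dplyr::case_when(
          (.data$gt_father == "0/1" & .data$gt_mother == "0/0") |
            (.data$gt_father == "0/0" & .data$gt_mother == "0/1") ~
            "het_homref",
          (.data$gt_father == "0/0" & .data$gt_mother == "1/1") |
            (.data$gt_father == "1/1" & .data$gt_mother == "0/0") ~
            "homref_homalt",
          (.data$gt_father == "0/1" & .data$gt_mother == "1/1") |
            (.data$gt_father == "1/1" & .data$gt_mother == "0/1") ~
            "het_homalt",
          .default = "other"
        )
      )
    n_injectable <- sum(flagged$combo == "het_homref")
    n_analyzable <- sum(flagged$combo %in%
                          c("het_homref", "homref_homalt", "het_homalt"))
    injection <- list(n_flagged = nrow(flagged),
                      n_injectable = n_injectable,
                      n_analyzable = n_analyzable)
    if (n_injectable > 0L) {
      alpha <- min(m * n_analyzable / n_injectable, 1)
      injection$alpha <- alpha
      if (alpha * n_injectable / n_analyzable < m - 1e-12) {
        warn("injection rate capped: too few het x hom-ref sites")
      }
      hit <- flagged |>
        filter(.data$combo == "het_homref") |>
        filter(runif(dplyr::n()) < alpha)
      if (nrow(hit) > 0L) {
        idx <- match(paste0(hit$variant_id, "_", hit$sample),
                     paste0(genotypes$variant_id, "_", genotypes$sample))
        genotypes$gt[idx] <- "1/1"
        genotypes$corrupted[idx] <- TRUE
        genotypes$carrier[idx] <- TRUE
      }
    }
  }

  sv <- simulate_truth_sv(config, regions)

  structure(
    list(config = config, regions = regions, variants = variants,
         genotypes = genotypes, dropout = dropout, sv = sv,
         pedigree = pedigree, injection = injection),
    class = "fe_truth"
  )
}

simulate_truth_sv <- function(config, regions) {
  n <- config$n_truth_sv
  if (n == 0L) {
    return(tibble(sv_id = character(), contig1 = character(),
                  start1 = integer(), end1 = integer(),
                  contig2 = character(), start2 = integer(),
                  end2 = integer(), strand1 = character(),
                  strand2 = character(), svtype = character(),
                  region = character()))
  }
  min_len <- min(config$contigs)
  if (min_len < 2e5) {
    abort("contigs too short for SV simulation")
  }
  ctg <- sample(names(config$contigs), n, replace = TRUE,
                prob = config$contigs / sum(config$contigs))
  size <- sample(500:50000, n, replace = TRUE)
  b1 <- purrr::map2_int(ctg, size, function(c1, s) {
    sample.int(as.integer(config$contigs[[c1]]) - s - 200L, 1L) + 100L
  })
  b2 <- b1 + size
  svtype <- sample(c("DEL", "DUP", "INV"), n, replace = TRUE,
                   prob = c(0.5, 0.25, 0.25))
  inv_minus <- runif(n) < 0.5
  strand1 <- dplyr::case_when(svtype == "DEL" ~ "+", svtype == "DUP" ~ "-",
                              inv_minus ~ "-", .default = "+")
  strand2 <- dplyr::case_when(svtype == "DEL" ~ "-", svtype == "DUP" ~ "+",
                              inv_minus ~ "-", .default = "+")
  sv <- tibble(
    sv_id = sprintf("sv%04d", seq_len(n)),
    contig1 = ctg, start1 = b1 - 1L, end1 = b1 + 2L,
    contig2 = ctg, start2 = b2 - 1L, end2 = b2 + 2L,
    strand1 = strand1, strand2 = strand2, svtype = svtype
  )
  sv$region <- classify_sv_region(regions, sv)
  arrange(sv, .data$contig1, .data$start1)
}

truncated_normal <- function(n, location_scale) {
  pmax(rnorm(n, location_scale[[1L]], location_scale[[2L]]), 1)
}

#' Emit per-pipeline callsets from a simulated truth
#'
#' Materializes each pipeline's small-variant and SV callsets: carrier
#' genotypes minus the pre-drawn dropouts (dropped carriers appear as
#' missing genotypes in the cohort table), genotype errors (het/hom-alt
#' flips) at the configured per-region rate, spurious calls at positions
#' absent from the truth, site QUALs drawn from the concordant
#' distribution when every pipeline kept every carrier call at the site
#' and from the discordant distribution otherwise, and SVs with
#' per-pipeline breakpoint jitter, type flips and strand flips.
#'
#' @param truth An `fe_truth` from [simulate_truth()].
#' @param config The same [sim_config()] used for the truth.
#' @return A list of class `fe_callsets` with `small` (long tibble:
#'   `pipeline`, `sample`, `contig`, `pos`, `ref`, `alt`, `qual`,
#'   `filter`, `gt`, `class`, `region`), `sv` (long tibble of per-pipeline
#'   padded SV calls with `msq`), `pipelines`, `samples`.
#' @export
emit_pipeline_callsets <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "fe_truth"))
  # distinct stream from the truth layer; modulus keeps it a valid seed
  set.seed(config$seed %% 2147483646L + 1L)
  variants <- truth$variants
  pipelines <- config$pipelines

  # site-level QUAL class: concordant iff no carrier record of the site
  # was dropped by any pipeline
  site_discordant <- truth$dropout |>
    group_by(.data$variant_id) |>
    summarize(discordant = any(.data$dropped), .groups = "drop")
  qual_tbl <- tidyr::crossing(
    variant_id = variants$variant_id, pipeline = pipelines
  ) |>
    left_join(site_discordant, by = "variant_id") |>
    mutate(
      discordant = dplyr::coalesce(.data$discordant, FALSE),
      qual = ifelse(
        .data$discordant,
        truncated_normal(dplyr::n(), config$qual_discordant),
        truncated_normal(dplyr::n(), config$qual_concordant)
      )
    )

  records <- truth$genotypes |>
    filter(.data$carrier) |>
    select("variant_id", "sample", "gt") |>
    tidyr::crossing(pipeline = pipelines) |>
    left_join(truth$dropout |>
                select("variant_id", "sample", "pipeline", "dropped"),
              by = c("variant_id", "sample", "pipeline")) |>
    mutate(dropped = dplyr::coalesce(.data$dropped, FALSE)) |>
    left_join(select(variants, "variant_id", "contig", "pos", "ref",
                     "alt", "class", "region"),
              by = "variant_id")
  # genotype errors: het <-> hom-alt flip on retained carrier records
  flip <- !records$dropped &
    runif(nrow(records)) < unname(config$genotype_error[records$region])
  records$gt[flip] <- ifelse(records$gt[flip] == "0/1", "1/1", "0/1")
  records$gt[records$dropped] <- NA_character_

  small <- records |>
    left_join(qual_tbl |> select("variant_id", "pipeline", "qual"),
              by = c("variant_id", "pipeline")) |>
    transmute(
      pipeline = .data$pipeline, sample = .data$sample,
      contig = .data$contig, pos = .data$pos, ref = .data$ref,
      alt = .data$alt, qual = .data$qual, filter = "PASS",
      gt = .data$gt, class = .data$class, region = .data$region
    )

  spurious <- simulate_spurious(truth, config)
  small <- bind_rows(small, spurious) |>
    arrange(.data$pipeline, .data$sample, .data$contig, .data$pos,
            .data$ref, .data$alt)

  sv <- emit_sv_callsets(truth, config)

  structure(
    list(small = small, sv = sv, pipelines = pipelines,
         samples = sort(unique(truth$genotypes$sample))),
    class = "fe_callsets"
  )
}

simulate_spurious <- function(truth, config) {
  regions <- truth$regions
  region_sizes <- regions |>
    as_tibble() |>
    group_by(.data$region) |>
    summarize(mb = sum(.data$end - .data$start) / 1e6, .groups = "drop")
  samples <- unique(truth$genotypes$sample)
  truth_keys <- paste0(truth$variants$contig, ":", truth$variants$pos)
  grid <- tidyr::crossing(pipeline = config$pipelines, sample = samples,
                          region_sizes)
  grid$n <- rpois(nrow(grid),
                  unname(config$spurious_per_mb[grid$region]) * grid$mb)
  if (sum(grid$n) == 0L) {
    return(tibble(pipeline = character(), sample = character(),
                  contig = character(), pos = integer(), ref = character(),
                  alt = character(), qual = numeric(), filter = character(),
                  gt = character(), class = character(),
                  region = character()))
  }
  reg_tbl <- as_tibble(regions)
  out <- grid |>
    filter(.data$n > 0L) |>
    purrr::pmap(function(pipeline, sample, region, mb, n) {
      segs <- filter(reg_tbl, .data$region == .env$region)
      w <- segs$end - segs$start
      seg_idx <- sample.int(nrow(segs), n, replace = TRUE, prob = w)
      pos <- segs$start[seg_idx] +
        purrr::map_int(w[seg_idx], function(m) sample.int(m, 1L))
      tibble(pipeline = pipeline, sample = sample,
             contig = segs$contig[seg_idx], pos = as.integer(pos),
             region = region)
    }) |>
    list_rbind() |>
    filter(!paste0(.data$contig, ":", .data$pos) %in% truth_keys) |>
    distinct(.data$pipeline, .data$sample, .data$contig, .data$pos,
             .keep_all = TRUE)
  al <- random_alleles(rep("snv", nrow(out)))
  out |>
    mutate(
      ref = al$ref, alt = al$alt,
      qual = truncated_normal(dplyr::n(), config$qual_discordant),
      filter = "PASS", gt = "0/1", class = "snv"
    ) |>
    select("pipeline", "sample", "contig", "pos", "ref", "alt", "qual",
           "filter", "gt", "class", "region")
}

emit_sv_callsets <- function(truth, config) {
  sv <- truth$sv
  if (nrow(sv) == 0L) {
    return(mutate(empty_sv_calls(), pipeline = character(),
                  region = character()))
  }
  grid <- tidyr::crossing(sv, pipeline = config$pipelines) |>
    mutate(dropped = runif(dplyr::n()) <
             unname(config$sv_dropout[.data$region]))
  retained_by_all <- grid |>
    group_by(.data$sv_id) |>
    summarize(all_kept = !any(.data$dropped), .groups = "drop")
  j <- config$sv_jitter_bp
  out <- grid |>
    filter(!.data$dropped) |>
    left_join(retained_by_all, by = "sv_id") |>
    mutate(
      shift1 = if (j > 0L) sample(seq(-j, j), dplyr::n(), replace = TRUE)
               else 0L,
      shift2 = if (j > 0L) sample(seq(-j, j), dplyr::n(), replace = TRUE)
               else 0L,
      start1 = .data$start1 + .data$shift1, end1 = .data$end1 + .data$shift1,
      start2 = .data$start2 + .data$shift2, end2 = .data$end2 + .data$shift2,
      type_flip = runif(dplyr::n()) < config$sv_type_flip_prob,
      strand_flip = runif(dplyr::n()) < config$sv_strand_flip_prob,
      svtype = ifelse(
        .data$type_flip,
        purrr::map_chr(.data$svtype, function(t) {
          sample(setdiff(c("DEL", "DUP", "INV"), t), 1L)
        }),
        .data$svtype
      ),
      strand1 = ifelse(.data$strand_flip, flip_strand(.data$strand1),
                       .data$strand1),
      strand2 = ifelse(.data$strand_flip, flip_strand(.data$strand2),
                       .data$strand2),
      msq = ifelse(
        .data$all_kept & !.data$type_flip & !.data$strand_flip,
        truncated_normal(dplyr::n(), config$qual_concordant),
        truncated_normal(dplyr::n(), config$qual_discordant)
      )
    ) |>
    transmute(
      pipeline = .data$pipeline, name = .data$sv_id,
      contig1 = .data$contig1, start1 = .data$start1, end1 = .data$end1,
      contig2 = .data$contig2, start2 = .data$start2, end2 = .data$end2,
      score = .data$msq, strand1 = .data$strand1, strand2 = .data$strand2,
      svtype = .data$svtype, msq = .data$msq, region = .data$region
    ) |>
    arrange(.data$pipeline, .data$contig1, .data$start1, .data$start2)
  out
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

#' Simulate a complete study
#'
#' Convenience wrapper: [simulate_truth()] then
#' [emit_pipeline_callsets()].
#'
#' @param config A [sim_config()].
#' @return List with elements `truth` and `callsets`.
#' @export
simulate_study <- function(config) {
  truth <- simulate_truth(config)
  list(truth = truth, callsets = emit_pipeline_callsets(truth, config))
}

#' Write a simulated study to disk
#'
#' Writes one BED per region label, a PED pedigree, one multi-sample VCF
#' per pipeline (dropped carrier genotypes appear as `./.`; non-carriers
#' as `0/0`) and one padded BEDPE per pipeline. All outputs are
#' deterministically ordered.
#'
#' @param sim Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- sim$truth
  for (lvl in REGION_LEVELS) {
    write_bed(filter(as_tibble(truth$regions), .data$region == lvl),
              file.path(dir, paste0("regions_", lvl, ".bed")))
  }
  write_ped(truth$pedigree, file.path(dir, "pedigree.ped"))
  for (p in sim$callsets$pipelines) {
    small <- filter(sim$callsets$small, .data$pipeline == p)
    write_variant_vcf(
      small |> mutate(gt = dplyr::coalesce(.data$gt, "./.")),
      file.path(dir, paste0(p, ".vcf")),
      contig_lengths = truth$config$contigs
    )
    write_bedpe(filter(sim$callsets$sv, .data$pipeline == p),
                file.path(dir, paste0(p, ".bedpe")))
  }
  invisible(dir)
}
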