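# Independent brute-force oracles used to validate the package's
# vectorized implementations on small randomized instances.

# --- small-variant pairwise comparison: exhaustive double loop ----------

key_of <- function(df) paste(df$contig, df$pos, df$ref, df$alt, sep = ":")

oracle_compare_counts <- function(a, b, require_genotype_match = FALSE) {
  ka <- key_of(a); kb <- key_of(b)
  ga <- a$gt; gb <- b$gt
  tp <- fn <- fp <- 0L
  for (i in seq_along(ka)) {
    j <- which(kb == ka[i])
    if (length(j) == 0L) {
      fn <- fn + 1L
    } else if (require_genotype_match &&
                 !identical(ga[i], gb[j[1L]])) {
      fn <- fn + 1L
      fp <- fp + 1L
    } else {
      tp <- tp + 1L
    }
  }
  for (j in seq_along(kb)) {
    if (!kb[j] %in% ka) fp <- fp + 1L
  }
  list(tp = tp, fn = fn, fp = fp)
}

# --- k-way sharing: membership bitmap tally -----------------------------

oracle_sharing <- function(key_sets) {
  k <- length(key_sets)
  all_keys <- unique(unlist(key_sets))
  hits <- vapply(all_keys, function(key) {
    sum(vapply(key_sets, function(s) key %in% s, logical(1)))
  }, integer(1))
  c(all = sum(hits == k), unique = sum(hits == 1L),
    partial = sum(hits > 1L & hits < k))
}

# --- SV pairwise classification: all-pairs greedy ----------------------

oracle_sv_category <- function(x, y) {
  strands <- x$strand1 == y$strand1 && x$strand2 == y$strand2
  type <- x$svtype == y$svtype
  if (strands && type) "match"
  else if (strands) "match_discordant_type"
  else if (type) "discordant"
  else "discordant_discordant_type"
}

oracle_sv_overlap <- function(x, y) {
  x$contig1 == y$contig1 && x$contig2 == y$contig2 &&
    x$start1 < y$end1 && y$start1 < x$end1 &&
    x$start2 < y$end2 && y$start2 < x$end2
}

oracle_sv_counts <- function(a, b) {
  prec <- c(match = 1, match_discordant_type = 2, discordant = 3,
            discordant_discordant_type = 4)
  cand <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      x <- a[i, ]; y <- b[j, ]
      if (oracle_sv_overlap(x, y)) {
        cat_ij <- oracle_sv_category(x, y)
        cand[[length(cand) + 1L]] <- data.frame(
          i = i, j = j, category = cat_ij, rank = prec[[cat_ij]],
          dist = abs(x$start1 - y$start1) + abs(x$start2 - y$start2),
          k1 = min(x$start1, y$start1), k2 = max(x$start1, y$start1),
          k3 = min(x$start2, y$start2), k4 = max(x$start2, y$start2),
          k5 = min(i, j), k6 = max(i, j)
        )
      }
    }
  }
  counts <- setNames(as.list(rep(0L, 6L)),
                     c("match", "discordant", "match_discordant_type",
                       "discordant_discordant_type", "zero_only",
                       "one_only"))
  used_a <- rep(FALSE, nrow(a)); used_b <- rep(FALSE, nrow(b))
  if (length(cand) > 0L) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$rank, cand$dist, cand$k1, cand$k2, cand$k3,
                       cand$k4, cand$k5, cand$k6), ]
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE; used_b[j] <- TRUE
        counts[[cand$category[r]]] <- counts[[cand$category[r]]] + 1L
      }
    }
  }
  counts$zero_only <- sum(!used_a)
  counts$one_only <- sum(!used_b)
  tibble::as_tibble(counts)
}

# --- trio classification: enumerate the four transmissions --------------

oracle_trio <- function(child, father, mother) {
  al <- function(gt) as.integer(strsplit(gt, "/", fixed = TRUE)[[1L]])
  ch <- sort(al(child)); fa <- al(father); mo <- al(mother)
  possible <- list()
  for (x in fa) {
    for (y in mo) {
      possible[[length(possible) + 1L]] <- sort(c(x, y))
    }
  }
  consistent <- any(vapply(possible, identical, logical(1), y = ch))
  if (!consistent) {
    "informative_error"
  } else if (fa[1L] != fa[2L] && mo[1L] != mo[2L]) {
    "uninformative"
  } else {
    "informative_consistent"
  }
}

# --- region partition: per-base array painting -------------------------

oracle_paint <- function(easy, hard, len) {
  lab <- rep("medium", len) # 0-based positions 0..len-1 at index 1..len
  for (r in seq_len(nrow(hard))) {
    lab[(hard$start[r] + 1L):hard$end[r]] <- "hard"
  }
  for (r in seq_len(nrow(easy))) {
    lab[(easy$start[r] + 1L):easy$end[r]] <- "easy"
  }
  lab
}

# --- normalization: exhaustive leftmost-representation search -----------

apply_variant <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(seq, 1L, pos - 1L), alt,
         substr(seq, pos + nchar(ref), nchar(seq)))
}

oracle_leftmost <- function(seq, pos, ref, alt) {
  mutated <- apply_variant(seq, pos, ref, alt)
  L <- nchar(seq); M <- nchar(mutated)
  best <- NULL
  for (p in 1:L) {
    for (rl in 1:(L - p + 1L)) {
      al <- M - (L - rl)
      if (al < 1L) next
      r <- substr(seq, p, p + rl - 1L)
      a <- substr(mutated, p, p + al - 1L)
      if (r == a) next
      if (apply_variant(seq, p, r, a) != mutated) next
      # locally untrimmable representations only
      if (rl > 1L && al > 1L &&
            substr(r, 1L, 1L) == substr(a, 1L, 1L)) next
      if (rl > 1L && al > 1L &&
            substr(r, rl, rl) == substr(a, al, al)) next
      if (is.null(best) || p < best$pos ||
            (p == best$pos && rl + al < nchar(best$ref) + nchar(best$alt))) {
        best <- list(pos = p, ref = r, alt = a)
      }
    }
  }
  best
}

# --- misc fixtures ------------------------------------------------------

random_small_callset <- function(n, n_pos = 400L, contig = "c1",
                                 with_gt = TRUE) {
  pos <- sample.int(n_pos, n, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                character(1))
  out <- tibble::tibble(
    contig = contig, pos = pos, ref = ref, alt = alt,
    qual = round(runif(n, 1, 100), 1), filter = "PASS",
    gt = if (with_gt) sample(c("0/1", "1/1"), n, replace = TRUE)
         else NA_character_
  )
  dplyr::distinct(out, contig, pos, ref, alt, .keep_all = TRUE)
}

random_sv_callset <- function(n, contig = "c1", span = 100000L) {
  b1 <- sample.int(span, n) + 100L
  b2 <- b1 + sample(500:5000, n, replace = TRUE)
  types <- sample(c("DEL", "DUP", "INV"), n, replace = TRUE)
  s1 <- sample(c("+", "-"), n, replace = TRUE)
  s2 <- sample(c("+", "-"), n, replace = TRUE)
  tibble::tibble(
    contig1 = contig, start1 = b1 - 1L, end1 = b1 + 2L,
    contig2 = contig, start2 = b2 - 1L, end2 = b2 + 2L,
    name = sprintf("sv%03d", seq_len(n)), score = 1,
    strand1 = s1, strand2 = s2, svtype = types,
    msq = round(runif(n, 10, 500), 1)
  )
}
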