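#' Haploid call matrix for LD analysis
#'
#' Inbred varieties carry essentially one haplotype, so two-locus haplotype
#' tables can be read directly off homozygous calls. Homozygotes project to
#' their allele; residual heterozygotes are set to missing under the
#' default policy (phase is never modelled), and missing stays missing.
#'
#' @param panel An [ssr_panel].
#' @param het_policy `"missing"` (default) or `"drop"`; both remove
#'   heterozygous calls from LD, "drop" is the pairwise-deletion synonym.
#' @return An integer varieties x loci matrix of allele sizes with `NA`
#'   for missing/heterozygous calls.
#' @export
haploid_calls <- function(panel, het_policy = c("missing", "drop")) {
  het_policy <- match.arg(het_policy)
  al <- panel_alleles(panel)
  out <- al$a1
  out[al$a1 != al$a2] <- NA_integer_
  out
}

# Allele codes for one locus with rare alleles (count < min_count) pooled
# into a single "other" class; returns an integer factor-like vector.
pool_rare <- function(v, min_count = 2L) {
  tab <- table(v)
  keep <- names(tab)[tab >= min_count]
  code <- match(as.character(v), keep)
  code[is.na(code) & !is.na(v)] <- length(keep) + 1L
  if (any(code == length(keep) + 1L, na.rm = TRUE)) {
    levels_n <- length(keep) + 1L
  } else {
    levels_n <- length(keep)
  }
  list(code = code, n_levels = levels_n)
}

#' Multiallelic linkage disequilibrium for one locus pair
#'
#' From the two-locus haplotype table of jointly non-missing haploid calls
#' with frequencies `x_ij` and marginals `p_i`, `q_j`:
#' `D_ij = x_ij - p_i q_j`; `D'_ij = |D_ij| / Dmax(i, j)` with the usual
#' allele-pair maximum; the weighted standardized coefficient
#' `D' = sum_ij p_i q_j D'_ij`; the per-cell correlation
#' `r_ij = D_ij / sqrt(p_i (1 - p_i) q_j (1 - q_j))`; and the weighted
#' squared correlation `r2 = sum_ij p_i q_j r_ij^2`. For biallelic pairs
#' both collapse to the classical D' and r-squared.
#'
#' Significance is a two-sided Fisher exact test for 2x2 tables and a
#' seeded Monte-Carlo permutation test of one call vector for larger
#' tables (statistic: table chi-square; add-one numerator keeps p > 0).
#' Alleles rarer than `min_count` are pooled into an "other" class before
#' testing.
#'
#' @param a,b Haploid call vectors (columns of [haploid_calls()]).
#' @param n_shuffles Permutations for the Monte-Carlo test.
#' @param seed Integer seed for the permutations.
#' @param min_count Rare-allele pooling threshold (0 disables pooling).
#' @return One-row tibble: `r2`, `d_prime`, `p_value`, `n` (haplotypes
#'   used), `k_a`, `k_b` (allele classes per side). Statistics are `NA`
#'   when fewer than 2 varieties or fewer than 2 alleles on either side
#'   remain.
#' @export
pair_ld <- function(a, b, n_shuffles = 10000L, seed = NULL, min_count = 2L) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  empty <- tibble(r2 = NA_real_, d_prime = NA_real_, p_value = NA_real_,
                  n = length(a), k_a = NA_integer_, k_b = NA_integer_)
  if (length(a) < 2L) return(empty)
  if (min_count > 0L) {
    pa <- pool_rare(a, min_count); pb <- pool_rare(b, min_count)
    ia <- pa$code; ib <- pb$code
  } else {
    ia <- match(a, sort(unique(a))); ib <- match(b, sort(unique(b)))
  }
  ka <- length(unique(ia)); kb <- length(unique(ib))
  ia <- match(ia, sort(unique(ia))); ib <- match(ib, sort(unique(ib)))
  if (ka < 2L || kb < 2L) {
    empty$k_a <- ka; empty$k_b <- kb
    return(empty)
  }
  n <- length(ia)
  tab <- matrix(tabulate(ia + ka * (ib - 1L), nbins = ka * kb), ka, kb)
  x <- tab / n
  p <- rowSums(x); q <- colSums(x)
  if (any(p == 0) || any(q == 0)) {
    empty$k_a <- ka; empty$k_b <- kb
    return(empty)
  }
  D <- x - outer(p, q)
  dmax <- matrix(0, ka, kb)
  for (i in seq_len(ka)) for (j in seq_len(kb)) {
    dmax[i, j] <- if (D[i, j] < 0) {
      min(p[i] * q[j], (1 - p[i]) * (1 - q[j]))
    } else {
      min(p[i] * (1 - q[j]), (1 - p[i]) * q[j])
    }
  }
  dprime_ij <- ifelse(dmax > 0, abs(D) / dmax, 0)
  d_prime <- sum(outer(p, q) * dprime_ij)
  denom <- outer(p * (1 - p), q * (1 - q))
  r2 <- sum(outer(p, q) * D^2 / denom)
  p_value <- ld_test(tab, ia, ib, ka, kb, n_shuffles, seed)
  tibble(r2 = r2, d_prime = min(d_prime, 1), p_value = p_value, n = n,
         k_a = ka, k_b = kb)
}

chisq_stat <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - e)^2 / e)
}

ld_test <- function(tab, ia, ib, ka, kb, n_shuffles, seed) {
  if (ka == 2L && kb == 2L) {
    return(fisher.test(tab)$p.value)
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- chisq_stat(tab)
  n <- length(ia)
  exceed <- 0L
  for (s in seq_len(n_shuffles)) {
    perm <- matrix(tabulate(ia + ka * (ib[sample.int(n)] - 1L),
                            nbins = ka * kb), ka, kb)
    if (chisq_stat(perm) >= obs - 1e-12) exceed <- exceed + 1L
  }
  (1 + exceed) / (n_shuffles + 1)
}

#' All pairwise LD statistics for a panel
#'
#' Computes [pair_ld()] for every unordered locus pair within each group of
#' varieties, annotated with the genetic map: same-chromosome (linked)
#' flag, and inter-locus distance in cM for linked pairs. Loci left with
#' fewer than two allele classes in a group are excluded for that group.
#' Groups with fewer than 2 varieties are skipped with a warning.
#'
#' @param panel An [ssr_panel].
#' @param map A [genetic_map] covering all panel loci.
#' @param grouping See [allele_frequencies()]; `NULL` analyses everything
#'   as one group.
#' @param n_shuffles,min_count Passed to [pair_ld()].
#' @param seed Master seed; each pair's permutation stream is derived from it.
#' @return Tibble: `group`, `locus_a`, `locus_b`, `chr_a`, `chr_b`,
#'   `linked`, `dist_cm` (`NA` for unlinked), `r2`, `d_prime`, `p_value`,
#'   `n`.
#' @export
ld_pairs <- function(panel, map, grouping = NULL, n_shuffles = 1000L,
                     seed = 1L, min_count = 2L) {
  check_map_covers(map, panel, strict = TRUE)
  grouping <- as_grouping(grouping, panel)
  calls <- haploid_calls(panel)
  loci <- panel_loci(panel)
  minfo <- map[match(loci, map$locus), ]
  pairs <- utils::combn(seq_along(loci), 2L)
  groups <- split(match(names(grouping), panel$variety_id), grouping)
  purrr::imap_dfr(groups, function(rows, g) {
    if (length(rows) < 2L) {
      warn(paste0("group ", g, " has < 2 varieties; skipped"))
      return(tibble())
    }
    sub <- calls[rows, , drop = FALSE]
    set.seed(seed + sum(utf8ToInt(g)))
    pair_seeds <- sample.int(.Machine$integer.max, ncol(pairs))
    res <- purrr::map_dfr(seq_len(ncol(pairs)), function(idx) {
      i <- pairs[1L, idx]; j <- pairs[2L, idx]
      pair_ld(sub[, i], sub[, j], n_shuffles = n_shuffles,
              seed = pair_seeds[idx], min_count = min_count)
    })
    ca <- minfo$chr[pairs[1L, ]]; cb <- minfo$chr[pairs[2L, ]]
    linked <- ca == cb
    tibble(group = g,
           locus_a = loci[pairs[1L, ]], locus_b = loci[pairs[2L, ]],
           chr_a = ca, chr_b = cb, linked = linked,
           dist_cm = ifelse(linked,
                            abs(minfo$pos_cm[pairs[1L, ]] - minfo$pos_cm[pairs[2L, ]]),
                            NA_real_),
           res)
  })
}

#' Summarise significant LD by linkage status
#'
#' Fractions of locus pairs in significant LD (p < alpha) among linked
#' (same chromosome), unlinked and all pairs per group, and the
#' linked/unlinked ratio of those percentages — the panel-level LD profile
#' in which population structure shows up as inflated unlinked LD.
#'
#' @param pairs Output of [ld_pairs()], or an [ssr_panel] (then `map`,
#'   `grouping`, ... are used to compute the pairs first).
#' @param map,grouping,n_shuffles,seed Used only when `pairs` is a panel.
#' @param alpha Significance level (published setting 0.05).
#' @return An `ld_summary` object: list with `summary` (tibble `group`,
#'   `pct_linked`, `pct_unlinked`, `pct_total`, `ratio`, pair counts) and
#'   the `pairs` table.
#' @export
ld_summary <- function(pairs, map = NULL, grouping = NULL, alpha = 0.05,
                       n_shuffles = 1000L, seed = 1L) {
  if (inherits(pairs, "ssr_panel")) {
    if (is.null(map)) abort("ld_summary on a panel needs a genetic map; run read_genetic_map first")
    pairs <- ld_pairs(pairs, map, grouping, n_shuffles = n_shuffles, seed = seed)
  }
  summary <- pairs |>
    filter(!is.na(.data$p_value)) |>
    group_by(.data$group) |>
    summarise(
      n_linked = sum(.data$linked),
      n_unlinked = sum(!.data$linked),
      pct_linked = 100 * mean(.data$p_value[.data$linked] < alpha),
      pct_unlinked = 100 * mean(.data$p_value[!.data$linked] < alpha),
      pct_total = 100 * mean(.data$p_value < alpha),
      ratio = .data$pct_linked / .data$pct_unlinked,
      .groups = "drop")
  structure(list(summary = summary, pairs = pairs, alpha = alpha),
            class = "ld_summary")
}

#' @export
print.ld_summary <- function(x, ...) {
  cat("<ld_summary> alpha =", x$alpha, "\n")
  print(x$summary)
  invisible(x)
}

#' LD decay distance against the unlinked-pair quantile
#'
#' The decay threshold is the interpolated 75th percentile (configurable)
#' of r-squared over inter-chromosomal pairs. Linked pairs are binned by cM
#' distance in sliding windows `[left, left + width)` advanced by `step`;
#' the decay distance is the left edge of the first window whose mean
#' r-squared falls below the threshold with every later (non-empty) window
#' also below. If no window is below, decay is flagged as beyond the map
#' extent (`Inf`); if already the first window is below and stays below,
#' decay is 0.
#'
#' @param pairs Output of [ld_pairs()] (a single group's rows).
#' @param probs Quantile of unlinked r-squared used as threshold.
#' @param window Window width in cM.
#' @param step Window step in cM.
#' @return An `ld_decay` object: list with `threshold`, `decay_cm`, and
#'   `curve` (tibble `left`, `mid`, `mean_r2`, `n_pairs`).
#' @export
decay_distance <- function(pairs, probs = 0.75, window = 5, step = 1) {
  pairs <- filter(pairs, !is.na(.data$r2))
  unl <- filter(pairs, !.data$linked)
  lnk <- filter(pairs, .data$linked)
  if (nrow(unl) == 0L || nrow(lnk) == 0L) {
    abort("need at least one linked and one unlinked pair")
  }
  threshold <- unname(quantile(unl$r2, probs = probs, type = 7))
  max_d <- max(lnk$dist_cm)
  lefts <- seq(0, max(0, max_d - step), by = step)
  curve <- purrr::map_dfr(lefts, function(l) {
    inw <- lnk$r2[lnk$dist_cm >= l & lnk$dist_cm < l + window]
    tibble(left = l, mid = l + window / 2,
           mean_r2 = if (length(inw)) mean(inw) else NA_real_,
           n_pairs = length(inw))
  })
  below <- curve$mean_r2 < threshold
  below[is.na(below)] <- TRUE          # empty windows do not break a decay run
  decay_cm <- Inf
  nonempty_below <- below | curve$n_pairs == 0L
  for (i in seq_along(below)) {
    if (curve$n_pairs[i] > 0L && below[i] && all(nonempty_below[i:length(below)])) {
      decay_cm <- curve$left[i]
      break
    }
  }
  structure(list(threshold = threshold, decay_cm = decay_cm, curve = curve,
                 probs = probs, window = window, step = step),
            class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  cat("<ld_decay> threshold (", x$probs * 100, "th pct unlinked r2) = ",
      round(x$threshold, 4), "; decay at ",
      if (is.finite(x$decay_cm)) paste0(x$decay_cm, " cM") else "beyond map extent",
      "\n", sep = "")
  invisible(x)
}

#' LD blocks on the genetic map
#'
#' A block is a maximal run of at least `min_loci` map-adjacent loci on one
#' chromosome in which every consecutive pair is in significant LD
#' (p < alpha). The span is the cM distance between the first and last
#' locus of the run. Block calling is invariant to locus relabeling and to
#' uniform shifts of the cM positions.
#'
#' @param pairs Output of [ld_pairs()] for one group (must contain the
#'   adjacent linked pairs).
#' @param map A [genetic_map].
#' @param alpha Significance level.
#' @param min_loci Minimum run length counted as a block (>= 2).
#' @return Tibble: `chr`, `start_locus`, `end_locus`, `n_loci`, `span_cm`,
#'   `loci` (list column).
#' @export
find_blocks <- function(pairs, map, alpha = 0.05, min_loci = 2L) {
  stopifnot(min_loci >= 2L)
  map <- arrange(as_tibble(map), .data$chr, .data$pos_cm)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  sig <- setNames(pairs$p_value < alpha, key(pairs$locus_a, pairs$locus_b))
  out <- purrr::map_dfr(split(map, map$chr), function(mc) {
    k <- nrow(mc)
    if (k < 2L) return(tibble())
    adj_sig <- purrr::map_lgl(seq_len(k - 1L), function(i) {
      s <- sig[key(mc$locus[i], mc$locus[i + 1L])]
      !is.na(s) && s
    })
    runs <- rle(adj_sig)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    purrr::map_dfr(which(runs$values), function(r) {
      i0 <- starts[r]; i1 <- ends[r] + 1L       # locus indices of the run
      if (i1 - i0 + 1L < min_loci) return(tibble())
      tibble(chr = mc$chr[1L],
             start_locus = mc$locus[i0], end_locus = mc$locus[i1],
             n_loci = i1 - i0 + 1L,
             span_cm = mc$pos_cm[i1] - mc$pos_cm[i0],
             loci = list(mc$locus[i0:i1]))
    })
  })
  out
}

#' Per-chromosome block counts and mean lengths
#'
#' Summarises a block list the way the published per-chromosome tables do:
#' block count and mean span per chromosome, the total count, and the
#' group-level mean length under both averaging rules — the unweighted
#' mean over chromosomes that have blocks, and over all chromosomes with
#' blockless ones contributing 0 (the published averaging rule is
#' ambiguous, so both are emitted).
#'
#' @param blocks Output of [find_blocks()].
#' @param n_chromosomes Number of chromosomes of the map.
#' @return A list with `per_chromosome` (tibble `chr`, `n_blocks`,
#'   `mean_length_cm`), `total_blocks`, `mean_length_chromosomes_with_blocks`,
#'   `mean_length_all_chromosomes`.
#' @export
block_summary <- function(blocks, n_chromosomes = 12L) {
  per_chr <- tibble(chr = seq_len(n_chromosomes)) |>
    left_join(blocks |>
                group_by(.data$chr) |>
                summarise(n_blocks = dplyr::n(),
                          mean_length_cm = mean(.data$span_cm), .groups = "drop"),
              by = "chr") |>
    mutate(n_blocks = ifelse(is.na(.data$n_blocks), 0L, .data$n_blocks),
           mean_length_cm = ifelse(.data$n_blocks == 0L, 0,
                                   .data$mean_length_cm))
  with_blocks <- filter(per_chr, .data$n_blocks > 0L)
  list(per_chromosome = per_chr,
       total_blocks = sum(per_chr$n_blocks),
       mean_length_chromosomes_with_blocks =
         if (nrow(with_blocks)) mean(with_blocks$mean_length_cm) else NA_real_,
       mean_length_all_chromosomes = mean(per_chr$mean_length_cm))
}
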