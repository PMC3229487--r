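#' Allele frequencies per group and locus
#'
#' Counts allele copies (two per variety; heterozygotes contribute both
#' alleles) over the non-missing calls of each group at each locus and
#' normalises to frequencies. Missing data are handled by pairwise deletion
#' per locus: the gene count behind every frequency vector is reported, and
#' no imputation is done. Loci with zero non-missing calls in a group are
#' absent from that group's rows and listed in the `absent` attribute.
#'
#' @param panel An [ssr_panel].
#' @param grouping A data frame with columns `variety_id` and `group`, a
#'   named character vector, or `NULL` for a single group `"all"`. Varieties
#'   absent from the grouping are ignored; unknown varieties in the grouping
#'   are an error.
#' @return A tibble with columns `group`, `locus`, `allele` (bp size),
#'   `freq` and `n_genes` (non-missing allele copies at that group/locus).
#'   Frequency vectors sum to 1 within each (group, locus).
#' @export
allele_frequencies <- function(panel, grouping = NULL) {
  grouping <- as_grouping(grouping, panel)
  al <- panel_alleles(panel)
  loci <- panel_loci(panel)
  groups <- split(match(names(grouping), panel$variety_id), grouping)
  out <- purrr::imap_dfr(groups, function(rows, g) {
    a <- rbind(al$a1[rows, , drop = FALSE], al$a2[rows, , drop = FALSE])
    purrr::map_dfr(seq_along(loci), function(j) {
      v <- a[, j]
      v <- v[!is.na(v)]
      if (length(v) == 0L) return(tibble())
      tab <- table(v)
      tibble(group = g, locus = loci[j],
             allele = as.integer(names(tab)),
             freq = as.numeric(tab) / length(v),
             n_genes = length(v))
    })
  })
  present <- distinct(out, .data$group, .data$locus)
  full <- tidyr::expand_grid(group = names(groups), locus = loci)
  absent <- dplyr::anti_join(full, present, by = c("group", "locus"))
  attr(out, "absent") <- absent
  out
}

# Normalise the grouping argument to a named character vector over varieties.
as_grouping <- function(grouping, panel) {
  ids <- panel_varieties(panel)
  if (is.null(grouping)) return(setNames(rep("all", length(ids)), ids))
  if (is.data.frame(grouping)) {
    if (!all(c("variety_id", "group") %in% names(grouping))) {
      abort("grouping data frame needs variety_id and group columns")
    }
    grouping <- setNames(as.character(grouping$group),
                         as.character(grouping$variety_id))
  }
  unknown <- setdiff(names(grouping), ids)
  if (length(unknown)) {
    abort(paste0("grouping names unknown varieties: ",
                 paste(unknown, collapse = ", ")))
  }
  grouping[!is.na(grouping)]
}

#' Gene diversity (expected heterozygosity)
#'
#' Nei's gene diversity of a frequency vector, `1 - sum(p^2)`: the chance
#' that two allele copies drawn at random differ. Bounded by `1 - 1/k` for
#' `k` alleles.
#'
#' @param p Numeric vector of allele frequencies (non-negative, summing to 1).
#' @return A number in `[0, 1)`.
#' @export
gene_diversity <- function(p) {
  check_freqs(p)
  1 - sum(p^2)
}

#' Polymorphism information content
#'
#' Botstein's PIC: gene diversity minus a correction for matings between
#' indistinguishable heterozygotes,
#' `1 - sum(p^2) - sum_{i<j} 2 p_i^2 p_j^2`. Always between 0 and the gene
#' diversity of the same vector.
#'
#' @inheritParams gene_diversity
#' @return A number in `[0, 1)`.
#' @export
pic <- function(p) {
  check_freqs(p)
  s2 <- sum(p^2)
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  1 - s2 - (s2^2 - sum(p^4))
}

check_freqs <- function(p) {
  if (length(p) == 0L) abort("empty frequency vector")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    abort("frequencies must be non-negative and sum to 1")
  }
  invisible(p)
}

#' Modified Rogers distance between two frequency tables
#'
#' Wright's modified Rogers distance over `m` loci:
#' `sqrt( (1/(2m)) * sum_loci sum_alleles (p_a - q_a)^2 )`. Alleles absent
#' from one group enter with frequency 0. A metric on frequency tables over
#' a fixed locus set, in `[0, 1]`.
#'
#' @param freq_a,freq_b Allele-frequency tibbles (columns `locus`, `allele`,
#'   `freq`) for a single group each, as produced by filtering
#'   [allele_frequencies()] output.
#' @param loci Loci to sum over; default, the loci present in both tables.
#' @return A number in `[0, 1]`.
#' @export
mrd <- function(freq_a, freq_b, loci = NULL) {
  loci <- loci %||% intersect(unique(freq_a$locus), unique(freq_b$locus))
  if (length(loci) == 0L) abort("empty locus set for MRD")
  fa <- filter(freq_a, .data$locus %in% loci)
  fb <- filter(freq_b, .data$locus %in% loci)
  if (!all(loci %in% fa$locus) || !all(loci %in% fb$locus)) {
    abort("both groups must have frequencies at every requested locus")
  }
  j <- dplyr::full_join(select(fa, "locus", "allele", fa = "freq"),
                        select(fb, "locus", "allele", fb = "freq"),
                        by = c("locus", "allele"))
  j$fa[is.na(j$fa)] <- 0
  j$fb[is.na(j$fb)] <- 0
  sqrt(sum((j$fa - j$fb)^2) / (2 * length(loci)))
}

#' Between-group MRD on a panel
#'
#' Convenience wrapper: computes group allele frequencies and the MRD
#' between two named groups over the loci both groups observe.
#'
#' @param panel An [ssr_panel].
#' @param grouping See [allele_frequencies()].
#' @param groups Character vector of the two group names.
#' @return A number in `[0, 1]`.
#' @export
mrd_between <- function(panel, grouping, groups) {
  stopifnot(length(groups) == 2L)
  fr <- allele_frequencies(panel, grouping)
  mrd(filter(fr, .data$group == groups[1L]),
      filter(fr, .data$group == groups[2L]))
}

#' Nei's coefficient of gene differentiation (Gst)
#'
#' `Gst = (Ht - Hs) / Ht`, where `Hs` is the size-weighted mean within-group
#' gene diversity and `Ht` the gene diversity of the size-weighted pooled
#' frequencies, each averaged over the loci observed in every group.
#' Returns `NA` (flagged undefined) when `Ht = 0`, i.e. all groups are
#' monomorphic for the same allele everywhere.
#'
#' @param freqs Allele-frequency tibble with a `group` column
#'   ([allele_frequencies()] output) covering at least two groups.
#' @param group_sizes Named numeric vector of group sample sizes.
#' @return A number in `[0, 1]`, or `NA_real_` when undefined.
#' @export
gst <- function(freqs, group_sizes) {
  groups <- unique(freqs$group)
  if (length(groups) < 2L) abort("Gst needs at least two groups")
  if (!all(groups %in% names(group_sizes))) abort("missing group sizes")
  w <- group_sizes[groups] / sum(group_sizes[groups])
  shared <- Reduce(intersect, lapply(groups, function(g) {
    unique(freqs$locus[freqs$group == g])
  }))
  if (length(shared) == 0L) abort("no locus observed in every group")
  per_locus <- purrr::map_dfr(shared, function(loc) {
    fl <- filter(freqs, .data$locus == loc)
    hs <- sum(purrr::map_dbl(groups, function(g) {
      unname(w[g]) * gene_diversity(fl$freq[fl$group == g])
    }))
    pooled <- fl |>
      mutate(wf = unname(w[.data$group]) * .data$freq) |>
      group_by(.data$allele) |>
      summarise(freq = sum(.data$wf), .groups = "drop")
    tibble(hs = hs, ht = gene_diversity(pooled$freq))
  })
  ht <- mean(per_locus$ht)
  hs <- mean(per_locus$hs)
  if (ht <= 0) return(NA_real_)
  (ht - hs) / ht
}

#' Genome-wide diversity and divergence scan
#'
#' Per-locus gene diversity and PIC for every group, per-locus MRD between
#' two groups, bootstrap standard errors from resampling varieties within
#' groups with replacement, and group-level summaries (mean alleles per
#' locus, mean allele frequency, unique-allele counts, mean gene diversity).
#' Unique alleles are alleles observed in exactly one group; mean allele
#' frequency is the mean over loci of the reciprocal allele count (the mean
#' frequency of a locus's alleles).
#'
#' @param panel An [ssr_panel].
#' @param grouping See [allele_frequencies()].
#' @param mrd_groups The two groups for the per-locus MRD scan; `NULL`
#'   skips it unless the grouping has exactly two groups. Requesting the
#'   scan with any other number of groups is an error.
#' @param n_bootstrap Bootstrap replicates (>= 1) for standard errors.
#' @param seed Integer seed for the bootstrap.
#' @return A `diversity_scan` object: list with tibbles `per_locus` (locus,
#'   group, n_alleles, gene_diversity, pic, se, n_genes), `mrd_scan`
#'   (locus, mrd, se), `group_summary`, and scalars `overall_mrd`, `gst`.
#' @export
diversity_scan <- function(panel, grouping = NULL, mrd_groups = NULL,
                           n_bootstrap = 1000L, seed = 1L) {
  stopifnot(n_bootstrap >= 1L)
  grouping <- as_grouping(grouping, panel)
  groups <- unique(grouping)
  if (is.null(mrd_groups) && length(groups) == 2L) mrd_groups <- groups
  do_mrd <- !is.null(mrd_groups)
  if (do_mrd && length(mrd_groups) != 2L) {
    abort("MRD scan requires exactly two groups")
  }
  al <- panel_alleles(panel)
  loci <- panel_loci(panel)
  rows_by_group <- split(match(names(grouping), panel$variety_id), grouping)

  freqs <- allele_frequencies(panel, grouping)
  per_locus <- freqs |>
    group_by(.data$group, .data$locus) |>
    summarise(n_alleles = dplyr::n(),
              gene_diversity = gene_diversity(.data$freq),
              pic = pic(.data$freq),
              n_genes = .data$n_genes[1L], .groups = "drop")

  mrd_scan <- NULL
  if (do_mrd) {
    mrd_scan <- purrr::map_dfr(loci, function(loc) {
      fl <- filter(freqs, .data$locus == loc, .data$group %in% mrd_groups)
      if (length(unique(fl$group)) < 2L) {
        return(tibble(locus = loc, mrd = NA_real_))
      }
      tibble(locus = loc,
             mrd = mrd(filter(fl, .data$group == mrd_groups[1L]),
                       filter(fl, .data$group == mrd_groups[2L]), loci = loc))
    })
  }

  # bootstrap across varieties within each group
  boot <- bootstrap_scan(al, loci, rows_by_group, mrd_groups, n_bootstrap, seed)
  per_locus <- left_join(per_locus, boot$he_se, by = c("group", "locus"))
  if (do_mrd) mrd_scan <- left_join(mrd_scan, boot$mrd_se, by = "locus")

  allele_groups <- freqs |>
    distinct(.data$group, .data$locus, .data$allele) |>
    count(.data$locus, .data$allele, name = "n_groups")
  unique_counts <- freqs |>
    distinct(.data$group, .data$locus, .data$allele) |>
    left_join(allele_groups, by = c("locus", "allele")) |>
    filter(.data$n_groups == 1L) |>
    count(.data$group, name = "unique_alleles")
  group_summary <- per_locus |>
    group_by(.data$group) |>
    summarise(mean_alleles = mean(.data$n_alleles),
              mean_allele_freq = mean(1 / .data$n_alleles),
              mean_gene_diversity = mean(.data$gene_diversity),
              mean_pic = mean(.data$pic), .groups = "drop") |>
    left_join(unique_counts, by = "group") |>
    mutate(unique_alleles = ifelse(is.na(.data$unique_alleles) & length(groups) > 1L,
                                   0L, .data$unique_alleles),
           n = purrr::map_int(.data$group, ~ length(rows_by_group[[.x]])),
           .after = "group")
  if (length(groups) == 1L) group_summary$unique_alleles <- NA_integer_

  overall_mrd <- if (do_mrd) {
    sqrt(mean(mrd_scan$mrd^2, na.rm = TRUE))
  } else NA_real_
  gst_val <- if (length(groups) >= 2L) {
    gst(freqs, setNames(lengths(rows_by_group), names(rows_by_group)))
  } else NA_real_

  structure(list(per_locus = per_locus, mrd_scan = mrd_scan,
                 group_summary = group_summary,
                 overall_mrd = overall_mrd, gst = gst_val,
                 n_bootstrap = n_bootstrap, seed = seed),
            class = "diversity_scan")
}

# Frequencies of one locus over given rows of the allele matrices.
locus_freqs <- function(al, rows, j) {
  v <- c(al$a1[rows, j], al$a2[rows, j])
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NULL)
  tab <- tabulate(match(v, unique(v)))
  tab / sum(tab)
}

bootstrap_scan <- function(al, loci, rows_by_group, mrd_groups, B, seed) {
  set.seed(seed)
  groups <- names(rows_by_group)
  m <- length(loci)
  he_reps <- lapply(groups, function(g) matrix(NA_real_, B, m))
  names(he_reps) <- groups
  mrd_reps <- if (!is.null(mrd_groups)) matrix(NA_real_, B, m) else NULL
  for (b in seq_len(B)) {
    rows_b <- lapply(rows_by_group, function(r) sample(r, length(r), replace = TRUE))
    freqs_b <- lapply(groups, function(g) {
      lapply(seq_len(m), function(j) {
        v <- c(al$a1[rows_b[[g]], j], al$a2[rows_b[[g]], j])
        v <- v[!is.na(v)]
        if (!length(v)) return(NULL)
        tab <- table(v)
        setNames(as.numeric(tab) / length(v), names(tab))
      })
    })
    names(freqs_b) <- groups
    for (g in groups) {
      he_reps[[g]][b, ] <- purrr::map_dbl(freqs_b[[g]], function(p) {
        if (is.null(p)) NA_real_ else 1 - sum(p^2)
      })
    }
    if (!is.null(mrd_groups)) {
      f1 <- freqs_b[[mrd_groups[1L]]]
      f2 <- freqs_b[[mrd_groups[2L]]]
      mrd_reps[b, ] <- purrr::map_dbl(seq_len(m), function(j) {
        p <- f1[[j]]; q <- f2[[j]]
        if (is.null(p) || is.null(q)) return(NA_real_)
        alleles <- union(names(p), names(q))
        pa <- ifelse(alleles %in% names(p), p[alleles], 0)
        qa <- ifelse(alleles %in% names(q), q[alleles], 0)
        sqrt(sum((pa - qa)^2) / 2)
      })
    }
  }
  col_sd <- function(mat) apply(mat, 2L, sd, na.rm = TRUE)
  he_se <- purrr::imap_dfr(he_reps, function(mat, g) {
    tibble(group = g, locus = loci, se = col_sd(mat))
  })
  out <- list(he_se = he_se)
  if (!is.null(mrd_reps)) {
    out$mrd_se <- tibble(locus = loci, se = col_sd(mrd_reps))
  }
  out
}

#' @export
print.diversity_scan <- function(x, ...) {
  cat("<diversity_scan> ", length(unique(x$per_locus$locus)), " loci, groups: ",
      paste(x$group_summary$group, collapse = ", "), "\n", sep = "")
  if (!is.na(x$overall_mrd)) cat("  overall MRD:", round(x$overall_mrd, 4), "\n")
  if (!is.na(x$gst)) cat("  Gst:", round(x$gst, 4), "\n")
  print(x$group_summary)
  invisible(x)
}
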