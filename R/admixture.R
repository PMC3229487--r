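#' Maximum-likelihood admixture proportions
#'
#' Membership probabilities in the threshold sense are genome fractions:
#' the proportion of a variety's allele copies drawn from each subgroup's
#' allele-frequency pool. This is the maximum-likelihood admixture model
#' fitted by block expectation-maximisation: the likelihood of an allele
#' copy `a` in variety `i` is `sum_k q_ik f_k(a)`; the E-step computes
#' per-copy responsibilities, and the M-step re-estimates both each
#' variety's admixture vector `q_i` (mean responsibility over its copies)
#' and each subgroup's allele frequencies `f_k` (responsibility-weighted
#' allele counts), so admixed varieties do not contaminate the subgroup
#' frequency pools. Initialisation comes from subgroup labels (typically
#' the max-rule assignment of a [fit_mixture()]); a small frequency floor
#' keeps alleles private to one subgroup from zeroing the likelihood.
#'
#' An intermediate variety ends up with an intermediate `q`, so the
#' 0.80-threshold rule of [assign_membership()] retains it in the admixed
#' group — the behaviour expected of admixture-type membership
#' probabilities, which sharp Gaussian-mixture posteriors do not
#' reproduce.
#'
#' @param panel An [ssr_panel].
#' @param labels Initial subgroup labels: tibble (`variety_id`, `label`)
#'   or named vector. Varieties labelled `"AD"` or `NA` start from a
#'   uniform `q` but are fitted like all others.
#' @param floor_freq Frequency floor added before renormalising.
#' @param max_iter Outer EM iterations.
#' @param tol Convergence tolerance on the largest `q` change.
#' @return A membership tibble: `variety_id`, one probability column per
#'   subgroup label (rows sum to 1), `label` (arg-max), `max_prob`;
#'   directly consumable by [assign_membership()].
#' @export
estimate_admixture <- function(panel, labels, floor_freq = 1e-3,
                               max_iter = 100L, tol = 1e-5) {
  lab <- as_labels(labels)
  lab <- lab[!is.na(lab) & lab != "AD"]
  groups <- sort(unique(lab))
  K <- length(groups)
  if (K < 2L) abort("need at least two labelled subgroups")
  if (length(setdiff(names(lab), panel_varieties(panel)))) {
    abort("labels name varieties absent from the panel")
  }

  al <- panel_alleles(panel)
  loci <- panel_loci(panel)
  n <- nrow(panel)
  m <- length(loci)
  # per-copy allele indices within each locus; columns j and j+m are the
  # two copies at locus j
  sizes <- purrr::map(seq_len(m), function(j) sort(unique(c(al$a1[, j], al$a2[, j]))))
  idx <- matrix(NA_integer_, n, 2L * m)
  for (j in seq_len(m)) {
    idx[, j] <- match(al$a1[, j], sizes[[j]])
    idx[, j + m] <- match(al$a2[, j], sizes[[j]])
  }

  lab_row <- match(names(lab), panel_varieties(panel))
  q <- matrix(1 / K, n, K)
  q[lab_row, ] <- 0.02 / (K - 1)
  q[cbind(lab_row, match(lab, groups))] <- 0.98

  norm_freq <- function(counts) {
    f <- counts / max(sum(counts), 1e-12)
    (f + floor_freq) / (1 + floor_freq * length(counts))
  }
  # initial frequencies from the labelled cores
  freqs <- lapply(seq_len(K), function(k) {
    rows <- lab_row[lab == groups[k]]
    lapply(seq_len(m), function(j) {
      v <- idx[rows, c(j, j + m)]
      norm_freq(tabulate(v[!is.na(v)], nbins = length(sizes[[j]])))
    })
  })

  lookup <- function(k) {
    FK <- matrix(NA_real_, n, 2L * m)
    for (j in seq_len(m)) {
      f <- freqs[[k]][[j]]
      FK[, j] <- f[idx[, j]]
      FK[, j + m] <- f[idx[, j + m]]
    }
    FK
  }

  for (it in seq_len(max_iter)) {
    FKs <- lapply(seq_len(K), lookup)
    num <- lapply(seq_len(K), function(k) q[, k] * FKs[[k]])
    denom <- Reduce(`+`, num)
    resp <- lapply(num, function(x) x / denom)
    q_new <- vapply(resp, rowMeans, numeric(n), na.rm = TRUE)
    q_new <- q_new / rowSums(q_new)
    for (k in seq_len(K)) {
      rk <- resp[[k]]
      for (j in seq_len(m)) {
        w <- c(rk[, j], rk[, j + m])
        a <- c(idx[, j], idx[, j + m])
        ok <- !is.na(a) & !is.na(w)
        counts <- vapply(seq_along(sizes[[j]]), function(s) sum(w[ok][a[ok] == s]),
                         numeric(1))
        freqs[[k]][[j]] <- norm_freq(counts)
      }
    }
    moved <- max(abs(q_new - q))
    q <- q_new
    if (moved < tol) break
  }

  colnames(q) <- groups
  tibble(variety_id = panel_varieties(panel), as_tibble(q)) |>
    mutate(label = groups[max.col(q, ties.method = "first")],
           max_prob = apply(q, 1L, max))
}
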