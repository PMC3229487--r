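# Small panels built in code, plus independent brute-force oracles used to
# freeze expected values. Oracles deliberately share no code with the
# package internals.

tiny_panel <- function() {
  ssr_panel(tibble::tibble(
    variety_id = c("v1", "v2", "v3", "v4"),
    RM1 = c("120/124", "120", "124", "120"),
    RM2 = c("200", "200/210", "210", NA),
    RM3 = c("95", "95", "95", "95")
  ))
}

tiny_map <- function() {
  genetic_map(tibble::tibble(locus = c("RM1", "RM2", "RM3"),
                             chr = c(1L, 1L, 2L),
                             pos_cm = c(0, 7.5, 3.2)))
}

random_panel <- function(n = 12L, m = 8L, k = 3L, seed = 1L,
                         missing_rate = 0.05, hom = 0.7) {
  set.seed(seed)
  sizes <- lapply(seq_len(m), function(j) sort(sample(100:300, k)))
  calls <- sapply(seq_len(m), function(j) {
    a1 <- sample(sizes[[j]], n, replace = TRUE)
    a2 <- ifelse(runif(n) < hom, a1, sample(sizes[[j]], n, replace = TRUE))
    out <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
    out[runif(n) < missing_rate] <- NA_character_
    out
  })
  # guarantee at least one call per locus
  calls[1L, ] <- ifelse(is.na(calls[1L, ]), "100/100", calls[1L, ])
  colnames(calls) <- sprintf("M%02d", seq_len(m))
  ssr_panel(tibble::tibble(variety_id = sprintf("v%02d", seq_len(n)),
                           tibble::as_tibble(calls)))
}

random_freq_vector <- function(k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- rgamma(k, 1)
  p / sum(p)
}

# frequency list -> allele_frequencies()-shaped tibble
freq_tbl <- function(lst, group = "g") {
  purrr::imap_dfr(lst, function(f, loc) {
    tibble::tibble(group = group, locus = loc,
                   allele = as.integer(names(f)), freq = as.numeric(f))
  })
}

# --- oracles --------------------------------------------------------------

# PIC by the explicit double sum over ordered pairs i < j.
oracle_pic <- function(p) {
  s <- 1 - sum(p^2)
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      if (i < j) s <- s - 2 * p[i]^2 * p[j]^2
    }
  }
  s
}

# MRD by direct summation over a named frequency list per locus.
oracle_mrd <- function(fa, fb) {
  loci <- intersect(names(fa), names(fb))
  total <- 0
  for (loc in loci) {
    alleles <- union(names(fa[[loc]]), names(fb[[loc]]))
    pa <- ifelse(alleles %in% names(fa[[loc]]), fa[[loc]][alleles], 0)
    qa <- ifelse(alleles %in% names(fb[[loc]]), fb[[loc]][alleles], 0)
    total <- total + sum((pa - qa)^2)
  }
  sqrt(total / (2 * length(loci)))
}

# Per-group allele-frequency list by exhaustive tallying of allele copies.
oracle_freq_list <- function(panel, group_ids) {
  loci <- setdiff(names(panel), "variety_id")
  rows <- panel[panel$variety_id %in% group_ids, ]
  out <- list()
  for (loc in loci) {
    copies <- integer()
    for (call in rows[[loc]]) {
      if (!is.na(call)) {
        copies <- c(copies, as.integer(strsplit(call, "/")[[1]]))
      }
    }
    if (length(copies)) out[[loc]] <- table(copies) / length(copies)
  }
  out
}

# Nei Gst by direct per-locus computation over a frequency list per group.
oracle_gst <- function(freq_lists, sizes) {
  w <- sizes / sum(sizes)
  loci <- Reduce(intersect, lapply(freq_lists, names))
  hs_l <- ht_l <- numeric(0)
  for (loc in loci) {
    alleles <- unique(unlist(lapply(freq_lists, function(f) names(f[[loc]]))))
    pooled <- rep(0, length(alleles)); names(pooled) <- alleles
    hs <- 0
    for (g in seq_along(freq_lists)) {
      f <- rep(0, length(alleles)); names(f) <- alleles
      f[names(freq_lists[[g]][[loc]])] <- freq_lists[[g]][[loc]]
      hs <- hs + w[g] * (1 - sum(f^2))
      pooled <- pooled + w[g] * f
    }
    hs_l <- c(hs_l, hs)
    ht_l <- c(ht_l, 1 - sum(pooled^2))
  }
  (mean(ht_l) - mean(hs_l)) / mean(ht_l)
}

# Classical biallelic r^2 as the squared Pearson correlation of 0/1 allele
# indicators over the raw call vectors.
oracle_biallelic_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  ia <- as.integer(a[ok] == sort(unique(a[ok]))[1L])
  ib <- as.integer(b[ok] == sort(unique(b[ok]))[1L])
  cor(ia, ib)^2
}

# Correspondence by exhaustive search over injections of the smaller label
# alphabet into the larger.
oracle_correspondence <- function(a, b) {
  common <- intersect(names(a), names(b))
  a <- a[common]; b <- b[common]
  la <- unique(a); lb <- unique(b)
  if (length(la) > length(lb)) {
    tmp <- a; a <- b; b <- tmp
    tmp <- la; la <- lb; lb <- tmp
  }
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  best <- 0
  for (subset in utils::combn(lb, length(la), simplify = FALSE)) {
    for (target in perms(subset)) {
      mapping <- stats::setNames(target, la)
      best <- max(best, mean(mapping[a] == b))
    }
  }
  best
}

# Maximal significant-adjacent runs by a direct scan over map order.
oracle_blocks <- function(order_loci, pos, sig_adjacent, min_loci = 2L) {
  blocks <- list()
  i <- 1L
  while (i <= length(sig_adjacent)) {
    if (sig_adjacent[i]) {
      j <- i
      while (j < length(sig_adjacent) && sig_adjacent[j + 1L]) j <- j + 1L
      if (j - i + 2L >= min_loci) {
        blocks[[length(blocks) + 1L]] <-
          list(loci = order_loci[i:(j + 1L)], span = pos[j + 1L] - pos[i])
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  blocks
}
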