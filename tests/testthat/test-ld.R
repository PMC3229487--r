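test_that("haploid projection keeps homozygotes and drops heterozygotes", {
  p <- ssr_panel(data.frame(variety_id = c("a", "b", "c"),
                            L1 = c("120", "120/124", NA),
                            L2 = c("200", "210", "200")))
  h <- haploid_calls(p)
  expect_equal(unname(h[, "L1"]), c(120L, NA, NA))
  expect_equal(unname(h[, "L2"]), c(200L, 210L, 200L))
  # fully homozygous panel equals the first-allele projection
  p2 <- random_panel(n = 8, m = 4, k = 3, seed = 2, hom = 1, missing_rate = 0)
  expect_equal(haploid_calls(p2), panel_alleles(p2)$a1)
})

test_that("perfect coupling and exact independence hit the r2/D' bounds", {
  a <- rep(c(100L, 104L), each = 10)
  b <- rep(c(200L, 204L), each = 10)
  res <- pair_ld(a, b, seed = 1)
  expect_equal(res$r2, 1)
  expect_equal(res$d_prime, 1)
  expect_lt(res$p_value, 0.001)
  # joint counts exactly p_i * q_j: 9 haplotypes, margins 2/3 and 2/3
  a2 <- c(rep(100L, 6), rep(104L, 3))
  b2 <- c(rep(200L, 4), rep(204L, 2), rep(200L, 2), rep(204L, 1))
  res2 <- pair_ld(a2, b2, seed = 1)
  expect_equal(res2$r2, 0, tolerance = 1e-12)
  expect_equal(res2$d_prime, 0, tolerance = 1e-12)
})

test_that("biallelic r2 equals the indicator-correlation oracle", {
  set.seed(12)
  for (rep in 1:25) {
    n <- 40
    a <- sample(c(100L, 104L), n, replace = TRUE)
    b <- sample(c(200L, 204L), n, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    res <- pair_ld(a, b, n_shuffles = 10, seed = 1, min_count = 0)
    expect_equal(res$r2, oracle_biallelic_r2(a, b), tolerance = 1e-12)
  }
})

test_that("D' is 1 whenever a haplotype class is absent in a 2x2 table", {
  a <- c(rep(100L, 12), rep(104L, 8))
  b <- c(rep(200L, 8), rep(204L, 4), rep(204L, 8))  # haplotype (104,200) absent
  res <- pair_ld(a, b, seed = 1)
  expect_equal(res$d_prime, 1, tolerance = 1e-12)
})

test_that("degenerate inputs are flagged missing", {
  res <- pair_ld(rep(100L, 10), sample(c(200L, 204L), 10, replace = TRUE))
  expect_true(is.na(res$r2))
  res2 <- pair_ld(c(100L, NA), c(200L, 204L))
  expect_true(is.na(res2$r2))
})

test_that("permutation p-values are seeded, reproducible and never zero", {
  set.seed(3)
  a <- sample(c(100L, 104L, 108L), 40, replace = TRUE)
  b <- sample(c(200L, 204L, 208L), 40, replace = TRUE)
  p1 <- pair_ld(a, b, n_shuffles = 200, seed = 9)$p_value
  p2 <- pair_ld(a, b, n_shuffles = 200, seed = 9)$p_value
  expect_identical(p1, p2)
  expect_gt(p1, 0)
  # perfectly coupled multiallelic pair: p bounded by add-one correction
  a3 <- rep(c(100L, 104L, 108L), each = 8)
  b3 <- rep(c(200L, 204L, 208L), each = 8)
  p3 <- pair_ld(a3, b3, n_shuffles = 200, seed = 9)$p_value
  expect_gte(p3, 1 / 201)
  expect_lt(p3, 0.02)
})

test_that("rare-allele pooling folds singleton alleles into one class", {
  a <- c(rep(100L, 18), 104L, 108L)          # two singleton alleles
  b <- rep(c(200L, 204L), 10)
  res <- pair_ld(a, b, n_shuffles = 100, seed = 2)
  expect_equal(res$k_a, 2L)                  # 100 vs pooled "other"
  res_off <- pair_ld(a, b, n_shuffles = 100, seed = 2, min_count = 0)
  expect_equal(res_off$k_a, 3L)
})

test_that("ld_pairs annotates linkage and distance from the map", {
  p <- random_panel(n = 12, m = 3, k = 3, seed = 5, hom = 1, missing_rate = 0)
  names(p)[2:4] <- c("RM1", "RM2", "RM3")
  res <- ld_pairs(p, tiny_map(), n_shuffles = 100, seed = 1)
  expect_equal(nrow(res), 3L)
  r12 <- res[res$locus_a == "RM1" & res$locus_b == "RM2", ]
  expect_true(r12$linked)
  expect_equal(r12$dist_cm, 7.5)
  r13 <- res[res$locus_a == "RM1" & res$locus_b == "RM3", ]
  expect_false(r13$linked)
  expect_true(is.na(r13$dist_cm))
  # single-group, single-pair toy: summary percentages are 0 or 100
  one <- res[1, ]
  s <- ld_summary(one)
  expect_true(all(na.omit(unlist(s$summary[c("pct_linked", "pct_unlinked",
                                             "pct_total")])) %in% c(0, 100)))
  # groups smaller than 2 varieties are skipped with a warning
  grp <- data.frame(variety_id = panel_varieties(p),
                    group = c("solo", rep("rest", 11)))
  expect_warning(ld_pairs(p, tiny_map(), grp, n_shuffles = 10, seed = 1),
                 "solo")
})

test_that("interpolated quantile threshold matches hand arithmetic", {
  pairs <- tibble::tibble(
    group = "all",
    locus_a = paste0("A", 1:8), locus_b = paste0("B", 1:8),
    chr_a = c(1, 1, 1, 1, 1, 2, 3, 4), chr_b = c(1, 1, 1, 1, 2, 3, 4, 5),
    linked = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    dist_cm = c(1, 2, 3, 4, NA, NA, NA, NA),
    r2 = c(0.5, 0.4, 0.3, 0.2, 0.0, 0.1, 0.2, 0.3),
    d_prime = 0.5, p_value = 0.5, n = 20)
  dec <- decay_distance(pairs, probs = 0.75, window = 2, step = 1)
  expect_equal(dec$threshold, 0.225)        # interpolation between 0.2 and 0.3
})

test_that("decay distance follows the windowed threshold crossing", {
  # linked r2 declining linearly from 0.8 at 0 cM to 0 at 40 cM, one pair
  # per cM; unlinked quantile fixed at 0.2
  dist <- 0:40
  lnk <- tibble::tibble(group = "all", locus_a = paste0("L", dist),
                        locus_b = paste0("R", dist), chr_a = 1, chr_b = 1,
                        linked = TRUE, dist_cm = dist,
                        r2 = 0.8 * (1 - dist / 40), d_prime = 0.5,
                        p_value = 0.5, n = 20)
  unl <- tibble::tibble(group = "all", locus_a = paste0("U", 1:4),
                        locus_b = paste0("V", 1:4), chr_a = 1, chr_b = 2,
                        linked = FALSE, dist_cm = NA_real_,
                        r2 = c(0.15, 0.18, 0.2, 0.26), d_prime = 0.1,
                        p_value = 0.5, n = 20)
  dec <- decay_distance(rbind(lnk, unl), probs = 0.75, window = 5, step = 1)
  # independent window scan under the same stated convention
  threshold <- unname(quantile(unl$r2, 0.75))
  expected <- NA_real_
  for (l in 0:39) {
    means <- sapply(l:39, function(ll) {
      v <- lnk$r2[lnk$dist_cm >= ll & lnk$dist_cm < ll + 5]
      if (length(v)) mean(v) else NA_real_
    })
    if (!is.na(means[1]) && all(means < threshold, na.rm = TRUE)) {
      expected <- l
      break
    }
  }
  expect_equal(dec$decay_cm, expected)
  # all linked r2 already below threshold -> decay at 0
  low <- lnk
  low$r2 <- 0.01
  expect_equal(decay_distance(rbind(low, unl))$decay_cm, 0)
  # never below -> beyond map extent
  high <- lnk
  high$r2 <- 0.9
  expect_equal(decay_distance(rbind(high, unl))$decay_cm, Inf)
})

test_that("block calling matches the brute-force run scan", {
  mk_map <- function(pos) genetic_map(tibble::tibble(
    locus = paste0("L", seq_along(pos)), chr = 1L, pos_cm = pos))
  mk_pairs <- function(map, sig) {
    # adjacent pairs only; p-value 0.01 if significant else 0.5
    tibble::tibble(group = "all",
                   locus_a = map$locus[-nrow(map)], locus_b = map$locus[-1],
                   chr_a = 1, chr_b = 1, linked = TRUE,
                   dist_cm = diff(map$pos_cm),
                   r2 = 0.5, d_prime = 0.5,
                   p_value = ifelse(sig, 0.01, 0.5), n = 20)
  }
  map5 <- mk_map(c(0, 2, 5, 9, 14))
  sig <- c(TRUE, TRUE, FALSE, TRUE)          # blocks L1-L3 and L4-L5
  blocks <- find_blocks(mk_pairs(map5, sig), map5)
  expect_equal(nrow(blocks), 2L)
  expect_equal(blocks$start_locus, c("L1", "L4"))
  expect_equal(blocks$end_locus, c("L3", "L5"))
  expect_equal(blocks$n_loci, c(3L, 2L))
  expect_equal(blocks$span_cm, c(5, 5))
  # no significant adjacent pairs -> no blocks
  expect_equal(nrow(find_blocks(mk_pairs(map5, rep(FALSE, 4)), map5)), 0L)
  # random patterns vs oracle
  set.seed(8)
  for (rep in 1:10) {
    pos <- sort(runif(8, 0, 50))
    mp <- mk_map(pos)
    sig <- runif(7) < 0.5
    got <- find_blocks(mk_pairs(mp, sig), mp)
    want <- oracle_blocks(mp$locus, mp$pos_cm, sig)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$span_cm, vapply(want, `[[`, numeric(1), "span"),
                   tolerance = 1e-12)
    }
  }
})

test_that("block calling is invariant to relabeling and cM shifts", {
  pos <- c(0, 3, 7, 12, 20)
  map1 <- genetic_map(tibble::tibble(locus = paste0("L", 1:5), chr = 1L,
                                     pos_cm = pos))
  sig <- c(TRUE, TRUE, TRUE, FALSE)
  pairs1 <- tibble::tibble(group = "all", locus_a = map1$locus[-5],
                           locus_b = map1$locus[-1], chr_a = 1, chr_b = 1,
                           linked = TRUE, dist_cm = diff(pos), r2 = 0.5,
                           d_prime = 0.5, p_value = ifelse(sig, 0.01, 0.9),
                           n = 10)
  b1 <- find_blocks(pairs1, map1)
  # shift positions and relabel loci
  new_names <- paste0("XX", 5:1)
  map2 <- genetic_map(tibble::tibble(locus = new_names, chr = 1L,
                                     pos_cm = pos + 100))
  pairs2 <- pairs1
  pairs2$locus_a <- new_names[1:4]
  pairs2$locus_b <- new_names[2:5]
  b2 <- find_blocks(pairs2, map2)
  expect_equal(b2$span_cm, b1$span_cm)
  expect_equal(b2$n_loci, b1$n_loci)
})

test_that("block summaries report both averaging conventions", {
  blocks <- tibble::tibble(chr = c(1L, 1L, 3L),
                           start_locus = c("a", "c", "e"),
                           end_locus = c("b", "d", "f"),
                           n_loci = 2L, span_cm = c(4, 6, 10),
                           loci = list(c("a", "b"), c("c", "d"), c("e", "f")))
  s <- block_summary(blocks, n_chromosomes = 3L)
  expect_equal(s$total_blocks, 3L)
  expect_equal(s$per_chromosome$n_blocks, c(2L, 0L, 1L))
  expect_equal(s$mean_length_chromosomes_with_blocks, mean(c(5, 10)))
  expect_equal(s$mean_length_all_chromosomes, mean(c(5, 0, 10)))
})
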