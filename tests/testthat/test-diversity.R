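test_that("allele frequencies count copies, not varieties", {
  p <- ssr_panel(data.frame(variety_id = c("a", "b"),
                            L1 = c("120", "120/124")))
  fr <- allele_frequencies(p)
  expect_equal(fr$freq[fr$allele == 120], 0.75)
  expect_equal(fr$freq[fr$allele == 124], 0.25)
  expect_equal(unique(fr$n_genes), 4L)
})

test_that("group-absent loci are flagged and unknown varieties rejected", {
  p <- ssr_panel(data.frame(variety_id = c("a", "b"),
                            L1 = c("120", NA), L2 = c("100", "102")))
  grp <- data.frame(variety_id = c("a", "b"), group = c("g1", "g2"))
  fr <- allele_frequencies(p, grp)
  absent <- attr(fr, "absent")
  expect_equal(nrow(absent), 1L)
  expect_equal(absent$group, "g2")
  expect_equal(absent$locus, "L1")
  expect_error(allele_frequencies(p, data.frame(variety_id = "zz", group = "g")),
               "unknown")
})

test_that("frequencies match the exhaustive tally oracle on random panels", {
  for (seed in 1:5) {
    p <- random_panel(n = 10, m = 6, k = 4, seed = seed)
    fr <- allele_frequencies(p)
    want <- oracle_freq_list(p, panel_varieties(p))
    for (loc in names(want)) {
      got <- fr[fr$locus == loc, ]
      expect_equal(got$freq[order(got$allele)],
                   as.numeric(want[[loc]])[order(as.integer(names(want[[loc]])))],
                   tolerance = 1e-12)
    }
  }
})

test_that("gene diversity and PIC agree with closed forms and oracles", {
  expect_equal(gene_diversity(1), 0)
  expect_equal(gene_diversity(c(0.5, 0.5)), 0.5)
  expect_equal(gene_diversity(rep(0.25, 4)), 0.75)
  expect_equal(pic(1), 0)
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_error(gene_diversity(numeric(0)), "empty")
  expect_error(pic(numeric(0)), "empty")
  for (seed in 1:20) {
    p <- random_freq_vector(sample(2:8, 1), seed = seed)
    expect_equal(pic(p), oracle_pic(p), tolerance = 1e-12)
    expect_lte(pic(p), gene_diversity(p) + 1e-12)
    expect_gte(pic(p), 0)
    expect_lt(gene_diversity(p), 1)
  }
})

test_that("MRD boundary cases and oracle equivalence", {
  fa <- list(L1 = c(`120` = 1))
  fb <- list(L1 = c(`124` = 1))
  expect_equal(mrd(freq_tbl(fa), freq_tbl(fa)), 0)
  expect_equal(mrd(freq_tbl(fa), freq_tbl(fb)), 1)
  expect_error(mrd(freq_tbl(fa), freq_tbl(fb), loci = character(0)), "empty")
  for (seed in 1:10) {
    set.seed(seed)
    mk <- function() {
      lst <- lapply(1:4, function(j) {
        alleles <- sort(sample(100:120, sample(2:5, 1)))
        f <- random_freq_vector(length(alleles))
        names(f) <- alleles
        f
      })
      names(lst) <- paste0("L", 1:4)
      lst
    }
    fa <- mk(); fb <- mk()
    expect_equal(mrd(freq_tbl(fa), freq_tbl(fb)), oracle_mrd(fa, fb),
                 tolerance = 1e-12)
  }
})

test_that("MRD is a metric on frequency tables", {
  set.seed(99)
  tables <- lapply(1:3, function(i) {
    lst <- lapply(1:3, function(j) {
      f <- random_freq_vector(4)
      names(f) <- c(100, 104, 108, 112)
      f
    })
    names(lst) <- paste0("L", 1:3)
    lst
  })
  d <- function(i, j) mrd(freq_tbl(tables[[i]]), freq_tbl(tables[[j]]))
  expect_equal(d(1, 1), 0)
  expect_equal(d(1, 2), d(2, 1))
  expect_lte(d(1, 3), d(1, 2) + d(2, 3) + 1e-12)
  expect_lte(d(1, 2), d(1, 3) + d(3, 2) + 1e-12)
})

test_that("Gst boundary cases and oracle equivalence", {
  p_same <- ssr_panel(data.frame(variety_id = c("a", "b", "c", "d"),
                                 L1 = c("120/124", "120", "120/124", "120")))
  grp2 <- data.frame(variety_id = c("a", "b", "c", "d"),
                     group = c("g1", "g1", "g2", "g2"))
  fr <- allele_frequencies(p_same, grp2)
  expect_equal(gst(fr, c(g1 = 2, g2 = 2)), 0, tolerance = 1e-12)

  p_fixed <- ssr_panel(data.frame(variety_id = c("a", "b", "c", "d"),
                                  L1 = c("120", "120", "124", "124")))
  fr <- allele_frequencies(p_fixed, grp2)
  expect_equal(gst(fr, c(g1 = 2, g2 = 2)), 1)

  p_mono <- ssr_panel(data.frame(variety_id = c("a", "b"), L1 = c("120", "120")))
  fr <- allele_frequencies(p_mono, data.frame(variety_id = c("a", "b"),
                                              group = c("g1", "g2")))
  expect_true(is.na(gst(fr, c(g1 = 1, g2 = 1))))   # Ht = 0 flagged undefined
  expect_error(gst(allele_frequencies(p_mono), c(all = 2)), "two groups")

  for (seed in 1:5) {
    p <- random_panel(n = 15, m = 5, k = 3, seed = seed, missing_rate = 0)
    ids <- panel_varieties(p)
    g <- rep(c("g1", "g2", "g3"), length.out = 15)
    fr <- allele_frequencies(p, data.frame(variety_id = ids, group = g))
    sizes <- table(g)
    want <- oracle_gst(list(oracle_freq_list(p, ids[g == "g1"]),
                            oracle_freq_list(p, ids[g == "g2"]),
                            oracle_freq_list(p, ids[g == "g3"])),
                       as.numeric(sizes))
    expect_equal(gst(fr, setNames(as.numeric(sizes), names(sizes))), want,
                 tolerance = 1e-10)
  }
})

test_that("diversity scan handles monomorphic loci, private alleles and SEs", {
  p <- ssr_panel(data.frame(variety_id = c("a", "b", "c", "d"),
                            MONO = c("100", "100", "100", "100"),
                            PRIV = c("120", "120", "124", "120/124"),
                            POLY = c("130", "134", "130/134", "138")))
  grp <- data.frame(variety_id = c("a", "b", "c", "d"),
                    group = c("g1", "g1", "g2", "g2"))
  scan <- diversity_scan(p, grp, n_bootstrap = 50, seed = 4)
  mono <- scan$per_locus[scan$per_locus$locus == "MONO", ]
  expect_equal(mono$gene_diversity, c(0, 0))
  expect_equal(mono$se, c(0, 0))                  # bootstrap SE exactly 0
  expect_equal(scan$mrd_scan$mrd[scan$mrd_scan$locus == "MONO"], 0)
  expect_equal(scan$mrd_scan$se[scan$mrd_scan$locus == "MONO"], 0)
  # PRIV: allele 120 in both groups, 124 only in g2 -> one unique for g2
  gs <- scan$group_summary
  expect_equal(gs$unique_alleles[gs$group == "g2"], 2L)  # 124 at PRIV, 138 at POLY
  expect_equal(gs$unique_alleles[gs$group == "g1"], 0L)
  expect_equal(gs$n, c(2L, 2L))
  expect_equal(gs$mean_allele_freq, sapply(split(scan$per_locus, scan$per_locus$group),
                                           function(d) mean(1 / d$n_alleles)),
               ignore_attr = TRUE)
})

test_that("whole-panel MRD equals the root-mean of per-locus contributions", {
  sim <- simulate_panel(sim_config(n_subpop1 = 20L, n_subpop2 = 20L,
                                   n_admixed = 0L,
                                   loci_per_chromosome = rep(4L, 12L),
                                   spacing_cm = rep(6, 12L),
                                   divergence = 0.3, seed = 31))
  grp <- sim$truth[c("variety_id", "group")]
  scan <- diversity_scan(sim$panel, grp, n_bootstrap = 100, seed = 9)
  direct <- mrd_between(sim$panel, grp, c("subpop1", "subpop2"))
  expect_equal(scan$overall_mrd, direct, tolerance = 1e-10)
  # per-locus MRDs are plausible draws around the aggregate
  mean_locus <- mean(scan$mrd_scan$mrd, na.rm = TRUE)
  pooled_se <- sqrt(mean(scan$mrd_scan$se^2, na.rm = TRUE))
  expect_lt(abs(mean_locus - direct), 3 * pooled_se + 0.05)
})
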