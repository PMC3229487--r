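test_that("encoding produces within-variety frequencies with block sums 1", {
  p <- ssr_panel(data.frame(variety_id = c("a", "b", "c"),
                            L1 = c("120/124", "130", "120"),
                            L2 = c("200", "200", NA)))
  x <- encode_panel(p)
  # heterozygote at a 3-allele locus
  expect_equal(unname(x["a", c("L1@120", "L1@124", "L1@130")]), c(0.5, 0.5, 0))
  expect_equal(unname(x["b", "L1@130"]), 1)
  # missing block mean-filled with the panel-wide frequency, flag retained
  expect_equal(unname(x["c", "L2@200"]), 1)
  expect_true(attr(x, "missing")["c", "L2"])
  # block sums
  loci <- attr(x, "locus")
  for (loc in unique(loci)) {
    expect_equal(unname(rowSums(x[, loci == loc, drop = FALSE])), rep(1, 3))
  }
  raw <- encode_panel(p, impute = FALSE)
  expect_true(all(is.na(raw["c", loci == "L2"])))
})

test_that("PCA puts duplicated profiles at zero higher-axis variance", {
  p <- ssr_panel(data.frame(variety_id = c("a", "b"),
                            L1 = c("120/124", "120/124"),
                            L2 = c("200", "200")))
  expect_warning(ord <- pca_panel(p, n_components = 2), "rank")
  expect_equal(sum(ord$prop_var), 0)   # no variance at all between clones
})

test_that("PCA variance proportions match an independent spectral oracle", {
  set.seed(5)
  x <- matrix(rnorm(40), 5, 8)
  ord <- pca_panel(x, n_components = 4)
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(xc) / (nrow(x) - 1), symmetric = TRUE)$values
  ev <- ev[ev > 1e-12]
  expect_equal(ord$prop_var, (ev / sum(ev))[1:4], tolerance = 1e-9)
  expect_true(all(diff(ord$prop_var) <= 1e-12))
})

test_that("PCA axis 1 separates simulated subpopulations", {
  sim <- simulate_panel(sim_config(n_subpop1 = 40L, n_subpop2 = 40L,
                                   n_admixed = 0L,
                                   loci_per_chromosome = rep(10L, 12L),
                                   spacing_cm = rep(6, 12L),
                                   divergence = 0.3, seed = 77))
  ord <- pca_panel(sim$panel, n_components = 2)
  side <- ord$scores$PC1 > 0
  truth <- sim$truth$group == "subpop1"
  acc <- max(mean(side == truth), mean(side != truth))
  expect_gte(acc, 0.95)
})

test_that("PCoA recovers planar configurations and the 2-point case", {
  set.seed(11)
  pts <- cbind(runif(9), runif(9))
  d <- as.matrix(dist(pts))
  ord <- pcoa(d, n_axes = 2)
  rec <- as.matrix(ord$scores[c("PCo1", "PCo2")])
  expect_equal(as.matrix(dist(rec)), d, ignore_attr = TRUE, tolerance = 1e-8)

  d2 <- matrix(c(0, 3, 3, 0), 2, 2)
  ord2 <- pcoa(d2, n_axes = 1)
  expect_equal(sort(abs(ord2$scores$PCo1)), c(1.5, 1.5), tolerance = 1e-9)

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa(bad), "symmetric")
})

test_that("MRD matrices are Euclidean-embeddable", {
  for (seed in c(2, 9)) {
    p <- random_panel(n = 12, m = 10, k = 4, seed = seed)
    d <- mrd_matrix(p)
    expect_true(isSymmetric(unname(d)))
    expect_equal(unname(diag(d)), rep(0, 12))
    # Gower-centred squared distances have no meaningfully negative eigenvalue
    n <- nrow(d)
    J <- diag(n) - matrix(1 / n, n, n)
    B <- -0.5 * J %*% (d^2) %*% J
    ev <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-9)
  }
})

test_that("pairwise-deletion MRD matches per-pair direct computation", {
  p <- random_panel(n = 8, m = 6, k = 3, seed = 14, missing_rate = 0.1)
  d <- mrd_matrix(p)
  ids <- panel_varieties(p)
  for (pair in list(c(1, 2), c(3, 7), c(5, 8))) {
    fa <- oracle_freq_list(p, ids[pair[1]])
    fb <- oracle_freq_list(p, ids[pair[2]])
    shared <- intersect(names(fa), names(fb))
    expect_equal(d[pair[1], pair[2]],
                 oracle_mrd(fa[shared], fb[shared]), tolerance = 1e-10)
  }
})

test_that("Laplacian embedding separates disconnected similarity blocks", {
  set.seed(3)
  base1 <- rnorm(40); base2 <- rnorm(40)
  x <- rbind(t(replicate(5, base1 + rnorm(40, sd = 0.1))),
             t(replicate(5, base2 + rnorm(40, sd = 0.1))))
  rownames(x) <- paste0("v", 1:10)
  ord <- laplacian_embed(x, eps = 0.8, n_axes = 1)
  lap1 <- ord$scores$Lap1
  # the zero-eigenvalue lapvector of a two-component graph is sign-constant
  # within components (entries scale with sqrt(degree)) and separates them
  expect_equal(length(unique(sign(lap1[1:5]))), 1L)
  expect_equal(length(unique(sign(lap1[6:10]))), 1L)
  expect_false(sign(lap1[1]) == sign(lap1[6]))
})

test_that("eps = 1 isolates distinct varieties with a warning", {
  set.seed(4)
  x <- matrix(rnorm(50), 5, 10)
  expect_warning(laplacian_embed(x, eps = 1.0), "isolated")
})

test_that("Laplacian axis separates simulated subpopulations", {
  sim <- simulate_panel(sim_config(n_subpop1 = 30L, n_subpop2 = 30L,
                                   n_admixed = 0L,
                                   loci_per_chromosome = rep(8L, 12L),
                                   spacing_cm = rep(6, 12L),
                                   divergence = 0.3, seed = 13))
  enc <- encode_panel(sim$panel)
  ord <- suppressWarnings(laplacian_embed(enc, eps = 0.1, n_axes = 1))
  side <- ord$scores$Lap1 > median(ord$scores$Lap1)
  truth <- sim$truth$group == "subpop1"
  acc <- max(mean(side == truth), mean(side != truth))
  expect_gte(acc, 0.95)
})

test_that("PCA and PCoA order varieties identically on axis 1", {
  sim <- simulate_panel(sim_config(n_subpop1 = 25L, n_subpop2 = 25L,
                                   n_admixed = 5L,
                                   loci_per_chromosome = rep(8L, 12L),
                                   spacing_cm = rep(6, 12L),
                                   divergence = 0.35, seed = 23,
                                   missing_rate = 0))
  pc <- pca_panel(sim$panel, n_components = 2)
  po <- pcoa(mrd_matrix(sim$panel), n_axes = 2)
  expect_gte(abs(cor(pc$scores$PC1, po$scores$PCo1)), 0.99)
})
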