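#' Simulation settings for a two-subpopulation selfing SSR panel
#'
#' The generator emulates the statistical structure of an inbred rice core
#' collection genotyped with genome-wide SSRs: two diverged subpopulations
#' plus a minority of admixed varieties, multiallelic loci spread over 12
#' chromosomes, near-complete homozygosity from selfing, and a small missing
#' call rate. Defaults reproduce the published panel's shape: 111 + 20 + 19 =
#' 150 varieties, per-chromosome marker counts summing to 274, the reported
#' mean inter-marker spacings, and an alleles-per-locus distribution on 2-12
#' whose mean is close to 3.9.
#'
#' Subpopulation allele frequencies follow a Balding-Nichols-style model:
#' ancestral frequencies at each locus are drawn from a flat Dirichlet, and
#' each subpopulation's frequencies from a Dirichlet concentrated around the
#' ancestral vector with concentration `(1 - F) / F`, so the divergence
#' parameter `F` in [0, 1) controls how far the two subpopulations drift
#' apart. An admixed variety draws alleles from `q * p1 + (1 - q) * p2` with
#' its own admixture proportion `q`.
#'
#' @param n_subpop1,n_subpop2,n_admixed Varieties per group.
#' @param loci_per_chromosome Integer vector of marker counts, one per
#'   chromosome.
#' @param spacing_cm Mean inter-locus spacing per chromosome (cM); gaps are
#'   drawn uniformly between 0.5 and 1.5 times the mean.
#' @param allele_range Smallest and largest permitted allele count per locus.
#' @param allele_geom Ratio of the truncated-geometric weights on allele
#'   counts; 0.65 gives a mean near 3.9 alleles per locus on 2..12.
#' @param divergence Balding-Nichols `F` in [0, 1).
#' @param admix_range Range of the uniform admixture-proportion draw.
#' @param homozygosity Probability that a variety is homozygous at a locus
#'   (selfing rate; residual heterozygotes exercise the LD haplotype policy).
#' @param missing_rate Per-call missing probability.
#' @param trait_p Named vector of per-trait success probabilities for the
#'   class-conditional Binomial(4, p) trait-score draws (see
#'   [simulate_traits()]).
#' @param seed Integer seed; mandatory, every stochastic run is reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subpop1 = 111L, n_subpop2 = 20L, n_admixed = 19L,
                       loci_per_chromosome = c(23L, 25L, 24L, 22L, 21L, 22L,
                                               21L, 25L, 23L, 24L, 23L, 21L),
                       spacing_cm = c(7.5, 8.2, 9.4, 7.4, 7.1, 6.3,
                                      5.8, 5.4, 5.2, 4.7, 5.6, 5.3),
                       allele_range = c(2L, 12L), allele_geom = 0.65,
                       divergence = 0.35, admix_range = c(0.2, 0.8),
                       homozygosity = 0.95, missing_rate = 0.02,
                       trait_p = c(subpop1 = 0.12, subpop2 = 0.88, admixed = 0.5),
                       seed) {
  if (missing(seed)) abort("sim_config requires an explicit integer seed")
  stopifnot(length(loci_per_chromosome) == length(spacing_cm),
            all(loci_per_chromosome >= 1L),
            allele_range[1L] >= 2L, allele_range[2L] >= allele_range[1L],
            divergence >= 0, divergence < 1,
            homozygosity >= 0, homozygosity <= 1,
            missing_rate >= 0, missing_rate < 1,
            all(trait_p >= 0 & trait_p <= 1),
            all(c("subpop1", "subpop2", "admixed") %in% names(trait_p)))
  structure(list(
    n_subpop1 = as.integer(n_subpop1), n_subpop2 = as.integer(n_subpop2),
    n_admixed = as.integer(n_admixed),
    loci_per_chromosome = as.integer(loci_per_chromosome),
    spacing_cm = as.numeric(spacing_cm),
    allele_range = as.integer(allele_range), allele_geom = allele_geom,
    divergence = divergence, admix_range = as.numeric(admix_range),
    homozygosity = homozygosity, missing_rate = missing_rate,
    trait_p = trait_p, seed = as.integer(seed)
  ), class = "sim_config")
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))  # degenerate guard
  g / sum(g)
}

#' Simulate an SSR panel with known structure
#'
#' Draws a genotype panel, a genetic map and the ground truth (group labels
#' and admixture proportions) from a [sim_config]. Each inbred variety draws
#' one allele per locus from its (possibly admixture-weighted) subpopulation
#' frequency vector and is homozygous with the configured selfing rate,
#' otherwise the second allele is drawn independently; missing calls are
#' injected uniformly. With a fixed seed the output is byte-identical across
#' runs.
#'
#' @param config A [sim_config].
#' @return A list with elements `panel` ([ssr_panel]), `map`
#'   ([genetic_map]) and `truth`, a tibble with `variety_id`, `group`
#'   (`subpop1`/`subpop2`/`admixed`) and `q1`, the proportion of the genome
#'   drawn from subpopulation 1 (1 or 0 for the pure groups).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_chr <- length(config$loci_per_chromosome)
  n_loci <- sum(config$loci_per_chromosome)
  n1 <- config$n_subpop1; n2 <- config$n_subpop2; na <- config$n_admixed
  n <- n1 + n2 + na
  if (config$divergence == 0 && n1 > 0 && n2 > 0) {
    warn("divergence F = 0: subpopulations are exchangeable")
  }

  variety_id <- sprintf("V%03d", seq_len(n))
  group <- rep(c("subpop1", "subpop2", "admixed"), times = c(n1, n2, na))
  q1 <- c(rep(1, n1), rep(0, n2),
          runif(na, config$admix_range[1L], config$admix_range[2L]))

  locus_id <- sprintf("L%03d", seq_len(n_loci))
  chr <- rep(seq_len(n_chr), times = config$loci_per_chromosome)
  pos_cm <- unlist(lapply(seq_len(n_chr), function(cc) {
    k <- config$loci_per_chromosome[cc]
    gaps <- runif(k - 1L, 0.5, 1.5) * config$spacing_cm[cc]
    cumsum(c(0, gaps))
  }), use.names = FALSE)
  map <- genetic_map(tibble(locus = locus_id, chr = chr, pos_cm = pos_cm),
                     n_chromosomes = n_chr)

  kr <- config$allele_range
  k_support <- kr[1L]:kr[2L]
  k_weights <- config$allele_geom^(k_support - kr[1L])
  F <- config$divergence
  conc <- if (F > 0) (1 - F) / F else Inf

  a1 <- matrix(NA_integer_, n, n_loci)
  a2 <- matrix(NA_integer_, n, n_loci)
  for (j in seq_len(n_loci)) {
    k <- k_support[sample.int(length(k_support), 1L, prob = k_weights)]
    sizes <- sort(sample(seq(100L, 400L, by = 2L), k))
    anc <- rdirichlet1(rep(1, k))
    if (is.finite(conc)) {
      p1 <- rdirichlet1(anc * conc)
      p2 <- rdirichlet1(anc * conc)
    } else {
      p1 <- p2 <- anc
    }
    fr <- q1 %o% p1 + (1 - q1) %o% p2      # n x k per-variety frequency rows
    cum <- t(apply(fr, 1L, cumsum))
    draw <- function() {
      u <- runif(n)
      idx <- rowSums(u > cum) + 1L
      pmin(idx, k)
    }
    i1 <- draw()
    hom <- runif(n) < config$homozygosity
    i2 <- ifelse(hom, i1, draw())
    a1[, j] <- sizes[pmin(i1, i2)]
    a2[, j] <- sizes[pmax(i1, i2)]
  }
  if (config$missing_rate > 0) {
    miss <- matrix(runif(n * n_loci) < config$missing_rate, n, n_loci)
    # keep the invariant that every locus retains at least one call
    full_loss <- which(colSums(!miss) == 0L)
    if (length(full_loss)) miss[1L, full_loss] <- FALSE
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
  }

  calls <- matrix(paste0(a1, "/", a2), n, n_loci)
  calls[is.na(a1)] <- NA_character_
  colnames(calls) <- locus_id
  panel <- ssr_panel(tibble(variety_id = variety_id, as_tibble(calls)))

  list(panel = panel, map = map,
       truth = tibble(variety_id = variety_id, group = group, q1 = q1))
}

#' Calibrate the divergence parameter to a target between-group MRD
#'
#' Finite allele sampling makes the mapping from the Balding-Nichols `F` to
#' the realised modified Rogers distance configuration-dependent, so the
#' target is hit by bisection: panels are simulated at candidate `F` values
#' (same seed, so the comparison is paired) and the realised MRD between the
#' two pure subpopulations is driven to `target_mrd`.
#'
#' @param config A [sim_config]; its `divergence` field is ignored.
#' @param target_mrd Desired between-subpopulation MRD (published value
#'   0.443 for indica vs japonica).
#' @param tol Convergence tolerance on the realised MRD.
#' @param max_iter Bisection iteration cap.
#' @return The calibrated `F`, with the realised MRD as attribute
#'   `realized_mrd`.
#' @export
calibrate_divergence <- function(config, target_mrd = 0.443, tol = 0.005,
                                 max_iter = 30L) {
  realized <- function(F) {
    cfg <- config
    cfg$divergence <- F
    sim <- simulate_panel(cfg)
    grp <- setNames(sim$truth$group, sim$truth$variety_id)
    keep <- grp[grp %in% c("subpop1", "subpop2")]
    mrd_between(sim$panel, tibble(variety_id = names(keep), group = unname(keep)),
                c("subpop1", "subpop2"))
  }
  lo <- 0.01; hi <- 0.95
  f_lo <- realized(lo); f_hi <- realized(hi)
  if (target_mrd <= f_lo) return(structure(lo, realized_mrd = f_lo))
  if (target_mrd >= f_hi) return(structure(hi, realized_mrd = f_hi))
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- realized(mid)
    if (abs(f_mid - target_mrd) < tol) {
      return(structure(mid, realized_mrd = f_mid))
    }
    if (f_mid < target_mrd) lo <- mid else hi <- mid
  }
  structure(mid, realized_mrd = f_mid)
}

#' Simulate class-conditional morphological traits
#'
#' Draws the six Cheng traits so that subpopulation 1 varieties concentrate
#' at low scores (index mass in the typical-indica band), subpopulation 2 at
#' high scores (typical-japonica band) and admixed varieties in between.
#' Each trait's intended 0-4 level is drawn Binomial(4, p) with the
#' class-conditional p from the config; the two numeric traits are then
#' drawn uniformly inside the measurement interval that scores at the
#' intended level, so re-scoring them reproduces it.
#'
#' @param truth Truth tibble from [simulate_panel()] (columns `variety_id`,
#'   `group`).
#' @param config The [sim_config] used for the panel.
#' @return A [trait_table].
#' @export
simulate_traits <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"),
            all(c("variety_id", "group") %in% names(truth)))
  set.seed(config$seed + 1L)
  n <- nrow(truth)
  p <- unname(config$trait_p[truth$group])
  if (anyNA(p)) abort("truth groups must be subpop1/subpop2/admixed")
  draw_level <- function() rbinom(n, 4L, p)
  # measurement intervals per score level under the Cheng scoring standard
  rachis_lo <- c(1.2, 2.0, 2.5, 3.0, 3.5)
  rachis_hi <- c(2.0, 2.5, 3.0, 3.5, 4.3)
  grain_lo  <- c(3.5, 3.1, 2.6, 2.1, 1.4)
  grain_hi  <- c(4.2, 3.5, 3.1, 2.6, 2.1)
  rl <- draw_level() + 1L
  gl <- draw_level() + 1L
  trait_table(tibble(
    variety_id = truth$variety_id,
    glume_hair = draw_level(),
    phenol_reaction = draw_level(),
    rachis_cm = runif(n, rachis_lo[rl] + 1e-6, rachis_hi[rl] - 1e-6),
    glume_color = draw_level(),
    leaf_hair = draw_level(),
    grain_lw = runif(n, grain_lo[gl] + 1e-6, grain_hi[gl] - 1e-6)
  ))
}
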