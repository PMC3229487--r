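#' Draw a marker subset, at random or stratified across the genome
#'
#' Random sampling draws uniformly without replacement over all loci.
#' Stratified sampling spreads the picks evenly across the genome:
#' per-chromosome quotas proportional to chromosome locus counts
#' (largest-remainder rounding), then within each chromosome the loci
#' closest to evenly spaced target positions along the chromosome are
#' chosen greedily on the sorted cM positions; residual choices (quota
#' remainders and distance ties) are randomised by the seed.
#'
#' @param map A [genetic_map].
#' @param n Subset size (1 <= n <= number of loci).
#' @param strategy `"random"` or `"stratified"`.
#' @param seed Integer seed.
#' @return Character vector of `n` locus ids.
#' @export
subsample_markers <- function(map, n, strategy = c("random", "stratified"),
                              seed = 1L) {
  strategy <- match.arg(strategy)
  map <- as_tibble(map)
  total <- nrow(map)
  if (n < 1L || n > total) abort(paste0("n must be in 1..", total))
  set.seed(seed)
  if (strategy == "random") {
    return(sample(map$locus, n))
  }
  counts <- count(map, .data$chr)
  quota_raw <- n * counts$n / total
  quota <- floor(quota_raw)
  remainder <- n - sum(quota)
  if (remainder > 0L) {
    frac <- quota_raw - quota
    # largest remainders win; ties randomised by the seed
    order_idx <- order(frac, runif(length(frac)), decreasing = TRUE)
    quota[order_idx[seq_len(remainder)]] <- quota[order_idx[seq_len(remainder)]] + 1L
  }
  quota <- pmin(quota, counts$n)
  short <- n - sum(quota)
  while (short > 0L) {                       # capped chromosomes spill over
    room <- which(quota < counts$n)
    add <- room[order(runif(length(room)))][seq_len(min(short, length(room)))]
    quota[add] <- quota[add] + 1L
    short <- n - sum(quota)
  }
  unlist(purrr::map2(counts$chr, quota, function(cc, k) {
    if (k == 0L) return(character())
    mc <- arrange(filter(map, .data$chr == cc), .data$pos_cm)
    if (k >= nrow(mc)) return(mc$locus)
    # evenly spaced targets with a seed-randomised phase, then greedy
    # nearest-locus matching on the sorted positions; the random phase keeps
    # repetitions exchangeable while preserving even genome coverage
    lo <- min(mc$pos_cm); hi <- max(mc$pos_cm)
    s <- (hi - lo) / k
    targets <- lo + s * (runif(1) + seq_len(k) - 1)
    picked <- integer(0)
    for (ti in sample.int(length(targets))) { # randomised target order
      avail <- setdiff(seq_len(nrow(mc)), picked)
      d <- abs(mc$pos_cm[avail] - targets[ti])
      best <- avail[d == min(d)]
      picked <- c(picked, if (length(best) > 1L) best[sample.int(length(best), 1L)] else best)
    }
    mc$locus[sort(picked)]
  }), use.names = FALSE)
}

#' Marker-number sufficiency curves
#'
#' How many markers are enough? For each subset size on the grid and each
#' sampling strategy, over seeded repetitions: a marker subset is drawn,
#' the mixture clustering is refitted on it, and the assignment is compared
#' (via [correspondence()]) to the reference assignment from the full
#' marker set; the variety-pairwise MRD is recomputed on the subset and the
#' per-pair coefficient of variation across repetitions (population SD over
#' mean, pairs with zero mean excluded) is averaged over pairs. The plateau
#' size is the smallest grid size whose mean correspondence reaches 0.95.
#'
#' @param panel An [ssr_panel].
#' @param map A [genetic_map] covering the panel.
#' @param grid Subset sizes; sizes beyond the locus count are dropped with
#'   a warning.
#' @param reps Repetitions per size and strategy.
#' @param strategies Subset of `c("random", "stratified")`.
#' @param n_pcs Principal components fed to the mixture fit.
#' @param K_range Subgroup numbers examined per refit.
#' @param seed Master seed; per-repetition seeds are derived
#'   deterministically, so curves are reproducible bit for bit.
#' @param plateau_threshold Mean correspondence defining the plateau.
#' @return A `sufficiency_curves` object: list with `curves` (tibble
#'   `strategy`, `size`, `mean_correspondence`, `se_correspondence`,
#'   `mean_cv`), `plateau` (named per strategy), `reference` labels, and
#'   the call settings.
#' @export
sufficiency_curves <- function(panel, map, grid = seq(12L, 274L, by = 12L),
                               reps = 100L,
                               strategies = c("random", "stratified"),
                               n_pcs = 10L, K_range = 1:5, seed = 1L,
                               plateau_threshold = 0.95) {
  loci <- panel_loci(panel)
  if (any(grid > length(loci))) {
    warn("grid truncated to the number of loci")
    grid <- grid[grid <= length(loci)]
  }
  grid <- sort(unique(grid))
  encoded <- encode_panel(panel)
  col_locus <- attr(encoded, "locus")
  raw <- encode_panel(panel, impute = FALSE)
  fit_labels <- function(x) {
    sc <- pca_panel(x, n_components = min(n_pcs, nrow(x) - 1L))
    fit <- fit_mixture(sc, K_range = K_range)
    assign_membership(fit$membership, rule = "max")
  }
  reference <- fit_labels(encoded)

  run_one <- function(strategy, size, rep_seed) {
    sub <- subsample_markers(map, size, strategy = strategy, seed = rep_seed)
    cols <- col_locus %in% sub
    labs <- fit_labels(encoded[, cols, drop = FALSE])
    dm <- mrd_matrix(raw, loci = sub)
    list(corr = correspondence(reference, labs),
         mrd = dm[lower.tri(dm)])
  }

  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max,
                                 length(grid) * reps),
                      nrow = reps)
  curves <- purrr::map_dfr(strategies, function(strategy) {
    purrr::map_dfr(seq_along(grid), function(gi) {
      size <- grid[gi]
      runs <- purrr::map(seq_len(reps), function(r) {
        run_one(strategy, size, rep_seeds[r, gi])
      })
      corr <- purrr::map_dbl(runs, "corr")
      mrds <- do.call(cbind, purrr::map(runs, "mrd"))  # pairs x reps
      mu <- rowMeans(mrds, na.rm = TRUE)
      pop_sd <- sqrt(pmax(rowMeans(mrds^2, na.rm = TRUE) - mu^2, 0))
      cv <- (pop_sd / mu)[mu > 0]
      tibble(strategy = strategy, size = size,
             mean_correspondence = mean(corr),
             se_correspondence = sd(corr) / sqrt(length(corr)),
             mean_cv = mean(cv, na.rm = TRUE))
    })
  })
  plateau <- purrr::map_dbl(setNames(strategies, strategies), function(s) {
    cs <- filter(curves, .data$strategy == s)
    hit <- cs$size[cs$mean_correspondence >= plateau_threshold]
    if (length(hit)) min(hit) else NA_real_
  })
  structure(list(curves = curves, plateau = plateau, reference = reference,
                 grid = grid, reps = reps, seed = seed,
                 plateau_threshold = plateau_threshold),
            class = "sufficiency_curves")
}

#' @export
print.sufficiency_curves <- function(x, ...) {
  cat("<sufficiency_curves> ", x$reps, " reps, sizes ",
      min(x$grid), "-", max(x$grid), "\n", sep = "")
  cat("  plateau (corr >= ", x$plateau_threshold, "): ",
      paste(names(x$plateau), "=", x$plateau, collapse = ", "), "\n", sep = "")
  print(x$curves)
  invisible(x)
}
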