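mixture_families <- c(spherical_equal = "EII", spherical_varying = "VII",
                      diagonal_equal = "EEI", diagonal_varying = "VVI",
                      full_shared = "EEE", full_varying = "VVV")

# Accept an encoded matrix, an ordination, or a tibble with variety_id.
as_feature_matrix <- function(x) {
  if (inherits(x, "panel_ordination")) x <- x$scores
  if (is.data.frame(x)) {
    ids <- if ("variety_id" %in% names(x)) x$variety_id else NULL
    m <- as.matrix(x[setdiff(names(x), "variety_id")])
    rownames(m) <- ids %||% rownames(m)
    return(m)
  }
  as.matrix(x)
}

#' Gaussian-mixture clustering with BIC model selection
#'
#' Fits Gaussian mixtures by expectation-maximisation for every number of
#' subgroups in `K_range` and every covariance family, and selects the pair
#' maximising the Bayesian information criterion in its larger-is-better
#' form (`2*loglik - n_params*log(n)`). Families are the MCLUST models:
#' spherical equal/varying volume (EII/VII), diagonal (EEI/VVI) and full
#' covariance shared/varying (EEE/VVV). Fits that fail (singular
#' covariance) are recorded as `NA` in the BIC table and skipped; if every
#' fit fails, an error is raised.
#'
#' High-dimensional genotype encodings should be reduced first (e.g. the
#' top principal components via [pca_panel()]); with n of order 150 and a
#' ~1000-column allele space, full-covariance families are otherwise
#' singular.
#'
#' @param x A features-by-variety input: `panel_ordination`, tibble with
#'   `variety_id`, or numeric matrix with rownames.
#' @param K_range Numbers of subgroups to examine (default 1-30).
#' @param families Covariance families (MCLUST model names).
#' @return A `mixture_fit` object: list with `membership` (tibble of
#'   `variety_id`, one probability column per subgroup, `label`,
#'   `max_prob`), `bic` (tibble K x family), `K`, `family`, `loglik`,
#'   `n`, and the underlying `mclust` model.
#' @export
fit_mixture <- function(x, K_range = 1:30, families = unname(mixture_families)) {
  x <- as_feature_matrix(x)
  if (nrow(x) < max(K_range)) {
    abort("need at least max(K_range) varieties")
  }
  if (ncol(x) == 1L) {
    # univariate data: the covariance families collapse to equal/varying
    families <- unique(ifelse(grepl("^E", families), "E", "V"))
  }
  mclustBIC <- mclust::mclustBIC   # Mclust() resolves this in the caller frame
  fit <- suppressWarnings(
    mclust::Mclust(x, G = K_range, modelNames = families, verbose = FALSE)
  )
  if (is.null(fit)) abort("all mixture fits failed")
  bm <- fit$BIC
  bm <- matrix(as.numeric(bm), nrow = nrow(bm), dimnames = dimnames(bm))
  bic_tbl <- as_tibble(bm, rownames = "K") |>
    mutate(K = as.integer(.data$K)) |>
    tidyr::pivot_longer(-"K", names_to = "family", values_to = "bic")
  z <- fit$z
  if (is.null(z)) z <- matrix(1, nrow(x), 1L)
  colnames(z) <- paste0("SG", seq_len(ncol(z)))
  membership <- tibble(variety_id = rownames(x) %||% paste0("V", seq_len(nrow(x))),
                       as_tibble(z)) |>
    mutate(label = colnames(z)[max.col(z, ties.method = "first")],
           max_prob = apply(z, 1L, max))
  structure(list(membership = membership, bic = bic_tbl,
                 K = fit$G, family = fit$modelName,
                 loglik = fit$loglik, n = nrow(x), model = fit),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit> K = ", x$K, " (", x$family, "), n = ", x$n,
      ", loglik = ", round(x$loglik, 2), "\n", sep = "")
  invisible(x)
}

#' Replicated mixture log-likelihoods across K
#'
#' Runs EM from seeded random soft initialisations, several replicates per
#' K, and records the converged log-likelihood of each run — the replicated
#' L(K) series consumed by [delta_k()]. Replicate-to-run variation comes
#' from EM converging from different starting partitions.
#'
#' @param x Features (as in [fit_mixture()]).
#' @param K_range Consecutive K values (need >= 3 for a ΔK curve).
#' @param n_reps Replicates per K (>= 2).
#' @param family Covariance family used for the runs.
#' @param seed Integer seed.
#' @return A tibble with columns `K`, `replicate`, `loglik`.
#' @export
mixture_runs <- function(x, K_range = 1:5, n_reps = 3L, family = "VVI",
                         seed = 1L) {
  x <- as_feature_matrix(x)
  set.seed(seed)
  n <- nrow(x)
  em_fun <- getExportedValue("mclust", paste0("me", family))
  purrr::map_dfr(K_range, function(K) {
    purrr::map_dfr(seq_len(n_reps), function(r) {
      if (K == 1L) {
        z <- matrix(1, n, 1L)
      } else {
        z <- matrix(rgamma(n * K, shape = 1), n, K)
        z <- z / rowSums(z)
      }
      ll <- tryCatch({
        em <- em_fun(data = x, z = z)
        em$loglik
      }, error = function(e) NA_real_)
      tibble(K = K, replicate = r, loglik = ll)
    })
  })
}

#' Evanno's delta-K statistic
#'
#' The second-difference statistic for picking the number of subgroups from
#' replicated clustering log-likelihoods:
#' `ΔK = mean_runs |L(K+1) - 2 L(K) + L(K-1)| / sd_runs L(K)`,
#' defined for interior K with positive run-to-run standard deviation.
#' Accepts any (K, replicate, loglik) table — including log-likelihood
#' series produced by external admixture software — so the formula is the
#' sole contract.
#'
#' @param runs Tibble with columns `K`, `replicate`, `loglik` (>= 3
#'   consecutive K values, >= 2 replicates per K).
#' @return A `delta_k` object: list with `curve` (tibble `K`,
#'   `mean_loglik`, `sd_loglik`, `delta_k`; `NA` where sd = 0, flagged in
#'   `undefined`) and `K_hat`, the arg-max over defined interior K.
#' @export
delta_k <- function(runs) {
  runs <- as_tibble(runs)
  stopifnot(all(c("K", "replicate", "loglik") %in% names(runs)))
  ks <- sort(unique(runs$K))
  if (length(ks) < 3L || !all(diff(ks) == 1L)) {
    abort("delta_k needs >= 3 consecutive K values")
  }
  if (any(table(runs$K) < 2L)) abort("delta_k needs >= 2 replicates per K")
  wide <- runs |>
    select("K", "replicate", "loglik") |>
    tidyr::pivot_wider(names_from = "K", values_from = "loglik")
  curve <- purrr::map_dfr(ks, function(K) {
    lk <- runs$loglik[runs$K == K]
    dk <- NA_real_
    if (K > min(ks) && K < max(ks)) {
      l_prev <- wide[[as.character(K - 1L)]]
      l_here <- wide[[as.character(K)]]
      l_next <- wide[[as.character(K + 1L)]]
      second <- abs(l_next - 2 * l_here + l_prev)
      s <- sd(lk)
      dk <- if (is.na(s) || s == 0) NA_real_ else mean(second, na.rm = TRUE) / s
    }
    tibble(K = K, mean_loglik = mean(lk), sd_loglik = sd(lk), delta_k = dk)
  })
  interior <- filter(curve, !is.na(.data$delta_k))
  undefined <- filter(curve, .data$K > min(ks), .data$K < max(ks),
                      is.na(.data$delta_k))$K
  K_hat <- if (nrow(interior)) interior$K[which.max(interior$delta_k)] else NA_integer_
  structure(list(curve = curve, K_hat = K_hat, undefined = undefined),
            class = "delta_k")
}

#' @export
print.delta_k <- function(x, ...) {
  cat("<delta_k> K_hat =", x$K_hat, "\n")
  print(x$curve)
  invisible(x)
}

#' Assign varieties to subgroups from membership probabilities
#'
#' Under the `threshold` rule (published cutoff 0.80, inclusive: a maximum
#' membership of exactly 0.80 assigns), a variety whose maximum membership
#' probability falls below the threshold is retained in the admixed group
#' `"AD"`. Under the `max` rule the arg-max label is always assigned and
#' the admixed set is empty. Arg-max ties break toward the lowest subgroup
#' index and are reported via a message.
#'
#' @param memberships Tibble with `variety_id` and one numeric probability
#'   column per subgroup (rows summing to 1), e.g. the `membership` field
#'   of a [fit_mixture()].
#' @param rule `"threshold"` or `"max"`.
#' @param threshold Membership cutoff for the threshold rule.
#' @return A tibble with `variety_id`, `label` and logical `admixed`.
#' @export
assign_membership <- function(memberships, rule = c("threshold", "max"),
                              threshold = 0.80) {
  rule <- match.arg(rule)
  if (inherits(memberships, "mixture_fit")) memberships <- memberships$membership
  memberships <- as_tibble(memberships)
  prob_cols <- names(memberships)[vapply(memberships, is.numeric, TRUE)]
  prob_cols <- setdiff(prob_cols, c("max_prob", "cheng_index"))
  z <- as.matrix(memberships[prob_cols])
  if (any(abs(rowSums(z) - 1) > 1e-6)) abort("membership rows must sum to 1")
  best <- max.col(z, ties.method = "first")
  mx <- z[cbind(seq_len(nrow(z)), best)]
  ties <- rowSums(z == mx) > 1L
  if (any(ties)) {
    inform(paste0("argmax tie for ", sum(ties),
                  " varieties broken toward the lowest subgroup index"))
  }
  label <- prob_cols[best]
  admixed <- rule == "threshold" & mx < threshold
  label[admixed] <- "AD"
  tibble(variety_id = memberships$variety_id, label = label, admixed = admixed)
}

#' Correspondence between two assignments
#'
#' The maximum achievable fraction of varieties on which two labelings
#' agree, over all injective relabelings of the smaller label alphabet into
#' the larger (optimal assignment on the confusion matrix; unmatched labels
#' count as disagreement). The admixed label is treated as a label of its
#' own. Invariant to label permutations.
#'
#' @param labels_a,labels_b Named character vectors (names = variety ids)
#'   or tibbles with `variety_id` and `label`; must cover a common variety
#'   set.
#' @return The agreement fraction in `[0, 1]`.
#' @export
correspondence <- function(labels_a, labels_b) {
  a <- as_labels(labels_a)
  b <- as_labels(labels_b)
  common <- intersect(names(a), names(b))
  if (length(common) == 0L) abort("assignments share no varieties")
  a <- a[common]; b <- b[common]
  conf <- table(a, b)
  if (nrow(conf) > ncol(conf)) conf <- t(conf)
  best_assignment_score(unclass(conf)) / length(common)
}

as_labels <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("variety_id", "label") %in% names(x)))
    return(setNames(as.character(x$label), as.character(x$variety_id)))
  }
  if (is.null(names(x))) names(x) <- paste0("V", seq_along(x))
  setNames(as.character(x), names(x))
}

# Exact maximum-agreement injective matching by bitmask dynamic programming
# over columns (rows <= cols guaranteed by the caller).
best_assignment_score <- function(conf) {
  nr <- nrow(conf); nc <- ncol(conf)
  if (nc > 20L) abort("too many labels for exact matching")
  n_states <- bitwShiftL(1L, nc)
  dp <- rep(-Inf, n_states)
  dp[1L] <- 0
  for (i in seq_len(nr)) {
    ndp <- rep(-Inf, n_states)
    for (s in which(dp > -Inf) - 1L) {
      for (j in seq_len(nc)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(s, bit) == 0L) {
          t <- bitwOr(s, bit) + 1L
          cand <- dp[s + 1L] + conf[i, j]
          if (cand > ndp[t]) ndp[t] <- cand
        }
      }
    }
    dp <- ndp
  }
  max(dp)
}
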