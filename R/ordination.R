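#' Principal component analysis of a genotype panel
#'
#' Column-centred PCA of the within-variety allele-frequency encoding
#' ([encode_panel()]), the standard marker-based ordination for revealing
#' population structure. Variance proportions are eigenvalues over the
#' total variance, non-increasing and summing to at most 1.
#'
#' @param panel An [ssr_panel] or an encoded matrix.
#' @param n_components Number of axes to return; truncated to the matrix
#'   rank with a warning if larger.
#' @return A `panel_ordination` object: list with `scores` (tibble of
#'   `variety_id` and axis coordinates), `prop_var` and `method`.
#' @export
pca_panel <- function(panel, n_components = 10L) {
  x <- if (inherits(panel, "ssr_panel")) encode_panel(panel) else as.matrix(panel)
  if (nrow(x) < 2L) abort("PCA needs at least 2 varieties")
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  rank <- sum(ev > max(ev) * 1e-12)
  if (n_components > rank) {
    warn(paste0("n_components reduced to rank ", rank))
    n_components <- rank
  }
  k <- seq_len(n_components)
  sc <- fit$x[, k, drop = FALSE]
  if (length(k)) colnames(sc) <- paste0("PC", k)
  scores <- as_tibble(sc, .name_repair = "minimal")
  new_ordination(tibble(variety_id = rownames(x), scores),
                 prop_var = ev[k] / sum(ev), method = "pca")
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical metric MDS: Gower double-centring of the squared distances
#' followed by eigendecomposition, as used on variety-pairwise MRD
#' matrices. Negative eigenvalues are reported but never used for
#' coordinates; MRD matrices are Euclidean-embeddable so theirs stay at
#' numerical zero.
#'
#' @param d A symmetric matrix (or `dist`) with zero diagonal.
#' @param n_axes Number of coordinate axes.
#' @return A `panel_ordination` with an extra `eigenvalues` field (all of
#'   them, including any negative ones).
#' @export
pcoa <- function(d, n_axes = 2L) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) abort("distance matrix must be symmetric")
  ids <- rownames(d) %||% paste0("V", seq_len(nrow(d)))
  fit <- cmdscale(as.dist(d), k = min(n_axes, nrow(d) - 1L), eig = TRUE)
  pos <- fit$eig[fit$eig > 0]
  k <- seq_len(ncol(fit$points))
  pts <- fit$points
  colnames(pts) <- paste0("PCo", k)
  scores <- as_tibble(pts)
  out <- new_ordination(tibble(variety_id = ids, scores),
                        prop_var = fit$eig[k] / sum(pos), method = "pcoa")
  out$eigenvalues <- fit$eig
  out
}

#' Laplacian embedding of a genotype panel
#'
#' Builds a similarity graph on varieties: edge weight equals the Pearson
#' correlation between two varieties' encoded rows when it reaches the
#' threshold `eps`, else no edge. Eigenvectors of the smallest nonzero
#' eigenvalues of the symmetric normalised Laplacian (the "lapvectors")
#' reveal cluster structure; disconnected blocks separate exactly.
#' Isolated varieties are kept with a unit self-loop and reported with a
#' warning. The variance proportion of a lapvector is the share of the
#' centred encoding's variance explained by projecting onto it.
#'
#' @param panel An [ssr_panel] or encoded matrix.
#' @param eps Correlation threshold in (0, 1] (published setting 0.8).
#' @param n_axes Number of lapvectors.
#' @return A `panel_ordination` with fields `eigenvalues` (Laplacian
#'   spectrum) and `n_isolated`.
#' @export
laplacian_embed <- function(panel, eps = 0.8, n_axes = 2L) {
  stopifnot(eps > 0, eps <= 1)
  x <- if (inherits(panel, "ssr_panel")) encode_panel(panel) else as.matrix(panel)
  n <- nrow(x)
  w <- stats::cor(t(x))
  w[w < eps] <- 0
  diag(w) <- 0
  isolated <- which(rowSums(w) == 0)
  if (length(isolated)) {
    warn(paste0(length(isolated), " isolated varieties kept with self-loops"))
    diag(w)[isolated] <- 1
  }
  dg <- rowSums(w)
  inv_sqrt <- 1 / sqrt(dg)
  lap <- diag(n) - (inv_sqrt * w) * rep(inv_sqrt, each = n)
  es <- eigen((lap + t(lap)) / 2, symmetric = TRUE)
  ev <- rev(es$values)                      # ascending
  vec <- es$vectors[, rev(seq_len(n)), drop = FALSE]
  # drop the trivial leading eigenvector; for a disconnected graph the next
  # (numerically zero) eigenvalues carry the component-indicator vectors
  k <- seq(2L, min(n, 1L + n_axes))
  lv <- vec[, k, drop = FALSE]
  colnames(lv) <- paste0("Lap", seq_along(k))
  scores <- as_tibble(lv)
  xc <- scale(x, center = TRUE, scale = FALSE)
  total_ss <- sum(xc^2)
  prop <- purrr::map_dbl(seq_along(k), function(i) {
    v <- vec[, k[i]]
    sum(crossprod(xc, v)^2) / (sum(v^2) * total_ss)
  })
  out <- new_ordination(tibble(variety_id = rownames(x) %||% paste0("V", 1:n),
                               scores),
                        prop_var = prop, method = "laplacian")
  out$eigenvalues <- ev
  out$n_isolated <- length(isolated)
  out
}

new_ordination <- function(scores, prop_var, method) {
  structure(list(scores = scores, prop_var = prop_var, method = method),
            class = "panel_ordination")
}

#' @export
print.panel_ordination <- function(x, ...) {
  cat("<panel_ordination: ", x$method, "> ", nrow(x$scores), " varieties, ",
      length(x$prop_var), " axes\n", sep = "")
  cat("  variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$prop_var), collapse = ", "), "\n")
  invisible(x)
}
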