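#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor-joining agglomeration of a symmetric,
#' zero-diagonal distance matrix (typically the variety-pairwise MRD from
#' [mrd_matrix()]). Negative branch lengths, which NJ can produce on
#' non-additive matrices, are clamped to zero with the deficit transferred
#' to the sister branch so path lengths through the parent are preserved.
#' The unrooted tree is serialised as Newick text.
#'
#' @param d Symmetric matrix or `dist` with at least 3 taxa.
#' @return An `nj_result`: list with `phylo` (an \pkg{ape} tree) and
#'   `newick` (the serialisation).
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) < 3L) abort("neighbor-joining needs >= 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8)) abort("distance matrix must be symmetric")
  if (is.null(rownames(d))) {
    dimnames(d) <- list(paste0("V", seq_len(nrow(d))), paste0("V", seq_len(nrow(d))))
  }
  tree <- ape::nj(as.dist(d))
  tree <- clamp_negative_branches(tree)
  structure(list(phylo = tree, newick = ape::write.tree(tree)),
            class = "nj_result")
}

# Zero out negative edges, adding each deficit to the sister edge (the other
# edge sharing the same parent node), per common NJ practice.
clamp_negative_branches <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0L) break
    e <- neg[1L]
    parent <- tree$edge[e, 1L]
    sisters <- setdiff(which(tree$edge[, 1L] == parent), e)
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sisters)) {
      tree$edge.length[sisters[1L]] <- tree$edge.length[sisters[1L]] + deficit
    }
  }
  tree
}

#' @export
print.nj_result <- function(x, ...) {
  cat("<nj_result> ", length(x$phylo$tip.label), " tips\n", sep = "")
  cat(substr(x$newick, 1L, 200L), "\n")
  invisible(x)
}

#' Ward clustering of Cheng trait scores
#'
#' Agglomerative clustering with Ward linkage on the seven-column matrix of
#' the six Cheng trait scores plus the index, the morphology-based
#' counterpart of the marker clustering. Merge heights are non-decreasing;
#' a cut yields flat subgroup labels.
#'
#' @param scores Output of [cheng_classify()] (six score columns plus
#'   `cheng_index`).
#' @param k Number of clusters for the flat cut.
#' @return A `ward_clustering`: list with `hclust`, `labels` (tibble
#'   `variety_id`, `cluster`) and `heights`.
#' @export
ward_cluster <- function(scores, k = 2L) {
  scores <- as_tibble(scores)
  cols <- c("glume_hair", "phenol_reaction", "rachis_internode",
            "glume_color", "leaf_hair", "grain_lw", "cheng_index")
  if (!all(cols %in% names(scores))) {
    if (!"cheng_index" %in% names(scores)) scores <- cheng_classify(scores)
    cols <- intersect(cols, names(scores))
    if (length(cols) != 7L) abort("scores must contain the six traits and cheng_index")
  }
  x <- as.matrix(scores[cols])
  rownames(x) <- scores$variety_id
  if (nrow(x) < 2L) abort("need >= 2 varieties")
  hc <- hclust(dist(x), method = "ward.D2")
  labels <- tibble(variety_id = scores$variety_id,
                   cluster = unname(cutree(hc, k = k)))
  structure(list(hclust = hc, labels = labels, heights = hc$height, k = k),
            class = "ward_clustering")
}

#' @export
print.ward_clustering <- function(x, ...) {
  cat("<ward_clustering> ", nrow(x$labels), " varieties, cut at k = ", x$k,
      "\n", sep = "")
  print(count(x$labels, .data$cluster))
  invisible(x)
}
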