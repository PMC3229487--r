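#' Encode a panel as within-variety allele frequencies
#'
#' Builds the varieties x alleles matrix used by the ordinations and the
#' mixture clustering: one column per (locus, allele), with the
#' within-variety frequency of that allele — 1 for a homozygote, 0.5/0.5
#' for a heterozygote, 0 otherwise — so each variety's row sums to 1 within
#' every locus's column block. A missing call leaves the block undefined;
#' with `impute = TRUE` (the default) it is filled with the locus's
#' panel-wide mean frequencies so the matrix is complete for ordination and
#' clustering, and the flag is retained in the `missing` attribute.
#'
#' @param panel An [ssr_panel].
#' @param impute Mean-fill missing locus blocks? If `FALSE` they are `NA`.
#' @return A numeric matrix with variety ids as rownames and
#'   `"locus@allele"` colnames; attributes `locus` (the locus of each
#'   column), `allele` (bp size of each column) and `missing` (varieties x
#'   loci logical matrix of missing calls).
#' @export
encode_panel <- function(panel, impute = TRUE) {
  al <- panel_alleles(panel)
  loci <- panel_loci(panel)
  n <- nrow(panel)
  blocks <- purrr::map(seq_along(loci), function(j) {
    sizes <- sort(unique(c(al$a1[, j], al$a2[, j])))
    block <- matrix(0, n, length(sizes))
    i1 <- match(al$a1[, j], sizes)
    i2 <- match(al$a2[, j], sizes)
    ok <- which(!is.na(i1))
    block[cbind(ok, i1[ok])] <- block[cbind(ok, i1[ok])] + 0.5
    block[cbind(ok, i2[ok])] <- block[cbind(ok, i2[ok])] + 0.5
    block[is.na(i1), ] <- NA_real_
    colnames(block) <- paste0(loci[j], "@", sizes)
    block
  })
  x <- do.call(cbind, blocks)
  rownames(x) <- panel$variety_id
  missing <- is.na(al$a1)
  if (impute && any(missing)) {
    for (j in which(colSums(missing) > 0L)) {
      cols <- which(attr_locus(x, loci) == loci[j])
      mu <- colMeans(x[, cols, drop = FALSE], na.rm = TRUE)
      bad <- which(missing[, j])
      x[bad, cols] <- rep(mu, each = length(bad))
    }
  }
  structure(x,
            locus = sub("@.*$", "", colnames(x)),
            allele = as.integer(sub("^.*@", "", colnames(x))),
            missing = missing)
}

attr_locus <- function(x, loci) sub("@.*$", "", colnames(x))

#' Pairwise modified Rogers distance between varieties
#'
#' The variety-by-variety MRD matrix, treating each variety's diploid call
#' as a frequency vector (0 / 0.5 / 1 per allele). Missing data are handled
#' pairwise: each pair is averaged over the loci where both varieties have
#' calls.
#'
#' @param panel An [ssr_panel], or a matrix from `encode_panel(..., impute
#'   = FALSE)`.
#' @param loci Optional subset of loci to use.
#' @return A symmetric numeric matrix with zero diagonal and variety ids as
#'   dimnames.
#' @export
mrd_matrix <- function(panel, loci = NULL) {
  x <- if (inherits(panel, "ssr_panel")) encode_panel(panel, impute = FALSE) else panel
  col_locus <- attr(x, "locus")
  miss <- attr(x, "missing")
  if (!is.null(loci)) {
    keep <- col_locus %in% loci
    x <- x[, keep, drop = FALSE]
    col_locus <- col_locus[keep]
    miss <- miss[, colnames(miss) %in% loci, drop = FALSE]
  }
  # allele-level availability mask; squared differences restricted to loci
  # observed in both members of a pair
  wa <- 1 - miss[, match(col_locus, colnames(miss)), drop = FALSE]
  x0 <- x
  x0[is.na(x0)] <- 0
  sq <- x0^2
  cross <- tcrossprod(x0)
  d2 <- tcrossprod(sq, wa) + tcrossprod(wa, sq) - 2 * cross
  mloc <- tcrossprod(1 - miss)          # shared locus counts
  d <- sqrt(pmax(d2, 0) / (2 * mloc))
  d[mloc == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}
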