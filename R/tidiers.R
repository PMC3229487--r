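#' Tidy and glance methods
#'
#' Broom-style accessors for the package's fitted objects: `tidy()` returns
#' the per-component table, `glance()` a one-row model summary.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name ssrpop-tidiers
NULL

#' @rdname ssrpop-tidiers
#' @export
tidy.mixture_fit <- function(x, ...) x$bic

#' @rdname ssrpop-tidiers
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(K = x$K, family = x$family, loglik = x$loglik,
         bic = max(x$bic$bic, na.rm = TRUE), n = x$n)
}

#' @rdname ssrpop-tidiers
#' @export
tidy.diversity_scan <- function(x, ...) x$per_locus

#' @rdname ssrpop-tidiers
#' @export
glance.diversity_scan <- function(x, ...) {
  tibble(n_loci = length(unique(x$per_locus$locus)),
         n_groups = nrow(x$group_summary),
         overall_mrd = x$overall_mrd, gst = x$gst,
         n_bootstrap = x$n_bootstrap)
}

#' @rdname ssrpop-tidiers
#' @export
tidy.delta_k <- function(x, ...) x$curve

#' @rdname ssrpop-tidiers
#' @export
glance.delta_k <- function(x, ...) {
  tibble(K_hat = x$K_hat, n_undefined = length(x$undefined))
}

#' @rdname ssrpop-tidiers
#' @export
tidy.ld_summary <- function(x, ...) x$summary

#' @rdname ssrpop-tidiers
#' @export
tidy.ld_decay <- function(x, ...) x$curve

#' @rdname ssrpop-tidiers
#' @export
glance.ld_decay <- function(x, ...) {
  tibble(threshold = x$threshold, decay_cm = x$decay_cm,
         window = x$window, step = x$step)
}

#' @rdname ssrpop-tidiers
#' @export
tidy.sufficiency_curves <- function(x, ...) x$curves

#' @rdname ssrpop-tidiers
#' @export
tidy.panel_ordination <- function(x, ...) x$scores

#' @rdname ssrpop-tidiers
#' @export
glance.panel_ordination <- function(x, ...) {
  tibble(method = x$method, n = nrow(x$scores),
         axis1_var = x$prop_var[1L],
         axis2_var = if (length(x$prop_var) > 1L) x$prop_var[2L] else NA_real_)
}
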