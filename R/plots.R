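#' Plot methods
#'
#' `autoplot()` methods give a quick ggplot for each result type:
#' ordination scatter, membership bar chart, delta-K curve, genome scan,
#' sufficiency curves and LD decay.
#'
#' @param object A result object.
#' @param labels Optional tibble (`variety_id`, `label`) or named vector
#'   used to colour varieties.
#' @param ... Unused.
#' @return A ggplot object.
#' @name ssrpop-plots
NULL

#' @rdname ssrpop-plots
#' @export
autoplot.panel_ordination <- function(object, labels = NULL, ...) {
  sc <- object$scores
  axes <- setdiff(names(sc), "variety_id")[1:2]
  if (!is.null(labels)) {
    lab <- as_labels(labels)
    sc$label <- unname(lab[sc$variety_id])
  }
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data[[axes[1L]]], .data[[axes[2L]]])) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", axes[1L], 100 * object$prop_var[1L]),
      y = sprintf("%s (%.1f%%)", axes[2L], 100 * object$prop_var[2L])) +
    ggplot2::theme_minimal()
  if (is.null(labels)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$label))
}

#' @rdname ssrpop-plots
#' @export
autoplot.mixture_fit <- function(object, ...) {
  mem <- object$membership
  prob_cols <- grep("^SG", names(mem), value = TRUE)
  long <- tidyr::pivot_longer(mem[c("variety_id", prob_cols)], -"variety_id",
                              names_to = "subgroup", values_to = "probability")
  long$variety_id <- factor(long$variety_id,
                            levels = mem$variety_id[order(mem$label, -mem$max_prob)])
  ggplot2::ggplot(long, ggplot2::aes(.data$variety_id, .data$probability,
                                     fill = .data$subgroup)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "membership probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @rdname ssrpop-plots
#' @export
autoplot.delta_k <- function(object, ...) {
  ggplot2::ggplot(filter(object$curve, !is.na(.data$delta_k)),
                  ggplot2::aes(.data$K, .data$delta_k)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(y = expression(Delta * K)) +
    ggplot2::theme_minimal()
}

#' @rdname ssrpop-plots
#' @param map Optional [genetic_map] to order loci along the genome.
#' @export
autoplot.diversity_scan <- function(object, map = NULL, ...) {
  pl <- object$per_locus
  if (!is.null(map)) {
    pl <- left_join(pl, as_tibble(map), by = "locus") |>
      arrange(.data$chr, .data$pos_cm)
    pl$x <- match(pl$locus, unique(pl$locus))
  } else {
    pl$x <- match(pl$locus, unique(pl$locus))
  }
  ggplot2::ggplot(pl, ggplot2::aes(.data$x, .data$gene_diversity,
                                   colour = .data$group)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$gene_diversity - .data$se,
                                      ymax = .data$gene_diversity + .data$se,
                                      fill = .data$group),
                         alpha = 0.2, colour = NA) +
    ggplot2::labs(x = "locus (map order)", y = "gene diversity") +
    ggplot2::theme_minimal()
}

#' @rdname ssrpop-plots
#' @export
autoplot.sufficiency_curves <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(.data$size, .data$mean_correspondence,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_correspondence - .data$se_correspondence,
      ymax = .data$mean_correspondence + .data$se_correspondence)) +
    ggplot2::geom_hline(yintercept = object$plateau_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "number of markers", y = "correspondence to full set") +
    ggplot2::theme_minimal()
}

#' @rdname ssrpop-plots
#' @export
autoplot.ld_decay <- function(object, ...) {
  ggplot2::ggplot(filter(object$curve, .data$n_pairs > 0L),
                  ggplot2::aes(.data$mid, .data$mean_r2)) +
    ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "genetic distance (cM)",
                  y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}
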