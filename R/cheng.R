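#' Score the numeric Cheng traits
#'
#' Converts the two measured traits of Cheng's index to 0-4 scores. Rachis
#' internode length (cm) scores upward with length; grain length/width ratio
#' scores downward with the ratio (slender grains are indica-like). The
#' published scoring standard leaves small gaps between printed intervals
#' (e.g. rachis 2.01-2.09 cm); bins here are half-open and anchored so that
#' every printed boundary keeps its printed score, with gap values resolved
#' to the adjacent lower-magnitude bin:
#' rachis `<=2.0 -> 0`, `<=2.5 -> 1`, `<=3.0 -> 2`, `<=3.5 -> 3`, else 4;
#' grain `>3.5 -> 0`, `>=3.1 -> 1`, `>=2.6 -> 2`, `>=2.1 -> 3`, else 4.
#'
#' @param x Numeric vector of measurements (must be positive).
#' @return Integer scores in 0..4.
#' @examples
#' score_rachis_internode(c(2.3, 3.6))  # 1, 4
#' score_grain_ratio(2.3)               # 3
#' @export
score_rachis_internode <- function(x) {
  if (any(!is.finite(x) | x <= 0)) abort("rachis length must be positive")
  as.integer(findInterval(x, c(2.0, 2.5, 3.0, 3.5), left.open = TRUE))
}

#' @rdname score_rachis_internode
#' @export
score_grain_ratio <- function(x) {
  if (any(!is.finite(x) | x <= 0)) abort("grain length/width ratio must be positive")
  4L - as.integer(findInterval(x, c(2.1, 2.6, 3.1), left.open = FALSE)) -
    as.integer(x > 3.5)
}

#' Score all six Cheng traits
#'
#' Takes a [trait_table] (four pre-scored ordinal traits plus the two
#' measurements) and returns the six 0-4 scores per variety.
#'
#' @param traits A [trait_table].
#' @return A tibble with `variety_id` and integer columns `glume_hair`,
#'   `phenol_reaction`, `rachis_internode`, `glume_color`, `leaf_hair`,
#'   `grain_lw`.
#' @export
score_traits <- function(traits) {
  traits <- trait_table(traits)
  tibble(
    variety_id = traits$variety_id,
    glume_hair = traits$glume_hair,
    phenol_reaction = traits$phenol_reaction,
    rachis_internode = score_rachis_internode(traits$rachis_cm),
    glume_color = traits$glume_color,
    leaf_hair = traits$leaf_hair,
    grain_lw = score_grain_ratio(traits$grain_lw)
  )
}

cheng_levels <- c("typical-indica", "indica-clined",
                  "japonica-clined", "typical-japonica")

#' Cheng's index and indica/japonica classification
#'
#' Sums the six 0-4 trait scores into Cheng's index (0-24) and classifies
#' each variety: index <= 7 typical indica, 8-13 indica-clined, 14-17
#' japonica-clined, >= 18 typical japonica. The published ranges start at 1;
#' an all-zero score vector (index 0) is classified typical indica by
#' monotone extension.
#'
#' @param scores A data frame with `variety_id` and six score columns in
#'   0..4 (as produced by [score_traits()]).
#' @return A tibble with the six scores, `cheng_index` and `class` (ordered
#'   factor typical-indica < indica-clined < japonica-clined <
#'   typical-japonica).
#' @examples
#' cheng_classify(data.frame(variety_id = "v1", glume_hair = 4,
#'   phenol_reaction = 4, rachis_internode = 4, glume_color = 4,
#'   leaf_hair = 4, grain_lw = 4))  # index 24, typical japonica
#' @export
cheng_classify <- function(scores) {
  scores <- as_tibble(scores)
  if (!"variety_id" %in% names(scores)) abort("scores need a variety_id column")
  score_cols <- setdiff(names(scores), "variety_id")
  if (length(score_cols) != 6L) abort("exactly six trait scores are required")
  sm <- as.matrix(scores[score_cols])
  if (anyNA(sm) || !all(sm %in% 0:4)) abort("scores must be integers in 0..4")
  idx <- as.integer(rowSums(sm))
  cls <- cut(idx, breaks = c(-1L, 7L, 13L, 17L, 24L), labels = cheng_levels,
             ordered_result = TRUE)
  mutate(scores, cheng_index = idx, class = cls)
}
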