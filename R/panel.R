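#' SSR genotype panels
#'
#' An `ssr_panel` is a tibble holding diploid allele-size calls for a set of
#' varieties (rows) at a set of SSR loci (columns). The first column,
#' `variety_id`, identifies the variety; every other column is a locus whose
#' entries are strings of the form `"120/124"` (allele fragment sizes in base
#' pairs, order-insensitive), `"130"` (homozygote shorthand, expanded to
#' `130/130`), or `NA` for a missing call. Both alleles of a call are present
#' or both are missing.
#'
#' @param x A data frame with a `variety_id` column and one column per locus.
#' @return A validated `ssr_panel` tibble with calls normalised to
#'   `"a/b"` with `a <= b`.
#' @examples
#' ssr_panel(data.frame(variety_id = c("v1", "v2"),
#'                      RM1 = c("120/124", "130"),
#'                      RM2 = c("200", NA)))
#' @export
ssr_panel <- function(x) {
  x <- as_tibble(x)
  if (!"variety_id" %in% names(x)) {
    abort("panel must have a `variety_id` column")
  }
  x$variety_id <- as.character(x$variety_id)
  if (anyDuplicated(x$variety_id)) {
    dup <- unique(x$variety_id[duplicated(x$variety_id)])
    abort(paste0("duplicate variety id(s): ", paste(dup, collapse = ", ")))
  }
  loci <- setdiff(names(x), "variety_id")
  if (anyDuplicated(loci)) {
    dup <- unique(loci[duplicated(loci)])
    abort(paste0("duplicate locus id(s): ", paste(dup, collapse = ", ")))
  }
  if (length(loci) == 0L) abort("panel must contain at least one locus")
  for (loc in loci) {
    x[[loc]] <- normalise_calls(as.character(x[[loc]]), locus = loc)
    if (all(is.na(x[[loc]]))) {
      abort(paste0("locus ", loc, " has no non-missing call"))
    }
  }
  class(x) <- c("ssr_panel", class(tibble()))
  x
}

# Parse one column of call strings into canonical "a/b" (a <= b) or NA.
normalise_calls <- function(calls, locus, missing_tokens = c("NA", "-9", "")) {
  calls <- trimws(calls)
  calls[calls %in% missing_tokens | is.na(calls)] <- NA_character_
  out <- calls
  idx <- which(!is.na(calls))
  if (length(idx) == 0L) return(out)
  parts <- strsplit(calls[idx], "/", fixed = TRUE)
  bad_n <- lengths(parts) > 2L
  if (any(bad_n)) {
    abort(paste0("locus ", locus, ", row ", idx[which(bad_n)[1L]],
                 ": call has more than two alleles"))
  }
  for (j in seq_along(idx)) {
    a <- suppressWarnings(as.numeric(parts[[j]]))
    if (anyNA(a) || any(a != round(a)) || any(a <= 0)) {
      abort(paste0("locus ", locus, ", row ", idx[j],
                   ": non-integer or non-positive allele '", calls[idx[j]], "'"))
    }
    a <- as.integer(a)
    if (length(a) == 1L) a <- c(a, a)
    out[idx[j]] <- paste(sort(a), collapse = "/")
  }
  out
}

#' @export
print.ssr_panel <- function(x, ...) {
  cat("<ssr_panel> ", nrow(x), " varieties x ", ncol(x) - 1L, " loci\n", sep = "")
  NextMethod()
}

#' Panel accessors
#'
#' `panel_loci()` and `panel_varieties()` return the locus and variety
#' identifiers of an [ssr_panel]. `panel_alleles()` unpacks the call strings
#' into a pair of integer matrices (varieties x loci) holding the two allele
#' sizes of every call (`NA` where missing).
#'
#' @param panel An [ssr_panel].
#' @return Character vectors, or for `panel_alleles()` a list with integer
#'   matrices `a1` and `a2`.
#' @export
panel_loci <- function(panel) setdiff(names(panel), "variety_id")

#' @rdname panel_loci
#' @export
panel_varieties <- function(panel) panel$variety_id

#' @rdname panel_loci
#' @export
panel_alleles <- function(panel) {
  loci <- panel_loci(panel)
  m <- as.matrix(panel[loci])
  split_at <- regexpr("/", m, fixed = TRUE)
  a1 <- matrix(suppressWarnings(as.integer(substr(m, 1L, split_at - 1L))),
               nrow = nrow(m), dimnames = list(panel$variety_id, loci))
  a2 <- matrix(suppressWarnings(as.integer(substring(m, split_at + 1L))),
               nrow = nrow(m), dimnames = list(panel$variety_id, loci))
  list(a1 = a1, a2 = a2)
}

#' Genetic maps
#'
#' A `genetic_map` is a tibble with columns `locus`, `chr` (integer
#' chromosome, 1-12 for rice) and `pos_cm` (map position in centimorgans).
#' Positions are purely genetic; no physical coordinates are used anywhere.
#'
#' @param x A data frame with columns `locus`, `chr`, `pos_cm`.
#' @param n_chromosomes Highest admissible chromosome number.
#' @return A validated `genetic_map` tibble sorted by chromosome and position.
#' @export
genetic_map <- function(x, n_chromosomes = 12L) {
  x <- as_tibble(x)
  need <- c("locus", "chr", "pos_cm")
  if (!all(need %in% names(x))) {
    abort("map must have columns locus, chr, pos_cm")
  }
  x <- x[need]
  x$locus <- as.character(x$locus)
  if (anyDuplicated(x$locus)) {
    dup <- unique(x$locus[duplicated(x$locus)])
    abort(paste0("duplicate locus row(s) in map: ", paste(dup, collapse = ", ")))
  }
  chr <- suppressWarnings(as.integer(x$chr))
  if (anyNA(chr) || any(chr < 1L) || any(chr > n_chromosomes)) {
    abort(paste0("chromosome outside 1-", n_chromosomes))
  }
  x$chr <- chr
  x$pos_cm <- as.numeric(x$pos_cm)
  if (anyNA(x$pos_cm) || any(x$pos_cm < 0)) abort("positions must be numeric cM >= 0")
  x <- arrange(x, .data$chr, .data$pos_cm)
  class(x) <- c("genetic_map", class(tibble()))
  x
}

# Warn (listing them) if panel loci are missing from the map; error optionally.
check_map_covers <- function(map, panel, strict = FALSE) {
  missing <- setdiff(panel_loci(panel), map$locus)
  if (length(missing)) {
    msg <- paste0("loci absent from map: ", paste(missing, collapse = ", "))
    if (strict) abort(msg) else warn(msg)
  }
  invisible(missing)
}

#' Morphological trait tables
#'
#' A `trait_table` records the six traits of Cheng's indica/japonica index:
#' four pre-scored ordinal traits (`glume_hair`, `phenol_reaction`,
#' `glume_color`, `leaf_hair`, each 0-4) and two numeric measurements
#' (`rachis_cm`, the 1st-2nd rachis internode length in cm, and `grain_lw`,
#' the grain length/width ratio), which are converted to 0-4 scores by
#' [score_traits()].
#'
#' @param x A data frame with columns `variety_id`, `glume_hair`,
#'   `phenol_reaction`, `rachis_cm`, `glume_color`, `leaf_hair`, `grain_lw`.
#' @return A validated `trait_table` tibble.
#' @export
trait_table <- function(x) {
  x <- as_tibble(x)
  need <- c("variety_id", "glume_hair", "phenol_reaction", "rachis_cm",
            "glume_color", "leaf_hair", "grain_lw")
  if (!all(need %in% names(x))) {
    abort(paste0("trait table must have columns: ", paste(need, collapse = ", ")))
  }
  x <- x[need]
  x$variety_id <- as.character(x$variety_id)
  for (tr in c("glume_hair", "phenol_reaction", "glume_color", "leaf_hair")) {
    v <- x[[tr]]
    if (anyNA(v) || !all(v %in% 0:4)) {
      abort(paste0("ordinal trait ", tr, " must have scores in 0..4"))
    }
    x[[tr]] <- as.integer(v)
  }
  for (tr in c("rachis_cm", "grain_lw")) {
    v <- as.numeric(x[[tr]])
    if (anyNA(v) || any(v <= 0)) abort(paste0(tr, " must be positive"))
    x[[tr]] <- v
  }
  class(x) <- c("trait_table", class(tibble()))
  x
}
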