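#' Read and write SSR genotype tables
#'
#' Genotype tables are delimited text with varieties as rows and loci as
#' columns; the first column is the variety identifier and the header row
#' names the loci. Calls are `"a/b"` allele-size pairs in bp, `"a"` as
#' homozygote shorthand, or a missing token (`"NA"`, `"-9"`, `""` by
#' default). The delimiter is taken from the file extension (`.csv` comma,
#' otherwise tab) unless given.
#'
#' @param path File path.
#' @param delim Field delimiter; `NULL` picks by extension.
#' @param missing_tokens Strings treated as missing calls.
#' @return `read_ssr_panel()` returns an [ssr_panel]; `write_ssr_panel()`
#'   returns `path` invisibly.
#' @export
read_ssr_panel <- function(path, delim = NULL, missing_tokens = c("NA", "-9", "")) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = character(), show_col_types = FALSE)
  names(raw)[1L] <- "variety_id"
  loci <- setdiff(names(raw), "variety_id")
  for (loc in loci) {
    v <- trimws(raw[[loc]])
    v[v %in% missing_tokens] <- NA_character_
    raw[[loc]] <- v
  }
  ssr_panel(raw)
}

#' @rdname read_ssr_panel
#' @param panel An [ssr_panel].
#' @export
write_ssr_panel <- function(panel, path, delim = NULL) {
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(as_tibble(panel), path, delim = delim, na = "NA")
  invisible(path)
}

#' Read and write genetic maps
#'
#' Map files are tab-separated with three columns `locus`, `chr`, `pos_cm`
#' (chromosome 1-12, position in cM). If a panel is supplied, loci present in
#' the panel but absent from the map are reported with a warning.
#'
#' @param path File path.
#' @param panel Optional [ssr_panel] to check coverage against.
#' @return A [genetic_map].
#' @export
read_genetic_map <- function(path, panel = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         show_col_types = FALSE)
  names(raw)[1:3] <- c("locus", "chr", "pos_cm")
  map <- genetic_map(raw)
  if (!is.null(panel)) check_map_covers(map, panel)
  map
}

#' @rdname read_genetic_map
#' @param map A [genetic_map].
#' @export
write_genetic_map <- function(map, path) {
  readr::write_tsv(as_tibble(map), path)
  invisible(path)
}

#' Read and write morphological trait tables
#'
#' Trait tables are CSV with columns `variety_id`, `glume_hair`,
#' `phenol_reaction`, `rachis_cm`, `glume_color`, `leaf_hair`, `grain_lw`.
#'
#' @param path File path.
#' @return A [trait_table].
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  trait_table(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_trait_table
#' @param traits A [trait_table].
#' @export
write_trait_table <- function(traits, path) {
  readr::write_csv(as_tibble(traits), path)
  invisible(path)
}

#' Export a panel in STRUCTURE numeric format
#'
#' Writes the two-rows-per-individual integer matrix consumed by the
#' STRUCTURE program: per locus, observed allele sizes are recoded to
#' consecutive integers (1, 2, ...) in increasing bp order and missing calls
#' become -9 in both rows. The bijective recoding table (locus, code, bp
#' size) is written alongside as `<path>.codes.tsv`.
#'
#' @param panel An [ssr_panel].
#' @param path Output path for the genotype matrix.
#' @return Invisibly, a list with the matrix path and the recoding-table path.
#' @export
write_structure_format <- function(panel, path) {
  al <- panel_alleles(panel)
  loci <- panel_loci(panel)
  codes <- purrr::map(loci, function(loc) {
    sort(unique(c(al$a1[, loc], al$a2[, loc])))
  })
  names(codes) <- loci
  recode_one <- function(mat) {
    out <- matrix(-9L, nrow = nrow(mat), ncol = ncol(mat))
    for (j in seq_along(loci)) {
      out[, j] <- match(mat[, j], codes[[j]])
    }
    out[is.na(out)] <- -9L
    out
  }
  r1 <- recode_one(al$a1)
  r2 <- recode_one(al$a2)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("variety", loci), collapse = "\t"), con)
  for (i in seq_len(nrow(r1))) {
    writeLines(paste(c(panel$variety_id[i], r1[i, ]), collapse = "\t"), con)
    writeLines(paste(c(panel$variety_id[i], r2[i, ]), collapse = "\t"), con)
  }
  code_tbl <- purrr::map2_dfr(loci, codes, function(loc, sizes) {
    tibble(locus = loc, code = seq_along(sizes), size_bp = sizes)
  })
  codes_path <- paste0(path, ".codes.tsv")
  readr::write_tsv(code_tbl, codes_path)
  invisible(list(genotypes = path, codes = codes_path))
}
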