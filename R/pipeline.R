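#' Configuration for a full analysis run
#'
#' Bundles the inputs and the printed study constants — membership
#' threshold 0.80, Laplacian eps 0.8, LD alpha 0.05, unlinked-r2 quantile
#' 0.75, the 12-step resampling grid — with a master seed from which every
#' stochastic stage derives its own seed deterministically.
#'
#' @param panel,map,traits Input objects, or `NULL` to simulate them from
#'   `sim` in the `simulate` stage.
#' @param sim A [sim_config] used when inputs are not supplied.
#' @param k_range,n_pcs,membership_threshold,lap_eps Structure options.
#' @param resample_grid,resample_reps,strategies Resampling options.
#' @param ld_alpha,ld_shuffles,ld_quantile,ld_window LD options.
#' @param n_bootstrap Bootstrap replicates for the diversity scan.
#' @param seed Master seed.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(panel = NULL, map = NULL, traits = NULL,
                            sim = NULL, k_range = 1:10, n_pcs = 10L,
                            membership_threshold = 0.80, lap_eps = 0.8,
                            resample_grid = NULL, resample_reps = 25L,
                            strategies = c("random", "stratified"),
                            ld_alpha = 0.05, ld_shuffles = 1000L,
                            ld_quantile = 0.75, ld_window = 5,
                            n_bootstrap = 200L, seed = 1L) {
  if (is.null(panel) && is.null(sim)) {
    abort("provide a panel (with map) or a sim_config")
  }
  structure(as.list(environment()), class = "analysis_config")
}

stage_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 1009 + sum(utf8ToInt(stage))) %% 2147483647)
}

#' Run the analysis pipeline
#'
#' Orchestrates the study stages on a panel (given or simulated):
#' `simulate`, `classify` (Cheng scoring, needs traits), `diversity`
#' (scan + summaries), `structure` (PCA, PCoA, Laplacian embedding,
#' mixture fit, delta-K, threshold and max assignments, NJ tree),
#' `resample` (sufficiency curves) and `ld` (pairs, summary, decay,
#' blocks). Each stage writes its tabular outputs as TSV into `outdir`
#' and a `manifest.json` records inputs (hashed), seeds and versions, so
#' identical configs and seeds give byte-identical outputs.
#'
#' @param config An [analysis_config].
#' @param stages Character subset of
#'   `c("simulate", "classify", "diversity", "structure", "resample", "ld")`.
#' @param outdir Output directory (created if needed); `NULL` skips
#'   writing files.
#' @return A named list of stage results (invisible file paths in
#'   `$files`).
#' @export
run_analysis <- function(config,
                         stages = c("simulate", "classify", "diversity",
                                    "structure", "resample", "ld"),
                         outdir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  known <- c("simulate", "classify", "diversity", "structure", "resample", "ld")
  stages <- match.arg(stages, known, several.ok = TRUE)
  res <- list()
  files <- character()
  emit <- function(tbl, name) {
    if (!is.null(outdir)) {
      if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
      path <- file.path(outdir, paste0(name, ".tsv"))
      readr::write_tsv(as_tibble(tbl), path)
      files <<- c(files, path)
    }
  }

  panel <- config$panel; map <- config$map; traits <- config$traits
  truth <- NULL
  if ("simulate" %in% stages && !is.null(config$sim)) {
    sim <- simulate_panel(config$sim)
    panel <- sim$panel; map <- sim$map; truth <- sim$truth
    traits <- traits %||% simulate_traits(truth, config$sim)
    res$simulate <- sim
    emit(panel, "panel"); emit(map, "map"); emit(truth, "truth")
    emit(traits, "traits")
  }
  if (is.null(panel)) abort("no panel: run the simulate stage first or supply one")

  if ("classify" %in% stages) {
    if (is.null(traits)) abort("classify stage needs traits: supply them or run simulate")
    res$classify <- cheng_classify(score_traits(traits))
    emit(res$classify, "cheng_classification")
  }

  grouping <- if (!is.null(truth)) {
    tibble(variety_id = truth$variety_id, group = truth$group)
  } else NULL

  if ("diversity" %in% stages) {
    res$diversity <- diversity_scan(
      panel, grouping,
      mrd_groups = if (!is.null(grouping)) c("subpop1", "subpop2") else NULL,
      n_bootstrap = config$n_bootstrap,
      seed = stage_seed(config$seed, "diversity"))
    emit(res$diversity$per_locus, "diversity_per_locus")
    emit(res$diversity$group_summary, "diversity_groups")
    if (!is.null(res$diversity$mrd_scan)) emit(res$diversity$mrd_scan, "mrd_scan")
  }

  if ("structure" %in% stages) {
    enc <- encode_panel(panel)
    pca <- pca_panel(enc, n_components = config$n_pcs)
    lap <- tryCatch(laplacian_embed(enc, eps = config$lap_eps),
                    warning = function(w) suppressWarnings(
                      laplacian_embed(enc, eps = config$lap_eps)))
    dm <- mrd_matrix(panel)
    pco <- pcoa(dm, n_axes = 2L)
    fit <- fit_mixture(pca, K_range = config$k_range)
    runs <- mixture_runs(pca, K_range = seq_len(min(max(config$k_range), 5L)),
                         n_reps = 3L, seed = stage_seed(config$seed, "structure"))
    dk <- delta_k(runs)
    assignment_max <- assign_membership(fit$membership, rule = "max")
    q_hat <- estimate_admixture(panel, assignment_max)
    assignment <- assign_membership(q_hat, rule = "threshold",
                                    threshold = config$membership_threshold)
    nj <- nj_tree(dm)
    res$structure <- list(pca = pca, pcoa = pco, laplacian = lap,
                          mixture = fit, delta_k = dk,
                          membership_q = q_hat,
                          assignment = assignment,
                          assignment_max = assignment_max,
                          nj = nj)
    emit(fit$membership, "membership")
    emit(q_hat, "membership_q")
    emit(assignment, "assignment_threshold")
    emit(dk$curve, "delta_k")
    emit(pca$scores, "pca_scores")
    if (!is.null(outdir)) {
      writeLines(nj$newick, file.path(outdir, "nj_tree.nwk"))
      files <- c(files, file.path(outdir, "nj_tree.nwk"))
    }
  }

  if ("resample" %in% stages) {
    if (is.null(map)) abort("resample stage needs a map: run read_genetic_map or simulate first")
    grid <- config$resample_grid %||%
      seq(12L, length(panel_loci(panel)), by = 12L)
    res$resample <- sufficiency_curves(
      panel, map, grid = grid, reps = config$resample_reps,
      strategies = config$strategies, n_pcs = config$n_pcs,
      seed = stage_seed(config$seed, "resample"))
    emit(res$resample$curves, "sufficiency_curves")
  }

  if ("ld" %in% stages) {
    if (is.null(map)) abort("ld stage needs a map: run read_genetic_map or simulate first")
    pairs <- ld_pairs(panel, map, grouping = NULL,
                      n_shuffles = config$ld_shuffles,
                      seed = stage_seed(config$seed, "ld"))
    summ <- ld_summary(pairs, alpha = config$ld_alpha)
    decay <- decay_distance(pairs, probs = config$ld_quantile,
                            window = config$ld_window)
    blocks <- find_blocks(pairs, map, alpha = config$ld_alpha)
    res$ld <- list(pairs = pairs, summary = summ, decay = decay,
                   blocks = blocks,
                   block_summary = block_summary(blocks,
                                                 max(as_tibble(map)$chr)))
    emit(pairs, "ld_pairs")
    emit(summ$summary, "ld_summary")
    emit(decay$curve, "ld_decay_curve")
    emit(select(blocks, -"loci"), "ld_blocks")
  }

  if (!is.null(outdir)) {
    manifest <- list(
      package = "ssrpop",
      version = as.character(utils::packageVersion("ssrpop")),
      r_version = R.version.string,
      seed = config$seed,
      stages = stages,
      stage_seeds = setNames(lapply(stages, stage_seed, master = config$seed),
                             stages),
      files = lapply(setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f)))
    )
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res$files <- files
  invisible(res)
}
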