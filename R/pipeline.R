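# End-to-end orchestration: simulate/ingest -> filter -> per-protein GP
# selection -> summaries -> cord-blood comparison, with a run manifest.

#' Build a pipeline configuration
#'
#' Assembles the full configuration of [run_pipeline()] with documented
#' defaults; any subset can be overridden by passing nested lists, and a
#' configuration can equivalently be read from a YAML file with
#' [read_pipeline_config()].
#'
#' @param outdir output directory.
#' @param seed master seed; every random stage derives its own seed from it.
#' @param simulate list: `n_proteins`, `class_mix`, `effect_var`,
#'   `missing_prob` plus any [study_design()] fields. Used by the `simulate`
#'   stage.
#' @param input list: paths `protein_groups`, `annotation`, `replicate_map`
#'   and the `intensity_prefix`; required when the `simulate` stage is not
#'   run.
#' @param filtering list: `min_unique_peptides`, `min_run_fraction`,
#'   `min_sample_fraction`.
#' @param selection list: `delta`, `rho`, `n_restarts`, `period`,
#'   `max_proteins` (cap on the number of proteins modelled, `Inf` by
#'   default).
#' @param summaries list: `age_bins`, `bin_tol`, `k_clusters`.
#' @param cord list: `B` (rank-product permutations), `pfp_threshold`,
#'   `fdr_threshold`, `followup_bin` (the follow-up age bin paired against
#'   cord blood, default 3 months), `min_subjects`.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(outdir = "serogp_run", seed = 1,
                            simulate = list(), input = list(),
                            filtering = list(), selection = list(),
                            summaries = list(), cord = list()) {
  config <- list(
    outdir = outdir, seed = seed,
    simulate = modifyList(list(
      n_subjects = 15, n_proteins = 24,
      class_mix = c(age = 0.4, location = 0.1, id = 0.2, null = 0.3),
      effect_var = 1, missing_prob = 0.1), simulate),
    input = modifyList(list(
      protein_groups = NULL, annotation = NULL, replicate_map = NULL,
      intensity_prefix = "LFQ intensity "), input),
    filtering = modifyList(list(
      min_unique_peptides = 2, min_run_fraction = 0.25,
      min_sample_fraction = 0.5), filtering),
    selection = modifyList(list(
      delta = 0.05, rho = 0.01, n_restarts = 5, period = 12,
      max_proteins = Inf), selection),
    summaries = modifyList(list(
      age_bins = c(3, 6, 12, 18, 24, 36), bin_tol = 1.5, k_clusters = 6),
      summaries),
    cord = modifyList(list(
      B = 2000, pfp_threshold = 0.05, fdr_threshold = 0.1, followup_bin = 3,
      min_subjects = 5), cord))
  validate_pipeline_config(config)
  structure(config, class = "pipeline_config")
}

validate_pipeline_config <- function(config) {
  stopifnot(is.numeric(config$seed), length(config$seed) == 1L)
  f <- config$filtering
  if (f$min_run_fraction <= 0 || f$min_run_fraction > 1)
    stop("filtering$min_run_fraction must be in (0, 1]")
  if (f$min_sample_fraction < 0 || f$min_sample_fraction > 1)
    stop("filtering$min_sample_fraction must be in [0, 1]")
  s <- config$selection
  if (s$delta < 0) stop("selection$delta must be nonnegative")
  if (s$rho < 0 || s$rho > 1) stop("selection$rho must be in [0, 1]")
  if (config$cord$B < 1) stop("cord$B must be >= 1")
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [pipeline_config()].
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate$class_mix))
    y$simulate$class_mix <- unlist(y$simulate$class_mix)
  do.call(pipeline_config, y[intersect(names(y),
    c("outdir", "seed", "simulate", "input", "filtering", "selection",
      "summaries", "cord"))])
}

pipeline_paths <- function(outdir) {
  list(input = file.path(outdir, "input"),
       tables = file.path(outdir, "tables"),
       manifest = file.path(outdir, "manifest.json"))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the longitudinal proteome analysis pipeline
#'
#' Orchestrates the stages `simulate` (synthetic raw data with ground truth),
#' `ingest` (parse, identification filter, replicate collapse, coverage
#' filter — cord and follow-up samples are filtered separately), `select`
#' (per-protein additive GP covariate selection), `summarize` (child-specific
#' Z-scores, age-binned averages, trajectory clustering, paired fold changes)
#' and `cordcompare` (intensity ranks, paired rank product, cord/follow-up
#' correlations). Every stage writes TSV tables under `<outdir>/tables` (the
#' simulate stage writes its raw exports under `<outdir>/input`) and the run
#' ends with a JSON manifest recording seeds, thresholds, versions and the
#' protein counts after every step. Reruns with an identical configuration
#' reproduce every report byte for byte. If a stage fails, the outputs of the
#' completed stages are retained and the manifest records the failure point.
#'
#' @param config a [pipeline_config()].
#' @param stages stages to run, in order; `"all"` expands to every stage.
#'   When `simulate` is not included, `config$input` must point at existing
#'   files.
#' @param resume skip stages whose outputs already exist.
#' @param verbose print one line per stage.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, stages = "all", resume = FALSE,
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "ingest", "select", "summarize", "cordcompare")
  if (identical(stages, "all")) stages <- all_stages
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  paths <- pipeline_paths(config$outdir)
  dir.create(paths$input, recursive = TRUE, showWarnings = FALSE)
  dir.create(paths$tables, recursive = TRUE, showWarnings = FALSE)

  if ("ingest" %in% stages && !"simulate" %in% stages) {
    # validate the inputs up front, before any computation
    need <- c(protein_groups = "protein_groups.tsv",
              annotation = "annotation.tsv",
              replicate_map = "replicate_map.tsv")
    for (nm in names(need)) {
      p <- resolve_input(config, paths, nm, need[[nm]])
      if (!file.exists(p))
        stop("config$input$", nm, " is required when the simulate stage ",
             "is not run (no file at ", p, ")")
    }
  }

  manifest <- list(
    package = "serogp",
    versions = list(serogp = as.character(utils::packageVersion("serogp")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    seed = config$seed,
    config = unclass(config),
    stages = list(), status = "ok", failed_stage = NULL)
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    if (verbose) message("[serogp] stage: ", name)
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$status <<- "failed"
      manifest$failed_stage <<- name
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      write_manifest(manifest, paths$manifest)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res),
           " (partial outputs retained in ", config$outdir, ")",
           call. = FALSE)
    }
    manifest$stages[[name]] <<- c(list(status = "ok"), res)
    invisible(NULL)
  }

  run_stage("simulate", function()
    stage_simulate(config, paths, state, resume))
  run_stage("ingest", function() stage_ingest(config, paths, state, resume))
  run_stage("select", function() stage_select(config, paths, state, resume))
  run_stage("summarize", function()
    stage_summarize(config, paths, state, resume))
  run_stage("cordcompare", function()
    stage_cordcompare(config, paths, state, resume))

  write_manifest(manifest, paths$manifest)
  if (verbose) message("[serogp] done; manifest at ", paths$manifest)
  invisible(manifest)
}

write_manifest <- function(manifest, path) {
  manifest$config$selection$max_proteins <-
    if (is.finite(manifest$config$selection$max_proteins))
      manifest$config$selection$max_proteins else "Inf"
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

stage_simulate <- function(config, paths, state, resume) {
  sim <- config$simulate
  pg_path <- file.path(paths$input, "protein_groups.tsv")
  if (resume && file.exists(pg_path)) return(list(resumed = TRUE))
  design_args <- sim[intersect(names(sim), names(formals(study_design)))]
  design_args$missing_prob <- NULL
  design_args$seed <- NULL
  design <- do.call(study_design, c(design_args, list(seed = config$seed)))
  ann <- simulate_design(design, seed = config$seed)
  ds <- simulate_dataset(ann, n_proteins = sim$n_proteins,
                         class_mix = sim$class_mix,
                         effect_var = sim$effect_var,
                         missing_prob = sim$missing_prob,
                         seed = config$seed + 1)
  pgs <- simulate_protein_groups(ds$data, seed = config$seed + 2)
  write_protein_groups(pgs$quant, pg_path,
                       intensity_prefix = config$input$intensity_prefix)
  write_tsv(ann, file.path(paths$input, "annotation.tsv"))
  write_tsv(pgs$replicate_map, file.path(paths$input, "replicate_map.tsv"))
  write_tsv(ds$truth, file.path(paths$input, "truth.tsv"))
  list(n_proteins = nrow(ds$data$values) ,
       n_samples = ncol(ds$data$values),
       n_runs = ncol(pgs$quant$intensities),
       class_counts = as.list(table(ds$truth$class)))
}

resolve_input <- function(config, paths, name, default) {
  p <- config$input[[name]]
  if (!is.null(p) && file.exists(p)) return(p)
  file.path(paths$input, default)
}

stage_ingest <- function(config, paths, state, resume) {
  quant <- read_protein_groups(
    resolve_input(config, paths, "protein_groups", "protein_groups.tsv"),
    intensity_prefix = config$input$intensity_prefix)
  ann <- read_sample_annotation(
    resolve_input(config, paths, "annotation", "annotation.tsv"))
  rmap <- read_replicate_map(
    resolve_input(config, paths, "replicate_map", "replicate_map.tsv"))
  n_raw <- nrow(quant$proteins)
  f <- config$filtering
  quant <- filter_identifications(quant, f$min_unique_peptides,
                                  f$min_run_fraction)
  n_ident <- nrow(quant$proteins)
  es <- collapse_replicates(quant, rmap, ann)

  # cord and follow-up samples are processed (coverage-filtered) separately
  follow <- es[, !es$annotation$is_cord]
  cord <- if (any(es$annotation$is_cord)) es[, es$annotation$is_cord] else NULL
  follow <- filter_sample_coverage(follow, f$min_sample_fraction)
  if (!is.null(cord)) cord <- filter_sample_coverage(cord,
                                                     f$min_sample_fraction)
  state$follow <- follow
  state$cord <- cord
  write_expression_matrix(follow, file.path(paths$tables,
                                            "expression_followup.tsv"))
  if (!is.null(cord))
    write_expression_matrix(cord, file.path(paths$tables,
                                            "expression_cord.tsv"))
  counts <- data.frame(
    step = c("parsed", "identification_filter", "followup_coverage_filter",
             "cord_coverage_filter"),
    n_proteins = c(n_raw, n_ident, nrow(follow$values),
                   if (is.null(cord)) NA else nrow(cord$values)))
  write_tsv(counts, file.path(paths$tables, "filter_counts.tsv"))
  list(n_parsed = n_raw, n_after_identification = n_ident,
       n_followup = nrow(follow$values),
       n_cord = if (is.null(cord)) 0L else nrow(cord$values))
}

require_state <- function(state, config, paths, what) {
  if (!is.null(state[[what]])) return(state[[what]])
  # stage run standalone: reload from the tables written by 'ingest'
  file <- switch(what, follow = "expression_followup.tsv",
                 cord = "expression_cord.tsv")
  p <- file.path(paths$tables, file)
  if (!file.exists(p)) {
    if (what == "cord") return(NULL)
    stop("run the 'ingest' stage first (missing ", p, ")")
  }
  ann <- read_sample_annotation(
    resolve_input(config, paths, "annotation", "annotation.tsv"))
  es <- read_expression_matrix(p)
  expression_set(es$values, ann[match(colnames(es$values), ann$sample_id), ])
}

stage_select <- function(config, paths, state, resume) {
  out_path <- file.path(paths$tables, "selection.tsv")
  if (resume && file.exists(out_path)) return(list(resumed = TRUE))
  follow <- require_state(state, config, paths, "follow")
  s <- config$selection
  ids <- rownames(follow$values)
  if (is.finite(s$max_proteins) && length(ids) > s$max_proteins)
    ids <- ids[seq_len(s$max_proteins)]
  tab <- select_proteome(follow, proteins = ids, seed = config$seed,
                         delta = s$delta, rho = s$rho,
                         n_restarts = s$n_restarts, period = s$period)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) round(x, 6))
  write_tsv(tab, out_path)
  state$selection <- tab
  flagged <- function(cv) sum(tab[[paste0("flag_", cv)]], na.rm = TRUE)
  list(n_modelled = sum(is.na(tab$skipped)),
       n_skipped = sum(!is.na(tab$skipped)),
       n_age = flagged("age"), n_season = flagged("season"),
       n_gender = flagged("gender"), n_location = flagged("location"))
}

stage_summarize <- function(config, paths, state, resume) {
  follow <- require_state(state, config, paths, "follow")
  sm <- config$summaries
  z <- suppressWarnings(per_child_zscore(follow))
  write_expression_matrix(z, file.path(paths$tables, "zscore_matrix.tsv"))
  avg <- average_zscores_by_age(z, bins = sm$age_bins, tol = sm$bin_tol)
  write_expression_matrix(avg, file.path(paths$tables,
                                         "zscore_age_means.tsv"))
  cl_input <- avg[rowSums(is.na(avg)) == 0L, , drop = FALSE]
  clusters <- NULL
  if (nrow(cl_input) >= sm$k_clusters) {
    clusters <- cluster_age_profiles(cl_input, k = sm$k_clusters)
    write_tsv(data.frame(protein_id = names(clusters), cluster = clusters),
              file.path(paths$tables, "clusters.tsv"))
  }
  fc <- tryCatch(paired_fold_changes(follow, bins = sm$age_bins,
                                     tol = sm$bin_tol),
                 error = function(e) NULL)
  if (!is.null(fc)) {
    num <- vapply(fc, is.numeric, logical(1))
    fc[num] <- lapply(fc[num], function(x) round(x, 6))
    write_tsv(fc, file.path(paths$tables, "fold_changes.tsv"))
  }
  list(n_zscore_proteins = nrow(z$values),
       n_clustered = if (is.null(clusters)) 0L else length(clusters),
       n_fold_change_pairs = if (is.null(fc)) 0L else
         sum(grepl("^pair_", colnames(fc))))
}

stage_cordcompare <- function(config, paths, state, resume) {
  follow <- require_state(state, config, paths, "follow")
  cord <- require_state(state, config, paths, "cord")
  if (is.null(cord)) return(list(skipped = "no cord samples"))
  cc <- config$cord
  sm <- config$summaries

  subj_matrix <- function(es, bin_label) {
    bin <- assign_age_bins(es$annotation, sm$age_bins, sm$bin_tol)
    cols <- which(!is.na(bin) & bin == bin_label)
    mat <- es$values[, cols, drop = FALSE]
    colnames(mat) <- as.character(es$annotation$subject_id[cols])
    mat[, !duplicated(colnames(mat)), drop = FALSE]
  }
  cord_mat <- subj_matrix(cord, "cord")
  follow_mat <- subj_matrix(follow, as.character(cc$followup_bin))

  cord_ranks <- intensity_ranks(cord_mat)
  follow_ranks <- intensity_ranks(follow_mat)
  medians <- data.frame(
    protein_id = union(rownames(cord_ranks), rownames(follow_ranks)),
    stringsAsFactors = FALSE)
  medians$median_rank_cord <-
    apply(cord_ranks, 1L, median, na.rm = TRUE)[medians$protein_id]
  medians$median_rank_followup <-
    apply(follow_ranks, 1L, median, na.rm = TRUE)[medians$protein_id]
  write_tsv(medians, file.path(paths$tables, "rank_medians.tsv"))

  rp <- withCallingHandlers(
    rank_product_test(cord_ranks, follow_ranks, B = cc$B,
                      seed = config$seed + 3,
                      pfp_threshold = cc$pfp_threshold),
    warning = function(w) invokeRestart("muffleWarning"))
  num <- vapply(rp, is.numeric, logical(1))
  rp[num] <- lapply(rp[num], function(x) round(x, 6))
  write_tsv(rp, file.path(paths$tables, "rank_product.tsv"))

  corr <- cord_followup_correlation(cord_mat, follow, bins = sm$age_bins,
                                    tol = sm$bin_tol,
                                    min_subjects = cc$min_subjects,
                                    fdr = cc$fdr_threshold)
  num <- vapply(corr, is.numeric, logical(1))
  corr[num] <- lapply(corr[num], function(x) round(x, 6))
  write_tsv(corr, file.path(paths$tables, "correlations.tsv"))

  sig_corr <- unique(corr$protein_id[corr$significant])
  list(n_rank_product_significant = sum(rp$significant),
       n_rank_product_up = sum(rp$significant & rp$direction == "up"),
       n_rank_product_down = sum(rp$significant & rp$direction == "down"),
       n_correlation_tests = nrow(corr),
       n_correlated_proteins = length(sig_corr))
}

#' Cluster average age-trajectory profiles
#'
#' Hierarchical agglomerative clustering (Euclidean distance, Ward linkage)
#' of proteins' average Z-score profiles over age bins, cut at `k` clusters —
#' the grouping used to organise age-associated proteins into rising/falling
#' trajectory families.
#'
#' @param avg_zscores proteins x age-groups matrix (no missing rows).
#' @param k number of clusters (default 6).
#' @return A named integer vector of cluster assignments (1..k).
#' @export
cluster_age_profiles <- function(avg_zscores, k = 6) {
  stopifnot(is.matrix(avg_zscores))
  if (anyNA(avg_zscores))
    stop("profiles with missing values cannot be clustered; drop them first")
  if (k > nrow(avg_zscores))
    stop("k = ", k, " exceeds the number of proteins (", nrow(avg_zscores),
         ")")
  hc <- hclust(dist(avg_zscores), method = "ward.D2")
  cutree(hc, k = k)
}
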