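# Config-driven orchestration: simulate -> preprocess -> call hits -> rank,
# and the expression-signature branch. Every run writes its resolved config
# and a stage-by-stage record-count log next to its outputs.

#' Default pipeline configuration
#'
#' A nested list holding every module threshold and simulation parameter,
#' overridable field-by-field (see [run_screen_pipeline()]). All seeds are
#' explicit; nothing reads the wall clock.
#'
#' @return named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    screen = list(
      n_genes = 500L, hairpins_per_gene = c(4L, 4L), n_pools = 6L,
      n_replicates = 3L, n_protective = 20L, n_lethal = 20L,
      effect_size = 1.2, efficacy_range = c(0.6, 1.0),
      baseline_stress_survival = 0.5, representation = 1000L,
      noise_sd = 0.25, conditions = c("hypoxia", "lactic_acidosis")
    ),
    preprocess = list(background_fold = 2.0, background_rule = "either",
                      use_net = TRUE, group_by_pool = TRUE,
                      median_center = TRUE),
    hits = list(tau = 0.7, min_reps = 2L, cv_max = 0.5, min_hairpins = 2L,
                allow_mixed_direction = FALSE),
    ranking = list(direction = "enrichment", B = 1000L),
    signature = list(n_genes = 1000L, n_de = 50L, overlap = 0.6,
                     samples_per_class = 3L, effect_size = 1.0,
                     noise_sd = 0.5, n_cohort = 130L, n_sig = 100L,
                     k_factors = 2L, ridge = 0.01,
                     fold = 1.7, min_arrays = 6L, filter_scale = "fold")
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a pipeline configuration from YAML, merged over the defaults
#' @param path YAML file; fields present override [default_config()].
#' @return named list.
#' @export
read_config <- function(path) {
  merge_config(default_config(), yaml::read_yaml(path))
}

validate_config <- function(config, fields) {
  for (f in fields) {
    parts <- strsplit(f, "\\$")[[1]]
    x <- config
    for (p in parts) {
      x <- x[[p]]
      if (is.null(x)) stop("config is missing required field: ", f, call. = FALSE)
    }
  }
  invisible(config)
}

log_line <- function(log, stage, msg) c(log, sprintf("[%s] %s", stage, msg))

#' Run the full screen branch of the pipeline
#'
#' Simulates a genome-wide pooled screen per stress condition from the
#' configured truth (planted protective and lethal genes among neutrals),
#' preprocesses each condition (background filter, log2 R/G, pool-wise
#' quantile normalization, replicate QC), calls multiple-hairpin gene hits,
#' ranks genes by the second-best-hairpin permutation NES, and summarizes
#' the cross-condition hit overlap. All artifacts are written under
#' `outdir`; outputs are deterministic for a fixed config.
#'
#' @param config list from [default_config()] / [read_config()]; partial
#'   lists are merged over the defaults.
#' @param outdir output directory (created).
#' @return (invisibly) list with `library`, `truth`, and per-condition
#'   `rg`, `qc`, `calls`, `hits`, `ranking`, plus `overlap` and `log`.
#' @export
run_screen_pipeline <- function(config = list(), outdir = tempfile("screen_")) {
  config <- merge_config(default_config(), config)
  validate_config(config, c("seed", "screen$n_genes", "screen$n_replicates",
                            "hits$tau", "hits$min_reps", "hits$cv_max",
                            "hits$min_hairpins", "ranking$B"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sc <- config$screen
  log <- character()

  lib <- make_library(sc$n_genes, sc$hairpins_per_gene, sc$n_pools,
                      efficacy_range = sc$efficacy_range,
                      seed = config$seed)
  log <- log_line(log, "simulate", sprintf("library: %d genes, %d hairpins, %d pools",
                                           sc$n_genes, nrow(lib), sc$n_pools))
  genes <- unique(lib$gene_id)
  eff <- with_seed(config$seed + 1L, {
    picked <- sample(genes, sc$n_protective + sc$n_lethal)
    stats::setNames(rep(c(sc$effect_size, -sc$effect_size),
                        c(sc$n_protective, sc$n_lethal)), picked)
  })
  truth <- screen_truth(gene_effects = eff,
                        baseline_stress_survival = sc$baseline_stress_survival,
                        representation = sc$representation,
                        noise_sd = sc$noise_sd)

  res <- list(library = lib, truth = truth, per_condition = list())
  pp <- config$preprocess; hc <- config$hits
  for (i in seq_along(sc$conditions)) {
    cond <- sc$conditions[i]
    raw <- simulate_screen(lib, truth, sc$n_replicates, condition = cond,
                           seed = config$seed + 10L * i)
    log <- log_line(log, cond, sprintf("raw probe rows: %d", nrow(raw)))
    filt <- filter_background(raw, fold = pp$background_fold,
                              rule = pp$background_rule)
    log <- log_line(log, cond, sprintf("after background filter: %d (removed %d)",
                                       nrow(filt), nrow(attr(filt, "removed"))))
    rg <- compute_log_ratios(filt, use_net = pp$use_net)
    rg <- quantile_normalize(rg, group_by_pool = pp$group_by_pool)
    if (isTRUE(pp$median_center)) rg <- median_center(rg, by_pool = pp$group_by_pool)
    qc <- replicate_qc(rg)
    calls <- call_hairpin_events(rg, tau = hc$tau, min_reps = hc$min_reps,
                                 cv_max = hc$cv_max)
    hits <- call_gene_hits(calls, lib, min_hairpins = hc$min_hairpins,
                           allow_mixed_direction = hc$allow_mixed_direction)
    log <- log_line(log, cond, sprintf("hits: %d protective, %d lethal",
                                       sum(hits$class == "protective"),
                                       sum(hits$class == "lethal")))
    scores <- hairpin_scores(rg)
    gs <- second_best_gene_score(scores, lib, direction = config$ranking$direction)
    ranking <- permutation_nes(gs, scores, B = config$ranking$B,
                               seed = config$seed + 100L * i)
    write_rg_matrix(rg, file.path(outdir, paste0("rg_", cond, ".tsv")))
    write_qc_json(qc, file.path(outdir, paste0("qc_", cond, ".json")))
    write_hits_tsv(calls, file.path(outdir, paste0("hairpin_calls_", cond, ".tsv")))
    write_hits_tsv(hits, file.path(outdir, paste0("gene_hits_", cond, ".tsv")))
    write_ranking_tsv(ranking, file.path(outdir, paste0("ranking_", cond, ".tsv")))
    res$per_condition[[cond]] <- list(rg = rg, qc = qc, calls = calls,
                                      hits = hits, ranking = ranking)
  }
  if (length(sc$conditions) >= 2L) {
    ov <- cross_condition_overlap(res$per_condition[[1]]$hits,
                                  res$per_condition[[2]]$hits,
                                  sc$conditions[1], sc$conditions[2])
    write_overlap_json(ov, file.path(outdir, "overlap.json"))
    res$overlap <- ov
  }
  yaml::write_yaml(config, file.path(outdir, "config_resolved.yaml"))
  writeLines(log, file.path(outdir, "pipeline.log"))
  res$log <- log
  invisible(res)
}

#' Run the expression-signature branch of the pipeline
#'
#' Simulates scramble-vs-knockdown training sets for two overlapping gene
#' programs plus a cohort with latent program activities, zero-transforms to
#' the scramble controls, writes the occurrence/fold-filtered matrix, trains
#' one signature per program, projects both onto the cohort, and regresses
#' one projected probability on the other.
#'
#' @inheritParams run_screen_pipeline
#' @return (invisibly) list with `truth`, `models`, `filtered` matrix,
#'   cohort `prob_a` / `prob_b`, `regression`, `log`.
#' @export
run_signature_pipeline <- function(config = list(), outdir = tempfile("sig_")) {
  config <- merge_config(default_config(), config)
  validate_config(config, c("seed", "signature$n_genes", "signature$n_de",
                            "signature$samples_per_class", "signature$n_sig"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sg <- config$signature
  log <- character()

  truth <- make_expression_truth(sg$n_genes, n_de = sg$n_de,
                                 overlap = sg$overlap, seed = config$seed)
  models <- list(); exprs <- list()
  for (pr in c("a", "b")) {
    x <- simulate_expression(truth, sg$samples_per_class, program = pr,
                             effect_size = sg$effect_size,
                             noise_sd = sg$noise_sd,
                             seed = config$seed + ifelse(pr == "a", 2L, 3L))
    labels <- attr(x, "class_labels")
    zt <- zero_transform(x, names(labels)[labels == 0L])
    models[[pr]] <- create_signature(zt, names(labels)[labels == 0L],
                                     names(labels)[labels == 1L],
                                     n_sig = sg$n_sig, k_factors = sg$k_factors,
                                     ridge = sg$ridge)
    exprs[[pr]] <- x
    log <- log_line(log, paste0("signature_", pr),
                    sprintf("%d genes selected of %d", length(models[[pr]]$genes),
                            nrow(x)))
  }
  combined <- cbind(exprs$a, exprs$b[, attr(exprs$b, "class_labels") == 1L])
  ctrl <- colnames(exprs$a)[attr(exprs$a, "class_labels") == 0L]
  zt_all <- zero_transform(combined, ctrl)
  filt <- fold_filter(zt_all, fold = sg$fold, min_arrays = sg$min_arrays,
                      scale = sg$filter_scale)
  log <- log_line(log, "fold_filter", sprintf("%d of %d genes retained",
                                              nrow(filt), nrow(zt_all)))
  write_gct(filt, file.path(outdir, "filtered_zero_transformed.gct"))

  cohort <- simulate_cohort(truth, sg$n_cohort, effect_size = sg$effect_size,
                            noise_sd = sg$noise_sd, seed = config$seed + 4L)
  cohort_zt <- cohort - truth$baseline   # cohort relative to its baseline
  prob_a <- project_signature(models$a, cohort_zt)
  prob_b <- project_signature(models$b, cohort_zt)
  reg <- signature_regression(prob_a, prob_b)
  log <- log_line(log, "regression",
                  sprintf("slope %.3f, r2 %.3f, p %.3g over %d samples",
                          reg$slope, reg$r_squared, reg$p_value, reg$n))
  write_signature_json(models$a, file.path(outdir, "signature_a.json"))
  write_signature_json(models$b, file.path(outdir, "signature_b.json"))
  write_signature_json(reg, file.path(outdir, "regression.json"))
  utils::write.csv(data.frame(sample = names(prob_a), prob_a = prob_a,
                              prob_b = prob_b, row.names = NULL),
                   file.path(outdir, "cohort_probabilities.csv"),
                   row.names = FALSE)
  yaml::write_yaml(config, file.path(outdir, "config_resolved.yaml"))
  writeLines(log, file.path(outdir, "pipeline.log"))
  invisible(list(truth = truth, models = models, filtered = filt,
                 prob_a = prob_a, prob_b = prob_b, regression = reg,
                 log = log))
}
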