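#' Validate and default a pipeline configuration
#'
#' The configuration is a JSON file (or an equivalent R list) with exactly one
#' of a \code{synthetic} block (fields of \code{\link{synthetic_config}}) or
#' an \code{inputs} block (paths \code{edge_list}, \code{positives},
#' \code{drug_targets}, and optionally \code{gmt}). Optional blocks
#' \code{autoencoder} (profile desk/paper, d_latent, n_layers, optimizer
#' overrides), \code{prioritizer} (n_datasets, n_negatives, threshold,
#' smote_k, grid overrides) and \code{enrichment} (fdr_threshold, gmt) are
#' filled with the reference defaults: latent d 100, SMOTE k 2, 100 datasets,
#' 500 negatives, probability threshold 0.75, FDR 0.05.
#'
#' @param config path to a JSON config file, or a list.
#' @return a fully defaulted list of class \code{pipeline_config}.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  problems <- character()
  known <- c("seed", "outdir", "synthetic", "inputs", "autoencoder",
             "prioritizer", "enrichment")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0L)
    problems <- c(problems, paste("unknown config keys:",
                                  paste(unknown, collapse = ", ")))
  has_syn <- !is.null(config$synthetic)
  has_real <- !is.null(config$inputs)
  if (has_syn == has_real)
    problems <- c(problems,
                  "exactly one of 'synthetic' or 'inputs' must be present")
  if (has_real) {
    req <- c("edge_list", "positives", "drug_targets")
    miss <- setdiff(req, names(config$inputs))
    if (length(miss) > 0L)
      problems <- c(problems, paste("inputs block missing:",
                                    paste(miss, collapse = ", ")))
    for (p in unlist(config$inputs))
      if (!file.exists(p))
        problems <- c(problems, paste("input file not found:", p))
  }
  if (!is.null(config$enrichment$gmt) && !file.exists(config$enrichment$gmt))
    problems <- c(problems,
                  paste("GMT file not found:", config$enrichment$gmt))
  if (length(problems) > 0L)
    stop("invalid pipeline config:\n  - ",
         paste(problems, collapse = "\n  - "))

  seed <- as.integer(config$seed %||% 1L)
  out <- list(
    seed = seed,
    outdir = config$outdir %||% "pin2target_out",
    synthetic = if (has_syn)
      do.call(synthetic_config,
              c(config$synthetic[setdiff(names(config$synthetic), "seed")],
                list(seed = seed))) else NULL,
    inputs = config$inputs,
    autoencoder = {
      ae <- config$autoencoder %||% list()
      list(profile = ae$profile %||% "desk",
           d_latent = as.integer(ae$d_latent %||% 100L),
           n_layers = as.integer(ae$n_layers %||% 7L),
           learning_rate = ae$learning_rate,
           epochs = if (!is.null(ae$epochs)) as.integer(ae$epochs),
           batch_size = if (!is.null(ae$batch_size)) as.integer(ae$batch_size))
    },
    prioritizer = {
      pr <- config$prioritizer %||% list()
      list(n_datasets = as.integer(pr$n_datasets %||% 100L),
           n_negatives = as.integer(pr$n_negatives %||% 500L),
           threshold = pr$threshold %||% 0.75,
           smote_k = as.integer(pr$smote_k %||% 2L),
           grid = do.call(grid_config, pr$grid %||% list()))
    },
    enrichment = {
      en <- config$enrichment %||% list()
      list(fdr_threshold = en$fdr_threshold %||% 0.05,
           gmt = en$gmt)
    })
  class(out) <- "pipeline_config"
  message("pipeline config validated: seed=", out$seed,
          ", outdir=", out$outdir,
          ", mode=", if (has_syn) "synthetic" else "real",
          ", d_latent=", out$autoencoder$d_latent,
          ", n_datasets=", out$prioritizer$n_datasets,
          ", threshold=", out$prioritizer$threshold)
  out
}

#' The desk-scale reduced hyperparameter grid
#'
#' Single-CPU profile used by the synthetic-recovery runs: learning_rate
#' {0.1, 0.5}, max_depth {2, 3}, gamma 0, reg_lambda 1, reg_alpha 0 (100
#' estimators, 5 folds). The full reference grid remains the
#' \code{\link{grid_config}} default.
#'
#' @return a \code{grid_config}.
#' @export
desk_grid <- function() {
  grid_config(learning_rate = c(0.1, 0.5), max_depth = c(2L, 3L),
              gamma = 0, reg_lambda = 1.0, reg_alpha = 0)
}

# artifact file names, fixed
.pipeline_files <- function(outdir) {
  list(edge_list = file.path(outdir, "pin_edges.tsv"),
       positives = file.path(outdir, "positives.txt"),
       drug_targets = file.path(outdir, "drug_targets.tsv"),
       gmt = file.path(outdir, "gene_sets.gmt"),
       graph_summary = file.path(outdir, "graph_summary.tsv"),
       latent = file.path(outdir, "latent_matrix.tsv"),
       loss_trace = file.path(outdir, "loss_trace.tsv"),
       metrics = file.path(outdir, "metric_table.tsv"),
       correlation = file.path(outdir, "latent_metric_correlation.tsv"),
       scores = file.path(outdir, "gene_scores.tsv"),
       putative = file.path(outdir, "putative_targets.txt"),
       repositioning = file.path(outdir, "repositioning.tsv"),
       enrichment = file.path(outdir, "enrichment.tsv"),
       manifest = file.path(outdir, "manifest.json"))
}

# resolve the three primary inputs for downstream stages
.pipeline_inputs <- function(config) {
  f <- .pipeline_files(config$outdir)
  if (!is.null(config$synthetic))
    list(edge_list = f$edge_list, positives = f$positives,
         drug_targets = f$drug_targets,
         gmt = config$enrichment$gmt %||% f$gmt)
  else
    list(edge_list = config$inputs$edge_list,
         positives = config$inputs$positives,
         drug_targets = config$inputs$drug_targets,
         gmt = config$enrichment$gmt %||% config$inputs$gmt)
}

#' Run one pipeline stage
#'
#' Stages: \code{simulate} (synthetic inputs), \code{embed} (autoencoder
#' latent matrix), \code{metrics} (nine-metric table + latent correlation),
#' \code{prioritize} (ensemble scores + putative set), \code{reposition}
#' (drug overlap ranking), \code{enrich} (pathway ORA). Each stage reads its
#' upstream artifacts from the output directory, so stages re-run
#' individually byte-match a full pipeline run with the same config.
#'
#' @param stage stage name.
#' @param config a \code{pipeline_config}.
#' @return invisibly, a list of the stage's outputs.
#' @export
run_stage <- function(stage, config) {
  stopifnot(inherits(config, "pipeline_config"))
  f <- .pipeline_files(config$outdir)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  inp <- .pipeline_inputs(config)
  seed <- config$seed
  switch(stage,
    simulate = {
      if (is.null(config$synthetic))
        stop("simulate stage requires a synthetic config block")
      scfg <- config$synthetic
      g0 <- generate_pin(scfg)
      planted <- plant_positives(g0, scfg)
      write_edge_list(planted$graph, f$edge_list)
      write_gene_list(planted$positives, f$positives)
      dmap <- generate_drug_target_map(planted$graph, planted$positives, scfg,
                                       neighborhood = planted$neighborhood)
      write_drug_target_table(dmap, f$drug_targets)
      sets <- generate_gene_sets(planted$graph, planted$positives, scfg)
      write_gmt(sets, f$gmt)
      g <- planted$graph
      utils::write.table(
        data.frame(n_genes = length(g$nodes), n_edges = nrow(g$edges),
                   n_duplicates_dropped = g$report$n_duplicates_dropped,
                   n_self_loops_dropped = g$report$n_self_loops_dropped),
        f$graph_summary, sep = "\t", quote = FALSE, row.names = FALSE)
      invisible(list(graph = g, positives = planted$positives))
    },
    embed = {
      g <- read_edge_list(inp$edge_list)
      if (is.null(config$synthetic)) {
        utils::write.table(
          data.frame(n_genes = length(g$nodes), n_edges = nrow(g$edges),
                     n_duplicates_dropped = g$report$n_duplicates_dropped,
                     n_self_loops_dropped = g$report$n_self_loops_dropped),
          f$graph_summary, sep = "\t", quote = FALSE, row.names = FALSE)
      }
      adj <- to_adjacency(g)
      ae <- config$autoencoder
      sizes <- make_layer_pyramid(ncol(adj), ae$d_latent, ae$n_layers)
      acfg <- autoencoder_config(sizes, profile = ae$profile,
                                 learning_rate = ae$learning_rate,
                                 epochs = ae$epochs,
                                 batch_size = ae$batch_size,
                                 seed = seed + 10L)
      model <- train_autoencoder(adj, acfg)
      latent <- encode(model, adj)
      write_latent_matrix(latent, f$latent)
      utils::write.table(
        data.frame(epoch = seq_along(model$loss_trace),
                   loss = model$loss_trace),
        f$loss_trace, sep = "\t", quote = FALSE, row.names = FALSE)
      invisible(list(model = model, latent = latent))
    },
    metrics = {
      g <- read_edge_list(inp$edge_list)
      latent <- read_latent_matrix(f$latent)
      metrics <- assemble_metric_table(g)
      write_metric_table(metrics, f$metrics)
      corr <- correlate_latent_metrics(latent[metrics$gene, , drop = FALSE],
                                       metrics)
      write_correlation_matrix(corr, f$correlation)
      invisible(list(metrics = metrics, correlation = corr))
    },
    prioritize = {
      g <- read_edge_list(inp$edge_list)
      latent <- read_latent_matrix(f$latent)
      positives <- map_genes_to_pin(read_gene_list(inp$positives), g)
      pr <- config$prioritizer
      datasets <- build_datasets(latent, positives,
                                 n_datasets = pr$n_datasets,
                                 n_negatives = pr$n_negatives,
                                 seed = seed + 20L)
      ensemble <- fit_ensemble(datasets, pr$grid, seed = seed + 30L,
                               smote_k = pr$smote_k)
      message(sprintf("prioritize: mean CV AUC %.3f over %d datasets",
                      ensemble$mean_cv_auc, length(datasets)))
      scores <- score_genes(ensemble, latent, positives)
      write_gene_scores(scores, f$scores)
      putative <- suppressWarnings(select_putative(scores, pr$threshold))
      write_gene_list(names(putative), f$putative)
      invisible(list(ensemble = ensemble, scores = scores,
                     putative = putative))
    },
    reposition = {
      dmap <- read_drug_target_table(inp$drug_targets)
      putative <- read_gene_list(f$putative)
      tbl <- suppressWarnings(infer_candidates(dmap, putative))
      if (nrow(tbl) > 0L) write_repositioning_report(tbl, f$repositioning)
      else writeLines("drug\toverlap_genes\tn_overlap\trank",
                      f$repositioning)
      invisible(list(repositioning = tbl))
    },
    enrich = {
      g <- read_edge_list(inp$edge_list)
      putative <- read_gene_list(f$putative)
      collection <- read_gmt(inp$gmt)
      tbl <- enrich(intersect(putative, g$nodes), collection, g$nodes,
                    fdr_threshold = config$enrichment$fdr_threshold)
      write_enrichment_table(tbl, f$enrichment)
      invisible(list(enrichment = tbl))
    },
    stop("unknown pipeline stage: ", stage))
}

#' Run the full pipeline
#'
#' Executes simulate (when configured), embed, metrics, prioritize,
#' reposition and enrich in order, writing all artifacts plus a
#' reproducibility manifest (config echo, seed, package versions, per-stage
#' wall times) into the output directory. Identical config + seed reruns
#' produce byte-identical ranked-score and repositioning files.
#'
#' @param config a \code{pipeline_config} (or path / list accepted by
#'   \code{\link{validate_config}}).
#' @return invisibly, the output directory path.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  f <- .pipeline_files(config$outdir)
  stages <- c(if (!is.null(config$synthetic)) "simulate",
              "embed", "metrics", "prioritize", "reposition", "enrich")
  timings <- numeric(0)
  for (st in stages) {
    message("== pipeline stage: ", st)
    t0 <- proc.time()[["elapsed"]]
    tryCatch(run_stage(st, config), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", st, conditionMessage(e)),
           call. = FALSE))
    timings[st] <- round(proc.time()[["elapsed"]] - t0, 3)
  }
  manifest <- list(
    package = "pin2target",
    version = as.character(utils::packageVersion("pin2target")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config = unclass(config)[c("seed", "outdir")],
    synthetic = if (!is.null(config$synthetic)) unclass(config$synthetic),
    autoencoder = config$autoencoder,
    prioritizer = list(n_datasets = config$prioritizer$n_datasets,
                       n_negatives = config$prioritizer$n_negatives,
                       threshold = config$prioritizer$threshold,
                       smote_k = config$prioritizer$smote_k,
                       grid = config$prioritizer$grid$grid),
    stage_seconds = as.list(timings),
    artifacts = unname(unlist(f)))
  jsonlite::write_json(manifest, f$manifest, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(config$outdir)
}

#' Command-line entry point
#'
#' Implements \code{pin2target <run|simulate|embed|metrics|prioritize|
#' reposition|enrich> -c config.json [--seed S] [--outdir DIR]
#' [--profile desk|paper]}. Installed as \code{exec/pin2target}.
#'
#' @param args character vector of CLI arguments (default
#'   \code{commandArgs(trailingOnly = TRUE)}).
#' @return invisibly, the output directory.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: pin2target <run|simulate|embed|metrics|prioritize|reposition|enrich>",
    "-c CONFIG.json [--seed S] [--outdir DIR] [--profile desk|paper]")
  if (length(args) < 1L) stop(usage, call. = FALSE)
  cmd <- args[1L]; args <- args[-1L]
  opt <- list(config = NULL, seed = NULL, outdir = NULL, profile = NULL)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    take <- function() { i <<- i + 1L; args[i] }
    switch(a,
      "-c" = , "--config" = { opt$config <- take() },
      "--seed" = { opt$seed <- as.integer(take()) },
      "--outdir" = { opt$outdir <- take() },
      "--profile" = { opt$profile <- take() },
      stop("unknown argument: ", a, "\n", usage, call. = FALSE))
    i <- i + 1L
  }
  if (is.null(opt$config)) stop("missing -c CONFIG.json\n", usage,
                                call. = FALSE)
  raw <- jsonlite::read_json(opt$config, simplifyVector = TRUE)
  if (!is.null(opt$seed)) raw$seed <- opt$seed
  if (!is.null(opt$outdir)) raw$outdir <- opt$outdir
  if (!is.null(opt$profile)) {
    if (is.null(raw$autoencoder)) raw$autoencoder <- list()
    raw$autoencoder$profile <- opt$profile
  }
  config <- validate_config(raw)
  if (cmd == "run") run_pipeline(config)
  else run_stage(cmd, config)
  invisible(config$outdir)
}
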