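# Orchestration: simulate/load -> preprocess -> detect -> consensus ->
# network, with a reproducible run manifest. One experiment = one
# treated arm with its time-matched controls; a run holds one or two
# experiments (e.g. SB-like and SU-like) and, if both are present and an
# edge table is given, builds the merged network and its crosstalk
# subnetwork.

#' Per-experiment pipeline settings
#'
#' @param treatment treated arm label (`"SB"` or `"SU"`).
#' @param counts,sample_sheet TSV paths (ignored when `simulate` given).
#' @param simulate optional [sim_config()] generating this experiment's
#'   data in place of files.
#' @param alpha,lambda,k_min_tools,use_adjusted,control_gene consensus
#'   settings, see [consensus_config()]; `lambda = "auto"` anchors the
#'   threshold on `control_gene` via [calibrate_lfc_threshold()].
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(treatment, counts = NULL, sample_sheet = NULL,
                              simulate = NULL, alpha = 0.05, lambda = 0.5,
                              k_min_tools = 3L, use_adjusted = TRUE,
                              control_gene = NULL) {
  if (is.null(simulate)) {
    if (is.null(counts) || is.null(sample_sheet)) {
      stopf("experiment %s: give either simulate or counts + sample_sheet", treatment)
    }
  } else if (!inherits(simulate, "sim_config")) {
    stopf("simulate must be a sim_config()")
  }
  auto <- identical(lambda, "auto")
  if (auto && is.null(control_gene)) {
    stopf("lambda = 'auto' needs a control_gene")
  }
  cc <- consensus_config(alpha = alpha, lambda = if (auto) 0 else lambda,
                         k_min_tools = k_min_tools,
                         use_adjusted = use_adjusted,
                         control_gene = control_gene)
  structure(list(treatment = treatment, counts = counts,
                 sample_sheet = sample_sheet, simulate = simulate,
                 consensus = cc, auto_lambda = auto),
            class = "experiment_config")
}

#' Whole-run pipeline settings
#'
#' @param out_dir output directory (created; must not be an existing
#'   non-empty run unless `overwrite`).
#' @param experiments named list of [experiment_config()]s (1 or 2).
#' @param edge_file optional STRING-dialect edge TSV enabling the
#'   network stage.
#' @param min_score edge score cutoff (default 400).
#' @param min_cpm expression pre-filter floor (default 1).
#' @param seed integer seed recorded in the manifest and used for any
#'   simulation whose own seed is unset.
#' @param overwrite allow writing into an existing directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, experiments, edge_file = NULL,
                            min_score = 400, min_cpm = 1, seed = 1L,
                            overwrite = FALSE) {
  if (!length(experiments) || length(experiments) > 2L) {
    stopf("need one or two experiments")
  }
  if (is.null(names(experiments)) || any(!nzchar(names(experiments)))) {
    stopf("experiments must be a named list")
  }
  for (e in experiments) {
    if (!inherits(e, "experiment_config")) stopf("experiments must come from experiment_config()")
    for (p in c(e$counts, e$sample_sheet)) {
      if (!is.null(p) && !file.exists(p)) stopf("input file missing: %s", p)
    }
  }
  if (!is.null(edge_file) && !file.exists(edge_file)) {
    stopf("edge file missing: %s", edge_file)
  }
  structure(list(out_dir = out_dir, experiments = experiments,
                 edge_file = edge_file, min_score = min_score,
                 min_cpm = min_cpm, seed = as.integer(seed),
                 overwrite = isTRUE(overwrite)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipeline_config()] arguments; each entry of
#' `experiments:` mirrors [experiment_config()], with an optional
#' `simulate:` block of [sim_config()] arguments.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  exps <- lapply(y$experiments, function(e) {
    if (!is.null(e$simulate)) e$simulate <- do.call(sim_config, e$simulate)
    do.call(experiment_config, e)
  })
  pipeline_config(out_dir = y$out_dir, experiments = exps,
                  edge_file = y$edge_file, min_score = y$min_score %||% 400,
                  min_cpm = y$min_cpm %||% 1, seed = y$seed %||% 1L,
                  overwrite = y$overwrite %||% FALSE)
}

run_stage <- function(stage, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    try(writeLines(conditionMessage(e),
                   file.path(out_dir, sprintf("failed_%s.marker", stage))),
        silent = TRUE)
    stopf("stage %s failed: %s", stage, conditionMessage(e))
  })
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(rapply(unclass(config), unclass, how = "replace"),
                              auto_unbox = TRUE, digits = NA, force = TRUE,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Stages: validate, data (simulate or load), preprocess (filter + LFC),
#' detect (all four detectors), consensus, network (when an edge table
#' and two experiments are present), manifest. Every stage writes its
#' outputs under `out_dir`; a failing stage leaves a
#' `failed_<stage>.marker` file and aborts with a stage-named error.
#'
#' @param config a [pipeline_config()] or a YAML path.
#' @return the run manifest (list), invisibly written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) stopf("config must come from pipeline_config()")
  out <- config$out_dir
  if (dir.exists(out) && length(dir(out)) && !config$overwrite) {
    stopf("output directory %s exists and is non-empty", out)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(package = "tcensemble",
                   version = as.character(utils::packageVersion("tcensemble")),
                   seed = config$seed,
                   config_hash = config_hash(config),
                   stages = list())
  exp_data <- list()

  run_stage("data", out, {
    for (nm in names(config$experiments)) {
      e <- config$experiments[[nm]]
      if (!is.null(e$simulate)) {
        sim <- simulate_experiment(e$simulate)
        write_simulation(sim, file.path(out, paste0("sim_", nm)))
        exp_data[[nm]] <- list(counts = sim$counts, sheet = sim$sample_sheet,
                               truth = sim$truth)
      } else {
        counts <- read_counts(e$counts)
        sheet <- read_sample_sheet(e$sample_sheet, counts)
        exp_data[[nm]] <- list(counts = counts, sheet = sheet, truth = NULL)
      }
      manifest$stages$data[[nm]] <- list(n_genes = nrow(exp_data[[nm]]$counts),
                                         n_samples = ncol(exp_data[[nm]]$counts))
    }
  })

  lfc_tables <- list()
  run_stage("preprocess", out, {
    for (nm in names(exp_data)) {
      d <- exp_data[[nm]]
      d$counts <- filter_low_expression(d$counts, min_cpm = config$min_cpm)
      lfc_tables[[nm]] <- lfc_vs_control(d$counts, d$sheet,
                                         config$experiments[[nm]]$treatment)
      write_lfc_table(lfc_tables[[nm]], file.path(out, sprintf("lfc_%s.tsv", nm)))
      exp_data[[nm]] <- d
      manifest$stages$preprocess[[nm]] <- list(n_genes_kept = nrow(d$counts))
    }
  })

  det_results <- list()
  run_stage("detect", out, {
    for (nm in names(exp_data)) {
      d <- exp_data[[nm]]
      res <- run_detectors(d$counts, d$sheet, config$experiments[[nm]]$treatment)
      det_results[[nm]] <- res
      wide <- Reduce(function(a, b) merge(a, b, by = "gene_id"),
                     lapply(res, function(r) {
                       out_r <- r[, c("gene_id", "statistic", "p_raw", "p_adj")]
                       names(out_r)[-1L] <- paste(r$detector_name[1L],
                                                  names(out_r)[-1L], sep = "_")
                       out_r
                     }))
      utils::write.table(wide[order(wide$gene_id), ],
                         file.path(out, sprintf("detectors_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$detect[[nm]] <-
        lapply(res, function(r) sum(r$p_adj < config$experiments[[nm]]$consensus$alpha))
    }
  })

  calls <- list()
  run_stage("consensus", out, {
    for (nm in names(exp_data)) {
      e <- config$experiments[[nm]]
      cc <- e$consensus
      if (e$auto_lambda) {
        cc$lambda <- as.numeric(calibrate_lfc_threshold(lfc_tables[[nm]],
                                                        cc$control_gene))
      }
      calls[[nm]] <- consensus_calls(det_results[[nm]], lfc_tables[[nm]], cc)
      utils::write.table(calls[[nm]], file.path(out, sprintf("consensus_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ov <- overlap_summary(attr(calls[[nm]], "tool_sets"))
      utils::write.table(ov, file.path(out, sprintf("overlap_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$consensus[[nm]] <- list(lambda = cc$lambda,
                                              n_candidates = nrow(calls[[nm]]))
    }
  })

  if (!is.null(config$edge_file)) run_stage("network", out, {
    edges <- load_edges(config$edge_file, config$min_score)
    nets <- list()
    for (nm in names(calls)) {
      if (!nrow(calls[[nm]])) { warnf("no candidates for %s; network skipped", nm); next }
      e <- config$experiments[[nm]]
      lam <- manifest$stages$consensus[[nm]]$lambda
      net <- build_subnetwork(calls[[nm]]$gene_id, edges, experiment = nm)
      net <- annotate_first_de(net, lfc_tables[[nm]], lam)
      nets[[nm]] <- net
      write_graphml(net, file.path(out, sprintf("network_%s.graphml", nm)))
      manifest$stages$network[[nm]] <- list(n_nodes = nrow(net$nodes),
                                            n_edges = nrow(net$edges),
                                            coverage = attr(net, "coverage"))
    }
    if (length(nets) == 2L) {
      merged <- merge_networks(nets[[1L]], nets[[2L]])
      write_graphml(merged, file.path(out, "network_merged.graphml"))
      shared <- intersect(calls[[1L]]$gene_id, calls[[2L]]$gene_id)
      cross <- extract_crosstalk(merged, shared)
      write_graphml(cross, file.path(out, "network_crosstalk.graphml"))
      if (length(shared)) {
        lam1 <- manifest$stages$consensus[[names(calls)[1L]]]$lambda
        lam2 <- manifest$stages$consensus[[names(calls)[2L]]]$lambda
        cls <- vapply(shared, function(g) {
          classify_direction(
            lfc_matrix(lfc_tables[[1L]])[g, ],
            lfc_matrix(lfc_tables[[2L]])[g, ], lam1, lam2)
        }, "")
        utils::write.table(
          data.frame(gene_id = shared, concordance = cls,
                     stringsAsFactors = FALSE),
          file.path(out, "crosstalk_concordance.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
      manifest$stages$network$merged <- list(n_nodes = nrow(merged$nodes),
                                             n_shared_targets = length(shared),
                                             n_crosstalk_nodes = nrow(cross$nodes))
    }
  })

  run_stage("manifest", out, {
    files <- sort(setdiff(dir(out, recursive = TRUE), "manifest.json"))
    md5 <- tools::md5sum(file.path(out, files))
    manifest$outputs <- stats::setNames(unname(md5), files)
    tmp <- tempfile()
    writeLines(unname(md5), tmp)
    manifest$run_hash <- unname(tools::md5sum(tmp))
    unlink(tmp)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  invisible(manifest)
}

#' Summary tables for a completed run
#'
#' Builds a heatmap-ready LFC matrix for the run's candidate genes
#' (common genes when two experiments are present), sorted by maximal
#' downregulation at the earliest timepoint of the first experiment
#' (most negative LFC first, ties broken by gene id), plus the overlap
#' region counts and, when present, the crosstalk node/edge lists.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return list of data.frames (`heatmap`, `overlap`, `crosstalk_nodes`,
#'   `crosstalk_edges`), also written under `run_dir/report/`.
#' @export
make_report <- function(run_dir) {
  man_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(man_path)) stopf("no manifest.json in %s: not a completed run", run_dir)
  cons_files <- dir(run_dir, pattern = "^consensus_.*\\.tsv$", full.names = TRUE)
  exps <- sub("^consensus_(.*)\\.tsv$", "\\1", basename(cons_files))
  calls <- lapply(cons_files, utils::read.delim, stringsAsFactors = FALSE)
  names(calls) <- exps
  lfcs <- lapply(exps, function(nm) {
    utils::read.delim(file.path(run_dir, sprintf("lfc_%s.tsv", nm)),
                      stringsAsFactors = FALSE)
  })
  names(lfcs) <- exps
  genes <- if (length(exps) >= 2L) {
    Reduce(intersect, lapply(calls, function(x) x$gene_id))
  } else calls[[1L]]$gene_id
  heat <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (nm in exps) {
    m <- lfc_matrix(lfcs[[nm]])
    idx <- match(genes, rownames(m))
    for (j in colnames(m)) heat[[paste(nm, sub("^lfc_", "", j), sep = "_")]] <- m[idx, j]
  }
  if (nrow(heat)) {
    first_col <- names(heat)[2L]
    heat <- heat[order(heat[[first_col]], heat$gene_id), , drop = FALSE]
    rownames(heat) <- NULL
  }
  ov_files <- dir(run_dir, pattern = "^overlap_.*\\.tsv$", full.names = TRUE)
  overlap <- do.call(rbind, lapply(ov_files, function(f) {
    d <- utils::read.delim(f, stringsAsFactors = FALSE)
    d$experiment <- sub("^overlap_(.*)\\.tsv$", "\\1", basename(f))
    d
  }))
  report <- list(heatmap = heat, overlap = overlap)
  cn <- file.path(run_dir, "network_crosstalk.graphml.nodes.tsv")
  if (file.exists(cn)) {
    report$crosstalk_nodes <- utils::read.delim(cn, stringsAsFactors = FALSE)
    report$crosstalk_edges <- utils::read.delim(
      file.path(run_dir, "network_crosstalk.graphml.edges.tsv"),
      stringsAsFactors = FALSE)
  }
  rep_dir <- file.path(run_dir, "report")
  dir.create(rep_dir, showWarnings = FALSE)
  for (nm in names(report)) {
    if (!is.null(report[[nm]])) {
      utils::write.table(report[[nm]], file.path(rep_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  report
}
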