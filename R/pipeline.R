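#' Assemble a pipeline configuration
#'
#' Thresholds default to the study's conventions: detection p < 0.01 on at
#' least 2 chips of one tissue x state group, overall state effect p < 0.05,
#' within-tissue simple effect p < 0.01, tendency p < 0.05 for pattern coding,
#' panel positive-test p < 0.01.
#'
#' @param seed root seed for the simulate stage
#' @param simulate a [simulation_config()], or NULL to read the inputs below
#' @param inputs named list of file paths (\code{design}, \code{expression},
#'   \code{exons}, \code{annotation}, \code{gene_sets}); ignored when
#'   \code{simulate} is given
#' @param alpha_dabg,min_chips,expressed_mode detection-filter settings
#' @param alpha_state,alpha_simple,alpha_tendency significance thresholds
#' @param panel_cutoff within-tissue p cutoff for panel positive tests
#' @param q_mode \code{"as_stated"} or \code{"step_up"}
#' @param min_mean_log2,top_k reference-gene candidate settings
#' @return list of class \code{pipeline_config}
#' @export
pipeline_config <- function(seed = 1L, simulate = simulation_config(seed = seed),
                            inputs = NULL,
                            alpha_dabg = 0.01, min_chips = 2,
                            expressed_mode = "same_exon",
                            alpha_state = 0.05, alpha_simple = 0.01,
                            alpha_tendency = 0.05, panel_cutoff = 0.01,
                            q_mode = "as_stated",
                            min_mean_log2 = 10, top_k = 20) {
  for (a in c(alpha_dabg, alpha_state, alpha_simple, alpha_tendency,
              panel_cutoff)) {
    if (a <= 0 || a >= 1) stop("config_bad_threshold: thresholds must lie in (0,1)",
                               call. = FALSE)
  }
  structure(list(seed = as.integer(seed), simulate = simulate, inputs = inputs,
                 alpha_dabg = alpha_dabg, min_chips = min_chips,
                 expressed_mode = expressed_mode,
                 alpha_state = alpha_state, alpha_simple = alpha_simple,
                 alpha_tendency = alpha_tendency, panel_cutoff = panel_cutoff,
                 q_mode = q_mode, min_mean_log2 = min_mean_log2, top_k = top_k),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the arguments of [pipeline_config()];
#' a \code{simulate:} mapping is passed to [simulation_config()], and an
#' \code{inputs:} mapping replaces simulation with files on disk.
#'
#' @param path YAML file
#' @param seed optional override of the file's seed
#' @return a \code{pipeline_config}
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- seed
  if (is.null(y$seed)) y$seed <- 1L
  sim <- NULL
  if (!is.null(y$simulate)) {
    sim_args <- y$simulate
    if (!is.null(sim_args$pattern_table)) {
      sim_args$pattern_table <- lapply(sim_args$pattern_table, function(e) {
        list(pattern = as.integer(e$pattern), effect = e$effect,
             fraction = e$fraction)
      })
    }
    sim_args$seed <- y$seed
    sim <- do.call(simulation_config, sim_args)
  }
  args <- y[setdiff(names(y), c("simulate", "inputs"))]
  args$simulate <- sim
  args$inputs <- y$inputs
  do.call(pipeline_config, args)
}

pipeline_paths <- function(dir) {
  list(design = file.path(dir, "design.tsv"),
       expression = file.path(dir, "expression.tsv"),
       exons = file.path(dir, "exon_detection.tsv"),
       annotation = file.path(dir, "annotation.tsv"),
       gene_sets = file.path(dir, "gene_sets.gmt"),
       truth_genes = file.path(dir, "truth_genes.tsv"),
       truth_sets = file.path(dir, "truth_sets.tsv"),
       filter_report = file.path(dir, "filter_report.tsv"),
       tested_expression = file.path(dir, "tested_expression.tsv"),
       anova = file.path(dir, "anova_results.tsv"),
       de_calls = file.path(dir, "de_calls.tsv"),
       pfp = file.path(dir, "pfp_summary.tsv"),
       q_values = file.path(dir, "q_values.tsv"),
       patterns = file.path(dir, "patterns.tsv"),
       enrichment = file.path(dir, "enrichment.tsv"),
       stability = file.path(dir, "refgene_stability.tsv"),
       norm_const = file.path(dir, "normalization_constants.tsv"),
       manifest = file.path(dir, "manifest.json"))
}

stage_fail <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' @rdname run_pipeline
#' @export
stage_simulate <- function(config, dir) {
  p <- pipeline_paths(dir)
  stage_fail("simulate", {
    if (is.null(config$simulate)) stop("no simulate block in the config")
    sim <- simulate_study(config$simulate)
    write_design(sim$design, p$design)
    write_expression(sim$expression, p$expression)
    write_results_table(sim$exons, p$exons)
    write_results_table(sim$annotation, p$annotation)
    write_gmt(sim$gene_sets, p$gene_sets)
    write_results_table(sim$truth$genes, p$truth_genes)
    write_results_table(sim$truth$sets, p$truth_sets)
    invisible(sim)
  })
}

pipeline_inputs <- function(config, dir) {
  p <- pipeline_paths(dir)
  if (is.null(config$simulate)) {
    if (is.null(config$inputs)) {
      stop("no simulate block and no inputs block in the config")
    }
    for (nm in c("design", "expression", "exons", "annotation")) {
      if (is.null(config$inputs[[nm]]) || !file.exists(config$inputs[[nm]])) {
        stop("input file for '", nm, "' is missing")
      }
      p[[nm]] <- config$inputs[[nm]]
    }
    if (!is.null(config$inputs$gene_sets)) p$gene_sets <- config$inputs$gene_sets
  }
  p
}

#' @rdname run_pipeline
#' @export
stage_filter <- function(config, dir) {
  stage_fail("filter", {
    p <- pipeline_inputs(config, dir)
    out <- pipeline_paths(dir)
    design <- read_design(p$design)
    expr <- read_expression(p$expression, design)
    exons <- read_exon_detection(p$exons, design)
    annot <- read_annotation(p$annotation)
    calls <- call_presence(exons, config$alpha_dabg)
    expressed <- gene_expressed(calls, design, config$min_chips,
                                mode = config$expressed_mode)
    annotated <- gene_annotated(annot, genes = rownames(expr))
    report <- gene_filter_report(rownames(expr), expressed, annotated)
    write_results_table(report, out$filter_report)
    tested <- select_tested_genes(expr, report)
    write_expression(tested, out$tested_expression)
    invisible(report)
  })
}

#' @rdname run_pipeline
#' @export
stage_anova <- function(config, dir) {
  stage_fail("anova", {
    p <- pipeline_inputs(config, dir)
    out <- pipeline_paths(dir)
    design <- read_design(p$design)
    expr <- read_expression(out$tested_expression, design)
    fit <- splitplot_fit(expr, design)
    write_results_table(fit$results, out$anova)
    invisible(fit)
  })
}

read_anova_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname run_pipeline
#' @export
stage_calls <- function(config, dir) {
  stage_fail("calls", {
    out <- pipeline_paths(dir)
    results <- read_anova_results(out$anova)
    calls <- call_de(results, config$alpha_state, config$alpha_simple,
                     config$alpha_tendency)
    write_results_table(calls, out$de_calls)
    write_results_table(pfp_summary(results,
                                    alphas_state = c(config$alpha_state, 0.01),
                                    alpha_simple = config$alpha_simple),
                        out$pfp)
    qtab <- data.frame(gene = results$gene,
                       q_state = q_values(results$p_state, config$q_mode),
                       q_interaction = q_values(results$p_interaction,
                                                config$q_mode))
    write_results_table(qtab, out$q_values)
    invisible(calls)
  })
}

#' @rdname run_pipeline
#' @export
stage_patterns <- function(config, dir) {
  stage_fail("patterns", {
    out <- pipeline_paths(dir)
    results <- read_anova_results(out$anova)
    calls <- utils::read.delim(out$de_calls, stringsAsFactors = FALSE)
    codes <- pattern_code(calls, results)
    tissues <- sub("^change_", "", grep("^change_", names(codes), value = TRUE))
    tab <- cbind(results[c("gene", "p_tissue", "p_state", "p_interaction",
                           paste0("p_simple_", tissues))],
                 pattern = codes$pattern,
                 results[paste0("ratio_", tissues)])
    write_results_table(tab, out$patterns)
    invisible(codes)
  })
}

#' @rdname run_pipeline
#' @export
stage_enrich <- function(config, dir) {
  stage_fail("enrich", {
    p <- pipeline_inputs(config, dir)
    out <- pipeline_paths(dir)
    results <- read_anova_results(out$anova)
    calls <- utils::read.delim(out$de_calls, stringsAsFactors = FALSE)
    sets <- read_gmt(p$gene_sets)
    enr <- enrich_collection(sets, calls$gene[calls$any_de], results$gene,
                             q_mode = config$q_mode)
    write_results_table(enr, out$enrichment)
    invisible(enr)
  })
}

#' @rdname run_pipeline
#' @export
stage_refgenes <- function(config, dir) {
  stage_fail("refgenes", {
    p <- pipeline_inputs(config, dir)
    out <- pipeline_paths(dir)
    design <- read_design(p$design)
    expr <- read_expression(out$tested_expression, design)
    cand <- candidate_genes(expr, config$min_mean_log2, config$top_k)
    scores <- stability_scores(expr[cand, , drop = FALSE], design)
    write_results_table(scores, out$stability)
    chosen <- scores$gene[scores$rank <= min(3, nrow(scores))]
    nc <- normalization_constant(expr, chosen)
    write_results_table(data.frame(sample = names(nc), constant = unname(nc),
                                   stringsAsFactors = FALSE),
                        out$norm_const)
    invisible(scores)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate (when the config has a \code{simulate} block) then
#' filter, anova, calls, patterns, enrich and refgenes, communicating only
#' through files under \code{dir}, and writes a JSON manifest recording the
#' seed, thresholds, per-stage row counts and output checksums. Identical
#' config and seed give byte-identical artifacts. Each stage can also be run
#' alone via its \code{stage_*} function; chained stages reproduce
#' \code{run_pipeline} exactly.
#'
#' @param config a [pipeline_config()] or path to a YAML file
#' @param dir output directory (created if needed)
#' @param seed optional seed override
#' @return invisibly, the manifest list
#' @export
run_pipeline <- function(config, dir, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config, seed = seed)
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    if (!is.null(config$simulate)) config$simulate$seed <- as.integer(seed)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- pipeline_paths(dir)
  counts <- list()
  log_stage <- function(stage, ...) {
    message("[", stage, "] ", ...)
  }
  if (!is.null(config$simulate)) {
    log_stage("simulate", "n_genes=", config$simulate$n_genes,
              " seed=", config$seed)
    sim <- stage_simulate(config, dir)
    counts$simulate <- nrow(sim$expression)
  }
  log_stage("filter", "alpha_dabg=", config$alpha_dabg,
            " min_chips=", config$min_chips)
  report <- stage_filter(config, dir)
  counts$filter_tested <- sum(report$tested)
  log_stage("anova", counts$filter_tested, " genes")
  fit <- stage_anova(config, dir)
  counts$anova <- nrow(fit$results)
  log_stage("calls", "alpha_state=", config$alpha_state,
            " alpha_simple=", config$alpha_simple)
  calls <- stage_calls(config, dir)
  counts$de_any <- sum(calls$any_de)
  log_stage("patterns", "")
  codes <- stage_patterns(config, dir)
  counts$patterns_nonzero <- sum(codes$pattern != 0)
  if (file.exists(pipeline_inputs(config, dir)$gene_sets)) {
    log_stage("enrich", "")
    enr <- stage_enrich(config, dir)
    counts$enrichment_sets <- nrow(enr)
  }
  log_stage("refgenes", "top_k=", config$top_k)
  scores <- stage_refgenes(config, dir)
  counts$refgene_candidates <- nrow(scores)

  artifacts <- Filter(file.exists, unlist(p[names(p) != "manifest"]))
  manifest <- list(seed = config$seed,
                   thresholds = config[c("alpha_dabg", "min_chips",
                                         "alpha_state", "alpha_simple",
                                         "alpha_tendency", "panel_cutoff",
                                         "q_mode")],
                   counts = counts,
                   checksums = as.list(tools::md5sum(artifacts)))
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
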