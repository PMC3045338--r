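#' Configuration for a synthetic multi-tissue lactation study
#'
#' Parameterizes the generative model the analysis assumes: per gene,
#' \deqn{y_{tsp} = \mu_g + a_{gt} + d_{gt} 1[s = treated] + \pi_{g,(s,p)} + \epsilon}
#' with a subject (pool) effect \eqn{\pi} shared across all tissues of a
#' subject — exactly compound symmetry — and independent residual noise.
#' Defaults mirror the rat lactation study's layout: 4 tissues (liver,
#' duodenum, jejunum, ileum) x 2 physiologic states (control, lactating) x 4
#' pools per state = 32 chips. The default gene count is 2,000 for quick
#' runs; \code{paper_scale = TRUE} switches to 19,434 genes with
#' absent/unannotated fractions sized so roughly 14,129 survive filtering.
#'
#' @param seed integer root seed; every table draws from a named substream
#'   derived from it, so adding a table never perturbs another's draws
#' @param n_genes number of genes
#' @param tissues tissue levels (first = heaviest pattern weight)
#' @param states the two physiologic states (second = treated)
#' @param n_pools pools per state
#' @param sigma_pool subject (pool) SD, log2 units
#' @param sigma_resid residual SD, log2 units
#' @param baseline_mean,baseline_sd per-gene baseline log2 level
#' @param tissue_effect_sd SD of per-gene fixed tissue effects (log2)
#' @param pattern_table list of lists, each with \code{pattern} (integer
#'   vector in \{-1,0,1\} over tissues), \code{effect} (log2 shift applied in
#'   the treated state, signed by the pattern) and \code{fraction} of genes
#' @param absent_fraction fraction of genes forced undetected on all chips
#' @param unannotated_fraction fraction (disjoint from absent) given the
#'   "---" description
#' @param exons_per_gene exons simulated per gene
#' @param dabg_present_miss_rate probability an exon of an expressed gene
#'   fails detection on a chip
#' @param n_gene_sets,set_size gene-set collection dimensions
#' @param planted_enrichment_factor sampling weight multiplier on truly-DE
#'   genes for the first (planted) set; remaining sets draw uniformly
#' @param paper_scale if TRUE, use the full study's gene count
#' @return list of class \code{simulation_config}
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 2000L,
                              tissues = c("liver", "duodenum", "jejunum", "ileum"),
                              states = c("control", "lactating"),
                              n_pools = 4L,
                              sigma_pool = 0.3,
                              sigma_resid = 0.3,
                              baseline_mean = 7,
                              baseline_sd = 1.5,
                              tissue_effect_sd = 1,
                              pattern_table = NULL,
                              absent_fraction = 0.2,
                              unannotated_fraction = 0.073,
                              exons_per_gene = 4L,
                              dabg_present_miss_rate = 0.1,
                              n_gene_sets = 10L,
                              set_size = 30L,
                              planted_enrichment_factor = 5,
                              paper_scale = FALSE) {
  if (paper_scale) n_genes <- 19434L
  T_ <- length(tissues)
  if (is.null(pattern_table)) {
    up <- rep(1L, T_); dn <- -up
    si_up <- c(0L, rep(1L, T_ - 1L)); si_dn <- -si_up
    liver_up <- c(1L, rep(0L, T_ - 1L))
    duod_dn <- c(0L, -1L, rep(0L, T_ - 2L))
    pattern_table <- list(
      list(pattern = up, effect = 1.0, fraction = 0.02),
      list(pattern = dn, effect = 1.0, fraction = 0.02),
      list(pattern = si_up, effect = 1.0, fraction = 0.01),
      list(pattern = si_dn, effect = 1.0, fraction = 0.01),
      list(pattern = liver_up, effect = 1.0, fraction = 0.02),
      list(pattern = -liver_up, effect = 1.0, fraction = 0.02),
      list(pattern = duod_dn, effect = 1.0, fraction = 0.01))
  }
  fr <- sum(vapply(pattern_table, `[[`, 0, "fraction"))
  if (fr + absent_fraction + unannotated_fraction > 1) {
    stop("config_fractions: pattern, absent and unannotated fractions exceed 1",
         call. = FALSE)
  }
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              tissues = tissues, states = states, n_pools = as.integer(n_pools),
              sigma_pool = sigma_pool, sigma_resid = sigma_resid,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              tissue_effect_sd = tissue_effect_sd,
              pattern_table = pattern_table,
              absent_fraction = absent_fraction,
              unannotated_fraction = unannotated_fraction,
              exons_per_gene = as.integer(exons_per_gene),
              dabg_present_miss_rate = dabg_present_miss_rate,
              n_gene_sets = as.integer(n_gene_sets),
              set_size = as.integer(set_size),
              planted_enrichment_factor = planted_enrichment_factor)
  class(cfg) <- "simulation_config"
  cfg
}

# deterministic per-table seed derived from the root seed and a stream name
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Generate a complete synthetic study with ground truth
#'
#' Emits every table the pipeline consumes — expression matrix, exon
#' detection p-values, annotations, gene sets — plus a truth ledger recording
#' each gene's planted cross-tissue pattern and filter status. Detection
#' p-values of genes marked absent are guaranteed not to satisfy the
#' presence filter, and expressed genes are guaranteed to satisfy it, so the
#' ledger and the emitted tables agree by construction. Fully reproducible
#' from the config's seed.
#'
#' @param config a [simulation_config()]
#' @return list with elements \code{design}, \code{expression},
#'   \code{exons}, \code{annotation}, \code{gene_sets}, \code{truth} (a list
#'   with \code{genes} and \code{sets} data.frames), \code{config}
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  tissues <- config$tissues; states <- config$states
  T_ <- length(tissues); P_ <- config$n_pools; G <- config$n_genes

  grid <- expand.grid(pool = seq_len(P_), state = states, tissue = tissues,
                      stringsAsFactors = FALSE)
  grid$sample <- sprintf("%s_%s_p%d",
                         substr(grid$tissue, 1, 3), substr(grid$state, 1, 4),
                         grid$pool)
  design <- study_design(grid[, c("sample", "tissue", "state", "pool")],
                         tissues = tissues, states = states)
  N <- nrow(design)
  genes <- sprintf("g%05d", seq_len(G))

  # --- gene-role assignment -------------------------------------------------
  set.seed(substream_seed(config$seed, "assign"))
  roles <- rep("null", G)
  n_absent <- round(config$absent_fraction * G)
  n_unannot <- round(config$unannotated_fraction * G)
  shuffled <- sample(G)
  absent_idx <- shuffled[seq_len(n_absent)]
  unannot_idx <- shuffled[n_absent + seq_len(n_unannot)]
  roles[absent_idx] <- "absent"
  roles[unannot_idx] <- "unannotated"

  true_change <- matrix(0L, G, T_, dimnames = list(genes, tissues))
  true_effect <- numeric(G)
  eligible <- which(roles == "null")
  eligible <- eligible[sample(length(eligible))]
  pos <- 0L
  for (entry in config$pattern_table) {
    n_k <- round(entry$fraction * G)
    if (n_k == 0) next
    idx <- eligible[pos + seq_len(n_k)]
    pos <- pos + n_k
    true_change[idx, ] <- matrix(entry$pattern, n_k, T_, byrow = TRUE)
    true_effect[idx] <- entry$effect
  }

  # --- expression -----------------------------------------------------------
  set.seed(substream_seed(config$seed, "expression"))
  mu <- stats::rnorm(G, config$baseline_mean, config$baseline_sd)
  tissue_eff <- matrix(stats::rnorm(G * T_, 0, config$tissue_effect_sd), G, T_)
  n_subj <- 2L * P_
  pool_eff <- matrix(stats::rnorm(G * n_subj, 0, config$sigma_pool), G, n_subj)
  eps <- matrix(stats::rnorm(G * N, 0, config$sigma_resid), G, N)

  t_idx <- as.integer(design$tissue)
  s_idx <- as.integer(design$state)
  subj_idx <- as.integer(design$subject)
  d <- true_change * true_effect  # G x T signed treated shift
  expr <- mu + tissue_eff[, t_idx, drop = FALSE] +
    d[, t_idx, drop = FALSE] * rep(s_idx - 1L, each = G) +
    pool_eff[, subj_idx, drop = FALSE] + eps
  dimnames(expr) <- list(genes, design$sample)

  # --- exon detection p-values ---------------------------------------------
  set.seed(substream_seed(config$seed, "detection"))
  E <- config$exons_per_gene
  exon_ids <- sprintf("%s_e%d", rep(genes, each = E), rep(seq_len(E), G))
  n_rows <- G * E * N
  exons <- data.frame(
    exon = rep(exon_ids, each = N),
    gene = rep(genes, each = E * N),
    sample = rep(design$sample, G * E),
    stringsAsFactors = FALSE)
  expressed_gene <- roles != "absent"
  is_expr_row <- rep(expressed_gene, each = E * N)
  p <- stats::runif(n_rows)
  hit <- is_expr_row & (stats::runif(n_rows) >= config$dabg_present_miss_rate)
  p[hit] <- p[hit] * 0.01           # a clean present call
  exons$dabg_p <- p
  exons <- enforce_detection_truth(exons, design, expressed_gene, genes, E)

  # --- annotation -----------------------------------------------------------
  set.seed(substream_seed(config$seed, "annotation"))
  desc <- sprintf("synthetic transcript %s", genes)
  desc[roles == "unannotated"] <- "---"
  annotation <- data.frame(gene = genes, mrna_description = desc,
                           stringsAsFactors = FALSE)

  # --- gene sets ------------------------------------------------------------
  tested <- expressed_gene & roles != "unannotated"
  any_change <- rowSums(true_change != 0L) > 0
  background <- genes[tested]
  de_truth <- genes[tested & any_change]
  gene_sets <- simulate_gene_sets(background, de_truth,
                                  n_sets = config$n_gene_sets,
                                  set_size = min(config$set_size,
                                                 length(background)),
                                  enrichment_factor = config$planted_enrichment_factor,
                                  seed = substream_seed(config$seed, "gene_sets"))

  truth_genes <- data.frame(gene = genes,
                            role = roles,
                            expressed = expressed_gene,
                            annotated = roles != "unannotated",
                            tested = tested,
                            effect = true_effect,
                            pattern = as.integer(true_change %*%
                                                   pattern_weights(tissues)),
                            stringsAsFactors = FALSE)
  for (ti in seq_len(T_)) {
    truth_genes[[paste0("change_", tissues[ti])]] <- true_change[, ti]
  }
  truth_sets <- data.frame(set = names(gene_sets),
                           planted = seq_along(gene_sets) == 1L &
                             config$planted_enrichment_factor > 1,
                           stringsAsFactors = FALSE)

  list(design = design, expression = expr, exons = exons,
       annotation = annotation, gene_sets = gene_sets,
       truth = list(genes = truth_genes, sets = truth_sets),
       config = config)
}

# Guarantee the presence filter agrees with the ledger: absent genes must not
# have any exon present on >= 2 chips of one tissue x state group; expressed
# genes must have at least one. Redraws are rare corrections at the margins.
enforce_detection_truth <- function(exons, design, expressed_gene, genes, E) {
  group <- paste(design$tissue, design$state)[match(exons$sample, design$sample)]
  unit <- paste(exons$exon, group, sep = "\r")
  present <- exons$dabg_p < 0.01
  counts <- tapply(present, unit, sum)
  gene_of_unit <- sub("_e[0-9]+\r.*$", "", names(counts))
  expressed_lookup <- stats::setNames(expressed_gene, genes)

  # absent genes: knock offending exon-groups back above the threshold
  bad_units <- names(counts)[counts >= 2 & !expressed_lookup[gene_of_unit]]
  if (length(bad_units) > 0) {
    rows <- which(unit %in% bad_units & present)
    exons$dabg_p[rows] <- 0.01 + exons$dabg_p[rows] * 0.99
  }
  # expressed genes with no qualifying exon-group: force exon 1, first group
  ok_genes <- unique(gene_of_unit[counts >= 2 & expressed_lookup[gene_of_unit]])
  need <- setdiff(genes[expressed_gene], ok_genes)
  if (length(need) > 0) {
    first_group <- paste(design$tissue, design$state)[1]
    chips <- design$sample[paste(design$tissue, design$state) == first_group][1:2]
    rows <- which(exons$gene %in% need &
                    exons$exon %in% paste0(need, "_e1") &
                    exons$sample %in% chips)
    exons$dabg_p[rows] <- exons$dabg_p[rows] * 0.01
  }
  exons
}

#' Generate a gene-set collection with one planted enriched set
#'
#' The first set draws its members with sampling weight
#' \code{enrichment_factor} on the truly differentially expressed genes and
#' weight 1 elsewhere; the remaining sets draw uniformly from the background.
#'
#' @param background gene universe
#' @param de_genes truly-DE genes (subset of background)
#' @param n_sets number of sets
#' @param set_size members per set
#' @param enrichment_factor weight multiplier for the planted set
#' @param seed integer seed
#' @return named list of gene vectors (\code{set01} is the planted set)
#' @export
simulate_gene_sets <- function(background, de_genes, n_sets = 10,
                               set_size = 30, enrichment_factor = 5,
                               seed = 1L) {
  set.seed(seed)
  stopifnot(length(background) >= set_size)
  weights <- ifelse(background %in% de_genes, enrichment_factor, 1)
  sets <- vector("list", n_sets)
  names(sets) <- sprintf("set%02d", seq_len(n_sets))
  for (i in seq_len(n_sets)) {
    w <- if (i == 1L) weights else rep(1, length(background))
    sets[[i]] <- sample(background, set_size, prob = w)
  }
  attr(sets, "descriptions") <- stats::setNames(
    c("planted enriched set", rep("random set", n_sets - 1))[seq_len(n_sets)],
    names(sets))
  sets
}

#' Score pipeline output against the generator's truth
#'
#' @param calls output of [call_de()]
#' @param codes output of [pattern_code()]
#' @param enrichment output of [enrich_collection()] (or NULL)
#' @param truth the \code{truth} element of [simulate_study()]
#' @return list: \code{per_tissue} data.frame of true/false positive rates,
#'   \code{pattern_recovery} (fraction of truly-patterned tested genes whose
#'   code matches the planted code), \code{empirical_pfp} (fraction of
#'   detected genes that are truly null), \code{planted_set_rank}
#' @export
evaluate_against_truth <- function(calls, codes, enrichment, truth) {
  tg <- truth$genes
  tested <- tg[tg$tested, , drop = FALSE]
  if (!setequal(calls$gene, tested$gene)) {
    stop("truth_gene_mismatch: calls cover a different gene universe than the",
         " truth ledger's tested genes", call. = FALSE)
  }
  tissues <- sub("^de_", "", grep("^de_", names(calls), value = TRUE))
  idx <- match(calls$gene, tested$gene)
  per_tissue <- do.call(rbind, lapply(tissues, function(t) {
    truth_de <- tested[[paste0("change_", t)]][idx] != 0L
    called <- calls[[paste0("de_", t)]]
    data.frame(tissue = t,
               tpr = if (any(truth_de)) mean(called[truth_de]) else NA_real_,
               fpr = if (any(!truth_de)) mean(called[!truth_de]) else NA_real_)
  }))
  truly_patterned <- tested$pattern[idx] != 0L
  code_idx <- match(calls$gene, codes$gene)
  recovered <- codes$pattern[code_idx] == tested$pattern[idx]
  pattern_recovery <- if (any(truly_patterned)) {
    mean(recovered[truly_patterned])
  } else NA_real_
  null_nonzero <- if (any(!truly_patterned)) {
    mean(codes$pattern[code_idx][!truly_patterned] != 0L)
  } else NA_real_
  detected <- calls$any_de
  empirical_pfp <- if (any(detected)) {
    mean(!truly_patterned[detected])
  } else NA_real_
  planted_rank <- NA_integer_
  if (!is.null(enrichment) && nrow(enrichment) > 0) {
    planted <- truth$sets$set[truth$sets$planted]
    if (length(planted) == 1) {
      planted_rank <- match(planted, enrichment$set)
    }
  }
  list(per_tissue = per_tissue, pattern_recovery = pattern_recovery,
       null_nonzero_rate = null_nonzero, empirical_pfp = empirical_pfp,
       planted_set_rank = planted_rank)
}
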