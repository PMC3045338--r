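#' Construct and validate a study design
#'
#' A study design describes a balanced repeated-measures layout: subjects (RNA
#' pools) belong to one of two physiologic states and each subject is assayed
#' once in every tissue, so there is exactly one sample per
#' (tissue, state, pool) triple. Pools are nested in state: pool 1 of the
#' control group and pool 1 of the lactating group are different subjects.
#'
#' @param samples data.frame with columns \code{sample}, \code{tissue},
#'   \code{state}, \code{pool}.
#' @param tissues optional character vector fixing the tissue level order;
#'   defaults to order of first appearance.
#' @param states optional character vector of length 2 fixing the state order;
#'   the second level is the "treated" state whose contrast against the first
#'   is reported throughout (default \code{c("control", "lactating")} when
#'   those levels are present, otherwise order of first appearance).
#' @return An object of class \code{study_design}: the sample table with
#'   factor-encoded columns plus a \code{subject} id (state x pool), and
#'   attributes \code{tissues}, \code{states}, \code{n_pools}.
#' @export
study_design <- function(samples, tissues = NULL, states = NULL) {
  required <- c("sample", "tissue", "state", "pool")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    stop("design_missing_column: design table lacks column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  samples <- as.data.frame(samples)[required]
  samples$sample <- as.character(samples$sample)
  samples$tissue <- as.character(samples$tissue)
  samples$state <- as.character(samples$state)
  samples$pool <- as.integer(samples$pool)

  if (anyDuplicated(samples$sample)) {
    stop("design_duplicate_sample: duplicated sample id(s): ",
         paste(unique(samples$sample[duplicated(samples$sample)]), collapse = ", "),
         call. = FALSE)
  }

  if (is.null(tissues)) tissues <- unique(samples$tissue)
  if (is.null(states)) {
    states <- unique(samples$state)
    if (setequal(states, c("control", "lactating"))) {
      states <- c("control", "lactating")
    }
  }
  bad_tissue <- setdiff(samples$tissue, tissues)
  if (length(bad_tissue) > 0) {
    stop("design_unknown_tissue: unknown tissue level(s): ",
         paste(bad_tissue, collapse = ", "), call. = FALSE)
  }
  bad_state <- setdiff(samples$state, states)
  if (length(bad_state) > 0) {
    stop("design_unknown_state: unknown state level(s): ",
         paste(bad_state, collapse = ", "), call. = FALSE)
  }
  if (length(states) != 2) {
    stop("design_state_count: the design must have exactly 2 states, got ",
         length(states), call. = FALSE)
  }

  pools <- sort(unique(samples$pool))
  if (!identical(pools, seq_along(pools))) {
    stop("design_pool_levels: pools must be numbered 1..P, got {",
         paste(pools, collapse = ", "), "}", call. = FALSE)
  }

  # Completeness/balance: exactly one sample per (tissue, state, pool).
  cells <- expand.grid(tissue = tissues, state = states, pool = pools,
                       stringsAsFactors = FALSE)
  key <- function(t, s, p) paste(t, s, p, sep = "\r")
  counts <- table(factor(key(samples$tissue, samples$state, samples$pool),
                         levels = key(cells$tissue, cells$state, cells$pool)))
  if (any(counts != 1L)) {
    bad <- which(counts != 1L)[1]
    parts <- strsplit(names(counts)[bad], "\r", fixed = TRUE)[[1]]
    stop("design_unbalanced: cell (tissue=", parts[1], ", state=", parts[2],
         ", pool=", parts[3], ") has ", counts[bad],
         " samples; the design requires exactly one per cell", call. = FALSE)
  }

  samples$tissue <- factor(samples$tissue, levels = tissues)
  samples$state <- factor(samples$state, levels = states)
  samples$subject <- factor(paste(samples$state, samples$pool, sep = "."),
                            levels = paste(rep(states, each = length(pools)),
                                           pools, sep = "."))
  structure(samples,
            class = c("study_design", "data.frame"),
            tissues = tissues, states = states, n_pools = length(pools))
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", length(attr(x, "tissues")), "tissues x",
      length(attr(x, "states")), "states x", attr(x, "n_pools"),
      "pools =", nrow(x), "samples\n")
  cat("  tissues:", paste(attr(x, "tissues"), collapse = ", "), "\n")
  cat("  states: ", paste(attr(x, "states"), collapse = ", "),
      " (contrast: ", attr(x, "states")[2], " - ", attr(x, "states")[1], ")\n",
      sep = "")
  invisible(x)
}

design_tissues <- function(design) attr(design, "tissues")
design_states <- function(design) attr(design, "states")
design_pools <- function(design) attr(design, "n_pools")

#' Read a study design table
#'
#' @param path TSV file with header columns \code{sample}, \code{tissue},
#'   \code{state}, \code{pool}.
#' @param ... passed to [study_design()].
#' @return A \code{study_design}.
#' @export
read_design <- function(path, ...) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  study_design(tab, ...)
}

#' Write a study design table
#' @param design a \code{study_design}
#' @param path output TSV path
#' @export
write_design <- function(design, path) {
  out <- data.frame(sample = design$sample,
                    tissue = as.character(design$tissue),
                    state = as.character(design$state),
                    pool = design$pool)
  write_results_table(out, path)
}

#' Read a gene-level log2 expression matrix
#'
#' First column holds gene ids, remaining columns are samples. Columns are
#' reordered to the design's sample order; genes keep file order.
#'
#' @param path TSV path
#' @param design a \code{study_design} the columns must match exactly
#' @return numeric matrix (genes x samples) with dimnames
#' @export
read_expression <- function(path, design) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  gene_ids <- as.character(tab[[1]])
  if (anyDuplicated(gene_ids)) {
    stop("expression_duplicate_gene: duplicated gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  file_samples <- names(tab)[-1]
  extra <- setdiff(file_samples, design$sample)
  absent <- setdiff(design$sample, file_samples)
  if (length(extra) > 0 || length(absent) > 0) {
    stop("expression_sample_mismatch: ",
         if (length(extra) > 0) paste0("column(s) not in design: ",
                                       paste(extra, collapse = ", "), "; ") else "",
         if (length(absent) > 0) paste0("design sample(s) missing: ",
                                        paste(absent, collapse = ", ")) else "",
         call. = FALSE)
  }
  m <- as.matrix(tab[, design$sample, drop = FALSE])
  if (!is.numeric(m) || any(!is.finite(m))) {
    stop("expression_non_numeric: expression values must all be finite numbers",
         call. = FALSE)
  }
  rownames(m) <- gene_ids
  m
}

#' Write an expression matrix
#' @param expr genes x samples numeric matrix with dimnames
#' @param path output TSV path
#' @export
write_expression <- function(expr, path) {
  out <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_results_table(out, path)
}

#' Read exon-level detection p-values
#'
#' @param path TSV with columns \code{exon}, \code{gene}, \code{sample},
#'   \code{dabg_p}
#' @param design optional \code{study_design}; when given, sample ids are
#'   checked against it
#' @return data.frame with those four columns
#' @export
read_exon_detection <- function(path, design = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("exon", "gene", "sample", "dabg_p")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("exon_missing_column: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$dabg_p < 0 | tab$dabg_p > 1)) {
    stop("exon_bad_p: dabg_p outside [0, 1]", call. = FALSE)
  }
  if (!is.null(design)) {
    unknown <- setdiff(unique(tab$sample), design$sample)
    if (length(unknown) > 0) {
      stop("exon_unknown_sample: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  tab[required]
}

#' Read a gene annotation table
#' @param path TSV with columns \code{gene}, \code{mrna_description}
#' @return data.frame, one row per gene
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = NULL)
  required <- c("gene", "mrna_description")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("annotation_missing_column: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab$gene)) {
    stop("annotation_duplicate_gene", call. = FALSE)
  }
  tab[required]
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, fields are name, description, then
#' member genes, tab-separated. The description is retained but unused.
#'
#' @param path GMT file path
#' @return named list of character vectors of member genes; set descriptions
#'   in attribute \code{descriptions}
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short) > 0) {
    stop("gmt_short_line: line ", short[1], " has fewer than 3 fields",
         call. = FALSE)
  }
  names_ <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names_)) {
    stop("gmt_duplicate_name: ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- names_
  attr(sets, "descriptions") <- stats::setNames(vapply(fields, `[[`, "", 2L),
                                                names_)
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors
#' @param path output path
#' @param descriptions optional named character vector of set descriptions
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions")
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
}

#' Write a tabular result as TSV
#'
#' Header row, one row per record, input row order preserved. Reals are
#' serialized at full (repr-level) precision so read-back reproduces values
#' to at least 12 significant digits.
#'
#' @param results data.frame
#' @param path output TSV path
#' @export
write_results_table <- function(results, path) {
  out <- as.data.frame(results)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
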