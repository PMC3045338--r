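#' Present/absent calls from exon detection p-values
#'
#' An exon is called present on a chip when its detection-above-background
#' p-value is strictly below \code{alpha_dabg}: the exon's intensity exceeds
#' that of matched background probes with high confidence.
#'
#' @param exons exon detection table (see [read_exon_detection()])
#' @param alpha_dabg detection threshold, strict "<" (default 0.01)
#' @return the table with a logical \code{present} column added
#' @export
call_presence <- function(exons, alpha_dabg = 0.01) {
  exons$present <- exons$dabg_p < alpha_dabg
  exons
}

#' Which genes are expressed?
#'
#' A gene counts as expressed when at least one of its exons is detected on at
#' least \code{min_chips} chips belonging to the same tissue x state group
#' (e.g. present on two control liver chips). The default reading requires the
#' SAME exon on >= min_chips chips of one group; \code{mode = "any_exon"}
#' instead counts chips of a group on which any exon of the gene is present.
#'
#' @param calls output of [call_presence()]
#' @param design a \code{study_design}
#' @param min_chips minimum chips within one tissue x state group (default 2)
#' @param mode \code{"same_exon"} (default) or \code{"any_exon"}
#' @return named logical vector over the genes appearing in \code{calls}
#' @export
gene_expressed <- function(calls, design, min_chips = 2, mode = c("same_exon", "any_exon")) {
  mode <- match.arg(mode)
  unknown <- setdiff(unique(calls$sample), design$sample)
  if (length(unknown) > 0) {
    stop("exon_unknown_sample: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  group <- paste(design$tissue, design$state)[match(calls$sample, design$sample)]
  present <- calls[calls$present, , drop = FALSE]
  group <- group[calls$present]
  genes <- unique(calls$gene)
  expressed <- stats::setNames(rep(FALSE, length(genes)), genes)
  if (nrow(present) > 0) {
    unit <- if (mode == "same_exon") {
      paste(present$gene, present$exon, group, sep = "\r")
    } else {
      paste(present$gene, group, sep = "\r")
    }
    # chips within a unit are distinct samples; count unique chips per unit
    chip <- paste(unit, present$sample, sep = "\r")
    unit <- unit[!duplicated(chip)]
    counts <- table(unit)
    hit <- names(counts)[counts >= min_chips]
    hit_genes <- unique(vapply(strsplit(hit, "\r", fixed = TRUE), `[[`, "", 1L))
    expressed[hit_genes] <- TRUE
  }
  expressed
}

#' Which genes are annotated?
#'
#' A gene is annotated when its mRNA description is neither empty, whitespace,
#' nor the sentinel \code{"---"} used by array annotation files for missing
#' descriptions. Genes absent from the annotation table are treated as
#' unannotated (with a message), not as an error.
#'
#' @param annot annotation table (see [read_annotation()])
#' @param genes optional gene universe; defaults to the table's genes
#' @return named logical vector
#' @export
gene_annotated <- function(annot, genes = NULL) {
  if (is.null(genes)) genes <- annot$gene
  desc <- annot$mrna_description[match(genes, annot$gene)]
  missing <- is.na(match(genes, annot$gene))
  if (any(missing)) {
    message(sum(missing), " gene(s) absent from the annotation table; treated as unannotated")
  }
  ok <- !missing & !is.na(desc) & trimws(desc) != "" & trimws(desc) != "---"
  stats::setNames(ok, genes)
}

#' Per-gene filter report
#'
#' @param genes gene universe (character)
#' @param expressed named logical from [gene_expressed()]
#' @param annotated named logical from [gene_annotated()]
#' @return data.frame with columns gene, expressed, annotated, tested
#'   (tested = expressed AND annotated)
#' @export
gene_filter_report <- function(genes, expressed, annotated) {
  e <- unname(expressed[genes])
  a <- unname(annotated[genes])
  e[is.na(e)] <- FALSE
  a[is.na(a)] <- FALSE
  data.frame(gene = genes, expressed = e, annotated = a, tested = e & a,
             stringsAsFactors = FALSE)
}

#' Restrict an expression matrix to tested genes
#'
#' @param expr genes x samples matrix
#' @param report output of [gene_filter_report()]; must cover all genes of
#'   \code{expr}
#' @return the submatrix of tested genes, row order preserved
#' @export
select_tested_genes <- function(expr, report) {
  uncovered <- setdiff(rownames(expr), report$gene)
  if (length(uncovered) > 0) {
    stop("filter_uncovered_gene: report lacks gene(s) ",
         paste(utils::head(uncovered, 5), collapse = ", "), call. = FALSE)
  }
  tested <- report$gene[report$tested]
  expr[rownames(expr) %in% tested, , drop = FALSE]
}
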