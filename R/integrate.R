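.num_or_inf <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  low <- tolower(trimws(x))
  v[low %in% c("inf", "+inf")] <- Inf
  v[low == "-inf"] <- -Inf
  v[low %in% c("nan", "na")] <- NA_real_
  v
}

#' Read a Cuffdiff gene_exp.diff table
#'
#' Consumes the tab-separated `gene_exp.diff` dialect. Significance is
#' taken from the upstream caller's `significant` column (`"yes"`/`"no"`),
#' not re-thresholded; direction is the sign of the log2 fold change
#' (condition 2 over condition 1). Infinite fold changes (one condition at
#' zero FPKM) are preserved as +/-Inf.
#'
#' @param path `gene_exp.diff`-style TSV with header. Required columns:
#'   `gene_id`, `value_1`, `value_2`, `log2(fold_change)`, `q_value`,
#'   `significant`; `gene` (symbol) is used when present.
#' @return data.frame of DE records: `gene_id`, `gene_name`, `fpkm_1`,
#'   `fpkm_2`, `log2fc`, `q_value`, `significant` (logical), `direction`
#'   (`"up"`, `"down"` or `"none"`).
#' @export
read_cuffdiff <- function(path) {
  if (!file.exists(path)) stop("DE table not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", comment.char = "")
  req <- c("gene_id", "value_1", "value_2", "log2(fold_change)", "q_value",
           "significant")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("DE table missing required column(s): ",
                         paste(miss, collapse = ", "))
  q <- .num_or_inf(tab$q_value)
  if (anyNA(q))
    stop("non-numeric q_value at row ", which(is.na(q))[1])
  if (any(q < 0 | q > 1)) stop("q_value outside [0,1]")
  lfc <- .num_or_inf(tab[["log2(fold_change)"]])
  sig <- tolower(tab$significant) == "yes"
  data.frame(gene_id = as.character(tab$gene_id),
             gene_name = if ("gene" %in% names(tab)) as.character(tab$gene)
             else as.character(tab$gene_id),
             fpkm_1 = .num_or_inf(tab$value_1),
             fpkm_2 = .num_or_inf(tab$value_2),
             log2fc = lfc,
             q_value = q,
             significant = sig,
             direction = ifelse(!sig, "none", ifelse(lfc > 0, "up", "down")),
             stringsAsFactors = FALSE)
}

#' Read a generic differential-expression TSV
#'
#' Maps arbitrarily named columns onto the DE record shape used by
#' [read_cuffdiff()].
#'
#' @param path TSV with header.
#' @param columns named character vector mapping
#'   `c(gene_id=, log2fc=, q_value=, significant=)` (and optionally
#'   `gene_name`, `fpkm_1`, `fpkm_2`) to column names in the file.
#' @return data.frame of DE records.
#' @export
read_de_table <- function(path, columns) {
  need <- c("gene_id", "log2fc", "q_value", "significant")
  miss <- setdiff(need, names(columns))
  if (length(miss)) stop("columns mapping missing: ", paste(miss, collapse = ", "))
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  absent <- setdiff(unname(columns), names(tab))
  if (length(absent)) stop("DE table missing required column(s): ",
                           paste(absent, collapse = ", "))
  lfc <- .num_or_inf(tab[[columns[["log2fc"]]]])
  sigraw <- tab[[columns[["significant"]]]]
  sig <- if (is.logical(sigraw)) sigraw else tolower(sigraw) %in% c("yes", "true", "1")
  data.frame(gene_id = as.character(tab[[columns[["gene_id"]]]]),
             gene_name = if ("gene_name" %in% names(columns))
               as.character(tab[[columns[["gene_name"]]]])
             else as.character(tab[[columns[["gene_id"]]]]),
             fpkm_1 = if ("fpkm_1" %in% names(columns))
               .num_or_inf(tab[[columns[["fpkm_1"]]]]) else NA_real_,
             fpkm_2 = if ("fpkm_2" %in% names(columns))
               .num_or_inf(tab[[columns[["fpkm_2"]]]]) else NA_real_,
             log2fc = lfc,
             q_value = .num_or_inf(tab[[columns[["q_value"]]]]),
             significant = sig,
             direction = ifelse(!sig, "none", ifelse(lfc > 0, "up", "down")),
             stringsAsFactors = FALSE)
}

#' Write DE records in the gene_exp.diff layout
#'
#' @param degs DE record data.frame (shape of [read_cuffdiff()] output).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cuffdiff <- function(degs, path) {
  fmt <- function(x) ifelse(is.infinite(x), ifelse(x > 0, "inf", "-inf"),
                            format(x, trim = TRUE, scientific = FALSE, digits = 15))
  header <- paste("test_id", "gene_id", "gene", "locus", "sample_1", "sample_2",
                  "status", "value_1", "value_2", "log2(fold_change)",
                  "test_stat", "p_value", "q_value", "significant", sep = "\t")
  rows <- paste(degs$gene_id, degs$gene_id, degs$gene_name, "-", "WT", "mutant",
                "OK", fmt(degs$fpkm_1), fmt(degs$fpkm_2), fmt(degs$log2fc),
                "0", fmt(degs$q_value), fmt(degs$q_value),
                ifelse(degs$significant, "yes", "no"), sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Intersect differentially expressed genes with peak-associated genes
#'
#' A DEG counts as peak-associated when at least one peak annotation lists
#' its `gene_id` in any association (promoter, exonic or intronic);
#' intergenic peaks carry no gene association and contribute nothing
#' unless `include_intergenic_nearest` re-assigns them (see below).
#' Association is gene-level: multiple transcripts or peaks on one gene
#' are deduplicated.
#'
#' @param degs DE record data.frame ([read_cuffdiff()] shape).
#' @param annotations a `peak_annotations` object from [annotate_peaks()].
#' @param include_intergenic_nearest if `TRUE`, each intergenic peak is
#'   assigned to the gene of the nearest TSS within `distal_max`, when the
#'   annotation run retained such information; with the default classifier
#'   an intergenic peak has no TSS within `distal_max`, so this only
#'   matters for annotations produced under a different window. Default
#'   `FALSE`.
#' @return list of class `integration_result`: `n_deg`, `n_deg_with_peak`,
#'   `genes` (data.frame `gene_id`, `direction`, `peak_classes`),
#'   `venn` (list `deg_only`, `peak_genes_only`, `intersection`).
#' @export
intersect_deg_peaks <- function(degs, annotations,
                                include_intergenic_nearest = FALSE) {
  assoc <- if (inherits(annotations, "peak_annotations"))
    annotations$associations else annotations
  deg <- degs[degs$significant, , drop = FALSE]
  peak_genes <- unique(assoc$gene_id)
  if (include_intergenic_nearest &&
      inherits(annotations, "peak_annotations")) {
    ann <- annotations$annotations
    extra <- ann$best_gene_id[ann$peak_class == "intergenic" &
                                !is.na(ann$best_gene_id)]
    peak_genes <- unique(c(peak_genes, extra))
  }
  hit <- deg$gene_id %in% peak_genes
  classes_by_gene <- if (nrow(assoc))
    tapply(assoc$relation, assoc$gene_id,
           function(r) paste(sort(unique(r)), collapse = ","))
  else character(0)
  genes <- data.frame(gene_id = deg$gene_id[hit],
                      direction = deg$direction[hit],
                      peak_classes = unname(classes_by_gene[deg$gene_id[hit]]),
                      stringsAsFactors = FALSE)
  structure(list(
    n_deg = nrow(deg),
    n_deg_with_peak = sum(hit),
    genes = genes,
    venn = list(deg_only = nrow(deg) - sum(hit),
                peak_genes_only = length(setdiff(peak_genes, deg$gene_id)),
                intersection = sum(hit))),
    class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf("integration: %d DEGs, %d with associated peaks (%.2f%%)\n",
              x$n_deg, x$n_deg_with_peak,
              if (x$n_deg > 0) 100 * x$n_deg_with_peak / x$n_deg else NA))
  invisible(x)
}

#' Replicate quality control by pairwise Pearson correlation
#'
#' Pearson correlation is computed on `log2(FPKM + 1)` for every replicate
#' pair. A replicate is discarded when the median of its correlations with
#' the other replicates of the same condition falls below `min_corr`.
#' A zero-variance replicate has undefined correlations and is discarded
#' with a warning.
#'
#' @param mat numeric matrix, genes x replicates, non-negative FPKM.
#' @param conditions character vector, one condition label per column.
#' @param min_corr discard threshold in (-1, 1); default 0.9.
#' @return list of class `replicate_qc`: `kept` and `discarded` (column
#'   names), `cor_matrix` (replicates x replicates Pearson r on the log
#'   scale), `median_same_condition` (named numeric).
#' @export
replicate_qc <- function(mat, conditions, min_corr = 0.9) {
  if (ncol(mat) < 2L) stop("need at least 2 replicates")
  if (length(conditions) != ncol(mat))
    stop("conditions must label every column of mat")
  if (!(min_corr > -1 && min_corr < 1)) stop("min_corr must be in (-1, 1)")
  if (any(mat < 0)) stop("FPKM values must be non-negative")
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("rep%d", seq_len(ncol(mat)))
  lg <- log2(mat + 1)
  zero_var <- apply(lg, 2, stats::sd) == 0
  if (any(zero_var))
    warning("zero-variance replicate(s) discarded: ",
            paste(colnames(mat)[zero_var], collapse = ", "))
  cm <- suppressWarnings(stats::cor(lg, method = "pearson"))
  med <- vapply(seq_len(ncol(mat)), function(j) {
    same <- which(conditions == conditions[j])
    same <- setdiff(same, j)
    if (!length(same)) return(NA_real_)
    stats::median(cm[j, same], na.rm = TRUE)
  }, numeric(1))
  names(med) <- colnames(mat)
  discard <- zero_var | is.na(med) | med < min_corr
  structure(list(kept = colnames(mat)[!discard],
                 discarded = colnames(mat)[discard],
                 cor_matrix = cm,
                 median_same_condition = med),
            class = "replicate_qc")
}
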