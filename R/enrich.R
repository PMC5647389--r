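#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least `k` annotated genes in a sample of `n` from a universe of `N`
#' genes of which `K` are annotated. This is the standard over-
#' representation null for term enrichment. Computed via the upper tail of
#' [stats::phyper()] (log-space internals), vectorized over `k`.
#'
#' @param k observed annotated genes in the study set.
#' @param K annotated genes in the background.
#' @param n study-set size.
#' @param N background size.
#' @return probability in (0, 1]; `k = 0` gives exactly 1.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (any(N < 0) || any(K < 0) || any(K > N) || any(n < 0) || any(n > N))
    stop("require 0 <= K <= N and 0 <= n <= N")
  if (any(k < 0) || any(k > pmin(n, K)))
    stop("require 0 <= k <= min(n, K)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment with monotonicity enforcement; output order
#' matches input order. Thin validated front end to
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Read a gene-to-term mapping table
#'
#' The mapping is a flat TSV (`gene_id`, `term_id`, `term_name`); term
#' graphs are expected pre-propagated. An optional slim file (one term_id
#' per line) marks a reduced high-level subset.
#'
#' @param path mapping TSV with header.
#' @param slim_path optional file listing slim term ids.
#' @return data.frame `gene_id`, `term_id`, `term_name`, `is_slim`.
#' @export
read_term_mapping <- function(path, slim_path = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  req <- c("gene_id", "term_id", "term_name")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("mapping missing column(s): ", paste(miss, collapse = ", "))
  slim <- if (!is.null(slim_path)) readLines(slim_path) else character(0)
  tab <- tab[, req, drop = FALSE]
  tab$is_slim <- tab$term_id %in% slim
  tab
}

#' Term over-representation analysis
#'
#' Tests every term for over-representation of the study set within the
#' background via the upper-tail hypergeometric probability, adjusts for
#' multiple testing, and returns the table ranked by p-value with a second
#' rank by fold enrichment `(k/n)/(K/N)`. Terms never hit by the study set
#' (`k = 0`) are not reported. Mapping genes outside the background are
#' ignored.
#'
#' @param study character vector of study gene ids (must be a subset of
#'   `background`).
#' @param background character vector of background (universe) gene ids.
#' @param mapping mapping data.frame from [read_term_mapping()] (columns
#'   `gene_id`, `term_id`, `term_name`, optional `is_slim`).
#' @param slim_only restrict tested terms to the slim subset.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param correction `"bh"` (default), `"bonferroni"` or `"none"`.
#' @return data.frame of class `enrichment_results`, sorted by p ascending:
#'   `term_id`, `term_name`, `k`, `n`, `K`, `N`, `p_value`, `fold`,
#'   `q_value`, `significant`, `rank_p`, `rank_fold`.
#' @export
run_enrichment <- function(study, background, mapping, slim_only = FALSE,
                           alpha = 0.05, correction = c("bh", "bonferroni", "none")) {
  correction <- match.arg(correction)
  study <- unique(as.character(study))
  background <- unique(as.character(background))
  if (!length(study)) stop("empty study set")
  outside <- setdiff(study, background)
  if (length(outside))
    stop("study genes absent from background: ", paste(utils::head(outside, 5), collapse = ", "))
  if (slim_only) {
    if (!"is_slim" %in% names(mapping)) stop("mapping has no is_slim column")
    mapping <- mapping[mapping$is_slim, , drop = FALSE]
  }
  mapping <- mapping[mapping$gene_id %in% background, , drop = FALSE]
  if (!nrow(mapping)) {
    out <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), n = integer(), K = integer(), N = integer(),
                      p_value = numeric(), fold = numeric(), q_value = numeric(),
                      significant = logical(), rank_p = integer(),
                      rank_fold = integer(), stringsAsFactors = FALSE)
    class(out) <- c("enrichment_results", "data.frame")
    return(out)
  }
  N <- length(background)
  n <- length(study)
  terms <- split(mapping, mapping$term_id)
  rows <- lapply(terms, function(tm) {
    genes <- unique(tm$gene_id)
    K <- length(genes)
    k <- length(intersect(genes, study))
    data.frame(term_id = tm$term_id[1], term_name = tm$term_name[1],
               k = k, n = n, K = K, N = N, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[res$k >= 1L, , drop = FALSE]
  if (!nrow(res)) {
    class(res) <- c("enrichment_results", "data.frame")
    return(res)
  }
  res$p_value <- hypergeom_upper(res$k, res$K, res$n, res$N)
  res$fold <- (res$k / res$n) / (res$K / res$N)
  res$q_value <- switch(correction,
                        bh = bh_fdr(res$p_value),
                        bonferroni = pmin(1, res$p_value * nrow(res)),
                        none = res$p_value)
  res$significant <- res$q_value < alpha
  # deterministic ranks: ties broken by term_id
  ord_p <- order(res$p_value, res$term_id)
  ord_f <- order(-res$fold, res$term_id)
  res$rank_p[ord_p] <- seq_len(nrow(res))
  res$rank_fold[ord_f] <- seq_len(nrow(res))
  res <- res[ord_p, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_results", "data.frame")
  res
}
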