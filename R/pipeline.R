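#' @importFrom methods is
NULL

.stage <- function(name, verbose, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

.log_msg <- function(verbose, ...) if (verbose) message(...)

.write_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full peak-to-target pipeline
#'
#' Chains annotation, differential-expression integration, term enrichment
#' and motif-cluster scanning over file inputs, writing per-stage tables
#' and a single JSON report. Enrichment runs when a gene-to-term mapping
#' is supplied (study set: the peak-associated DEGs; background: all genes
#' in the DE table); motif scanning runs when a genome FASTA is supplied.
#' Stage failures abort with a message naming the stage. Given identical
#' inputs and configuration the report is identical.
#'
#' @param gtf gene models (Ensembl-dialect GTF).
#' @param peaks peak calls; format per `peak_format`.
#' @param de_table Cuffdiff-style `gene_exp.diff` TSV.
#' @param out_dir output directory (created if missing).
#' @param peak_format `"narrowpeak"` (default), `"bed"` or `"macs14"`.
#' @param blacklist optional BED3 of artifact regions; peaks overlapping it
#'   are removed before annotation (interval-level filtering; the
#'   read-level filtering applied upstream of peak calling is out of
#'   scope, and the substitution is noted in the report).
#' @param blacklist_mode `"interval"` (default) or `"summit"`.
#' @param mapping optional gene-to-term TSV ([read_term_mapping()]).
#' @param slim optional slim term-id list (one per line).
#' @param slim_only restrict enrichment to slim terms.
#' @param fasta optional genome FASTA for promoter motif scanning.
#' @param motif,motif_upstream,motif_window,motif_min_hits motif-stage
#'   parameters (word, promoter window upstream of TSS, cluster chaining
#'   window, minimum hits per cluster).
#' @param proximal_max,distal_max classifier thresholds (bp).
#' @param alpha enrichment significance level.
#' @param include_intergenic_nearest see [intersect_deg_peaks()].
#' @param verbose log per-stage record counts to standard error.
#' @return the report, invisibly (a list; also written to
#'   `out_dir/report.json`).
#' @export
run_all <- function(gtf, peaks, de_table, out_dir,
                    peak_format = c("narrowpeak", "bed", "macs14"),
                    blacklist = NULL, blacklist_mode = "interval",
                    mapping = NULL, slim = NULL, slim_only = FALSE,
                    fasta = NULL, motif = "GGCCGG", motif_upstream = 3000L,
                    motif_window = 200L, motif_min_hits = 2L,
                    proximal_max = 2000L, distal_max = 50000L,
                    alpha = 0.05, include_intergenic_nearest = FALSE,
                    verbose = TRUE) {
  peak_format <- match.arg(peak_format)
  for (arg in c("gtf", "peaks", "de_table")) {
    p <- get(arg)
    if (is.null(p) || !file.exists(p))
      stop("input file for --", gsub("_", "-", arg), " not found: ",
           if (is.null(p)) "(missing)" else p)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg <- list(gtf = gtf, peaks = peaks, de_table = de_table,
              peak_format = peak_format, blacklist = blacklist,
              blacklist_mode = blacklist_mode, mapping = mapping, slim = slim,
              slim_only = slim_only, fasta = fasta, motif = motif,
              motif_upstream = motif_upstream, motif_window = motif_window,
              motif_min_hits = motif_min_hits, proximal_max = proximal_max,
              distal_max = distal_max, alpha = alpha,
              include_intergenic_nearest = include_intergenic_nearest)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, null = "null")
  hash <- unname(tools::md5sum(cfg_path))

  models <- .stage("genome_models", verbose, parse_gtf(gtf))
  .log_msg(verbose, "genome_models: ", nrow(models$transcripts), " transcripts")

  pk <- .stage("peak_io", verbose, switch(peak_format,
    narrowpeak = read_narrowpeak(peaks),
    bed = read_bed_peaks(peaks),
    macs14 = read_macs_xls(peaks)))
  n_read <- nrow(pk)
  n_removed <- 0L
  if (!is.null(blacklist)) {
    bl <- .stage("peak_io", verbose, read_blacklist(blacklist))
    flt <- filter_blacklist(pk, bl, mode = blacklist_mode)
    n_removed <- nrow(flt$removed)
    pk <- flt$kept
  }
  .log_msg(verbose, "peak_io: ", n_read, " peaks read, ", n_removed,
           " blacklisted, ", nrow(pk), " kept")

  config <- classifier_config(proximal_max, distal_max)
  ann <- .stage("annotate", verbose, annotate_peaks(pk, models, config))
  dist <- summarize_distribution(ann)
  .write_tsv(ann$annotations, file.path(out_dir, "annotations.tsv"), hash)
  jsonlite::write_json(
    list(config_hash = hash, n_peaks = dist$n_peaks,
         counts = as.list(dist$counts),
         percentages = as.list(dist$percentages),
         promoter_total_percent = dist$promoter_total_percent),
    file.path(out_dir, "distribution.json"), auto_unbox = TRUE, digits = NA)
  .log_msg(verbose, "annotate: ", dist$n_peaks, " peaks classified")

  degs <- .stage("integrate", verbose, read_cuffdiff(de_table))
  integ <- .stage("integrate", verbose,
                  intersect_deg_peaks(degs, ann, include_intergenic_nearest))
  .write_tsv(integ$genes, file.path(out_dir, "deg_peak_genes.tsv"), hash)
  jsonlite::write_json(
    list(config_hash = hash, n_deg = integ$n_deg,
         n_deg_with_peak = integ$n_deg_with_peak, venn = integ$venn),
    file.path(out_dir, "integration.json"), auto_unbox = TRUE, digits = NA)
  .log_msg(verbose, "integrate: ", integ$n_deg, " DEGs, ",
           integ$n_deg_with_peak, " with peaks")

  enr <- NULL
  if (!is.null(mapping)) {
    enr <- .stage("enrich", verbose, {
      mp <- read_term_mapping(mapping, slim)
      run_enrichment(study = integ$genes$gene_id,
                     background = unique(degs$gene_id),
                     mapping = mp, slim_only = slim_only, alpha = alpha)
    })
    .write_tsv(enr, file.path(out_dir, "enrichment_by_p.tsv"), hash)
    .write_tsv(enr[order(enr$rank_fold), ],
               file.path(out_dir, "enrichment_by_fold.tsv"), hash)
    .log_msg(verbose, "enrich: ", nrow(enr), " terms tested, ",
             sum(enr$significant), " significant at alpha ", alpha)
  }

  mot <- NULL
  if (!is.null(fasta)) {
    mot <- .stage("motif", verbose, {
      prom <- extract_promoter_sequences(models, fasta,
                                         upstream_bp = motif_upstream,
                                         downstream_bp = 500L)
      hits <- do.call(rbind, lapply(names(prom$sequences), function(id)
        scan_motif(prom$sequences[[id]], motif, seq_id = id)))
      if (is.null(hits)) hits <- scan_motif("ACGTACGTACGT", motif)[0, ]
      list(hits = hits,
           clusters = call_clusters(hits, motif_window, motif_min_hits))
    })
    .write_tsv(mot$hits, file.path(out_dir, "motif_hits.tsv"), hash)
    .write_tsv(mot$clusters, file.path(out_dir, "motif_clusters.tsv"), hash)
    .log_msg(verbose, "motif: ", nrow(mot$hits), " hits, ",
             nrow(mot$clusters), " clusters")
  }

  report <- list(
    config_hash = hash,
    notes = if (!is.null(blacklist))
      "blacklist applied to peak intervals (post peak-calling substitute for read-level filtering)"
    else NULL,
    peaks = list(read = n_read, blacklisted = n_removed, kept = nrow(pk)),
    distribution = list(n_peaks = dist$n_peaks, counts = as.list(dist$counts),
                        percentages = as.list(dist$percentages),
                        promoter_total_percent = dist$promoter_total_percent),
    integration = list(n_deg = integ$n_deg,
                       n_deg_with_peak = integ$n_deg_with_peak,
                       venn = integ$venn),
    enrichment = if (!is.null(enr))
      list(n_terms = nrow(enr), n_significant = sum(enr$significant),
           top_by_p = utils::head(enr$term_id, 10)) else NULL,
    motif = if (!is.null(mot))
      list(n_hits = nrow(mot$hits), n_clusters = nrow(mot$clusters)) else NULL)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
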