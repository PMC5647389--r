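#' Classifier configuration
#'
#' Distance thresholds for the summit-to-TSS classification. A summit on
#' the upstream (5') side of a TSS is a proximal-promoter hit when its
#' distance is at most `proximal_max` bp (boundary inclusive) and a
#' distal-promoter hit when the distance is in `(proximal_max, distal_max]`.
#'
#' @param proximal_max proximal promoter cutoff in bp (default 2000).
#' @param distal_max distal promoter cutoff in bp (default 50000).
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(proximal_max = 2000L, distal_max = 50000L) {
  proximal_max <- as.integer(proximal_max)
  distal_max <- as.integer(distal_max)
  if (!(proximal_max > 0L && distal_max > proximal_max))
    stop("require 0 < proximal_max < distal_max")
  structure(list(proximal_max = proximal_max, distal_max = distal_max),
            class = "classifier_config")
}

.PEAK_CLASSES <- c("proximal_promoter", "distal_promoter", "exonic",
                   "intronic", "intergenic")
.RELATION_PRECEDENCE <- c(proximal = 1L, distal = 2L, exonic = 3L, intronic = 4L)

#' Relation of a summit to a single TSS
#'
#' The signed distance is measured along the direction of transcription:
#' `d = tss - summit` on the `+` strand and `d = summit - tss` on the `-`
#' strand, so `d >= 0` means the summit lies upstream (5') of the TSS.
#' `d = 0` (summit exactly at the TSS) is proximal. A summit downstream of
#' the TSS (`d < 0`) or on another chromosome has no promoter relation.
#'
#' @param summit 0-based summit position.
#' @param chrom summit chromosome.
#' @param tss one-row data.frame from [derive_tss()] (or any list with
#'   `chrom`, `position`, `strand`).
#' @param config a [classifier_config()].
#' @return list with `relation` (`"proximal"`, `"distal"` or `"none"`) and
#'   `distance` (the signed upstream offset `d`, `NA` on chromosome
#'   mismatch).
#' @export
summit_tss_relation <- function(summit, chrom, tss, config = classifier_config()) {
  if (!identical(as.character(chrom), as.character(tss$chrom)))
    return(list(relation = "none", distance = NA_integer_))
  d <- if (tss$strand == "+") tss$position - summit else summit - tss$position
  relation <- if (d >= 0 && d <= config$proximal_max) "proximal"
  else if (d > config$proximal_max && d <= config$distal_max) "distal"
  else "none"
  list(relation = relation, distance = as.integer(d))
}

# vectorized core shared by classify_summit/annotate_peaks.
# peaks: data.frame(peak_id, chrom, summit); returns association table.
.collect_associations <- function(peaks, models, config) {
  tx <- models$transcripts
  tss <- derive_tss(models)
  out <- vector("list", 0L)
  for (ch in unique(peaks$chrom)) {
    psel <- which(peaks$chrom == ch)
    tsel <- which(tx$chrom == ch)
    if (!length(tsel)) next
    spos <- peaks$summit[psel]
    q <- IRanges(spos + 1L, spos + 1L)

    # promoter relations: any TSS within +/- distal_max, then sign filter
    tpos <- tss$position[tsel]
    win <- IRanges(pmax(tpos - config$distal_max, 0L) + 1L,
                   tpos + config$distal_max + 1L)
    ov <- findOverlaps(q, win)
    if (length(ov)) {
      pi <- psel[queryHits(ov)]; ti <- tsel[subjectHits(ov)]
      d <- ifelse(tx$strand[ti] == "+",
                  tss$position[ti] - peaks$summit[pi],
                  peaks$summit[pi] - tss$position[ti])
      keep <- d >= 0L & d <= config$distal_max
      if (any(keep)) {
        pi <- pi[keep]; ti <- ti[keep]; d <- d[keep]
        out[[length(out) + 1L]] <- data.frame(
          peak_id = peaks$peak_id[pi],
          transcript_id = tx$transcript_id[ti],
          gene_id = tx$gene_id[ti],
          relation = ifelse(d <= config$proximal_max, "proximal", "distal"),
          signed_distance = as.integer(d),
          stringsAsFactors = FALSE)
      }
    }

    # genic relations: summit inside a transcript locus -> exon check
    loci <- IRanges(tx$start[tsel] + 1L, tx$end[tsel])
    ov <- findOverlaps(q, loci)
    if (length(ov)) {
      pi <- psel[queryHits(ov)]; ti <- tsel[subjectHits(ov)]
      # exonic test per (peak, transcript): overlap summit point with that
      # transcript's exons
      ex <- models$exons[models$exons$transcript_id %in% tx$transcript_id[ti], ]
      ex_ir <- IRanges(ex$start + 1L, ex$end)
      exonic <- logical(length(pi))
      if (nrow(ex)) {
        ovx <- findOverlaps(IRanges(peaks$summit[pi] + 1L, peaks$summit[pi] + 1L), ex_ir)
        if (length(ovx)) {
          same_tx <- tx$transcript_id[ti][queryHits(ovx)] ==
            ex$transcript_id[subjectHits(ovx)]
          exonic[unique(queryHits(ovx)[same_tx])] <- TRUE
        }
      }
      d <- ifelse(tx$strand[ti] == "+",
                  tss$position[ti] - peaks$summit[pi],
                  peaks$summit[pi] - tss$position[ti])
      out[[length(out) + 1L]] <- data.frame(
        peak_id = peaks$peak_id[pi],
        transcript_id = tx$transcript_id[ti],
        gene_id = tx$gene_id[ti],
        relation = ifelse(exonic, "exonic", "intronic"),
        signed_distance = as.integer(d),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(peak_id = character(), transcript_id = character(),
                      gene_id = character(), relation = character(),
                      signed_distance = integer(), stringsAsFactors = FALSE))
  assoc <- do.call(rbind, out)
  rownames(assoc) <- NULL
  assoc
}

#' Annotate peak summits against transcript models
#'
#' For each peak the summit (a single base) is compared with every TSS
#' within `distal_max` and every transcript locus containing it. All
#' relations are retained as associations; the peak class is the highest-
#' precedence relation present, under
#' `proximal_promoter > distal_promoter > exonic > intronic`, or
#' `intergenic` when no relation exists (no upstream TSS within
#' `distal_max` and summit inside no locus).
#'
#' @param peaks peak data.frame (needs `peak_id`, `chrom`, `summit`;
#'   extra columns such as `summit_imputed` are carried through).
#' @param models a [transcript_models] object.
#' @param config a [classifier_config()].
#' @return list of class `peak_annotations` with elements
#'   \describe{
#'     \item{annotations}{one row per peak: `peak_id`, `chrom`, `summit`,
#'       `peak_class`, `n_associations`, `best_gene_id`,
#'       `best_transcript_id`, `signed_distance`, `summit_imputed`.}
#'     \item{associations}{one row per (peak, transcript) relation:
#'       `peak_id`, `transcript_id`, `gene_id`, `relation`,
#'       `signed_distance`.}
#'   }
#' @export
annotate_peaks <- function(peaks, models, config = classifier_config()) {
  stopifnot(inherits(models, "transcript_models"))
  need <- c("peak_id", "chrom", "summit")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stop("peaks table missing column(s): ", paste(miss, collapse = ", "))
  assoc <- .collect_associations(peaks, models, config)

  cls <- rep("intergenic", nrow(peaks))
  n_assoc <- integer(nrow(peaks))
  best_gene <- rep(NA_character_, nrow(peaks))
  best_tx <- rep(NA_character_, nrow(peaks))
  best_d <- rep(NA_integer_, nrow(peaks))
  if (nrow(assoc)) {
    prec <- .RELATION_PRECEDENCE[assoc$relation]
    # deterministic best association: precedence, then |distance|, then id
    ord <- order(assoc$peak_id, prec, abs(assoc$signed_distance),
                 assoc$transcript_id)
    a <- assoc[ord, , drop = FALSE]
    first <- !duplicated(a$peak_id)
    i <- match(a$peak_id[first], peaks$peak_id)
    rel2class <- c(proximal = "proximal_promoter", distal = "distal_promoter",
                   exonic = "exonic", intronic = "intronic")
    cls[i] <- rel2class[a$relation[first]]
    best_gene[i] <- a$gene_id[first]
    best_tx[i] <- a$transcript_id[first]
    best_d[i] <- a$signed_distance[first]
    cnt <- table(assoc$peak_id)
    j <- match(names(cnt), peaks$peak_id)
    n_assoc[j] <- as.integer(cnt)
  }
  ann <- data.frame(peak_id = peaks$peak_id, chrom = peaks$chrom,
                    summit = peaks$summit, peak_class = cls,
                    n_associations = n_assoc, best_gene_id = best_gene,
                    best_transcript_id = best_tx, signed_distance = best_d,
                    summit_imputed = if ("summit_imputed" %in% names(peaks))
                      peaks$summit_imputed else FALSE,
                    stringsAsFactors = FALSE)
  structure(list(annotations = ann, associations = assoc),
            class = "peak_annotations")
}

#' Classify a single peak summit
#'
#' Convenience wrapper around [annotate_peaks()] for one peak.
#'
#' @param peak one-row peak data.frame (or list with `peak_id`, `chrom`,
#'   `summit`).
#' @param models a [transcript_models] object.
#' @param config a [classifier_config()].
#' @return list with `peak_id`, `peak_class` and the `associations`
#'   data.frame for this peak.
#' @export
classify_summit <- function(peak, models, config = classifier_config()) {
  pk <- data.frame(peak_id = as.character(peak$peak_id),
                   chrom = as.character(peak$chrom),
                   summit = as.integer(peak$summit), stringsAsFactors = FALSE)
  res <- annotate_peaks(pk, models, config)
  list(peak_id = pk$peak_id,
       peak_class = res$annotations$peak_class[1],
       associations = res$associations)
}

#' @export
print.peak_annotations <- function(x, ...) {
  cat(sprintf("peak_annotations: %d peaks, %d associations\n",
              nrow(x$annotations), nrow(x$associations)))
  print(table(factor(x$annotations$peak_class, levels = .PEAK_CLASSES)))
  invisible(x)
}

#' Summarize the genomic distribution of annotated peaks
#'
#' @param annotations a `peak_annotations` object (or its `annotations`
#'   data.frame).
#' @return list of class `distribution_summary`: `n_peaks`, named `counts`,
#'   named `percentages` (summing to 100 within rounding) and
#'   `promoter_total_percent` (proximal + distal).
#' @export
summarize_distribution <- function(annotations) {
  ann <- if (inherits(annotations, "peak_annotations")) annotations$annotations
  else annotations
  if (!nrow(ann)) stop("cannot summarize an empty annotation set")
  counts <- table(factor(ann$peak_class, levels = .PEAK_CLASSES))
  counts <- stats::setNames(as.integer(counts), names(counts))
  n <- sum(counts)
  pct <- 100 * counts / n
  structure(list(n_peaks = n, counts = counts, percentages = pct,
                 promoter_total_percent =
                   unname(pct["proximal_promoter"] + pct["distal_promoter"])),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("distribution over %d peaks:\n", x$n_peaks))
  for (cl in names(x$counts))
    cat(sprintf("  %-18s %6d  (%5.1f%%)\n", cl, x$counts[[cl]], x$percentages[[cl]]))
  cat(sprintf("  promoter total     %5.1f%%\n", x$promoter_total_percent))
  invisible(x)
}
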