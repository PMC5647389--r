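#' @importFrom IRanges IRanges findOverlaps reduce
#' @importFrom S4Vectors queryHits subjectHits
NULL

.peak_frame <- function(peak_id, chrom, start, end, summit, score,
                        enrichment = NA_real_, summit_imputed = FALSE) {
  df <- data.frame(peak_id = as.character(peak_id), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   summit = as.integer(summit), score = as.numeric(score),
                   enrichment = as.numeric(enrichment),
                   summit_imputed = as.logical(summit_imputed),
                   stringsAsFactors = FALSE)
  bad <- df$summit < df$start | df$summit >= df$end
  if (any(bad))
    stop("summit outside peak interval for: ", paste(df$peak_id[bad], collapse = ", "))
  df
}

#' Read ENCODE narrowPeak peak calls
#'
#' Parses the 10-column narrowPeak format (BED6+4). The summit is
#' `start + offset` where offset is column 10; an offset of `-1` imputes
#' the interval midpoint and flags the peak (`summit_imputed`). Files with
#' fewer than 10 columns fall back to plain BED parsing with midpoint
#' summits (a message is emitted).
#'
#' @param path narrowPeak (or BED3/BED4) file.
#' @return data.frame of peak calls with columns `peak_id`, `chrom`,
#'   `start`, `end`, `summit`, `score`, `enrichment`, `summit_imputed`
#'   (0-based half-open coordinates).
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "")
  if (ncol(tab) < 10L) {
    message("fewer than 10 columns in ", path, "; parsing as BED with midpoint summits")
    return(read_bed_peaks(path))
  }
  start <- as.integer(tab[[2]]); end <- as.integer(tab[[3]])
  offset <- as.integer(tab[[10]])
  if (any(offset >= end - start))
    stop("summit offset beyond peak length at row ",
         which(offset >= end - start)[1])
  imputed <- offset < 0L
  summit <- ifelse(imputed, (start + end) %/% 2L, start + offset)
  .peak_frame(tab[[4]], tab[[1]], start, end, summit,
              score = as.numeric(tab[[5]]), enrichment = as.numeric(tab[[7]]),
              summit_imputed = imputed)
}

#' Read BED3/BED4 intervals as peaks with midpoint summits
#'
#' @param path BED file (3 or more columns; column 4 used as peak id if
#'   present, otherwise ids are generated).
#' @return data.frame of peak calls; every summit is the interval midpoint
#'   and flagged `summit_imputed`.
#' @export
read_bed_peaks <- function(path) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "")
  if (ncol(tab) < 3L) stop("BED file needs at least 3 columns: ", path)
  start <- as.integer(tab[[2]]); end <- as.integer(tab[[3]])
  ids <- if (ncol(tab) >= 4L) as.character(tab[[4]]) else
    sprintf("peak_%d", seq_len(nrow(tab)))
  score <- if (ncol(tab) >= 5L) as.numeric(tab[[5]]) else NA_real_
  .peak_frame(ids, tab[[1]], start, end, (start + end) %/% 2L, score,
              summit_imputed = TRUE)
}

#' Write peak calls as narrowPeak
#'
#' Column 10 carries the summit offset from the interval start; peaks with
#' imputed summits are written with offset -1 so a read round-trip
#' re-imputes the midpoint.
#'
#' @param peaks peak data.frame as returned by [read_narrowpeak()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  offset <- ifelse(peaks$summit_imputed, -1L, peaks$summit - peaks$start)
  enr <- ifelse(is.na(peaks$enrichment), 0, peaks$enrichment)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t.\t%s\t-1\t-1\t%d",
                   peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                   format(peaks$score, trim = TRUE, scientific = FALSE),
                   format(enr, trim = TRUE, scientific = FALSE), offset)
  writeLines(lines, path)
  invisible(path)
}

#' Read a MACS14 peak table
#'
#' MACS14 `.xls` output is a tab-separated table with `#` comment lines and
#' a header row; coordinates are 1-based inclusive and the summit column is
#' an absolute 1-based position. Both are converted to the internal 0-based
#' half-open convention. A missing summit column triggers midpoint
#' imputation with a warning.
#'
#' @param path MACS14 `.xls`-style table.
#' @return data.frame of peak calls (same shape as [read_narrowpeak()]).
#' @export
read_macs_xls <- function(path) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path)
  n_comment <- sum(startsWith(lines, "#") | !nzchar(lines))
  if (n_comment > 0)
    message(n_comment, " comment/blank line(s) skipped in ", path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) stop("no data rows in ", path)
  tab <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("chr", "start", "end")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("MACS table missing column(s): ", paste(miss, collapse = ", "))
  start0 <- as.integer(tab$start) - 1L
  end0 <- as.integer(tab$end)
  if ("summit" %in% names(tab)) {
    summit <- as.integer(tab$summit) - 1L
    imputed <- rep(FALSE, nrow(tab))
  } else {
    warning("no summit column in ", path, "; imputing interval midpoints")
    summit <- (start0 + end0) %/% 2L
    imputed <- rep(TRUE, nrow(tab))
  }
  score_col <- grep("log10\\(pvalue\\)", names(tab), value = TRUE)
  score <- if (length(score_col)) as.numeric(tab[[score_col[1]]]) else NA_real_
  enr <- if ("fold_enrichment" %in% names(tab)) as.numeric(tab$fold_enrichment) else NA_real_
  ids <- if ("name" %in% names(tab)) as.character(tab$name) else
    sprintf("macs_peak_%d", seq_len(nrow(tab)))
  .peak_frame(ids, tab$chr, start0, end0, summit, score, enr, imputed)
}

#' Write peak calls as a MACS14-style table
#'
#' @param peaks peak data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_macs_xls <- function(peaks, path) {
  header <- c("# peaktargets export, MACS14-compatible layout",
              paste("chr", "start", "end", "length", "summit", "tags",
                    "-10*log10(pvalue)", "fold_enrichment", "name", sep = "\t"))
  enr <- ifelse(is.na(peaks$enrichment), 0, peaks$enrichment)
  rows <- sprintf("%s\t%d\t%d\t%d\t%d\t0\t%s\t%s\t%s",
                  peaks$chrom, peaks$start + 1L, peaks$end,
                  peaks$end - peaks$start, peaks$summit + 1L,
                  format(peaks$score, trim = TRUE, scientific = FALSE),
                  format(enr, trim = TRUE, scientific = FALSE),
                  peaks$peak_id)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Load an artifact blacklist from BED
#'
#' Intervals are sorted per chromosome and overlapping or book-ended
#' entries are merged on load.
#'
#' @param path BED3 file of artifact regions (0-based half-open).
#' @return data.frame with columns `chrom`, `start`, `end`, sorted, merged;
#'   class `blacklist_set`.
#' @export
read_blacklist <- function(path) {
  if (!file.exists(path)) stop("blacklist file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  blacklist_set(data.frame(chrom = as.character(tab[[1]]),
                           start = as.integer(tab[[2]]),
                           end = as.integer(tab[[3]]),
                           stringsAsFactors = FALSE))
}

#' Construct a blacklist set from an interval table
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open); overlapping entries are merged.
#' @return data.frame of class `blacklist_set`.
#' @export
blacklist_set <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$end <= intervals$start)) stop("blacklist interval with end <= start")
  parts <- split(intervals, intervals$chrom)
  merged <- lapply(names(parts), function(ch) {
    ir <- reduce(IRanges(parts[[ch]]$start + 1L, parts[[ch]]$end))
    data.frame(chrom = ch, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("blacklist_set", "data.frame")
  out
}

#' Filter peaks against a blacklist
#'
#' A peak is removed when its interval overlaps any blacklist interval by
#' at least 1 bp (`mode = "interval"`, the default) or when its summit base
#' falls inside a blacklist interval (`mode = "summit"`). Intervals are
#' half-open, so book-ended features never overlap. The two returned sets
#' partition the input in its original order.
#'
#' @param peaks peak data.frame.
#' @param blacklist a `blacklist_set` (or `NULL` for a no-op).
#' @param mode `"interval"` or `"summit"`.
#' @return list with elements `kept` and `removed`, both peak data.frames.
#' @export
filter_blacklist <- function(peaks, blacklist, mode = c("interval", "summit")) {
  mode <- match.arg(mode)
  if (is.null(blacklist) || nrow(blacklist) == 0L || nrow(peaks) == 0L)
    return(list(kept = peaks, removed = peaks[0, , drop = FALSE]))
  hit <- rep(FALSE, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    bl <- blacklist[blacklist$chrom == ch, , drop = FALSE]
    if (!nrow(bl)) next
    sel <- which(peaks$chrom == ch)
    q <- if (mode == "interval")
      IRanges(peaks$start[sel] + 1L, peaks$end[sel])
    else
      IRanges(peaks$summit[sel] + 1L, peaks$summit[sel] + 1L)
    ov <- findOverlaps(q, IRanges(bl$start + 1L, bl$end))
    hit[sel[unique(queryHits(ov))]] <- TRUE
  }
  list(kept = peaks[!hit, , drop = FALSE], removed = peaks[hit, , drop = FALSE])
}
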