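#' Construct a set of transcript models
#'
#' Bundles a transcript table and an exon table into a validated
#' `transcript_models` container. All coordinates are 0-based half-open;
#' conversion from 1-based file formats (GTF) happens at the I/O boundary.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `gene_name`, `chrom`, `start`, `end`, `strand` (`"+"` or `"-"`).
#'   `start`/`end` delimit the transcript locus, 0-based half-open.
#' @param exons data.frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open). Every transcript must own at least one exon;
#'   exons of a transcript must be sorted and non-overlapping and contained
#'   in the transcript locus.
#' @return An object of class `transcript_models`: a list with elements
#'   `transcripts` and `exons` (both data.frames, exons sorted by
#'   transcript then start).
#' @export
transcript_models <- function(transcripts, exons) {
  req_t <- c("transcript_id", "gene_id", "gene_name", "chrom", "start", "end", "strand")
  req_e <- c("transcript_id", "start", "end")
  miss <- setdiff(req_t, names(transcripts))
  if (length(miss)) stop("transcripts table missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(req_e, names(exons))
  if (length(miss)) stop("exons table missing column(s): ", paste(miss, collapse = ", "))

  transcripts <- as.data.frame(transcripts)[req_t]
  exons <- as.data.frame(exons)[req_e]
  transcripts$start <- as.integer(transcripts$start)
  transcripts$end <- as.integer(transcripts$end)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)

  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicate transcript_id in transcript table: ",
         paste(unique(transcripts$transcript_id[duplicated(transcripts$transcript_id)]),
               collapse = ", "))
  if (!all(transcripts$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(transcripts$start < 0) || any(transcripts$end <= transcripts$start))
    stop("invalid transcript locus: require 0 <= start < end")
  if (any(!nzchar(transcripts$chrom))) stop("empty chromosome name")

  ord <- order(exons$transcript_id, exons$start)
  exons <- exons[ord, , drop = FALSE]
  rownames(exons) <- NULL
  rownames(transcripts) <- NULL

  if (!all(exons$transcript_id %in% transcripts$transcript_id))
    stop("exon refers to unknown transcript_id")
  if (!all(transcripts$transcript_id %in% exons$transcript_id))
    stop("transcript without exons: ",
         paste(setdiff(transcripts$transcript_id, exons$transcript_id), collapse = ", "))
  if (any(exons$start < 0) || any(exons$end <= exons$start))
    stop("invalid exon interval: require 0 <= start < end")

  # containment + non-overlap, vectorized over the sorted exon table
  idx <- match(exons$transcript_id, transcripts$transcript_id)
  if (any(exons$start < transcripts$start[idx]) || any(exons$end > transcripts$end[idx]))
    stop("exon outside its transcript locus")
  same_tx <- exons$transcript_id[-1] == exons$transcript_id[-nrow(exons)]
  if (nrow(exons) > 1 && any(same_tx & exons$start[-1] < exons$end[-nrow(exons)]))
    stop("overlapping exons within a transcript")

  structure(list(transcripts = transcripts, exons = exons),
            class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat(sprintf("transcript_models: %d transcripts, %d exons, %d chromosome(s)\n",
              nrow(x$transcripts), nrow(x$exons),
              length(unique(x$transcripts$chrom))))
  invisible(x)
}

.parse_gtf_attr <- function(attr, key) {
  pat <- paste0(key, ' "([^"]*)"')
  m <- regmatches(attr, regexec(pat, attr))
  vapply(m, function(g) if (length(g) == 2L) g[2] else NA_character_, character(1))
}

#' Parse gene models from a GTF file
#'
#' Reads an Ensembl-dialect GTF (9 tab-separated columns, attributes as
#' `key "value";` pairs) and returns strand-aware transcript models with
#' exon structure. GTF 1-based inclusive coordinates are converted to the
#' internal 0-based half-open convention. When a `transcript` feature line
#' is present it defines the locus; otherwise the locus is the envelope of
#' the transcript's exons.
#'
#' Exon records lacking a `transcript_id` attribute are skipped with a
#' warning (count reported); a structurally malformed line (wrong column
#' count) is a hard error naming the line number. A transcript_id observed
#' on more than one chromosome is a hard error.
#'
#' @param path path to a GTF file.
#' @param feature_filter character vector of feature types (column 3) to
#'   consume; default `c("transcript", "exon")`.
#' @return A [transcript_models] object. An empty file yields a container
#'   with zero transcripts.
#' @export
parse_gtf <- function(path, feature_filter = c("transcript", "exon")) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    empty_t <- data.frame(transcript_id = character(), gene_id = character(),
                          gene_name = character(), chrom = character(),
                          start = integer(), end = integer(), strand = character(),
                          stringsAsFactors = FALSE)
    empty_e <- data.frame(transcript_id = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
    return(structure(list(transcripts = empty_t, exons = empty_e),
                     class = "transcript_models"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1]
    stop("malformed GTF line ", bad, ": expected 9 tab-separated columns, got ", nf[bad])
  }
  mat <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  keep <- mat[, 3] %in% feature_filter
  mat <- mat[keep, , drop = FALSE]
  if (!nrow(mat)) stop("no records of type ", paste(feature_filter, collapse = "/"),
                       " in ", path)

  chrom <- mat[, 1]
  feature <- mat[, 3]
  start1 <- suppressWarnings(as.integer(mat[, 4]))
  end1 <- suppressWarnings(as.integer(mat[, 5]))
  strand <- mat[, 7]
  if (anyNA(start1) || anyNA(end1))
    stop("malformed GTF line ", which(keep)[which(is.na(start1) | is.na(end1))[1]],
         ": non-numeric coordinates")
  attr_col <- mat[, 9]
  tx_id <- .parse_gtf_attr(attr_col, "transcript_id")
  g_id <- .parse_gtf_attr(attr_col, "gene_id")
  g_name <- .parse_gtf_attr(attr_col, "gene_name")

  no_tx <- is.na(tx_id)
  if (any(no_tx)) {
    warning(sum(no_tx), " record(s) without transcript_id skipped")
    chrom <- chrom[!no_tx]; feature <- feature[!no_tx]
    start1 <- start1[!no_tx]; end1 <- end1[!no_tx]; strand <- strand[!no_tx]
    tx_id <- tx_id[!no_tx]; g_id <- g_id[!no_tx]; g_name <- g_name[!no_tx]
  }

  # internal convention: 0-based half-open
  start0 <- start1 - 1L
  end0 <- end1

  is_exon <- feature == "exon"
  if (!any(is_exon)) stop("GTF contains no exon records for requested features")

  ex <- data.frame(transcript_id = tx_id[is_exon], start = start0[is_exon],
                   end = end0[is_exon], chrom = chrom[is_exon],
                   strand = strand[is_exon], gene_id = g_id[is_exon],
                   gene_name = g_name[is_exon], stringsAsFactors = FALSE)

  if (any(tapply(ex$chrom, ex$transcript_id, function(x) length(unique(x))) > 1L))
    stop("transcript_id present on multiple chromosomes")

  # per-transcript metadata from exon lines; transcript feature lines override the locus
  first <- !duplicated(ex$transcript_id)
  tx <- data.frame(transcript_id = ex$transcript_id[first],
                   gene_id = ex$gene_id[first],
                   gene_name = ifelse(is.na(ex$gene_name[first]), "",
                                      ex$gene_name[first]),
                   chrom = ex$chrom[first],
                   strand = ex$strand[first],
                   stringsAsFactors = FALSE)
  env_start <- tapply(ex$start, ex$transcript_id, min)
  env_end <- tapply(ex$end, ex$transcript_id, max)
  tx$start <- as.integer(env_start[tx$transcript_id])
  tx$end <- as.integer(env_end[tx$transcript_id])

  is_tx_line <- feature == "transcript"
  if (any(is_tx_line)) {
    tl_id <- tx_id[is_tx_line]
    hit <- match(tx$transcript_id, tl_id)
    has <- !is.na(hit)
    tx$start[has] <- start0[is_tx_line][hit[has]]
    tx$end[has] <- end0[is_tx_line][hit[has]]
    # transcript lines may carry gene_name where exon lines do not
    tl_name <- g_name[is_tx_line]
    upd <- has & !nzchar(tx$gene_name) & !is.na(tl_name[hit])
    tx$gene_name[upd] <- tl_name[hit[upd]]
  }

  transcript_models(tx[, c("transcript_id", "gene_id", "gene_name",
                           "chrom", "start", "end", "strand")],
                    ex[, c("transcript_id", "start", "end")])
}

#' Write transcript models to GTF
#'
#' Emits one `transcript` line and one `exon` line per exon, converting the
#' internal 0-based half-open coordinates back to GTF's 1-based inclusive
#' convention. `parse_gtf(write_gtf(x))` is the identity on valid models.
#'
#' @param models a [transcript_models] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  stopifnot(inherits(models, "transcript_models"))
  tx <- models$transcripts
  ex <- models$exons
  attr_str <- function(tid, gid, gname) {
    base <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
    ifelse(nzchar(gname), paste0(base, sprintf(' gene_name "%s";', gname)), base)
  }
  tx_lines <- sprintf("%s\tpeaktargets\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                      tx$chrom, tx$start + 1L, tx$end, tx$strand,
                      attr_str(tx$transcript_id, tx$gene_id, tx$gene_name))
  i <- match(ex$transcript_id, tx$transcript_id)
  ex_lines <- sprintf("%s\tpeaktargets\texon\t%d\t%d\t.\t%s\t.\t%s",
                      tx$chrom[i], ex$start + 1L, ex$end, tx$strand[i],
                      attr_str(ex$transcript_id, tx$gene_id[i], tx$gene_name[i]))
  # keep transcript line adjacent to its exons
  ord_t <- order(tx$chrom, tx$start)
  out <- character(0)
  for (k in ord_t) {
    out <- c(out, tx_lines[k], ex_lines[i == k])
  }
  writeLines(out, path)
  invisible(path)
}

#' Derive transcription start sites
#'
#' The TSS is the first transcribed base: locus start on the `+` strand,
#' `end - 1` on the `-` strand (0-based).
#'
#' @param models a [transcript_models] object.
#' @return data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `position` (0-based), `strand`, one row per transcript.
#' @export
derive_tss <- function(models) {
  stopifnot(inherits(models, "transcript_models"))
  tx <- models$transcripts
  if (!all(tx$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  data.frame(transcript_id = tx$transcript_id,
             gene_id = tx$gene_id,
             chrom = tx$chrom,
             position = ifelse(tx$strand == "+", tx$start, tx$end - 1L),
             strand = tx$strand,
             stringsAsFactors = FALSE)
}

#' Locate a position relative to a transcript's exon structure
#'
#' @param models a [transcript_models] object.
#' @param transcript_id single transcript identifier.
#' @param position integer vector of 0-based positions (on the transcript's
#'   chromosome).
#' @return character vector: `"exonic"` if the position falls inside an
#'   exon, `"intronic"` if inside the locus but in no exon, `"outside"`
#'   otherwise.
#' @export
point_in_exon <- function(models, transcript_id, position) {
  stopifnot(inherits(models, "transcript_models"))
  i <- match(transcript_id, models$transcripts$transcript_id)
  if (is.na(i)) stop("unknown transcript_id: ", transcript_id)
  locus <- models$transcripts[i, ]
  ex <- models$exons[models$exons$transcript_id == transcript_id, ]
  inside <- position >= locus$start & position < locus$end
  in_exon <- vapply(position, function(p) any(p >= ex$start & p < ex$end), logical(1))
  out <- rep("outside", length(position))
  out[inside] <- "intronic"
  out[inside & in_exon] <- "exonic"
  out
}
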