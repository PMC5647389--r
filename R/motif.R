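#' @importFrom Biostrings DNAString DNAStringSet matchPattern reverseComplement
#'   readDNAStringSet subseq
NULL

.check_motif <- function(motif) {
  motif <- toupper(motif)
  if (nchar(motif) < 4L) stop("motif must be at least 4 bases")
  if (grepl("[^ACGT]", motif))
    stop("motif may contain only A, C, G, T (no ambiguity codes)")
  motif
}

#' Scan a sequence for exact occurrences of a fixed motif
#'
#' Reports every exact occurrence of `motif` on the forward strand and,
#' when `both_strands`, of its reverse complement (reported as a `-`
#' strand hit at its forward-strand offset). Overlapping occurrences are
#' all reported; `N` in the sequence never matches.
#'
#' @param sequence DNA as a character string or [Biostrings::DNAString]
#'   (alphabet A/C/G/T/N).
#' @param motif exact word over A/C/G/T, length >= 4.
#' @param both_strands scan the reverse complement word too (default TRUE).
#' @param seq_id identifier recorded in the hit table.
#' @return data.frame of hits: `seq_id`, `position` (0-based forward-strand
#'   offset), `strand`, `motif`; sorted by position. A motif longer than
#'   the sequence yields zero rows.
#' @export
scan_motif <- function(sequence, motif, both_strands = TRUE, seq_id = "seq") {
  motif <- .check_motif(motif)
  seq <- if (is(sequence, "DNAString")) sequence else DNAString(toupper(as.character(sequence)))
  empty <- data.frame(seq_id = character(), position = integer(),
                      strand = character(), motif = character(),
                      stringsAsFactors = FALSE)
  if (nchar(motif) > length(seq)) return(empty)
  hit_df <- function(word, strand) {
    m <- matchPattern(DNAString(word), seq, fixed = TRUE)
    if (!length(m)) return(empty)
    data.frame(seq_id = seq_id, position = BiocGenerics::start(m) - 1L,
               strand = strand, motif = motif, stringsAsFactors = FALSE)
  }
  out <- hit_df(motif, "+")
  if (both_strands) {
    rc <- as.character(reverseComplement(DNAString(motif)))
    # a palindromic word would duplicate the forward hits; report once
    if (!identical(rc, motif)) out <- rbind(out, hit_df(rc, "-"))
  }
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call motif clusters by positional chaining
#'
#' A cluster is a maximal run of hits (per sequence) in which consecutive
#' hit starts differ by at most `window_bp`; runs with fewer than
#' `min_hits` members are dropped.
#'
#' @param hits hit data.frame from [scan_motif()].
#' @param window_bp maximum gap between consecutive hit starts (default 200).
#' @param min_hits minimum hits per reported cluster (default 2).
#' @return data.frame of clusters: `seq_id`, `start`, `end` (0-based
#'   half-open span of member hit words), `n_hits`, `positions`
#'   (comma-separated member starts).
#' @export
call_clusters <- function(hits, window_bp = 200L, min_hits = 2L) {
  if (window_bp <= 0L) stop("window_bp must be positive")
  if (min_hits < 2L) stop("min_hits must be at least 2")
  empty <- data.frame(seq_id = character(), start = integer(), end = integer(),
                      n_hits = integer(), positions = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(hits)) return(empty)
  out <- empty
  for (sid in unique(hits$seq_id)) {
    h <- hits[hits$seq_id == sid, , drop = FALSE]
    pos <- sort(h$position)
    wlen <- nchar(h$motif[1])
    run_id <- cumsum(c(1L, as.integer(diff(pos) > window_bp)))
    for (r in unique(run_id)) {
      p <- pos[run_id == r]
      if (length(p) >= min_hits)
        out <- rbind(out, data.frame(seq_id = sid, start = min(p),
                                     end = max(p) + wlen,
                                     n_hits = length(p),
                                     positions = paste(p, collapse = ","),
                                     stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Extract strand-aware promoter windows around TSSs
#'
#' For each transcript a window of `upstream_bp` before and `downstream_bp`
#' after the TSS is cut from the genome. Minus-strand windows are
#' reverse-complemented so that, in every returned sequence, offset 0 is
#' the most upstream base and the TSS sits at offset `upstream_bp`.
#' Windows running off a contig edge are truncated and flagged.
#'
#' @param models a [transcript_models] object.
#' @param fasta genome sequence: a named [Biostrings::DNAStringSet] or a
#'   FASTA file path.
#' @param upstream_bp bases upstream of the TSS (default 3000).
#' @param downstream_bp bases downstream (default 500).
#' @return list with `sequences` (DNAStringSet named by transcript_id) and
#'   `info` (data.frame `transcript_id`, `chrom`, `genomic_start`,
#'   `genomic_end`, `strand`, `truncated`).
#' @export
extract_promoter_sequences <- function(models, fasta, upstream_bp = 3000L,
                                       downstream_bp = 500L) {
  stopifnot(inherits(models, "transcript_models"))
  genome <- if (is.character(fasta)) readDNAStringSet(fasta) else fasta
  names(genome) <- sub("\\s.*$", "", names(genome))
  tss <- derive_tss(models)
  absent <- setdiff(unique(tss$chrom), names(genome))
  if (length(absent))
    stop("chromosome(s) absent from FASTA: ", paste(absent, collapse = ", "))
  seqs <- vector("list", nrow(tss))
  info <- data.frame(transcript_id = tss$transcript_id, chrom = tss$chrom,
                     genomic_start = NA_integer_, genomic_end = NA_integer_,
                     strand = tss$strand, truncated = FALSE,
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tss))) {
    clen <- length(genome[[tss$chrom[i]]])
    if (tss$strand[i] == "+") {
      s0 <- tss$position[i] - upstream_bp
      e0 <- tss$position[i] + downstream_bp
    } else {
      s0 <- tss$position[i] - downstream_bp + 1L
      e0 <- tss$position[i] + upstream_bp + 1L
    }
    cs <- max(s0, 0L); ce <- min(e0, clen)
    info$truncated[i] <- (cs != s0) || (ce != e0)
    info$genomic_start[i] <- cs
    info$genomic_end[i] <- ce
    piece <- subseq(genome[[tss$chrom[i]]], start = cs + 1L, end = ce)
    if (tss$strand[i] == "-") piece <- reverseComplement(piece)
    seqs[[i]] <- piece
  }
  sequences <- DNAStringSet(seqs)
  names(sequences) <- tss$transcript_id
  list(sequences = sequences, info = info)
}
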