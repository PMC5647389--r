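# Small constructed fixtures and independent brute-force oracles.
# Oracles here never call the vectorized implementation paths they check.

# two-gene toy: a + strand two-exon gene and a - strand single-exon gene
toy_models <- function() {
  transcript_models(
    transcripts = data.frame(
      transcript_id = c("t1", "t2"),
      gene_id = c("g1", "g2"),
      gene_name = c("alpha", "beta"),
      chrom = c("chr1", "chr1"),
      start = c(100L, 100000L),
      end = c(400L, 100200L),
      strand = c("+", "-"),
      stringsAsFactors = FALSE),
    exons = data.frame(
      transcript_id = c("t1", "t1", "t2"),
      start = c(100L, 300L, 100000L),
      end = c(200L, 400L, 100200L),
      stringsAsFactors = FALSE))
}

random_peak_frame <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6) {
  start <- sample.int(max_pos, n, replace = TRUE)
  w <- sample(50:500, n, replace = TRUE)
  data.frame(peak_id = sprintf("p%04d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + w,
             summit = start + sample(0:49, n, replace = TRUE),
             score = runif(n, 1, 100), enrichment = NA_real_,
             summit_imputed = FALSE, stringsAsFactors = FALSE)
}

# O(n*m) pairwise half-open overlap scan
oracle_blacklist_hit <- function(peaks, blacklist, mode = "interval") {
  vapply(seq_len(nrow(peaks)), function(i) {
    s <- if (mode == "interval") peaks$start[i] else peaks$summit[i]
    e <- if (mode == "interval") peaks$end[i] else peaks$summit[i] + 1L
    any(blacklist$chrom == peaks$chrom[i] &
          blacklist$start < e & s < blacklist$end)
  }, logical(1))
}

# per-peak linear scan over every transcript; mirrors the stated rules,
# not the indexed implementation
oracle_classify <- function(summit, chrom, models,
                            config = classifier_config()) {
  tx <- models$transcripts
  best <- 5L  # intergenic
  prec <- c(proximal = 1L, distal = 2L, exonic = 3L, intronic = 4L)
  for (i in seq_len(nrow(tx))) {
    if (tx$chrom[i] != chrom) next
    tss_pos <- if (tx$strand[i] == "+") tx$start[i] else tx$end[i] - 1L
    d <- if (tx$strand[i] == "+") tss_pos - summit else summit - tss_pos
    if (d >= 0 && d <= config$proximal_max) best <- min(best, prec[["proximal"]])
    else if (d > config$proximal_max && d <= config$distal_max)
      best <- min(best, prec[["distal"]])
    if (summit >= tx$start[i] && summit < tx$end[i]) {
      ex <- models$exons[models$exons$transcript_id == tx$transcript_id[i], ]
      in_ex <- any(summit >= ex$start & summit < ex$end)
      best <- min(best, if (in_ex) prec[["exonic"]] else prec[["intronic"]])
    }
  }
  c("proximal_promoter", "distal_promoter", "exonic", "intronic",
    "intergenic")[best]
}

# exact upper-tail hypergeometric by enumeration of all C(N, n) draws:
# items 1..K are annotated; count draws with >= k of them
oracle_hyper_tail <- function(k, K, n, N) {
  if (n == 0L) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  succ <- colSums(draws <= K)
  mean(succ >= k)
}

# sliding-window exact match scan, both strands
oracle_scan <- function(seq_chr, motif) {
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(motif, "")[[1]]), collapse = ""))
  L <- nchar(motif)
  n <- nchar(seq_chr)
  hits <- list()
  if (n >= L) for (p in 0:(n - L)) {
    word <- substr(seq_chr, p + 1L, p + L)
    if (word == motif)
      hits[[length(hits) + 1L]] <- data.frame(position = p, strand = "+")
    if (rc != motif && word == rc)
      hits[[length(hits) + 1L]] <- data.frame(position = p, strand = "-")
  }
  if (!length(hits)) return(data.frame(position = integer(), strand = character()))
  do.call(rbind, hits)
}

# transitive closure of the pairwise |p_i - p_j| <= window relation; on a
# line this equals consecutive-gap chaining
oracle_clusters <- function(positions, window_bp, min_hits) {
  n <- length(positions)
  if (!n) return(list())
  pos <- sort(positions)
  comp <- seq_len(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(pos[i] - pos[j]) <= window_bp) {
      ci <- comp[i]; cj <- comp[j]
      comp[comp == max(ci, cj)] <- min(ci, cj)
    }
  }
  runs <- split(pos, comp)
  Filter(function(p) length(p) >= min_hits, unname(runs))
}

# coordinate reflection: maps every interval [s, e) on a chromosome of
# length len to [len - e, len - s) and flips strands/summits
mirror_models <- function(models, len) {
  tx <- models$transcripts
  ex <- models$exons
  new_tx <- tx
  new_tx$start <- len - tx$end
  new_tx$end <- len - tx$start
  new_tx$strand <- ifelse(tx$strand == "+", "-", "+")
  new_ex <- ex
  new_ex$start <- len - ex$end
  new_ex$end <- len - ex$start
  transcript_models(new_tx, new_ex)
}

make_study_files <- function(cfg, dir) {
  models <- simulate_annotation(cfg, gtf_path = file.path(dir, "genes.gtf"))
  sp <- simulate_peaks(cfg, models,
                       narrowpeak_path = file.path(dir, "peaks.narrowPeak"))
  de <- simulate_de_table(cfg, models, sp$truth,
                          path = file.path(dir, "gene_exp.diff"))
  list(models = models, peaks = sp, de = de)
}
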