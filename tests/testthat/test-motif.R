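test_that("exact scan reports overlapping hits on both strands", {
  hits <- scan_motif("GGCCGGCCGG", "GGCCGG")
  expect_equal(hits$position[hits$strand == "+"], c(0L, 4L))
  expect_equal(hits$position[hits$strand == "-"], 2L)  # CCGGCC at offset 2

  expect_equal(nrow(scan_motif("ATATATATAT", "GGCCGG")), 0L)
  expect_equal(nrow(scan_motif("ACGT", "GGCCGG")), 0L)  # motif longer than seq
  # N never matches
  expect_equal(nrow(scan_motif("GGCCGNGGCCGN", "GGCCGG")), 0L)
  expect_error(scan_motif("ACGTACGT", "GGYCGG"), "A, C, G, T")
})

test_that("scan is symmetric under reverse complement", {
  set.seed(14)
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
    fwd <- scan_motif(s, "GGCCGG")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    rev_hits <- scan_motif(rc, "GGCCGG")
    # mirror positions and swap strands
    mirrored <- data.frame(
      position = nchar(s) - 6L - rev_hits$position,
      strand = as.character(ifelse(rev_hits$strand == "+", "-", "+")),
      stringsAsFactors = FALSE)
    mirrored <- mirrored[order(mirrored$position, mirrored$strand), ]
    expect_equal(fwd$position, mirrored$position)
    expect_equal(fwd$strand, mirrored$strand)
  }
})

test_that("scan equals the sliding-window brute force on random sequences", {
  set.seed(26)
  for (rep in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 400,
                      replace = TRUE, prob = c(.24, .24, .28, .2, .04)),
               collapse = "")
    motif <- c("GGCCGG", "ACGT", "GGGG")[1 + rep %% 3]
    got <- scan_motif(s, motif)
    exp <- oracle_scan(s, motif)
    exp <- exp[order(exp$position, exp$strand), ]
    expect_equal(got$position, exp$position)
    expect_equal(got$strand, exp$strand)
  }
})

test_that("cluster chaining: definition cases and brute-force equivalence", {
  hits <- data.frame(seq_id = "s", position = c(0L, 10L, 500L),
                     strand = "+", motif = "GGCCGG", stringsAsFactors = FALSE)
  cl <- call_clusters(hits, window_bp = 100, min_hits = 2)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$positions, "0,10")
  expect_equal(cl$n_hits, 2L)
  expect_equal(cl$end, 10L + 6L)

  expect_equal(nrow(call_clusters(hits[0, ], 100, 2)), 0L)

  set.seed(37)
  for (rep in 1:20) {
    n <- sample(2:60, 1)
    pos <- sort(sample.int(3000, n))
    hits <- data.frame(seq_id = "s", position = pos, strand = "+",
                       motif = "GGCCGG", stringsAsFactors = FALSE)
    w <- sample(c(20L, 100L, 300L), 1)
    mh <- sample(2:3, 1)
    got <- call_clusters(hits, w, mh)
    exp <- oracle_clusters(pos, w, mh)
    expect_equal(nrow(got), length(exp))
    if (length(exp))
      expect_equal(got$positions,
                   vapply(exp, function(p) paste(p, collapse = ","), character(1)))
  }
})

test_that("cluster calling is idempotent and order-independent", {
  set.seed(41)
  pos <- sample.int(2000, 30)
  hits <- data.frame(seq_id = "s", position = pos, strand = "+",
                     motif = "GGCCGG", stringsAsFactors = FALSE)
  a <- call_clusters(hits, 150, 2)
  b <- call_clusters(hits[sample(nrow(hits)), ], 150, 2)
  expect_equal(a, b)
})

test_that("promoter extraction windows are strand-aware", {
  # chr of 2000 bp with distinguishable content
  chars <- rep(c("A", "C", "G", "T"), 500)
  genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genome) <- "chr1"
  m <- transcript_models(
    data.frame(transcript_id = c("tp", "tm"), gene_id = c("gp", "gm"),
               gene_name = "", chrom = "chr1", start = c(1000L, 500L),
               end = c(1400L, 1001L), strand = c("+", "-"),
               stringsAsFactors = FALSE),
    data.frame(transcript_id = c("tp", "tm"), start = c(1000L, 500L),
               end = c(1400L, 1001L)))
  ex <- extract_promoter_sequences(m, genome, upstream_bp = 100L,
                                   downstream_bp = 50L)
  # + strand TSS 1000: genomic [900, 1050) forward
  expect_equal(ex$info$genomic_start[1], 900L)
  expect_equal(ex$info$genomic_end[1], 1050L)
  expect_equal(as.character(ex$sequences[["tp"]]),
               paste(chars[901:1050], collapse = ""))
  # - strand TSS 1000: genomic [951, 1101) reverse-complemented
  expect_equal(ex$info$genomic_start[2], 951L)
  expect_equal(ex$info$genomic_end[2], 1101L)
  expect_equal(as.character(ex$sequences[["tm"]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(paste(chars[952:1101], collapse = "")))))
  expect_false(any(ex$info$truncated))

  # windows beyond the contig edge are truncated and flagged
  ex2 <- extract_promoter_sequences(m, genome, upstream_bp = 1500L,
                                    downstream_bp = 1500L)
  expect_true(all(ex2$info$truncated))

  bad <- m
  bad$transcripts$chrom <- "chrX"
  expect_error(extract_promoter_sequences(bad, genome), "absent from FASTA")
})

test_that("extraction plus scan recovers every planted motif, both strands", {
  cfg <- sim_config(seed = 19, n_genes = 10, n_chroms = 2, n_peaks = 10)
  models <- simulate_annotation(cfg)
  sim <- simulate_sequences(cfg, models)
  U <- 2000L
  prom <- extract_promoter_sequences(models, sim$sequences, upstream_bp = U,
                                     downstream_bp = 100L)
  for (tid in names(prom$sequences)) {
    hits <- scan_motif(prom$sequences[[tid]], cfg$motif, seq_id = tid)
    planted <- sim$planted[sim$planted$transcript_id == tid, ]
    # plants appear on the promoter's forward strand at U - upstream_offset
    expect_setequal(hits$position[hits$strand == "+"],
                    U - planted$upstream_offset)
  }
  # genome-wide there are no hits beyond the planted ones
  all_hits <- do.call(rbind, lapply(names(sim$sequences), function(ch)
    scan_motif(sim$sequences[[ch]], cfg$motif, seq_id = ch)))
  expect_equal(nrow(all_hits), nrow(sim$planted))

  # zero copies -> zero hits genome-wide
  cfg0 <- sim_config(seed = 19, n_genes = 6, n_chroms = 1, n_peaks = 10,
                     motif_copies = 0L)
  m0 <- simulate_annotation(cfg0)
  s0 <- simulate_sequences(cfg0, m0)
  hits0 <- do.call(rbind, lapply(names(s0$sequences), function(ch)
    scan_motif(s0$sequences[[ch]], cfg0$motif, seq_id = ch)))
  expect_equal(nrow(hits0), 0L)
})
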