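test_that("summit-TSS relation: sign convention and inclusive boundaries", {
  cfg <- classifier_config()
  tss_plus <- list(chrom = "chr1", position = 10000L, strand = "+")
  expect_equal(summit_tss_relation(8500L, "chr1", tss_plus, cfg)$relation, "proximal")
  expect_equal(summit_tss_relation(8500L, "chr1", tss_plus, cfg)$distance, 1500L)
  # 2 kb boundary is inclusive ("less than or equal")
  expect_equal(summit_tss_relation(8000L, "chr1", tss_plus, cfg)$relation, "proximal")
  expect_equal(summit_tss_relation(7999L, "chr1", tss_plus, cfg)$relation, "distal")
  # 50 kb boundary inclusive, beyond it none
  expect_equal(summit_tss_relation(10000L - 50000L, "chr1", tss_plus, cfg)$relation, "distal")
  expect_equal(summit_tss_relation(10000L - 50001L, "chr1", tss_plus, cfg)$relation, "none")
  # summit at the TSS is proximal; past the TSS is not a promoter relation
  expect_equal(summit_tss_relation(10000L, "chr1", tss_plus, cfg)$relation, "proximal")
  expect_equal(summit_tss_relation(10050L, "chr1", tss_plus, cfg)$relation, "none")
  # strand mirror of the first case
  tss_minus <- list(chrom = "chr1", position = 19999L, strand = "-")
  expect_equal(summit_tss_relation(21499L, "chr1", tss_minus, cfg)$relation, "proximal")
  expect_equal(summit_tss_relation(19000L, "chr1", tss_minus, cfg)$relation, "none")
  # chromosome mismatch is none, not an error
  expect_equal(summit_tss_relation(8500L, "chr2", tss_plus, cfg)$relation, "none")
})

test_that("relation sign matches exhaustive enumeration around a toy TSS", {
  cfg <- classifier_config(proximal_max = 20L, distal_max = 100L)
  for (strand in c("+", "-")) {
    tss <- list(chrom = "c", position = 500L, strand = strand)
    for (s in 350:650) {
      d <- if (strand == "+") 500L - s else s - 500L
      expected <- if (d >= 0 && d <= 20) "proximal"
      else if (d > 20 && d <= 100) "distal" else "none"
      expect_equal(summit_tss_relation(s, "c", tss, cfg)$relation, expected)
    }
  }
})

test_that("classify_summit applies precedence and retains associations", {
  # gene A (+, intron 200-300 within [100,400)), gene B with TSS 1 kb
  # downstream of a summit sitting in A's intron
  m <- transcript_models(
    data.frame(transcript_id = c("tA", "tB"), gene_id = c("gA", "gB"),
               gene_name = c("A", "B"), chrom = "chr1",
               start = c(100L, 1250L), end = c(400L, 2000L),
               strand = c("+", "+"), stringsAsFactors = FALSE),
    data.frame(transcript_id = c("tA", "tA", "tB"),
               start = c(100L, 300L, 1250L), end = c(200L, 400L, 2000L)))
  res <- classify_summit(list(peak_id = "p", chrom = "chr1", summit = 250L), m)
  expect_equal(res$peak_class, "proximal_promoter")
  expect_setequal(res$associations$relation, c("proximal", "intronic"))
  expect_equal(res$associations$gene_id[res$associations$relation == "proximal"], "gB")
  expect_equal(res$associations$signed_distance[res$associations$relation == "proximal"], 1000L)

  # 2.5 kb upstream of the only TSS, outside all loci -> distal promoter
  res2 <- classify_summit(list(peak_id = "p2", chrom = "chr1", summit = 100L),
                          transcript_models(
                            data.frame(transcript_id = "t", gene_id = "g",
                                       gene_name = "", chrom = "chr1",
                                       start = 2600L, end = 4000L, strand = "+",
                                       stringsAsFactors = FALSE),
                            data.frame(transcript_id = "t", start = 2600L, end = 4000L)))
  expect_equal(res2$peak_class, "distal_promoter")

  # far from every TSS and inside no locus -> intergenic, no associations
  res3 <- classify_summit(list(peak_id = "p3", chrom = "chr1", summit = 900000L), m)
  expect_equal(res3$peak_class, "intergenic")
  expect_equal(nrow(res3$associations), 0L)
})

test_that("classifier equals the brute-force scan on random summits", {
  cfg <- sim_config(seed = 13, n_genes = 30, n_chroms = 2, n_peaks = 10)
  models <- simulate_annotation(cfg)
  set.seed(99)
  n <- 400
  chroms <- unique(models$transcripts$chrom)
  max_pos <- max(models$transcripts$end) + 60000L
  pk <- data.frame(peak_id = sprintf("r%03d", seq_len(n)),
                   chrom = sample(chroms, n, replace = TRUE),
                   summit = sample.int(max_pos, n) - 1L,
                   stringsAsFactors = FALSE)
  ann <- annotate_peaks(pk, models)$annotations
  expected <- mapply(oracle_classify, pk$summit, pk$chrom,
                     MoreArgs = list(models = models))
  expect_equal(ann$peak_class, unname(expected))
})

test_that("classification is invariant to transcript order and strand mirror", {
  cfg <- sim_config(seed = 21, n_genes = 24, n_chroms = 2, n_peaks = 300)
  models <- simulate_annotation(cfg)
  sp <- simulate_peaks(cfg, models)
  ref <- annotate_peaks(sp$peaks, models)$annotations

  set.seed(1)
  perm <- sample(nrow(models$transcripts))
  shuffled <- transcript_models(models$transcripts[perm, ],
                                models$exons[sample(nrow(models$exons)), ])
  expect_equal(annotate_peaks(sp$peaks, shuffled)$annotations$peak_class,
               ref$peak_class)

  len <- max(models$transcripts$end) + 100000L
  mirrored <- mirror_models(models, len)
  pk_m <- sp$peaks
  pk_m$summit <- len - 1L - sp$peaks$summit
  pk_m$start <- len - sp$peaks$end
  pk_m$end <- len - sp$peaks$start
  expect_equal(annotate_peaks(pk_m, mirrored)$annotations$peak_class,
               ref$peak_class)
})

test_that("distribution summary conserves counts and reports percentages", {
  ann <- data.frame(
    peak_id = sprintf("p%d", 1:4), chrom = "chr1", summit = 1:4,
    peak_class = c("proximal_promoter", "distal_promoter", "exonic", "intergenic"),
    stringsAsFactors = FALSE)
  d <- summarize_distribution(ann)
  expect_equal(unname(d$percentages), c(25, 25, 25, 0, 25))
  expect_equal(d$promoter_total_percent, 50)

  # the published-shape case: counts scaled to n = 1000
  classes <- rep(c("proximal_promoter", "distal_promoter", "exonic",
                   "intronic", "intergenic"), c(43, 297, 9, 179, 472))
  d2 <- summarize_distribution(data.frame(peak_id = seq_along(classes),
                                          chrom = "c", summit = 1,
                                          peak_class = classes))
  expect_equal(unname(d2$percentages), c(4.3, 29.7, 0.9, 17.9, 47.2))
  expect_equal(d2$promoter_total_percent, 34.0)
  expect_equal(sum(d2$counts), d2$n_peaks)
  expect_equal(sum(d2$percentages), 100)

  expect_error(summarize_distribution(ann[0, ]), "empty")
})
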