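test_that("read_cuffdiff: significance, direction and infinities", {
  path <- withr::local_tempfile(fileext = ".diff")
  writeLines(c(
    paste("test_id", "gene_id", "gene", "locus", "sample_1", "sample_2",
          "status", "value_1", "value_2", "log2(fold_change)", "test_stat",
          "p_value", "q_value", "significant", sep = "\t"),
    "g1\tg1\talpha\t-\tWT\tmut\tOK\t10\t2.5\t-1.2\t0\t0.001\t0.01\tyes",
    "g2\tg2\tbeta\t-\tWT\tmut\tOK\t5\t5.2\t0.06\t0\t0.5\t0.8\tno",
    "g3\tg3\tgamma\t-\tWT\tmut\tOK\t0\t7\tinf\t0\t0.001\t0.02\tyes",
    "g4\tg4\tdelta\t-\tWT\tmut\tOK\t7\t0\t-inf\t0\t0.001\t0.02\tyes"), path)
  de <- read_cuffdiff(path)
  expect_equal(de$direction, c("down", "none", "up", "down"))
  expect_equal(de$significant, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(de$log2fc[3:4], c(Inf, -Inf))

  writeLines(c("gene_id\tvalue_1\tvalue_2", "g1\t1\t2"), path)
  expect_error(read_cuffdiff(path), "log2\\(fold_change\\)")

  writeLines(c(
    paste("gene_id", "value_1", "value_2", "log2(fold_change)", "q_value",
          "significant", sep = "\t"),
    "g1\t1\t2\t1\tnot_a_number\tyes"), path)
  expect_error(read_cuffdiff(path), "q_value")
})

test_that("synthetic DE table recovers the constructed down/up totals", {
  cfg <- sim_config(seed = 2, n_genes = 50, n_peaks = 10,
                    n_deg_down = 223, n_deg_up = 220, n_nonsig = 3361)
  models <- simulate_annotation(cfg)
  path <- withr::local_tempfile(fileext = ".diff")
  simulate_de_table(cfg, models, path = path)
  de <- read_cuffdiff(path)
  expect_equal(sum(de$significant), 443L)
  expect_equal(sum(de$direction == "down"), 223L)
  expect_equal(sum(de$direction == "up"), 220L)
  expect_true(all(de$q_value[de$significant] < 0.05))
  expect_true(all(de$q_value[!de$significant] >= 0.05))
})

test_that("DEG-peak intersection follows set algebra on a constructed cohort", {
  # 400 DEGs; peaks on 75 of them and on 120 non-DEG genes
  degs <- data.frame(
    gene_id = sprintf("g%04d", 1:1000),
    gene_name = "x", fpkm_1 = 1, fpkm_2 = 2, log2fc = 1,
    q_value = c(rep(0.01, 400), rep(0.5, 600)),
    significant = rep(c(TRUE, FALSE), c(400, 600)),
    direction = rep(c("up", "none"), c(400, 600)),
    stringsAsFactors = FALSE)
  assoc <- data.frame(
    peak_id = sprintf("p%03d", 1:195),
    transcript_id = "t", relation = "proximal", signed_distance = 100L,
    gene_id = c(sprintf("g%04d", 1:75), sprintf("g%04d", 401:520)),
    stringsAsFactors = FALSE)
  res <- intersect_deg_peaks(degs, assoc)
  expect_equal(res$n_deg, 400L)
  expect_equal(res$n_deg_with_peak, 75L)
  expect_equal(res$venn, list(deg_only = 325L, peak_genes_only = 120L,
                              intersection = 75L))
  expect_equal(res$venn$deg_only + res$venn$intersection, res$n_deg)

  # no peaks -> empty intersection
  res0 <- intersect_deg_peaks(degs, assoc[0, ])
  expect_equal(res0$n_deg_with_peak, 0L)

  # monotone: adding peaks never decreases the intersection; adding
  # non-significant genes never changes it
  extra <- rbind(assoc, data.frame(peak_id = "pX", transcript_id = "t",
                                   relation = "intronic", signed_distance = -5L,
                                   gene_id = "g0076", stringsAsFactors = FALSE))
  expect_gte(intersect_deg_peaks(degs, extra)$n_deg_with_peak, res$n_deg_with_peak)
  more_ns <- rbind(degs, data.frame(gene_id = "zzz", gene_name = "x", fpkm_1 = 1,
                                    fpkm_2 = 1, log2fc = 0, q_value = 1,
                                    significant = FALSE, direction = "none",
                                    stringsAsFactors = FALSE))
  expect_equal(intersect_deg_peaks(more_ns, assoc)$n_deg_with_peak,
               res$n_deg_with_peak)
})

test_that("planted peak-DEG associations are recovered exactly", {
  cfg <- sim_config(seed = 4, n_genes = 120, n_peaks = 600,
                    n_deg_down = 50, n_deg_up = 50, n_nonsig = 400,
                    frac_deg_with_peak = 0.3)
  models <- simulate_annotation(cfg)
  sp <- simulate_peaks(cfg, models)
  de <- simulate_de_table(cfg, models, sp$truth)
  ann <- annotate_peaks(sp$peaks, models)
  res <- intersect_deg_peaks(de$degs, ann)
  expect_equal(res$n_deg, 100L)
  expect_equal(res$n_deg_with_peak, 30L)
  expect_setequal(res$genes$gene_id,
                  de$truth$gene_id[de$truth$significant & de$truth$has_peak])

  # frac 0 -> empty intersection
  cfg0 <- sim_config(seed = 4, n_genes = 120, n_peaks = 600,
                     n_deg_down = 50, n_deg_up = 50, n_nonsig = 400,
                     frac_deg_with_peak = 0)
  de0 <- simulate_de_table(cfg0, models, sp$truth)
  expect_equal(intersect_deg_peaks(de0$degs, ann)$n_deg_with_peak, 0L)
})

test_that("replicate QC: perfect and affine-equivalent replicates are kept", {
  set.seed(8)
  base <- 2^rnorm(500, 8, 2)          # large FPKM so the +1 pseudocount is negligible
  mat <- cbind(r1 = base, r2 = base, r3 = base * 2)
  qc <- replicate_qc(mat, rep("WT", 3))
  expect_equal(qc$cor_matrix["r1", "r2"], 1.0)
  expect_gt(qc$cor_matrix["r1", "r3"], 0.999)  # scaling is a log-scale shift
  expect_equal(qc$discarded, character(0))

  # per-replicate positive scaling (library size) does not change the outcome
  mat2 <- sweep(mat, 2, c(0.5, 1, 7), "*")
  expect_equal(replicate_qc(mat2, rep("WT", 3))$kept, qc$kept)

  # zero-variance replicate is auto-discarded with a warning
  mat3 <- cbind(mat, r4 = rep(3, 500))
  expect_warning(qc3 <- replicate_qc(mat3, rep("WT", 4)), "zero-variance")
  expect_true("r4" %in% qc3$discarded)
  expect_true(all(c("r1", "r2", "r3") %in% qc3$kept))
})

test_that("planted outlier replicates are the ones discarded", {
  cfg <- sim_config(seed = 6)
  sim <- simulate_replicate_matrix(cfg)
  qc <- replicate_qc(sim$mat, sim$conditions, min_corr = 0.9)
  expect_equal(sort(qc$discarded), sim$outliers)
  expect_equal(length(qc$kept), 8L)
})
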