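#' Simulation configuration
#'
#' Parameters for the seeded generators that emit every input the pipeline
#' consumes, with known ground truth. Defaults mirror the shapes of the
#' study this pipeline reproduces: a peak class mix of
#' 4.3/29.7/0.9/17.9/47.2 percent
#' (proximal/distal/exonic/intronic/intergenic), a differential-expression
#' table with 2233 down- and 2206 up-regulated genes among 38,052, a
#' peak-associated DEG fraction of 344/4439, GGCCGG motif clusters of 3
#' copies within 200 bp placed ~1.5 kb upstream of the TSS, and a 5+5
#' replicate design with 2 corrupted wild-type replicates.
#'
#' @param seed integer seed; every generator derives its RNG stream from it.
#' @param n_chroms number of chromosomes.
#' @param n_genes number of genes (one transcript each).
#' @param exons_per_gene integer range `c(min, max)` of exons per gene.
#' @param chrom_length_bp chromosome length; `NULL` (default) sizes
#'   chromosomes automatically from the slot layout.
#' @param n_peaks number of peaks to place.
#' @param class_mix named proportions over the five peak classes; must sum
#'   to 1.
#' @param peak_width integer range of peak interval widths.
#' @param n_deg_down,n_deg_up,n_nonsig DE table composition.
#' @param frac_deg_with_peak fraction of DEGs planted on peak-hosting genes.
#' @param motif exact binding word planted in promoters.
#' @param motif_copies copies planted per promoter.
#' @param motif_window span (bp) containing the planted copies.
#' @param motif_upstream center of the planted cluster, bp upstream of TSS.
#' @param qc_n_genes,qc_reps_per_condition,qc_n_outliers,qc_noise_sd
#'   replicate-matrix generator: gene count, replicates per condition,
#'   corrupted wild-type replicates, and the extra log2-scale noise sd
#'   injected into them.
#' @param proximal_max,distal_max classifier thresholds the ground truth is
#'   constructed against.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 5L,
                       n_genes = 1000L,
                       exons_per_gene = c(2L, 6L),
                       chrom_length_bp = NULL,
                       n_peaks = 5000L,
                       class_mix = c(proximal_promoter = 0.043,
                                     distal_promoter = 0.297,
                                     exonic = 0.009,
                                     intronic = 0.179,
                                     intergenic = 0.472),
                       peak_width = c(200L, 400L),
                       n_deg_down = 2233L,
                       n_deg_up = 2206L,
                       n_nonsig = 33613L,
                       frac_deg_with_peak = 344 / 4439,
                       motif = "GGCCGG",
                       motif_copies = 3L,
                       motif_window = 200L,
                       motif_upstream = 1500L,
                       qc_n_genes = 2000L,
                       qc_reps_per_condition = 5L,
                       qc_n_outliers = 2L,
                       qc_noise_sd = 1.2,
                       proximal_max = 2000L,
                       distal_max = 50000L) {
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix must sum to 1")
  if (!all(names(class_mix) %in% .PEAK_CLASSES) || length(class_mix) != 5L)
    stop("class_mix must name the five peak classes")
  if (any(c(n_deg_down, n_deg_up, n_nonsig, n_peaks, n_genes) < 0))
    stop("counts must be non-negative")
  if (exons_per_gene[1] < 1L) stop("genes need at least one exon")
  structure(as.list(environment()), class = "sim_config")
}

# fixed slot layout used by the geometric constructions:
# [ upstream clearance C | gene (<= Lmax) | clearance C | intergenic zone Z ]
# C exceeds distal_max so placements relative to one gene can never acquire
# an unintended relation to a neighbour.
.slot_geometry <- function(config) {
  C <- config$distal_max + 5000L
  Lmax <- 20000L
  Z <- 20000L
  list(C = C, Lmax = Lmax, Z = Z, W = C + Lmax + C + Z)
}

#' Simulate a stranded multi-exon genome annotation
#'
#' Genes are laid out one per fixed-width slot with clearance larger than
#' `distal_max` on both sides plus a reserved intergenic zone, so peak
#' classes can later be realized by pure geometric construction. Strands
#' alternate, guaranteeing both are represented for `n_genes >= 2`. The
#' same seed yields identical models (and hence identical GTF files).
#'
#' @param config a [sim_config()].
#' @param gtf_path optional path; when given, the models are also written
#'   as Ensembl-dialect GTF via [write_gtf()].
#' @return a [transcript_models] object.
#' @export
simulate_annotation <- function(config, gtf_path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  geo <- .slot_geometry(config)
  n <- config$n_genes
  chrom_of <- rep(seq_len(config$n_chroms), each = ceiling(n / config$n_chroms))[seq_len(n)]
  slot_in_chrom <- stats::ave(seq_len(n), chrom_of, FUN = seq_along) - 1L
  needed <- max(table(chrom_of)) * geo$W + 1000L
  if (!is.null(config$chrom_length_bp) && config$chrom_length_bp < needed)
    stop("infeasible packing: need chrom_length_bp >= ", needed,
         "; increase chrom_length_bp (or reduce n_genes/n_chroms ratio)")

  tx_list <- vector("list", n)
  ex_list <- vector("list", n)
  for (g in seq_len(n)) {
    slot_start <- slot_in_chrom[g] * geo$W
    n_ex <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1L)
    ex_len <- sample(100:600, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1L) sample(200:3000, n_ex - 1L, replace = TRUE) else integer(0)
    gene_start <- slot_start + geo$C
    starts <- gene_start + cumsum(c(0L, ex_len[-n_ex] + in_len))
    ends <- starts + ex_len
    tid <- sprintf("TX%05d", g)
    tx_list[[g]] <- data.frame(transcript_id = tid,
                               gene_id = sprintf("G%05d", g),
                               gene_name = sprintf("gene%d", g),
                               chrom = sprintf("chr%d", chrom_of[g]),
                               start = gene_start, end = ends[n_ex],
                               strand = if (g %% 2L == 1L) "+" else "-",
                               stringsAsFactors = FALSE)
    ex_list[[g]] <- data.frame(transcript_id = tid, start = starts, end = ends,
                               stringsAsFactors = FALSE)
  }
  models <- transcript_models(do.call(rbind, tx_list), do.call(rbind, ex_list))
  if (!is.null(gtf_path)) write_gtf(models, gtf_path)
  models
}

# deterministic largest-remainder apportionment of n into proportions
.apportion <- function(mix, n) {
  raw <- mix * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(-(raw - counts), seq_along(raw))
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
  }
  stats::setNames(as.integer(counts), names(mix))
}

#' Simulate peaks with geometrically constructed true classes
#'
#' Class counts follow `class_mix` by largest-remainder apportionment
#' (exact, not sampled). Each non-intergenic peak is assigned a host
#' transcript round-robin and its summit is placed to realize the class
#' under the classifier's precedence rules: proximal summits uniformly in
#' `[TSS - proximal_max, TSS]` along the direction of transcription (the
#' first two fixed at the inclusive boundary `d = proximal_max` and at
#' `d = 0`), distal summits in `(proximal_max, distal_max]`, exonic and
#' intronic summits inside the host's exons/introns (never on the TSS
#' base), and intergenic summits in the reserved zone, farther than
#' `distal_max` from every TSS and outside every locus.
#'
#' @param config a [sim_config()].
#' @param models output of [simulate_annotation()] under the same config.
#' @param narrowpeak_path optional path for a narrowPeak export.
#' @return list with `peaks` (peak data.frame) and `truth` (data.frame
#'   `peak_id`, `true_class`, `host_transcript`, `host_gene`; intergenic
#'   peaks have `NA` hosts).
#' @export
simulate_peaks <- function(config, models, narrowpeak_path = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(models, "transcript_models"))
  set.seed(config$seed + 1L)
  geo <- .slot_geometry(config)
  tx <- models$transcripts
  tss <- derive_tss(models)
  counts <- .apportion(config$class_mix[.PEAK_CLASSES], config$n_peaks)

  with_introns <- vapply(tx$transcript_id, function(tid)
    sum(models$exons$transcript_id == tid) > 1L, logical(1))
  if (counts[["intronic"]] > 0L && !any(with_introns))
    stop("intronic peaks unrealizable: no multi-exon transcript in the simulated genome")

  rows <- list(); truths <- list()
  pid <- 0L
  place <- function(class, k) {
    if (k == 0L) return(invisible(NULL))
    hosts <- if (class == "intronic") which(with_introns) else seq_len(nrow(tx))
    hosts <- rep(hosts, length.out = k)
    for (j in seq_len(k)) {
      h <- hosts[j]
      t_pos <- tss$position[h]; s <- tx$strand[h]
      summit <- switch(class,
        proximal_promoter = {
          d <- if (j == 1L) config$proximal_max else if (j == 2L) 0L
          else sample(0:config$proximal_max, 1L)
          if (s == "+") t_pos - d else t_pos + d
        },
        distal_promoter = {
          d <- if (j == 1L) config$distal_max else if (j == 2L) config$proximal_max + 1L
          else sample((config$proximal_max + 1L):config$distal_max, 1L)
          if (s == "+") t_pos - d else t_pos + d
        },
        exonic = {
          ex <- models$exons[models$exons$transcript_id == tx$transcript_id[h], ]
          cand_ex <- ex[sample(nrow(ex), 1L), ]
          p <- sample(cand_ex$start:(cand_ex$end - 1L), 1L)
          while (p == t_pos)  # d = 0 would be proximal, not exonic
            p <- sample(cand_ex$start:(cand_ex$end - 1L), 1L)
          p
        },
        intronic = {
          ex <- models$exons[models$exons$transcript_id == tx$transcript_id[h], ]
          i <- sample(nrow(ex) - 1L, 1L)
          sample(ex$end[i]:(ex$start[i + 1L] - 1L), 1L)
        },
        intergenic = {
          slot_start <- tx$start[h] - geo$C
          zone_start <- slot_start + geo$W - geo$Z
          sample(zone_start:(zone_start + geo$Z - 1L), 1L)
        })
      pid <<- pid + 1L
      w <- sample(config$peak_width[1]:config$peak_width[2], 1L)
      start <- max(summit - w %/% 2L, 0L)
      rows[[pid]] <<- data.frame(
        peak_id = sprintf("peak_%05d", pid), chrom = tx$chrom[h],
        start = start, end = start + w, summit = summit,
        score = round(stats::runif(1, 50, 500), 2),
        enrichment = round(stats::runif(1, 2, 50), 2),
        summit_imputed = FALSE, stringsAsFactors = FALSE)
      truths[[pid]] <<- data.frame(
        peak_id = sprintf("peak_%05d", pid), true_class = class,
        host_transcript = if (class == "intergenic") NA_character_ else tx$transcript_id[h],
        host_gene = if (class == "intergenic") NA_character_ else tx$gene_id[h],
        stringsAsFactors = FALSE)
    }
  }
  for (cl in .PEAK_CLASSES) place(cl, counts[[cl]])
  peaks <- do.call(rbind, rows)
  truth <- do.call(rbind, truths)
  # interleave classes so file order carries no signal
  perm <- sample(nrow(peaks))
  peaks <- peaks[perm, , drop = FALSE]
  truth <- truth[perm, , drop = FALSE]
  rownames(peaks) <- rownames(truth) <- NULL
  if (!is.null(narrowpeak_path)) write_narrowpeak(peaks, narrowpeak_path)
  list(peaks = peaks, truth = truth)
}

#' Simulate a Cuffdiff-style differential-expression table
#'
#' Builds a `gene_exp.diff`-shaped table with exact down/up/non-significant
#' counts. When peak ground truth is supplied, DEG labels are planted so
#' that `frac_deg_with_peak` of the significant genes host at least one
#' non-intergenic peak, making the DEG-peak intersection exact by
#' construction. Gene ids beyond the simulated genome are padded.
#'
#' @param config a [sim_config()].
#' @param models output of [simulate_annotation()].
#' @param peak_truth optional `truth` component of [simulate_peaks()].
#' @param path optional path for a `gene_exp.diff` export.
#' @return list with `degs` (DE record data.frame, [read_cuffdiff()]
#'   shape) and `truth` (data.frame `gene_id`, `significant`, `direction`,
#'   `has_peak`).
#' @export
simulate_de_table <- function(config, models, peak_truth = NULL, path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n_deg <- config$n_deg_down + config$n_deg_up
  n_total <- n_deg + config$n_nonsig
  genome_genes <- unique(models$transcripts$gene_id)
  gene_ids <- c(genome_genes,
                sprintf("PAD%06d", seq_len(max(0L, n_total - length(genome_genes)))))
  gene_ids <- gene_ids[seq_len(n_total)]

  hosts <- if (!is.null(peak_truth))
    intersect(unique(peak_truth$host_gene[!is.na(peak_truth$host_gene)]), gene_ids)
  else character(0)
  if (length(hosts)) {
    n_host_deg <- round(config$frac_deg_with_peak * n_deg)
    if (n_host_deg > length(hosts))
      stop("frac_deg_with_peak requires ", n_host_deg,
           " peak-hosting genes but only ", length(hosts), " exist")
    deg_genes <- c(sample(hosts, n_host_deg),
                   sample(setdiff(gene_ids, hosts), n_deg - n_host_deg))
  } else {
    deg_genes <- sample(gene_ids, n_deg)
  }
  down_genes <- sample(deg_genes, config$n_deg_down)
  is_deg <- gene_ids %in% deg_genes
  is_down <- gene_ids %in% down_genes

  lfc <- numeric(n_total)
  mag <- stats::rlnorm(n_total, meanlog = 0.3, sdlog = 0.5)
  lfc[is_deg & is_down] <- -mag[is_deg & is_down]
  lfc[is_deg & !is_down] <- mag[is_deg & !is_down]
  lfc[!is_deg] <- stats::rnorm(sum(!is_deg), 0, 0.1)
  q <- ifelse(is_deg, stats::runif(n_total, 0, 0.0499),
              stats::runif(n_total, 0.05, 1))
  fpkm1 <- stats::rlnorm(n_total, meanlog = log(20), sdlog = 1)
  degs <- data.frame(gene_id = gene_ids,
                     gene_name = sub("^G", "gene", gene_ids),
                     fpkm_1 = round(fpkm1, 4),
                     fpkm_2 = round(fpkm1 * 2^lfc, 4),
                     log2fc = round(lfc, 5),
                     q_value = round(q, 6),
                     significant = is_deg,
                     direction = ifelse(!is_deg, "none",
                                        ifelse(is_down, "down", "up")),
                     stringsAsFactors = FALSE)
  perm <- sample(n_total)
  degs <- degs[perm, , drop = FALSE]
  rownames(degs) <- NULL
  truth <- data.frame(gene_id = degs$gene_id, significant = degs$significant,
                      direction = degs$direction,
                      has_peak = degs$gene_id %in% hosts,
                      stringsAsFactors = FALSE)
  if (!is.null(path)) write_cuffdiff(degs, path)
  list(degs = degs, truth = truth)
}

.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

# replace every occurrence of motif (either strand) by fresh random bases,
# re-scanning until clean; protected positions are never rewritten.
.scrub_motif <- function(seq_chr, motif, protected = integer(0), max_iter = 25L) {
  L <- nchar(motif)
  prot_idx <- unique(unlist(lapply(protected, function(q) q + seq_len(L) - 1L)))
  for (iter in seq_len(max_iter)) {
    hits <- scan_motif(seq_chr, motif, both_strands = TRUE)
    hits <- hits[!(hits$position %in% protected), , drop = FALSE]
    if (!nrow(hits)) return(seq_chr)
    chars <- strsplit(seq_chr, "", fixed = TRUE)[[1]]
    for (p in hits$position) {
      idx <- setdiff(p + seq_len(L) - 1L, prot_idx)  # never rewrite a plant
      if (length(idx))
        chars[idx + 1L] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE)
    }
    seq_chr <- paste(chars, collapse = "")
  }
  stop("failed to generate motif-free background after ", max_iter, " passes")
}

#' Simulate genome sequence with planted promoter motif clusters
#'
#' Emits one random sequence per chromosome, scrubbed of accidental exact
#' occurrences of the motif (either strand) by bounded rejection
#' resampling, then plants `motif_copies` copies per promoter centred
#' `motif_upstream` bp upstream of each TSS within a `motif_window` bp
#' span, strand-aware (minus-strand plants carry the reverse-complement
#' word on the genome's forward strand). Intended for small simulated
#' genomes; the geometry-only generators scale independently of sequence.
#'
#' @param config a [sim_config()].
#' @param models output of [simulate_annotation()]; promoters of every
#'   transcript receive a plant.
#' @param fasta_path optional path for a FASTA export.
#' @return list with `sequences` (DNAStringSet named by chromosome) and
#'   `planted` (data.frame `transcript_id`, `chrom`, `genomic_start`,
#'   `strand`, `upstream_offset`, `motif`): `upstream_offset` is the
#'   promoter-local distance from the TSS to the motif start, so after
#'   [extract_promoter_sequences()] with `upstream_bp = U` the word begins
#'   at local position `U - upstream_offset`.
#' @export
simulate_sequences <- function(config, models, fasta_path = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(models, "transcript_models"))
  set.seed(config$seed + 3L)
  motif <- .check_motif(config$motif)
  L <- nchar(motif)
  rc <- as.character(reverseComplement(DNAString(motif)))
  tx <- models$transcripts
  tss <- derive_tss(models)

  spacing <- max(L + 4L, config$motif_window %/% max(config$motif_copies, 1L))
  offsets <- if (config$motif_copies > 0L)
    config$motif_upstream +
      (seq_len(config$motif_copies) - (config$motif_copies + 1) / 2) * spacing
  else numeric(0)
  offsets <- as.integer(round(offsets))

  chroms <- unique(tx$chrom)
  seqs <- list(); planted <- list()
  for (ch in chroms) {
    clen <- max(tx$end[tx$chrom == ch]) + 2000L
    s <- .scrub_motif(.random_dna(clen), motif)
    sel <- which(tss$chrom == ch)
    prot <- integer(0)
    for (i in sel) {
      for (u in offsets) {
        if (tss$strand[i] == "+") {
          g0 <- tss$position[i] - u          # motif start, forward word
          word <- motif
        } else {
          g0 <- tss$position[i] + u - L + 1L # rc word on forward strand
          word <- rc
        }
        if (g0 < 0L || g0 + L > clen) stop("plant outside chromosome bounds")
        substring(s, g0 + 1L, g0 + L) <- word
        prot <- c(prot, g0)
        planted[[length(planted) + 1L]] <- data.frame(
          transcript_id = tss$transcript_id[i], chrom = ch, genomic_start = g0,
          strand = tss$strand[i], upstream_offset = u, motif = motif,
          stringsAsFactors = FALSE)
      }
    }
    # planting can create incidental boundary matches; scrub around plants
    s <- .scrub_motif(s, motif, protected = prot)
    seqs[[ch]] <- s
  }
  sequences <- DNAStringSet(unlist(seqs))
  names(sequences) <- names(seqs)
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(transcript_id = character(), chrom = character(),
               genomic_start = integer(), strand = character(),
               upstream_offset = integer(), motif = character(),
               stringsAsFactors = FALSE)
  if (!is.null(fasta_path)) Biostrings::writeXStringSet(sequences, fasta_path)
  list(sequences = sequences, planted = planted)
}

#' Simulate an FPKM replicate matrix with planted outliers
#'
#' Gene-level log2 expression is drawn once per gene (sd 2), a condition
#' effect shifts a subset of genes in the mutant, and each replicate adds
#' independent log2 noise (sd 0.15). The configured number of wild-type
#' replicates receives additional heavy independent noise
#' (`qc_noise_sd`, log2 scale), calibrated so that the corrupted
#' replicates - and only they - fall below the default 0.9 median-
#' correlation threshold of [replicate_qc()].
#'
#' @param config a [sim_config()].
#' @return list with `mat` (genes x replicates FPKM), `conditions`
#'   (per-column labels, `"WT"`/`"mutant"`) and `outliers` (planted
#'   replicate names).
#' @export
simulate_replicate_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  G <- config$qc_n_genes
  r <- config$qc_reps_per_condition
  mu <- stats::rnorm(G, mean = 5, sd = 2)
  effect <- ifelse(stats::runif(G) < 0.1, sample(c(-1, 1), G, replace = TRUE), 0)
  cols <- c(sprintf("WT_%d", seq_len(r)), sprintf("mut_%d", seq_len(r)))
  conditions <- rep(c("WT", "mutant"), each = r)
  mat <- matrix(0, nrow = G, ncol = 2L * r, dimnames = list(NULL, cols))
  for (j in seq_len(2L * r)) {
    base <- if (conditions[j] == "WT") mu else mu + effect
    mat[, j] <- 2^(base + stats::rnorm(G, 0, 0.15))
  }
  outliers <- sample(sprintf("WT_%d", seq_len(r)), config$qc_n_outliers)
  for (o in outliers)
    mat[, o] <- mat[, o] * 2^stats::rnorm(G, 0, config$qc_noise_sd)
  list(mat = mat, conditions = conditions, outliers = sort(outliers))
}

#' Simulate a gene-to-term mapping with planted enrichment
#'
#' Null terms draw their genes uniformly from the background
#' (hypergeometric null); planted terms over-represent the study set at
#' the requested fold.
#'
#' @param config a [sim_config()] (only the seed is used).
#' @param study study gene ids.
#' @param background background gene ids (superset of `study`).
#' @param n_terms total terms (default 50).
#' @param n_planted terms with planted over-representation (default 5).
#' @param term_size genes per term (default 300).
#' @param fold planted fold enrichment of study genes (default 3).
#' @return list with `mapping` (data.frame `gene_id`, `term_id`,
#'   `term_name`, `is_slim`) and `planted` (planted term ids). One planted
#'   and four null terms are marked `is_slim`.
#' @export
simulate_term_mapping <- function(config, study, background, n_terms = 50L,
                                  n_planted = 5L, term_size = 300L, fold = 3) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 5L)
  n <- length(study); N <- length(background)
  k_planted <- round(fold * term_size * n / N)
  if (k_planted > min(n, term_size)) stop("planted enrichment infeasible")
  term_ids <- sprintf("TERM:%04d", seq_len(n_terms))
  planted_ids <- sample(term_ids, n_planted)
  rows <- lapply(seq_len(n_terms), function(i) {
    tid <- term_ids[i]
    genes <- if (tid %in% planted_ids) {
      in_study <- sample(study, k_planted)
      c(in_study, sample(setdiff(background, in_study), term_size - k_planted))
    } else sample(background, term_size)
    data.frame(gene_id = genes, term_id = tid,
               term_name = sprintf("synthetic process %d", i),
               stringsAsFactors = FALSE)
  })
  mapping <- do.call(rbind, rows)
  slim <- c(sample(planted_ids, 1L), sample(setdiff(term_ids, planted_ids), 4L))
  mapping$is_slim <- mapping$term_id %in% slim
  list(mapping = mapping, planted = sort(planted_ids))
}

#' Simulate an artifact blacklist
#'
#' Draws random intervals inside the simulated genome's coordinate space.
#'
#' @param config a [sim_config()].
#' @param models output of [simulate_annotation()].
#' @param n_intervals number of intervals (default 100).
#' @param width_range interval width range.
#' @param bed_path optional BED3 export path.
#' @return a `blacklist_set`.
#' @export
simulate_blacklist <- function(config, models, n_intervals = 100L,
                               width_range = c(500L, 2000L), bed_path = NULL) {
  set.seed(config$seed + 6L)
  tx <- models$transcripts
  chroms <- unique(tx$chrom)
  clen <- vapply(chroms, function(ch) max(tx$end[tx$chrom == ch]) + 2000L, integer(1))
  ch <- sample(chroms, n_intervals, replace = TRUE)
  w <- sample(width_range[1]:width_range[2], n_intervals, replace = TRUE)
  start <- vapply(seq_len(n_intervals),
                  function(i) sample.int(clen[ch[i]] - w[i], 1L) - 1L, integer(1))
  bl <- blacklist_set(data.frame(chrom = ch, start = start, end = start + w,
                                 stringsAsFactors = FALSE))
  if (!is.null(bed_path))
    writeLines(sprintf("%s\t%d\t%d", bl$chrom, bl$start, bl$end), bed_path)
  bl
}

#' Write ground truth as JSON
#'
#' @param truth any list/data.frame bundle of generator ground truth.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
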