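# Seeded synthetic-data generator.  Emulates the study conditions: two
# inbred strains (B6 = reference, D2 = variant) sequenced as 76-base
# single-end reads on 21 lanes (10 B6 + 11 D2) across three flowcells, with
# strain SNPs at a few per kilobase, negative-binomial gene counts with a
# common dispersion and planted fold changes, and probe-level result tables
# for two microarray platforms.  Every generator is deterministic under the
# config seed.

#' Simulation configuration
#'
#' Returns the default configuration, with any field overridden by name.
#' Defaults mirror the study design: 10 B6 + 11 D2 lanes over 3 flowcells,
#' 76-base reads, ~5 SNPs/kb between the strains, a common NB dispersion of
#' 0.1 and a 10% DE fraction with 2-fold planted effects.
#'
#' @param seed Integer seed (mandatory; all generators derive their RNG
#'   streams from it).
#' @param ... Named overrides of nested fields, e.g.
#'   `genome = list(n_chroms = 1)` replaces only the given subfields.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  cfg <- list(
    seed = as.integer(seed),
    genome = list(n_chroms = 2L, chrom_length = 60000L,
                  duplication_fraction = 0, n_run_per_chrom = 1L),
    genes = list(n_genes = 40L, transcripts_per_gene = c(1L, 3L),
                 exons_per_transcript = c(1L, 3L),
                 exon_length = c(150L, 350L), intron_length = c(60L, 150L),
                 overlap_prob = 0),
    snps = list(density_per_kb = 5, dense_gene_fraction = 0,
                dense_spacing = 9L),
    reads = list(reads_per_sample = 4000L, read_length = 76L,
                 error_rate = 0.002),
    counts = list(n_genes = 2000L, meanlog = log(100), sdlog = 1,
                  phi = 0.1, pi_de = 0.1, log2fc = 1,
                  libsize_factors = 1),
    arrays = list(probesets_per_gene = 1L, probes_per_set = 11L,
                  mask_prob = 0.15, heavy_mask_fraction = 0.08,
                  heavy_mask_keep_prob = 0.25, affy_unmapped_fraction = 0.05,
                  affy_nonunique_fraction = 0.03,
                  illumina_spans_snp_fraction = 0.08,
                  illumina_nonunique_fraction = 0.05,
                  illumina_unmapped_fraction = 0.05,
                  detection_threshold = 3.5, noise_sd = 0.25)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      for (sub in names(overrides[[nm]])) cfg[[nm]][[sub]] <- overrides[[nm]][[sub]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Default 21-lane sample design
#'
#' 10 B6 and 11 D2 lanes spread over three flowcells, sample ids of the
#' form `strain_lane_flowcell`.
#'
#' @return Sample metadata data.frame.
#' @export
default_samples <- function() {
  strain <- c(rep("B6", 10), rep("D2", 11))
  lane <- c(1:10, 1:11)
  flowcell <- paste0("FC", rep(1:3, length.out = 21))
  data.frame(
    sample_id = sprintf("%s_%d_%s", strain, lane, flowcell),
    strain = strain, lane = lane, flowcell = flowcell,
    stringsAsFactors = FALSE
  )
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a toy genome and exon annotation with ground truth
#'
#' Lays genes left to right along random chromosomes.  Each gene has 1-3
#' exons per transcript; the first transcript carries every exon so the
#' union model equals the laid-out exon set.  Optional features: adjacent
#' gene pairs overlapping in their terminal exons (probability
#' `genes$overlap_prob`), short `N` runs in intergenic gaps, and an exact
#' duplicated block copied into a gap (when
#' `genome$duplication_fraction > 0`) to exercise multi-mapping.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named character vector), `annotation` (exon
#'   record data.frame as from [read_exon_annotation()]) and `truth` (gene
#'   layout, duplicated blocks, N runs).
#' @export
generate_genome_and_annotation <- function(config) {
  set.seed(config$seed)
  gcf <- config$genome; ncf <- config$genes
  chroms <- paste0("chr", seq_len(gcf$n_chroms))
  genome <- vapply(chroms, function(ch) .rand_dna(gcf$chrom_length), "")
  names(genome) <- chroms
  cursor <- stats::setNames(rep(1L, length(chroms)), chroms)
  rows <- list(); gene_rows <- list()
  prev_exon_by_chrom <- list()
  for (g in seq_len(ncf$n_genes)) {
    ch <- chroms[(g - 1) %% length(chroms) + 1]
    gid <- sprintf("G%03d", g)
    n_ex <- sample(ncf$exons_per_transcript[1]:ncf$exons_per_transcript[2], 1)
    widths <- sample(ncf$exon_length[1]:ncf$exon_length[2], n_ex, replace = TRUE)
    introns <- if (n_ex > 1)
      sample(ncf$intron_length[1]:ncf$intron_length[2], n_ex - 1, replace = TRUE)
      else integer(0)
    gap <- sample(150:300, 1)
    start <- cursor[ch] + gap
    pe <- prev_exon_by_chrom[[ch]]
    if (!is.null(pe) && stats::runif(1) < ncf$overlap_prob) {
      # overlap the previous gene's last exon by roughly half
      start <- pe$start + (pe$end - pe$start) %/% 2
    }
    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    pos <- start
    for (e in seq_len(n_ex)) {
      ex_start[e] <- pos
      ex_end[e] <- pos + widths[e] - 1L
      pos <- ex_end[e] + 1L + if (e < n_ex) introns[e] else 0L
    }
    if (ex_end[n_ex] > gcf$chrom_length) {
      stop("genes do not fit chromosome ", ch, "; reduce n_genes or gene size")
    }
    strand <- sample(c("+", "-"), 1)
    n_tr <- sample(ncf$transcripts_per_gene[1]:ncf$transcripts_per_gene[2], 1)
    for (t in seq_len(n_tr)) {
      tid <- sprintf("%s.T%d", gid, t)
      ex_idx <- if (t == 1) seq_len(n_ex) else {
        a <- sample(seq_len(n_ex), 1); b <- sample(a:n_ex, 1); a:b
      }
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = gid, transcript_id = tid, chrom = ch,
        start = ex_start[ex_idx], end = ex_end[ex_idx], strand = strand,
        stringsAsFactors = FALSE
      )
    }
    gene_rows[[g]] <- data.frame(gene_id = gid, chrom = ch, strand = strand,
                                 start = ex_start[1], end = ex_end[n_ex],
                                 n_exons = n_ex, stringsAsFactors = FALSE)
    cursor[ch] <- max(cursor[ch], ex_end[n_ex])
    prev_exon_by_chrom[[ch]] <- list(start = ex_start[n_ex], end = ex_end[n_ex])
  }
  annotation <- do.call(rbind, rows)
  truth <- list(genes = do.call(rbind, gene_rows),
                n_runs = NULL, duplications = NULL)
  # N runs in intergenic space near each chromosome end
  if (gcf$n_run_per_chrom > 0) {
    nr <- list()
    for (ch in chroms) {
      gene_end <- cursor[ch]
      for (k in seq_len(gcf$n_run_per_chrom)) {
        run_start <- gene_end + 50L + (k - 1L) * 100L
        run_len <- 30L
        if (run_start + run_len <= gcf$chrom_length) {
          substr(genome[[ch]], run_start, run_start + run_len - 1L) <-
            paste(rep("N", run_len), collapse = "")
          nr[[length(nr) + 1]] <- data.frame(chrom = ch, start = run_start,
                                             end = run_start + run_len - 1L)
        }
      }
    }
    truth$n_runs <- if (length(nr)) do.call(rbind, nr) else NULL
  }
  if (gcf$duplication_fraction > 0) {
    # copy the first ~200 bases of some exons into intergenic space
    n_dup <- max(1L, as.integer(round(gcf$duplication_fraction * ncf$n_genes)))
    dups <- list()
    for (k in seq_len(n_dup)) {
      src <- annotation[sample(nrow(annotation), 1), ]
      blk <- min(200L, src$end - src$start + 1L)
      seq_ <- substr(genome[[src$chrom]], src$start, src$start + blk - 1L)
      ch2 <- chroms[sample(length(chroms), 1)]
      dest <- cursor[ch2] + 400L + k * 300L
      if (dest + blk <= config$genome$chrom_length) {
        substr(genome[[ch2]], dest, dest + blk - 1L) <- seq_
        dups[[length(dups) + 1]] <- data.frame(
          src_chrom = src$chrom, src_start = src$start,
          dest_chrom = ch2, dest_start = dest, length = blk)
      }
    }
    truth$duplications <- if (length(dups)) do.call(rbind, dups) else NULL
  }
  list(genome = genome, annotation = annotation, truth = truth)
}

#' Write exon records as GTF
#'
#' @param annotation Exon record data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_exon_gtf <- function(annotation, path) {
  lines <- sprintf(
    '%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    annotation$chrom, annotation$start, annotation$end, annotation$strand,
    annotation$gene_id, annotation$transcript_id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Generate strain SNPs over union-exon models
#'
#' Places SNPs uniformly in union exons at `snps$density_per_kb`, and makes
#' a designated fraction of genes SNP-dense by planting SNPs every
#' `snps$dense_spacing` bases across their exons (spacing 9 guarantees at
#' least 3 SNPs in every 32-base seed window, so variant-strain reads from
#' these genes exhaust the mismatch budget on the reference).  The reference
#' allele is always the genome base; SNPs are never placed on `N`.
#'
#' @param genome Named character vector.
#' @param models A `GeneModelSet`.
#' @param config A [sim_config()].
#' @return List with `snps` (data.frame `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`) and `dense_genes` (character vector of SNP-dense gene
#'   ids).
#' @export
generate_snps <- function(genome, models, config) {
  set.seed(config$seed + 1L)
  scf <- config$snps
  genes <- models$genes
  n_dense <- as.integer(round(scf$dense_gene_fraction * nrow(genes)))
  eligible <- genes$gene_id[genes$union_exon_length > 0]
  dense_genes <- if (n_dense > 0) sort(sample(eligible, min(n_dense, length(eligible))))
                 else character(0)
  ex <- models$exons
  pos_list <- list()
  for (i in seq_along(ex)) {
    gid <- ex$gene_id[i]
    ch <- as.character(GenomicRanges::seqnames(ex[i]))
    s <- GenomicRanges::start(ex[i]); e <- GenomicRanges::end(ex[i])
    if (gid %in% dense_genes) {
      p <- seq(s, e, by = scf$dense_spacing)
    } else {
      n <- stats::rbinom(1, e - s + 1, scf$density_per_kb / 1000)
      p <- if (n > 0) sort(sample(s:e, n)) else integer(0)
    }
    if (length(p) > 0) pos_list[[length(pos_list) + 1]] <-
      data.frame(chrom = ch, pos = p, stringsAsFactors = FALSE)
  }
  if (length(pos_list) == 0) {
    return(list(snps = data.frame(chrom = character(), pos = integer(),
                                  ref_allele = character(),
                                  alt_allele = character()),
                dense_genes = dense_genes))
  }
  snps <- unique(do.call(rbind, pos_list))
  snps <- snps[order(snps$chrom, snps$pos), ]
  ref <- vapply(seq_len(nrow(snps)), function(i)
    substr(genome[[snps$chrom[i]]], snps$pos[i], snps$pos[i]), "")
  keep <- ref %in% c("A", "C", "G", "T")
  snps <- snps[keep, ]; ref <- ref[keep]
  bases <- c("A", "C", "G", "T")
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  snps$ref_allele <- ref
  snps$alt_allele <- unname(alt)
  rownames(snps) <- NULL
  list(snps = snps, dense_genes = dense_genes)
}

#' Simulate strain-specific reads with true origins
#'
#' For each sample, genes are drawn in proportion to a true mean (flat by
#' default) times the strain effect, a 76-base window is placed uniformly
#' within a single union exon (so the splice-unaware 43-base aligner always
#' has an exact target), D2 reads carry the alternate allele at every SNP
#' position in the window, substitution errors are applied at the
#' configured rate, and half the reads are emitted reverse-complemented.
#' Genes with no exon long enough for a read are excluded from sampling and
#' listed in `excluded_genes`.
#'
#' @param genome Reference genome (B6 alleles).
#' @param models A `GeneModelSet` (post overlap removal).
#' @param snps SNP data.frame (D2 alleles).
#' @param samples Sample metadata.
#' @param config A [sim_config()].
#' @param gene_means Optional named vector of true mean weights per gene
#'   (default flat).
#' @param log2fc Optional named vector of true log2 fold changes (B6/D2)
#'   per gene (default 0).
#' @return List with `reads_by_sample` (named list of data.frames
#'   `read_id`, `sequence`), `truth` (per-read origin: `sample_id`,
#'   `read_id`, `gene_id`, `chrom`, `pos` 0-based leftmost, `strand`) and
#'   `excluded_genes`.
#' @export
simulate_reads <- function(genome, models, snps, samples, config,
                           gene_means = NULL, log2fc = NULL) {
  set.seed(config$seed + 2L)
  rcf <- config$reads
  L <- rcf$read_length
  ex <- models$exons
  ex_gene <- ex$gene_id
  ex_chrom <- as.character(GenomicRanges::seqnames(ex))
  ex_start <- GenomicRanges::start(ex)
  ex_valid <- GenomicRanges::width(ex) - L + 1L
  usable <- ex_valid > 0
  genes_usable <- unique(ex_gene[usable])
  excluded <- setdiff(models$genes$gene_id, genes_usable)
  if (is.null(gene_means)) {
    gene_means <- stats::setNames(rep(1, length(genes_usable)), genes_usable)
  }
  gene_means <- gene_means[names(gene_means) %in% genes_usable]
  if (is.null(log2fc)) log2fc <- stats::setNames(rep(0, length(gene_means)),
                                                 names(gene_means))
  snp_by_chrom <- split(snps, snps$chrom)
  reads_by_sample <- list(); truth_rows <- list()
  for (si in seq_len(nrow(samples))) {
    sid <- samples$sample_id[si]
    is_d2 <- samples$strain[si] == "D2"
    eff <- 2^(ifelse(is_d2, -0.5, 0.5) * log2fc[names(gene_means)])
    w <- gene_means * eff
    gsel <- sample(names(gene_means), rcf$reads_per_sample, replace = TRUE,
                   prob = w / sum(w))
    n <- length(gsel)
    # choose an exon within the gene, weighted by valid start positions
    cand_by_gene <- split(which(usable), ex_gene[usable])
    exi <- vapply(gsel, function(g) {
      cand <- cand_by_gene[[g]]
      if (length(cand) == 1) cand else
        sample(cand, 1, prob = ex_valid[cand])
    }, integer(1))
    off <- vapply(exi, function(i) sample.int(ex_valid[i], 1), integer(1))
    start1 <- ex_start[exi] + off - 1L   # 1-based leftmost of the window
    ch <- ex_chrom[exi]
    seqs <- character(n)
    minus <- stats::runif(n) < 0.5
    for (i in seq_len(n)) {
      s <- substr(genome[[ch[i]]], start1[i], start1[i] + L - 1L)
      if (is_d2) {
        sn <- snp_by_chrom[[ch[i]]]
        if (!is.null(sn)) {
          inwin <- sn$pos >= start1[i] & sn$pos <= start1[i] + L - 1L
          if (any(inwin)) {
            v <- strsplit(s, "", fixed = TRUE)[[1]]
            v[sn$pos[inwin] - start1[i] + 1L] <- sn$alt_allele[inwin]
            s <- paste(v, collapse = "")
          }
        }
      }
      if (rcf$error_rate > 0) {
        ne <- stats::rbinom(1, L, rcf$error_rate)
        if (ne > 0) {
          posn <- sample.int(L, ne)
          v <- strsplit(s, "", fixed = TRUE)[[1]]
          for (p in posn) {
            v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
          }
          s <- paste(v, collapse = "")
        }
      }
      if (minus[i]) s <- .revcomp(s)
      seqs[i] <- s
    }
    rid <- sprintf("%s_r%06d", sid, seq_len(n))
    reads_by_sample[[sid]] <- data.frame(read_id = rid, sequence = seqs,
                                         stringsAsFactors = FALSE)
    truth_rows[[sid]] <- data.frame(
      sample_id = sid, read_id = rid, gene_id = gsel, chrom = ch,
      pos = start1 - 1L, strand = ifelse(minus, "-", "+"),
      stringsAsFactors = FALSE
    )
  }
  list(reads_by_sample = reads_by_sample,
       truth = do.call(rbind, truth_rows),
       excluded_genes = excluded)
}

#' Write reads as FASTQ
#'
#' Constant qualities (`I`); qualities are ignored downstream.
#'
#' @param reads Data.frame with `read_id`, `sequence`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reads_fastq <- function(reads, path) {
  q <- vapply(nchar(reads$sequence), function(n)
    paste(rep("I", n), collapse = ""), "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", q), con)
  invisible(path)
}

#' Simulate an NB count matrix with planted fold changes
#'
#' Draws `y_gj ~ NB(mean = s_j * lambda_g * 2^(+/- log2fc_g / 2), phi)`
#' where `lambda_g` is log-normal, a fraction `pi_de` of genes carries a
#' planted log2 fold change (sign random, B6 over D2), and `s_j` are the
#' per-sample library-size factors.  Per-sample totals `N_j` are set equal
#' across samples (larger than any column sum), so library-size
#' heterogeneity enters only through the planted factors — the situation
#' upper-quartile normalization is designed to correct.
#'
#' @param config A [sim_config()]; fields under `counts` are used.
#' @param samples Sample metadata.
#' @return List with `counts` (a `CountMatrix`), `truth` (data.frame
#'   `gene_id`, `mean`, `log2fc`, `is_de`) and `libsize_factors`.
#' @export
simulate_count_matrix <- function(config, samples) {
  set.seed(config$seed + 3L)
  ccf <- config$counts
  G <- ccf$n_genes
  n <- nrow(samples)
  s <- rep_len(ccf$libsize_factors, n)
  lam <- stats::rlnorm(G, ccf$meanlog, ccf$sdlog)
  is_de <- stats::runif(G) < ccf$pi_de
  fc <- ifelse(is_de, sample(c(-1, 1), G, replace = TRUE) * ccf$log2fc, 0)
  b6 <- samples$strain == "B6"
  mu <- outer(lam, s) * 2^(outer(fc / 2, ifelse(b6, 1, -1)))
  y <- matrix(0L, G, n)
  if (ccf$phi > 0) {
    y[] <- stats::rnbinom(length(mu), mu = mu, size = 1 / ccf$phi)
  } else {
    y[] <- stats::rpois(length(mu), mu)
  }
  gene_ids <- sprintf("G%04d", seq_len(G))
  dimnames(y) <- list(gene_ids, samples$sample_id)
  N <- rep(max(colSums(y)) + 1L, n)
  names(N) <- samples$sample_id
  cm <- count_matrix(y, samples, N)
  list(counts = cm,
       truth = data.frame(gene_id = gene_ids, mean = lam, log2fc = fc,
                          is_de = is_de, stringsAsFactors = FALSE),
       libsize_factors = s)
}

#' Simulate probe-level microarray result tables
#'
#' For each platform and gene, per-sample log2 signals are drawn around the
#' gene's true abundance with the strain effect and Gaussian measurement
#' noise; detection calls compare the noisy signal to a threshold (with a
#' narrow `marginal` band); p-values come from per-probe two-sample t-tests,
#' q-values from [storey_qvalues()], fold changes from the anti-logged
#' strain means.  Configured fractions of probes are made SNP-spanning,
#' non-uniquely mapping, or unmapped to a gene so that every filter rule is
#' exercised.
#'
#' @param truth Gene truth data.frame (`gene_id`, `mean`, `log2fc`), e.g.
#'   from [simulate_count_matrix()].
#' @param samples Array sample metadata (`sample_id`, `strain`).
#' @param config A [sim_config()].
#' @return List with `affy` and `illumina` probe data.frames in the format
#'   expected by [filter_affy()]/[filter_illumina()].
#' @export
simulate_probe_tables <- function(truth, samples, config) {
  set.seed(config$seed + 4L)
  acf <- config$arrays
  n <- nrow(samples)
  b6 <- samples$strain == "B6"
  base_log2 <- log2(truth$mean)
  gene_signal <- function(fc) {
    outer(rep(1, nrow(truth)), ifelse(b6, 1, -1)) * (fc / 2) + base_log2
  }
  sim_platform <- function(platform) {
    G <- nrow(truth)
    n_rec <- G * acf$probesets_per_gene
    gene <- rep(truth$gene_id, each = acf$probesets_per_gene)
    fc_true <- rep(truth$log2fc, each = acf$probesets_per_gene)
    mu <- gene_signal(truth$log2fc)[rep(seq_len(G), each = acf$probesets_per_gene), ,
                                    drop = FALSE]
    sig <- mu + matrix(stats::rnorm(n_rec * n, 0, acf$noise_sd), n_rec, n)
    p <- vapply(seq_len(n_rec), function(i)
      stats::t.test(sig[i, b6], sig[i, !b6])$p.value, numeric(1))
    q <- as.numeric(storey_qvalues(p))
    fold <- 2^(rowMeans(sig[, b6, drop = FALSE]) -
               rowMeans(sig[, !b6, drop = FALSE]))
    det <- matrix("present", n_rec, n)
    det[sig < acf$detection_threshold + 0.1] <- "marginal"
    det[sig < acf$detection_threshold] <- "absent"
    df <- data.frame(platform = platform,
                     gene_id = gene, p_value = p, q_value = q,
                     fold_change = fold, true_log2fc = fc_true,
                     stringsAsFactors = FALSE)
    colnames(det) <- paste0("detection_", samples$sample_id)
    cbind(df, as.data.frame(det, stringsAsFactors = FALSE))
  }
  affy <- sim_platform("affy")
  affy$probeset_id <- sprintf("AFFX%05d_at", seq_len(nrow(affy)))
  affy$probe_id <- affy$probeset_id
  affy$maps_unique <- stats::runif(nrow(affy)) >= acf$affy_nonunique_fraction
  affy$n_probes_total <- acf$probes_per_set
  # most probesets lose a probe or two to SNP/uniqueness masking; a SNP-rich
  # minority loses most of its probes and trips the >=4-probe rule
  heavy <- stats::runif(nrow(affy)) < acf$heavy_mask_fraction
  affy$n_probes_after_mask <- ifelse(
    heavy,
    stats::rbinom(nrow(affy), acf$probes_per_set, acf$heavy_mask_keep_prob),
    stats::rbinom(nrow(affy), acf$probes_per_set, 1 - acf$mask_prob))
  unmapped <- stats::runif(nrow(affy)) < acf$affy_unmapped_fraction
  affy$gene_id[unmapped] <- NA_character_

  illumina <- sim_platform("illumina")
  illumina$probe_id <- sprintf("ILMN_%07d", seq_len(nrow(illumina)))
  illumina$maps_unique <- stats::runif(nrow(illumina)) >=
    acf$illumina_nonunique_fraction
  illumina$spans_snp <- stats::runif(nrow(illumina)) <
    acf$illumina_spans_snp_fraction
  unmapped <- stats::runif(nrow(illumina)) < acf$illumina_unmapped_fraction
  illumina$gene_id[unmapped] <- NA_character_

  list(affy = affy, illumina = illumina)
}

#' Generate a complete read-level dataset
#'
#' Composes [generate_genome_and_annotation()], [build_union_exons()],
#' [remove_intergene_overlaps()], [generate_snps()] and [simulate_reads()]
#' into one deterministic dataset.
#'
#' @param config A [sim_config()].
#' @param samples Sample metadata (default [default_samples()]).
#' @param gene_means,log2fc Passed to [simulate_reads()].
#' @return List with `genome`, `annotation`, `models`, `snps`,
#'   `dense_genes`, `reads_by_sample`, `read_truth`, `samples`.
#' @export
simulate_read_dataset <- function(config, samples = default_samples(),
                                  gene_means = NULL, log2fc = NULL) {
  ga <- generate_genome_and_annotation(config)
  models <- remove_intergene_overlaps(build_union_exons(ga$annotation))
  sn <- generate_snps(ga$genome, models, config)
  rd <- simulate_reads(ga$genome, models, sn$snps, samples, config,
                       gene_means = gene_means, log2fc = log2fc)
  list(genome = ga$genome, annotation = ga$annotation, models = models,
       snps = sn$snps, dense_genes = sn$dense_genes,
       reads_by_sample = rd$reads_by_sample, read_truth = rd$truth,
       excluded_genes = rd$excluded_genes,
       layout_truth = ga$truth, samples = samples)
}
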