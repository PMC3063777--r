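test_that("generators are byte-deterministic under the seed", {
  cfg <- sim_config(901, genes = list(n_genes = 10),
                    genome = list(chrom_length = 20000),
                    reads = list(reads_per_sample = 200))
  samples <- default_samples()[c(1, 11), ]
  d1 <- simulate_read_dataset(cfg, samples)
  d2 <- simulate_read_dataset(cfg, samples)
  expect_identical(d1$genome, d2$genome)
  expect_identical(d1$annotation, d2$annotation)
  expect_identical(d1$snps, d2$snps)
  expect_identical(d1$reads_by_sample, d2$reads_by_sample)
  c1 <- simulate_count_matrix(cfg, samples)
  c2 <- simulate_count_matrix(cfg, samples)
  expect_identical(c1$counts$counts, c2$counts$counts)
  arr_samples <- probe_fixture_samples()
  t1 <- simulate_probe_tables(c1$truth, arr_samples, cfg)
  t2 <- simulate_probe_tables(c2$truth, arr_samples, cfg)
  expect_identical(t1, t2)
  d3 <- simulate_read_dataset(sim_config(902, genes = list(n_genes = 10),
                                         genome = list(chrom_length = 20000),
                                         reads = list(reads_per_sample = 200)),
                              samples)
  expect_false(identical(d1$genome, d3$genome))
})

test_that("genome/annotation honor the layout contract", {
  cfg <- sim_config(903, genes = list(n_genes = 12, overlap_prob = 0))
  ga <- generate_genome_and_annotation(cfg)
  expect_equal(length(ga$genome), 2)
  expect_true(all(nchar(ga$genome) == cfg$genome$chrom_length))
  # no overlap requested -> overlap removal is the identity
  m <- build_union_exons(ga$annotation)
  m2 <- remove_intergene_overlaps(m)
  expect_equal(length(m2$removed), 0)
  # with overlap probability 1, adjacent genes overlap somewhere
  cfg_o <- sim_config(904, genes = list(n_genes = 12, overlap_prob = 1))
  ga_o <- generate_genome_and_annotation(cfg_o)
  m_o <- remove_intergene_overlaps(build_union_exons(ga_o$annotation))
  expect_gt(length(m_o$removed), 0)
  # genes too large for the chromosome error out
  expect_error(generate_genome_and_annotation(
    sim_config(905, genome = list(chrom_length = 2000),
               genes = list(n_genes = 30))), "fit")
})

test_that("duplicated blocks create multi-mapping reads", {
  cfg <- sim_config(906, genome = list(duplication_fraction = 0.2,
                                       chrom_length = 40000),
                    genes = list(n_genes = 10))
  ga <- generate_genome_and_annotation(cfg)
  dup <- ga$truth$duplications
  expect_gt(nrow(dup), 0)
  s <- substr(ga$genome[[dup$src_chrom[1]]], dup$src_start[1],
              dup$src_start[1] + 42)
  al <- seed_align(data.frame(read_id = "d", sequence = s), ga$genome)
  expect_equal(al$status, "multi")
})

test_that("SNP generation respects density, dense windows and ref alleles", {
  cfg0 <- sim_config(907, snps = list(density_per_kb = 0,
                                      dense_gene_fraction = 0))
  ds0 <- generate_genome_and_annotation(cfg0)
  m0 <- remove_intergene_overlaps(build_union_exons(ds0$annotation))
  expect_equal(nrow(generate_snps(ds0$genome, m0, cfg0)$snps), 0)

  cfg <- sim_config(908, snps = list(density_per_kb = 3,
                                     dense_gene_fraction = 0.2,
                                     dense_spacing = 9))
  ga <- generate_genome_and_annotation(cfg)
  models <- remove_intergene_overlaps(build_union_exons(ga$annotation))
  sn <- generate_snps(ga$genome, models, cfg)
  # every emitted ref allele matches the genome
  ref <- vapply(seq_len(nrow(sn$snps)), function(i)
    substr(ga$genome[[sn$snps$chrom[i]]], sn$snps$pos[i], sn$snps$pos[i]), "")
  expect_equal(ref, sn$snps$ref_allele)
  expect_true(all(sn$snps$ref_allele != sn$snps$alt_allele))
  # dense genes: every 43-base exon window contains >= 3 SNPs
  ex <- models$exons
  for (g in sn$dense_genes) {
    sel <- ex[ex$gene_id == g]
    for (i in seq_along(sel)) {
      s <- GenomicRanges::start(sel[i]); e <- GenomicRanges::end(sel[i])
      if (e - s + 1 < 43) next
      ch <- as.character(GenomicRanges::seqnames(sel[i]))
      pos <- sn$snps$pos[sn$snps$chrom == ch]
      wins <- s:(e - 42)
      cnt <- vapply(wins, function(w) sum(pos >= w & pos <= w + 42), integer(1))
      expect_true(all(cnt >= 3), info = paste("gene", g))
    }
  }
})

test_that("error-free reads from a SNP-free unique genome recover the gene labels", {
  cfg <- sim_config(909,
    genome = list(n_chroms = 1, chrom_length = 30000,
                  duplication_fraction = 0),
    genes = list(n_genes = 12),
    snps = list(density_per_kb = 0, dense_gene_fraction = 0),
    reads = list(reads_per_sample = 600, error_rate = 0))
  samples <- default_samples()[c(1, 11), ]
  ds <- simulate_read_dataset(cfg, samples)
  aln <- lapply(samples$sample_id, function(s) {
    tr <- trim_reads(ds$reads_by_sample[[s]])
    a <- seed_align(tr$trimmed, ds$genome)
    a$sample_id <- s
    a
  })
  aln <- do.call(rbind, aln)
  expect_true(all(aln$status == "unique"))
  expect_true(all(aln$total_mismatches == 0))
  # alignment recovers each read's true origin
  truth <- ds$read_truth
  m <- match(aln$read_id, truth$read_id)
  left_true <- ifelse(truth$strand[m] == "+", truth$pos[m], truth$pos[m] + 33)
  expect_equal(aln$pos, left_true)
  # counts equal the multinomial gene-label tallies
  cm <- count_reads(aln, ds$models, samples)
  lab <- table(factor(truth$gene_id, levels = rownames(cm$counts)),
               factor(truth$sample_id, levels = samples$sample_id))
  expect_equal(unclass(cm$counts), unclass(lab), ignore_attr = TRUE)
})

test_that("D2 reads carry one mismatch per spanned SNP against the reference", {
  cfg <- sim_config(910,
    genome = list(n_chroms = 1, chrom_length = 30000),
    genes = list(n_genes = 10),
    snps = list(density_per_kb = 8, dense_gene_fraction = 0),
    reads = list(reads_per_sample = 300, error_rate = 0))
  samples <- default_samples()[c(1, 11), ]
  ds <- simulate_read_dataset(cfg, samples)
  d2 <- samples$sample_id[samples$strain == "D2"]
  truth <- ds$read_truth[ds$read_truth$sample_id == d2, ]
  reads <- ds$reads_by_sample[[d2]]
  for (i in sample(nrow(reads), 20)) {
    tr <- truth[truth$read_id == reads$read_id[i], ]
    win <- (tr$pos + 1):(tr$pos + 76)
    n_snp <- sum(ds$snps$pos %in% win)
    s <- reads$sequence[i]
    if (tr$strand == "-") s <- chartr("ACGTN", "TGCAN",
      paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    ref <- substr(ds$genome[[tr$chrom]], tr$pos + 1, tr$pos + 76)
    mm <- sum(strsplit(s, "")[[1]] != strsplit(ref, "")[[1]])
    expect_equal(mm, n_snp, info = paste("read", i))
  }
})

test_that("NB count matrices have the planted moments and DE structure", {
  samples <- default_samples()
  cfg0 <- sim_config(911, counts = list(n_genes = 3000, phi = 0, pi_de = 0,
                                        meanlog = log(100), sdlog = 0,
                                        libsize_factors = 1))
  sim0 <- simulate_count_matrix(cfg0, samples)
  vm <- apply(sim0$counts$counts, 1, var) / rowMeans(sim0$counts$counts)
  expect_lt(abs(mean(vm) - 1), 0.05)   # Poisson: variance/mean ~ 1
  cfg1 <- sim_config(912, counts = list(n_genes = 1000, phi = 0.3, pi_de = 0.2,
                                        meanlog = log(100), sdlog = 0,
                                        libsize_factors = 1))
  sim1 <- simulate_count_matrix(cfg1, samples)
  vm1 <- apply(sim1$counts$counts[!sim1$truth$is_de, ], 1, var) /
    rowMeans(sim1$counts$counts[!sim1$truth$is_de, ])
  expect_gt(mean(vm1), 2)              # overdispersed
  expect_equal(mean(sim1$truth$is_de), 0.2, tolerance = 0.25)
  expect_true(all(sim1$truth$log2fc[!sim1$truth$is_de] == 0))
})

test_that("FASTQ and GTF emitted by the simulator re-parse to the same data", {
  cfg <- sim_config(913, genes = list(n_genes = 6),
                    reads = list(reads_per_sample = 50))
  samples <- default_samples()[c(1, 11), ]
  ds <- simulate_read_dataset(cfg, samples)
  gtf <- tempfile(fileext = ".gtf")
  write_exon_gtf(ds$annotation, gtf)
  back <- read_exon_annotation(gtf)
  expect_equal(back, ds$annotation, ignore_attr = TRUE)
  fq <- tempfile(fileext = ".fastq")
  write_reads_fastq(ds$reads_by_sample[[1]], fq)
  rb <- read_short_reads(fq)
  expect_equal(rb$sequence, ds$reads_by_sample[[1]]$sequence)
  fa <- tempfile(fileext = ".fa")
  write_genome_fasta(ds$genome, fa)
  expect_equal(read_genome_fasta(fa), ds$genome)
})
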