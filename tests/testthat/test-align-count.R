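test_that("reads are trimmed to 43 bases and short reads rejected", {
  reads <- data.frame(
    read_id = c("a", "b", "c"),
    sequence = c(paste(rep("A", 76), collapse = ""),
                 paste(rep("C", 43), collapse = ""),
                 paste(rep("G", 40), collapse = "")))
  tr <- trim_reads(reads)
  expect_equal(nrow(tr$trimmed), 2)
  expect_equal(nchar(tr$trimmed$sequence), c(43, 43))
  expect_equal(tr$trimmed$sequence[2], paste(rep("C", 43), collapse = ""))
  expect_equal(tr$n_rejected, 1)
})

test_that("exact-copy reads map uniquely; excess seed mismatches unmap", {
  set.seed(303)
  g <- random_genome(5000)
  pos <- 1234
  s <- substr(g[[1]], pos, pos + 42)
  al <- seed_align(data.frame(read_id = "r1", sequence = s), g)
  expect_equal(al$status, "unique")
  expect_equal(al$pos, pos - 1L)
  expect_equal(al$strand, "+")
  expect_equal(al$total_mismatches, 0L)

  # reverse-complement maps to the same leftmost position on the minus strand
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  al2 <- seed_align(data.frame(read_id = "r2", sequence = rc), g)
  expect_equal(al2$status, "unique")
  expect_equal(al2$pos, pos - 1L)
  expect_equal(al2$strand, "-")

  # 3 substitutions inside the 32-base seed exceed the mismatch budget
  v <- strsplit(s, "")[[1]]
  for (j in c(3, 15, 28)) v[j] <- setdiff(c("A", "C", "G", "T"), v[j])[1]
  al3 <- seed_align(data.frame(read_id = "r3",
                               sequence = paste(v, collapse = "")), g)
  expect_equal(al3$status, "unmapped")
})

test_that("reads from an exact tandem duplication are multi-mapped", {
  set.seed(304)
  block <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  left <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  g <- c(chr1 = paste0(left, block, block, right))
  read <- substr(block, 50, 92)
  al <- seed_align(data.frame(read_id = "dup", sequence = read), g)
  expect_equal(al$status, "multi")
  expect_true(is.na(al$pos))
})

test_that("N in read or genome counts as a mismatch, never a match", {
  set.seed(305)
  g <- random_genome(2000)
  pos <- 500
  s <- substr(g[[1]], pos, pos + 42)
  v <- strsplit(s, "")[[1]]; v[5] <- "N"
  al <- seed_align(data.frame(read_id = "n1", sequence = paste(v, collapse = "")), g)
  expect_equal(al$status, "unique")
  expect_equal(al$total_mismatches, 1L)
  # N-run genome region never matches an all-N read
  gn <- c(chr1 = paste0(substr(g[[1]], 1, 1000),
                        paste(rep("N", 100), collapse = ""),
                        substr(g[[1]], 1101, 2000)))
  nread <- paste(rep("N", 43), collapse = "")
  expect_equal(seed_align(data.frame(read_id = "n2", sequence = nread),
                          gn)$status, "unmapped")
})

test_that("seed_align agrees with the exhaustive-scan oracle", {
  set.seed(306)
  g <- random_genome(8000, n_chroms = 2)
  idx <- build_genome_index(g)
  n <- 60
  reads <- data.frame(read_id = paste0("r", seq_len(n)),
                      sequence = NA_character_)
  for (i in seq_len(n)) {
    ch <- sample(names(g), 1)
    p <- sample(nchar(g[[ch]]) - 43, 1)
    s <- mutate_read(substr(g[[ch]], p, p + 42), sample(0:4, 1))
    if (runif(1) < 0.5) s <- .orc_revcomp(s)
    reads$sequence[i] <- s
  }
  al <- seed_align(reads, idx)
  for (i in seq_len(n)) {
    o <- align_oracle(reads$sequence[i], g)
    expect_equal(al$status[i], o$status, info = paste("read", i))
    if (o$status == "unique") {
      expect_equal(al$chrom[i], o$chrom, info = paste("read", i))
      expect_equal(al$pos[i], o$pos, info = paste("read", i))
      expect_equal(al$strand[i], o$strand, info = paste("read", i))
      expect_equal(al$total_mismatches[i], o$total_mm, info = paste("read", i))
      expect_equal(al$seed_mismatches[i], o$seed_mm, info = paste("read", i))
    }
  }
})

test_that("read starts are counted into union exons with half-open boundaries", {
  ann <- data.frame(gene_id = c("G1", "G2"), transcript_id = c("T1", "T2"),
                    chrom = "chr1", start = c(101, 301), end = c(200, 400),
                    strand = "+")
  models <- remove_intergene_overlaps(build_union_exons(ann))
  samples <- data.frame(sample_id = c("s1", "s2"),
                        strain = c("B6", "D2"), stringsAsFactors = FALSE)
  aln <- data.frame(
    read_id = paste0("r", 1:6),
    status = c("unique", "unique", "unique", "multi", "unmapped", "unique"),
    chrom = c("chr1", "chr1", "chr1", "chr1", NA, "chrX"),
    pos = c(100L, 200L, 199L, 150L, NA, 10L),   # 0-based starts
    strand = "+", seed_mismatches = 0L, total_mismatches = 0L,
    sample_id = c("s1", "s1", "s2", "s1", "s1", "s2"))
  cm <- count_reads(aln, models, samples)
  # pos 100 (0-based) = first exon base; pos 200 = one past the last base
  expect_equal(cm$counts["G1", "s1"], 1L)
  expect_equal(cm$counts["G1", "s2"], 1L)  # pos 199 = last base of G1
  expect_equal(sum(cm$counts[, "s1"]), 1L) # multi/unmapped never counted
  expect_equal(unname(cm$N), c(2, 2))      # off-model unique still in N_j
  expect_equal(attr(cm, "n_off_model"), 1L)
})

test_that("counting matches a per-read membership oracle on simulated alignments", {
  set.seed(307)
  ann <- random_annotation(n_genes = 6, chrom_len = 4000)
  ann$chrom <- "chr1"
  models <- remove_intergene_overlaps(build_union_exons(ann))
  samples <- data.frame(sample_id = c("s1", "s2"), strain = c("B6", "D2"))
  n <- 1000
  aln <- data.frame(read_id = paste0("r", 1:n), status = "unique",
                    chrom = "chr1", pos = sample(0:4100, n, TRUE),
                    strand = "+", seed_mismatches = 0L, total_mismatches = 0L,
                    sample_id = sample(samples$sample_id, n, TRUE))
  cm <- count_reads(aln, models, samples)
  base_sets <- model_base_positions(models)
  oracle <- matrix(0L, nrow(models$genes), 2,
                   dimnames = list(models$genes$gene_id, samples$sample_id))
  for (i in seq_len(n)) {
    for (g in names(base_sets)) {
      if ((aln$pos[i] + 1) %in% base_sets[[g]]) {
        oracle[g, aln$sample_id[i]] <- oracle[g, aln$sample_id[i]] + 1L
      }
    }
  }
  expect_equal(cm$counts[rownames(oracle), ], oracle)
  expect_true(all(colSums(cm$counts) <= cm$N[colnames(cm$counts)]))
})

test_that("zero-count gene filters implement both rules with precedence", {
  strains <- c("B6", "B6", "D2", "D2")
  y <- rbind(
    g_allzero   = c(0L, 0L, 0L, 0L),
    g_bothzero  = c(0L, 5L, 0L, 7L),
    g_b6zero    = c(0L, 0L, 3L, 4L),
    g_keep      = c(2L, 3L, 4L, 5L))
  cm <- toy_counts(y, strains, N = rep(100, 4))
  out <- filter_genes(cm)
  expect_equal(rownames(out$counts), c("g_b6zero", "g_keep"))
  rep_ <- attr(out, "removal_report")
  expect_equal(rep_$reason[rep_$gene_id == "g_allzero"], "all_zero")
  expect_equal(rep_$reason[rep_$gene_id == "g_bothzero"], "zero_in_both_strains")
  expect_error(filter_genes(toy_counts(y, rep("B6", 4), N = rep(100, 4))),
               "no samples for strain D2")
})

test_that("SAM export round-trips through the standard SAM toolchain format", {
  set.seed(308)
  g <- random_genome(2000)
  reads <- data.frame(read_id = c("u1", "x1"),
                      sequence = c(substr(g[[1]], 100, 142),
                                   paste(rep("A", 43), collapse = "")))
  al <- seed_align(reads, g)
  path <- tempfile(fileext = ".sam")
  write_sam(al, reads, g, path)
  lines <- readLines(path)
  expect_true(any(grepl("^@SQ\tSN:chr1\tLN:2000", lines)))
  rec <- strsplit(grep("^u1\t", lines, value = TRUE), "\t")[[1]]
  expect_equal(as.integer(rec[2]), 0L)
  expect_equal(as.integer(rec[4]), 100L)  # SAM is 1-based
  expect_equal(rec[6], "43M")
})
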