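# Independent oracles and fixture builders shared across tests.  Each oracle
# deliberately takes a different computational route from the implementation
# it checks.

# ---- per-base gene-model oracle -------------------------------------------

# random annotation fixture: genes laid on one or two chromosomes with
# overlapping transcripts and (optionally forced) inter-gene overlaps
random_annotation <- function(n_genes = 8, chrom_len = 3000, n_chroms = 1,
                              overlap_pairs = TRUE) {
  rows <- list()
  for (g in seq_len(n_genes)) {
    ch <- paste0("c", (g - 1) %% n_chroms + 1)
    base <- sample(chrom_len - 400, 1)
    n_tr <- sample(1:4, 1)
    for (t in seq_len(n_tr)) {
      n_ex <- sample(1:3, 1)
      st <- sort(sample(base:(base + 300), n_ex))
      en <- st + sample(20:120, n_ex, replace = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = paste0("g", g), transcript_id = paste0("g", g, ".t", t),
        chrom = ch, start = st, end = pmin(en, chrom_len),
        strand = sample(c("+", "-"), 1))
    }
  }
  do.call(rbind, rows)
}

# brute-force boolean-array union/overlap-removal oracle; returns per gene
# the sorted base positions of the final model
per_base_oracle <- function(annotation) {
  out <- list()
  for (ch in unique(annotation$chrom)) {
    a <- annotation[annotation$chrom == ch, ]
    L <- max(a$end) + 10
    cov_gene <- list()
    for (g in unique(a$gene_id)) {
      v <- logical(L)
      ag <- a[a$gene_id == g, ]
      for (i in seq_len(nrow(ag))) v[ag$start[i]:ag$end[i]] <- TRUE
      cov_gene[[g]] <- v
    }
    n_cov <- Reduce(`+`, cov_gene)
    shared <- n_cov >= 2
    for (g in names(cov_gene)) {
      out[[g]] <- which(cov_gene[[g]] & !shared)
    }
  }
  out
}

model_base_positions <- function(models) {
  ex <- models$exons
  out <- list()
  for (g in models$genes$gene_id) {
    sel <- ex[ex$gene_id == g]
    out[[g]] <- sort(unlist(lapply(seq_along(sel), function(i)
      GenomicRanges::start(sel[i]):GenomicRanges::end(sel[i]))))
    if (length(sel) == 0) out[[g]] <- integer(0)
  }
  out
}

# ---- exhaustive-scan aligner oracle ---------------------------------------

.orc_code <- function(s, read = FALSE) {
  v <- utf8ToInt(toupper(s))
  code <- rep(if (read) 5L else 4L, length(v))
  code[v == 65L] <- 0L; code[v == 67L] <- 1L
  code[v == 71L] <- 2L; code[v == 84L] <- 3L
  code
}

.orc_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# exhaustive scan over every offset and strand of every chromosome,
# vectorized over offsets (no k-mer index, no candidate pruning)
align_oracle <- function(read, genome) {
  hits <- NULL
  for (ch in names(genome)) {
    gv <- .orc_code(genome[[ch]])
    L <- length(gv)
    if (L < 43) next
    n_off <- L - 43 + 1
    for (st in c("+", "-")) {
      q <- if (st == "+") read else .orc_revcomp(read)
      qv <- .orc_code(q, read = TRUE)
      seed_cols <- if (st == "+") 1:32 else 12:43
      tot <- integer(n_off); sd_ <- integer(n_off)
      for (k in 1:43) {
        mm <- gv[k:(n_off + k - 1)] != qv[k]
        tot <- tot + mm
        if (k %in% seed_cols) sd_ <- sd_ + mm
      }
      ok <- which(sd_ <= 2)
      if (length(ok) > 0) {
        hits <- rbind(hits, data.frame(chrom = ch, pos = ok - 1L, strand = st,
                                       seed_mm = sd_[ok], total_mm = tot[ok]))
      }
    }
  }
  if (is.null(hits)) return(list(status = "unmapped"))
  score <- hits$total_mm * 100 + hits$seed_mm
  best <- hits[score == min(score), , drop = FALSE]
  if (nrow(best) > 1) return(list(status = "multi"))
  list(status = "unique", chrom = best$chrom, pos = best$pos,
       strand = best$strand, seed_mm = best$seed_mm, total_mm = best$total_mm)
}

random_genome <- function(len, n_chroms = 1, prefix = "chr") {
  g <- vapply(seq_len(n_chroms), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""), "")
  names(g) <- paste0(prefix, seq_len(n_chroms))
  g
}

mutate_read <- function(seq_, k) {
  if (k == 0) return(seq_)
  v <- strsplit(seq_, "")[[1]]
  pos <- sample(length(v), k)
  for (j in pos) v[j] <- sample(setdiff(c("A", "C", "G", "T"), v[j]), 1)
  paste(v, collapse = "")
}

# ---- exact-test enumeration oracle ----------------------------------------

# direct log-gamma route (never calls dnbinom/dpois), full enumeration and
# explicit normalization; returns p-values for every possible s_a at once
exact_test_oracle_all <- function(S, n_a, n_b, phi) {
  if (S == 0) return(1)  # degenerate total: only one outcome
  s <- 0:S
  mu <- S / (n_a + n_b)
  lpmf <- function(x, m, r) {
    # NB with mean m, size r; Poisson limit handled by the caller
    lgamma(x + r) - lgamma(r) - lgamma(x + 1) +
      r * log(r / (r + m)) + x * log(m / (r + m))
  }
  lpois <- function(x, m) -m + x * log(m) - lgamma(x + 1)
  lp <- if (phi > 0) {
    lpmf(s, n_a * mu, n_a / phi) + lpmf(S - s, n_b * mu, n_b / phi)
  } else {
    lpois(s, n_a * mu) + lpois(S - s, n_b * mu)
  }
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  vapply(s + 1, function(i) min(sum(w[w <= w[i] * (1 + 1e-8)]), 1), numeric(1))
}

# ---- small count fixtures -------------------------------------------------

toy_counts <- function(y, strains, N = NULL) {
  samples <- data.frame(sample_id = paste0("s", seq_along(strains)),
                        strain = strains, stringsAsFactors = FALSE)
  colnames(y) <- samples$sample_id
  if (is.null(rownames(y))) rownames(y) <- paste0("g", seq_len(nrow(y)))
  if (is.null(N)) N <- colSums(y)
  names(N) <- samples$sample_id
  count_matrix(y, samples, N)
}

# ---- probe-table fixture builder ------------------------------------------

probe_fixture_samples <- function(n_b6 = 4, n_d2 = 4) {
  data.frame(
    sample_id = c(paste0("B", seq_len(n_b6)), paste0("D", seq_len(n_d2))),
    strain = c(rep("B6", n_b6), rep("D2", n_d2)),
    stringsAsFactors = FALSE)
}

make_probe <- function(samples, platform = "illumina", gene_id = "g1",
                       probe_id = "p1", maps_unique = TRUE, spans_snp = FALSE,
                       n_after_mask = 10, p = 0.5, q = 0.5, fold = 1,
                       detection = "present") {
  df <- data.frame(platform = platform, gene_id = gene_id,
                   probe_id = probe_id, maps_unique = maps_unique,
                   p_value = p, q_value = q, fold_change = fold,
                   stringsAsFactors = FALSE)
  if (platform == "affy") {
    df$probeset_id <- probe_id
    df$n_probes_total <- 11L
    df$n_probes_after_mask <- n_after_mask
  } else {
    df$spans_snp <- spans_snp
  }
  det <- rep(detection, length.out = nrow(samples))
  for (i in seq_len(nrow(samples))) {
    df[[paste0("detection_", samples$sample_id[i])]] <- det[i]
  }
  df
}
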