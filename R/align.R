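# Toy-scale deterministic seeded aligner.
#
# Mirrors the alignment parameters used for the striatal strain comparison:
# reads trimmed to 43 bases, a seed of the first 32 bases allowing up to 2
# mismatches, full-length mismatch counting for ranking, and a strict
# unique-only policy (equal-score loci never yield a unique call).  The
# implementation indexes the genome by exact 10-mers: any 32-base seed hit
# with <= 2 mismatches must contain an exact 10-mer at one of three fixed
# probe offsets (pigeonhole over a 3-way partition of the seed), so probing
# three 10-mers per read and strand yields a candidate superset that is then
# verified base-by-base.

.READ_TRIM_LEN <- 43L
.SEED_LEN <- 32L
.SEED_MAX_MM <- 2L
.PROBE_LEN <- 10L
.PROBE_OFFSETS <- c(0L, 11L, 22L)  # partition 32 = 11 + 11 + 10

# base codes: genome A,C,G,T,N -> 0,1,2,3,4; read N -> 5 so N never matches N;
# inter-chromosome sentinel 9 never matches anything.
.encode_dna <- function(x, read = FALSE) {
  v <- utf8ToInt(toupper(x))
  code <- rep(if (read) 5L else 4L, length(v))  # unknown/N
  code[v == 65L] <- 0L  # A
  code[v == 67L] <- 1L  # C
  code[v == 71L] <- 2L  # G
  code[v == 84L] <- 3L  # T
  code
}

.revcomp <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan", vapply(x, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""), character(1)))
}

#' Trim reads to the alignment length
#'
#' Retains the first 43 bases of each read; shorter reads are rejected and
#' tallied.
#'
#' @param reads Data.frame with columns `read_id` and `sequence` (and any
#'   others, carried through).
#' @return List with `trimmed` (the surviving reads, sequences cut to 43
#'   bases) and `n_rejected` (reads shorter than 43 bases).
#' @export
trim_reads <- function(reads) {
  len <- nchar(reads$sequence)
  keep <- len >= .READ_TRIM_LEN
  trimmed <- reads[keep, , drop = FALSE]
  trimmed$sequence <- substr(trimmed$sequence, 1L, .READ_TRIM_LEN)
  rownames(trimmed) <- NULL
  list(trimmed = trimmed, n_rejected = sum(!keep))
}

#' Build a 10-mer index over a reference genome
#'
#' Concatenates the chromosomes (separated by sentinel runs that can never
#' match read bases), encodes bases as integers, and records the sorted
#' rolling 10-mer hash of every genomic offset for exact-probe lookup.
#'
#' @param genome Named character vector of chromosome sequences (A/C/G/T/N).
#' @return A genome index object used by [seed_align()].
#' @export
build_genome_index <- function(genome) {
  stopifnot(is.character(genome), !is.null(names(genome)), all(nzchar(genome)))
  if (anyDuplicated(names(genome))) stop("duplicate chromosome names")
  chrom_len <- nchar(genome)
  spacer <- rep(9L, .READ_TRIM_LEN)
  codes <- integer(0)
  offset <- integer(length(genome))  # 0-based global offset of chrom start
  for (i in seq_along(genome)) {
    offset[i] <- length(codes)
    codes <- c(codes, .encode_dna(genome[[i]]))
    codes <- c(codes, spacer)
  }
  L <- length(codes)
  # rolling base-6 hash of 10-mers (sentinel digits may collide; verification
  # is the arbiter so collisions only cost a wasted check)
  pw <- 6^(seq_len(.PROBE_LEN) - 1)
  H <- numeric(L - .PROBE_LEN + 1)
  for (k in seq_len(.PROBE_LEN)) {
    H <- H + codes[k:(L - .PROBE_LEN + k)] * pw[k]
  }
  ord <- order(H)
  list(
    chroms = names(genome), chrom_len = chrom_len, offset = offset,
    codes = codes, hash_sorted = H[ord], pos_sorted = ord  # 1-based offsets
  )
}

.query_hash <- function(code_mat, start_col) {
  # code_mat: n x 43 integer matrix; probe of 10 columns from start_col
  pw <- 6^(seq_len(.PROBE_LEN) - 1)
  h <- numeric(nrow(code_mat))
  for (k in seq_len(.PROBE_LEN)) h <- h + code_mat[, start_col + k - 1L] * pw[k]
  h
}

.lookup_probes <- function(index, h) {
  # returns list(read = candidate read row, gpos = 1-based global position)
  lo <- findInterval(h - 0.5, index$hash_sorted) + 1L
  hi <- findInterval(h, index$hash_sorted)
  n <- pmax(hi - lo + 1L, 0L)
  reads <- rep(seq_along(h), n)
  idx <- sequence(n) + rep(lo, n) - 1L
  list(read = reads, gpos = index$pos_sorted[idx])
}

#' Align trimmed reads with the seeded mismatch-counting scheme
#'
#' For each trimmed 43-base read, candidate loci on either strand are those
#' where the read's first 32 bases (in read orientation) match the genome
#' with at most 2 mismatches and the full 43 bases lie within one chromosome.
#' Candidates are ranked by total mismatches over 43 bases, ties broken by
#' seed mismatches; a read is `unique` only if a single best locus remains,
#' `multi` if several tie, `unmapped` if there is no candidate.  `N` in read
#' or genome never matches.
#'
#' @param reads Data.frame with `read_id` and `sequence` (43 bases; use
#'   [trim_reads()] first).
#' @param genome Named character vector of chromosomes, or an index from
#'   [build_genome_index()].
#' @return Data.frame with columns `read_id`, `status`
#'   (`unique`/`multi`/`unmapped`), `chrom`, `pos` (0-based leftmost base of
#'   the alignment on the forward strand), `strand`, `seed_mismatches`,
#'   `total_mismatches`; locus columns are `NA` unless the read is unique.
#' @export
seed_align <- function(reads, genome) {
  index <- if (is.list(genome) && !is.null(genome$hash_sorted)) genome
           else build_genome_index(genome)
  n <- nrow(reads)
  out <- data.frame(
    read_id = reads$read_id, status = rep("unmapped", n),
    chrom = NA_character_, pos = NA_integer_, strand = NA_character_,
    seed_mismatches = NA_integer_, total_mismatches = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (n == 0) return(out)
  stopifnot(all(nchar(reads$sequence) == .READ_TRIM_LEN))

  fwd <- matrix(0L, n, .READ_TRIM_LEN)
  rev_ <- matrix(0L, n, .READ_TRIM_LEN)
  for (i in seq_len(n)) {
    fwd[i, ] <- .encode_dna(reads$sequence[i], read = TRUE)
  }
  rc <- .revcomp(reads$sequence)
  for (i in seq_len(n)) rev_[i, ] <- .encode_dna(rc[i], read = TRUE)

  # candidate (read, global 0-based alignment start, strand) triples
  cand_read <- integer(0); cand_g0 <- integer(0); cand_minus <- logical(0)
  for (po in .PROBE_OFFSETS) {
    hit <- .lookup_probes(index, .query_hash(fwd, po + 1L))
    cand_read <- c(cand_read, hit$read)
    cand_g0 <- c(cand_g0, hit$gpos - 1L - po)       # 0-based global start
    cand_minus <- c(cand_minus, rep(FALSE, length(hit$read)))
    # minus strand: seed occupies the last 32 bases of the reverse complement
    hit <- .lookup_probes(index, .query_hash(rev_, 11L + po + 1L))
    cand_read <- c(cand_read, hit$read)
    cand_g0 <- c(cand_g0, hit$gpos - 1L - po - 11L)
    cand_minus <- c(cand_minus, rep(TRUE, length(hit$read)))
  }
  if (length(cand_read) == 0) return(out)
  dup <- duplicated(data.frame(cand_read, cand_g0, cand_minus))
  cand_read <- cand_read[!dup]; cand_g0 <- cand_g0[!dup]; cand_minus <- cand_minus[!dup]

  # bounds: full 43-base window inside a single chromosome (candidates can
  # start before offset 0 after probe-offset subtraction; guard ci = 0)
  ci <- findInterval(cand_g0, index$offset)
  cis <- pmax(ci, 1L)
  ok <- ci >= 1L & cand_g0 >= index$offset[cis] &
    (cand_g0 + .READ_TRIM_LEN) <= (index$offset[cis] + index$chrom_len[cis])
  cand_read <- cand_read[ok]; cand_g0 <- cand_g0[ok]
  cand_minus <- cand_minus[ok]; ci <- ci[ok]
  if (length(cand_read) == 0) return(out)

  # verify: mismatches over seed region and full 43 bases
  total_mm <- integer(length(cand_read))
  seed_mm <- integer(length(cand_read))
  codes <- index$codes
  plus_idx <- !cand_minus
  for (k in seq_len(.READ_TRIM_LEN)) {
    g <- codes[cand_g0 + k]  # codes is 1-based; g0 is 0-based
    rb <- integer(length(cand_read))
    rb[plus_idx] <- fwd[cbind(cand_read[plus_idx], k)]
    rb[!plus_idx] <- rev_[cbind(cand_read[!plus_idx], k)]
    mm <- g != rb
    total_mm <- total_mm + mm
    # seed = first 32 read bases: columns 1..32 on +, columns 12..43 of rc on -
    in_seed <- (plus_idx & k <= .SEED_LEN) | (!plus_idx & k >= 12L)
    seed_mm <- seed_mm + (mm & in_seed)
  }
  ok <- seed_mm <= .SEED_MAX_MM
  cand_read <- cand_read[ok]; cand_g0 <- cand_g0[ok]; cand_minus <- cand_minus[ok]
  ci <- ci[ok]; total_mm <- total_mm[ok]; seed_mm <- seed_mm[ok]
  if (length(cand_read) == 0) return(out)

  # per read: rank by (total_mm, seed_mm); unique iff single best
  score <- total_mm * 100L + seed_mm
  o <- order(cand_read, score)
  r <- cand_read[o]
  first <- !duplicated(r)
  best_i <- o[first]
  best_read <- cand_read[best_i]
  best_score <- score[best_i]
  n_best <- tapply(score[o] == best_score[match(r, best_read)], r, sum)
  stat <- ifelse(as.integer(n_best) == 1L, "unique", "multi")
  out$status[best_read] <- stat
  uniq <- best_read[stat == "unique"]
  bi <- best_i[stat == "unique"]
  out$chrom[uniq] <- index$chroms[ci[bi]]
  out$pos[uniq] <- cand_g0[bi] - index$offset[ci[bi]]
  out$strand[uniq] <- ifelse(cand_minus[bi], "-", "+")
  out$seed_mismatches[uniq] <- seed_mm[bi]
  out$total_mismatches[uniq] <- total_mm[bi]
  out
}

#' Write alignments as minimal SAM
#'
#' Emits a header (`@SQ` per chromosome) and one record per read: unique
#' reads as mapped records (FLAG 0 or 16, MAPQ 255, CIGAR 43M), multi-mapped
#' reads as unmapped records carrying an `XM:Z:multi` tag, unmapped reads as
#' plain unmapped records.
#'
#' @param alignments Data.frame from [seed_align()].
#' @param reads Data.frame with `read_id` and (trimmed) `sequence`.
#' @param genome Named character vector of chromosomes (for `@SQ` lines).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(alignments, reads, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)), con)
  seqs <- reads$sequence[match(alignments$read_id, reads$read_id)]
  mapped <- alignments$status == "unique"
  flag <- ifelse(mapped, ifelse(alignments$strand == "-", 16L, 0L), 4L)
  rname <- ifelse(mapped, alignments$chrom, "*")
  pos <- ifelse(mapped, alignments$pos + 1L, 0L)
  mapq <- ifelse(mapped, 255L, 0L)
  cigar <- ifelse(mapped, sprintf("%dM", .READ_TRIM_LEN), "*")
  tag <- ifelse(alignments$status == "multi", "\tXM:Z:multi", "")
  writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*%s",
                     alignments$read_id, flag, rname, pos, mapq, cigar,
                     seqs, tag), con)
  invisible(path)
}

#' Read short reads from FASTA or FASTQ
#'
#' Qualities are ignored.  Reads shorter than 43 bases are dropped at IO and
#' tallied in the `n_rejected` attribute.
#'
#' @param path FASTA (`.fa`/`.fasta`) or FASTQ (`.fq`/`.fastq`) file.
#' @param sample_id Optional sample identifier attached to every read.
#' @return Data.frame with `read_id`, `sequence` and (if given) `sample_id`,
#'   with attribute `n_rejected`.
#' @export
read_short_reads <- function(path, sample_id = NULL) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  df <- data.frame(read_id = names(ss), sequence = as.character(ss),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  keep <- nchar(df$sequence) >= .READ_TRIM_LEN
  out <- df[keep, , drop = FALSE]
  if (!is.null(sample_id)) out$sample_id <- sample_id
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  g <- toupper(as.character(ss))
  names(g) <- sub("\\s.*$", "", names(ss))
  g
}

#' Write a genome as FASTA
#'
#' @param genome Named character vector of chromosome sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
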