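# Independent brute-force oracles used to check the fast implementations.
# These deliberately avoid the code paths (and packages) they verify.

suppressPackageStartupMessages(library(GenomicRanges))

# O(n*m) all-pairs overlap flags on BED-convention (0-based half-open)
# coordinate data.frames with columns chrom, start, end.
brute_overlap_flags <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

# Per-base-pair size of the union of intervals on a single chromosome.
brute_union_bp <- function(start, end, chrom_len) {
  covered <- logical(chrom_len)
  for (i in seq_along(start))
    covered[(start[i] + 1):end[i]] <- TRUE
  sum(covered)
}

# Exact two-sided Fisher p by full enumeration of tables with fixed
# margins, using only choose(): sum of probabilities of all tables whose
# probability is <= that of the observed table.
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, function(x)
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1), numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Spearman rho from first principles: average ranks, then the Pearson
# product-moment formula written out.
brute_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# data.frame of BED coordinates from a peak-set GRanges (0-based
# half-open), bypassing write_bed.
peaks_as_bed_df <- function(gr) {
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1,
             end = BiocGenerics::end(gr),
             stringsAsFactors = FALSE)
}

# Random non-degenerate peak data.frame for property tests.
random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 5000,
                         max_width = 120) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_width, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

df_to_peak_set <- function(df, label = "peaks") {
  peak_set(df$chrom, df$start, df$end, label = label)
}

# Minimal RIME record builder: one row per peptide.
rime_rows <- function(bait, condition, replicate, protein, peptides,
                      count = 1L) {
  data.frame(bait = bait, condition = condition, replicate = replicate,
             protein = protein, peptide = peptides, count = count,
             stringsAsFactors = FALSE)
}

make_profile <- function(values, bait = "BAIT", condition = "c") {
  structure(list(bait = bait, condition = condition, values = values,
                 n_replicates = 1L), class = "rime_profile")
}
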