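# GIGGLE-like ranking of a query cistrome against a reference library.
# The genome is partitioned into fixed-width bins; each reference set is
# scored by the 2x2 table of bin occupancy (query x reference) using
# Fisher's exact test, a Haldane-Anscombe-corrected odds ratio, and a
# combo score ln(OR) * (-log10 p) echoing the published GIGGLE score.
# This is a transparent reimplementation of the idea, not of GIGGLE's
# indexed search; rankings are comparable within a run only.

#' Binned genome universe for enrichment testing
#'
#' @param genome A [genome_spec()].
#' @param bin_size Bin width in bp (> 0); the last bin of each chromosome
#'   may be short.
#' @return A `universe_spec` object with `genome`, `bin_size`, `n_bins`.
#' @examples
#' universe_spec(genome_spec("chr1", 10000), bin_size = 1000)
#' @export
universe_spec <- function(genome, bin_size = 1000) {
  stopifnot(inherits(genome, "genome_spec"))
  check_scalar_number(bin_size, "bin_size", lower = 1, integer = TRUE)
  n_bins <- as.integer(sum(ceiling(genome$chrom_lengths / bin_size)))
  structure(list(genome = genome, bin_size = bin_size, n_bins = n_bins),
            class = "universe_spec")
}

# Indices (1-based, universe-wide) of bins touched by >= 1 bp of any
# interval of x. Bins are numbered chromosome by chromosome in genome
# order.
occupied_bins <- function(x, universe) {
  g <- universe$genome
  bs <- universe$bin_size
  bins_per_chrom <- ceiling(g$chrom_lengths / bs)
  offset <- setNames(cumsum(c(0, bins_per_chrom[-length(bins_per_chrom)])),
                     g$chrom_names)
  if (length(x) == 0) return(integer(0))
  chrom <- as.character(seqnames(x))
  unknown <- setdiff(unique(chrom), g$chrom_names)
  if (length(unknown))
    stop_("interval chromosome(s) outside universe: %s",
          paste(unknown, collapse = ", "))
  bed_start <- start(x) - 1
  bed_end <- end(x)
  if (any(bed_end > g$chrom_lengths[chrom]))
    stop_("interval extends beyond chromosome end in universe")
  first <- floor(bed_start / bs)
  last <- floor((bed_end - 1) / bs)
  idx <- unlist(lapply(seq_along(first), function(i)
    offset[chrom[i]] + first[i]:last[i]), use.names = FALSE)
  sort(unique(as.integer(idx + 1)))
}

#' Binned 2x2 occupancy contingency of two peak sets
#'
#' A bin is query-positive (reference-positive) if at least one bp of a
#' query (reference) interval falls in it. The four counts always sum to
#' the universe's `n_bins`.
#'
#' @param query,reference Peak-set `GRanges`.
#' @param universe A [universe_spec()] covering both sets' chromosomes.
#' @return Named integer vector `k_overlap`, `k_query_only`,
#'   `k_ref_only`, `k_neither`.
#' @export
binned_contingency <- function(query, reference, universe) {
  stopifnot(inherits(universe, "universe_spec"))
  qb <- occupied_bins(query, universe)
  rb <- occupied_bins(reference, universe)
  k11 <- length(intersect(qb, rb))
  k10 <- length(qb) - k11
  k01 <- length(rb) - k11
  k00 <- universe$n_bins - k11 - k10 - k01
  counts <- c(k_overlap = k11, k_query_only = k10,
              k_ref_only = k01, k_neither = k00)
  stopifnot(sum(counts) == universe$n_bins)
  counts
}

#' Fisher enrichment statistics for a 2x2 occupancy table
#'
#' Two-sided p comes from the exact conditional (hypergeometric) Fisher
#' test — the sum of probabilities of all tables with fixed margins whose
#' probability does not exceed the observed table's. The odds ratio is
#' the sample odds ratio `ad/bc`, with the Haldane-Anscombe +0.5
#' correction applied to all four cells when any cell is zero. The combo
#' score is `ln(OR) * (-log10 p)`: positive for enrichment, negative for
#' depletion, 0 at OR = 1.
#'
#' @param counts Named counts as from [binned_contingency()] (order
#'   `k_overlap`, `k_query_only`, `k_ref_only`, `k_neither`).
#' @param label Library-entry label carried into the result.
#' @return An `enrichment_result` one-row data.frame: `label`,
#'   `k_overlap`, `k_query_only`, `k_ref_only`, `k_neither`,
#'   `odds_ratio`, `p_two_sided`, `combo_score`.
#' @examples
#' fisher_enrichment(c(k_overlap = 5, k_query_only = 5,
#'                     k_ref_only = 5, k_neither = 85))
#' @export
fisher_enrichment <- function(counts, label = NA_character_) {
  if (length(counts) != 4 || any(counts < 0) || any(counts != floor(counts)))
    stop_("counts must be four non-negative integers")
  a <- counts[[1]]; b <- counts[[2]]; c <- counts[[3]]; d <- counts[[4]]
  if (a + b + c + d == 0) stop_("all-zero contingency table")
  m <- matrix(c(a, c, b, d), nrow = 2)
  p <- fisher.test(m, alternative = "two.sided")$p.value
  p <- min(max(p, .Machine$double.xmin), 1)
  if (min(a, b, c, d) == 0) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    or <- (a * d) / (b * c)
  }
  combo <- log(or) * (-log10(p))
  res <- data.frame(label = label, k_overlap = a, k_query_only = b,
                    k_ref_only = c, k_neither = d, odds_ratio = or,
                    p_two_sided = p, combo_score = combo,
                    row.names = NULL)
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Rank a cistrome library against a query peak set
#'
#' Scores every library entry with [binned_contingency()] +
#' [fisher_enrichment()] and sorts by combo score (descending), breaking
#' ties by smaller p and then by label.
#'
#' @param query Peak-set `GRanges`.
#' @param library Named list of peak-set `GRanges`.
#' @param universe A [universe_spec()].
#' @return data.frame of enrichment results, one row per library entry,
#'   best first, with a `rank` column.
#' @export
rank_library <- function(query, library, universe) {
  if (!is.list(library) || length(library) == 0 || is.null(names(library)))
    stop_("library must be a non-empty named list of peak sets")
  rows <- lapply(names(library), function(lbl)
    fisher_enrichment(binned_contingency(query, library[[lbl]], universe),
                      label = lbl))
  out <- do.call(rbind, rows)
  ord <- order(-out$combo_score, out$p_two_sided, out$label)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write a library ranking as TSV
#'
#' @param ranking Output of [rank_library()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_ranking_tsv <- function(ranking, path) {
  write.table(ranking, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
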