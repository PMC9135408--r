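test_that("binned contingency counts match forced cases", {
  g <- genome_spec("chr1", 10000)
  uni <- universe_spec(g, 1000)
  expect_identical(uni$n_bins, 10L)
  q <- peak_set("chr1", c(0, 2500), c(100, 2600))     # bins 1 and 3
  r <- peak_set("chr1", c(50, 5000), c(120, 5100))    # bins 1 and 6
  ct <- binned_contingency(q, r, uni)
  expect_identical(unname(ct), c(1L, 1L, 1L, 7L))
  # query vs itself: no one-sided bins
  self <- binned_contingency(q, q, uni)
  expect_identical(unname(self[c("k_query_only", "k_ref_only")]), c(0L, 0L))
  # empty query
  e <- binned_contingency(peak_set(character(), numeric(), numeric()), r, uni)
  expect_identical(unname(e[c("k_overlap", "k_query_only")]), c(0L, 0L))
  # bin-straddling interval occupies both bins
  s <- binned_contingency(peak_set("chr1", 990, 1010), r, uni)
  expect_identical(unname(s[["k_query_only"]]) + unname(s[["k_overlap"]]), 2L)
  expect_error(binned_contingency(peak_set("chr1", 9990, 10050), r, uni),
               "beyond chromosome end")
})

test_that("binned contingency equals a per-bin brute-force scan", {
  set.seed(31)
  g <- genome_spec(c("chr1", "chr2"), c(5200, 5200))
  uni <- universe_spec(g, 500)
  for (rep in 1:3) {
    dq <- random_peaks(40)
    dr <- random_peaks(40)
    ct <- binned_contingency(df_to_peak_set(dq), df_to_peak_set(dr), uni)
    # oracle: enumerate every bin and test interval intersection directly
    hit <- function(df, chrom, lo, hi)
      any(df$chrom == chrom & df$start < hi & df$end > lo)
    tab <- c(0L, 0L, 0L, 0L)
    for (chrom in c("chr1", "chr2")) for (b in 1:11) {
      lo <- (b - 1) * 500; hi <- min(b * 500, 5200)
      qh <- hit(dq, chrom, lo, hi); rh <- hit(dr, chrom, lo, hi)
      i <- if (qh && rh) 1 else if (qh) 2 else if (rh) 3 else 4
      tab[i] <- tab[i] + 1L
    }
    expect_identical(unname(ct), tab)
  }
})

test_that("Fisher p equals full enumeration over fixed margins", {
  tables <- list(c(5, 5, 5, 85), c(0, 10, 10, 80), c(20, 0, 0, 20),
                 c(3, 7, 11, 79), c(1, 1, 1, 1), c(12, 3, 4, 60))
  for (tb in tables) {
    res <- fisher_enrichment(tb)
    expect_equal(res$p_two_sided,
                 enum_fisher_p(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-10)
  }
})

test_that("odds ratio and combo score behave at boundary tables", {
  # zero overlap with positive margins: depletion, non-positive combo
  res <- fisher_enrichment(c(0, 10, 10, 80))
  expect_lt(res$odds_ratio, 1)
  expect_lte(res$combo_score, 0)
  # Haldane-Anscombe correction keeps the OR finite
  res2 <- fisher_enrichment(c(10, 0, 0, 90))
  expect_true(is.finite(res2$odds_ratio) && res2$odds_ratio > 1)
  # Fisher symmetry under transposition
  expect_equal(fisher_enrichment(c(6, 2, 9, 40))$p_two_sided,
               fisher_enrichment(c(6, 9, 2, 40))$p_two_sided)
  # independence table: OR 1, combo 0
  res3 <- fisher_enrichment(c(10, 10, 10, 10))
  expect_equal(res3$combo_score, 0)
  expect_error(fisher_enrichment(c(0, 0, 0, 0)), "all-zero")
})

test_that("combo score is monotone in overlap at fixed margins", {
  n <- 200; r1 <- 40; c1 <- 50
  scores <- vapply(10:40, function(a)
    fisher_enrichment(c(a, r1 - a, c1 - a, n - r1 - c1 + a))$combo_score,
    numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("a library containing the query ranks it first", {
  g <- generate_genome(4, 1e6)
  lib <- generate_cistrome_library(g, n_factors = 4, peaks_per_factor = 60,
                                   pioneer_overlap = 0.5, seed = 3)$library
  uni <- universe_spec(g, 1000)
  rk <- rank_library(lib$TF01, lib, uni)
  expect_identical(rk$label[1], "TF01")
})

test_that("planted high-overlap factor outranks the others", {
  g <- generate_genome(6, 1e6)
  lb <- generate_cistrome_library(
    g, n_factors = 5, peaks_per_factor = 100,
    pioneer_overlap = c(TF01 = 0.9, TF02 = 0.1, TF03 = 0.1, TF04 = 0.1),
    seed = 5)
  # planted overlap fractions are exact by construction
  fr <- vapply(names(lb$library)[-1], function(f)
    overlap_fraction(lb$library[[f]], lb$library[[lb$pioneer_factor]]),
    numeric(1))
  expect_equal(unname(fr), c(0.9, 0.1, 0.1, 0.1))
  uni <- universe_spec(g, 1000)
  rk <- rank_library(lb$library$FOXA1, lb$library[-1], uni)
  expect_identical(rk$label[1], "TF01")
})

test_that("library insertion order does not change the ranking", {
  g <- generate_genome(4, 1e6)
  lb <- generate_cistrome_library(g, n_factors = 5, peaks_per_factor = 50,
                                  pioneer_overlap = 0.4, seed = 9)$library
  uni <- universe_spec(g, 1000)
  r1 <- rank_library(lb$FOXA1, lb[-1], uni)
  r2 <- rank_library(lb$FOXA1, rev(lb[-1]), uni)
  expect_identical(r1$label, r2$label)
  expect_equal(r1$combo_score, r2$combo_score)
})
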