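test_that("genome generation is forced by its arguments", {
  g <- generate_genome(1, 1e6)
  expect_identical(g$chrom_names, "chr1")
  expect_identical(unname(g$chrom_lengths), 1e6)
  expect_identical(sum(generate_genome(5, 2e5)$chrom_lengths), 1e6)
  expect_error(generate_genome(0, 10), "n_chroms")
  expect_error(generate_genome(2, 0), "length_per_chrom")
})

test_that("largest-remainder apportionment sums exactly and splits fairly", {
  expect_identical(apportion(1000, c(0.2, 0.5, 0.3)), c(200L, 500L, 300L))
  expect_identical(apportion(506, c(77, 222, 207) / 506),
                   c(77L, 222L, 207L))
  expect_identical(sum(apportion(7, c(1, 1, 1) / 3)), 7L)
  set.seed(79)
  for (i in 1:20) {
    fr <- runif(4); fr <- fr / sum(fr)
    n <- sample.int(500, 1)
    k <- apportion(n, fr)
    expect_identical(sum(k), n)
    expect_true(all(abs(k - fr * n) < 1))
  }
  expect_error(apportion(10, c(0.5, 0.2)), "sum to 1")
})

test_that("identical seeds and params give byte-identical outputs", {
  g <- generate_genome(4, 5e5)
  p1 <- generate_condition_peaks(g, cistrome_params(n_peaks = 100), seed = 7)
  p2 <- generate_condition_peaks(g, cistrome_params(n_peaks = 100), seed = 7)
  expect_identical(p1$truth, p2$truth)
  expect_identical(as.character(p1$control), as.character(p2$control))
  r1 <- generate_rime_experiment(rime_params(n_specific_per_bait = 40,
                                             n_contaminants = 5), seed = 7)
  r2 <- generate_rime_experiment(rime_params(n_specific_per_bait = 40,
                                             n_contaminants = 5), seed = 7)
  expect_identical(r1$records, r2$records)
  e1 <- generate_expression_and_screens(
    expression_params(n_genes = 30, n_samples = 20),
    screen_params(n_orfs = 30, n_dep_genes = 30), seed = 7)
  e2 <- generate_expression_and_screens(
    expression_params(n_genes = 30, n_samples = 20),
    screen_params(n_orfs = 30, n_dep_genes = 30), seed = 7)
  expect_identical(e1$expression, e2$expression)
  expect_identical(e1$dependency$values, e2$dependency$values)
  # different seeds move the draws
  p3 <- generate_condition_peaks(g, cistrome_params(n_peaks = 100), seed = 8)
  expect_false(identical(as.character(p1$control), as.character(p3$control)))
})

test_that("infeasible peak packing raises an explicit error", {
  tiny <- genome_spec("chr1", 2000)
  expect_error(
    generate_condition_peaks(tiny, cistrome_params(n_peaks = 100,
                                                   peak_width = 200),
                             seed = 1),
    "placement-attempt cap|exceeds every chromosome")
})

test_that("condition peaks honour their class structure by construction", {
  g <- generate_genome(6, 1e6)
  cp <- generate_condition_peaks(
    g, cistrome_params(n_peaks = 300, frac_lost = 0.2, frac_retained = 0.5,
                       frac_gained = 0.3), seed = 17)
  expect_identical(unname(cp$planted_counts), c(60L, 150L, 90L))
  expect_identical(length(cp$control), 210L)   # lost + retained
  expect_identical(length(cp$treated), 240L)   # retained + gained
  # retained sites overlap across conditions; lost/gained are exclusive
  d <- classify_differential_peaks(cp$control, cp$treated)
  expect_identical(unname(d$counts), c(60L, 150L, 90L))
  # all retained, fully overlapping
  cp1 <- generate_condition_peaks(
    g, cistrome_params(n_peaks = 50, frac_lost = 0, frac_retained = 1,
                       frac_gained = 0), seed = 19)
  expect_true(all(overlaps(cp1$control, cp1$treated)))
  # empty request
  cp0 <- generate_condition_peaks(g, cistrome_params(n_peaks = 0), seed = 1)
  expect_length(cp0$control, 0)
  expect_length(cp0$treated, 0)
})

test_that("library planting hits the extreme overlap fractions exactly", {
  g <- generate_genome(5, 1e6)
  full <- generate_cistrome_library(g, n_factors = 3, peaks_per_factor = 40,
                                    pioneer_overlap = 1.0, seed = 23)
  none <- generate_cistrome_library(g, n_factors = 3, peaks_per_factor = 40,
                                    pioneer_overlap = 0.0, seed = 23)
  for (f in c("TF01", "TF02")) {
    expect_equal(overlap_fraction(full$library[[f]], full$library$FOXA1), 1)
    expect_equal(overlap_fraction(none$library[[f]], none$library$FOXA1), 0)
  }
  # no intra-set overlaps
  for (s in full$library)
    expect_false(any(countOverlaps(s, s) > 1))
})

test_that("noiseless RIME planting is recovered exactly downstream", {
  re <- generate_rime_experiment(rime_params(), seed = 29)
  nr <- re$params$n_replicates
  prof <- function(b, cond) {
    cleaned <- subtract_control(
      collapse_unique_peptides(re$records, b, cond, nr),
      collapse_unique_peptides(re$records, "LUCIFERASE", cond, nr))
    build_profile(cleaned, b, cond)
  }
  pc <- prof("CREB5", "control")
  pt <- prof("CREB5", "enzalutamide")
  # every planted protein detected in every replicate at detection_prob 1
  cc <- collapse_unique_peptides(re$records, "CREB5", "control", nr)
  planted_ctl <- re$truth$protein[re$truth$category == "interactor" &
                                    re$truth$class %in% c("lost", "retained")]
  expect_true(all(cc[planted_ctl, ] > 0))
  # all 50 contaminants removed, none of the interactors lost to subtraction
  expect_identical(sum(grepl("^CONT", names(pc$values))), 0L)
  d <- classify_differential_interactions(pc, pt)
  expect_identical(unname(d$counts), c(77L, 222L, 207L))
  expect_setequal(d$lost, re$truth$protein[!is.na(re$truth$class) &
                                             re$truth$class == "lost" &
                                             re$truth$category == "interactor"])
})

test_that("planted expression correlation hits its noiseless limit", {
  es <- generate_expression_and_screens(
    expression_params(n_genes = 50, n_samples = 30, target_rho = 1,
                      noise_sd = 0,
                      signature_genes = sprintf("SIG%03d", 1:10)),
    screen_params(n_orfs = 50, n_dep_genes = 50), seed = 31)
  a <- spearman_all_genes(es$expression, "CREB5")
  sig <- a[a$gene %in% es$truth$signature_genes, ]
  expect_equal(sig$rho, rep(1, 10))
  # TPM-like output is strictly positive
  expect_true(all(es$expression > 0))
})

test_that("planted screen hit with a large Z offset ranks first", {
  for (s in 1:5) {
    es <- generate_expression_and_screens(
      expression_params(n_genes = 10, n_samples = 10),
      screen_params(n_orfs = 500,
                    hits = list(HIT = c(0, 10)), hit_sd = 0.3), seed = s)
    dz <- differential_z_rank(es$screen, "enzalutamide", "standard")
    expect_identical(dz$gene[1], "HIT")
  }
})
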