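test_that("RIME table I/O validates and round-trips", {
  txt <- c("bait\tcondition\treplicate\tprotein_id\tpeptide_seq\tspectral_count",
           "CREB5\tcontrol\t1\tFOXA1\tAAAK\t3",
           "CREB5\tcontrol\t1\tFOXA1\tBBBK\t1",
           "CREB5\tcontrol\t2\tFOXA1\tAAAK\t2",
           "CREB5\tcontrol\t1\tKRT1\tCCCK\t9",
           "LUCIFERASE\tcontrol\t1\tKRT1\tCCCK\t4")
  rec <- read_rime_table(txt)
  expect_identical(nrow(rec), 5L)
  rt <- read_rime_table(write_rime_table(rec))
  expect_identical(rt, rec)

  expect_error(read_rime_table(txt[-1]), "required column")
  expect_error(read_rime_table(c(txt, txt[2])), "duplicate")
  bad <- sub("\t3$", "\tx", txt)
  expect_error(read_rime_table(bad), "spectral_count")
})

test_that("unique-peptide collapsing counts distinct sequences only", {
  rec <- rbind(
    rime_rows("B", "c", 1, "P1", c("a", "b"), count = c(50, 1)),
    rime_rows("B", "c", 2, "P1", "a"),
    rime_rows("B", "c", 1, "P2", c("x", "y", "z")),
    rime_rows("B", "t", 1, "P9", "q"),
    rime_rows("C", "c", 1, "P3", "w"))
  m <- collapse_unique_peptides(rec, "B", "c")
  expect_identical(m["P1", ], c(rep1 = 2L, rep2 = 1L))
  expect_identical(m["P2", ], c(rep1 = 3L, rep2 = 0L))
  expect_false("P9" %in% rownames(m))  # other condition
  expect_false("P3" %in% rownames(m))  # other bait
})

test_that("collapsing agrees with a set-based oracle on random tables", {
  set.seed(37)
  prot <- sprintf("P%02d", 1:12)
  rec <- unique(data.frame(
    bait = "B", condition = "c",
    replicate = sample(1:3, 400, replace = TRUE),
    protein = sample(prot, 400, replace = TRUE),
    peptide = sample(paste0("pep", 1:25), 400, replace = TRUE),
    count = 1L))
  m <- collapse_unique_peptides(rec, "B", "c", n_replicates = 3)
  for (p in rownames(m)) for (r in 1:3) {
    expect_identical(m[p, r],
                     length(unique(rec$peptide[rec$protein == p &
                                                 rec$replicate == r])))
  }
})

test_that("control subtraction removes detected proteins entirely", {
  bait <- matrix(c(7L, 0L, 3L, 2L, 0L, 1L), nrow = 3, byrow = TRUE,
                 dimnames = list(c("KRT1", "FOXA1", "AR"), NULL))
  ctl <- matrix(c(1L, 0L), nrow = 1, dimnames = list("KRT1", NULL))
  out <- subtract_control(bait, ctl)
  expect_identical(rownames(out), c("FOXA1", "AR"))
  # empty control is the identity; subtraction is idempotent
  empty <- matrix(0L, 0, 2)
  expect_identical(subtract_control(bait, empty), bait)
  expect_identical(subtract_control(out, ctl), out)
  # all-zero control rows do not subtract
  ctl0 <- matrix(c(0L, 0L), nrow = 1, dimnames = list("AR", NULL))
  expect_identical(subtract_control(bait, ctl0), bait)
})

test_that("profiles average distinct counts with absence as zero", {
  m <- matrix(c(4L, 0L, 2L, 3L, 0L, 0L), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("rep1", "rep2")))
  p <- build_profile(m, "B1", "c")
  expect_equal(unname(p$values["A"]), 2.0)  # (4 + 0) / 2
  expect_equal(unname(p$values["B"]), 2.5)
  expect_false("C" %in% names(p$values))    # never detected
  # strict presence rule drops single-replicate detections
  p_all <- build_profile(m, "B1", "c", presence = "all")
  expect_identical(names(p_all$values), "B")
  # single replicate: values equal the counts
  p1 <- build_profile(m[, 1, drop = FALSE], "B1", "c")
  expect_equal(unname(p1$values), c(4, 2))
})

test_that("bait self-peptide averages read from the profile", {
  p <- make_profile(c(CREB5 = 8, FOXA1 = 3.5))
  expect_equal(average_bait_peptides(p, "CREB5"), 8)
  expect_equal(average_bait_peptides(p, "ABSENT"), 0)
})

test_that("differential interaction classes partition the two profiles", {
  pc <- make_profile(c(P1 = 1, P2 = 2, P3 = 3), bait = "B")
  pt <- make_profile(c(P2 = 1, P3 = 1, P4 = 9), bait = "B")
  d <- classify_differential_interactions(pc, pt)
  expect_identical(d$lost, "P1")
  expect_identical(d$retained, c("P2", "P3"))
  expect_identical(d$gained, "P4")
  # identical profiles: nothing lost or gained
  d2 <- classify_differential_interactions(pc, pc)
  expect_identical(unname(d2$counts), c(0L, 3L, 0L))
  expect_error(classify_differential_interactions(
    pc, make_profile(c(P1 = 1), bait = "OTHER")), "different baits")
  # the bait protein itself is excluded by default but kept on request
  pcb <- make_profile(c(B = 8, P1 = 1), bait = "B")
  ptb <- make_profile(c(B = 7, P2 = 1), bait = "B")
  expect_identical(unname(classify_differential_interactions(pcb, ptb)$counts),
                   c(1L, 0L, 1L))
  expect_identical(unname(classify_differential_interactions(
    pcb, ptb, drop_bait = FALSE)$counts), c(1L, 1L, 1L))
})

test_that("profile correlation matches hand-computed Pearson on the union", {
  p1 <- make_profile(c(A = 1), bait = "X")
  p2 <- make_profile(c(B = 2, C = 1), bait = "Y")
  # aligned over {A, B, C}: x = (1, 0, 0), y = (0, 2, 1)
  # hand Pearson: cov = -1, sd_x = sqrt(2/3), sd_y = sqrt(2) -> -sqrt(3)/2
  expect_equal(correlate_profiles(p1, p2), -sqrt(3) / 2, tolerance = 1e-12)
  # self-correlation and perfect anticorrelation
  p <- make_profile(c(A = 1, B = 2, C = 3))
  expect_equal(correlate_profiles(p, p), 1.0)
  q <- make_profile(c(A = 3, B = 2, C = 1))
  expect_equal(correlate_profiles(p, q), -1.0)
  # symmetry
  expect_equal(correlate_profiles(p1, p2), correlate_profiles(p2, p1),
               tolerance = 1e-12)
})

test_that("profile correlation rejects degenerate inputs", {
  expect_error(correlate_profiles(make_profile(c(A = 1)),
                                  make_profile(c(A = 2))), ">= 3")
  expect_error(correlate_profiles(make_profile(c(A = 1, B = 1, C = 1)),
                                  make_profile(c(A = 1, B = 2, C = 3))),
               "zero variance")
})

test_that("bait and tag proteins are excluded from correlation by default", {
  p1 <- make_profile(c(X = 50, A = 1, B = 2, C = 3), bait = "X")
  p2 <- make_profile(c(Y = 60, A = 1, B = 2, C = 3), bait = "Y")
  expect_equal(correlate_profiles(p1, p2), 1.0)
  expect_lt(correlate_profiles(p1, p2, drop_bait = FALSE), 1.0)
})

test_that("Venn regions match an element-wise membership tally", {
  A <- as.character(1:5); B <- as.character(3:7); C <- as.character(5:9)
  v <- venn_counts(list(A = A, B = B, C = C))
  # brute-force tally over the universe
  uni <- unique(c(A, B, C))
  key <- vapply(uni, function(e)
    paste(c("A", "B", "C")[c(e %in% A, e %in% B, e %in% C)], collapse = "&"),
    character(1))
  expect_identical(v$regions[sort(names(v$regions))],
                   vapply(sort(names(v$regions)),
                          function(r) sum(key == r), integer(1)))
  # region counts reconstruct each set's size
  expect_identical(venn_pair_total(v, "A", "B"), 3L)
})

test_that("degenerate Venn configurations are exact", {
  d <- venn_counts(list(A = c("x", "y"), B = c("p", "q"), C = "r"))
  expect_identical(sum(d$regions[grepl("&", names(d$regions))]), 0L)
  s <- venn_counts(list(A = c("x", "y"), B = c("x", "y"), C = c("x", "y")))
  expect_identical(unname(s$regions["A&B&C"]), 2L)
  expect_identical(sum(s$regions), 2L)
  expect_error(venn_counts(list(A = "x")), "2 or 3")
  expect_error(venn_counts(setNames(list("x", "y"), c("A", "A"))),
               "unique")
})

test_that("co-factor nomination applies boolean criteria deterministically", {
  sets <- list(A = c("x", "y"), B = c("y", "z"), C = character(0))
  expect_identical(nominate_cofactors(sets, include = c("A", "B")), "y")
  # excluding an empty set changes nothing
  expect_identical(nominate_cofactors(sets, include = c("A", "B"),
                                      exclude = "C"), "y")
  expect_identical(nominate_cofactors(sets, include = "A", exclude = "B"),
                   "x")
  expect_identical(nominate_cofactors(sets, include = "A",
                                      restrict = c("y", "q")), "y")
  expect_error(nominate_cofactors(sets, include = "NOPE"), "unknown set")
})
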