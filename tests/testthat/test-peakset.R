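test_that("read_bed parses valid records and skips non-data lines", {
  txt <- c("track name=demo", "# a comment",
           "chr1\t0\t100\tpk1", "chr1\t150\t300\tpk2", "chr2\t10\t20")
  ps <- read_bed(txt)
  expect_length(ps, 3)
  expect_equal(start(ps) - 1, c(0, 150, 10))
  expect_equal(end(ps), c(100, 300, 20))
})

test_that("read_bed rejects malformed lines and names the line number", {
  expect_error(read_bed("chr1\t100\t50"), "line 1.*100.*50")
  expect_error(read_bed(c("chr1\t0\t10", "chr1\t5\t5")), "line 2")
  expect_error(read_bed("chr1\t1.5\t10"), "non-integer")
  expect_error(read_bed("chr1\t10"), ">= 3")
  expect_error(read_bed("chr1\t0\t10\tpk\tbad_summit"), "summit")
  expect_error(read_bed("chr1\t0\t10\tpk\t50"), "summit outside")
})

test_that("write_bed(read_bed(x)) round-trips coordinates exactly", {
  set.seed(42)
  df <- random_peaks(60)
  lines <- sprintf("%s\t%d\t%d\tp%03d\t%d", df$chrom, df$start, df$end,
                   seq_len(60), df$start + 3)
  ps <- read_bed(lines)
  expect_identical(sort(write_bed(ps)), sort(lines))
  # and a second round trip is byte-stable
  expect_identical(write_bed(read_bed(write_bed(ps))), write_bed(ps))
})

test_that("merge_union merges overlapping and book-ended intervals", {
  a <- peak_set("chr1", 0, 10)
  b <- peak_set("chr1", 5, 15)
  m <- merge_union(list(a, b))
  expect_length(m, 1)
  expect_equal(c(start(m) - 1, end(m)), c(0, 15))
  # book-ended intervals merge by convention
  m2 <- merge_union(list(peak_set("chr1", 0, 10), peak_set("chr1", 10, 20)))
  expect_length(m2, 1)
  expect_equal(end(m2), 20)
  expect_true(dynabind:::is_merged(m2))
  expect_error(merge_union(list()), "non-empty")
})

test_that("merge_union covered bp equals a per-base-pair oracle", {
  set.seed(7)
  for (rep in 1:3) {
    df <- random_peaks(200, chroms = "chr1", max_pos = 3000)
    m <- merge_union(list(df_to_peak_set(df)))
    expect_identical(sum(width(m)),
                     brute_union_bp(df$start, df$end, 4000))
  }
})

test_that("merge_union is idempotent and order-invariant", {
  set.seed(11)
  sets <- replicate(4, df_to_peak_set(random_peaks(40)), simplify = FALSE)
  m1 <- merge_union(sets)
  m2 <- merge_union(sets[c(3, 1, 4, 2)])
  expect_identical(as.character(m1), as.character(m2))
  expect_identical(as.character(merge_union(list(m1))), as.character(m1))
})

test_that("overlap flags follow half-open semantics", {
  a <- peak_set("chr1", 0, 10)
  expect_true(overlaps(a, peak_set("chr1", 9, 20)))
  expect_false(overlaps(a, peak_set("chr1", 10, 20)))  # abutting: 0 shared bp
  expect_false(overlaps(a, peak_set("chr2", 0, 10)))
})

test_that("overlap flags equal the all-pairs quadratic oracle", {
  set.seed(13)
  for (rep in 1:3) {
    da <- random_peaks(100)
    db <- random_peaks(100)
    A <- df_to_peak_set(da)
    got <- overlaps(A, df_to_peak_set(db))
    expect_identical(got, brute_overlap_flags(peaks_as_bed_df(A), db))
  }
})

test_that("summit mode uses the summit point, not the interval", {
  a <- peak_set("chr1", 0, 100, summit = 90)
  b <- peak_set("chr1", 10, 20)
  expect_true(overlaps(a, b))                     # region mode: 10 shared bp
  expect_false(overlaps(a, b, mode = "summit"))   # summit 90 outside [10,20)
  expect_true(overlaps(a, peak_set("chr1", 85, 95), mode = "summit"))
  expect_error(overlaps(peak_set("chr1", 0, 10), b, mode = "summit"),
               "summit")
})

test_that("mismatched chromosome namespaces error unless normalized", {
  a <- peak_set("chr1", 0, 10)
  b <- peak_set("1", 5, 15)
  expect_error(overlaps(a, b), "no chromosome names")
  expect_true(overlaps(a, b, normalize_chr = TRUE))
})

test_that("overlap_fraction is the flagged share of the query", {
  a <- peak_set("chr1", c(0, 100, 200, 300), c(50, 150, 250, 350))
  b <- peak_set("chr1", c(10, 110, 210), c(20, 120, 220))
  expect_equal(overlap_fraction(a, b), 0.75)
  expect_equal(overlap_fraction(b, a), 1.0)
  expect_equal(overlap_fraction(a, peak_set("chr2", 0, 10)), 0)
  expect_error(overlap_fraction(peak_set(character(), numeric(), numeric()),
                                b), "empty")
})
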