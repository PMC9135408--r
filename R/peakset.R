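# Peak sets are GRanges objects. User-facing coordinates follow the BED
# convention (0-based, half-open); internally ranges are stored 1-based
# closed as usual for IRanges, and converted back on output. The dataset
# label and the merged flag live in metadata(x).

#' Genome specification
#'
#' A minimal named-genome description: chromosome names and lengths.
#' Used to constrain synthetic-peak placement and to define the binned
#' universe of the enrichment module.
#'
#' @param chrom_names Character vector of unique chromosome names.
#' @param chrom_lengths Positive integer lengths (bp), one per chromosome.
#' @return A `genome_spec` object (list with `chrom_names`,
#'   `chrom_lengths`).
#' @examples
#' genome_spec(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_spec <- function(chrom_names, chrom_lengths) {
  if (length(chrom_names) != length(chrom_lengths))
    stop_("chrom_names and chrom_lengths differ in length")
  if (anyDuplicated(chrom_names))
    stop_("chromosome names must be unique")
  if (!is.numeric(chrom_lengths) || any(chrom_lengths < 1) ||
      any(chrom_lengths != floor(chrom_lengths)))
    stop_("chromosome lengths must be positive integers")
  structure(
    list(chrom_names = as.character(chrom_names),
         chrom_lengths = setNames(as.numeric(chrom_lengths),
                                  as.character(chrom_names))),
    class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("genome_spec: %d chromosome(s), %s bp total\n",
              length(x$chrom_names), format(sum(x$chrom_lengths))))
  invisible(x)
}

genome_seqinfo <- function(genome) {
  Seqinfo(seqnames = genome$chrom_names,
          seqlengths = as.integer(genome$chrom_lengths))
}

#' Construct a peak set
#'
#' Builds a peak set (a `GRanges`) from BED-convention coordinates:
#' 0-based starts, half-open ends, so a peak covering the first ten bases
#' of a chromosome is `start = 0, end = 10`.
#'
#' @param chrom Chromosome names.
#' @param start 0-based start positions.
#' @param end End positions (exclusive); must satisfy `end > start`.
#' @param name Optional peak names.
#' @param summit Optional absolute 0-based summit positions, each within
#'   `[start, end)`.
#' @param label Dataset label stored in `metadata()`.
#' @param genome Optional [genome_spec()]; when given, seqinfo is set and
#'   peaks beyond chromosome ends are rejected.
#' @param merged Logical flag recording that the set is the output of
#'   [merge_union()] (no two intervals overlap or abut).
#' @return A `GRanges` sorted by (chrom, start).
#' @examples
#' peak_set("chr1", c(0, 50), c(10, 80))
#' @export
peak_set <- function(chrom, start, end, name = NULL, summit = NULL,
                     label = "peaks", genome = NULL, merged = FALSE) {
  n <- length(start)
  if (length(chrom) == 1 && n > 1) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(end) != n)
    stop_("chrom, start, end must have equal length")
  if (n > 0) {
    if (any(start < 0)) stop_("negative start coordinate")
    if (any(end <= start)) stop_("end must exceed start for every peak")
    if (!is.null(summit) &&
        any(!is.na(summit) & (summit < start | summit >= end)))
      stop_("summit outside [start, end)")
  }
  gr <- GRanges(seqnames = as.character(chrom),
                ranges = IRanges(start = start + 1, end = end))
  if (!is.null(name)) mcols(gr)$name <- as.character(name)
  if (!is.null(summit)) mcols(gr)$summit <- as.numeric(summit)
  if (!is.null(genome)) {
    si <- genome_seqinfo(genome)
    bad <- setdiff(as.character(seqnames(gr)), genome$chrom_names)
    if (length(bad))
      stop_("chromosome(s) not in genome: %s", paste(bad, collapse = ", "))
    gr <- GRanges(seqnames = factor(as.character(seqnames(gr)),
                                    levels = genome$chrom_names),
                  ranges = ranges(gr), seqinfo = si)
    if (!is.null(name)) mcols(gr)$name <- as.character(name)
    if (!is.null(summit)) mcols(gr)$summit <- as.numeric(summit)
    over_end <- end(gr) > seqlengths(si)[as.character(seqnames(gr))]
    if (any(over_end)) stop_("peak extends beyond chromosome end")
  }
  gr <- sort(gr)
  metadata(gr)$label <- label
  metadata(gr)$merged <- isTRUE(merged)
  gr
}

peak_label <- function(x) metadata(x)$label %||% "peaks"

is_merged <- function(x) isTRUE(metadata(x)$merged)

# Chromosome naming-style mismatches (chr1 vs 1) are an error, not
# silently harmonized; normalize_chr opts in to stripping the "chr"
# prefix. Sets on genuinely different chromosomes simply do not overlap.
check_same_namespace <- function(a, b, normalize_chr = FALSE) {
  if (normalize_chr) return(invisible(TRUE))
  ca <- unique(as.character(seqnames(a)))
  cb <- unique(as.character(seqnames(b)))
  if (length(ca) == 0 || length(cb) == 0) return(invisible(TRUE))
  if (length(intersect(ca, cb)) == 0 &&
      length(intersect(sub("^chr", "", ca), sub("^chr", "", cb))) > 0)
    stop_(paste0("peak sets share no chromosome names (e.g. '%s' vs '%s') ",
                 "but would after stripping the 'chr' prefix; ",
                 "use normalize_chr = TRUE to opt in"),
          ca[1], cb[1])
  invisible(TRUE)
}

strip_chr <- function(x) {
  lv <- seqlevels(x)
  GenomeInfoDb::renameSeqlevels(x, setNames(sub("^chr", "", lv), lv))
}

#' Read a BED file into a peak set
#'
#' Accepts BED3 (chrom, start, end), BED4 (+ name) and an optional fifth
#' numeric column interpreted as the absolute 0-based summit position
#' (e.g. a MACS2 summit carried alongside the peak interval).
#' `track`, `browser` and `#` comment lines are skipped. Malformed lines —
#' fewer than three fields, non-integer coordinates, negative starts or
#' `start >= end` — raise an error naming the offending line.
#'
#' @param con A file path, or a character vector of BED text lines.
#' @param label Dataset label for the returned set.
#' @param genome Optional [genome_spec()] used to validate coordinates.
#' @return A peak-set `GRanges` (see [peak_set()]).
#' @examples
#' read_bed(c("chr1\t0\t100\tpk1", "chr1\t150\t300\tpk2"))
#' @export
read_bed <- function(con, label = NULL, genome = NULL) {
  if (is.character(con) && length(con) == 1 && file.exists(con)) {
    lines <- readLines(con)
    label <- label %||% sub("\\.bed$", "", basename(con))
  } else {
    lines <- as.character(con)
    label <- label %||% "peaks"
  }
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0)
    return(peak_set(character(), numeric(), numeric(),
                    label = label, genome = genome))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop_("line %d: expected >= 3 tab-separated fields, got %d",
          idx[which(nf < 3)[1]], nf[nf < 3][1])
  chrom <- vapply(fields, `[[`, "", 1L)
  start_s <- vapply(fields, `[[`, "", 2L)
  end_s <- vapply(fields, `[[`, "", 3L)
  start <- suppressWarnings(as.numeric(start_s))
  end <- suppressWarnings(as.numeric(end_s))
  bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad))
    stop_("line %d: non-integer coordinates '%s'/'%s'",
          idx[bad][1], start_s[bad][1], end_s[bad][1])
  if (any(start < 0))
    stop_("line %d: negative start coordinate", idx[start < 0][1])
  if (any(end <= start))
    stop_("line %d: start >= end (%s >= %s)",
          idx[end <= start][1], start_s[end <= start][1],
          end_s[end <= start][1])
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))],
                                 ""), NA_character_)
  if (all(is.na(name))) name <- NULL
  summit <- NULL
  if (any(nf >= 5)) {
    summit_s <- vapply(fields,
                       function(f) if (length(f) >= 5) f[[5]] else NA_character_,
                       "")
    summit <- suppressWarnings(as.numeric(summit_s))
    if (any(!is.na(summit_s) & is.na(summit)))
      stop_("line %d: non-numeric summit field '%s'",
            idx[!is.na(summit_s) & is.na(summit)][1],
            summit_s[!is.na(summit_s) & is.na(summit)][1])
    if (any(!is.na(summit) & (summit < start | summit >= end)))
      stop_("line %d: summit outside [start, end)",
            idx[!is.na(summit) & (summit < start | summit >= end)][1])
  }
  peak_set(chrom, start, end, name = name, summit = summit,
           label = label, genome = genome)
}

#' Write a peak set as BED
#'
#' Emits BED-convention coordinates (0-based half-open); the name column
#' is written when present, and the summit column (absolute 0-based) as a
#' fifth field when present.
#'
#' @param x A peak-set `GRanges`.
#' @param path Output file path, or `NULL` to return the lines.
#' @return Invisibly, the character vector of BED lines.
#' @export
write_bed <- function(x, path = NULL) {
  cols <- list(as.character(seqnames(x)),
               format(start(x) - 1, scientific = FALSE, trim = TRUE),
               format(end(x), scientific = FALSE, trim = TRUE))
  nm <- mcols(x)$name
  sm <- mcols(x)$summit
  if (!is.null(sm) && is.null(nm)) nm <- rep(".", length(x))
  if (!is.null(nm)) cols <- c(cols, list(ifelse(is.na(nm), ".", nm)))
  if (!is.null(sm))
    cols <- c(cols, list(format(sm, scientific = FALSE, trim = TRUE)))
  lines <- do.call(paste, c(cols, sep = "\t"))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Merge a list of peak sets into their union
#'
#' Returns a merged peak set covering exactly the union of input base
#' pairs. Overlapping and book-ended (abutting) intervals are merged into
#' one, the common default of interval merge tools.
#'
#' @param peak_sets A non-empty list of peak-set `GRanges` (a single
#'   `GRanges` is accepted).
#' @param label Label for the merged set.
#' @return A merged peak-set `GRanges` with `metadata()$merged = TRUE`.
#' @examples
#' a <- peak_set("chr1", 0, 10)
#' b <- peak_set("chr1", c(5, 10), c(8, 20))
#' merge_union(list(a, b))  # one interval [0, 20)
#' @export
merge_union <- function(peak_sets, label = "union") {
  if (inherits(peak_sets, "GRanges")) peak_sets <- list(peak_sets)
  if (!is.list(peak_sets) || length(peak_sets) == 0)
    stop_("merge_union requires a non-empty list of peak sets")
  if (!all(vapply(peak_sets, inherits, TRUE, "GRanges")))
    stop_("all inputs must be GRanges peak sets")
  combined <- suppressWarnings(do.call(c, lapply(peak_sets, function(g) {
    mcols(g) <- NULL
    g
  })))
  merged <- reduce(sort(combined))  # merges overlapping and abutting ranges
  metadata(merged)$label <- label
  metadata(merged)$merged <- TRUE
  merged
}

#' Per-interval overlap flags
#'
#' For each interval of `a`, reports whether it shares at least one base
#' pair with any interval of `b` (`mode = "region"`, default), or whether
#' its summit falls inside an interval of `b` (`mode = "summit"`; requires
#' a `summit` column on `a`). Half-open semantics: intervals that merely
#' abut share zero base pairs and do not overlap.
#'
#' @param a,b Peak-set `GRanges` on the same chromosome namespace.
#' @param mode `"region"` or `"summit"`.
#' @param normalize_chr Strip a `"chr"` prefix before comparing
#'   chromosome names (off by default; mismatched namespaces error).
#' @return Logical vector along `a`.
#' @examples
#' a <- peak_set("chr1", c(0, 20), c(10, 30))
#' b <- peak_set("chr1", 9, 15)
#' overlaps(a, b)  # TRUE FALSE
#' @export
overlaps <- function(a, b, mode = c("region", "summit"),
                     normalize_chr = FALSE) {
  mode <- match.arg(mode)
  if (length(a) == 0) return(logical(0))
  if (length(b) == 0) return(rep(FALSE, length(a)))
  check_same_namespace(a, b, normalize_chr = normalize_chr)
  if (normalize_chr) {
    a <- strip_chr(a)
    b <- strip_chr(b)
  }
  if (mode == "summit") {
    sm <- mcols(a)$summit
    if (is.null(sm) || anyNA(sm))
      stop_("summit mode requires a complete 'summit' column on 'a'")
    pts <- GRanges(seqnames(a), IRanges(start = sm + 1, width = 1))
    suppressWarnings(overlapsAny(pts, b))  # disjoint seqlevels are fine
  } else {
    suppressWarnings(overlapsAny(a, b))
  }
}

#' Fraction of peaks in `a` overlapping `b`
#'
#' @inheritParams overlaps
#' @return Proportion in `[0, 1]`: number of intervals of `a` flagged by
#'   [overlaps()] divided by `length(a)`.
#' @export
overlap_fraction <- function(a, b, mode = c("region", "summit"),
                             normalize_chr = FALSE) {
  if (length(a) == 0)
    stop_("overlap_fraction is undefined for an empty query set")
  mean(overlaps(a, b, mode = mode, normalize_chr = normalize_chr))
}
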