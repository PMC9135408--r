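# RIME (rapid immunoprecipitation and mass spectrometry of endogenous
# proteins) interactomics. The quantification unit throughout is the
# unique peptide: the number of DISTINCT peptide sequences mapping to a
# protein in one IP replicate, never summed spectral counts.

RIME_REQUIRED_COLS <- c("bait", "condition", "replicate", "protein_id",
                        "peptide_seq")

#' Read a RIME peptide table
#'
#' Expects a TSV with columns `bait`, `condition`, `replicate`,
#' `protein_id`, `peptide_seq` and optionally `spectral_count` (carried
#' along but ignored by unique-peptide logic). The key
#' `(bait, condition, replicate, protein_id, peptide_seq)` must be
#' unique.
#'
#' @param con File path, or character vector of TSV lines.
#' @return data.frame of peptide records with internal column names
#'   `bait`, `condition`, `replicate`, `protein`, `peptide`, `count`.
#' @export
read_rime_table <- function(con) {
  if (is.character(con) && length(con) == 1 && file.exists(con)) {
    df <- read.delim(con, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    df <- read.delim(textConnection(paste(con, collapse = "\n")),
                     stringsAsFactors = FALSE, check.names = FALSE)
  }
  missing_cols <- setdiff(RIME_REQUIRED_COLS, names(df))
  if (length(missing_cols))
    stop_("RIME table lacks required column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (!"spectral_count" %in% names(df)) df$spectral_count <- 1L
  cnt <- suppressWarnings(as.numeric(df$spectral_count))
  if (anyNA(cnt) || any(cnt < 1) || any(cnt != floor(cnt)))
    stop_("spectral_count must be positive integers")
  rep_i <- suppressWarnings(as.numeric(df$replicate))
  if (anyNA(rep_i) || any(rep_i < 1) || any(rep_i != floor(rep_i)))
    stop_("replicate must be positive integer indices")
  rec <- data.frame(bait = as.character(df$bait),
                    condition = as.character(df$condition),
                    replicate = as.integer(rep_i),
                    protein = as.character(df$protein_id),
                    peptide = as.character(df$peptide_seq),
                    count = as.integer(cnt),
                    stringsAsFactors = FALSE)
  key <- paste(rec$bait, rec$condition, rec$replicate, rec$protein,
               rec$peptide, sep = "\r")
  if (anyDuplicated(key))
    stop_("duplicate (bait, condition, replicate, protein, peptide) row: %s",
          gsub("\r", "/", key[duplicated(key)][1]))
  rec
}

#' Write peptide records as a RIME TSV
#'
#' Inverse of [read_rime_table()]; round-trips records exactly.
#'
#' @param records data.frame of peptide records.
#' @param path Output path, or `NULL` to return the lines.
#' @return Invisibly, the TSV lines.
#' @export
write_rime_table <- function(records, path = NULL) {
  out <- data.frame(bait = records$bait, condition = records$condition,
                    replicate = records$replicate,
                    protein_id = records$protein,
                    peptide_seq = records$peptide,
                    spectral_count = records$count)
  lines <- c(paste(names(out), collapse = "\t"),
             do.call(paste, c(out, sep = "\t")))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Collapse peptide records to unique-peptide counts per replicate
#'
#' For one bait and condition, counts the distinct peptide sequences per
#' protein per replicate. Spectral counts are ignored: a peptide seen
#' many times still counts once.
#'
#' @param records Peptide records (see [read_rime_table()]).
#' @param bait,condition Labels selecting the experiment slice.
#' @param n_replicates Number of replicates run; defaults to the largest
#'   replicate index present for this bait and condition. Replicates with
#'   no detections contribute columns of zeros.
#' @return Integer matrix, proteins x replicates; proteins never detected
#'   are absent (no all-zero rows).
#' @export
collapse_unique_peptides <- function(records, bait, condition,
                                     n_replicates = NULL) {
  sel <- records$bait == bait & records$condition == condition
  sub <- records[sel, , drop = FALSE]
  if (nrow(sub) == 0) {
    n_replicates <- n_replicates %||% 1L
    return(matrix(0L, nrow = 0, ncol = n_replicates,
                  dimnames = list(character(),
                                  paste0("rep", seq_len(n_replicates)))))
  }
  n_replicates <- n_replicates %||% max(sub$replicate)
  if (max(sub$replicate) > n_replicates)
    stop_("replicate index %d exceeds n_replicates = %d",
          max(sub$replicate), n_replicates)
  proteins <- sort(unique(sub$protein))
  m <- matrix(0L, nrow = length(proteins), ncol = n_replicates,
              dimnames = list(proteins, paste0("rep", seq_len(n_replicates))))
  tab <- table(sub$protein, sub$replicate)  # rows are keyed peptides: each
  # (protein, replicate, peptide) appears once, so the table of rows IS the
  # distinct-peptide count.
  m[rownames(tab), as.integer(colnames(tab))] <- as.integer(tab)
  m
}

#' Remove control-IP proteins from a bait's count matrix
#'
#' Any protein detected (>= 1 unique peptide in any replicate) in the
#' control IP — the tag-only / luciferase pulldown — is removed entirely
#' from the bait's matrix, the standard background subtraction of
#' affinity-purification MS. Idempotent.
#'
#' @param bait_counts,control_counts Matrices from
#'   [collapse_unique_peptides()].
#' @return `bait_counts` without contaminant rows.
#' @export
subtract_control <- function(bait_counts, control_counts) {
  if (nrow(control_counts) == 0) return(bait_counts)
  contaminants <- rownames(control_counts)[rowSums(control_counts > 0) > 0]
  bait_counts[!(rownames(bait_counts) %in% contaminants), , drop = FALSE]
}

#' Build a bait interaction profile
#'
#' Collapses a (cleaned) per-replicate unique-peptide matrix to one value
#' per protein: the mean unique-peptide count across all replicates,
#' where a replicate in which the protein was not detected contributes 0.
#' A protein is part of the profile if detected in at least one replicate
#' (`presence = "any"`, default) or in every replicate
#' (`presence = "all"`, the strict rule).
#'
#' @param counts Matrix from [collapse_unique_peptides()] /
#'   [subtract_control()].
#' @param bait,condition Labels recorded on the profile.
#' @param presence Detection rule, `"any"` or `"all"`.
#' @return A `rime_profile`: list with `bait`, `condition`, `values`
#'   (named numeric, protein -> mean unique peptides), `n_replicates`.
#' @export
build_profile <- function(counts, bait, condition,
                          presence = c("any", "all")) {
  presence <- match.arg(presence)
  if (ncol(counts) < 1) stop_("profile requires >= 1 replicate column")
  keep <- if (presence == "any") rowSums(counts > 0) > 0
          else rowSums(counts > 0) == ncol(counts)
  counts <- counts[keep, , drop = FALSE]
  structure(list(bait = bait, condition = condition,
                 values = setNames(rowMeans(counts), rownames(counts)),
                 n_replicates = ncol(counts)),
            class = "rime_profile")
}

#' @export
print.rime_profile <- function(x, ...) {
  cat(sprintf("RIME profile: bait %s, condition %s, %d proteins (%d reps)\n",
              x$bait, x$condition, length(x$values), x$n_replicates))
  invisible(x)
}

#' Average unique peptides mapping to one protein in a profile
#'
#' Reports the replicate-averaged unique-peptide count for `protein`
#' (commonly the bait itself, to confirm enrichment of the target), or 0
#' if the protein is absent from the profile.
#'
#' @param profile A `rime_profile`.
#' @param protein Protein label.
#' @return Non-negative number.
#' @export
average_bait_peptides <- function(profile, protein) {
  stopifnot(inherits(profile, "rime_profile"))
  unname(profile$values[protein] %|na|% 0)
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Classify interactions as lost, retained or gained across conditions
#'
#' Compares one bait's profiles between the control and treated
#' conditions: proteins present only in the control profile are *lost*,
#' present in both *retained*, present only in the treated profile
#' *gained*. The bait's own protein and the epitope tag are excluded by
#' default — their peptides report pulldown efficiency, not
#' interactions.
#'
#' @param profile_control,profile_treated `rime_profile`s for the same
#'   bait.
#' @param drop_bait Exclude the bait protein and `tag` (default `TRUE`).
#' @param tag Epitope-tag protein label.
#' @return A `differential_interactions` object: list of sorted character
#'   vectors `lost`, `retained`, `gained` plus `counts`.
#' @export
classify_differential_interactions <- function(profile_control,
                                               profile_treated,
                                               drop_bait = TRUE,
                                               tag = "V5") {
  stopifnot(inherits(profile_control, "rime_profile"),
            inherits(profile_treated, "rime_profile"))
  if (!identical(profile_control$bait, profile_treated$bait))
    stop_("profiles are for different baits: %s vs %s",
          profile_control$bait, profile_treated$bait)
  pc <- names(profile_control$values)
  pt <- names(profile_treated$values)
  if (drop_bait) {
    drop <- c(profile_control$bait, tag)
    pc <- setdiff(pc, drop)
    pt <- setdiff(pt, drop)
  }
  res <- structure(
    list(bait = profile_control$bait,
         lost = sort(setdiff(pc, pt)),
         retained = sort(intersect(pc, pt)),
         gained = sort(setdiff(pt, pc))),
    class = "differential_interactions")
  res$counts <- c(lost = length(res$lost), retained = length(res$retained),
                  gained = length(res$gained))
  stopifnot(length(intersect(res$lost, c(res$retained, res$gained))) == 0,
            length(intersect(res$retained, res$gained)) == 0,
            setequal(c(res$lost, res$retained), pc),
            setequal(c(res$retained, res$gained), pt))
  res
}

#' @export
print.differential_interactions <- function(x, ...) {
  cat(sprintf("differential interactions (%s): lost %d, retained %d, gained %d\n",
              x$bait, x$counts["lost"], x$counts["retained"],
              x$counts["gained"]))
  invisible(x)
}

#' Pearson correlation of two RIME profiles
#'
#' Aligns the two profiles on the union of their proteins (absent
#' proteins contribute 0) and computes the Pearson correlation of the
#' aligned count vectors. By default the baits' own proteins and the
#' epitope tag are removed first, since self-peptides only measure
#' pulldown efficiency, not shared interactions.
#'
#' @param p1,p2 `rime_profile`s.
#' @param log_transform Correlate `log1p` counts instead of raw counts.
#' @param drop_bait Remove both profiles' bait proteins and `tag` before
#'   aligning (default `TRUE`).
#' @param tag Epitope-tag protein label to drop alongside the baits.
#' @return Pearson R in `[-1, 1]`.
#' @export
correlate_profiles <- function(p1, p2, log_transform = FALSE,
                               drop_bait = TRUE, tag = "V5") {
  stopifnot(inherits(p1, "rime_profile"), inherits(p2, "rime_profile"))
  v1 <- p1$values
  v2 <- p2$values
  if (drop_bait) {
    drop <- c(p1$bait, p2$bait, tag)
    v1 <- v1[!(names(v1) %in% drop)]
    v2 <- v2[!(names(v2) %in% drop)]
  }
  prots <- sort(union(names(v1), names(v2)))
  if (length(prots) < 3)
    stop_("profile correlation needs >= 3 proteins in the union, got %d",
          length(prots))
  x <- unname(ifelse(prots %in% names(v1), v1[prots], 0))
  y <- unname(ifelse(prots %in% names(v2), v2[prots], 0))
  if (log_transform) {
    x <- log1p(x)
    y <- log1p(y)
  }
  if (sd(x) == 0 || sd(y) == 0)
    stop_("profile correlation undefined: zero variance in aligned vector")
  cor(x, y, method = "pearson")
}

#' Venn region counts for two or three protein sets
#'
#' Exact set algebra: counts the `2^k - 1` exclusive regions of 2 or 3
#' named sets. Region names join set names with `&` (e.g. `"A&B"` is the
#' region in A and B but not in C).
#'
#' @param sets Named list of 2 or 3 character vectors (duplicates within
#'   a set are ignored); names must be unique.
#' @return A `venn_counts` object: list with `regions` (named integer
#'   vector), `sets` (the deduplicated inputs), and `set_sizes`.
#' @examples
#' venn_counts(list(A = letters[1:5], B = letters[3:7], C = letters[5:9]))
#' @export
venn_counts <- function(sets) {
  if (!is.list(sets) || !(length(sets) %in% 2:3))
    stop_("venn_counts takes a named list of 2 or 3 sets")
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(!nzchar(names(sets))))
    stop_("set names must be present and unique")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  k <- length(sets)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, ncol = k, dimnames = list(NULL, names(sets)))
  regions <- integer(0)
  for (m in seq_len(2^k - 1)) {
    inc <- as.logical(bitwAnd(m, 2^(seq_len(k) - 1)))
    in_region <- rowSums(member[, inc, drop = FALSE]) == sum(inc) &
      rowSums(member[, !inc, drop = FALSE]) == 0
    regions[paste(names(sets)[inc], collapse = "&")] <- sum(in_region)
  }
  res <- structure(list(regions = regions, sets = sets,
                        set_sizes = lengths(sets)),
                   class = "venn_counts")
  # each set's cardinality must be reconstructable from its regions
  for (nm in names(sets)) {
    in_set <- vapply(names(regions),
                     function(r) nm %in% strsplit(r, "&", fixed = TRUE)[[1]],
                     logical(1))
    stopifnot(sum(regions[in_set]) == length(sets[[nm]]))
  }
  res
}

#' @export
print.venn_counts <- function(x, ...) {
  cat("Venn regions:\n")
  print(x$regions)
  invisible(x)
}

#' Total pairwise intersection of two sets in a Venn result
#'
#' Sum of all regions containing both named sets (i.e. `|A` \eqn{\cap}
#' `B|`, not the exclusive region).
#'
#' @param venn A `venn_counts` object.
#' @param a,b Set names.
#' @return Integer count.
#' @export
venn_pair_total <- function(venn, a, b) {
  stopifnot(inherits(venn, "venn_counts"))
  if (!all(c(a, b) %in% names(venn$sets)))
    stop_("unknown set name in venn_pair_total")
  length(intersect(venn$sets[[a]], venn$sets[[b]]))
}

#' Nominate co-factors by boolean set criteria
#'
#' Returns the sorted proteins belonging to every set in `include` and to
#' no set in `exclude` (e.g. "interacts with the bait and the pioneer
#' factor but not the inert family member"), optionally restricted to a
#' further set such as a differential-interaction group.
#'
#' @param sets Named list of character vectors.
#' @param include Set names the protein must belong to (>= 1).
#' @param exclude Set names the protein must not belong to.
#' @param restrict Optional character vector (e.g.
#'   `c(diff$retained, diff$gained)`) to intersect with.
#' @return Sorted character vector of protein labels.
#' @export
nominate_cofactors <- function(sets, include, exclude = character(),
                               restrict = NULL) {
  if (!is.list(sets) || is.null(names(sets)))
    stop_("sets must be a named list")
  unknown <- setdiff(c(include, exclude), names(sets))
  if (length(unknown))
    stop_("unknown set name(s) in criteria: %s",
          paste(unknown, collapse = ", "))
  if (length(include) == 0) stop_("at least one 'include' set required")
  hits <- Reduce(intersect, lapply(sets[include], unique))
  for (nm in exclude) hits <- setdiff(hits, sets[[nm]])
  if (!is.null(restrict)) hits <- intersect(hits, restrict)
  sort(hits)
}
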