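# Stage-specific AR binding-site (ARBS) taxonomy of a query peak set.
# Classes follow the tissue-stage nomenclature: NARBS (normal prostate),
# TARBS (primary tumor), metARBS (mCRPC), UARBS (universal / all tissues);
# query peaks touching none of the class sets are OTHER.

ARBS_CLASSES <- c("NARBS", "TARBS", "metARBS", "UARBS")
ARBS_PRECEDENCE <- c("metARBS", "TARBS", "NARBS", "UARBS")

#' Annotate peaks with ARBS tissue-stage classes
#'
#' Assigns each query peak exactly one class label. The reference class
#' sets are conceptually disjoint (each ARBS is exclusive to one stage),
#' but when a peak does overlap several class sets the progression-stage
#' precedence `metARBS > TARBS > NARBS > UARBS` decides; an auditable
#' non-exclusive overlap count table is returned alongside. Peaks
#' overlapping no class set are labelled `OTHER`.
#'
#' @param query Peak-set `GRanges`.
#' @param class_sets Named list of peak-set `GRanges`; names must be drawn
#'   from `NARBS`, `TARBS`, `metARBS`, `UARBS`.
#' @param mode,normalize_chr Passed to [overlaps()].
#' @return An `arbs_taxonomy` object: list with `labels` (factor along
#'   `query`), `counts`, `fractions` (summing to 1), `nonexclusive`
#'   (per-class overlap counts ignoring precedence) and the `query` set.
#' @examples
#' q <- peak_set("chr1", c(0, 500), c(100, 600))
#' cls <- list(metARBS = peak_set("chr1", 50, 120))
#' annotate_arbs_classes(q, cls)
#' @export
annotate_arbs_classes <- function(query, class_sets,
                                  mode = c("region", "summit"),
                                  normalize_chr = FALSE) {
  mode <- match.arg(mode)
  if (!is.list(class_sets) || is.null(names(class_sets)) ||
      any(!nzchar(names(class_sets))))
    stop_("class_sets must be a named list of peak sets")
  unknown <- setdiff(names(class_sets), ARBS_CLASSES)
  if (length(unknown))
    stop_("unknown ARBS class label(s): %s (expected %s)",
          paste(unknown, collapse = ", "),
          paste(ARBS_CLASSES, collapse = ", "))
  if (length(query) == 0)
    stop_("empty query peak set")
  flags <- vapply(class_sets, function(ref)
    overlaps(query, ref, mode = mode, normalize_chr = normalize_chr),
    logical(length(query)))
  flags <- matrix(flags, nrow = length(query),
                  dimnames = list(NULL, names(class_sets)))
  levels_all <- c(ARBS_CLASSES, "OTHER")
  labels <- rep("OTHER", length(query))
  for (cls in rev(intersect(ARBS_PRECEDENCE, colnames(flags))))
    labels[flags[, cls]] <- cls
  labels <- factor(labels, levels = levels_all)
  counts <- table(labels)
  fractions <- as.numeric(counts) / length(query)
  names(fractions) <- names(counts)
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  structure(
    list(labels = labels,
         counts = setNames(as.integer(counts), names(counts)),
         fractions = fractions,
         nonexclusive = colSums(flags),
         query = query),
    class = "arbs_taxonomy")
}

#' @export
print.arbs_taxonomy <- function(x, ...) {
  cat("ARBS taxonomy of", length(x$query), "peaks\n")
  print(data.frame(class = names(x$counts), n = x$counts,
                   fraction = round(x$fractions, 4), row.names = NULL))
  invisible(x)
}

#' Per-class overlap of a taxonomy with a reference peak set
#'
#' For each taxonomy class, the fraction of that class's query peaks that
#' overlap `reference` (e.g. per-ARBS-class overlap with a pioneer-factor
#' union set). Classes with zero peaks are reported as `NA` with
#' `defined = FALSE`, not as 0.
#'
#' @param taxonomy An `arbs_taxonomy` from [annotate_arbs_classes()].
#' @param reference Peak-set `GRanges`.
#' @param mode,normalize_chr Passed to [overlaps()].
#' @return data.frame with columns `class`, `n`, `n_overlap`, `fraction`,
#'   `defined`.
#' @export
class_overlap_summary <- function(taxonomy, reference,
                                  mode = c("region", "summit"),
                                  normalize_chr = FALSE) {
  stopifnot(inherits(taxonomy, "arbs_taxonomy"))
  mode <- match.arg(mode)
  hit <- overlaps(taxonomy$query, reference, mode = mode,
                  normalize_chr = normalize_chr)
  classes <- levels(taxonomy$labels)
  n <- integer(length(classes))
  k <- integer(length(classes))
  for (i in seq_along(classes)) {
    sel <- taxonomy$labels == classes[i]
    n[i] <- sum(sel)
    k[i] <- sum(hit[sel])
  }
  data.frame(class = classes, n = n, n_overlap = k,
             fraction = ifelse(n > 0, k / n, NA_real_),
             defined = n > 0, row.names = NULL)
}
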