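# ORF-screen differential viability Z analytics and RNAi dependency
# averaging / ranking. Dependency scores follow the DEMETER convention:
# more negative = stronger dependency.

#' Construct a screen matrix
#'
#' @param values Numeric matrix, genes/ORFs x arms (or cell lines), with
#'   unique row names; `NA` marks gene/line pairs not screened.
#' @param groups Optional named character vector mapping column names to
#'   group labels (e.g. `AR_positive`, `AR_negative`, `non_PC`).
#' @return A `screen_matrix` object (list with `values`, `groups`).
#' @export
screen_matrix <- function(values, groups = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_("values must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop_("values must have unique row names (genes)")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop_("values must have unique column names (arms / cell lines)")
  if (!is.null(groups)) {
    missing_cols <- setdiff(colnames(values), names(groups))
    if (length(missing_cols))
      stop_("columns without a group label: %s",
            paste(missing_cols, collapse = ", "))
    groups <- groups[colnames(values)]
  }
  structure(list(values = values, groups = groups), class = "screen_matrix")
}

#' @export
print.screen_matrix <- function(x, ...) {
  cat(sprintf("screen matrix: %d genes x %d columns%s\n",
              nrow(x$values), ncol(x$values),
              if (!is.null(x$groups))
                sprintf(" (%d groups)", length(unique(x$groups))) else ""))
  invisible(x)
}

#' Read a screen matrix (TSV + optional group manifest)
#'
#' @param path TSV with gene labels in the first column, one column per
#'   arm / cell line.
#' @param manifest_path Optional two-column TSV (`column`, `group`).
#' @return A `screen_matrix`.
#' @export
read_screen_matrix <- function(path, manifest_path = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  groups <- NULL
  if (!is.null(manifest_path)) {
    man <- read.delim(manifest_path, stringsAsFactors = FALSE)
    groups <- setNames(man$group, man$column)
  }
  screen_matrix(m, groups)
}

#' Differential viability Z ranking between two screen arms
#'
#' For each gene, `delta = z_treated - z_control`; rank 1 is the largest
#' delta (the strongest treatment-specific viability effect), with ties
#' given their average rank.
#'
#' @param x A `screen_matrix` of per-arm Z-scores.
#' @param treated_arm,control_arm Column names.
#' @return data.frame `gene`, `z_treated`, `z_control`, `delta`, `rank`,
#'   sorted by rank.
#' @export
differential_z_rank <- function(x, treated_arm, control_arm) {
  stopifnot(inherits(x, "screen_matrix"))
  for (arm in c(treated_arm, control_arm))
    if (!arm %in% colnames(x$values))
      stop_("unknown screen arm '%s'", arm)
  zt <- x$values[, treated_arm]
  zc <- x$values[, control_arm]
  delta <- zt - zc
  rk <- rank(-delta, ties.method = "average", na.last = "keep")
  out <- data.frame(gene = rownames(x$values), z_treated = zt,
                    z_control = zc, delta = delta, rank = rk,
                    row.names = NULL)
  out[order(out$rank), , drop = FALSE]
}

#' Average dependency score per gene over a cell-line group
#'
#' Arithmetic mean over the group's columns, excluding missing values
#' (genes not screened in a line). Genes missing in every group column
#' are returned as `NA` (undefined), never as 0.
#'
#' @param x A `screen_matrix` with `groups`.
#' @param group Group label.
#' @return Named numeric vector, gene -> mean score.
#' @export
average_dependency <- function(x, group) {
  stopifnot(inherits(x, "screen_matrix"))
  if (is.null(x$groups)) stop_("screen matrix has no column groups")
  cols <- names(x$groups)[x$groups == group]
  if (length(cols) == 0) stop_("no columns in group '%s'", group)
  rowMeans(x$values[, cols, drop = FALSE], na.rm = TRUE) |>
    (\(v) { v[is.nan(v)] <- NA_real_; v })()
}

#' Rank genes by dependency strength with percentiles
#'
#' Rank 1 is the most negative average score (strongest dependency);
#' ties receive their average rank; `percentile = rank / n * 100`. Genes
#' with undefined (`NA`) averages are dropped with a note attribute.
#'
#' @param avg_scores Named numeric vector from [average_dependency()].
#' @return data.frame `gene`, `score`, `rank`, `percentile`, sorted by
#'   rank.
#' @export
rank_percentile <- function(avg_scores) {
  if (length(avg_scores) == 0) stop_("no genes to rank")
  defined <- !is.na(avg_scores)
  v <- avg_scores[defined]
  rk <- rank(v, ties.method = "average")
  out <- data.frame(gene = names(v), score = unname(v), rank = unname(rk),
                    percentile = unname(rk / length(v) * 100),
                    row.names = NULL)
  out <- out[order(out$rank), , drop = FALSE]
  attr(out, "n_undefined") <- sum(!defined)
  out
}
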