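# Transcriptome-wide Spearman association of an index gene, BH
# correction, and signature-restricted volcano summaries.

#' Read an expression matrix (genes x samples TSV)
#'
#' @param path TSV with gene labels in the first column.
#' @return Numeric matrix with gene row names.
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  if (anyDuplicated(rownames(m))) stop_("duplicate gene labels")
  m
}

#' Read a gene signature (plain list or GMT line)
#'
#' Plain format: one gene per line. GMT: the first two fields (name,
#' description) of each line are dropped and the remainder taken as
#' genes.
#'
#' @param con File path or character vector of lines.
#' @param gmt Treat input as GMT.
#' @return Character vector of unique gene labels.
#' @export
read_signature <- function(con, gmt = FALSE) {
  lines <- if (length(con) == 1 && file.exists(con)) readLines(con) else con
  lines <- lines[nzchar(trimws(lines))]
  if (gmt) {
    genes <- unlist(lapply(strsplit(lines, "\t"), function(f) f[-(1:2)]))
  } else {
    genes <- trimws(lines)
  }
  unique(genes[nzchar(genes)])
}

spearman_rho_p <- function(x, y) {
  ok <- complete.cases(x, y)
  n <- sum(ok)
  if (n < 3) return(c(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x[ok], ties.method = "average")
  ry <- rank(y[ok], ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0) return(c(rho = NA_real_, p = NA_real_, n = n))
  rho <- cor(rx, ry)
  # two-sided p from the t approximation, the standard large-sample form
  # with average-rank ties
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  c(rho = rho, p = p, n = n)
}

#' Transcriptome-wide Spearman association with an index gene
#'
#' Correlates the index gene's expression with every detectable gene
#' (Spearman: average-rank transform, then Pearson on ranks; two-sided p
#' from the t approximation) and applies Benjamini-Hochberg correction
#' across all tested genes. The index gene itself is reported with
#' `rho = 1` but excluded from the BH adjustment. "Detectable" means
#' nonzero variance and expression > 0 in at least `detect_frac` of
#' samples.
#'
#' @param expr Numeric matrix, genes x samples (>= 3 samples).
#' @param index_gene Row name of the index gene.
#' @param detect_frac Minimum fraction of samples with expression > 0
#'   (default 0.2).
#' @return An `association_table` data.frame: `gene`, `rho`, `p`, `q`,
#'   `n_samples`, ordered by input gene order (index gene first among
#'   retained genes is not guaranteed; filter as needed).
#' @export
spearman_all_genes <- function(expr, index_gene, detect_frac = 0.2) {
  if (!is.matrix(expr) || !is.numeric(expr)) stop_("expr must be numeric matrix")
  if (ncol(expr) < 3) stop_("need >= 3 samples")
  if (!index_gene %in% rownames(expr))
    stop_("index gene '%s' absent from matrix", index_gene)
  check_proportion(detect_frac, "detect_frac")
  idx <- expr[index_gene, ]
  if (sd(idx, na.rm = TRUE) == 0 || all(is.na(idx)))
    stop_("index gene has constant expression; correlation undefined")
  detected <- apply(expr, 1, function(v)
    sd(v, na.rm = TRUE) > 0 && mean(v > 0, na.rm = TRUE) >= detect_frac)
  detected[index_gene] <- TRUE
  genes <- rownames(expr)[detected]
  stats <- t(vapply(genes, function(g) spearman_rho_p(idx, expr[g, ]),
                    c(rho = 0, p = 0, n = 0)))
  out <- data.frame(gene = genes, rho = stats[, "rho"], p = stats[, "p"],
                    q = NA_real_, n_samples = as.integer(stats[, "n"]),
                    row.names = NULL)
  self <- out$gene == index_gene
  out$rho[self] <- 1
  out$p[self] <- 0
  out$q[!self] <- bh_adjust(out$p[!self])
  class(out) <- c("association_table", class(out))
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; output order matches input order. Thin
#' validated wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues Numeric vector in `[0, 1]` (`NA` allowed, propagated).
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues))
    stop_("pvalues must be numeric")
  bad <- !is.na(pvalues) & (pvalues < 0 | pvalues > 1)
  if (any(bad))
    stop_("p-value outside [0, 1]: %s", format(pvalues[bad][1]))
  p.adjust(pvalues, method = "BH")
}

#' Signature-restricted volcano table
#'
#' Restricts an association table to a gene signature and tabulates rho
#' against `-log10(p)` with a significance flag. Signature genes missing
#' from the association table are reported in the `missing` attribute;
#' an empty intersection is an error naming them.
#'
#' @param assoc An `association_table` from [spearman_all_genes()].
#' @param signature Character vector of gene labels.
#' @param p_threshold Significance threshold on the raw p (default 0.05);
#'   the BH q column is carried along so either can be used.
#' @return data.frame `gene`, `rho`, `p`, `q`, `neg_log10_p`,
#'   `significant`; attribute `missing` lists absent signature genes.
#' @export
signature_volcano <- function(assoc, signature, p_threshold = 0.05) {
  stopifnot(inherits(assoc, "association_table"))
  check_proportion(p_threshold, "p_threshold")
  signature <- unique(signature)
  present <- intersect(signature, assoc$gene)
  missing_genes <- setdiff(signature, assoc$gene)
  if (length(present) == 0)
    stop_("no signature gene present in the association table; missing: %s",
          paste(head(missing_genes, 10), collapse = ", "))
  sub <- assoc[match(present, assoc$gene), , drop = FALSE]
  out <- data.frame(gene = sub$gene, rho = sub$rho, p = sub$p, q = sub$q,
                    neg_log10_p = -log10(pmax(sub$p, .Machine$double.xmin)),
                    significant = !is.na(sub$p) & sub$p < p_threshold,
                    row.names = NULL)
  attr(out, "missing") <- missing_genes
  out
}
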