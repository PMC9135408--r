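# Lost / retained / gained classification of peaks between two conditions.

#' Classify peaks as lost, retained or gained between two conditions
#'
#' A control-condition peak is *retained* if it overlaps at least one
#' treated-condition peak (once, regardless of how many treated peaks it
#' touches) and *lost* otherwise; a treated-condition peak that overlaps
#' no control peak is *gained*. The retained category is reported from
#' both sides (`retained_control`, `retained_treated`) because the two
#' conditions' peak boundaries differ.
#'
#' @param control,treated Peak-set `GRanges` for the pre-treatment and
#'   treated conditions.
#' @param mode Overlap criterion passed to [overlaps()]: full-interval
#'   `"region"` (default) or `"summit"`.
#' @param normalize_chr See [overlaps()].
#' @return A `differential_peaks` object: list with peak sets `lost`,
#'   `retained_control`, `retained_treated`, `gained` and an integer
#'   vector `counts`. Partition invariants
#'   (`lost + retained_control == length(control)`,
#'   `gained + retained_treated == length(treated)`) are asserted.
#' @examples
#' ctl <- peak_set("chr1", c(0, 200), c(100, 300))
#' trt <- peak_set("chr1", c(50, 500), c(150, 600))
#' classify_differential_peaks(ctl, trt)
#' @export
classify_differential_peaks <- function(control, treated,
                                        mode = c("region", "summit"),
                                        normalize_chr = FALSE) {
  mode <- match.arg(mode)
  in_treated <- overlaps(control, treated, mode = mode,
                         normalize_chr = normalize_chr)
  in_control <- overlaps(treated, control, mode = mode,
                         normalize_chr = normalize_chr)
  res <- structure(
    list(lost = control[!in_treated],
         retained_control = control[in_treated],
         retained_treated = treated[in_control],
         gained = treated[!in_control],
         counts = c(lost = sum(!in_treated),
                    retained = sum(in_treated),
                    gained = sum(!in_control))),
    class = "differential_peaks")
  stopifnot(length(res$lost) + length(res$retained_control) ==
              length(control),
            length(res$gained) + length(res$retained_treated) ==
              length(treated))
  res
}

#' @export
print.differential_peaks <- function(x, ...) {
  cat(sprintf("differential peaks: lost %d, retained %d, gained %d\n",
              x$counts["lost"], x$counts["retained"], x$counts["gained"]))
  invisible(x)
}

#' Union peak set across two conditions
#'
#' Merged union of the control and treated peak sets — the "present with
#' or without treatment" set used as the query for taxonomy and
#' enrichment analyses. Equivalent to
#' `merge_union(list(control, treated))`.
#'
#' @inheritParams classify_differential_peaks
#' @param label Label for the union set.
#' @return A merged peak-set `GRanges`.
#' @export
condition_union <- function(control, treated, label = "condition_union") {
  check_same_namespace(control, treated)
  merge_union(list(control, treated), label = label)
}

#' Write differential peak classes as three BED files
#'
#' @param x A `differential_peaks` object.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the three file paths.
#' @export
write_differential_beds <- function(x, dir, prefix = "peaks") {
  stopifnot(inherits(x, "differential_peaks"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_", c("lost", "retained", "gained"),
                                 ".bed"))
  write_bed(x$lost, paths[1])
  write_bed(x$retained_control, paths[2])
  write_bed(x$gained, paths[3])
  invisible(paths)
}
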