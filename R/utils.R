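# Internal helpers: argument checks, seed substreams, apportionment.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_("'%s' must be a single non-missing number", name)
  if (integer && x != floor(x))
    stop_("'%s' must be an integer, got %s", name, format(x))
  if (x < lower || x > upper)
    stop_("'%s' must be in [%s, %s], got %s", name, lower, upper, format(x))
  invisible(x)
}

check_proportion <- function(x, name) check_scalar_number(x, name, 0, 1)

# Derive a reproducible per-stream seed from one global seed so that adding
# a generator call does not perturb the draws of the others. Plain integer
# mixing (splitmix-style) folded into the 31-bit range set.seed accepts.
substream_seed <- function(seed, stream) {
  check_scalar_number(seed, "seed", integer = TRUE)
  h <- (as.double(seed) * 2654435761 + stream * 40503 + 97) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a local RNG state; global .Random.seed is restored.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Largest-remainder apportionment of n among fractions
#'
#' Splits an integer total into class counts proportional to `fracs`,
#' guaranteeing the counts sum exactly to `n`: each class first receives
#' `floor(frac * n)`, then the remaining units go to the classes with the
#' largest fractional remainders (ties resolved in input order).
#'
#' @param n Non-negative integer total.
#' @param fracs Named or unnamed non-negative fractions summing to <= 1 +
#'   1e-9. Fractions are renormalised to sum to 1 when their sum differs
#'   from 1 by more than 1e-9 is not allowed; supply fractions that sum
#'   to 1.
#' @return Integer vector of counts, same names as `fracs`, summing to `n`.
#' @examples
#' apportion(1000, c(lost = 0.2, retained = 0.5, gained = 0.3))
#' @export
apportion <- function(n, fracs) {
  check_scalar_number(n, "n", lower = 0, integer = TRUE)
  if (!is.numeric(fracs) || any(is.na(fracs)) || any(fracs < 0))
    stop_("'fracs' must be non-negative numbers")
  if (abs(sum(fracs) - 1) > 1e-9)
    stop_("'fracs' must sum to 1 (got %s)", format(sum(fracs)))
  quota <- fracs * n
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    take <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[take] <- counts[take] + 1
  }
  storage.mode(counts) <- "integer"
  counts
}
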