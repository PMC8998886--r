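# Internal helpers shared across modules.

# Evaluate `code` under a locally seeded RNG, restoring the caller's RNG
# state afterwards so package functions never clobber the session stream.
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) {
    stop("a seed is required for every stochastic stage", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Draw a fresh sub-seed from the current RNG stream (for nested stages).
draw_seed <- function() sample.int(.Machine$integer.max - 1L, 1L)

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement; the output is
#' aligned with the input positions. Input values must lie in \[0, 1\].
#'
#' @param pvals numeric vector of raw p-values.
#' @return numeric vector of BH-adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals)) stop("pvals must be numeric", call. = FALSE)
  bad <- which(!is.na(pvals) & (pvals < 0 | pvals > 1))
  if (length(bad)) {
    stop("p-value outside [0, 1] at position ", bad[1], call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' One-tail Wilcoxon signed-rank test for positive shift
#'
#' Tests whether a vector of values (typically predicted-vs-measured
#' correlation coefficients) is shifted above zero. Exact signed-rank
#' enumeration for n <= 25 when no ties occur in the absolute values;
#' otherwise the normal approximation with continuity correction. Zeros are
#' dropped before ranking.
#'
#' @param values numeric vector with at least one non-zero entry.
#' @return one-tailed p-value for a shift above zero.
#' @export
wilcoxon_one_tail_greater <- function(values) {
  if (!length(values)) stop("empty input", call. = FALSE)
  v <- values[!is.na(values) & values != 0]
  if (!length(v)) stop("at least one non-zero value is required", call. = FALSE)
  exact <- length(v) <= 25 && !anyDuplicated(abs(v))
  res <- suppressWarnings(
    stats::wilcox.test(v, mu = 0, alternative = "greater",
                       exact = exact, correct = TRUE)
  )
  unname(res$p.value)
}
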