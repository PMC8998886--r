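# Pearson correlation machinery with closed-form p-values.

# Two-sided p-value for a Pearson r on n complete pairs:
# t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 df; |r| = 1 gives p = 0.
r_to_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  p <- rep(NA_real_, length(r))
  at1 <- !is.na(r) & abs(r) >= 1
  p[at1] <- 0
  ok <- !is.na(r) & !at1 & n > 2
  if (any(ok)) {
    tt <- abs(r[ok]) * sqrt((n[ok] - 2) / (1 - r[ok]^2))
    p[ok] <- 2 * stats::pt(tt, df = n[ok] - 2, lower.tail = FALSE)
  }
  p
}

#' Pearson correlation with closed-form p-value
#'
#' Drops pairs where either member is missing, then computes the Pearson
#' coefficient and its two-sided p-value from the t-tail formula. Degenerate
#' input (fewer than 3 complete pairs, or zero variance) yields a
#' "not computable" marker rather than an error, so a full-matrix scan can
#' skip such pairs and keep going.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p`, `n_pairs`, and `ok` (FALSE when not
#'   computable).
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  n <- sum(keep)
  if (n < 3L) {
    return(list(r = NA_real_, p = NA_real_, n_pairs = n, ok = FALSE))
  }
  x <- x[keep]
  y <- y[keep]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n_pairs = n, ok = FALSE))
  }
  r <- stats::cor(x, y)
  list(r = r, p = r_to_p(r, n), n_pairs = n, ok = TRUE)
}

# All-pairs Pearson r, p, and complete-pair counts between the rows of two
# features-by-samples matrices, pairwise-complete over missing values.
# Pairs with < 3 complete observations or zero variance get NA r/p.
pair_cor <- function(X, Y) {
  tX <- t(X)
  tY <- t(Y)
  r <- suppressWarnings(stats::cor(tX, tY, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(tX) + 0, !is.na(tY) + 0)
  r[n < 3] <- NA_real_
  p <- array(r_to_p(as.vector(r), as.vector(n)), dim = dim(r),
             dimnames = dimnames(r))
  list(r = r, p = p, n = n)
}
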