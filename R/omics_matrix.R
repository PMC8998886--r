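#' Omics matrix container
#'
#' A features-by-samples numeric matrix with a feature-kind tag
#' ("metabolite" or "transcript") per row. Orientation is fixed: features in
#' rows, samples in columns; no auto-transposition is ever attempted.
#' Expression values are assumed pre-normalized (variance-stabilized or
#' log-scale); metabolite values are scaled arbitrary units. Missing values
#' are carried as NA and handled pairwise-complete downstream.
#'
#' @param values numeric matrix with feature ids as row names and sample ids
#'   as column names.
#' @param kind either a single tag recycled over rows or one tag per row;
#'   each must be "metabolite" or "transcript".
#' @return an object of class `omics_matrix`: a list with elements `values`
#'   (the matrix, ids whitespace-trimmed) and `kind` (character per row).
#' @export
omics_matrix <- function(values, kind) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry feature row names and sample column names",
         call. = FALSE)
  }
  rn <- trimws(rownames(values))
  cn <- trimws(colnames(values))
  dup <- unique(rn[duplicated(rn)])
  if (length(dup)) {
    stop("duplicate feature id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  dupc <- unique(cn[duplicated(cn)])
  if (length(dupc)) {
    stop("duplicate sample id(s): ", paste(dupc, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.infinite(values))) {
    stop("values must be finite or NA", call. = FALSE)
  }
  if (length(kind) == 1L) kind <- rep(kind, nrow(values))
  if (length(kind) != nrow(values)) {
    stop("kind must have length 1 or nrow(values)", call. = FALSE)
  }
  if (!all(kind %in% c("metabolite", "transcript"))) {
    stop("kind must be 'metabolite' or 'transcript'", call. = FALSE)
  }
  dimnames(values) <- list(rn, cn)
  structure(list(values = values, kind = kind), class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  tab <- table(x$kind)
  cat(sprintf("omics_matrix: %d features (%s) x %d samples\n",
              nrow(x$values),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              ncol(x$values)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

feature_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

# Column-subset an omics_matrix by sample index or id.
subset_samples <- function(x, samples) {
  omics_matrix(x$values[, samples, drop = FALSE], x$kind)
}

# Extract the rows of one feature kind as a plain matrix.
kind_values <- function(x, kind) {
  x$values[x$kind == kind, , drop = FALSE]
}

#' Read a features-by-samples TSV into an omics matrix
#'
#' Expects a tab-separated file: first column feature ids, header row sample
#' ids, remaining cells numeric or the token "NA" (missing). Feature ids are
#' whitespace-trimmed and must be unique; any non-numeric cell is a hard
#' error naming its position.
#'
#' @param path path to the TSV file.
#' @param kind feature kind tag for all rows ("metabolite" or "transcript").
#' @return an [omics_matrix].
#' @export
read_omics_matrix <- function(path, kind = c("transcript", "metabolite")) {
  kind <- match.arg(kind)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(raw) < 3L) {
    stop("matrix file must have at least 2 sample columns: ", path,
         call. = FALSE)
  }
  ids <- trimws(raw[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate feature id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !(is.na(cells) | trimws(cells) == "NA"),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-numeric cell '%s' at feature '%s' (row %d), sample '%s' (column %d) in %s",
      cells[bad[1, 1], bad[1, 2]], ids[bad[1, 1]], bad[1, 1],
      colnames(cells)[bad[1, 2]], bad[1, 2], path), call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(raw)[-1L])
  message(sprintf("read %d %s features x %d samples from %s (%d missing cells)",
                  nrow(num), kind, ncol(num), path, sum(is.na(num))))
  omics_matrix(num, kind)
}

#' Write an omics matrix as TSV
#'
#' Inverse of [read_omics_matrix()]: first column `feature`, one column per
#' sample, full double precision.
#'
#' @param x an [omics_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  vals <- format(x$values, digits = 17, trim = TRUE, scientific = FALSE)
  vals[is.na(x$values)] <- "NA"
  out <- cbind(feature = rownames(x$values), vals)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stack metabolite and transcript matrices over shared samples
#'
#' Restricts both inputs to the intersection of their sample ids (in the
#' metabolite matrix's order) and stacks metabolite rows above transcript
#' rows, preserving feature-kind tags.
#'
#' @param metab metabolite [omics_matrix].
#' @param expr transcript [omics_matrix].
#' @return a combined [omics_matrix] with mixed feature kinds.
#' @export
combine_matrices <- function(metab, expr) {
  stopifnot(inherits(metab, "omics_matrix"), inherits(expr, "omics_matrix"))
  if (!nrow(metab$values) || !nrow(expr$values)) {
    stop("both matrices must be non-empty", call. = FALSE)
  }
  shared <- intersect(sample_ids(metab), sample_ids(expr))
  if (!length(shared)) {
    stop("no shared sample ids between the two matrices", call. = FALSE)
  }
  clash <- intersect(feature_ids(metab), feature_ids(expr))
  if (length(clash)) {
    stop("feature id(s) present in both inputs: ",
         paste(utils::head(clash, 5), collapse = ", "), call. = FALSE)
  }
  message(sprintf("sample intersection: %d of %d/%d", length(shared),
                  ncol(metab$values), ncol(expr$values)))
  omics_matrix(
    rbind(metab$values[, shared, drop = FALSE],
          expr$values[, shared, drop = FALSE]),
    c(metab$kind, expr$kind)
  )
}

#' Harmonize feature names between two id lists
#'
#' Exact matching after normalization: case folding and removal of
#' whitespace and underscores. No fuzzy matching — metabolite naming is not
#' standardized across platforms, and approximate matching would fabricate
#' overlap. An empty overlap is a valid outcome.
#'
#' @param a,b character vectors of feature ids.
#' @return a list with `matched` (data.frame with columns `a`, `b`),
#'   `unmatched_a`, and `unmatched_b`.
#' @export
harmonize_feature_names <- function(a, b) {
  norm <- function(x) gsub("[[:space:]_]+", "", tolower(trimws(x)))
  ka <- norm(a)
  kb <- norm(b)
  hit <- match(ka, kb)
  ok <- !is.na(hit)
  list(
    matched = data.frame(a = a[ok], b = b[hit[ok]],
                         stringsAsFactors = FALSE),
    unmatched_a = a[!ok],
    unmatched_b = b[!(kb %in% ka)]
  )
}

#' Standardize rows to z-scores
#'
#' Each row becomes (x - mean) / sd with the sample sd (n - 1 divisor),
#' computed over non-missing entries. Zero-variance rows are dropped with a
#' message; if every row is constant that is a hard error.
#'
#' @param m an [omics_matrix] with at least 2 samples.
#' @return an [omics_matrix] of z-scored rows.
#' @export
zscore_rows <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  if (ncol(m$values) < 2L) stop("need at least 2 samples", call. = FALSE)
  mu <- rowMeans(m$values, na.rm = TRUE)
  sdv <- apply(m$values, 1L, stats::sd, na.rm = TRUE)
  keep <- !is.na(sdv) & sdv > 0
  if (!any(keep)) stop("all rows have zero variance", call. = FALSE)
  if (any(!keep)) {
    message("dropping ", sum(!keep), " zero-variance row(s): ",
            paste(utils::head(rownames(m$values)[!keep], 5), collapse = ", "))
  }
  z <- (m$values[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  omics_matrix(z, m$kind[keep])
}
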