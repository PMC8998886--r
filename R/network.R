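#' Metabolite-hub network container
#'
#' A strictly bipartite set of metabolite-transcript edges, each carrying the
#' full-data Pearson correlation `r`, its p-value `p`, the bootstrap
#' likelihood `likelihood` (fraction of supporting bootstraps, floored at
#' 1/B), and `dpi_survivor` (whether the edge survived full-data DPI).
#' Metabolite-metabolite correlations are used transiently during DPI and
#' are never stored as edges.
#'
#' @param edges data.frame with columns `metabolite`, `transcript`, `r`,
#'   `p`, `likelihood`, `dpi_survivor`.
#' @param meta list of inference metadata: `p_threshold`, `n_bootstraps`,
#'   `n_samples`, `seed`, `source`.
#' @return an object of class `metab_network`.
#' @export
metab_network <- function(edges, meta = list()) {
  req <- c("metabolite", "transcript", "r", "p", "likelihood", "dpi_survivor")
  miss <- setdiff(req, names(edges))
  if (length(miss)) {
    stop("edge table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  edges <- as.data.frame(edges)[req]
  if (nrow(edges)) {
    if (any(edges$r < -1 | edges$r > 1)) {
      stop("edge r outside [-1, 1]", call. = FALSE)
    }
    if (any(edges$r == 0)) stop("edge with r = 0 is not allowed", call. = FALSE)
    if (any(edges$p < 0 | edges$p > 1)) {
      stop("edge p outside [0, 1]", call. = FALSE)
    }
    if (any(edges$likelihood <= 0 | edges$likelihood > 1)) {
      stop("edge likelihood outside (0, 1]", call. = FALSE)
    }
    key <- paste(edges$metabolite, edges$transcript, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate (metabolite, transcript) edge", call. = FALSE)
    }
  }
  structure(list(edges = edges, meta = meta), class = "metab_network")
}

#' @export
print.metab_network <- function(x, ...) {
  cat(sprintf("metab_network: %d edges, %d metabolite hubs, %d transcripts\n",
              nrow(x$edges), length(unique(x$edges$metabolite)),
              length(unique(x$edges$transcript))))
  if (!is.null(x$meta$p_threshold)) {
    cat(sprintf("  p_threshold = %g, bootstraps = %s, n_samples = %s\n",
                x$meta$p_threshold,
                as.character(x$meta$n_bootstraps %||% NA),
                as.character(x$meta$n_samples %||% NA)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a network to a TSV edge table plus JSON metadata sidecar
#'
#' Six tab-separated columns (metabolite, transcript, r, p, likelihood,
#' dpi_survivor); numeric fields are serialized with 17 significant digits
#' so a round trip is value-exact. Metadata goes to `<path>.json`.
#'
#' @param net a [metab_network].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "metab_network"))
  e <- net$edges
  out <- data.frame(
    metabolite = e$metabolite,
    transcript = e$transcript,
    r = sprintf("%.17g", e$r),
    p = sprintf("%.17g", e$p),
    likelihood = sprintf("%.17g", e$likelihood),
    dpi_survivor = ifelse(e$dpi_survivor, "TRUE", "FALSE"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(net$meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a network edge table written by [write_network()]
#'
#' @param path TSV path; a `<path>.json` sidecar is read if present.
#' @return a [metab_network].
#' @export
read_network <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  req <- c("metabolite", "transcript", "r", "p", "likelihood", "dpi_survivor")
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    stop("malformed edge file ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  edges <- data.frame(
    metabolite = tab$metabolite,
    transcript = tab$transcript,
    r = as.numeric(tab$r),
    p = as.numeric(tab$p),
    likelihood = as.numeric(tab$likelihood),
    dpi_survivor = tab$dpi_survivor == "TRUE",
    stringsAsFactors = FALSE
  )
  if (nrow(edges) && any(is.na(edges$r) | is.na(edges$p) | is.na(edges$likelihood))) {
    stop("malformed edge file ", path, ": non-numeric r/p/likelihood",
         call. = FALSE)
  }
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  metab_network(edges, meta)
}
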