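#' Network inference configuration
#'
#' @param p_threshold raw p-value gate for candidate edges (default 0.001).
#' @param n_bootstraps number of bootstrap resamples B (default 100).
#' @param min_pairs minimum complete observations per pair (default 10).
#' @param seed RNG seed governing all bootstrap resamples.
#' @return a list of class `inference_config`.
#' @export
inference_config <- function(p_threshold = 0.001, n_bootstraps = 100,
                             min_pairs = 10, seed = NULL) {
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold >= 1) {
    stop("p_threshold must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(n_bootstraps) || n_bootstraps < 1) {
    stop("n_bootstraps must be >= 1", call. = FALSE)
  }
  if (!is.numeric(min_pairs) || min_pairs < 3) {
    stop("min_pairs must be >= 3", call. = FALSE)
  }
  structure(list(p_threshold = p_threshold,
                 n_bootstraps = as.integer(n_bootstraps),
                 min_pairs = as.integer(min_pairs),
                 seed = seed),
            class = "inference_config")
}

#' Scan all pairs for significant candidate edges
#'
#' Tests every metabolite-transcript pair (putative edges) and every
#' metabolite-metabolite pair (auxiliary correlations used only to form DPI
#' triplets) with [pearson_with_p()] semantics, retaining pairs with
#' p <= p_threshold and at least `min_pairs` complete observations.
#'
#' @param combined a combined [omics_matrix] (see [combine_matrices()]).
#' @param cfg an [inference_config].
#' @return a list of class `candidate_edges` with data.frames `mt`
#'   (metabolite, transcript, r, p, n_pairs) and `mm` (m1, m2, r, p,
#'   n_pairs).
#' @export
candidate_edges <- function(combined, cfg) {
  stopifnot(inherits(combined, "omics_matrix"),
            inherits(cfg, "inference_config"))
  M <- kind_values(combined, "metabolite")
  Tr <- kind_values(combined, "transcript")
  if (!nrow(M)) stop("combined matrix contains no metabolites", call. = FALSE)
  empty_mt <- data.frame(metabolite = character(), transcript = character(),
                         r = numeric(), p = numeric(), n_pairs = integer(),
                         stringsAsFactors = FALSE)
  empty_mm <- data.frame(m1 = character(), m2 = character(),
                         r = numeric(), p = numeric(), n_pairs = integer(),
                         stringsAsFactors = FALSE)
  if (!nrow(Tr)) {
    warning("combined matrix contains no transcripts; empty candidate set")
    return(structure(list(mt = empty_mt, mm = empty_mm, cfg = cfg),
                     class = "candidate_edges"))
  }
  sel <- function(pc, thr, minp) {
    which(!is.na(pc$p) & pc$p <= thr & pc$n >= minp, arr.ind = TRUE)
  }

  mt_pc <- pair_cor(M, Tr)
  idx <- sel(mt_pc, cfg$p_threshold, cfg$min_pairs)
  mt <- if (nrow(idx)) {
    data.frame(metabolite = rownames(M)[idx[, 1]],
               transcript = rownames(Tr)[idx[, 2]],
               r = mt_pc$r[idx], p = mt_pc$p[idx],
               n_pairs = as.integer(mt_pc$n[idx]),
               stringsAsFactors = FALSE)
  } else empty_mt

  mm <- empty_mm
  if (nrow(M) >= 2L) {
    mm_pc <- pair_cor(M, M)
    idx <- sel(mm_pc, cfg$p_threshold, cfg$min_pairs)
    if (nrow(idx)) {
      idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]  # upper triangle
    }
    if (nrow(idx)) {
      mm <- data.frame(m1 = rownames(M)[idx[, 1]],
                       m2 = rownames(M)[idx[, 2]],
                       r = mm_pc$r[idx], p = mm_pc$p[idx],
                       n_pairs = as.integer(mm_pc$n[idx]),
                       stringsAsFactors = FALSE)
    }
  }
  n_tested <- nrow(M) * nrow(Tr) + choose(nrow(M), 2)
  message(sprintf("candidate scan: %d pairs tested, %d m-t and %d m-m retained at p <= %g",
                  n_tested, nrow(mt), nrow(mm), cfg$p_threshold))
  if (!nrow(mt)) warning("no candidate metabolite-transcript edge survived the gate")
  structure(list(mt = mt, mm = mm, cfg = cfg), class = "candidate_edges")
}

# Core DPI rule: for every triplet (m1, m2, t) in which edges m1-t, m2-t and
# the auxiliary correlation m1-m2 are all present, flag the edge with the
# strictly lowest |r| among the three as removed IF it is a
# metabolite-transcript edge. Flags are computed against the original edge
# set in one pass (no cascading); ties keep all edges.
dpi_removed_flags <- function(mt, mm) {
  removed <- logical(nrow(mt))
  if (!nrow(mt) || !nrow(mm)) return(removed)
  absr <- abs(mt$r)
  by_met <- split(seq_len(nrow(mt)), mt$metabolite)
  for (i in seq_len(nrow(mm))) {
    e1 <- by_met[[mm$m1[i]]]
    e2 <- by_met[[mm$m2[i]]]
    if (is.null(e1) || is.null(e2)) next
    t1 <- mt$transcript[e1]
    common <- intersect(t1, mt$transcript[e2])
    if (!length(common)) next
    i1 <- e1[match(common, t1)]
    i2 <- e2[match(common, mt$transcript[e2])]
    r1 <- absr[i1]
    r2 <- absr[i2]
    raux <- abs(mm$r[i])
    removed[i1] <- removed[i1] | (r1 < r2 & r1 < raux)
    removed[i2] <- removed[i2] | (r2 < r1 & r2 < raux)
  }
  removed
}

#' Apply Data Processing Inequality pruning to a candidate edge set
#'
#' For every metabolite-metabolite-transcript triplet fully present among
#' the candidates, the metabolite-transcript edge with the strictly lowest
#' absolute correlation is flagged as a putative indirect association.
#' Exact ties keep all edges; flags do not cascade within one pass.
#'
#' @param cands a `candidate_edges` object.
#' @return the same object with a logical `dpi_survivor` column added to
#'   `$mt`.
#' @export
dpi_prune <- function(cands) {
  stopifnot(inherits(cands, "candidate_edges"))
  cands$mt$dpi_survivor <- !dpi_removed_flags(cands$mt, cands$mm)
  cands
}

#' Bootstrap support counts for candidate edges
#'
#' For each of B resamples of the sample set (with replacement, full size),
#' the candidate pairs — and only those — are re-tested: an edge is
#' supported in a bootstrap iff its within-bootstrap p <= p_threshold and it
#' survives DPI evaluated within that bootstrap. A pair that becomes
#' degenerate (constant) in a bootstrap counts as unsupported there.
#' Deterministic given `cfg$seed`.
#'
#' @param combined the combined [omics_matrix] the candidates came from.
#' @param cands a `candidate_edges` object.
#' @param cfg an [inference_config] with a seed.
#' @return integer vector of support counts k (0..B), one per row of
#'   `cands$mt`.
#' @export
bootstrap_likelihood <- function(combined, cands, cfg) {
  stopifnot(inherits(combined, "omics_matrix"),
            inherits(cands, "candidate_edges"),
            inherits(cfg, "inference_config"))
  mt <- cands$mt
  mm <- cands$mm
  if (!nrow(mt)) return(integer(0))
  mets <- unique(c(mt$metabolite, mm$m1, mm$m2))
  trs <- unique(mt$transcript)
  M <- combined$values[mets, , drop = FALSE]
  Tr <- combined$values[trs, , drop = FALSE]
  mt_i <- cbind(match(mt$metabolite, mets), match(mt$transcript, trs))
  mm_i <- cbind(match(mm$m1, mets), match(mm$m2, mets))
  k <- integer(nrow(mt))
  n <- ncol(combined$values)
  with_seed(cfg$seed, {
    for (b in seq_len(cfg$n_bootstraps)) {
      idx <- sample.int(n, n, replace = TRUE)
      pc_mt <- pair_cor(M[, idx, drop = FALSE], Tr[, idx, drop = FALSE])
      pass <- !is.na(pc_mt$p[mt_i]) & pc_mt$p[mt_i] <= cfg$p_threshold
      if (!any(pass)) next
      mm_b <- mm[0, ]
      if (nrow(mm)) {
        pc_mm <- pair_cor(M[, idx, drop = FALSE], M[, idx, drop = FALSE])
        mm_pass <- !is.na(pc_mm$p[mm_i]) & pc_mm$p[mm_i] <= cfg$p_threshold
        mm_b <- mm[mm_pass, , drop = FALSE]
        if (nrow(mm_b)) mm_b$r <- pc_mm$r[mm_i][mm_pass]
      }
      mt_b <- mt[pass, , drop = FALSE]
      mt_b$r <- pc_mt$r[mt_i][pass]
      surv <- !dpi_removed_flags(mt_b, mm_b)
      k[which(pass)[surv]] <- k[which(pass)[surv]] + 1L
    }
  })
  k
}

#' Infer a metabolite-transcript co-occurrence network
#'
#' The full pipeline: all-pairs correlation with a p-value gate, DPI pruning
#' of indirect triplet edges, and B bootstrap resamples scoring each edge's
#' likelihood. The final edge set consists of candidates that survive
#' full-data DPI or are supported by at least one bootstrap (recovery of
#' DPI-removed edges). Each edge carries its full-data r and p, the
#' likelihood k/B (floored at 1/B for a full-data survivor with zero
#' bootstrap support, so every stored edge has positive enrichment weight),
#' and its DPI-survivor flag.
#'
#' @param combined a combined [omics_matrix].
#' @param cfg an [inference_config] with a seed.
#' @param source label recorded in the network metadata.
#' @return a [metab_network].
#' @export
infer_network <- function(combined, cfg, source = "dataset") {
  cands <- dpi_prune(candidate_edges(combined, cfg))
  mt <- cands$mt
  k <- bootstrap_likelihood(combined, cands, cfg)
  keep <- if (nrow(mt)) mt$dpi_survivor | k >= 1L else logical(0)
  lik <- k / cfg$n_bootstraps
  lik[k == 0L] <- 1 / cfg$n_bootstraps
  edges <- data.frame(
    metabolite = mt$metabolite[keep],
    transcript = mt$transcript[keep],
    r = mt$r[keep],
    p = mt$p[keep],
    likelihood = lik[keep],
    dpi_survivor = mt$dpi_survivor[keep],
    stringsAsFactors = FALSE
  )
  n_removed <- sum(!mt$dpi_survivor)
  n_recovered <- sum(!mt$dpi_survivor & k >= 1L)
  message(sprintf(
    "network: %d candidates, %d DPI-flagged, %d recovered by bootstrap, %d final edges",
    nrow(mt), n_removed, n_recovered, nrow(edges)))
  metab_network(edges, meta = list(
    p_threshold = cfg$p_threshold,
    n_bootstraps = cfg$n_bootstraps,
    min_pairs = cfg$min_pairs,
    n_samples = ncol(combined$values),
    seed = cfg$seed,
    source = source
  ))
}
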