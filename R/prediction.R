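#' Sample-by-sample expression signatures
#'
#' Scores each gene relative to the mean of the dataset: per-gene z-scores
#' across samples (sample sd, n - 1 divisor). Zero-variance genes are
#' dropped with a message. One signature column per sample.
#'
#' @param expr a transcript [omics_matrix] with >= 3 samples.
#' @return a list of class `signature` with `scores` (genes x columns) and
#'   `mode = "sample"`.
#' @export
sample_signatures <- function(expr) {
  stopifnot(inherits(expr, "omics_matrix"))
  if (ncol(expr$values) < 3L) stop("need at least 3 samples", call. = FALSE)
  z <- zscore_rows(expr)
  structure(list(scores = z$values, mode = "sample"), class = "signature")
}

#' Two-group contrast signature (Welch t-statistics)
#'
#' Scores each gene in the intersection of the two groups' gene sets with
#' Welch's unequal-variance t-statistic (group1 minus group2). Welch is used
#' because across-dataset contrasts routinely have unequal group sizes and
#' variances. Genes with zero variance in both groups score 0 with a
#' warning.
#'
#' @param group1,group2 transcript [omics_matrix] objects with >= 2 samples
#'   each.
#' @return a list of class `signature` with a one-column `scores` matrix and
#'   `mode = "contrast"`.
#' @export
contrast_signature <- function(group1, group2) {
  stopifnot(inherits(group1, "omics_matrix"), inherits(group2, "omics_matrix"))
  if (ncol(group1$values) < 2L || ncol(group2$values) < 2L) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  genes <- intersect(feature_ids(group1), feature_ids(group2))
  if (!length(genes)) stop("empty gene intersection", call. = FALSE)
  x1 <- group1$values[genes, , drop = FALSE]
  x2 <- group2$values[genes, , drop = FALSE]
  n1 <- ncol(x1)
  n2 <- ncol(x2)
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- apply(x1, 1L, stats::var, na.rm = TRUE)
  v2 <- apply(x2, 1L, stats::var, na.rm = TRUE)
  se <- sqrt(v1 / n1 + v2 / n2)
  t_stat <- (m1 - m2) / se
  flat <- !is.na(se) & se == 0
  if (any(flat)) {
    warning(sum(flat), " gene(s) with zero variance in both groups scored 0")
    t_stat[flat] <- 0
  }
  scores <- matrix(t_stat, ncol = 1, dimnames = list(genes, "contrast"))
  structure(list(scores = scores, mode = "contrast"), class = "signature")
}

# Normal-quantile rank transform of one signature column:
# q_g = qnorm(rank_g / (G + 1)), average ranks for ties, G = all genes.
rank_quantiles <- function(scores) {
  stats::qnorm(rank(scores, ties.method = "average") / (length(scores) + 1))
}

#' Normalized Enrichment Score of one metabolite against one signature
#'
#' Analytic rank-based enrichment: all signature scores are rank-transformed
#' to normal quantiles; each target gene g contributes with weight
#' w_g = r_g * likelihood_g (signed correlation times bootstrap likelihood);
#' NES = sum(w * q) / sqrt(sum(w^2)), so a random signature yields a
#' standard-normal score; two-sided p = 2 * pnorm(-|NES|).
#'
#' @param scores named numeric vector: the signature column over all genes.
#' @param targets data.frame with columns `transcript`, `r`, `likelihood`
#'   (the metabolite's network neighborhood, gene ids already matched to the
#'   signature's).
#' @return list with `nes` and `p`, or `ok = FALSE` when no target is
#'   present in the signature.
#' @export
nes_score <- function(scores, targets) {
  q <- rank_quantiles(scores)
  names(q) <- names(scores)
  hit <- targets$transcript %in% names(scores)
  if (!any(hit)) return(list(nes = NA_real_, p = NA_real_, ok = FALSE))
  w <- targets$r[hit] * targets$likelihood[hit]
  nes <- sum(w * q[targets$transcript[hit]]) / sqrt(sum(w^2))
  list(nes = nes, p = 2 * stats::pnorm(-abs(nes)), ok = TRUE)
}

#' Predict metabolite abundances from expression data
#'
#' Applies a metabolite-transcript network to expression-only data. Gene ids
#' are matched to network transcripts with [harmonize_feature_names()].
#' Metabolites with fewer than `minsize` network targets measured in the
#' data are skipped with a recorded reason. Sample mode scores every sample
#' column against the dataset mean; contrast mode scores one Welch-t
#' signature between two sample groups and reports two-sided p and BH-FDR
#' per metabolite.
#'
#' @param net a [metab_network].
#' @param expr a transcript [omics_matrix].
#' @param mode "sample" or "contrast".
#' @param group1,group2 sample id vectors (contrast mode only).
#' @param minsize minimum number of network targets measured in `expr`
#'   (default 10, boundary inclusive).
#' @return a list of class `prediction_result`: `nes` (metabolites x samples
#'   matrix in sample mode; named vector in contrast mode), `p` and `fdr`
#'   (contrast mode), `skipped` (named character reasons), `mode`.
#' @export
predict_metabolites <- function(net, expr, mode = c("sample", "contrast"),
                                group1 = NULL, group2 = NULL, minsize = 10) {
  stopifnot(inherits(net, "metab_network"), inherits(expr, "omics_matrix"))
  mode <- match.arg(mode)
  edges <- net$edges
  if (!nrow(edges)) stop("network has no edges", call. = FALSE)

  hm <- harmonize_feature_names(unique(edges$transcript), feature_ids(expr))
  gene_map <- stats::setNames(hm$matched$b, hm$matched$a)
  edges$gene <- unname(gene_map[edges$transcript])

  sig <- if (mode == "sample") {
    sample_signatures(expr)
  } else {
    if (is.null(group1) || is.null(group2)) {
      stop("contrast mode requires group1 and group2 sample ids", call. = FALSE)
    }
    contrast_signature(subset_samples(expr, group1),
                       subset_samples(expr, group2))
  }

  mets <- unique(edges$metabolite)
  by_met <- split(edges, edges$metabolite)
  skipped <- character(0)
  usable <- list()
  for (m in mets) {
    tg <- by_met[[m]]
    measured <- !is.na(tg$gene)
    if (sum(measured) < minsize) {
      skipped[m] <- sprintf("targets_measured (%d) < minsize (%d)",
                            sum(measured), minsize)
      next
    }
    tg <- tg[measured, , drop = FALSE]
    tg <- tg[tg$gene %in% rownames(sig$scores), , drop = FALSE]
    if (!nrow(tg)) {
      skipped[m] <- "no target with usable signature score"
      next
    }
    usable[[m]] <- tg
  }
  if (!length(usable)) {
    stop(sprintf(
      paste0("no metabolite predictable: %d network transcripts, %d matched ",
             "to data genes, minsize = %d (%d metabolites skipped)"),
      length(unique(edges$transcript)), nrow(hm$matched), minsize,
      length(skipped)), call. = FALSE)
  }

  # Rank-transform each signature column once, then aggregate per metabolite.
  qmat <- apply(sig$scores, 2L, rank_quantiles)
  if (is.null(dim(qmat))) qmat <- matrix(qmat, ncol = 1)
  rownames(qmat) <- rownames(sig$scores)
  nes <- matrix(NA_real_, nrow = length(usable), ncol = ncol(qmat),
                dimnames = list(names(usable), colnames(sig$scores)))
  for (m in names(usable)) {
    tg <- usable[[m]]
    w <- tg$r * tg$likelihood
    nes[m, ] <- colSums(w * qmat[tg$gene, , drop = FALSE]) / sqrt(sum(w^2))
  }
  message(sprintf("predicted %d metabolites (%d skipped) in %s mode",
                  nrow(nes), length(skipped), mode))
  if (mode == "contrast") {
    v <- nes[, 1]
    p <- 2 * stats::pnorm(-abs(v))
    structure(list(nes = v, p = p, fdr = bh_adjust(p),
                   skipped = skipped, mode = mode),
              class = "prediction_result")
  } else {
    structure(list(nes = nes, p = NULL, fdr = NULL,
                   skipped = skipped, mode = mode),
              class = "prediction_result")
  }
}

#' @export
print.prediction_result <- function(x, ...) {
  if (x$mode == "sample") {
    cat(sprintf("prediction_result (sample mode): %d metabolites x %d samples, %d skipped\n",
                nrow(x$nes), ncol(x$nes), length(x$skipped)))
  } else {
    cat(sprintf("prediction_result (contrast mode): %d metabolites, %d skipped\n",
                length(x$nes), length(x$skipped)))
  }
  invisible(x)
}
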