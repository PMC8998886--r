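#' Score predicted against measured metabolite levels
#'
#' For every metabolite shared between a sample-mode prediction and a
#' measured metabolite matrix (names matched with
#' [harmonize_feature_names()]), computes the Pearson correlation between
#' predicted NES and measured values across shared samples, a two-sided p,
#' BH-FDR across metabolites, and a class at alpha = 0.05:
#' positive-significant / negative-significant / non-significant.
#' Significance classes use BH-adjusted p by default; a nominal-p class
#' column is reported alongside since figure-level conventions differ.
#' Metabolites with fewer than 3 shared samples are skipped.
#'
#' @param pred a sample-mode `prediction_result`.
#' @param measured a metabolite [omics_matrix].
#' @param alpha significance level for class assignment (default 0.05).
#' @return a list of class `eval_report`: `table` (per-metabolite r, p, fdr,
#'   n_samples, class, class_nominal), `summary` (mean_r, wilcoxon_p, class
#'   counts, n_evaluated).
#' @export
per_metabolite_correlation <- function(pred, measured, alpha = 0.05) {
  stopifnot(inherits(pred, "prediction_result"),
            inherits(measured, "omics_matrix"))
  if (pred$mode != "sample") stop("sample-mode prediction required", call. = FALSE)
  hm <- harmonize_feature_names(rownames(pred$nes), feature_ids(measured))
  if (!nrow(hm$matched)) {
    stop(sprintf(
      "no shared metabolite: %d predicted vs %d measured ids, 0 matched (unmatched examples: %s | %s)",
      nrow(pred$nes), nrow(measured$values),
      paste(utils::head(hm$unmatched_a, 3), collapse = ","),
      paste(utils::head(hm$unmatched_b, 3), collapse = ",")), call. = FALSE)
  }
  shared_s <- intersect(colnames(pred$nes), sample_ids(measured))
  if (length(shared_s) < 3L) stop("fewer than 3 shared samples", call. = FALSE)

  rows <- lapply(seq_len(nrow(hm$matched)), function(i) {
    a <- hm$matched$a[i]
    b <- hm$matched$b[i]
    pw <- pearson_with_p(pred$nes[a, shared_s], measured$values[b, shared_s])
    if (!pw$ok) return(NULL)
    data.frame(metabolite = a, r = pw$r, p = pw$p,
               n_samples = pw$n_pairs, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab)) {
    stop("no metabolite with enough shared, non-degenerate samples", call. = FALSE)
  }
  tab$fdr <- bh_adjust(tab$p)
  classify <- function(p) ifelse(p >= alpha, "non-significant",
                          ifelse(tab$r > 0, "positive-significant",
                                 "negative-significant"))
  tab$class <- classify(tab$fdr)
  tab$class_nominal <- classify(tab$p)
  summary <- list(
    mean_r = mean(tab$r),
    wilcoxon_p = wilcoxon_one_tail_greater(tab$r),
    n_evaluated = nrow(tab),
    n_positive_significant = sum(tab$class == "positive-significant"),
    n_negative_significant = sum(tab$class == "negative-significant"),
    n_non_significant = sum(tab$class == "non-significant")
  )
  structure(list(table = tab, summary = summary), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %d metabolites, mean r = %.3f, one-tail Wilcoxon p = %.3g\n",
              x$summary$n_evaluated, x$summary$mean_r, x$summary$wilcoxon_p))
  cat(sprintf("  %d positive-significant, %d negative-significant, %d non-significant (BH)\n",
              x$summary$n_positive_significant,
              x$summary$n_negative_significant,
              x$summary$n_non_significant))
  invisible(x)
}

#' Repeated split-half prediction within one dataset
#'
#' For each split: a random 50/50 sample partition (floor(n/2) training), a
#' network inferred on the training half, sample-mode prediction on the test
#' half, and per-metabolite Pearson correlation between predicted and
#' measured values. Optionally repeats each prediction with a
#' degree-proportional shuffled copy of the training network to build the
#' null distribution. Deterministic given `seed`: every inner stage draws
#' its sub-seed from one seeded stream.
#'
#' @param combined a combined [omics_matrix] with >= 20 samples.
#' @param n_splits number of random partitions (>= 1).
#' @param cfg an [inference_config] for the inner networks.
#' @param seed seed for the split/bootstrap/shuffle stream.
#' @param minsize prediction minsize gate.
#' @param shuffle_null also evaluate shuffled networks (default FALSE).
#' @return list of class `split_half_result`: `r` (n_splits x metabolites
#'   matrix of correlations, NA when skipped), `mean_r` (per metabolite,
#'   over non-NA splits), `shuffled_r` (same shape, if requested),
#'   `n_splits`.
#' @export
split_half_evaluate <- function(combined, n_splits, cfg, seed,
                                minsize = 10, shuffle_null = FALSE) {
  stopifnot(inherits(combined, "omics_matrix"),
            inherits(cfg, "inference_config"))
  n <- ncol(combined$values)
  if (n < 20L) stop("need at least 20 samples for split-half evaluation",
                    call. = FALSE)
  if (n_splits < 1L) stop("n_splits must be >= 1", call. = FALSE)
  mets <- feature_ids(combined)[combined$kind == "metabolite"]
  rmat <- matrix(NA_real_, n_splits, length(mets),
                 dimnames = list(NULL, mets))
  smat <- if (shuffle_null) rmat else NULL

  split_r <- function(net, test_expr, test_metab) {
    out <- rep(NA_real_, length(mets))
    names(out) <- mets
    pred <- suppressMessages(
      predict_metabolites(net, test_expr, mode = "sample", minsize = minsize))
    for (m in intersect(rownames(pred$nes), mets)) {
      pw <- pearson_with_p(pred$nes[m, ], test_metab$values[m, colnames(pred$nes)])
      if (pw$ok) out[m] <- pw$r
    }
    out
  }

  with_seed(seed, {
    for (s in seq_len(n_splits)) {
      train <- sample.int(n, floor(n / 2))
      cfg_s <- cfg
      cfg_s$seed <- draw_seed()
      shuffle_seed <- draw_seed()
      net <- suppressMessages(
        infer_network(subset_samples(combined, train), cfg_s,
                      source = sprintf("split_%d", s)))
      test <- subset_samples(combined, setdiff(seq_len(n), train))
      test_expr <- omics_matrix(kind_values(test, "transcript"), "transcript")
      test_metab <- omics_matrix(kind_values(test, "metabolite"), "metabolite")
      if (!nrow(net$edges)) next
      rmat[s, ] <- split_r(net, test_expr, test_metab)
      if (shuffle_null) {
        net0 <- suppressWarnings(shuffle_network(net, seed = shuffle_seed))
        smat[s, ] <- split_r(net0, test_expr, test_metab)
      }
    }
  })
  structure(list(
    r = rmat,
    mean_r = colMeans(rmat, na.rm = TRUE),
    shuffled_r = smat,
    n_splits = n_splits
  ), class = "split_half_result")
}

#' Degree-proportional shuffled-network null
#'
#' Relabels each edge's transcript endpoint with a draw from the multiset of
#' transcript endpoints (probability proportional to node degree, with
#' replacement), preserving per-metabolite edge counts, correlations,
#' likelihoods, and DPI flags while destroying biological edge identity.
#' Duplicate (metabolite, transcript) collisions are redrawn up to 100
#' times, then dropped with a warning. Deterministic given `seed`.
#'
#' @param net a non-empty [metab_network].
#' @param seed RNG seed.
#' @return a shuffled [metab_network].
#' @export
shuffle_network <- function(net, seed) {
  stopifnot(inherits(net, "metab_network"))
  e <- net$edges
  if (!nrow(e)) stop("network is empty", call. = FALSE)
  pool <- e$transcript  # multiset: each endpoint once per edge => degree-proportional
  if (length(unique(pool)) < 2L) {
    warning("single-transcript network; returned unchanged")
    return(net)
  }
  with_seed(seed, {
    lab <- sample(pool, length(pool), replace = TRUE)
    key <- function(l) paste(e$metabolite, l, sep = "\r")
    for (attempt in seq_len(100L)) {
      dup <- duplicated(key(lab))
      if (!any(dup)) break
      lab[dup] <- sample(pool, sum(dup), replace = TRUE)
    }
    dup <- duplicated(key(lab))
    if (any(dup)) {
      warning("dropping ", sum(dup), " unresolved duplicate edge(s) after shuffling")
    }
    e$transcript <- lab
    e <- e[!dup, , drop = FALSE]
  })
  meta <- net$meta
  meta$shuffled <- TRUE
  meta$shuffle_seed <- seed
  metab_network(e, meta)
}
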