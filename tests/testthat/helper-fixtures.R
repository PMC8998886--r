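# Shared fixture builders and independent oracles.

# Build an omics_matrix from a plain matrix, inventing ids as needed.
make_om <- function(values, kind = "transcript", ids = NULL, samples = NULL) {
  if (is.null(ids)) ids <- sprintf("%s%02d", substr(kind, 1, 1), seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(ids, samples)
  omics_matrix(values, kind)
}

# Hand-rolled network for prediction tests.
make_net <- function(metabolite, transcript, r, likelihood = 1,
                     dpi_survivor = TRUE, p = 1e-6) {
  metab_network(data.frame(
    metabolite = metabolite, transcript = transcript, r = r, p = p,
    likelihood = likelihood, dpi_survivor = dpi_survivor,
    stringsAsFactors = FALSE
  ), meta = list(p_threshold = 0.001, n_bootstraps = 100))
}

# Brute-force DPI oracle: enumerate every (m1, m2, t) triplet explicitly.
brute_dpi <- function(mt, mm) {
  removed <- logical(nrow(mt))
  if (!nrow(mt) || !nrow(mm)) return(removed)
  for (i in seq_len(nrow(mm))) {
    for (t in unique(mt$transcript)) {
      i1 <- which(mt$metabolite == mm$m1[i] & mt$transcript == t)
      i2 <- which(mt$metabolite == mm$m2[i] & mt$transcript == t)
      if (length(i1) != 1L || length(i2) != 1L) next
      v <- c(abs(mt$r[i1]), abs(mt$r[i2]), abs(mm$r[i]))
      if (v[1] < v[2] && v[1] < v[3]) removed[i1] <- TRUE
      if (v[2] < v[1] && v[2] < v[3]) removed[i2] <- TRUE
    }
  }
  removed
}

# Random candidate-set instance for DPI property tests.
random_dpi_instance <- function(max_metab = 10, max_transcripts = 50) {
  n_m <- sample(2:max_metab, 1)
  n_t <- sample(2:max_transcripts, 1)
  mets <- sprintf("m%02d", seq_len(n_m))
  trs <- sprintf("t%02d", seq_len(n_t))
  all_mt <- expand.grid(metabolite = mets, transcript = trs,
                        stringsAsFactors = FALSE)
  keep <- sample(nrow(all_mt), max(1, rbinom(1, nrow(all_mt), 0.3)))
  mt <- all_mt[keep, , drop = FALSE]
  mt$r <- runif(nrow(mt), -1, 1)
  mt$r[mt$r == 0] <- 0.5
  pairs <- t(combn(mets, 2))
  keep <- sample(nrow(pairs), max(1, rbinom(1, nrow(pairs), 0.5)))
  mm <- data.frame(m1 = pairs[keep, 1], m2 = pairs[keep, 2],
                   r = runif(length(keep), -1, 1), stringsAsFactors = FALSE)
  list(mt = mt, mm = mm)
}

# Exact signed-rank oracle: enumerate all 2^n sign assignments and compute
# P(W >= w_obs) for the one-tailed greater alternative.
brute_wilcoxon_greater <- function(values) {
  v <- values[values != 0]
  n <- length(v)
  rk <- rank(abs(v))
  w_obs <- sum(rk[v > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% rk)
  mean(w_all >= w_obs)
}

# Step-up BH oracle, written from the definition.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Wrap a bare NES matrix as a sample-mode prediction result.
fake_prediction <- function(nes) {
  structure(list(nes = nes, p = NULL, fdr = NULL, skipped = character(0),
                 mode = "sample"),
            class = "prediction_result")
}

# Standard simulated study: ground truth plus one training dataset.
sim_study <- function(seed, n_samples = 300, ...) {
  gt <- build_ground_truth(..., seed = seed)
  sim <- simulate_dataset(gt, n_samples, seed = seed + 1000L)
  combined <- suppressMessages(combine_matrices(sim$metabolites, sim$transcripts))
  list(gt = gt, sim = sim, combined = combined)
}
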