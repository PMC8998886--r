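test_that("configuration bounds are enforced", {
  expect_error(inference_config(n_bootstraps = 0, seed = 1), "n_bootstraps")
  expect_error(inference_config(p_threshold = 0, seed = 1), "p_threshold")
  expect_error(inference_config(p_threshold = 1, seed = 1), "p_threshold")
  expect_error(inference_config(min_pairs = 2, seed = 1), "min_pairs")
})

test_that("candidate scan retains planted pairs and gates noise at the threshold", {
  study <- sim_study(401, n_samples = 200, n_metab = 2,
                     targets_per_metab = 3, beta_range = c(1.2, 1.2),
                     n_background = 0)
  cfg <- inference_config(seed = 402)
  cands <- suppressMessages(candidate_edges(study$combined, cfg))
  planted <- paste(study$gt$targets$metabolite, study$gt$targets$transcript)
  found <- paste(cands$mt$metabolite, cands$mt$transcript)
  expect_true(all(planted %in% found))

  # one metabolite against 5000 independent transcripts: the fraction
  # retained should sit near the raw 0.001 gate (binomial noise around 5)
  set.seed(403)
  m <- make_om(matrix(rnorm(200), 1, 200), "metabolite", ids = "met01")
  tr <- make_om(matrix(rnorm(5000 * 200), 5000, 200), "transcript")
  comb <- suppressMessages(combine_matrices(m, tr))
  cands <- suppressMessages(candidate_edges(comb, cfg))
  expect_lte(nrow(cands$mt), qbinom(0.99995, 5000, 0.001))

  # zero transcripts -> empty set with a warning
  expect_warning(
    candidate_edges(make_om(matrix(rnorm(40), 2, 20), "metabolite"),
                    cfg) |> suppressMessages(),
    "no transcripts")
})

test_that("bootstrap support is maximal for a near-collinear pair", {
  set.seed(404)
  n <- 50
  a <- rnorm(n)
  m <- make_om(matrix(a + 0.2 * rnorm(n), 1, n), "metabolite", ids = "met01")
  tr <- make_om(matrix(c(a + 0.2 * rnorm(n), rnorm(n)), 2, n,
                       byrow = TRUE), "transcript")
  comb <- suppressMessages(combine_matrices(m, tr))
  cfg <- inference_config(n_bootstraps = 20, seed = 405)
  cands <- dpi_prune(suppressMessages(candidate_edges(comb, cfg)))
  k <- bootstrap_likelihood(comb, cands, cfg)
  strong <- which(cands$mt$transcript == "t01")
  expect_equal(k[strong], 20L)
})

test_that("final edges compose full-data DPI with bootstrap recovery and the 1/B floor", {
  study <- sim_study(406, n_samples = 150, n_metab = 8,
                     targets_per_metab = 6, coupling = 0.7,
                     n_background = 30)
  cfg <- inference_config(n_bootstraps = 10, seed = 407)
  cands <- dpi_prune(suppressMessages(candidate_edges(study$combined, cfg)))
  k <- bootstrap_likelihood(study$combined, cands, cfg)
  net <- suppressMessages(infer_network(study$combined, cfg))

  key_c <- paste(cands$mt$metabolite, cands$mt$transcript)
  key_n <- paste(net$edges$metabolite, net$edges$transcript)
  keep <- cands$mt$dpi_survivor | k >= 1L
  expect_setequal(key_n, key_c[keep])
  idx <- match(key_n, key_c)
  expect_equal(net$edges$likelihood, pmax(k[idx], 1L) / cfg$n_bootstraps)
  expect_equal(net$edges$dpi_survivor, cands$mt$dpi_survivor[idx])
  expect_equal(net$edges$r, cands$mt$r[idx])
  # recovered edges: DPI-flagged in the full data but bootstrap-supported
  recovered <- !net$edges$dpi_survivor
  if (any(recovered)) {
    expect_true(all(net$edges$likelihood[recovered] >= 1 / cfg$n_bootstraps))
    expect_true(all(k[idx][recovered] >= 1L))
  }
  expect_true(all(net$edges$likelihood * cfg$n_bootstraps >= 1))
})

test_that("inference is bit-identical across reruns with one seed", {
  study <- sim_study(408, n_samples = 80, n_metab = 4,
                     targets_per_metab = 4, n_background = 20)
  cfg <- inference_config(n_bootstraps = 8, seed = 409)
  n1 <- suppressMessages(infer_network(study$combined, cfg))
  n2 <- suppressMessages(infer_network(study$combined, cfg))
  expect_identical(n1, n2)
})

test_that("inference is invariant to sample and transcript permutation", {
  study <- sim_study(410, n_samples = 80, n_metab = 4,
                     targets_per_metab = 4, n_background = 20)
  cfg <- inference_config(n_bootstraps = 5, seed = 411)
  base <- suppressMessages(infer_network(study$combined, cfg))

  set.seed(412)
  v <- study$combined$values
  k <- study$combined$kind
  perm_s <- sample(ncol(v))
  tr_rows <- which(k == "transcript")
  perm_t <- c(which(k == "metabolite"), sample(tr_rows))
  comb2 <- omics_matrix(v[perm_t, perm_s], k[perm_t])
  net2 <- suppressMessages(infer_network(comb2, cfg))

  ord <- function(e) e[order(e$metabolite, e$transcript),
                       c("metabolite", "transcript", "r", "p", "dpi_survivor")]
  e1 <- ord(base$edges)
  e2 <- ord(net2$edges)
  rownames(e1) <- rownames(e2) <- NULL
  # full-data r, p and DPI flags are permutation-invariant; bootstrap
  # likelihoods are not (resampling addresses columns by position)
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("pure-noise data yields roughly gate-rate edges with low likelihoods", {
  set.seed(413)
  m <- make_om(matrix(rnorm(10 * 150), 10, 150), "metabolite")
  tr <- make_om(matrix(rnorm(300 * 150), 300, 150), "transcript")
  comb <- suppressMessages(combine_matrices(m, tr))
  cfg <- inference_config(n_bootstraps = 10, seed = 414)
  net <- suppressMessages(infer_network(comb, cfg))
  # 3000 m-t pairs at a raw 0.001 gate: a handful of spurious edges
  expect_lte(nrow(net$edges), qbinom(0.9999, 3000, 0.001) + 5)
})
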