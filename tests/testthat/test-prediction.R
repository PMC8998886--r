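test_that("sample signatures are per-gene z-scores against the dataset mean", {
  expr <- make_om(rbind(c(1, 2, 3), c(4, 4, 4), c(10, 20, 30)), "transcript")
  sig <- suppressMessages(sample_signatures(expr))
  expect_equal(rownames(sig$scores), c("t01", "t03"))  # constant gene dropped
  expect_equal(unname(sig$scores[1, ]), c(-1, 0, 1))
  expect_true(all(abs(rowSums(sig$scores)) < 1e-10))
  expect_error(sample_signatures(make_om(matrix(1:4, 2, 2), "transcript")),
               "3 samples")
})

test_that("contrast signatures are Welch t-statistics over the gene intersection", {
  g <- matrix(c(3, 4, 5, 0, 1, 2), 1)
  g1 <- make_om(matrix(c(3, 4, 5), 1), "transcript", ids = "g")
  g2 <- make_om(matrix(c(0, 1, 2), 1), "transcript", ids = "g")
  sig <- contrast_signature(g1, g2)
  expect_gt(sig$scores["g", 1], 0)

  # identical groups -> all scores 0
  sig <- contrast_signature(g1, g1)
  expect_equal(unname(sig$scores[, 1]), 0)

  # hand-evaluated Welch t: g1 = (2.0, 2.2), g2 = (1.0, 1.1)
  g1 <- make_om(matrix(c(2.0, 2.2), 1), "transcript", ids = "g")
  g2 <- make_om(matrix(c(1.0, 1.1), 1), "transcript", ids = "g")
  sig <- contrast_signature(g1, g2)
  welch <- (2.1 - 1.05) / sqrt(0.02 / 2 + 0.005 / 2)
  expect_equal(unname(sig$scores[, 1]), welch, tolerance = 1e-12)
  expect_equal(unname(sig$scores[, 1]),
               unname(t.test(c(2.0, 2.2), c(1.0, 1.1))$statistic),
               tolerance = 1e-12)

  # zero variance in both groups -> 0 with warning
  flat1 <- make_om(matrix(c(5, 5, 2, 3), 2, byrow = TRUE), "transcript",
                   ids = c("flat", "ok"))
  flat2 <- make_om(matrix(c(5, 5, 0, 1), 2, byrow = TRUE), "transcript",
                   ids = c("flat", "ok"))
  expect_warning(sig <- contrast_signature(flat1, flat2), "zero variance")
  expect_equal(unname(sig$scores["flat", 1]), 0)

  expect_error(contrast_signature(
    g1, make_om(matrix(1:4, 1), "transcript", ids = "other")),
    "intersection")
})

test_that("NES follows the documented rank-quantile formula", {
  G <- 19
  scores <- setNames(seq_len(G), paste0("g", seq_len(G)))
  # single target with r = 1, likelihood = 1: NES equals the target's normal
  # quantile q = qnorm(rank / (G + 1))
  out <- nes_score(scores, data.frame(transcript = "g15", r = 1, likelihood = 1))
  expect_equal(out$nes, qnorm(15 / 20))
  expect_equal(out$p, 2 * pnorm(-abs(out$nes)))

  # two targets with equal weights at symmetric quantiles -> NES = 0
  out <- nes_score(scores, data.frame(transcript = c("g5", "g15"),
                                      r = c(1, 1), likelihood = c(1, 1)))
  expect_equal(out$nes, 0, tolerance = 1e-12)

  # all targets absent -> not computable
  out <- nes_score(scores, data.frame(transcript = "nope", r = 1, likelihood = 1))
  expect_false(out$ok)
})

test_that("NES invariances: weight rescaling, negation, target order", {
  set.seed(500)
  scores <- setNames(rnorm(100), paste0("g", 1:100))
  targets <- data.frame(transcript = paste0("g", sample(100, 12)),
                        r = runif(12, -1, 1), likelihood = runif(12))
  base <- nes_score(scores, targets)

  scaled <- targets
  scaled$likelihood <- scaled$likelihood * 3.7
  expect_equal(nes_score(scores, scaled)$nes, base$nes, tolerance = 1e-12)

  expect_equal(nes_score(-scores, targets)$nes, -base$nes, tolerance = 1e-12)

  perm <- targets[sample(nrow(targets)), ]
  expect_equal(nes_score(scores, perm)$nes, base$nes, tolerance = 1e-12)
})

test_that("NES is null-calibrated against random signatures", {
  set.seed(501)
  G <- 300
  targets <- data.frame(transcript = paste0("g", sample(G, 15)),
                        r = runif(15, -1, 1), likelihood = runif(15))
  nes <- vapply(seq_len(2000), function(i) {
    s <- setNames(rnorm(G), paste0("g", seq_len(G)))
    nes_score(s, targets)$nes
  }, numeric(1))
  expect_lt(abs(mean(nes)), 0.08)  # se of the mean ~ 0.022
  expect_gt(sd(nes), 0.9)
  expect_lt(sd(nes), 1.1)
})

test_that("minsize gate is boundary-inclusive and records skip reasons", {
  set.seed(502)
  targets <- paste0("g", 1:12)
  net <- make_net(rep("met01", 12), targets, r = runif(12, 0.3, 0.8))
  expr9 <- make_om(matrix(rnorm(9 * 20), 9, 20), "transcript",
                   ids = targets[1:9])
  expect_error(
    suppressMessages(predict_metabolites(net, expr9, mode = "sample")),
    "no metabolite predictable")

  # met01 has 12 targets of which only 9 are measured; met02 has 10 targets,
  # all measured -> the inclusive boundary admits met02 and skips met01
  two_mets <- make_net(
    c(rep("met01", 12), rep("met02", 10)),
    c(targets[1:9], paste0("x", 1:3), targets[1:10]),
    r = runif(22, 0.3, 0.8))
  expr10 <- make_om(matrix(rnorm(10 * 20), 10, 20), "transcript",
                    ids = targets[1:10])
  pred <- suppressMessages(predict_metabolites(two_mets, expr10, mode = "sample"))
  expect_equal(rownames(pred$nes), "met02")
  expect_match(pred$skipped[["met01"]], "targets_measured \\(9\\) < minsize \\(10\\)")
  expect_true(all(is.finite(pred$nes)))
})

test_that("per-sample NES tracks the true latent metabolite level", {
  study <- sim_study(503, n_samples = 300)
  cfg <- inference_config(n_bootstraps = 10, seed = 504)
  net <- suppressMessages(infer_network(study$combined, cfg))
  held_out <- simulate_dataset(study$gt, 120, seed = 505)
  pred <- suppressMessages(predict_metabolites(net, held_out$transcripts,
                                               mode = "sample"))
  for (m in rownames(pred$nes)) {
    r <- cor(pred$nes[m, ], held_out$activities[m, colnames(pred$nes)])
    expect_gt(r, 0.5)
  }
})

test_that("contrast mode reports NES, p, and FDR per metabolite", {
  study <- sim_study(506, n_samples = 60, n_metab = 6,
                     targets_per_metab = 12, n_background = 40)
  cfg <- inference_config(n_bootstraps = 5, seed = 507)
  net <- suppressMessages(infer_network(study$combined, cfg))
  ds <- simulate_contrast(study$gt, affected = c("met01", "met02"),
                          shift = 2, n1 = 15, n2 = 15, seed = 508)
  pred <- suppressMessages(predict_metabolites(
    net, ds$transcripts, mode = "contrast",
    group1 = names(ds$groups)[ds$groups == "group1"],
    group2 = names(ds$groups)[ds$groups == "group2"]))
  expect_equal(length(pred$nes), length(pred$p))
  expect_true(all(pred$fdr >= pred$p - 1e-15))
  # group 2 was shifted up, so group1 - group2 contrast NES is negative for
  # the affected metabolites
  expect_lt(pred$nes[["met01"]], 0)
  expect_lt(pred$nes[["met02"]], 0)
  affected_rank <- rank(-abs(pred$nes))[c("met01", "met02")]
  expect_true(all(affected_rank <= 3))
})
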