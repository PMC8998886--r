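#' Run a configured experiment end to end
#'
#' Single programmatic entry point wiring the pipeline stages into the
#' standard experiments. The config is a named list (or a path to a YAML
#' file with the same fields). Required fields per experiment:
#'
#' * `simulate`: `seed`, `out_dir`; optional generator parameters
#'   (`n_metab`, `targets_per_metab`, `beta_range`, `coupling`,
#'   `n_background`, `sigma_m`, `prop_negative`, `n_samples`).
#' * `infer`: `metabolites`, `expression` (TSV paths), `seed`, `out_dir`;
#'   optional `p_threshold`, `bootstraps`, `min_pairs`.
#' * `predict`: `network`, `expression`, `out_dir`; `mode` ("sample" or
#'   "contrast"; contrast needs `group1`/`group2` sample-id files);
#'   optional `minsize`.
#' * `split`: `metabolites`, `expression`, `splits`, `seed`, `out_dir`;
#'   optional inner-network parameters and `shuffle_null`.
#' * `cross`: `network`, `metabolites`, `expression`, `out_dir`.
#' * `null`: as `split` with `shuffle_null = TRUE` forced.
#'
#' Every stochastic stage must carry an explicit seed; a missing seed is a
#' config error. All TSV outputs are accompanied by a machine-readable
#' `summary.json` with per-stage counts. Reruns with an identical config are
#' byte-identical.
#'
#' @param config named list or path to a YAML config file.
#' @return the summary list, invisibly.
#' @export
run_experiment <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path", call. = FALSE)
  exper <- config$experiment
  if (is.null(exper) ||
      !exper %in% c("simulate", "infer", "predict", "split", "cross", "null")) {
    stop("config$experiment must be one of simulate/infer/predict/split/cross/null",
         call. = FALSE)
  }
  need <- function(field) {
    if (is.null(config[[field]])) {
      stop(sprintf("config field '%s' is required for experiment '%s'",
                   field, exper), call. = FALSE)
    }
    config[[field]]
  }
  out_dir <- need("out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_net <- function() inference_config(
    p_threshold = config$p_threshold %||% 0.001,
    n_bootstraps = config$bootstraps %||% 100,
    min_pairs = config$min_pairs %||% 10,
    seed = need("seed"))

  summary <- list(experiment = exper)
  if (exper == "simulate") {
    seed <- need("seed")
    gt <- build_ground_truth(
      n_metab = config$n_metab %||% 20,
      targets_per_metab = config$targets_per_metab %||% 20,
      beta_range = unlist(config$beta_range) %||% c(0.8, 1.2),
      coupling = config$coupling,
      n_background = config$n_background %||% 100,
      sigma_m = config$sigma_m %||% 0.5,
      prop_negative = config$prop_negative %||% 0.25,
      seed = seed)
    sim <- simulate_dataset(gt, config$n_samples %||% 300, seed = seed + 1L)
    write_omics_matrix(sim$metabolites, file.path(out_dir, "metabolites.tsv"))
    write_omics_matrix(sim$transcripts, file.path(out_dir, "expression.tsv"))
    jsonlite::write_json(
      list(metabolites = gt$metabolites, targets = gt$targets,
           sigma_m = gt$sigma_m, coupling = gt$coupling,
           background_ids = gt$background_ids),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    summary$n_metabolites <- length(gt$metabolites)
    summary$n_transcripts <- nrow(sim$transcripts$values)
    summary$n_samples <- ncol(sim$metabolites$values)
  } else if (exper == "infer") {
    metab <- read_omics_matrix(need("metabolites"), "metabolite")
    expr <- read_omics_matrix(need("expression"), "transcript")
    net <- infer_network(combine_matrices(metab, expr), cfg_net(),
                         source = config$source %||% "cli")
    write_network(net, file.path(out_dir, "network.tsv"))
    summary$n_edges <- nrow(net$edges)
    summary$n_hubs <- length(unique(net$edges$metabolite))
    summary$n_samples <- net$meta$n_samples
  } else if (exper == "predict") {
    net <- read_network(need("network"))
    expr <- read_omics_matrix(need("expression"), "transcript")
    mode <- config$mode %||% "sample"
    g1 <- g2 <- NULL
    if (mode == "contrast") {
      g1 <- readLines(need("group1"))
      g2 <- readLines(need("group2"))
    }
    pred <- predict_metabolites(net, expr, mode = mode,
                                group1 = g1, group2 = g2,
                                minsize = config$minsize %||% 10)
    if (mode == "sample") {
      out <- cbind(metabolite = rownames(pred$nes),
                   format(pred$nes, digits = 17, trim = TRUE))
    } else {
      out <- data.frame(metabolite = names(pred$nes),
                        nes = sprintf("%.17g", pred$nes),
                        p = sprintf("%.17g", pred$p),
                        fdr = sprintf("%.17g", pred$fdr))
    }
    utils::write.table(out, file.path(out_dir, "nes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$n_predicted <- if (mode == "sample") nrow(pred$nes) else length(pred$nes)
    summary$skipped <- as.list(pred$skipped)
  } else if (exper %in% c("split", "null")) {
    metab <- read_omics_matrix(need("metabolites"), "metabolite")
    expr <- read_omics_matrix(need("expression"), "transcript")
    combined <- combine_matrices(metab, expr)
    res <- split_half_evaluate(
      combined, n_splits = need("splits"), cfg = cfg_net(),
      seed = need("seed"), minsize = config$minsize %||% 10,
      shuffle_null = exper == "null" || isTRUE(config$shuffle_null))
    out <- data.frame(metabolite = colnames(res$r),
                      mean_r = sprintf("%.17g", res$mean_r),
                      n_splits_evaluated = colSums(!is.na(res$r)))
    if (!is.null(res$shuffled_r)) {
      out$mean_r_shuffled <- sprintf("%.17g", colMeans(res$shuffled_r, na.rm = TRUE))
    }
    utils::write.table(out, file.path(out_dir, "split_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$n_splits <- res$n_splits
    summary$mean_r <- mean(res$r, na.rm = TRUE)
    if (!is.null(res$shuffled_r)) {
      summary$mean_r_shuffled <- mean(res$shuffled_r, na.rm = TRUE)
    }
  } else if (exper == "cross") {
    net <- read_network(need("network"))
    metab <- read_omics_matrix(need("metabolites"), "metabolite")
    expr <- read_omics_matrix(need("expression"), "transcript")
    pred <- predict_metabolites(net, expr, mode = "sample",
                                minsize = config$minsize %||% 10)
    rep <- per_metabolite_correlation(pred, metab)
    tab <- rep$table
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], function(v) sprintf("%.17g", v))
    utils::write.table(tab, file.path(out_dir, "cross_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- c(summary, rep$summary)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
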