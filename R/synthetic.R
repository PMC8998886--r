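#' Planted ground truth for paired-omics simulation
#'
#' Defines a linear-Gaussian latent-factor model: each metabolite m has a
#' latent activity a_m; its measured value is a_m + N(0, sigma_m^2); each of
#' its target transcripts g is s_g * beta_g * a_m + N(0, 1); background
#' transcripts are iid N(0, 1). Latent activities are jointly multivariate
#' normal with a coupling (correlation) matrix, which creates indirect
#' metabolite-transcript correlations for DPI to prune. Under this model the
#' expected metabolite-target Pearson correlation has the closed form
#' rho = s * beta / sqrt((1 + sigma_m^2) * (beta^2 + 1)).
#'
#' @param n_metab number of metabolites (default 20).
#' @param targets_per_metab targets per metabolite (default 20).
#' @param beta_range range for uniform draws of beta (default c(0.8, 1.2),
#'   giving rho roughly 0.56-0.69 at sigma_m = 0.5).
#' @param coupling latent coupling: NULL (independent), a scalar
#'   off-diagonal correlation, or a full correlation matrix (symmetric PSD,
#'   unit diagonal).
#' @param n_background uncorrelated background transcripts (default 100).
#' @param sigma_m metabolite measurement noise sd, scalar or per metabolite
#'   (default 0.5).
#' @param prop_negative fraction of targets with negative sign (default
#'   0.25).
#' @param seed RNG seed.
#' @return a list of class `ground_truth` with `metabolites`, `targets`
#'   (data.frame metabolite/transcript/beta/sign/rho), `coupling`,
#'   `sigma_m`, `background_ids`.
#' @export
build_ground_truth <- function(n_metab = 20, targets_per_metab = 20,
                               beta_range = c(0.8, 1.2), coupling = NULL,
                               n_background = 100, sigma_m = 0.5,
                               prop_negative = 0.25, seed) {
  if (n_metab < 1 || targets_per_metab < 1) {
    stop("n_metab and targets_per_metab must be >= 1", call. = FALSE)
  }
  mets <- sprintf("met%02d", seq_len(n_metab))
  C <- diag(n_metab)
  if (!is.null(coupling)) {
    if (is.matrix(coupling)) {
      C <- coupling
    } else if (length(coupling) == 1L) {
      C <- matrix(coupling, n_metab, n_metab)
      diag(C) <- 1
    } else stop("coupling must be a scalar or a matrix", call. = FALSE)
    if (nrow(C) != n_metab || ncol(C) != n_metab ||
        max(abs(C - t(C))) > 1e-10 || any(abs(diag(C) - 1) > 1e-10)) {
      stop("coupling must be a symmetric matrix with unit diagonal",
           call. = FALSE)
    }
    if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop("coupling matrix is not positive semi-definite", call. = FALSE)
    }
  }
  dimnames(C) <- list(mets, mets)
  sig <- rep_len(sigma_m, n_metab)
  names(sig) <- mets
  with_seed(seed, {
    beta <- stats::runif(n_metab * targets_per_metab,
                         beta_range[1], beta_range[2])
    sign_g <- ifelse(stats::runif(n_metab * targets_per_metab) < prop_negative,
                     -1, 1)
  })
  targets <- data.frame(
    metabolite = rep(mets, each = targets_per_metab),
    transcript = sprintf("gene_%s_t%02d", rep(mets, each = targets_per_metab),
                         rep(seq_len(targets_per_metab), n_metab)),
    beta = beta,
    sign = sign_g,
    stringsAsFactors = FALSE
  )
  targets$rho <- expected_correlation(targets$beta, targets$sign,
                                      sig[targets$metabolite])
  bg <- if (n_background > 0) sprintf("bg%04d", seq_len(n_background)) else character(0)
  structure(list(metabolites = mets, targets = targets, coupling = C,
                 sigma_m = sig, background_ids = bg),
            class = "ground_truth")
}

#' Closed-form metabolite-target correlation under the simulation model
#'
#' rho = s * beta / sqrt((1 + sigma_m^2) * (beta^2 + 1)).
#'
#' @param beta positive effect size.
#' @param sign +1 or -1.
#' @param sigma_m metabolite noise sd.
#' @return expected Pearson correlation.
#' @export
expected_correlation <- function(beta, sign = 1, sigma_m = 0.5) {
  sign * beta / sqrt((1 + sigma_m^2) * (beta^2 + 1))
}

# Draw latent activities (metabolites x samples) from MVN(0, coupling).
draw_activities <- function(gt, n_samples) {
  Z <- matrix(stats::rnorm(length(gt$metabolites) * n_samples),
              nrow = length(gt$metabolites))
  U <- chol(gt$coupling + diag(1e-10, nrow(gt$coupling)))
  A <- t(U) %*% Z
  rownames(A) <- gt$metabolites
  A
}

# Turn latent activities into measured metabolite and transcript matrices.
realize_dataset <- function(gt, A, sample_prefix) {
  n <- ncol(A)
  sids <- sprintf("%s%04d", sample_prefix, seq_len(n))
  colnames(A) <- sids
  metab <- A + gt$sigma_m * matrix(stats::rnorm(length(A)), nrow = nrow(A))
  tg <- gt$targets
  expr_t <- tg$sign * tg$beta * A[tg$metabolite, , drop = FALSE] +
    matrix(stats::rnorm(nrow(tg) * n), nrow = nrow(tg))
  rownames(expr_t) <- tg$transcript
  expr <- expr_t
  if (length(gt$background_ids)) {
    bg <- matrix(stats::rnorm(length(gt$background_ids) * n),
                 nrow = length(gt$background_ids),
                 dimnames = list(gt$background_ids, sids))
    expr <- rbind(expr_t, bg)
  }
  colnames(expr) <- sids
  list(
    metabolites = omics_matrix(metab, "metabolite"),
    transcripts = omics_matrix(expr, "transcript"),
    activities = A
  )
}

#' Simulate one paired metabolome/transcriptome dataset
#'
#' @param gt a [build_ground_truth()] object.
#' @param n_samples number of samples (>= 10).
#' @param seed RNG seed; different seeds on the same ground truth give the
#'   paired cross-dataset scenario.
#' @param sample_prefix prefix for generated sample ids.
#' @return a list of class `simulated_dataset` with `metabolites`,
#'   `transcripts` (both [omics_matrix]), `activities` (true latents),
#'   `groups = NULL`.
#' @export
simulate_dataset <- function(gt, n_samples, seed, sample_prefix = "s") {
  stopifnot(inherits(gt, "ground_truth"))
  if (n_samples < 10) stop("n_samples must be >= 10", call. = FALSE)
  out <- with_seed(seed, {
    A <- draw_activities(gt, n_samples)
    realize_dataset(gt, A, sample_prefix)
  })
  out$groups <- NULL
  structure(out, class = "simulated_dataset")
}

#' Simulate a two-group contrast dataset
#'
#' Same model as [simulate_dataset()], but group 2's latent activities are
#' shifted by `shift` for the `affected` metabolites only (an "aging"-style
#' differential-abundance scenario). The shift propagates to the affected
#' metabolites' measured values and their targets' expression.
#'
#' @param gt a [build_ground_truth()] object.
#' @param affected metabolite ids to shift (subset of `gt$metabolites`).
#' @param shift additive latent shift applied to group 2.
#' @param n1,n2 group sizes (>= 2 each).
#' @param seed RNG seed.
#' @return a `simulated_dataset` with `groups`: a named factor ("group1" /
#'   "group2") over sample ids.
#' @export
simulate_contrast <- function(gt, affected, shift, n1, n2, seed) {
  stopifnot(inherits(gt, "ground_truth"))
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per group", call. = FALSE)
  unknown <- setdiff(affected, gt$metabolites)
  if (length(unknown)) {
    stop("unknown metabolite(s) in affected: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- with_seed(seed, {
    A <- draw_activities(gt, n1 + n2)
    A[affected, (n1 + 1):(n1 + n2)] <- A[affected, (n1 + 1):(n1 + n2)] + shift
    realize_dataset(gt, A, "s")
  })
  sids <- sample_ids(out$metabolites)
  out$groups <- stats::setNames(
    factor(rep(c("group1", "group2"), c(n1, n2))), sids)
  structure(out, class = "simulated_dataset")
}

#' Edge recovery metrics against a planted ground truth
#'
#' An inferred edge is a true positive iff its (metabolite, transcript) pair
#' is planted AND the sign of the inferred correlation matches the planted
#' sign; a planted edge recovered with a flipped sign counts as a false
#' positive. An empty network has recall 0 and, by convention, precision 1
#' (with a warning).
#'
#' @param net a [metab_network].
#' @param gt a [build_ground_truth()] object.
#' @return named numeric vector `c(precision, recall)`.
#' @export
edge_recovery <- function(net, gt) {
  stopifnot(inherits(net, "metab_network"), inherits(gt, "ground_truth"))
  e <- net$edges
  if (!nrow(e)) {
    warning("empty network: precision reported as 1 by convention")
    return(c(precision = 1, recall = 0))
  }
  planted <- paste(gt$targets$metabolite, gt$targets$transcript,
                   gt$targets$sign, sep = "\r")
  inferred <- paste(e$metabolite, e$transcript, sign(e$r), sep = "\r")
  tp <- sum(inferred %in% planted)
  c(precision = tp / nrow(e), recall = tp / nrow(gt$targets))
}
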