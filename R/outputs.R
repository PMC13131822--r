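# Named model outputs and feature explanations.

#' Posterior-mean process exposures
#'
#' `pi_hat[n, k] = E_q[pi_nk] = beta_nk / sum_k beta_nk`.
#'
#' @param vstate Variational state with a `beta` matrix (or a `mutopia_fit`).
#' @return N x K matrix with rows on the simplex.
#' @export
process_contributions <- function(vstate) {
  if (inherits(vstate, "mutopia_fit")) vstate <- vstate$vstate
  beta <- vstate$beta
  beta / rowSums(beta)
}

#' Per-sample mutational topography
#'
#' `p(b, m | n) = sum_k pi_nk p(b, m | k)` — a convex mixture of the process
#' topographies.
#'
#' @param model A `mutopia_model`.
#' @param exposures Length-K simplex vector for the sample.
#' @param X,t Feature and availability matrices.
#' @return Matrix (bins x 192) summing to 1.
#' @export
sample_topography <- function(model, exposures, X, t) {
  stopifnot(length(exposures) == model$K)
  out <- 0
  for (k in seq_len(model$K))
    out <- out + exposures[k] *
      topography_distribution(model$processes[[k]], X, t)
  out
}

#' Cohort-level normalized mutation rate and per-bin spectra
#'
#' Samples are weighted by burden, `p(n) propto sum_bm Y_nbm`. The rate is
#' `p(b) = sum_nk p(n) pi_nk p(b | k)`; the per-bin cohort spectrum is
#' `p(m | b) propto sum_nk p(n) pi_nk p(b, m | k)`.
#'
#' @param model A `mutopia_model`.
#' @param vstate Variational state (or `mutopia_fit`).
#' @param tensor The `mutopia_tensor` used in fitting (for burdens).
#' @param binning The `mutopia_binning`.
#' @return List `rate` (length `N_bins`, sums to 1) and `spectra`
#'   (bins x 192, rows sum to 1 where the rate is positive).
#' @export
cohort_rate_and_spectra <- function(model, vstate, tensor, binning) {
  if (inherits(vstate, "mutopia_fit")) vstate <- vstate$vstate
  pi_hat <- vstate$beta / rowSums(vstate$beta)
  pn <- .rowsum_all(tensor$cells$weight, tensor$cells$sample,
                    nrow(tensor$samples))[, 1]
  pn <- pn / sum(pn)
  mix_k <- colSums(pn * pi_hat)   # sum_n p(n) pi_nk
  joint <- 0
  for (k in seq_len(model$K))
    joint <- joint + mix_k[k] *
      topography_distribution(model$processes[[k]], binning$X, binning$t)
  rate <- rowSums(joint)
  spectra <- joint / ifelse(rate > 0, rate, 1)
  list(rate = rate, spectra = spectra, process_mix = mix_k)
}

# exact linear-model Shapley values: coef_i * (x_i - mean(x_i))
.linear_shap <- function(macro, X) {
  Xm <- X[, macro$features, drop = FALSE]
  sweep(Xm, 2, colMeans(Xm)) %*% diag(macro$coef[macro$features],
                                      ncol(Xm), ncol(Xm))
}

# seeded permutation-sampling Shapley fallback for arbitrary functions
.sampling_shap <- function(fun, X, n_perm = 30, seed = 1) {
  set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  out <- matrix(0, n, p)
  base <- colMeans(X)
  for (r in seq_len(n_perm)) {
    perm <- sample.int(p)
    cur <- matrix(base, n, p, byrow = TRUE)
    colnames(cur) <- colnames(X)
    prev_val <- fun(cur)
    for (j in perm) {
      cur[, j] <- X[, j]
      val <- fun(cur)
      out[, j] <- out[, j] + (val - prev_val)
      prev_val <- val
    }
  }
  out / n_perm
}

#' Shapley feature attributions of the macro-scale effects
#'
#' Tree ensembles use exact tree-path (TreeSHAP) attributions with the bin
#' feature matrix as background, so per-bin attributions plus the baseline
#' reproduce `f_k(X_b)` (local accuracy). Linear effects use the exact
#' closed form; other flavors fall back to seeded permutation sampling.
#' Feature impact is the 0.97 quantile of absolute attributions;
#' directionality is the Pearson correlation between attributions and
#' feature values (0 on zero variance).
#'
#' @param model A `mutopia_model`.
#' @param X Feature matrix (bins x features).
#' @param quantile_impact Impact quantile (default 0.97).
#' @param seed Seed for the sampling fallback.
#' @return A `mutopia_shapley`: `values` (list of K bins x macro-features
#'   matrices), `impact` and `directionality` (K x macro-features matrices).
#' @export
explain_features <- function(model, X, quantile_impact = 0.97, seed = 1) {
  macro_feats <- unique(unlist(lapply(model$processes,
                                      function(p) p$macro$features)))
  if (!length(macro_feats))
    macro_feats <- colnames(X)
  K <- model$K
  values <- vector("list", K)
  impact <- matrix(0, K, length(macro_feats),
                   dimnames = list(NULL, macro_feats))
  direction <- impact
  for (k in seq_len(K)) {
    macro <- model$processes[[k]]$macro
    V <- matrix(0, nrow(X), length(macro_feats),
                dimnames = list(NULL, macro_feats))
    if (macro$flavor == "boosted_trees") {
      Xm <- X[, macro$features, drop = FALSE]
      ct <- stats::predict(macro$model, xgboost::xgb.DMatrix(Xm),
                           predcontrib = TRUE)
      V[, macro$features] <- ct[, macro$features, drop = FALSE]
      attr(V, "baseline") <- ct[1, ncol(ct)]
    } else if (macro$flavor == "linear") {
      V[, macro$features] <- .linear_shap(macro, X)
    } else if (macro$flavor == "custom") {
      Xm <- X[, macro$features, drop = FALSE]
      V[, macro$features] <- .sampling_shap(macro$fun, Xm, seed = seed + k)
    } # constant: all zeros
    values[[k]] <- V
    impact[k, ] <- apply(abs(V), 2, stats::quantile,
                         probs = quantile_impact)
    for (j in seq_along(macro_feats)) {
      v <- V[, j]; x <- X[, macro_feats[j]]
      direction[k, j] <- if (stats::sd(v) == 0 || stats::sd(x) == 0) 0
        else stats::cor(v, x)
    }
  }
  structure(list(values = values, impact = impact,
                 directionality = direction, features = macro_feats),
            class = "mutopia_shapley")
}

#' Write tidy model-output tables
#'
#' Exposures, cohort rate profile and per-process spectra as TSV, Shapley
#' summaries as JSON.
#'
#' @param fit A `mutopia_fit`.
#' @param tensor,binning The data the fit was produced from.
#' @param dir Output directory (created if needed).
#' @export
write_outputs <- function(fit, tensor, binning, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expo <- process_contributions(fit)
  rownames(expo) <- tensor$samples$sample_id
  colnames(expo) <- vapply(fit$model$processes, `[[`, "", "label")
  utils::write.table(data.frame(sample = rownames(expo), expo,
                                check.names = FALSE),
                     file.path(dir, "exposures.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  crs <- cohort_rate_and_spectra(fit$model, fit, tensor, binning)
  utils::write.table(data.frame(bin_id = binning$bins$bin_id,
                                rate = crs$rate),
                     file.path(dir, "rate_profile.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  spec <- t(vapply(fit$model$processes, function(p)
    marginal_spectrum(p, binning$X, binning$t), numeric(192)))
  colnames(spec) <- mutation_type_labels()
  utils::write.table(data.frame(process = colnames(expo), spec,
                                check.names = FALSE),
                     file.path(dir, "spectra.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sh <- explain_features(fit$model, binning$X)
  jsonlite::write_json(list(features = sh$features,
                            impact = sh$impact,
                            directionality = sh$directionality),
                       file.path(dir, "attributions.json"), digits = NA,
                       matrix = "rowmajor")
  invisible(dir)
}
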