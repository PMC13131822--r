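# Process topographies.
#
# A process k is a normalized distribution over (bin, channel):
#   p(b, m | k) propto t[b, m] * exp(f_k(X_b) + g_km(X_b))
# with t the context availability, f_k a macro-scale log-rate function
# (boosted trees, linear, constant, or an arbitrary function for
# simulation references), and g_km a spectrum term combining a baseline
# 192-channel log-spectrum with sparse feature-driven adjustments:
# per-channel coefficients on meso features, plus strand terms coupling a
# strand-oriented feature to the channel's orientation sign in two tiers
# (one lightly penalized uniform coefficient and heavily l1-penalized
# per-channel deviations).

#' Construct a macro-scale effect
#'
#' @param flavor One of `"constant"`, `"linear"`, `"boosted_trees"`,
#'   `"custom"`.
#' @param features Character vector of macro feature names the effect reads.
#' @param coef Named coefficients (linear flavor).
#' @param intercept Intercept for the linear flavor (absorbed by
#'   normalization but kept for fitting stability).
#' @param model An `xgb.Booster` (boosted_trees flavor).
#' @param fun A function of the feature sub-matrix returning a log-rate
#'   vector (custom flavor; used by simulation references).
#' @return A `mutopia_macro` object.
#' @export
macro_effect <- function(flavor = c("constant", "linear", "boosted_trees",
                                    "custom"),
                         features = character(0), coef = NULL,
                         intercept = 0, model = NULL, fun = NULL) {
  flavor <- match.arg(flavor)
  structure(list(flavor = flavor, features = features, coef = coef,
                 intercept = intercept, model = model, fun = fun),
            class = "mutopia_macro")
}

#' Evaluate a macro effect on a feature matrix
#'
#' @param macro A `mutopia_macro`.
#' @param X Feature matrix with named columns covering `macro$features`.
#' @return Numeric log-rate vector, one value per row of `X`.
#' @export
macro_values <- function(macro, X) {
  if (macro$flavor == "constant" || !length(macro$features))
    return(rep(0, nrow(X)))
  miss <- setdiff(macro$features, colnames(X))
  if (length(miss))
    stop("feature matrix lacks macro features: ", paste(miss, collapse = ", "))
  Xm <- X[, macro$features, drop = FALSE]
  switch(macro$flavor,
    linear = as.numeric(Xm %*% macro$coef[macro$features]) +
      (macro$intercept %||% 0),
    boosted_trees = {
      dm <- xgboost::xgb.DMatrix(Xm)
      as.numeric(stats::predict(macro$model, dm, outputmargin = TRUE))
    },
    custom = as.numeric(macro$fun(Xm)))
}

#' Construct a spectra effect
#'
#' @param baseline Length-192 baseline log-spectrum (defined up to an
#'   additive constant absorbed by normalization).
#' @param meso_coef Matrix (meso features x 192) of sparse per-channel
#'   adjustment coefficients, or NULL.
#' @param strand_uniform Named numeric: one orientation-uniform coefficient
#'   per strand feature.
#' @param strand_dev Matrix (strand features x 192) of per-channel strand
#'   deviations, or NULL.
#' @return A `mutopia_spectra` object.
#' @export
spectra_effect <- function(baseline = rep(0, 192), meso_coef = NULL,
                           strand_uniform = NULL, strand_dev = NULL) {
  stopifnot(length(baseline) == 192L)
  structure(list(baseline = as.numeric(baseline), meso_coef = meso_coef,
                 strand_uniform = strand_uniform, strand_dev = strand_dev),
            class = "mutopia_spectra")
}

#' Evaluate the spectra term g_km over bins
#'
#' @param spectra A `mutopia_spectra`.
#' @param X Feature matrix (bins x features).
#' @return Matrix (bins x 192) of log-spectrum values.
#' @export
spectra_values <- function(spectra, X) {
  n <- nrow(X)
  G <- matrix(spectra$baseline, nrow = n, ncol = 192, byrow = TRUE)
  if (!is.null(spectra$meso_coef) && nrow(spectra$meso_coef)) {
    feats <- rownames(spectra$meso_coef)
    miss <- setdiff(feats, colnames(X))
    if (length(miss))
      stop("feature matrix lacks meso features: ",
           paste(miss, collapse = ", "))
    G <- G + X[, feats, drop = FALSE] %*% spectra$meso_coef
  }
  sgn <- type_strand_sign()
  for (sf in names(spectra$strand_uniform)) {
    if (!sf %in% colnames(X))
      stop("feature matrix lacks strand feature: ", sf)
    z <- X[, sf]
    eff <- rep(spectra$strand_uniform[[sf]], 192)
    if (!is.null(spectra$strand_dev) && sf %in% rownames(spectra$strand_dev))
      eff <- eff + spectra$strand_dev[sf, ]
    G <- G + outer(z, sgn * eff)
  }
  G
}

#' Assemble one process topography
#'
#' @param macro A `mutopia_macro`.
#' @param spectra A `mutopia_spectra`.
#' @param label Process label.
#' @return A `mutopia_process`.
#' @export
process_topography <- function(macro, spectra, label = "process") {
  structure(list(macro = macro, spectra = spectra, label = label),
            class = "mutopia_process")
}

#' Unnormalized log-probabilities of a process topography
#'
#' `log t[b, m] + f_k(X_b) + g_km(X_b)`; cells with zero availability are
#' exactly `-Inf`.
#'
#' @param process A `mutopia_process`.
#' @param X Feature matrix (bins x features).
#' @param t Availability matrix (bins x 192).
#' @return Matrix (bins x 192) of logits.
#' @export
topography_logits <- function(process, X, t) {
  stopifnot(nrow(X) == nrow(t), ncol(t) == 192L)
  logt <- suppressWarnings(log(t))
  logt[t <= 0] <- -Inf
  f <- macro_values(process$macro, X)
  G <- spectra_values(process$spectra, X)
  logt + f + G
}

#' Normalized topography distribution over (bin, channel)
#'
#' @inheritParams topography_logits
#' @return Matrix (bins x 192) of probabilities summing to 1.
#' @export
topography_distribution <- function(process, X, t) {
  lg <- topography_logits(process, X, t)
  .normalize_logits(lg)
}

.normalize_logits <- function(lg) {
  finite <- is.finite(lg)
  if (!any(finite)) stop("all availability is zero; cannot normalize")
  m <- max(lg[finite])
  p <- exp(lg - m)
  p[!finite] <- 0
  p / sum(p)
}

# log-normalized topography (for likelihood evaluation); -Inf at t == 0
.log_topography <- function(process, X, t) {
  lg <- topography_logits(process, X, t)
  finite <- is.finite(lg)
  if (!any(finite)) stop("all availability is zero; cannot normalize")
  m <- max(lg[finite])
  lse <- m + log(sum(exp(lg[finite] - m)))
  lg - lse
}

#' Marginal spectrum of a process
#' @inheritParams topography_logits
#' @return Length-192 probability vector `p(m | k)`.
#' @export
marginal_spectrum <- function(process, X, t) {
  colSums(topography_distribution(process, X, t))
}

#' Marginal genomic distribution of a process
#' @inheritParams topography_logits
#' @return Length-`N_bins` probability vector `p(b | k)`.
#' @export
marginal_genomic <- function(process, X, t) {
  rowSums(topography_distribution(process, X, t))
}

#' Assemble a model state
#'
#' @param processes List of `mutopia_process` objects.
#' @param alpha Positive Dirichlet prior vector, length `K` (scalar
#'   recycled).
#' @param feature_class Named class map of the features the model was
#'   trained on.
#' @return A `mutopia_model`.
#' @export
model_state <- function(processes, alpha = 1, feature_class = NULL) {
  K <- length(processes)
  stopifnot(K >= 1)
  alpha <- rep_len(as.numeric(alpha), K)
  stopifnot(all(alpha > 0))
  structure(list(K = K, processes = processes, alpha = alpha,
                 feature_class = feature_class, schema_version = 1L),
            class = "mutopia_model")
}

#' @export
print.mutopia_model <- function(x, ...) {
  cat(sprintf("mutopia model: K = %d processes (%s)\n", x$K,
              paste(vapply(x$processes, `[[`, "", "label"), collapse = ", ")))
  invisible(x)
}

# Per-process normalized log-topographies, the core quantity used by
# inference and evaluation.
.model_log_topographies <- function(model, X, t) {
  lapply(model$processes, function(p) .log_topography(p, X, t))
}

#' Save / load a fitted model archive
#'
#' The archive is a versioned R list (config, alpha, per-process macro
#' models with serialized tree ensembles, spectra coefficients) written with
#' `saveRDS`.
#' @param model A `mutopia_model`.
#' @param path File path.
#' @export
write_model <- function(model, path) {
  ser <- model
  ser$processes <- lapply(model$processes, function(p) {
    if (p$macro$flavor == "boosted_trees")
      p$macro$model <- xgboost::xgb.save.raw(p$macro$model)
    p
  })
  saveRDS(ser, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  ser <- readRDS(path)
  ser$processes <- lapply(ser$processes, function(p) {
    if (p$macro$flavor == "boosted_trees" && is.raw(p$macro$model))
      p$macro$model <- xgboost::xgb.load.raw(p$macro$model)
    p
  })
  ser
}
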