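# Mean-field variational inference.
#
# The joint model is an LDA-style mixture: per-sample exposures pi_n ~
# Dir(alpha); each (weighted) mutation chooses a process z ~ Cat(pi_n) and a
# (bin, channel) cell from that process's topography. The variational family
# factorizes as q(pi_n | beta_n) q(z_cell | phi_cell); coordinate ascent
# alternates exact E-step updates of (phi, beta) with M-step refits of the
# topography parameters and a Minka fixed-point update of alpha. M-step
# regressions (boosted trees / penalized Poisson fits) are inexact, so every
# refit is guarded: new parameters are kept only if they do not decrease
# their ELBO term, making the traced objective monotone under full-batch
# ascent. The l1/l2 spectra penalties are treated as Laplace/Gaussian
# log-priors and included in the traced (MAP) objective.

#' Inference configuration
#'
#' @param K Number of mutational processes.
#' @param flavor Macro-effect flavor: `"boosted_trees"` (default),
#'   `"linear"`, or `"constant"` (the LDA ablation).
#' @param spectra_adjust Fit feature-driven spectrum adjustments (set FALSE
#'   to keep the baseline spectrum only, as in the LDA / locus-only
#'   ablations).
#' @param l1_penalty Lambda for the l1-penalized adjustment fit (glmnet
#'   scale; larger is sparser).
#' @param strand_uniform_pf,strand_dev_pf Penalty factors for the
#'   orientation-uniform strand coefficient (light) and the per-channel
#'   strand deviations (heavy), realising the preference for uniform strand
#'   effects over channel-specific asymmetries.
#' @param tree_nrounds,tree_eta,tree_depth,tree_min_child Boosted-tree
#'   hyperparameters (shallow trees, Poisson loss).
#' @param max_epochs Maximum coordinate-ascent epochs.
#' @param tol Relative ELBO change declaring convergence.
#' @param tol_window Epoch window over which `tol` must hold.
#' @param e_inner,e_tol Inner E-step iterations and tolerance.
#' @param spectra_every Refit spectra adjustments every j-th epoch
#'   (baseline still updates every epoch).
#' @param batch_fraction Fraction of bins visited per epoch (1 = full-batch
#'   coordinate ascent).
#' @param sv_kappa,sv_delay Stochastic step-size schedule
#'   `rho_t = (t + sv_delay)^(-sv_kappa)` used when `batch_fraction < 1`.
#' @param update_alpha Update the Dirichlet prior each epoch.
#' @param alpha_init Initial (symmetric) Dirichlet prior value.
#' @param spectra_seeds Optional K x 192 (or K x 96) matrix of reference
#'   spectra used to initialise baselines.
#' @param seed Integer seed driving all randomness in the fit.
#' @return A config list.
#' @export
mutopia_config <- function(K = 2, flavor = c("boosted_trees", "linear",
                                             "constant"),
                           spectra_adjust = TRUE, l1_penalty = 0.002,
                           strand_uniform_pf = 0.1, strand_dev_pf = 5,
                           tree_nrounds = 40, tree_eta = 0.3,
                           tree_depth = 3, tree_min_child = 1,
                           max_epochs = 100, tol = 1e-6, tol_window = 10,
                           e_inner = 50, e_tol = 1e-8, spectra_every = 1,
                           batch_fraction = 1, sv_kappa = 0.7, sv_delay = 1,
                           update_alpha = TRUE, alpha_init = 1,
                           spectra_seeds = NULL, seed = 1) {
  list(K = as.integer(K), flavor = match.arg(flavor),
       spectra_adjust = spectra_adjust, l1_penalty = l1_penalty,
       strand_uniform_pf = strand_uniform_pf, strand_dev_pf = strand_dev_pf,
       tree_nrounds = tree_nrounds, tree_eta = tree_eta,
       tree_depth = tree_depth, tree_min_child = tree_min_child,
       max_epochs = max_epochs, tol = tol, tol_window = tol_window,
       e_inner = e_inner, e_tol = e_tol, spectra_every = spectra_every,
       batch_fraction = batch_fraction, sv_kappa = sv_kappa,
       sv_delay = sv_delay, update_alpha = update_alpha,
       alpha_init = alpha_init, spectra_seeds = spectra_seeds,
       seed = as.integer(seed))
}

.elog_pi <- function(beta) {
  digamma(beta) - digamma(rowSums(beta))
}

.rowsum_all <- function(x, group, n_groups) {
  # rowsum() over integer groups 1..n_groups, returning zero rows for
  # absent groups
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  rs <- rowsum(x, group)
  out <- matrix(0, n_groups, ncol(x))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

.softmax_rows <- function(A) {
  m <- A[, 1]
  for (k in seq_len(ncol(A))[-1]) m <- pmax(m, A[, k])
  E <- exp(A - m)
  E / rowSums(E)
}

#' Variational E-step
#'
#' Iterates the exact coordinate updates
#' `phi_cell,k propto exp(E[log pi_nk]) p(b, m | k)` and
#' `beta_nk = alpha_k + sum_cells Y phi_k` to a local fixed point, so a
#' repeated call with an unchanged model is a no-op.
#'
#' @param cells Sparse tensor cells (`sample`, `weight`) with a
#'   `logp` matrix attribute or supplied `logp_cells`.
#' @param logp_cells Matrix (cells x K) of log p(b, m | k) at each cell.
#' @param beta Current N x K Dirichlet parameters.
#' @param alpha Prior vector, length K.
#' @param n_samples Number of samples N.
#' @param inner,tol Inner iteration cap and beta tolerance.
#' @param scale Multiplier on the data statistics (inverse sampling
#'   fraction under bin subsampling; 1 for full batch).
#' @return List with `phi` (cells x K), `beta` (N x K).
#' @export
e_step <- function(cells, logp_cells, beta, alpha, n_samples,
                   inner = 50, tol = 1e-8, scale = 1) {
  if (any(!is.finite(logp_cells)))
    stop("non-finite log-probability at observed cell(s): ",
         paste(utils::head(which(!is.finite(rowSums(logp_cells)))),
               collapse = ", "))
  K <- length(alpha)
  w <- cells$weight
  smp <- cells$sample
  phi <- NULL
  for (it in seq_len(inner)) {
    elog <- .elog_pi(beta)
    phi <- .softmax_rows(logp_cells + elog[smp, , drop = FALSE])
    stats <- .rowsum_all(w * phi, smp, n_samples) * scale
    beta_new <- matrix(alpha, n_samples, K, byrow = TRUE) + stats
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) break
  }
  list(phi = phi, beta = beta)
}

# ---- M-step helpers ---------------------------------------------------------

# responsibility-weighted count matrix for process k (bins x 192), on the
# bin subset used for fitting
.process_counts <- function(cells, phi_k, n_bins) {
  Matrix::sparseMatrix(i = cells$bin_row, j = cells$type,
                       x = cells$weight * phi_k, dims = c(n_bins, 192))
}

# multinomial likelihood term sum_bm C_bm log p(b,m|k) for sparse C
.lik_term <- function(C, logP) {
  s <- Matrix::summary(methods::as(C, "TsparseMatrix"))
  s <- s[s$x != 0, , drop = FALSE]   # explicit zeros would give 0 * -Inf
  if (!nrow(s)) return(0)
  sum(s$x * logP[cbind(s$i, s$j)])
}

# penalty (log-prior, likelihood units) of a spectra effect under the
# glmnet objective scaling: nobs * lambda * sum(pf * |coef|)
.spectra_penalty <- function(spectra, config, nobs) {
  if (is.null(nobs) || nobs == 0) return(0)
  pen <- 0
  if (!is.null(spectra$meso_coef)) pen <- pen + sum(abs(spectra$meso_coef))
  if (!is.null(spectra$strand_uniform))
    pen <- pen + config$strand_uniform_pf * sum(abs(spectra$strand_uniform))
  if (!is.null(spectra$strand_dev))
    pen <- pen + config$strand_dev_pf * sum(abs(spectra$strand_dev))
  nobs * config$l1_penalty * pen
}

# closed-form baseline update: Poisson MLE of per-channel intercepts given
# everything else in the offset; zero-count channels floored 30 nats below
# the maximum to stay finite
.update_baseline <- function(C, t, f, spectra, X) {
  sp0 <- spectra; sp0$baseline <- rep(0, 192)
  Gnb <- spectra_values(sp0, X)
  E <- colSums(t * exp(f + Gnb))
  Cm <- Matrix::colSums(C)
  base <- ifelse(Cm > 0 & E > 0, log(Cm / E), NA_real_)
  if (all(is.na(base))) base[] <- 0
  floor_val <- max(base, na.rm = TRUE) - 30
  base[is.na(base)] <- floor_val
  spectra$baseline <- base
  spectra
}

# sparse design matrix for the spectra-adjustment glmnet fit; built once per
# fit. Rows follow the cells of the (bin, channel) grid with t > 0, in
# column-major (bin fastest) order of which(t > 0).
.build_adjust_design <- function(X, t, feature_class, config) {
  meso <- names(feature_class)[feature_class == "meso"]
  strand <- names(feature_class)[feature_class == "strand"]
  if ((!length(meso) && !length(strand)) || !config$spectra_adjust)
    return(NULL)
  av <- which(t > 0, arr.ind = TRUE)  # t is a dense base matrix
  rows <- nrow(av)
  blocks <- list(); pf <- numeric(0); colmap <- list()
  bin_i <- av[, 1]; type_j <- av[, 2]
  for (f in meso) {
    # one column per channel: X[bin, f] on rows of that channel
    blocks[[length(blocks) + 1L]] <- Matrix::sparseMatrix(
      i = seq_len(rows), j = type_j, x = X[bin_i, f], dims = c(rows, 192))
    pf <- c(pf, rep(1, 192))
    colmap[[length(colmap) + 1L]] <- data.frame(kind = "meso", feature = f,
                                                type = 1:192)
  }
  sgn <- type_strand_sign()
  for (f in strand) {
    z <- X[bin_i, f] * sgn[type_j]
    blocks[[length(blocks) + 1L]] <- Matrix::sparseMatrix(
      i = seq_len(rows), j = rep(1L, rows), x = z, dims = c(rows, 1))
    pf <- c(pf, config$strand_uniform_pf)
    colmap[[length(colmap) + 1L]] <- data.frame(kind = "strand_uniform",
                                                feature = f, type = NA)
    blocks[[length(blocks) + 1L]] <- Matrix::sparseMatrix(
      i = seq_len(rows), j = type_j, x = z, dims = c(rows, 192))
    pf <- c(pf, rep(config$strand_dev_pf, 192))
    colmap[[length(colmap) + 1L]] <- data.frame(kind = "strand_dev",
                                                feature = f, type = 1:192)
  }
  D <- do.call(cbind, blocks)
  list(D = D, pf = pf, colmap = do.call(rbind, colmap), av = av,
       meso = meso, strand = strand)
}

.fit_adjustments <- function(C, t, f, spectra, X, design, config) {
  av <- design$av
  y <- as.numeric(C[av])
  off <- log(t[av]) + f[av[, 1]] + spectra$baseline[av[, 2]]
  fit <- tryCatch(
    glmnet::glmnet(design$D, y, family = "poisson", offset = off,
                   lambda = config$l1_penalty, penalty.factor = design$pf,
                   intercept = FALSE, standardize = FALSE,
                   thresh = 1e-8, maxit = 200000),
    error = function(e) NULL)
  if (is.null(fit)) return(spectra)
  cf <- as.numeric(fit$beta[, 1])
  cm <- design$colmap
  if (length(design$meso)) {
    mc <- matrix(0, length(design$meso), 192,
                 dimnames = list(design$meso, NULL))
    for (fn in design$meso) {
      sel <- cm$kind == "meso" & cm$feature == fn
      mc[fn, ] <- cf[sel]
    }
    spectra$meso_coef <- mc
  }
  if (length(design$strand)) {
    su <- stats::setNames(numeric(length(design$strand)), design$strand)
    sd_ <- matrix(0, length(design$strand), 192,
                  dimnames = list(design$strand, NULL))
    for (fn in design$strand) {
      su[fn] <- cf[cm$kind == "strand_uniform" & cm$feature == fn]
      sd_[fn, ] <- cf[cm$kind == "strand_dev" & cm$feature == fn]
    }
    spectra$strand_uniform <- su
    spectra$strand_dev <- sd_
  }
  spectra
}

.fit_macro <- function(flavor, y, offset, Xm, config) {
  if (flavor == "constant" || ncol(Xm) == 0)
    return(macro_effect("constant"))
  if (flavor == "linear") {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(`(Intercept)` = 1, Xm), y, offset = offset,
                     family = stats::poisson()))
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    return(macro_effect("linear", features = colnames(Xm),
                        coef = cf[colnames(Xm)], intercept = cf[1]))
  }
  dm <- xgboost::xgb.DMatrix(Xm, label = y, base_margin = offset)
  bst <- xgboost::xgb.train(
    params = list(objective = "count:poisson", max_depth = config$tree_depth,
                  eta = config$tree_eta,
                  min_child_weight = config$tree_min_child, nthread = 1,
                  max_delta_step = 0.7),
    data = dm, nrounds = config$tree_nrounds, verbose = 0)
  macro_effect("boosted_trees", features = colnames(Xm), model = bst)
}

#' Variational M-step
#'
#' Refits, for every process, the macro-scale rate function (boosted-tree or
#' linear Poisson regression of responsibility-weighted per-bin counts with
#' a log-availability offset), the baseline spectrum (closed form), and the
#' sparse spectra adjustments (l1-penalized Poisson regression); then
#' updates the Dirichlet prior by Minka's fixed point. Each refit is kept
#' only if it does not decrease its ELBO term.
#'
#' @param state Internal fit state (cells with `bin_row`, phi, beta, model,
#'   Xs, ts, design, config).
#' @param update_spectra Refit the adjustment coefficients this epoch.
#' @return Updated state (model, logP, penalty).
#' @keywords internal
.m_step <- function(state, update_spectra = TRUE) {
  config <- state$config
  cells <- state$cells
  Xs <- state$Xs; ts <- state$ts
  macro_feats <- names(state$feature_class)[state$feature_class == "macro"]
  Xm <- Xs[, macro_feats, drop = FALSE]
  n_bins <- nrow(Xs)
  for (k in seq_len(config$K)) {
    proc <- state$model$processes[[k]]
    C <- .process_counts(cells, state$phi[, k], n_bins) * state$scale
    if (sum(C) < 1e-10) {
      if (!state$frozen[k]) {
        warning("process ", k, " has no attributed mass; parameters frozen")
        state$frozen[k] <- TRUE
      }
      next
    }
    state$frozen[k] <- FALSE
    logP_old <- state$logP[[k]]
    term_old <- .lik_term(C, logP_old) -
      .spectra_penalty(proc$spectra, config, state$nobs_av)
    # --- macro refit (guarded) ---
    if (config$flavor != "constant") {
      Gk <- spectra_values(proc$spectra, Xs)
      off <- log(pmax(rowSums(ts * exp(Gk)), 1e-300))
      y <- as.numeric(Matrix::rowSums(C))
      macro_new <- .fit_macro(config$flavor, y, off, Xm, config)
      cand <- proc; cand$macro <- macro_new
      logP_new <- .log_topography(cand, Xs, ts)
      term_new <- .lik_term(C, logP_new) -
        .spectra_penalty(cand$spectra, config, state$nobs_av)
      if (term_new >= term_old - 1e-9) {
        proc <- cand; logP_old <- logP_new; term_old <- term_new
      }
    }
    # --- spectra refit (guarded) ---
    f <- macro_values(proc$macro, Xs)
    sp <- .update_baseline(C, ts, f, proc$spectra, Xs)
    if (update_spectra && !is.null(state$design))
      sp <- .fit_adjustments(C, ts, f, sp, Xs, state$design, config)
    sp <- .update_baseline(C, ts, f, sp, Xs)
    cand <- proc; cand$spectra <- sp
    logP_new <- .log_topography(cand, Xs, ts)
    term_new <- .lik_term(C, logP_new) -
      .spectra_penalty(sp, config, state$nobs_av)
    if (term_new >= term_old - 1e-9) {
      proc <- cand; logP_old <- logP_new
    }
    state$model$processes[[k]] <- proc
    state$logP[[k]] <- logP_old
  }
  if (config$update_alpha)
    state$model$alpha <- .update_alpha(state$model$alpha,
                                       .elog_pi(state$beta))
  state$penalty <- sum(vapply(state$model$processes, function(p)
    .spectra_penalty(p$spectra, config, state$nobs_av), numeric(1)))
  state
}

# Minka fixed-point update of the Dirichlet prior, guarded on its ELBO term
.update_alpha <- function(alpha, elog, iters = 20, floor = 1e-3) {
  N <- nrow(elog)
  s <- colMeans(elog)
  obj <- function(a) N * (lgamma(sum(a)) - sum(lgamma(a)) + sum((a - 1) * s))
  best <- alpha; best_obj <- obj(alpha)
  a <- alpha
  for (i in seq_len(iters)) {
    target <- digamma(sum(a)) + s
    a_new <- vapply(target, .inv_digamma, numeric(1))
    a_new <- pmax(a_new, floor)
    if (max(abs(a_new - a)) < 1e-10) { a <- a_new; break }
    a <- a_new
  }
  if (obj(a) >= best_obj) a else best
}

.inv_digamma <- function(y, iters = 8) {
  x <- if (y >= -2.22) exp(y) + 0.5 else -1 / (y - digamma(1))
  for (i in seq_len(iters)) x <- x - (digamma(x) - y) / trigamma(x)
  max(x, 1e-12)
}

# Full MAP ELBO given current state (likelihood + prior + entropies minus
# the spectra penalty); components returned for the trace.
.elbo_state <- function(state) {
  cells <- state$cells
  w <- cells$weight * state$scale
  K <- state$config$K
  logp_cells <- vapply(seq_len(K), function(k)
    state$logP[[k]][cbind(cells$bin_row, cells$type)],
    numeric(nrow(cells)))
  phi <- state$phi; beta <- state$beta; alpha <- state$model$alpha
  elog <- .elog_pi(beta)
  N <- nrow(beta)
  lik <- sum(w * rowSums(phi * (logp_cells + elog[cells$sample, ,
                                                 drop = FALSE])))
  ent_z <- -sum(w * rowSums(ifelse(phi > 0, phi * log(phi), 0)))
  prior <- N * (lgamma(sum(alpha)) - sum(lgamma(alpha))) +
    sum(sweep(elog, 2, alpha - 1, `*`))
  ent_pi <- -sum(lgamma(rowSums(beta))) + sum(lgamma(beta)) -
    sum((beta - 1) * elog)
  list(elbo = lik + ent_z + prior + ent_pi - state$penalty,
       likelihood = lik, penalty = state$penalty)
}

#' Evidence lower bound of a model / variational-state pair
#'
#' Computes the (MAP) ELBO: expected complete-data log likelihood under the
#' weighted counts, plus the Dirichlet prior term and entropies, minus the
#' spectra-penalty log-prior. Deterministic given its inputs.
#'
#' @param tensor A `mutopia_tensor`.
#' @param model A `mutopia_model`.
#' @param binning The `mutopia_binning` the tensor was built on.
#' @param vstate List with `phi` (cells x K) and `beta` (N x K), as returned
#'   by [fit_mutopia()] or [e_step()].
#' @return Scalar ELBO value.
#' @export
elbo <- function(tensor, model, binning, vstate) {
  logP <- .model_log_topographies(model, binning$X, binning$t)
  state <- list(cells = cbind(tensor$cells,
                              bin_row = tensor$cells$bin),
                phi = vstate$phi, beta = vstate$beta, model = model,
                logP = logP, scale = 1, penalty = 0,
                config = list(K = model$K))
  .elbo_state(state)$elbo
}

# ---- fit --------------------------------------------------------------------

.init_model <- function(tensor, binning, config, bins_idx) {
  set.seed(config$seed)
  K <- config$K
  cells <- tensor$cells
  emp <- .rowsum_all(cells$weight, cells$type, 192)[, 1]
  emp <- (emp + 1e-3) / sum(emp + 1e-3)
  baselines <- vector("list", K)
  seeds <- config$spectra_seeds
  if (!is.null(seeds)) {
    if (ncol(seeds) == 96) seeds <- cbind(seeds, seeds) / 2
    stopifnot(nrow(seeds) == K, ncol(seeds) == 192)
    for (k in seq_len(K)) {
      s <- pmax(seeds[k, ] / sum(seeds[k, ]), 1e-8)
      baselines[[k]] <- log(s)
    }
  } else {
    for (k in seq_len(K))
      baselines[[k]] <- log(emp) + stats::rnorm(192, sd = 0.05)
  }
  processes <- lapply(seq_len(K), function(k) {
    process_topography(macro_effect("constant"),
                       spectra_effect(baseline = baselines[[k]]),
                       label = paste0("P", k))
  })
  model_state(processes, alpha = config$alpha_init,
              feature_class = binning$feature_class)
}

#' Fit the model by (stochastic) variational inference
#'
#' @param tensor A `mutopia_tensor`.
#' @param binning The `mutopia_binning` the tensor was built on.
#' @param config A [mutopia_config()] list.
#' @param bins Optional integer vector of bin ids to train on (e.g. the
#'   complement of a held-out chromosome); the fitted topography functions
#'   still evaluate genome-wide.
#' @return A `mutopia_fit`: `model`, `vstate` (`beta`, `phi`, `cells`,
#'   `elbo_trace`), `config`, `converged`, `bins`.
#' @export
fit_mutopia <- function(tensor, binning, config = mutopia_config(),
                        bins = NULL) {
  if (is.null(bins)) bins <- binning$bins$bin_id
  bins <- sort(bins)
  cells <- tensor$cells[tensor$cells$bin %in% bins, , drop = FALSE]
  if (!nrow(cells)) stop("no observed cells on the training bins")
  cells$bin_row <- match(cells$bin, bins)
  Xs <- binning$X[bins, , drop = FALSE]
  ts <- binning$t[bins, , drop = FALSE]
  n_samples <- nrow(tensor$samples)
  model <- .init_model(list(cells = cells), binning, config, bins)
  design <- .build_adjust_design(Xs, ts, binning$feature_class, config)
  state <- list(cells = cells, Xs = Xs, ts = ts,
                feature_class = binning$feature_class, config = config,
                model = model, scale = 1,
                nobs_av = if (is.null(design)) 0 else nrow(design$av),
                design = design, frozen = rep(FALSE, config$K),
                penalty = 0)
  state$logP <- .model_log_topographies(model, Xs, ts)
  logp_cells <- vapply(seq_len(config$K), function(k)
    state$logP[[k]][cbind(cells$bin_row, cells$type)], numeric(nrow(cells)))
  # spectra-only initial E-step (uniform exposures)
  beta0 <- matrix(config$alpha_init, n_samples, config$K)
  es <- e_step(cells, logp_cells, beta0, model$alpha, n_samples,
               inner = config$e_inner, tol = config$e_tol)
  state$phi <- es$phi; state$beta <- es$beta
  trace <- numeric(0)
  full_batch <- config$batch_fraction >= 1
  converged <- FALSE
  set.seed(config$seed + 1L)
  full <- state
  for (epoch in seq_len(config$max_epochs)) {
    if (full_batch) {
      state <- .m_step(state, update_spectra =
                         (epoch %% config$spectra_every) == 0)
      logp_cells <- vapply(seq_len(config$K), function(k)
        state$logP[[k]][cbind(cells$bin_row, cells$type)],
        numeric(nrow(cells)))
      es <- e_step(cells, logp_cells, state$beta, state$model$alpha,
                   n_samples, inner = config$e_inner, tol = config$e_tol)
      state$phi <- es$phi; state$beta <- es$beta
      trace <- c(trace, .elbo_state(state)$elbo)
    } else {
      batch_bins <- sort(sample.int(length(bins),
                                    max(1L, round(config$batch_fraction *
                                                    length(bins)))))
      rho <- (epoch + config$sv_delay)^(-config$sv_kappa)
      bstate <- state
      keep <- cells$bin_row %in% batch_bins
      bcells <- cells[keep, , drop = FALSE]
      bcells$bin_row <- match(bcells$bin_row, batch_bins)
      bstate$cells <- bcells
      bstate$Xs <- Xs[batch_bins, , drop = FALSE]
      bstate$ts <- ts[batch_bins, , drop = FALSE]
      bstate$scale <- length(bins) / length(batch_bins)
      bstate$design <- .build_adjust_design(bstate$Xs, bstate$ts,
                                            binning$feature_class, config)
      bstate$nobs_av <- if (is.null(bstate$design)) 0 else
        nrow(bstate$design$av)
      bstate$logP <- lapply(state$logP, function(P)
        P[batch_bins, , drop = FALSE] -
          log(sum(exp(P[batch_bins, , drop = FALSE][
            is.finite(P[batch_bins, , drop = FALSE])]))))
      blogp <- vapply(seq_len(config$K), function(k)
        bstate$logP[[k]][cbind(bcells$bin_row, bcells$type)],
        numeric(nrow(bcells)))
      es <- e_step(bcells, blogp, state$beta, state$model$alpha, n_samples,
                   inner = config$e_inner, tol = config$e_tol,
                   scale = bstate$scale)
      bstate$phi <- es$phi
      bstate$beta <- (1 - rho) * state$beta + rho * es$beta
      bstate <- .m_step(bstate, update_spectra =
                          (epoch %% config$spectra_every) == 0)
      state$model <- bstate$model
      state$beta <- bstate$beta
      state$logP <- .model_log_topographies(state$model, Xs, ts)
      logp_cells <- vapply(seq_len(config$K), function(k)
        state$logP[[k]][cbind(cells$bin_row, cells$type)],
        numeric(nrow(cells)))
      state$phi <- .softmax_rows(logp_cells +
                                   .elog_pi(state$beta)[cells$sample, ,
                                                        drop = FALSE])
      state$penalty <- bstate$penalty
      trace <- c(trace, .elbo_state(state)$elbo)
    }
    if (full_batch && length(trace) > config$tol_window) {
      recent <- utils::tail(trace, config$tol_window + 1)
      rel <- abs(recent[length(recent)] - recent[1]) /
        (abs(recent[1]) + 1e-12)
      if (rel < config$tol) { converged <- TRUE; break }
    }
  }
  if (!converged && full_batch && config$max_epochs > config$tol_window)
    warning("fit did not converge within max_epochs; returning best state")
  structure(list(model = state$model,
                 vstate = list(beta = state$beta, phi = state$phi,
                               cells = cells, elbo_trace = trace),
                 config = config, converged = converged, bins = bins),
            class = "mutopia_fit")
}

#' @export
print.mutopia_fit <- function(x, ...) {
  cat(sprintf("mutopia fit: K = %d, %d epochs, ELBO %.3f (%s)\n",
              x$model$K, length(x$vstate$elbo_trace),
              utils::tail(x$vstate$elbo_trace, 1),
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Seeded random hyperparameter search
#'
#' Draws configurations uniformly from a discrete search space, fits each on
#' the training chromosomes, and scores held-out pseudo-R2.
#'
#' @param tensor A `mutopia_tensor`.
#' @param binning A `mutopia_binning`.
#' @param search_space Named list of candidate value vectors for
#'   [mutopia_config()] arguments (e.g. `list(K = 2:5)`).
#' @param heldout_chrom Chromosome(s) held out for scoring.
#' @param n_trials Number of sampled configurations.
#' @param seed Integer seed; trial seeds are derived from it and logged.
#' @param base_config Baseline config the sampled values overwrite.
#' @return data.frame of trials (sampled values, trial seed, pseudo-R2),
#'   sorted best-first.
#' @export
random_search <- function(tensor, binning, search_space, heldout_chrom,
                          n_trials = 5, seed = 1,
                          base_config = mutopia_config()) {
  if (!length(search_space)) stop("empty search space")
  set.seed(seed)
  picks <- lapply(seq_len(n_trials), function(i)
    lapply(search_space, function(v) v[[sample.int(length(v), 1)]]))
  trial_seeds <- sample.int(.Machine$integer.max %/% 2, n_trials)
  rows <- lapply(seq_len(n_trials), function(i) {
    cfg <- utils::modifyList(base_config, picks[[i]])
    cfg$seed <- trial_seeds[i]
    ev <- evaluate_heldout(tensor, binning, cfg, heldout_chrom)
    data.frame(trial = i, as.data.frame(picks[[i]]), seed = trial_seeds[i],
               pseudo_r2 = ev$report$pseudo_r2)
  })
  out <- do.call(rbind, rows)
  out[order(-out$pseudo_r2), , drop = FALSE]
}
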