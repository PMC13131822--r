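test_that("E-step reduces to closed forms in degenerate cases", {
  # K = 1: all responsibility on the single process, beta = alpha + burden
  cells <- data.frame(sample = c(1L, 1L, 2L), weight = c(0.5, 1.5, 2))
  logp <- matrix(log(0.1), 3, 1)
  es <- e_step(cells, logp, beta = matrix(1, 2, 1), alpha = 1,
               n_samples = 2)
  expect_true(all(es$phi == 1))
  expect_equal(as.numeric(es$beta), c(1 + 2, 1 + 2))
  # identical topographies + symmetric prior: responsibilities are 1/2
  logp2 <- cbind(logp, logp)
  es2 <- e_step(cells, logp2, beta = matrix(1, 2, 2), alpha = c(1, 1),
                n_samples = 2)
  expect_true(all(abs(es2$phi - 0.5) < 1e-12))
})

test_that("a single E-step iteration matches the hand-executed update", {
  cells <- data.frame(sample = c(1L, 2L), weight = c(2, 3))
  logp <- matrix(log(c(0.2, 0.1, 0.05, 0.4)), 2, 2)
  beta0 <- matrix(c(1.5, 0.5, 2.0, 1.0), 2, 2)
  alpha <- c(0.7, 0.3)
  es <- e_step(cells, logp, beta0, alpha, n_samples = 2, inner = 1)
  # hand update: phi propto exp(digamma(beta) - digamma(sum beta)) * p
  elog <- digamma(beta0) - digamma(rowSums(beta0))
  a <- exp(logp + elog)
  phi_hand <- a / rowSums(a)
  expect_equal(es$phi, phi_hand, tolerance = 1e-12)
  beta_hand <- rbind(alpha + cells$weight[1] * phi_hand[1, ],
                     alpha + cells$weight[2] * phi_hand[2, ])
  expect_equal(unname(es$beta), unname(beta_hand), tolerance = 1e-12)
})

test_that("a converged E-step is a fixed point", {
  co <- get_cohort(); toy <- get_toy(); ref <- get_ref()
  cells <- co$tensor$cells
  logp <- vapply(ref$model$processes, function(p) {
    P <- topography_distribution(p, toy$binning$X, toy$binning$t)
    log(P[cbind(cells$bin, cells$type)])
  }, numeric(nrow(cells)))
  N <- nrow(co$tensor$samples)
  es1 <- e_step(cells, logp, matrix(1, N, 4), ref$model$alpha, N,
                inner = 500, tol = 1e-12)
  es2 <- e_step(cells, logp, es1$beta, ref$model$alpha, N)
  expect_equal(es2$beta, es1$beta, tolerance = 1e-8)
  expect_equal(es2$phi, es1$phi, tolerance = 1e-8)
  # responsibilities and exposures stay on the simplex
  expect_equal(rowSums(es1$phi), rep(1, nrow(cells)), tolerance = 1e-12)
})

test_that("the ELBO is additive over samples and invariant to cell order", {
  co <- get_cohort(); toy <- get_toy(); ref <- get_ref()
  model2 <- model_state(ref$model$processes[1:2], alpha = c(1, 1),
                        feature_class = toy$binning$feature_class)
  tensor <- co$tensor
  cells <- tensor$cells
  logp <- vapply(model2$processes, function(p) {
    P <- topography_distribution(p, toy$binning$X, toy$binning$t)
    log(P[cbind(cells$bin, cells$type)])
  }, numeric(nrow(cells)))
  N <- nrow(tensor$samples)
  es <- e_step(cells, logp, matrix(1, N, 2), model2$alpha, N)
  e1 <- elbo(tensor, model2, toy$binning, es)
  # duplicate every sample
  cells2 <- cells; cells2$sample <- cells2$sample + N
  tensor2 <- tensor
  tensor2$cells <- rbind(cells, cells2)
  tensor2$samples <- rbind(tensor$samples, tensor$samples)
  es2 <- list(phi = rbind(es$phi, es$phi), beta = rbind(es$beta, es$beta))
  expect_equal(elbo(tensor2, model2, toy$binning, es2), 2 * e1,
               tolerance = 1e-8)
  # permutation invariance
  set.seed(3)
  ord <- sample.int(nrow(cells))
  tensor3 <- tensor; tensor3$cells <- cells[ord, ]
  es3 <- list(phi = es$phi[ord, ], beta = es$beta)
  expect_equal(elbo(tensor3, model2, toy$binning, es3), e1,
               tolerance = 1e-10)
})

test_that("the K=1 ELBO attains the closed-form log marginal", {
  co <- get_cohort(); toy <- get_toy(); ref <- get_ref()
  model1 <- model_state(ref$model$processes[1], alpha = 2)
  cells <- co$tensor$cells
  P <- topography_distribution(model1$processes[[1]], toy$binning$X,
                               toy$binning$t)
  logp <- matrix(log(P[cbind(cells$bin, cells$type)]), ncol = 1)
  N <- nrow(co$tensor$samples)
  es <- e_step(cells, logp, matrix(2, N, 1), model1$alpha, N)
  log_marginal <- sum(cells$weight * logp)   # pi is degenerate at 1
  e <- elbo(co$tensor, model1, toy$binning, es)
  expect_lte(e, log_marginal + 1e-8)
  expect_equal(e, log_marginal, tolerance = 1e-8)
})

test_that("boosted trees recover a step-function rate map", {
  toy <- get_toy()
  base <- log(rep(1 / 192, 192))
  proc <- process_topography(
    macro_effect("custom", features = "repli",
                 fun = function(X) 2 * (X[, "repli"] > 0.5)),
    spectra_effect(baseline = base), label = "step")
  ref <- list(model = model_state(list(proc), alpha = 1,
                                  feature_class = toy$binning$feature_class),
              ref_exposures = matrix(1, 1, 1), ref_burdens = 20000L)
  sim <- simulate_cohort(ref, toy$binning, toy$genome, n_samples = 1,
                         gamma = 1, seed = 13)
  ann <- annotate_mutations(sim$mutations, toy$binning, toy$genome)
  tensor <- build_count_tensor(ann, toy$binning, sim$samples)
  cfg <- mutopia_config(K = 1, max_epochs = 6, spectra_adjust = FALSE,
                        seed = 2)
  fit <- fit_mutopia(tensor, toy$binning, cfg)
  truth <- marginal_genomic(proc, toy$binning$X, toy$binning$t)
  est <- marginal_genomic(fit$model$processes[[1]], toy$binning$X,
                          toy$binning$t)
  expect_gt(poisson_pseudo_r2(truth * 20000, est), 0.8)
})

test_that("full-batch coordinate ascent is monotone and deterministic", {
  fit <- get_fit()
  tr <- fit$vstate$elbo_trace
  expect_true(all(diff(tr) >= -1e-6 * pmax(abs(tr[-length(tr)]), 1)))
  co <- get_cohort(); toy <- get_toy()
  cfg <- mutopia_config(K = 2, max_epochs = 3, seed = 17)
  f1 <- fit_mutopia(co$tensor, toy$binning, cfg)
  f2 <- fit_mutopia(co$tensor, toy$binning, cfg)
  expect_identical(f1$vstate$elbo_trace, f2$vstate$elbo_trace)
  expect_identical(f1$vstate$beta, f2$vstate$beta)
})

test_that("stochastic bin subsampling improves the ELBO reproducibly", {
  co <- get_cohort(); toy <- get_toy()
  cfg <- mutopia_config(K = 2, max_epochs = 4, batch_fraction = 0.5,
                        spectra_every = 2, seed = 23)
  f1 <- fit_mutopia(co$tensor, toy$binning, cfg)
  f2 <- fit_mutopia(co$tensor, toy$binning, cfg)
  expect_identical(f1$vstate$elbo_trace, f2$vstate$elbo_trace)
  expect_true(all(is.finite(f1$vstate$elbo_trace)))
  expect_gt(utils::tail(f1$vstate$elbo_trace, 1),
            f1$vstate$elbo_trace[1] - 1e-6)
})

test_that("a large l1 penalty shrinks every spectrum adjustment to zero", {
  co <- get_cohort(); toy <- get_toy()
  cfg <- mutopia_config(K = 2, max_epochs = 4, l1_penalty = 50, seed = 29)
  fit <- fit_mutopia(co$tensor, toy$binning, cfg)
  for (p in fit$model$processes) {
    if (!is.null(p$spectra$meso_coef))
      expect_true(all(p$spectra$meso_coef == 0))
    if (!is.null(p$spectra$strand_dev))
      expect_true(all(p$spectra$strand_dev == 0))
    if (!is.null(p$spectra$strand_uniform))
      expect_true(all(p$spectra$strand_uniform == 0))
  }
})

test_that("a process with no attributed mass is frozen with a warning", {
  toy <- get_toy(); co <- get_cohort(); ref <- get_ref()
  cfg <- mutopia_config(K = 2, seed = 1)
  cells <- co$tensor$cells
  cells$bin_row <- cells$bin
  model2 <- model_state(ref$model$processes[1:2], alpha = c(1, 1),
                        feature_class = toy$binning$feature_class)
  logP <- lapply(model2$processes, function(p)
    log(topography_distribution(p, toy$binning$X, toy$binning$t)))
  state <- list(cells = cells, Xs = toy$binning$X, ts = toy$binning$t,
                feature_class = toy$binning$feature_class, config = cfg,
                model = model2, scale = 1, nobs_av = 0, design = NULL,
                frozen = c(FALSE, FALSE), penalty = 0, logP = logP,
                phi = cbind(rep(1, nrow(cells)), 0),
                beta = matrix(1, nrow(co$tensor$samples), 2))
  expect_warning(out <- mutopia:::.m_step(state), "frozen")
  expect_identical(out$model$processes[[2]], model2$processes[[2]])
  expect_true(out$frozen[2])
})

test_that("random search is seeded, reproducible, and scores trials", {
  co <- get_cohort(); toy <- get_toy()
  base <- mutopia_config(K = 2, max_epochs = 3, spectra_adjust = FALSE,
                         tree_nrounds = 15)
  r1 <- random_search(co$tensor, toy$binning, list(K = list(2L)),
                      heldout_chrom = "chr2", n_trials = 1, seed = 31,
                      base_config = base)
  r2 <- random_search(co$tensor, toy$binning, list(K = list(2L)),
                      heldout_chrom = "chr2", n_trials = 1, seed = 31,
                      base_config = base)
  expect_identical(r1, r2)
  expect_equal(r1$K, 2L)
  expect_true(is.finite(r1$pseudo_r2))
  expect_error(random_search(co$tensor, toy$binning, list(),
                             "chr2"), "empty")
})
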