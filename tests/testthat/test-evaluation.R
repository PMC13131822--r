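make_eval_cells <- function(seed = 1, n_samples = 4, n_bins = 12) {
  set.seed(seed)
  t_av <- matrix(rpois(n_bins * 192, 20) + 1, n_bins, 192)
  cells <- do.call(rbind, lapply(seq_len(n_samples), function(n) {
    m <- 25
    data.frame(sample = n, bin = sample.int(n_bins, m, replace = TRUE),
               type = sample.int(192, m, replace = TRUE),
               weight = runif(m, 0.2, 2))
  }))
  key <- paste(cells$sample, cells$bin, cells$type)
  cells <- cells[!duplicated(key), ]
  list(cells = cells, t = t_av, n = n_samples)
}

test_that("pseudo-R2 anchors the null at 0 and the saturated model at 1", {
  d <- make_eval_cells()
  logt <- log(d$t) - log(sum(d$t))
  null_pred <- function(n) logt
  expect_equal(pseudo_r2(d$cells, null_pred, d$t, d$n)$pseudo_r2, 0)
  sat_pred <- function(n) {
    cn <- d$cells[d$cells$sample == n, ]
    lp <- matrix(-Inf, nrow(d$t), 192)
    lp[cbind(cn$bin, cn$type)] <- log(cn$weight / sum(cn$weight))
    lp
  }
  expect_equal(pseudo_r2(d$cells, sat_pred, d$t, d$n)$pseudo_r2, 1)
})

test_that("pseudo-R2 interpolates linearly in the score", {
  d <- make_eval_cells(seed = 2)
  logt <- log(d$t) - log(sum(d$t))
  rep0 <- pseudo_r2(d$cells, function(n) logt, d$t, d$n)
  # a prediction whose score is the S0/S1 midpoint scores 0.5
  mid_pred <- function(n) {
    cn <- d$cells[d$cells$sample == n, ]
    sat <- matrix(-Inf, nrow(d$t), 192)
    sat[cbind(cn$bin, cn$type)] <- log(cn$weight / sum(cn$weight))
    (sat + logt) / 2
  }
  expect_equal(pseudo_r2(d$cells, mid_pred, d$t, d$n)$pseudo_r2, 0.5,
               tolerance = 1e-12)
  expect_lte(rep0$S0, rep0$S1)
})

test_that("degenerate held-out data is rejected", {
  # one sample, one cell: the empirical and null scores coincide only if
  # availability is concentrated on that cell
  cells <- data.frame(sample = 1L, bin = 1L, type = 1L, weight = 2)
  t1 <- matrix(0, 1, 192); t1[1, 1] <- 5
  expect_error(pseudo_r2(cells, function(n) log(t1 / sum(t1)), t1, 1),
               "degenerate")
})

test_that("Poisson pseudo-R2 agrees with the family deviance", {
  expect_equal(poisson_pseudo_r2(c(2, 5, 3), c(2, 5, 3)), 1)
  expect_equal(poisson_pseudo_r2(rep(4, 6), rep(1, 6)), 1)  # both uniform
  obs <- c(2, 5, 3); pred <- c(1, 1, 2)
  # independent oracle: deviance residuals from the stats Poisson family
  mu <- pred / sum(pred) * sum(obs)
  mu0 <- rep(mean(obs), 3)
  dr <- function(m) sum(poisson()$dev.resids(obs, m, rep(1, 3)))
  expect_equal(poisson_pseudo_r2(obs, pred), 1 - dr(mu) / dr(mu0),
               tolerance = 1e-12)
  expect_error(poisson_pseudo_r2(c(0, 0), c(1, 1)), "zero observed")
})

test_that("quantile groups partition the genome into equal-bp groups", {
  toy <- get_toy()
  g <- quantile_groups(toy$binning, "repli", 8)
  expect_setequal(unique(g), 1:8)
  bp <- tapply(toy$binning$bins$length_bp, g, sum)
  expect_lt(max(bp) / min(bp), 1.3)
  expect_equal(sum(bp), sum(toy$binning$genome_lengths))
  # ordering: group means increase with the feature
  means <- tapply(toy$binning$X[, "repli"], g, mean)
  expect_true(all(diff(means) > 0))
})

test_that("NNLS and model contributions agree on a single-process model", {
  toy <- get_toy(); ref <- get_ref(); co <- get_cohort()
  model1 <- model_state(ref$model$processes[1], alpha = 1)
  vs <- list(beta = matrix(5, nrow(co$tensor$samples), 1))
  g <- quantile_groups(toy$binning, "repli", 3)
  out <- nnls_validation(model1, vs, co$tensor, toy$binning, g)
  expect_true(all(out$model_contrib == 1))
  expect_true(all(out$nnls_contrib[!out$skipped] == 1))
})

test_that("empty groups are skipped and flagged", {
  toy <- get_toy(); ref <- get_ref(); co <- get_cohort()
  tensor <- co$tensor
  # restrict observed cells to bins of group 1 so other groups are empty
  g <- quantile_groups(toy$binning, "repli", 2)
  keep_bins <- toy$binning$bins$bin_id[g == 1]
  tensor$cells <- tensor$cells[tensor$cells$bin %in% keep_bins, ]
  out <- nnls_validation(ref$model, list(beta = matrix(
    1, nrow(tensor$samples), 4)), tensor, toy$binning, g)
  expect_true(all(out$skipped[out$group == 2]))
  expect_true(all(is.na(out$nnls_contrib[out$group == 2])))
})

test_that("the ablation suite scores all variants on identical folds", {
  toy <- get_toy(); co <- get_cohort()
  cfg <- mutopia_config(K = 2, max_epochs = 4, tree_nrounds = 20,
                        spectra_every = 2, seed = 11)
  tab <- ablation_suite(co$tensor, toy$binning, cfg, "chr2")
  expect_setequal(tab$variant, c("full", "linear", "lda", "locus_only"))
  expect_true(all(is.finite(tab$pseudo_r2)))
  expect_true(all(tab$pseudo_r2 <= 1))
  expect_equal(tab$K[tab$variant == "locus_only"], 1L)
})

test_that("the LDA ablation is availability-proportional within channels", {
  toy <- get_toy()
  base <- log(runif(192, 0.5, 2))
  proc <- process_topography(macro_effect("constant"),
                             spectra_effect(baseline = base), "lda")
  P <- topography_distribution(proc, toy$binning$X, toy$binning$t)
  for (m in c(1, 50, 150)) {
    col <- P[, m]
    tcol <- toy$binning$t[, m]
    if (sum(tcol) == 0) next
    expect_equal(col / sum(col), tcol / sum(tcol), tolerance = 1e-12)
  }
})
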