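test_that("exposures are Dirichlet posterior means", {
  expect_equal(process_contributions(list(beta = matrix(5, 3, 1))),
               matrix(1, 3, 1))
  expect_equal(as.numeric(process_contributions(
    list(beta = matrix(c(2, 2), 1)))), c(0.5, 0.5))
  expect_equal(as.numeric(process_contributions(
    list(beta = matrix(c(3, 1), 1)))), c(0.75, 0.25))
})

test_that("sample topographies are convex mixtures of process tables", {
  toy <- get_toy(); ref <- get_ref()
  X <- toy$binning$X; t <- toy$binning$t
  # single process
  P1 <- topography_distribution(ref$model$processes[[1]], X, t)
  expect_equal(sample_topography(ref$model, c(1, 0, 0, 0), X, t), P1)
  # hand mixture against brute force
  expo <- c(0.3, 0.2, 0.4, 0.1)
  mix <- sample_topography(ref$model, expo, X, t)
  brute <- 0
  for (k in 1:4)
    brute <- brute + expo[k] *
      topography_distribution(ref$model$processes[[k]], X, t)
  expect_equal(mix, brute, tolerance = 1e-12)
  expect_equal(sum(mix), 1, tolerance = 1e-10)
})

test_that("cohort rate and spectra match the brute-force double sum", {
  toy <- get_toy(); co <- get_cohort(); fit <- get_fit()
  crs <- cohort_rate_and_spectra(fit$model, fit, co$tensor, toy$binning)
  expect_equal(sum(crs$rate), 1, tolerance = 1e-10)
  # brute force: explicit sum over samples and processes
  pi_hat <- process_contributions(fit)
  burd <- tapply(co$tensor$cells$weight, co$tensor$cells$sample, sum)
  pn <- as.numeric(burd[as.character(seq_len(nrow(pi_hat)))])
  pn <- pn / sum(pn)
  joint <- 0
  for (n in seq_len(nrow(pi_hat)))
    for (k in seq_len(fit$model$K))
      joint <- joint + pn[n] * pi_hat[n, k] *
        topography_distribution(fit$model$processes[[k]], toy$binning$X,
                                toy$binning$t)
  expect_equal(crs$rate, rowSums(joint), tolerance = 1e-10)
  rs <- rowSums(joint)
  expect_equal(crs$spectra[rs > 0, ], (joint / rs)[rs > 0, ],
               tolerance = 1e-10)
  # per-bin spectra live on the simplex wherever rate is positive
  expect_equal(unname(rowSums(crs$spectra[rs > 0, ])),
               rep(1, sum(rs > 0)), tolerance = 1e-8)
})

test_that("tree attributions are locally accurate and find the used feature", {
  # two independent features; the response uses only the first
  set.seed(6)
  X <- cbind(a = runif(1200), b = runif(1200))
  y <- rpois(1200, exp(1 + 2 * X[, "a"]))
  dm <- xgboost::xgb.DMatrix(X, label = y)
  bst <- xgboost::xgb.train(params = list(objective = "count:poisson",
                                          max_depth = 3, eta = 0.3,
                                          nthread = 1),
                            data = dm, nrounds = 40, verbose = 0)
  proc <- process_topography(
    macro_effect("boosted_trees", features = c("a", "b"), model = bst),
    spectra_effect(), label = "p")
  model <- model_state(list(proc), alpha = 1)
  sh <- explain_features(model, X)
  # local accuracy: contributions plus baseline reproduce f(X)
  V <- sh$values[[1]]
  f <- macro_values(proc$macro, X)
  expect_equal(unname(rowSums(V[, c("a", "b")]) + attr(V, "baseline")),
               unname(f), tolerance = 1e-5)
  # monotone single-feature dependence: matching sign, dominant impact
  expect_gt(sh$directionality[1, "a"], 0.9)
  expect_gt(sh$impact[1, "a"], 5 * sh$impact[1, "b"])
})

test_that("constant and linear effects attribute exactly", {
  toy <- get_toy()
  X <- toy$binning$X
  const <- model_state(list(process_topography(macro_effect("constant"),
                                               spectra_effect())), 1)
  sh0 <- explain_features(const, X)
  expect_true(all(sh0$impact == 0))
  expect_true(all(sh0$directionality == 0))
  lin <- model_state(list(process_topography(
    macro_effect("linear", features = "repli", coef = c(repli = -1.5)),
    spectra_effect())), 1)
  shl <- explain_features(lin, X)
  expect_equal(unname(shl$directionality[1, "repli"]), -1,
               tolerance = 1e-12)
  expect_equal(unname(shl$values[[1]][, "repli"]),
               unname(-1.5 * (X[, "repli"] - mean(X[, "repli"]))),
               tolerance = 1e-12)
})

test_that("output tables round-trip through the tidy writers", {
  dir <- withr::local_tempdir()
  toy <- get_toy(); co <- get_cohort(); fit <- get_fit()
  write_outputs(fit, co$tensor, toy$binning, dir)
  expo <- read.table(file.path(dir, "exposures.tsv"), sep = "\t",
                     header = TRUE, check.names = FALSE)
  expect_equal(nrow(expo), nrow(co$tensor$samples))
  expect_equal(unname(rowSums(expo[, -1])), rep(1, nrow(expo)),
               tolerance = 1e-6)
  rate <- read.table(file.path(dir, "rate_profile.tsv"), sep = "\t",
                     header = TRUE)
  expect_equal(sum(rate$rate), 1, tolerance = 1e-6)
  att <- jsonlite::read_json(file.path(dir, "attributions.json"))
  expect_true(all(c("features", "impact", "directionality") %in%
                    names(att)))
})
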