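# Cohort simulation from a reference model, and the recovery benchmark.
#
# Synthetic samples resample (exposure, burden) pairs from a reference set,
# preserving realistic covariance between process activity and burden; each
# mutation picks a process, a (bin, channel) cell from that process's
# topography, and a uniformly chosen context-compatible genomic position,
# so ingestion is exercised end to end.

.rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  g <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n)), n, K)
  g / rowSums(g)
}

#' Toy reference model for simulation and fixtures
#'
#' Builds a synthetic reference with distinctive sparse spectra (each
#' process concentrated on one substitution class), nonlinear macro-scale
#' feature responses (steps, saturating and interaction terms on the macro
#' features), modest strand and meso spectrum adjustments, and a reference
#' set of correlated exposures with lognormal burdens. This synthetic
#' reference stands in for a tumor-cohort-trained model at desk scale.
#'
#' @param binning A `mutopia_binning` whose features include at least two
#'   macro features.
#' @param K Number of processes (default 7).
#' @param n_ref Size of the reference exposure set (default 200).
#' @param mean_burden Median reference per-sample burden (default 500).
#' @param seed Seed.
#' @return List: `model` (`mutopia_model`), `ref_exposures` (n_ref x K),
#'   `ref_burdens` (length n_ref).
#' @export
toy_reference_model <- function(binning, K = 7, n_ref = 200,
                                mean_burden = 500, seed = 1) {
  set.seed(seed)
  fc <- binning$feature_class
  macro <- names(fc)[fc == "macro"]
  strand <- names(fc)[fc == "strand"]
  meso <- names(fc)[fc == "meso"]
  stopifnot(length(macro) >= 2)
  m1 <- macro[1]; m2 <- macro[2]
  # nonlinear responses first so that tree-based and linear rate models
  # separate on simulated data
  shapes <- list(
    function(X) 2.2 * (X[, m1] > 0.6),
    function(X) -6.0 * abs(X[, m1] - 0.5),
    function(X) 2.5 * X[, m1] * X[, m2],
    function(X) 1.5 * tanh(6 * (X[, m2] - 0.5)) - 1.0 * (X[, m1] < 0.3),
    function(X) 1.8 * X[, m1],
    function(X) -1.8 * X[, m1] + 1.2 * X[, m2],
    function(X) 1.2 * cos(2 * pi * X[, m1]))
  processes <- vector("list", K)
  for (k in seq_len(K)) {
    home <- ((k - 1) %% 6) + 1           # dominant substitution class
    idx <- (home - 1) * 16 + 1:16
    w <- stats::rexp(192) * 0.03
    w[c(idx, idx + 96)] <- w[c(idx, idx + 96)] + stats::rexp(32)
    # sharpen a context preference for extra separation
    pref <- sample.int(16, 4)
    w[c(idx[pref], idx[pref] + 96)] <- w[c(idx[pref], idx[pref] + 96)] * 4
    baseline <- log(w / sum(w))
    su <- NULL; sd_ <- NULL
    if (length(strand)) {
      sf <- strand[((k - 1) %% length(strand)) + 1]
      su <- stats::setNames((-1)^k * stats::runif(1, 0.2, 0.5), sf)
    }
    mc <- NULL
    if (length(meso) && k %% 3 == 0) {
      mc <- matrix(0, 1, 192, dimnames = list(meso[1], NULL))
      mc[1, sample.int(192, 8)] <- stats::runif(8, -0.6, 0.6)
    }
    mfun <- shapes[[((k - 1) %% length(shapes)) + 1]]
    processes[[k]] <- process_topography(
      macro_effect("custom", features = c(m1, m2), fun = mfun),
      spectra_effect(baseline = baseline, meso_coef = mc,
                     strand_uniform = su, strand_dev = sd_),
      label = paste0("R", k))
  }
  model <- model_state(processes, alpha = rep(0.5, K), feature_class = fc)
  # archetype-structured reference exposures: correlated process activity
  n_arch <- min(3, K)
  arch <- .rdirichlet(n_arch, rep(0.8, K)) * 8
  which_arch <- sample.int(n_arch, n_ref, replace = TRUE)
  ref_exposures <- t(vapply(which_arch, function(a)
    .rdirichlet(1, arch[a, ] + 0.05)[1, ], numeric(K)))
  ref_burdens <- pmax(20L, as.integer(round(
    stats::rlnorm(n_ref, log(mean_burden), 0.4))))
  list(model = model, ref_exposures = ref_exposures,
       ref_burdens = ref_burdens)
}

# position index: for each (bin, trinucleotide) the 0-based genomic
# positions providing that context
.context_site_index <- function(binning, genome) {
  genome <- .as_genome(genome)
  env <- new.env(parent = emptyenv())
  for (ch in names(binning$genome_lengths)) {
    L <- binning$genome_lengths[[ch]]
    if (L < 3) next
    chars <- strsplit(as.character(genome[[ch]]), "")[[1]]
    code <- match(chars, MUT_BASES)
    i <- 2:(L - 1)
    tri <- 16L * (code[i - 1] - 1L) + 4L * (code[i] - 1L) + code[i + 1]
    ok <- !is.na(tri)
    pos0 <- (i - 1L)[ok]
    tri <- tri[ok]
    segs <- binning$segments[binning$segments$chrom == ch, , drop = FALSE]
    segs <- segs[order(segs$start), , drop = FALSE]
    bin <- segs$bin_id[findInterval(pos0, segs$start)]
    key <- paste0(bin, "_", tri)
    sp <- split(pos0, key)
    for (k in names(sp)) assign(k, sp[[k]], envir = env)
  }
  # map channel -> trinucleotide code (1..64, alphabetical)
  tri_of_type <- apply(.tri_to_type, 2, function(col) which(col == 1))
  tri_code <- match(.tri_names, .tri_names)  # identity; codes follow order
  list(sites = env, tri_of_type = as.integer(tri_of_type))
}

.type_ref_alt <- local({
  ref <- substr(.type_table$sub, 1, 1)
  alt <- substr(.type_table$sub, 3, 3)
  minus <- .type_table$orient == "-"
  ref[minus] <- MUT_COMPLEMENT[ref[minus]]
  alt[minus] <- MUT_COMPLEMENT[alt[minus]]
  data.frame(ref = ref, alt = alt)
})

#' Simulate a synthetic tumor cohort
#'
#' @param reference Output of [toy_reference_model()] (or a list with
#'   `model`, `ref_exposures`, `ref_burdens`).
#' @param binning,genome The genome binning and sequence to place mutations
#'   on.
#' @param n_samples Number of synthetic samples.
#' @param gamma Burden scale: sample `n` receives
#'   `Poisson(gamma * M_ref)` mutations, with `(pi, M_ref)` resampled
#'   jointly from the reference set.
#' @param seed Seed.
#' @param purity_range Per-sample purity drawn uniformly from this range.
#' @param vaf_conc Beta concentration of simulated VAFs around the
#'   diploid-heterozygous mean `purity / 2`.
#' @param site_index Optional precomputed [.context_site_index] result to
#'   reuse across calls.
#' @return List: `mutations` (sample, chrom, pos, ref, alt, vaf),
#'   `samples` (sample_id, purity), `truth` (exposures, process counts,
#'   gamma, seed).
#' @export
simulate_cohort <- function(reference, binning, genome, n_samples = 100,
                            gamma = 1, seed = 1, purity_range = c(0.6, 1),
                            vaf_conc = 30, site_index = NULL) {
  stopifnot(gamma > 0, n_samples >= 1)
  set.seed(seed)
  model <- reference$model
  K <- model$K
  if (is.null(site_index))
    site_index <- .context_site_index(binning, genome)
  P <- lapply(model$processes, function(p)
    topography_distribution(p, binning$X, binning$t))
  Pflat <- lapply(P, function(p) {
    nz <- which(p > 0)
    list(idx = nz, prob = p[nz],
         bin = binning$bins$bin_id[(nz - 1) %% nrow(p) + 1],
         type = (nz - 1) %/% nrow(p) + 1)
  })
  pick <- sample.int(nrow(reference$ref_exposures), n_samples,
                     replace = TRUE)
  exposures <- reference$ref_exposures[pick, , drop = FALSE]
  burdens <- stats::rpois(n_samples, gamma * reference$ref_burdens[pick])
  purity <- stats::runif(n_samples, purity_range[1], purity_range[2])
  ids <- sprintf("S%04d", seq_len(n_samples))
  bins_tbl <- binning$bins
  chrom_of_bin <- stats::setNames(bins_tbl$chrom, bins_tbl$bin_id)
  rows <- vector("list", n_samples)
  proc_counts <- matrix(0L, n_samples, K)
  for (n in seq_len(n_samples)) {
    M <- burdens[n]
    if (M == 0) next
    z <- stats::rmultinom(1, M, exposures[n, ])[, 1]
    proc_counts[n, ] <- z
    parts <- list()
    for (k in which(z > 0)) {
      fl <- Pflat[[k]]
      draw <- sample.int(length(fl$prob), z[k], replace = TRUE,
                         prob = fl$prob)
      bin <- fl$bin[draw]; type <- fl$type[draw]
      tri <- site_index$tri_of_type[type]
      pos <- vapply(seq_along(draw), function(i) {
        sites <- get(paste0(bin[i], "_", tri[i]), envir = site_index$sites)
        sites[sample.int(length(sites), 1)]
      }, numeric(1))
      parts[[length(parts) + 1L]] <- data.frame(
        sample = ids[n], chrom = unname(chrom_of_bin[as.character(bin)]),
        pos = as.integer(pos), ref = .type_ref_alt$ref[type],
        alt = .type_ref_alt$alt[type], stringsAsFactors = FALSE)
    }
    rows[[n]] <- do.call(rbind, parts)
  }
  mutations <- do.call(rbind, rows)
  mu <- purity / 2
  a <- vaf_conc * mu; b <- vaf_conc * (1 - mu)
  smp_idx <- match(mutations$sample, ids)
  mutations$vaf <- stats::rbeta(nrow(mutations), a[smp_idx], b[smp_idx])
  mutations <- mutations[order(mutations$sample, mutations$chrom,
                               mutations$pos), , drop = FALSE]
  rownames(mutations) <- NULL
  list(mutations = mutations,
       samples = data.frame(sample_id = ids, purity = purity,
                            stringsAsFactors = FALSE),
       truth = list(exposures = exposures, process_counts = proc_counts,
                    gamma = gamma, seed = seed))
}

#' Recovery benchmark over a burden / cohort-size grid
#'
#' For each grid cell, simulates a cohort, ingests it, fits `replicates`
#' models with `k_fit` processes, keeps the best replicate by training
#' pseudo-R2, matches fitted to reference components on spectra cosine
#' (exact assignment), and reports per-component spectra cosine and Poisson
#' pseudo-R2 between matched genomic rate profiles.
#'
#' @param reference Output of [toy_reference_model()].
#' @param binning,genome Data context.
#' @param grid data.frame with columns `n_samples`, `gamma`.
#' @param k_fit Number of processes to fit (typically the true K).
#' @param replicates Replicate fits per cell (default 3).
#' @param seed Seed; per-cell and per-replicate seeds are derived from it.
#' @param config Base [mutopia_config()] (K is overridden by `k_fit`).
#' @return data.frame (n_samples, gamma, replicate, process, cosine,
#'   rate_r2) for the best replicate of each cell.
#' @export
recovery_benchmark <- function(reference, binning, genome, grid,
                               k_fit = reference$model$K, replicates = 3,
                               seed = 1, config = mutopia_config()) {
  site_index <- .context_site_index(binning, genome)
  ref_spectra <- vapply(reference$model$processes, function(p)
    marginal_spectrum(p, binning$X, binning$t), numeric(192))
  ref_profiles <- vapply(reference$model$processes, function(p)
    marginal_genomic(p, binning$X, binning$t), numeric(nrow(binning$X)))
  out <- list()
  for (g in seq_len(nrow(grid))) {
    cell_seed <- seed + 1000L * g
    sim <- simulate_cohort(reference, binning, genome,
                           n_samples = grid$n_samples[g],
                           gamma = grid$gamma[g], seed = cell_seed,
                           site_index = site_index)
    ann <- sim$mutations
    ann <- annotate_mutations(ann, binning, genome)
    tensor <- build_count_tensor(ann, binning, sim$samples)
    best <- NULL; best_r2 <- -Inf; best_rep <- NA_integer_
    for (r in seq_len(replicates)) {
      cfg <- utils::modifyList(config,
                               list(K = as.integer(k_fit),
                                    seed = cell_seed + r))
      fit <- fit_mutopia(tensor, binning, cfg)
      rep_r2 <- .score_heldout(fit$model, process_contributions(fit),
                               tensor, binning,
                               binning$bins$bin_id)$pseudo_r2
      if (rep_r2 > best_r2) { best <- fit; best_r2 <- rep_r2; best_rep <- r }
    }
    fit_spectra <- vapply(best$model$processes, function(p)
      marginal_spectrum(p, binning$X, binning$t), numeric(192))
    fit_profiles <- vapply(best$model$processes, function(p)
      marginal_genomic(p, binning$X, binning$t),
      numeric(nrow(binning$X)))
    simMat <- matrix(0, reference$model$K, k_fit)
    for (i in seq_len(reference$model$K))
      for (j in seq_len(k_fit))
        simMat[i, j] <- cosine_similarity(ref_spectra[, i], fit_spectra[, j])
    assign <- .match_components(simMat)
    n_mut_k <- colSums(sim$truth$process_counts)
    for (i in seq_len(reference$model$K)) {
      j <- assign[i]
      obs <- ref_profiles[, i] * max(n_mut_k[i], 1)
      out[[length(out) + 1L]] <- data.frame(
        n_samples = grid$n_samples[g], gamma = grid$gamma[g],
        replicate = best_rep, process = i,
        cosine = simMat[i, j],
        rate_r2 = poisson_pseudo_r2(obs, fit_profiles[, j]))
    }
  }
  do.call(rbind, out)
}
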