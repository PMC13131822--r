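# Goodness of fit, ablations, and NNLS validation.
#
# The pseudo-R2 normalizes a model's multinomial held-out log-likelihood
# between a null model proportional to context availability (score S0 -> 0)
# and the saturated empirical distribution (score S1 -> 1).

#' Multinomial pseudo-R2 of per-sample predictions
#'
#' For held-out counts `Y` and per-sample predicted distributions
#' `p_hat(b, m | n)`, the score is `S = sum Y log p_hat`; the metric is
#' `1 - (S1 - S) / (S1 - S0)` with `S0` from the availability-proportional
#' null and `S1` from the per-sample empirical distribution. Cells with
#' `Y = 0` contribute nothing.
#'
#' @param cells Held-out tensor cells (`sample`, `bin`, `type`, `weight`)
#'   with `bin` indexing rows of `availability`.
#' @param log_pred Function `(sample_index) -> matrix (bins x 192)` of
#'   log-probabilities normalized over the held-out cells, or a
#'   precomputed list of such matrices indexed by sample.
#' @param availability Availability matrix over the held-out bins.
#' @param n_samples Number of samples.
#' @return A `PseudoR2Report` list: `S`, `S0`, `S1`, `pseudo_r2`.
#' @export
pseudo_r2 <- function(cells, log_pred, availability, n_samples) {
  logt <- suppressWarnings(log(availability))
  lse_t <- log(sum(availability))
  S <- 0; S0 <- 0; S1 <- 0
  for (n in seq_len(n_samples)) {
    cn <- cells[cells$sample == n, , drop = FALSE]
    if (!nrow(cn)) next
    idx <- cbind(cn$bin, cn$type)
    lp <- if (is.function(log_pred)) log_pred(n) else log_pred[[n]]
    S <- S + sum(cn$weight * lp[idx])
    S0 <- S0 + sum(cn$weight * (logt[idx] - lse_t))
    emp <- cn$weight / sum(cn$weight)
    S1 <- S1 + sum(cn$weight * log(emp))
  }
  if (abs(S1 - S0) < 1e-12)
    stop("degenerate held-out data: saturated and null scores coincide")
  structure(list(S = S, S0 = S0, S1 = S1,
                 pseudo_r2 = 1 - (S1 - S) / (S1 - S0)),
            class = "PseudoR2Report")
}

#' Poisson (deviance) pseudo-R2 between rate profiles
#'
#' `1 - D(observed, predicted) / D(observed, uniform)` with deviances of the
#' Poisson family; the prediction is rescaled to the observed total mass, the
#' null is uniform at the same mass, and the saturated model is the observed
#' profile itself. Equals 1 at an exact match and is bounded above by 1.
#'
#' @param observed,predicted Nonnegative vectors of equal length.
#' @return Scalar pseudo-R2.
#' @export
poisson_pseudo_r2 <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted),
            all(observed >= 0), all(predicted >= 0))
  total <- sum(observed)
  if (total <= 0) stop("zero observed mass")
  mu <- predicted / sum(predicted) * total
  mu0 <- rep(total / length(observed), length(observed))
  dev <- function(m) {
    term <- ifelse(observed > 0, observed * log(observed / m), 0)
    2 * sum(term - (observed - m))
  }
  d1 <- dev(pmax(mu, 1e-300)); d0 <- dev(mu0)
  if (d0 < 1e-12) {
    if (d1 < 1e-12) return(1)
    stop("degenerate profile: observed is uniform but prediction is not")
  }
  1 - d1 / d0
}

#' Held-out evaluation of one configuration
#'
#' Trains on the bins outside `heldout_chrom`, refits exposures for every
#' sample from the training region, forms held-out per-sample predictions
#' `sum_k pi_hat_nk p(b, m | k)` renormalized over the held-out bins, and
#' scores them with [pseudo_r2()].
#'
#' @param tensor A `mutopia_tensor`.
#' @param binning A `mutopia_binning`.
#' @param config A [mutopia_config()].
#' @param heldout_chrom Chromosome name(s) to hold out.
#' @return List: `fit`, `report` (PseudoR2Report), `heldout_bins`.
#' @export
evaluate_heldout <- function(tensor, binning, config, heldout_chrom) {
  ho_bins <- bins_on_chromosomes(binning, heldout_chrom)
  tr_bins <- setdiff(binning$bins$bin_id, ho_bins)
  if (!length(ho_bins) || !length(tr_bins))
    stop("held-out split leaves an empty side")
  fit <- fit_mutopia(tensor, binning, config, bins = tr_bins)
  rf <- refit_exposures(fit$model, tensor, binning, bins = tr_bins)
  report <- .score_heldout(fit$model, rf$exposures, tensor, binning, ho_bins)
  list(fit = fit, report = report, heldout_bins = ho_bins)
}

.score_heldout <- function(model, exposures, tensor, binning, ho_bins) {
  ho_bins <- sort(ho_bins)
  cells <- tensor$cells[tensor$cells$bin %in% ho_bins, , drop = FALSE]
  cells$bin <- match(cells$bin, ho_bins)
  Xh <- binning$X[ho_bins, , drop = FALSE]
  th <- binning$t[ho_bins, , drop = FALSE]
  # per-process unnormalized probabilities on the held-out region
  Pk <- lapply(model$processes, function(p) {
    lg <- topography_logits(p, Xh, th)
    .normalize_logits(lg)
  })
  log_pred <- function(n) {
    mix <- 0
    for (k in seq_len(model$K)) mix <- mix + exposures[n, k] * Pk[[k]]
    mix <- mix / sum(mix)
    lp <- suppressWarnings(log(mix))
    lp[mix <= 0] <- -Inf
    lp
  }
  pseudo_r2(cells, log_pred, th, nrow(tensor$samples))
}

#' Ablation benchmark
#'
#' Trains the full model and its ablations on identical folds and seeds and
#' scores each on the held-out chromosome: `full` (boosted trees),
#' `linear` (linear macro effects), `lda` (constant macro effects, baseline
#' spectra only — availability-weighted LDA), and `locus_only` (K = 1,
#' baseline spectra, boosted trees).
#'
#' @param tensor,binning Data.
#' @param config Base configuration (defines K, seeds, epochs).
#' @param heldout_chrom Held-out chromosome name(s).
#' @param variants Character subset of the four variant names.
#' @return data.frame (variant, K, pseudo_r2).
#' @export
ablation_suite <- function(tensor, binning, config, heldout_chrom,
                           variants = c("full", "linear", "lda",
                                        "locus_only")) {
  variants <- match.arg(variants, several.ok = TRUE)
  cfgs <- list(
    full = config,
    linear = utils::modifyList(config, list(flavor = "linear")),
    lda = utils::modifyList(config, list(flavor = "constant",
                                         spectra_adjust = FALSE)),
    locus_only = utils::modifyList(config, list(K = 1L,
                                                spectra_adjust = FALSE)))
  rows <- lapply(variants, function(v) {
    ev <- evaluate_heldout(tensor, binning, cfgs[[v]], heldout_chrom)
    data.frame(variant = v, K = cfgs[[v]]$K,
               pseudo_r2 = ev$report$pseudo_r2)
  })
  do.call(rbind, rows)
}

#' Equal-bp quantile groups of bins by a feature
#'
#' Partitions bins into `n_groups` groups of (as nearly as possible) equal
#' total base pairs, ordered by the feature value.
#'
#' @param binning A `mutopia_binning`.
#' @param feature Feature column name.
#' @param n_groups Number of groups (default 8).
#' @return Integer group label per bin (1..n_groups).
#' @export
quantile_groups <- function(binning, feature, n_groups = 8) {
  x <- binning$X[, feature]
  len <- binning$bins$length_bp
  ord <- order(x)
  cum <- cumsum(len[ord])
  g_sorted <- pmin(ceiling(cum / (sum(len) / n_groups)), n_groups)
  g <- integer(length(x))
  g[ord] <- g_sorted
  g
}

#' Gene-relative bin groups
#'
#' Classifies bins into five positional classes relative to the nearest gene
#' (far upstream, near upstream/downstream, 5' body, mid body, 3' body)
#' crossed with three expression tertiles of that gene — 15 groups.
#'
#' @param binning A `mutopia_binning`.
#' @param genes BED6-style data.frame with gene intervals and strands.
#' @param expression Numeric expression per gene (aligned with `genes`
#'   rows).
#' @param near_bp Distance defining "near" (default 10000).
#' @return Integer group label per bin (1..15).
#' @export
gene_relative_groups <- function(binning, genes, expression,
                                 near_bp = 10000L) {
  bins <- binning$bins
  mid <- bins$first_start + 0.5 * bins$length_bp / 1  # representative point
  pos_class <- integer(nrow(bins)); expr_t <- integer(nrow(bins))
  tert <- cut(rank(expression, ties.method = "first"),
              breaks = 3, labels = FALSE)
  for (i in seq_len(nrow(bins))) {
    g <- genes[genes$chrom == bins$chrom[i], , drop = FALSE]
    if (!nrow(g)) { pos_class[i] <- 1L; expr_t[i] <- 1L; next }
    p <- mid[i]
    inside <- which(g$start <= p & p < g$end)
    if (length(inside)) {
      j <- inside[1]
      rel <- (p - g$start[j]) / (g$end[j] - g$start[j])
      if (!is.null(g$strand) && g$strand[j] == "-") rel <- 1 - rel
      pos_class[i] <- 3L + findInterval(rel, c(1 / 3, 2 / 3))
      expr_t[i] <- tert[which(genes$chrom == bins$chrom[i])[j]]
    } else {
      d <- pmin(abs(p - g$start), abs(p - g$end))
      j <- which.min(d)
      pos_class[i] <- if (d[j] <= near_bp) 2L else 1L
      expr_t[i] <- tert[which(genes$chrom == bins$chrom[i])[j]]
    }
  }
  (pos_class - 1L) * 3L + expr_t
}

#' Compare model and NNLS group contributions
#'
#' For each bin group `G`, the model-derived process contribution is
#' `p(z = k | G) propto sum_{b in G} p(b | k) sum_n p(n) pi_nk`; the
#' comparison pools all mutations in the group and refits proportions by
#' non-negative least squares against the model's marginal spectra.
#'
#' @param model A `mutopia_model`.
#' @param vstate Variational state or `mutopia_fit`.
#' @param tensor,binning Data.
#' @param groups Integer group label per bin (see [quantile_groups()]).
#' @param collapse Use 96-channel spectra for the NNLS (default FALSE).
#' @return data.frame (group, process, model_contrib, nnls_contrib,
#'   n_mutations); groups with zero mutations carry NA NNLS values and a
#'   `skipped` flag.
#' @export
nnls_validation <- function(model, vstate, tensor, binning, groups,
                            collapse = FALSE) {
  if (inherits(vstate, "mutopia_fit")) vstate <- vstate$vstate
  K <- model$K
  pi_hat <- vstate$beta / rowSums(vstate$beta)
  pn <- .rowsum_all(tensor$cells$weight, tensor$cells$sample,
                    nrow(tensor$samples))[, 1]
  pn <- pn / sum(pn)
  mix_k <- colSums(pn * pi_hat)
  Pb <- vapply(model$processes, function(p)
    marginal_genomic(p, binning$X, binning$t), numeric(nrow(binning$X)))
  spectra <- vapply(model$processes, function(p)
    marginal_spectrum(p, binning$X, binning$t), numeric(192))
  if (collapse) spectra <- apply(spectra, 2, collapse_to_96)
  rows <- list()
  for (g in sort(unique(groups))) {
    gb <- which(groups == g)
    mc <- colSums(Pb[gb, , drop = FALSE]) * mix_k
    mc <- mc / sum(mc)
    cg <- tensor$cells[tensor$cells$bin %in% binning$bins$bin_id[gb], ,
                       drop = FALSE]
    if (nrow(cg)) {
      obs <- .rowsum_all(cg$weight, cg$type, 192)[, 1]
      if (collapse) obs <- collapse_to_96(obs)
      sol <- pracma::lsqnonneg(spectra, obs / sum(obs))$x
      nn <- if (sum(sol) > 0) sol / sum(sol) else rep(NA_real_, K)
      skipped <- FALSE
      n_mut <- sum(cg$weight)
    } else {
      nn <- rep(NA_real_, K); skipped <- TRUE; n_mut <- 0
    }
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, process = seq_len(K), model_contrib = mc,
      nnls_contrib = nn, n_mutations = n_mut, skipped = skipped)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Hungarian-style matching of fitted to reference components by spectra
# cosine: exact over permutations for K <= 8, greedy beyond.
.match_components <- function(sim) {
  K <- nrow(sim)
  stopifnot(ncol(sim) == K)
  if (K <= 8) {
    perms <- .permutations(K)
    scores <- apply(perms, 1, function(p) sum(sim[cbind(seq_len(K), p)]))
    perms[which.max(scores), ]
  } else {
    assign <- integer(K); used <- logical(K)
    for (i in order(-apply(sim, 1, max))) {
      j <- order(-sim[i, ])
      j <- j[!used[j]][1]
      assign[i] <- j; used[j] <- TRUE
    }
    assign
  }
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Cosine similarity between columns / vectors
#' @param a,b Numeric vectors.
#' @return Scalar cosine similarity.
#' @export
cosine_similarity <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
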