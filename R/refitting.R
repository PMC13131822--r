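# Exposure refitting against a frozen pretrained model.

#' Refit sample exposures under a frozen model
#'
#' Runs E-step iterations only: the topography parameters and the Dirichlet
#' prior stay fixed, and only the per-sample variational parameters
#' (`beta`, `phi`) are optimized. Deterministic given its inputs. Samples
#' with no observed mutations receive prior-mean exposures and are flagged.
#'
#' @param model A frozen `mutopia_model`.
#' @param tensor A `mutopia_tensor` on the model's binning.
#' @param binning The `mutopia_binning`.
#' @param bins Optional bin subset; topographies are renormalized over it
#'   (used when refitting from a training region).
#' @param max_iter,tol E-step iteration cap and beta tolerance.
#' @return List: `exposures` (N x K, rows on the simplex), `beta`,
#'   `empty` (logical flag per sample).
#' @export
refit_exposures <- function(model, tensor, binning, bins = NULL,
                            max_iter = 200, tol = 1e-10) {
  if (is.null(bins)) bins <- binning$bins$bin_id
  bins <- sort(bins)
  cells <- tensor$cells[tensor$cells$bin %in% bins, , drop = FALSE]
  cells$bin_row <- match(cells$bin, bins)
  Xs <- binning$X[bins, , drop = FALSE]
  ts <- binning$t[bins, , drop = FALSE]
  n_samples <- nrow(tensor$samples)
  K <- model$K
  logP <- .model_log_topographies(model, Xs, ts)
  logp_cells <- vapply(seq_len(K), function(k)
    logP[[k]][cbind(cells$bin_row, cells$type)], numeric(nrow(cells)))
  if (nrow(cells) == 0)
    logp_cells <- matrix(numeric(0), 0, K)
  beta0 <- matrix(model$alpha, n_samples, K, byrow = TRUE)
  if (nrow(cells)) {
    es <- e_step(cells, logp_cells, beta0, model$alpha, n_samples,
                 inner = max_iter, tol = tol)
    beta <- es$beta
  } else beta <- beta0
  empty <- !(seq_len(n_samples) %in% unique(cells$sample))
  exposures <- beta / rowSums(beta)
  list(exposures = exposures, beta = beta, empty = empty)
}

#' Refitting accuracy versus mutation burden
#'
#' Subsamples each sample's raw mutations (before weighting) to the target
#' burdens, re-runs ingestion (including cluster detection) on the
#' subsample, refits exposures under the frozen model, and reports the mean
#' absolute error against the full-data exposures.
#'
#' @param model Frozen `mutopia_model`.
#' @param mutations Annotated cohort mutation table (see
#'   [annotate_mutations()]).
#' @param binning A `mutopia_binning`.
#' @param samples Sample metadata (`sample_id`, `purity`).
#' @param burdens Integer vector of target per-sample burdens; values at or
#'   above a sample's burden reproduce its full data.
#' @param seed Seed for subsampling (without replacement).
#' @param min_burden Only samples with more than this many mutations are
#'   benchmarked (default 0).
#' @param cluster_adjust Passed to ingestion.
#' @return Tidy data.frame (sample, burden, mae).
#' @export
refit_benchmark <- function(model, mutations, binning, samples, burdens,
                            seed = 1, min_burden = 0,
                            cluster_adjust = TRUE) {
  full_tensor <- build_count_tensor(mutations, binning, samples,
                                    cluster_adjust = cluster_adjust)
  full_rf <- refit_exposures(model, full_tensor, binning)
  keep <- full_tensor$samples$sample_id[full_tensor$samples$burden >
                                          min_burden]
  set.seed(seed)
  rows <- list()
  for (b in sort(burdens)) {
    sub <- do.call(rbind, lapply(keep, function(sm) {
      mi <- which(mutations$sample == sm)
      if (length(mi) > b) mi <- sort(sample(mi, b))
      mutations[mi, , drop = FALSE]
    }))
    attr(sub, "n_dropped") <- 0L
    sub_tensor <- build_count_tensor(sub, binning, samples,
                                     cluster_adjust = cluster_adjust)
    sub_rf <- refit_exposures(model, sub_tensor, binning)
    idx_full <- match(keep, full_tensor$samples$sample_id)
    idx_sub <- match(keep, sub_tensor$samples$sample_id)
    mae <- rowMeans(abs(full_rf$exposures[idx_full, , drop = FALSE] -
                          sub_rf$exposures[idx_sub, , drop = FALSE]))
    rows[[length(rows) + 1L]] <- data.frame(sample = keep, burden = b,
                                            mae = mae)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
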