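# Topotype analysis: transfer of rate profiles to a shared feature space,
# similarity clustering, and attribution.

#' Transfer process rate profiles onto a shared feature matrix
#'
#' Evaluates every model's process topographies on a shared genomic state
#' (feature matrix + availability) and returns the marginal genomic
#' distribution of each process, isolating intrinsic topographic properties
#' from tissue-specific feature landscapes. Transferring a model onto its
#' own training features reproduces [marginal_genomic()] exactly.
#'
#' @param models Named list of `mutopia_model` objects.
#' @param shared_X Shared feature matrix; must contain every macro, meso
#'   and strand feature the models reference (matched by name).
#' @param shared_t Shared availability matrix.
#' @return Matrix (signatures x bins); rownames `<model>:<label>`.
#' @export
transfer_profiles <- function(models, shared_X, shared_t) {
  if (is.null(names(models)))
    names(models) <- paste0("model", seq_along(models))
  rows <- list()
  for (mn in names(models)) {
    model <- models[[mn]]
    for (k in seq_len(model$K)) {
      prof <- marginal_genomic(model$processes[[k]], shared_X, shared_t)
      rows[[paste0(mn, ":", model$processes[[k]]$label)]] <- prof
    }
  }
  do.call(rbind, rows)
}

#' Cluster rate profiles into topotypes
#'
#' Computes pairwise cosine similarity between profiles restricted to the
#' evaluation bins (a held-out chromosome in practice), builds a symmetrized
#' kNN graph weighted by similarity, detects communities with the Leiden
#' algorithm, and lays the graph out in 2-D with a seeded force-directed
#' (Fruchterman-Reingold) embedding of the same graph.
#'
#' @param profiles Matrix (signatures x bins), nonnegative.
#' @param eval_bins Optional column subset (e.g. held-out-chromosome bins).
#' @param knn Number of nearest neighbours (default 10; reduced with a
#'   warning when fewer profiles are available).
#' @param resolution Leiden resolution (default 0.2).
#' @param seed Seed for clustering and layout.
#' @return List: `labels` (integer per signature), `similarity`
#'   (signatures x signatures), `embedding` (signatures x 2), `graph`.
#' @export
topotype_cluster <- function(profiles, eval_bins = NULL, knn = 10,
                             resolution = 0.2, seed = 1) {
  P <- if (is.null(eval_bins)) profiles else
    profiles[, eval_bins, drop = FALSE]
  n <- nrow(P)
  if (n < 2) stop("need at least two profiles to cluster")
  if (knn >= n) {
    warning("fewer profiles than knn; reducing knn to ", n - 1)
    knn <- n - 1
  }
  norm <- sqrt(rowSums(P^2))
  S <- (P / norm) %*% t(P / norm)
  S <- pmin(pmax(S, 0), 1)
  diag(S) <- 1
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(-S[i, -i])
    cand <- seq_len(n)[-i][nb[seq_len(knn)]]
    A[i, cand] <- S[i, cand]
  }
  A <- pmax(A, t(A))   # symmetrized union kNN graph
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution,
                               weights = igraph::E(g)$weight)
  labels <- igraph::membership(cl)
  set.seed(seed)
  emb <- igraph::layout_with_fr(g, weights = igraph::E(g)$weight)
  rownames(emb) <- rownames(profiles)
  list(labels = stats::setNames(as.integer(labels), rownames(profiles)),
       similarity = S, embedding = emb, graph = g)
}

#' Topotype attributions for one cohort
#'
#' Aggregates per-sample process exposures and burdens onto topotype labels:
#' each sample's topotype exposure vector sums its process exposures by
#' label; signature-level mass places each process's burden-weighted
#' exposure mass into its topotype column.
#'
#' @param labels Integer topotype label per process (length K).
#' @param exposures N x K exposure matrix (rows on the simplex).
#' @param burdens Length-N per-sample mutation burdens.
#' @return List: `sample_topotype` (N x T, rows on the simplex),
#'   `signature_mass` (K x T mutation mass), `cohort_fraction` (length T,
#'   fraction of cohort mutations per topotype).
#' @export
topotype_attribution <- function(labels, exposures, burdens) {
  K <- length(labels)
  stopifnot(ncol(exposures) == K, length(burdens) == nrow(exposures))
  tt <- sort(unique(labels))
  Tn <- length(tt)
  onehot <- matrix(0, K, Tn, dimnames = list(NULL, tt))
  onehot[cbind(seq_len(K), match(labels, tt))] <- 1
  sample_topotype <- exposures %*% onehot
  mass_k <- colSums(burdens * exposures)           # mutations per process
  signature_mass <- diag(mass_k, K, K) %*% onehot
  rownames(signature_mass) <- colnames(exposures)
  cohort <- colSums(signature_mass)
  list(sample_topotype = sample_topotype,
       signature_mass = signature_mass,
       cohort_fraction = cohort / sum(cohort))
}
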