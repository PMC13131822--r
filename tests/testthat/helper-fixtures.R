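# Shared fixtures, memoised so expensive objects are built once per run.

.fixture_env <- new.env(parent = emptyenv())

.memo <- function(key, build) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- build()
  .fixture_env[[key]]
}

# full toy genome + binning (two chromosomes, all feature classes)
get_toy <- function() .memo("toy", function() make_toy_binning(seed = 42))

# 4-process reference over the toy binning
get_ref <- function() .memo("ref", function()
  toy_reference_model(get_toy()$binning, K = 4, seed = 42))

# moderate simulated cohort + ingested tensor
get_cohort <- function() .memo("cohort", function() {
  toy <- get_toy()
  sim <- simulate_cohort(get_ref(), toy$binning, toy$genome,
                         n_samples = 30, gamma = 1, seed = 7)
  ann <- annotate_mutations(sim$mutations, toy$binning, toy$genome)
  tensor <- build_count_tensor(ann, toy$binning, sim$samples)
  list(sim = sim, mutations = ann, tensor = tensor)
})

# small fitted model reused by output/evaluation tests (few epochs, so the
# non-convergence warning is expected and silenced)
get_fit <- function() .memo("fit", function() {
  suppressWarnings(
    fit_mutopia(get_cohort()$tensor, get_toy()$binning,
                mutopia_config(K = 4, max_epochs = 12, spectra_every = 3,
                               tree_nrounds = 30, seed = 5)))
})

# one-chromosome micro genome for hand calculations
tiny_lengths <- c(chrA = 25000L)

# a minimal binning around an explicit sequence (single chromosome)
tiny_binning <- function(seq_string, interval_bp = 1e6L, tracks = list(),
                         continuous = list(), feature_class = NULL) {
  genome <- Biostrings::DNAStringSet(seq_string)
  names(genome) <- "chrA"
  build_binning(genome, tracks, continuous, feature_class,
                interval_bp = interval_bp)
}

# brute-force availability oracle: loops positions, resolves each oriented
# context through mutation_type_index
availability_oracle <- function(seq_string) {
  t_or <- numeric(192)
  chars <- strsplit(seq_string, "")[[1]]
  L <- length(chars)
  bases <- c("A", "C", "G", "T")
  if (L >= 3) for (p in 2:(L - 1)) {
    ctx <- paste(chars[(p - 1):(p + 1)], collapse = "")
    ref <- chars[p]
    if (grepl("[^ACGT]", ctx)) next
    for (alt in setdiff(bases, ref)) {
      idx <- mutation_type_index(ref, alt, ctx)
      t_or[idx] <- t_or[idx] + 1
    }
  }
  t_or
}

# random DNA string
random_dna <- function(n, seed = 1, with_n = FALSE) {
  set.seed(seed)
  alpha <- c("A", "C", "G", "T", if (with_n) "N")
  paste(sample(alpha, n, replace = TRUE), collapse = "")
}
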