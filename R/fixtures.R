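# Synthetic fixture generation: a toy genome, feature tracks and cohorts
# that exercise the whole pipeline without any external download. The
# defaults embed known nonlinear feature-rate relationships (steps,
# saturation, interactions on replication timing and a heterochromatin
# mark) so that model ablations separate, plus meso and strand features.

#' Build toy genome and tracks in memory
#'
#' @param seed Seed; identical seeds give identical data.
#' @param chr_lengths Named chromosome lengths (default chr1 600 kb,
#'   chr2 400 kb; chr2 is the conventional held-out chromosome).
#' @return List: `genome` (DNAStringSet), `discrete_tracks`,
#'   `continuous_tracks`, `feature_class`.
#' @export
make_toy_data <- function(seed = 1,
                          chr_lengths = c(chr1 = 600000L, chr2 = 400000L)) {
  set.seed(seed)
  seqs <- lapply(names(chr_lengths), function(ch) {
    L <- chr_lengths[[ch]]
    paste(sample(MUT_BASES, L, replace = TRUE), collapse = "")
  })
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- names(chr_lengths)
  genes <- list(); atac <- list()
  repli <- list(); h3k9 <- list(); expr <- list(); repstr <- list()
  for (ch in names(chr_lengths)) {
    L <- chr_lengths[[ch]]
    # genes: sequential non-overlapping placement
    pos <- 5000L; g <- list()
    while (pos < L - 30000L) {
      len <- sample(5000:20000, 1)
      g[[length(g) + 1L]] <- data.frame(
        chrom = ch, start = pos, end = min(pos + len, L),
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
      pos <- pos + len + sample(10000:25000, 1)
    }
    g <- do.call(rbind, g)
    genes[[ch]] <- g
    # ATAC peaks
    starts <- seq(2000L, L - 3000L, by = 15000L) +
      sample(0:5000, length(seq(2000L, L - 3000L, by = 15000L)),
             replace = TRUE)
    atac[[ch]] <- data.frame(chrom = ch, start = starts,
                             end = pmin(starts + sample(800:2500,
                                                        length(starts),
                                                        replace = TRUE), L),
                             stringsAsFactors = FALSE)
    # continuous macro tracks on a 10 kb lattice
    gs <- seq(0L, L - 1L, by = 10000L)
    ge <- pmin(gs + 10000L, L)
    midf <- (gs + ge) / 2
    phase <- stats::runif(1, 0, 2 * pi)
    rt <- 0.5 + 0.45 * sin(2 * pi * midf / 280000 + phase)
    repli[[ch]] <- data.frame(chrom = ch, start = gs, end = ge, value = rt,
                              stringsAsFactors = FALSE)
    hk <- pmin(pmax(0.75 * (1 - rt) + 0.25 * stats::runif(length(gs)), 0), 1)
    h3k9[[ch]] <- data.frame(chrom = ch, start = gs, end = ge, value = hk,
                             stringsAsFactors = FALSE)
    # replication strand: alternating 100 kb blocks
    bs <- seq(0L, L - 1L, by = 100000L)
    be <- pmin(bs + 100000L, L)
    repstr[[ch]] <- data.frame(chrom = ch, start = bs, end = be,
                               value = rep_len(c(1, -1), length(bs)),
                               stringsAsFactors = FALSE)
    # expression: per-gene lognormal over gene bodies, zero elsewhere
    ex <- g[, c("chrom", "start", "end")]
    ex$value <- stats::rlnorm(nrow(g), 0, 1)
    gaps <- data.frame(chrom = ch,
                       start = c(0L, g$end),
                       end = c(g$start, L), value = 0)
    gaps <- gaps[gaps$start < gaps$end, , drop = FALSE]
    expr[[ch]] <- rbind(ex, gaps)
  }
  bindall <- function(x) {
    out <- do.call(rbind, unname(x)); rownames(out) <- NULL; out
  }
  list(genome = genome,
       discrete_tracks = list(gene = bindall(genes), atac = bindall(atac)),
       continuous_tracks = list(repli = bindall(repli),
                                h3k9me3 = bindall(h3k9),
                                expression = bindall(expr),
                                rep_strand = bindall(repstr)),
       feature_class = c(gene = "meso", gene_strand = "strand",
                         atac = "meso", repli = "macro",
                         h3k9me3 = "macro", expression = "meso",
                         rep_strand = "strand"))
}

#' Build the toy binning directly
#'
#' @param seed Seed forwarded to [make_toy_data()].
#' @param interval_bp Grid width (default 10000).
#' @param ... Passed to [make_toy_data()].
#' @return List: `binning`, `genome`, plus the toy-data components.
#' @export
make_toy_binning <- function(seed = 1, interval_bp = 10000L, ...) {
  toy <- make_toy_data(seed, ...)
  binning <- build_binning(toy$genome, toy$discrete_tracks,
                           toy$continuous_tracks, toy$feature_class,
                           interval_bp = interval_bp)
  c(list(binning = binning), toy)
}

#' Write the complete fixture set to disk
#'
#' Emits the toy genome (FASTA), discrete tracks (BED), continuous tracks
#' (bedGraph), a simulated cohort (MAF-style TSV + sample TSV), the ground
#' truth (JSON) and a feature-class YAML — everything needed to run the
#' pipeline end to end. Identical seeds give byte-identical files.
#'
#' @param dir Output directory.
#' @param seed Seed.
#' @param n_samples Cohort size (default 40).
#' @param K Reference model size (default 4).
#' @param gamma Burden scale (default 1).
#' @return Invisibly, the named vector of written paths.
#' @export
fixture_generator <- function(dir, seed = 1, n_samples = 40, K = 4,
                              gamma = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  toy <- make_toy_binning(seed)
  paths <- c(genome = file.path(dir, "genome.fa"))
  Biostrings::writeXStringSet(toy$genome, paths["genome"], width = 80)
  for (nm in names(toy$discrete_tracks)) {
    p <- file.path(dir, paste0(nm, ".bed"))
    tr <- toy$discrete_tracks[[nm]]
    out <- if (!is.null(tr$strand))
      data.frame(tr$chrom, tr$start, tr$end, ".", 0, tr$strand)
    else data.frame(tr$chrom, tr$start, tr$end)
    utils::write.table(out, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths[nm] <- p
  }
  for (nm in names(toy$continuous_tracks)) {
    p <- file.path(dir, paste0(nm, ".bedgraph"))
    utils::write.table(toy$continuous_tracks[[nm]], p, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths[nm] <- p
  }
  yaml::write_yaml(list(feature_class = as.list(toy$feature_class),
                        binning = list(interval_bp = 10000L),
                        heldout_chrom = "chr2"),
                   file.path(dir, "config.yaml"))
  paths["config"] <- file.path(dir, "config.yaml")
  ref <- toy_reference_model(toy$binning, K = K, seed = seed)
  sim <- simulate_cohort(ref, toy$binning, toy$genome,
                         n_samples = n_samples, gamma = gamma,
                         seed = seed + 1L)
  mut_out <- sim$mutations
  mut_out$pos <- mut_out$pos + 1L   # external tables are 1-based
  utils::write.table(mut_out, file.path(dir, "mutations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(exposures = sim$truth$exposures,
                            process_counts = sim$truth$process_counts,
                            gamma = gamma, seed = seed),
                       file.path(dir, "truth.json"), digits = NA)
  paths[c("mutations", "samples", "truth")] <-
    file.path(dir, c("mutations.tsv", "samples.tsv", "truth.json"))
  invisible(paths)
}
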