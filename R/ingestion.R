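# Sample ingestion: SNV calls -> weighted count tensor.
#
# Each mutation is weighted by VAF/purity (the exact reduction of the
# copy-number multiplicity at total copy number 2), then runs of mutations
# closer than expected under a cohort-calibrated Poisson null are grouped
# into clusters and their weights divided by cluster size, so a clustered
# event contributes the equivalent of one observation.

#' Read a MAF-style mutation table
#'
#' Expects a tab-delimited file with a header containing at least
#' `sample`, `chrom`, `pos`, `ref`, `alt` and optionally `vaf`. Positions in
#' the file are 1-based and converted to the package's 0-based convention.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `sample`, `chrom`, `pos` (0-based),
#'   `ref`, `alt`, `vaf`.
#' @export
read_mutations_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("mutation table lacks columns: ",
                         paste(miss, collapse = ", "))
  out <- data.frame(sample = as.character(df$sample),
                    chrom = as.character(df$chrom),
                    pos = as.integer(df$pos) - 1L,
                    ref = toupper(df$ref), alt = toupper(df$alt),
                    stringsAsFactors = FALSE)
  out$vaf <- if ("vaf" %in% colnames(df)) as.numeric(df$vaf) else NA_real_
  out
}

#' Read SNVs from a VCF
#'
#' A minimal single- or multi-sample VCF reader for SNV records. VAF is
#' taken, in order of precedence, from the per-sample `AD` field
#' (alt / total depth), the per-sample `AF` field, then the INFO `AF` field.
#'
#' @param path Path to an uncompressed VCF.
#' @param sample_id Sample name to assign when the VCF has no genotype
#'   columns (default `"sample1"`).
#' @return data.frame as in [read_mutations_tsv()].
#' @export
read_mutations_vcf <- function(path, sample_id = "sample1") {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("not a VCF: missing #CHROM header line")
  cols <- strsplit(sub("^#", "", lines[hdr[1]]), "\t")[[1]]
  body <- lines[-seq_len(hdr[1])]
  body <- body[nzchar(body)]
  if (!length(body))
    return(data.frame(sample = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      vaf = numeric(), stringsAsFactors = FALSE))
  mat <- do.call(rbind, strsplit(body, "\t"))
  colnames(mat) <- cols[seq_len(ncol(mat))]
  keep <- nchar(mat[, "REF"]) == 1 & nchar(mat[, "ALT"]) == 1 &
    mat[, "REF"] %in% MUT_BASES & mat[, "ALT"] %in% MUT_BASES
  mat <- mat[keep, , drop = FALSE]
  info_af <- suppressWarnings(as.numeric(
    sub(".*(?:^|;)AF=([^;]*).*", "\\1", mat[, "INFO"])))
  samples <- if (ncol(mat) > 9) cols[10:ncol(mat)] else character(0)
  parse_one <- function(srow, fmt, val, fallback) {
    keys <- strsplit(fmt, ":")[[1]]
    vals <- strsplit(val, ":")[[1]]
    ad <- vals[match("AD", keys)]
    if (!is.na(ad)) {
      d <- suppressWarnings(as.numeric(strsplit(ad, ",")[[1]]))
      if (length(d) >= 2 && sum(d, na.rm = TRUE) > 0)
        return(d[2] / sum(d, na.rm = TRUE))
    }
    af <- suppressWarnings(as.numeric(vals[match("AF", keys)]))
    if (!is.na(af)) return(af)
    fallback
  }
  rows <- list()
  for (i in seq_len(nrow(mat))) {
    base <- data.frame(chrom = mat[i, "CHROM"],
                       pos = as.integer(mat[i, "POS"]) - 1L,
                       ref = mat[i, "REF"], alt = mat[i, "ALT"],
                       stringsAsFactors = FALSE)
    if (length(samples)) {
      for (sm in samples) {
        gt <- mat[i, sm]
        if (startsWith(gt, "0/0") || startsWith(gt, "./.") ||
            startsWith(gt, "0|0")) next
        vaf <- parse_one(sm, mat[i, "FORMAT"], gt, info_af[i])
        rows[[length(rows) + 1L]] <- cbind(sample = sm, base, vaf = vaf)
      }
    } else {
      rows[[length(rows) + 1L]] <- cbind(sample = sample_id, base,
                                         vaf = info_af[i])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("sample", "chrom", "pos", "ref", "alt", "vaf")]
}

#' Copy-number-aware mutation weight
#'
#' The weight `vaf / purity` estimates a mutation's multiplicity fraction at
#' total copy number 2 and is capped to guard against VAF or purity
#' artifacts.
#'
#' @param vaf Variant allele frequency in `[0, 1]`.
#' @param purity Tumor purity in `(0, 1]`.
#' @param cap Maximum weight (default 2; `Inf` disables the cap).
#' @return Numeric weight(s).
#' @export
mutation_weight <- function(vaf, purity, cap = 2) {
  if (any(purity <= 0)) stop("purity must be positive")
  if (any(vaf < 0, na.rm = TRUE)) stop("vaf must be nonnegative")
  pmin(vaf / purity, cap)
}

#' Full copy-number multiplicity fraction
#'
#' The multiplicity fraction `CN_mut / CN_tot` implied by an observed VAF at
#' a locus of total copy number `cn_tot` in a tumor of given purity:
#' `vaf * (1 + 2 (1 - purity) / (cn_tot * purity))`. At `cn_tot = 2` this
#' reduces exactly to `vaf / purity`, the simplified weight used by
#' [mutation_weight()].
#'
#' @param vaf,purity As in [mutation_weight()].
#' @param cn_tot Total copy number at the locus.
#' @return Numeric multiplicity fraction(s).
#' @export
mutation_weight_full <- function(vaf, purity, cn_tot) {
  if (any(purity <= 0)) stop("purity must be positive")
  vaf * (1 + 2 * (1 - purity) / (cn_tot * purity))
}

#' Cohort-averaged local mutation rate
#'
#' Per-base relative mutation density in a window (50 kb by default) centred
#' on each query position, computed across all cohort mutations and
#' normalized so the genome-wide density integrates to one. Windows with no
#' cohort mutations fall back to the genome-wide mean rate.
#'
#' @param chrom,pos Query positions (0-based).
#' @param cohort Data.frame of all cohort mutations (`chrom`, `pos`).
#' @param lengths Named chromosome lengths.
#' @param window_bp Window width (default 50000), centred on the position
#'   and clipped at chromosome ends.
#' @return Numeric vector of relative per-base rates `mu_i` (summing to 1
#'   over all genomic bases when uniform).
#' @export
local_rate_relative <- function(chrom, pos, cohort, lengths,
                                window_bp = 50000L) {
  total <- nrow(cohort)
  L <- sum(lengths)
  if (total == 0) return(rep(1 / L, length(pos)))
  half <- window_bp / 2
  out <- numeric(length(pos))
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    cp <- sort(cohort$pos[cohort$chrom == ch])
    lo <- pmax(pos[qi] - half, 0)
    hi <- pmin(pos[qi] + half, lengths[[ch]])
    cnt <- findInterval(hi - 0.5, cp) - findInterval(lo - 0.5, cp)
    mu <- (cnt / (hi - lo)) / total
    mu[cnt == 0] <- 1 / L
    out[qi] <- mu
  }
  out
}

#' Expected per-base mutation rate for a sample
#'
#' `mu_hat = M_n * mu + M / window_bp`: the sample's burden scaled by the
#' cohort-relative local density, plus a pseudo-mutation spread over the
#' window to stabilise sparse estimates.
#'
#' @param mu Relative per-base rates from [local_rate_relative()].
#' @param burden Sample mutation count `M_n`.
#' @param pseudocount Pseudo-mutations per window (default 1).
#' @param window_bp Window width used for `mu` (default 50000).
#' @return Positive per-base rates.
#' @export
local_rate <- function(mu, burden, pseudocount = 1, window_bp = 50000L) {
  mu_hat <- burden * mu + pseudocount / window_bp
  stopifnot(all(mu_hat > 0))
  mu_hat
}

#' Critical inter-mutation distance
#'
#' Under a Poisson null with per-base rate `mu_hat` on two copies, the
#' distance to the next mutation is exponential with rate `mu_hat / 2`; the
#' alpha-quantile `-2 log(1 - alpha) / mu_hat` is the distance below which
#' proximity is called significant.
#'
#' @param mu_hat Per-base rate(s), positive.
#' @param alpha_clust Significance level in `(0, 1)` (default 0.005).
#' @return Critical distance(s) in bp.
#' @export
critical_distance <- function(mu_hat, alpha_clust = 0.005) {
  if (any(alpha_clust <= 0) || any(alpha_clust >= 1))
    stop("alpha_clust must lie in (0, 1)")
  stopifnot(all(mu_hat > 0))
  -2 * log(1 - alpha_clust) / mu_hat
}

#' Detect clustered mutations in one sample
#'
#' Consecutive same-chromosome mutations are linked whenever their
#' separation is at most `min(10 kb, d*)`, where `d*` is the critical
#' distance of the left mutation; maximal linked runs form clusters
#' (singletons allowed).
#'
#' @param mutations One sample's mutations (`chrom`, `pos`), any order.
#' @param mu_hat Per-base rates aligned with `mutations` rows.
#' @param alpha_clust Significance level (default 0.005).
#' @param max_gap Hard cap on the linking distance (default 10000).
#' @return Integer vector of cluster ids aligned with the input rows.
#' @export
detect_clusters <- function(mutations, mu_hat, alpha_clust = 0.005,
                            max_gap = 10000L) {
  n <- nrow(mutations)
  if (n == 0) return(integer(0))
  ord <- order(mutations$chrom, mutations$pos)
  pos <- mutations$pos[ord]; chrom <- mutations$chrom[ord]
  dstar <- critical_distance(mu_hat[ord], alpha_clust)
  link <- logical(n - 1)
  if (n > 1) {
    gap <- pos[-1] - pos[-n]
    same <- chrom[-1] == chrom[-n]
    link <- same & gap <= pmin(max_gap, dstar[-n])
  }
  cl_sorted <- cumsum(c(1L, as.integer(!link)))
  cl <- integer(n)
  cl[ord] <- cl_sorted
  cl
}

#' Divide clustered-mutation weights by cluster size
#'
#' @param weights Per-mutation weights.
#' @param cluster Cluster ids from [detect_clusters()].
#' @param enabled Set `FALSE` to return raw weights unchanged.
#' @return Adjusted weights; each cluster's total equals its mean raw weight.
#' @export
adjust_cluster_weights <- function(weights, cluster, enabled = TRUE) {
  if (!enabled) return(weights)
  size <- table(cluster)
  weights / as.numeric(size[as.character(cluster)])
}

#' Annotate mutations with channel and bin
#'
#' Resolves each mutation's trinucleotide context from the genome, its
#' stranded channel, and its genomic bin. Mutations with ambiguous context,
#' reference mismatch, or ref == alt are dropped with a message.
#'
#' @param mutations data.frame (`sample`, `chrom`, `pos`, `ref`, `alt`,
#'   optional `vaf`).
#' @param binning A `mutopia_binning`.
#' @param genome `DNAStringSet` or FASTA path.
#' @return The input with `type` and `bin` columns, dropped rows removed;
#'   the number dropped is attached as attribute `n_dropped`.
#' @export
annotate_mutations <- function(mutations, binning, genome) {
  genome <- .as_genome(genome)
  n <- nrow(mutations)
  ctx <- rep(NA_character_, n)
  for (ch in unique(mutations$chrom)) {
    if (!ch %in% names(genome)) stop("mutation chromosome not in genome: ", ch)
    qi <- which(mutations$chrom == ch)
    L <- length(genome[[ch]])
    ok <- mutations$pos[qi] >= 1 & mutations$pos[qi] <= L - 2
    if (any(ok)) {
      v <- Biostrings::Views(genome[[ch]], start = mutations$pos[qi][ok],
                             width = 3)
      ctx[qi[ok]] <- as.character(v)
    }
  }
  type <- mutation_type_index(mutations$ref, mutations$alt, ctx)
  drop <- is.na(type)
  if (any(drop))
    message(sum(drop), " mutation(s) dropped (ambiguous context or ",
            "reference mismatch)")
  out <- mutations[!drop, , drop = FALSE]
  out$type <- type[!drop]
  # bin lookup through the segment partition
  out$bin <- rep(NA_integer_, nrow(out))
  for (ch in unique(out$chrom)) {
    qi <- which(out$chrom == ch)
    segs <- binning$segments[binning$segments$chrom == ch, , drop = FALSE]
    if (!nrow(segs)) stop("no bins cover chromosome ", ch)
    segs <- segs[order(segs$start), , drop = FALSE]
    idx <- findInterval(out$pos[qi], segs$start)
    bad <- idx < 1 | out$pos[qi] >= segs$end[pmax(idx, 1)]
    if (any(bad)) stop("mutation position outside the binning on ", ch)
    out$bin[qi] <- segs$bin_id[idx]
  }
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Build the weighted count tensor
#'
#' Runs the full ingestion path: VAF/purity weighting, cohort local-rate
#' estimation, cluster detection and down-weighting, and aggregation into a
#' sparse (sample x bin x channel) tensor.
#'
#' @param mutations Annotated mutations (see [annotate_mutations()]) or a raw
#'   table plus `genome` to annotate on the fly.
#' @param binning A `mutopia_binning`.
#' @param samples Optional data.frame (`sample_id`, `purity`). Missing
#'   purity defaults to 1 with a warning.
#' @param genome Optional genome for annotation if `mutations` lacks
#'   `type`/`bin` columns.
#' @param alpha_clust Clustering significance level (default 0.005).
#' @param cluster_adjust Apply cluster down-weighting (default TRUE).
#' @param weight_cap Cap on VAF/purity weights (default 2).
#' @param pseudocount Pseudo-mutations per rate window (default 1).
#' @param window_bp Local-rate window (default 50000).
#' @return A `mutopia_tensor`: sparse cells (`sample`, `bin`, `type`,
#'   `weight`), per-sample metadata with raw burdens, and bookkeeping.
#' @export
build_count_tensor <- function(mutations, binning, samples = NULL,
                               genome = NULL, alpha_clust = 0.005,
                               cluster_adjust = TRUE, weight_cap = 2,
                               pseudocount = 1, window_bp = 50000L) {
  if (!all(c("type", "bin") %in% colnames(mutations))) {
    if (is.null(genome))
      stop("mutations lack type/bin annotation; supply `genome`")
    mutations <- annotate_mutations(mutations, binning, genome)
  }
  sample_ids <- sort(unique(mutations$sample))
  if (is.null(samples)) {
    warning("no sample metadata supplied; assuming purity 1 for all samples")
    samples <- data.frame(sample_id = sample_ids, purity = 1,
                          stringsAsFactors = FALSE)
  }
  if (!all(sample_ids %in% samples$sample_id))
    stop("samples table lacks metadata for some samples")
  purity <- stats::setNames(samples$purity, samples$sample_id)
  if (any(is.na(purity))) {
    warning("missing purity for some samples; defaulting to 1")
    purity[is.na(purity)] <- 1
  }
  vaf <- mutations$vaf
  if (any(is.na(vaf))) vaf[is.na(vaf)] <- NA  # handled below
  w <- ifelse(is.na(vaf), 1,
              mutation_weight(ifelse(is.na(vaf), 0, vaf),
                              purity[mutations$sample], cap = weight_cap))
  mu <- local_rate_relative(mutations$chrom, mutations$pos, mutations,
                            binning$genome_lengths, window_bp)
  burden <- table(mutations$sample)
  Mn <- as.numeric(burden[mutations$sample])
  mu_hat <- local_rate(mu, Mn, pseudocount, window_bp)
  cluster <- integer(nrow(mutations))
  off <- 0L
  for (sm in sample_ids) {
    si <- which(mutations$sample == sm)
    cl <- detect_clusters(mutations[si, , drop = FALSE], mu_hat[si],
                          alpha_clust)
    cluster[si] <- cl + off
    off <- off + max(cl, 0L)
  }
  w_adj <- adjust_cluster_weights(w, cluster, enabled = cluster_adjust)
  key <- paste(mutations$sample, mutations$bin, mutations$type, sep = "\r")
  agg <- rowsum(w_adj, key)
  parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  cells <- data.frame(sample = match(parts[, 1], sample_ids),
                      bin = as.integer(parts[, 2]),
                      type = as.integer(parts[, 3]),
                      weight = as.numeric(agg[, 1]))
  cells <- cells[order(cells$sample, cells$bin, cells$type), , drop = FALSE]
  rownames(cells) <- NULL
  meta <- data.frame(sample_id = sample_ids,
                     purity = as.numeric(purity[sample_ids]),
                     burden = as.integer(burden[sample_ids]),
                     stringsAsFactors = FALSE)
  structure(list(cells = cells, samples = meta, n_bins = nrow(binning$bins),
                 n_types = 192L, alpha_clust = alpha_clust,
                 cluster_adjust = cluster_adjust,
                 n_dropped = attr(mutations, "n_dropped") %||% 0L),
            class = "mutopia_tensor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mutopia_tensor <- function(x, ...) {
  cat(sprintf("mutopia tensor: %d samples, %d bins, %d nonzero cells, total weight %.2f\n",
              nrow(x$samples), x$n_bins, nrow(x$cells), sum(x$cells$weight)))
  invisible(x)
}

#' Serialize / read a weighted count tensor as sparse triplets
#' @param tensor A `mutopia_tensor`.
#' @param prefix Output path prefix (`<prefix>.cells.tsv`,
#'   `<prefix>.samples.tsv`).
#' @export
write_tensor <- function(tensor, prefix) {
  cells <- tensor$cells
  cells$sample <- tensor$samples$sample_id[cells$sample]
  utils::write.table(cells, paste0(prefix, ".cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tensor$samples, paste0(prefix, ".samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_tensor
#' @param n_bins Number of bins of the binning the tensor refers to.
#' @export
read_tensor <- function(prefix, n_bins) {
  cells <- utils::read.table(paste0(prefix, ".cells.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  meta <- utils::read.table(paste0(prefix, ".samples.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  cells$sample <- match(cells$sample, meta$sample_id)
  structure(list(cells = cells, samples = meta, n_bins = n_bins,
                 n_types = 192L, alpha_clust = NA_real_,
                 cluster_adjust = NA, n_dropped = 0L),
            class = "mutopia_tensor")
}
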