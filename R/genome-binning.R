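# Feature-defined genome binning.
#
# The genome is partitioned at every discrete-feature state change and at a
# fixed-width grid (10 kb by default), giving segments within which discrete
# state is constant. Segments sharing a discrete state are aggregated into
# bins; by default aggregation is scoped to the fixed-width window, so a bin
# is a (possibly non-contiguous) group of same-state segments inside one
# window, preserving macro-scale feature resolution. Continuous features are
# length-weighted averages per bin; the context-availability matrix counts,
# per bin, the positions at which each of the 192 stranded channels can occur.
# All coordinates are 0-based half-open (BED convention).

#' Read a BED3/BED6 interval track
#'
#' @param path Path to a tab-delimited BED file (no header). Columns beyond
#'   the sixth are ignored; column 6, when present, is the strand.
#' @return A data.frame with columns `chrom`, `start`, `end` and, if present,
#'   `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  out <- data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]), stringsAsFactors = FALSE)
  if (ncol(df) >= 6) out$strand <- as.character(df[[6]])
  out
}

#' Read a bedGraph / 4-column continuous track
#' @param path Path to a tab-delimited file with columns chrom, start, end,
#'   value (no header).
#' @return A data.frame with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
             end = as.integer(df[[3]]), value = as.numeric(df[[4]]),
             stringsAsFactors = FALSE)
}

#' Chromosome lengths of a genome
#' @param genome A `Biostrings::DNAStringSet` or path to a FASTA file.
#' @return Named integer vector of chromosome lengths.
#' @export
genome_lengths <- function(genome) {
  genome <- .as_genome(genome)
  stats::setNames(Biostrings::width(genome), names(genome))
}

.as_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a DNAStringSet or FASTA path")
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

.check_track <- function(track, name, lengths) {
  if (nrow(track) == 0) return(invisible(NULL))
  bad <- setdiff(unique(track$chrom), names(lengths))
  if (length(bad))
    stop(sprintf("track '%s' references chromosomes absent from the genome: %s",
                 name, paste(bad, collapse = ", ")))
  if (any(track$start < 0) || any(track$end > lengths[track$chrom]) ||
      any(track$start >= track$end))
    stop(sprintf("track '%s' has invalid interval coordinates", name))
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    if (nrow(tr) > 1 && any(tr$start[-1] < tr$end[-nrow(tr)]))
      stop(sprintf("track '%s' has overlapping intervals on %s", name, ch))
  }
  invisible(NULL)
}

#' Partition the genome into constant-state segments
#'
#' Breakpoints are the union of every discrete-feature state change and a
#' fixed-width grid restarting at each chromosome boundary.
#'
#' @param lengths Named chromosome lengths (see [genome_lengths()]).
#' @param discrete_tracks Named list of BED-style data.frames
#'   (`chrom`, `start`, `end`, optional `strand`). Intervals within one track
#'   must not overlap.
#' @param interval_bp Fixed grid width in bp (default 10000).
#' @return data.frame of segments (`chrom`, `start`, `end`), 0-based
#'   half-open, sorted by chromosome (genome order) then start, with
#'   `interval_bp` stored as an attribute.
#' @export
segment_genome <- function(lengths, discrete_tracks = list(),
                           interval_bp = 10000L) {
  stopifnot(interval_bp > 0)
  if (length(discrete_tracks) && is.null(names(discrete_tracks)))
    stop("discrete_tracks must be a named list")
  for (nm in names(discrete_tracks))
    .check_track(discrete_tracks[[nm]], nm, lengths)
  segs <- lapply(names(lengths), function(ch) {
    L <- lengths[[ch]]
    if (L <= 0) return(NULL)
    bp <- c(0L, seq.int(interval_bp, by = interval_bp,
                        length.out = max(0L, (L - 1L) %/% interval_bp)), L)
    for (nm in names(discrete_tracks)) {
      tr <- discrete_tracks[[nm]]
      tr <- tr[tr$chrom == ch, , drop = FALSE]
      bp <- c(bp, tr$start, tr$end)
    }
    bp <- sort(unique(pmin(pmax(bp, 0L), L)))
    data.frame(chrom = ch, start = bp[-length(bp)], end = bp[-1],
               stringsAsFactors = FALSE)
  })
  segs <- Filter(Negate(is.null), segs)
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "interval_bp") <- as.integer(interval_bp)
  out
}

# Per-segment discrete state columns: membership 0/1 per track, plus a signed
# strand column for BED6 tracks (+1/-1 inside, 0 outside).
.segment_states <- function(segments, discrete_tracks) {
  n <- nrow(segments)
  states <- list()
  for (nm in names(discrete_tracks)) {
    tr <- discrete_tracks[[nm]]
    member <- numeric(n)
    strand <- if (!is.null(tr$strand)) numeric(n) else NULL
    for (ch in unique(segments$chrom)) {
      si <- which(segments$chrom == ch)
      trc <- tr[tr$chrom == ch, , drop = FALSE]
      if (!nrow(trc)) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(segments$start[si] + 1L, segments$end[si]),
        IRanges::IRanges(trc$start + 1L, trc$end))
      q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
      member[si[q]] <- 1
      if (!is.null(strand))
        strand[si[q]] <- ifelse(trc$strand[s] == "+", 1,
                                ifelse(trc$strand[s] == "-", -1, 0))
    }
    states[[nm]] <- member
    if (!is.null(strand)) states[[paste0(nm, "_strand")]] <- strand
  }
  as.data.frame(states, optional = TRUE)
}

#' Aggregate constant-state segments into bins
#'
#' Segments sharing an identical discrete state are merged into one bin even
#' when not contiguous. With `scope = "window"` (default) merging is confined
#' to each fixed-width window, so bins never cross windows or chromosomes;
#' `scope = "chromosome"` merges same-state segments chromosome-wide.
#'
#' @param segments Output of [segment_genome()].
#' @param discrete_tracks The same named track list used for segmentation.
#' @param scope `"window"` or `"chromosome"`.
#' @return List with `bins` (bin table: `bin_id`, `chrom`, `window`,
#'   `state_key`, `first_start`, `length_bp`), `segments` (with a `bin_id`
#'   column), and `states` (per-bin discrete feature values).
#' @export
aggregate_bins <- function(segments, discrete_tracks = list(),
                           scope = c("window", "chromosome")) {
  scope <- match.arg(scope)
  interval_bp <- attr(segments, "interval_bp")
  if (is.null(interval_bp)) interval_bp <- 10000L
  st <- .segment_states(segments, discrete_tracks)
  n <- nrow(segments)
  state_key <- if (ncol(st)) {
    do.call(paste, c(lapply(st, format), list(sep = "|")))
  } else rep("()", n)
  window <- segments$start %/% interval_bp
  group <- switch(scope,
    window = paste(segments$chrom, window, state_key, sep = "\r"),
    chromosome = paste(segments$chrom, state_key, sep = "\r"))
  if (n == 0) {
    bins <- data.frame(bin_id = integer(), chrom = character(),
                       window = integer(), state_key = character(),
                       first_start = integer(), length_bp = integer(),
                       stringsAsFactors = FALSE)
    return(list(bins = bins, segments = segments, states = st))
  }
  first <- !duplicated(group)
  binfo <- data.frame(group = group[first],
                      chrom = segments$chrom[first],
                      window = window[first],
                      state_key = state_key[first],
                      first_start = segments$start[first],
                      stringsAsFactors = FALSE)
  len <- tapply(segments$end - segments$start, group, sum)
  binfo$length_bp <- as.integer(len[binfo$group])
  # deterministic ordering: discrete state, then genomic coordinate
  chrom_rank <- match(binfo$chrom, unique(segments$chrom))
  ord <- order(binfo$state_key, chrom_rank, binfo$first_start)
  binfo <- binfo[ord, , drop = FALSE]
  binfo$bin_id <- seq_len(nrow(binfo))
  segments$bin_id <- binfo$bin_id[match(group, binfo$group)]
  states <- st[first, , drop = FALSE][ord, , drop = FALSE]
  rownames(states) <- NULL
  bins <- binfo[, c("bin_id", "chrom", "window", "state_key",
                    "first_start", "length_bp")]
  rownames(bins) <- NULL
  list(bins = bins, segments = segments, states = states)
}

# Length-weighted segment means of one continuous track, with imputation of
# uncovered bases from the bp-weighted chromosome (or genome) mean.
.segment_track_means <- function(segments, track, impute, name) {
  n <- nrow(segments)
  val_sum <- numeric(n); cov_bp <- numeric(n)
  chrom_mean <- tapply(track$value * (track$end - track$start), track$chrom,
                       sum) /
    tapply(track$end - track$start, track$chrom, sum)
  genome_mean <- sum(track$value * (track$end - track$start)) /
    sum(track$end - track$start)
  for (ch in unique(segments$chrom)) {
    si <- which(segments$chrom == ch)
    trc <- track[track$chrom == ch, , drop = FALSE]
    if (nrow(trc)) {
      ir_seg <- IRanges::IRanges(segments$start[si] + 1L, segments$end[si])
      ir_trk <- IRanges::IRanges(trc$start + 1L, trc$end)
      ov <- IRanges::findOverlaps(ir_seg, ir_trk)
      q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
      w <- pmin(segments$end[si][q], trc$end[s]) -
        pmax(segments$start[si][q], trc$start[s])
      if (length(q)) {
        add_v <- tapply(w * trc$value[s], q, sum)
        add_w <- tapply(w, q, sum)
        ii <- si[as.integer(names(add_v))]
        val_sum[ii] <- val_sum[ii] + as.numeric(add_v)
        cov_bp[ii] <- cov_bp[ii] + as.numeric(add_w)
      }
    }
  }
  seg_len <- segments$end - segments$start
  uncov <- seg_len - cov_bp
  if (any(uncov > 0)) {
    if (identical(impute, "none"))
      stop(sprintf("continuous track '%s' leaves %d bp uncovered and imputation is disabled",
                   name, sum(uncov)))
    fill <- chrom_mean[segments$chrom]
    fill[is.na(fill)] <- genome_mean
    val_sum <- val_sum + uncov * fill
  }
  val_sum / seg_len
}

#' Build the per-bin feature matrix
#'
#' Discrete-state columns (membership and strand) are constant within each
#' bin by construction; continuous tracks contribute the length-weighted mean
#' value across the bin's bases.
#'
#' @param agg Output of [aggregate_bins()].
#' @param continuous_tracks Named list of bedGraph-style data.frames
#'   (`chrom`, `start`, `end`, `value`).
#' @param impute `"chrom_mean"` (default; uncovered bases take the track's
#'   bp-weighted chromosome mean) or `"none"` (error on any uncovered base).
#' @return Numeric matrix (bins x features).
#' @export
build_feature_matrix <- function(agg, continuous_tracks = list(),
                                 impute = "chrom_mean") {
  segments <- agg$segments
  bins <- agg$bins
  seg_len <- segments$end - segments$start
  cols <- list()
  for (nm in colnames(agg$states)) cols[[nm]] <- agg$states[[nm]]
  for (nm in names(continuous_tracks)) {
    segv <- .segment_track_means(segments, continuous_tracks[[nm]], impute, nm)
    num <- rowsum(segv * seg_len, segments$bin_id)
    cols[[nm]] <- as.numeric(num[as.character(bins$bin_id), 1]) / bins$length_bp
  }
  X <- do.call(cbind, cols)
  if (is.null(X)) X <- matrix(numeric(0), nrow = nrow(bins), ncol = 0)
  rownames(X) <- bins$bin_id
  X
}

# 64-long trinucleotide count vector for one segment, counting only centres
# that lie inside the segment and have both flanks on the chromosome. The
# segment is extended by one flanking base on each side (clipped at the
# chromosome ends); triplet centres of the extended window then coincide
# exactly with the segment's usable positions.
.segment_tri_counts <- function(chrseq, start, end) {
  L <- length(chrseq)
  lo <- max(start - 1L, 0L); hi <- min(end + 1L, L)
  if (hi - lo < 3L) return(stats::setNames(rep(0L, 64), .tri_names))
  s <- Biostrings::subseq(chrseq, lo + 1L, hi)
  Biostrings::trinucleotideFrequency(s, step = 1)[.tri_names]
}

#' Per-bin context availability over the 192 channels
#'
#' `t[b, m]` counts the positions in bin `b` whose reference trinucleotide
#' provides the context of channel `m` in its orientation; each usable
#' position contributes to exactly the three substitution channels of its
#' oriented context. Positions with ambiguous bases (N) or without a full
#' trinucleotide context contribute zero.
#'
#' @param agg Output of [aggregate_bins()].
#' @param genome `DNAStringSet` or FASTA path covering all segments.
#' @return Integer matrix (bins x 192).
#' @export
compute_context_availability <- function(agg, genome) {
  genome <- .as_genome(genome)
  segments <- agg$segments
  bins <- agg$bins
  miss <- setdiff(unique(segments$chrom), names(genome))
  if (length(miss))
    stop("missing sequence for chromosome(s): ", paste(miss, collapse = ", "))
  tri <- matrix(0, nrow = nrow(segments), ncol = 64,
                dimnames = list(NULL, .tri_names))
  for (i in seq_len(nrow(segments))) {
    tri[i, ] <- .segment_tri_counts(genome[[segments$chrom[i]]],
                                    segments$start[i], segments$end[i])
  }
  bin_tri <- rowsum(tri, segments$bin_id)
  bin_tri <- bin_tri[as.character(bins$bin_id), , drop = FALSE]
  t_bm <- bin_tri %*% .tri_to_type
  dimnames(t_bm) <- list(bins$bin_id, mutation_type_labels())
  t_bm
}

#' Build a complete genome binning
#'
#' Convenience constructor running segmentation, aggregation, feature-matrix
#' assembly and context-availability counting.
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param discrete_tracks Named list of BED-style data.frames.
#' @param continuous_tracks Named list of bedGraph-style data.frames.
#' @param feature_class Named character vector mapping every feature column
#'   to one of `"macro"`, `"meso"`, `"strand"`. Features absent from the map
#'   default to `"meso"` (`"strand"` for `*_strand` columns).
#' @param interval_bp Fixed grid width (default 10000).
#' @param scope Aggregation scope, see [aggregate_bins()].
#' @param impute Continuous-feature imputation policy.
#' @param gc Logical; add a `gc` macro feature computed from the sequence.
#' @return A `mutopia_binning` object.
#' @export
build_binning <- function(genome, discrete_tracks = list(),
                          continuous_tracks = list(), feature_class = NULL,
                          interval_bp = 10000L,
                          scope = c("window", "chromosome"),
                          impute = "chrom_mean", gc = FALSE) {
  scope <- match.arg(scope)
  genome <- .as_genome(genome)
  lengths <- genome_lengths(genome)
  segments <- segment_genome(lengths, discrete_tracks, interval_bp)
  agg <- aggregate_bins(segments, discrete_tracks, scope)
  X <- build_feature_matrix(agg, continuous_tracks, impute)
  if (gc && nrow(agg$bins)) {
    segs <- agg$segments
    gcv <- vapply(seq_len(nrow(segs)), function(i) {
      s <- Biostrings::subseq(genome[[segs$chrom[i]]], segs$start[i] + 1L,
                              segs$end[i])
      fr <- Biostrings::alphabetFrequency(s)[c("A", "C", "G", "T")]
      if (sum(fr) == 0) return(NA_real_)
      (fr[["C"]] + fr[["G"]]) / sum(fr)
    }, numeric(1))
    seg_len <- segs$end - segs$start
    gcv[is.na(gcv)] <- mean(gcv, na.rm = TRUE)
    num <- rowsum(gcv * seg_len, segs$bin_id)
    X <- cbind(X, gc = as.numeric(num[as.character(agg$bins$bin_id), 1]) /
                 agg$bins$length_bp)
  }
  fc <- stats::setNames(rep("meso", ncol(X)), colnames(X))
  fc[grepl("_strand$", names(fc))] <- "strand"
  if (gc) fc["gc"] <- "macro"
  if (!is.null(feature_class)) {
    bad <- setdiff(names(feature_class), names(fc))
    if (length(bad)) stop("feature_class names not in feature matrix: ",
                          paste(bad, collapse = ", "))
    fc[names(feature_class)] <- feature_class
  }
  stopifnot(all(fc %in% c("macro", "meso", "strand")))
  t_bm <- compute_context_availability(agg, genome)
  structure(list(segments = agg$segments, bins = agg$bins, X = X,
                 feature_class = fc, t = t_bm,
                 interval_bp = as.integer(interval_bp), scope = scope,
                 genome_lengths = lengths,
                 type_labels = mutation_type_labels()),
            class = "mutopia_binning")
}

#' @export
print.mutopia_binning <- function(x, ...) {
  cat(sprintf("mutopia binning: %d bins / %d segments over %d chromosome(s) (%d bp)\n",
              nrow(x$bins), nrow(x$segments), length(x$genome_lengths),
              sum(x$genome_lengths)))
  cat(sprintf("  features: %s\n",
              paste(sprintf("%s[%s]", colnames(x$X), x$feature_class),
                    collapse = ", ")))
  invisible(x)
}

#' Indices of bins on given chromosomes
#' @param binning A `mutopia_binning`.
#' @param chroms Character vector of chromosome names.
#' @return Integer vector of bin ids.
#' @export
bins_on_chromosomes <- function(binning, chroms) {
  binning$bins$bin_id[binning$bins$chrom %in% chroms]
}

#' Serialize a binning to plain-text tables
#'
#' Writes `<prefix>.bins.tsv`, `<prefix>.segments.tsv`, `<prefix>.X.tsv` and
#' a sparse triplet `<prefix>.availability.tsv`.
#' @param binning A `mutopia_binning`.
#' @param prefix Output path prefix.
#' @export
write_binning <- function(binning, prefix) {
  utils::write.table(binning$bins, paste0(prefix, ".bins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(binning$segments, paste0(prefix, ".segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  Xdf <- data.frame(bin_id = binning$bins$bin_id, binning$X,
                    check.names = FALSE)
  utils::write.table(Xdf, paste0(prefix, ".X.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  idx <- which(binning$t > 0, arr.ind = TRUE)
  trip <- data.frame(bin_id = binning$bins$bin_id[idx[, 1]],
                     type = idx[, 2], count = binning$t[idx])
  utils::write.table(trip[order(trip$bin_id, trip$type), ],
                     paste0(prefix, ".availability.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
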