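test_that("segmentation unions the fixed grid with track breakpoints", {
  # grid only
  segs <- segment_genome(c(chr1 = 25000L), interval_bp = 10000L)
  expect_equal(segs$start, c(0L, 10000L, 20000L))
  expect_equal(segs$end, c(10000L, 20000L, 25000L))
  # grid + one gene interval
  gene <- data.frame(chrom = "chr1", start = 4000L, end = 6000L)
  segs <- segment_genome(c(chr1 = 25000L), list(gene = gene), 10000L)
  expect_equal(sort(unique(c(segs$start, segs$end))),
               c(0L, 4000L, 6000L, 10000L, 20000L, 25000L))
  # zero-length genome
  expect_equal(nrow(segment_genome(c(chr1 = 0L), interval_bp = 10000L)), 0)
})

test_that("segmentation validates tracks", {
  bad <- data.frame(chrom = "chr1", start = c(0L, 500L), end = c(1000L, 900L))
  expect_error(segment_genome(c(chr1 = 5000L), list(peaks = bad)),
               "peaks.*overlap")
  off <- data.frame(chrom = "chrX", start = 0L, end = 10L)
  expect_error(segment_genome(c(chr1 = 5000L), list(g = off)),
               "absent from the genome")
})

test_that("same-state segments aggregate into one bin, conserving length", {
  # two non-adjacent gene segments inside one window share a bin
  gene <- data.frame(chrom = "chr1", start = c(1000L, 4000L),
                     end = c(2000L, 5000L))
  segs <- segment_genome(c(chr1 = 10000L), list(gene = gene), 10000L)
  agg <- aggregate_bins(segs, list(gene = gene))
  expect_equal(nrow(agg$bins), 2L)      # gene bin + background bin
  gene_bin <- agg$bins[agg$bins$length_bp == 2000L, ]
  expect_equal(nrow(gene_bin), 1L)
  members <- agg$segments[agg$segments$bin_id == gene_bin$bin_id, ]
  expect_equal(nrow(members), 2L)
  # total length conserved
  expect_equal(sum(agg$bins$length_bp), 10000L)
  # all-distinct states: one bin per segment
  toy <- get_toy()
  expect_equal(sum(toy$binning$bins$length_bp),
               sum(toy$binning$genome_lengths))
})

test_that("feature matrix takes length-weighted means with convexity", {
  gene <- data.frame(chrom = "chrA", start = c(0L, 200L),
                     end = c(100L, 500L))
  segs <- segment_genome(c(chrA = 1000L), list(gene = gene), 1000000L)
  agg <- aggregate_bins(segs, list(gene = gene))
  trk <- data.frame(chrom = "chrA", start = c(0L, 100L),
                    end = c(100L, 1000L), value = c(1.0, 2.0))
  X <- build_feature_matrix(agg, list(sig = trk))
  gene_bin <- which(agg$bins$length_bp == 400L)
  expect_equal(X[gene_bin, "sig"], (100 * 1 + 300 * 2) / 400)  # 1.75
  # constant track: every bin gets the constant
  cst <- data.frame(chrom = "chrA", start = 0L, end = 1000L, value = 3.3)
  Xc <- build_feature_matrix(agg, list(c0 = cst))
  expect_true(all(Xc[, "c0"] == 3.3))
  # convexity: [0, 1] tracks give values in [0, 1]
  toy <- get_toy()
  expect_true(all(toy$binning$X[, "repli"] >= 0 &
                    toy$binning$X[, "repli"] <= 1))
  # imputation disabled errors on gaps
  gap <- data.frame(chrom = "chrA", start = 0L, end = 500L, value = 1)
  expect_error(build_feature_matrix(agg, list(g = gap), impute = "none"),
               "uncovered")
})

test_that("context availability matches a brute-force positional oracle", {
  # printed example: AAAA has two usable centres, context AAA -> the three
  # reverse-orientation channels of TTT
  b <- tiny_binning("AAAA")
  expect_equal(sum(b$t), 6)
  lab <- mutation_type_labels()
  hit <- which(b$t[1, ] > 0)
  expect_true(all(grepl("^T\\[T>[ACG]\\]T:-$", lab[hit])))
  expect_true(all(b$t[1, hit] == 2))
  # ambiguous bases contribute nothing
  bn <- tiny_binning("NNNNNNNN")
  expect_true(all(bn$t == 0))
  # random sequence, exact agreement with the independent oracle
  s <- random_dna(500, seed = 9, with_n = TRUE)
  b2 <- tiny_binning(s)
  expect_equal(unname(colSums(b2$t)), availability_oracle(s))
})

test_that("availability is additive over merged bins", {
  s <- random_dna(4000, seed = 5)
  # fine grid: many bins
  fine <- tiny_binning(s, interval_bp = 500L)
  # coarse: one bin
  coarse <- tiny_binning(s, interval_bp = 1e6L)
  # interior context positions around the artificial grid cuts are kept by
  # the flank extension, so the totals agree exactly
  expect_equal(unname(colSums(fine$t)), unname(colSums(coarse$t)))
})

test_that("binning identical inputs is deterministic", {
  a <- make_toy_binning(seed = 3, chr_lengths = c(chr1 = 50000L))
  b <- make_toy_binning(seed = 3, chr_lengths = c(chr1 = 50000L))
  expect_identical(a$binning$bins, b$binning$bins)
  expect_identical(a$binning$X, b$binning$X)
  expect_identical(a$binning$t, b$binning$t)
})
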