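test_that("mutation weights follow VAF/purity with the exact CN=2 reduction", {
  expect_equal(mutation_weight(0.5, 1.0), 0.5)
  expect_equal(mutation_weight(0.25, 0.5), 0.5)
  expect_equal(mutation_weight(1.9, 0.5), 2)          # cap binds
  expect_equal(mutation_weight(1.9, 0.5, cap = Inf), 3.8)
  expect_error(mutation_weight(0.5, 0), "purity")
  # the full multiplicity expression reduces exactly to VAF/purity at CN=2
  set.seed(4)
  vaf <- runif(20, 0.05, 0.6); pur <- runif(20, 0.2, 1)
  expect_equal(mutation_weight_full(vaf, pur, cn_tot = 2), vaf / pur)
  # and differs away from CN = 2
  expect_false(isTRUE(all.equal(mutation_weight_full(0.3, 0.8, 4),
                                0.3 / 0.8)))
})

test_that("critical distance is the alpha-quantile of the exponential null", {
  expect_equal(critical_distance(0.001, 0.005), -2 * log(0.995) / 0.001)
  # alpha -> 0 collapses the distance
  expect_lt(critical_distance(0.001, 1e-9), 1e-2)
  # halving the rate doubles the distance
  expect_equal(critical_distance(0.0005, 0.01),
               2 * critical_distance(0.001, 0.01))
  expect_error(critical_distance(0.001, 0), "alpha")
  expect_error(critical_distance(0.001, 1), "alpha")
})

test_that("cohort local rates average a centred 50-kb window", {
  L <- c(chr1 = 1000000L)
  set.seed(11)
  # uniform cohort: everywhere the genome-wide mean
  coh <- data.frame(chrom = "chr1", pos = sort(sample.int(1e6, 5000) - 1L))
  mu <- local_rate_relative("chr1", 500000L, coh, L)
  expect_equal(mu, 1 / 1e6, tolerance = 0.15)
  # hotspot holding 10% of cohort mutations: brute-force window count
  hot <- data.frame(chrom = "chr1",
                    pos = c(sort(sample(480000:520000, 500)),
                            sort(sample.int(1e6, 4500) - 1L)))
  p <- 500000L
  cnt <- sum(hot$pos >= p - 25000 & hot$pos < p + 25000)
  expect_equal(local_rate_relative("chr1", p, hot, L),
               (cnt / 50000) / nrow(hot))
  # burden linearity of the data term
  expect_equal(local_rate(2e-6, burden = 2000, pseudocount = 0),
               2 * local_rate(2e-6, burden = 1000, pseudocount = 0))
  expect_equal(local_rate(1e-6, 1000, pseudocount = 1),
               1e-3 + 1 / 50000)
})

test_that("cluster detection caps linking at 10 kb and groups runs", {
  # d* far above 10 kb, but the cap separates mutations 10001 bp apart
  m <- data.frame(chrom = "chr1", pos = c(0L, 10001L))
  cl <- detect_clusters(m, mu_hat = rep(1e-9, 2), alpha_clust = 0.5)
  expect_equal(length(unique(cl)), 2L)
  # 1-bp spacing clusters regardless
  m3 <- data.frame(chrom = "chr1", pos = c(100L, 101L, 102L))
  cl3 <- detect_clusters(m3, mu_hat = rep(1e-4, 3))
  expect_equal(length(unique(cl3)), 1L)
  # chromosome boundaries break clusters
  m4 <- data.frame(chrom = c("chr1", "chr2"), pos = c(100L, 101L))
  expect_equal(length(unique(detect_clusters(m4, rep(1e-4, 2)))), 2L)
})

test_that("cluster weight adjustment conserves one observation per cluster", {
  expect_equal(adjust_cluster_weights(0.7, 1L), 0.7)
  expect_equal(adjust_cluster_weights(c(0.6, 0.6, 0.6), c(1L, 1L, 1L)),
               c(0.2, 0.2, 0.2))
  set.seed(8)
  w <- runif(30); cl <- sample.int(6, 30, replace = TRUE)
  adj <- adjust_cluster_weights(w, cl)
  expect_true(all(adj <= w + 1e-15))
  for (g in unique(cl))
    expect_equal(sum(adj[cl == g]), mean(w[cl == g]))
  expect_identical(adjust_cluster_weights(w, cl, enabled = FALSE), w)
})

test_that("the count tensor conserves adjusted weight mass", {
  toy <- get_toy()
  co <- get_cohort()
  tensor <- co$tensor
  # totals: weights capped at 2, positive
  expect_true(all(tensor$cells$weight > 0))
  # conservation against an independent re-aggregation of the same inputs
  raw <- mutation_weight(co$mutations$vaf,
                         tensor$samples$purity[
                           match(co$mutations$sample,
                                 tensor$samples$sample_id)])
  expect_lte(sum(tensor$cells$weight), sum(raw) + 1e-8)
  # disabling cluster adjustment reproduces raw weights exactly
  t2 <- build_count_tensor(co$mutations, toy$binning, co$sim$samples,
                           cluster_adjust = FALSE)
  expect_equal(sum(t2$cells$weight), sum(raw))
  # identical (sample, bin, type) entries merge additively
  m <- co$mutations[1, , drop = FALSE]
  two <- rbind(m, m)
  attr(two, "n_dropped") <- 0L
  t3 <- build_count_tensor(two, toy$binning, co$sim$samples)
  expect_equal(nrow(t3$cells), 1L)
  w1 <- mutation_weight(m$vaf, tensor$samples$purity[
    match(m$sample, tensor$samples$sample_id)])
  # the two duplicates form one cluster of 2: each contributes w/2
  expect_equal(t3$cells$weight, w1)
})

test_that("ingestion is deterministic and drops unresolvable contexts", {
  toy <- get_toy()
  co <- get_cohort()
  a <- build_count_tensor(co$mutations, toy$binning, co$sim$samples)
  b <- build_count_tensor(co$mutations, toy$binning, co$sim$samples)
  expect_identical(a$cells, b$cells)
  # a mutation at position 0 has no 5' flank: dropped with a message
  bad <- co$sim$mutations[1, , drop = FALSE]
  bad$pos <- 0L
  expect_message(ann <- annotate_mutations(bad, toy$binning, toy$genome),
                 "dropped")
  expect_equal(nrow(ann), 0L)
})

test_that("MAF-style TSV and VCF readers agree on shared records", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "m.tsv")
  writeLines(c("sample\tchrom\tpos\tref\talt\tvaf",
               "s1\tchr1\t101\tC\tA\t0.4",
               "s1\tchr1\t201\tG\tT\t0.2"), tsv)
  m <- read_mutations_tsv(tsv)
  expect_equal(m$pos, c(100L, 200L))   # 1-based input -> 0-based internal
  vcf <- file.path(dir, "m.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
               "chr1\t101\t.\tC\tA\t.\t.\t.\tGT:AD\t0/1:6,4",
               "chr1\t201\t.\tG\tT\t.\t.\tAF=0.2\tGT\t0/1"), vcf)
  v <- read_mutations_vcf(vcf)
  expect_equal(v$pos, m$pos)
  expect_equal(v$vaf, c(0.4, 0.2))     # AD takes precedence, then AF
})
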