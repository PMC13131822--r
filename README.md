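# mutopia

Joint inference of mutational-process spectra and their genome-wide
mutation-rate topographies from somatic SNV calls.

## The problem

Mutational-signature analysis decomposes a tumor's single-base
substitutions into processes by their characteristic base-change patterns
(e.g. 96 or 192 trinucleotide channels), but says nothing about **where**
in the genome each process acts. Mutation rates vary several-fold with
replication timing, chromatin state, transcription and strand — and that
topography carries biology that spectra alone cannot resolve (repair
proficiency, replication stress, damage processing). `mutopia` is for
cancer-genomics analysts who want to infer, from a cohort of
whole-genome-sequenced tumors plus genomic feature tracks, both each
process's spectrum and its genome-wide rate profile as a nonlinear function
of genomic state — and to compare those profiles across cohorts
("topotypes").

## The model

Mutations are draws from a mixture of K latent processes. Sample exposures
follow `pi_n ~ Dir(alpha)`; a mutation picks a process
`z ~ Cat(pi_n)`, then a genomic bin `b` and stranded trinucleotide channel
`m` from the process topography

```
p(b, m | z = k)  ∝  t[b,m] · exp( f_k(X_b) + g_km(X_b) )
```

where `t[b,m]` counts the positions in bin `b` offering channel `m`'s
context (context availability), `f_k` is a gradient-boosted-tree log-rate
function of macro-scale features (replication timing, histone marks,
accessibility, expression), and `g_km` combines a baseline 192-channel
log-spectrum with sparse l1-penalized adjustments from meso-scale and
strand-oriented features. Mutations are weighted `VAF/purity` (the exact
copy-number multiplicity at total copy number 2) and clustered mutations
(kataegis-like runs closer than the critical distance
`d* = -2 ln(1 - alpha) / mu_hat`, capped at 10 kb) are down-weighted so
each cluster counts once. Fitting is LDA-style mean-field variational
inference (coordinate-ascent E/M with optional stochastic subsampling over
genomic bins); goodness of fit is a multinomial pseudo-R² anchored at 0 by
an availability-proportional null and at 1 by the saturated per-sample
empirical distribution. See `vignettes/mutopia-methods.Rmd` for the full
account.

## Worked example

Everything below runs on bundled synthetic fixtures — no downloads. A toy
genome (1 Mb, two chromosomes) with gene/ATAC/replication-timing/strand
tracks is binned, a 4-process reference simulates a cohort, and the model
is re-fitted from the raw mutation table:

```r
library(mutopia)

toy <- make_toy_binning(seed = 1)        # genome + tracks -> feature bins
toy$binning

ref <- toy_reference_model(toy$binning, K = 4, seed = 1)
sim <- simulate_cohort(ref, toy$binning, toy$genome,
                       n_samples = 40, gamma = 1, seed = 2)
ann <- annotate_mutations(sim$mutations, toy$binning, toy$genome)
tensor <- build_count_tensor(ann, toy$binning, sim$samples)
tensor

fit <- fit_mutopia(tensor, toy$binning,
                   mutopia_config(K = 4, seed = 3))
fit

# how well do fitted spectra match the generating processes?
fitted <- sapply(fit$model$processes, function(p)
  marginal_spectrum(p, toy$binning$X, toy$binning$t))
truth <- sapply(ref$model$processes, function(p)
  marginal_spectrum(p, toy$binning$X, toy$binning$t))
round(apply(t(truth) %*% fitted /
  outer(sqrt(colSums(truth^2)), sqrt(colSums(fitted^2))), 1, max), 3)

# generalization to the held-out chromosome
ev <- evaluate_heldout(tensor, toy$binning,
                       mutopia_config(K = 4, seed = 3), "chr2")
ev$report$pseudo_r2
```

Output with the seeds above:

```
mutopia binning: 246 bins / 298 segments over 2 chromosome(s) (1000000 bp)
  features: gene[meso], gene_strand[strand], atac[meso], repli[macro], h3k9me3[macro], expression[meso], rep_strand[strand]
mutopia tensor: 40 samples, 246 bins, 18899 nonzero cells, total weight 10290.04
mutopia fit: K = 4, 42 epochs, ELBO -92866.500 (converged)
[1] 0.999 0.839 0.979 0.998
[1] 0.3173357
```

The binning line reports feature-defined bins over the toy genome; the
tensor line gives the weighted mutation mass after VAF/purity weighting and
cluster adjustment (~21k raw mutations). The per-process cosine
similarities (one per generating process, best fitted match) show three of
the four spectra recovered near-exactly at this modest burden, with the
weakest-exposed process at 0.84 — recovery sharpens with cohort size and
burden, as the test suite's benchmark demonstrates. The held-out pseudo-R²
of 0.32 is the fraction of the null-to-saturated likelihood gap explained
on a chromosome never seen during training; the saturated reference is
per-sample and at this per-sample burden (~500 mutations) mostly memorizes
sampling noise, so values well below 1 are expected even for the
generating model.

Exposures, rate profiles, spectra and Shapley feature attributions are
written as tidy tables by `write_outputs(fit, tensor, toy$binning, dir)`;
`transfer_profiles()` + `topotype_cluster()` compare rate profiles across
models and cluster them with Leiden. A thin command-line wrapper lives at
`inst/cli/mutopia.R` (subcommands `fixtures`, `bin`, `ingest`, `train`,
`simulate`, `refit`, `evaluate`).

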