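---
title: "Modelling mutational topography with mutopia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mutational topography with mutopia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Somatic mutations in a tumor genome are treated as draws from a mixture of
$K$ latent mutational processes. Each sample $n$ carries an exposure vector
$\pi_n \sim \mathrm{Dir}(\alpha)$ on the $K$-simplex; each mutation first
selects a process $z \sim \mathrm{Cat}(\pi_n)$ and then a genomic bin $b$
and a stranded trinucleotide channel $m \in \{1,\dots,192\}$ from the
process-specific *topography*

$$
p(b, m \mid z = k) \;\propto\; t_{bm}\,
\exp\!\big(f_k(X_b) + g_{km}(X_b)\big),
$$

normalized over all bins and channels. The three factors are

* $t_{bm}$, the **context availability**: the number of positions in bin
  $b$ whose reference trinucleotide provides channel $m$'s context in its
  orientation. Channels whose context never occurs in a bin receive
  probability exactly zero, never a floor value.
* $f_k(X_b)$, the **macro-scale log-rate**: a function of macro-class
  features (replication timing, heterochromatin marks, accessibility,
  expression summaries) fitted by histogram gradient-boosted trees with a
  Poisson objective (shallow trees, depth 3 by default). A linear and a
  constant flavor exist as ablations.
* $g_{km}(X_b)$, the **spectrum term**: a baseline 192-channel
  log-spectrum plus sparse adjustments. Meso-class features (gene bodies,
  accessibility peaks, expression) carry per-channel $\ell_1$-penalized
  coefficients. Strand-class features (transcription strand, replication
  strand) enter through the product of the feature value and the channel's
  orientation sign, in two tiers: one lightly penalized coefficient shared
  across channels, and heavily penalized per-channel deviations. The tiers
  encode a preference for uniform strand effects over channel-specific
  asymmetries; the exact parameterization is this package's own design.

Mutation counts are real-valued weights rather than integers: each SNV
contributes $w = \mathrm{VAF}/\mathrm{purity}$ (capped at 2 by default),
the exact reduction of the copy-number multiplicity fraction at total copy
number two. Runs of mutations closer than expected under a cohort-calibrated
Poisson null are grouped and down-weighted by cluster size, so a clustered
event (e.g. kataegis) contributes one observation-equivalent. The critical
distance is $d^{*} = -2\ln(1-\alpha_{\mathrm{clust}})/\hat\mu$ with
$\hat\mu = M_n \mu_i + M/50{,}000$ per base: the sample burden $M_n$ times
the cohort-relative density $\mu_i$ in a centred 50-kb window, plus one
pseudo-mutation spread over the window ($M = 1$). The $\hat\mu/2$
exponential null embeds a copy-number-2 assumption: mutations arise per
genome copy at rate $\hat\mu/2$, so the test's rejection rate equals
$\alpha_{\mathrm{clust}}$ under that generative null (the package's
calibration test simulates exactly this). Linking is capped at 10 kb.

## Genome binning

The genome is partitioned at every discrete-feature state change and at a
fixed 10-kb grid (restarting at chromosome boundaries), producing segments
of constant discrete state. Segments with identical discrete state merge
into one bin even when non-contiguous. Merging is scoped to the 10-kb
window by default: the window index is part of the aggregation key. A
genome- or chromosome-wide merge would average continuous macro features
(replication timing above all) across distant loci and destroy the very
rate-feature relationships the model estimates, and it would create bins
spanning chromosomes, which the held-out-chromosome evaluation forbids; a
`"chromosome"` scope remains available for callers who want it. Continuous
features are length-weighted means over the bin's bases; uncovered bases
take the track's chromosome mean (configurable to an error). Ambiguous (N)
bases contribute no context availability; soft-masked bases are treated as
ordinary sequence because the sequence container upper-cases on read.

## Inference

The marginal likelihood integrates over $\pi_n$ and sums over assignments,
so the model is fitted by mean-field variational inference with
$q(\pi, z) = \prod_n q(\pi_n \mid \beta_n) \prod_{c} q(z_c \mid \phi_c)$
over the nonzero tensor cells $c$. The E-step iterates the exact updates
$\phi_{c,k} \propto \exp(\mathbb{E}[\log \pi_{nk}])\, p(b, m \mid k)$ (the
digamma identity supplies the expectation) and
$\beta_{nk} = \alpha_k + \sum_c Y_c \phi_{c,k}$ to a local fixed point, so
a repeated E-step is a no-op. The M-step refits, per process,

1. the macro trees: Poisson regression of responsibility-weighted per-bin
   counts against macro features with offset
   $\log \sum_m t_{bm} e^{g_{km}(X_b)}$;
2. the baseline spectrum in closed form (per-channel Poisson intercepts;
   zero-count channels are floored 30 nats below the maximum to stay
   finite, a change of at most $\sim 10^{-13}$ in any probability);
3. the sparse adjustments by a penalized Poisson fit over all available
   $(b, m)$ cells, with the tiered penalty factors above;

and updates $\alpha$ by Minka's fixed point (floored at $10^{-3}$).

Two design choices keep the optimization honest. First, every regression
refit is **guarded**: new parameters are kept only when they do not
decrease their ELBO term, so full-batch coordinate ascent is monotone even
though tree and lasso fits are inexact. Second, the $\ell_1$ penalties are
treated as Laplace log-priors and *included* in the traced objective (a MAP
ELBO); excluding them would allow legitimate penalized updates to lower the
traced quantity. The likelihood and penalty components are available
separately.

Stochastic training subsamples genomic bins (not samples), scales the
sufficient statistics by the inverse sampling fraction, and blends the
exposure posteriors with a $(t + \tau)^{-\kappa}$ step size; at batch
fraction 1 the code path is plain coordinate ascent. Convergence is
declared when the relative ELBO change over a 10-epoch window falls below
$10^{-6}$ (500-epoch cap; all configurable). Initialization seeds baseline
spectra either from supplied reference spectra or from the cohort's
empirical spectrum with small seeded jitter to break symmetry; macro
effects start constant and responsibilities come from a spectra-only
E-step.

## Evaluation

Goodness of fit on held-out chromosomes uses the multinomial pseudo-$R^2$:
with score $S = \sum Y \log \hat p(b, m \mid n)$, the metric
$1 - (S^{(1)} - S)/(S^{(1)} - S^{(0)})$ anchors the
availability-proportional null at 0 and the per-sample empirical
(saturated) distribution at 1. Held-out exposures are re-estimated from the
training region only (E-steps under the frozen model, topographies
renormalized over the training bins), then predictions are renormalized
over the held-out bins. Rate-profile agreement uses a Poisson deviance
pseudo-$R^2$ with a uniform null scaled to the observed mass. Ablations
(`linear` macro effects; `lda` with constant rates and baseline spectra
only; `locus_only` with $K = 1$) train on identical folds and seeds.
Group-level validation compares the mixture identity
$p(z = k \mid G) \propto \sum_{b \in G} p(b \mid k) \sum_n p(n) \pi_{nk}$
against non-negative least squares on the group's pooled spectrum, over
equal-bp feature quantiles (eight by default) or a 15-way gene-relative
grouping (five positional classes crossed with expression tertiles — the
positional scheme is this package's reading of a loosely specified
protocol, and arbitrary group vectors are accepted).

## The synthetic cohort generator

The bundled generator emulates every input the pipeline consumes: a
two-chromosome toy genome (600 kb + 400 kb; chr2 is the conventional
held-out chromosome), gene and accessibility-peak BED tracks, smooth
replication-timing and heterochromatin bedGraphs, per-gene expression, and
an alternating replication-strand track. The toy reference model assigns
each process a sparse spectrum concentrated on one substitution class with
a sharpened context preference, a nonlinear macro response (step, V-shape,
interaction, saturating — ordered nonlinear-first so rate-model ablations
separate), mild strand coefficients, and occasional meso adjustments.
Reference exposures are drawn from three Dirichlet archetypes (inducing
realistic process covariance) with lognormal burdens around 500 mutations
per sample; simulated cohorts resample (exposure, burden) pairs jointly,
draw Poisson($\gamma M$) mutations, and place each mutation uniformly among
the context-compatible positions of its sampled bin, with Beta-distributed
VAFs around purity/2. What the generator does *not* emulate: real
chromatin covariance structure, copy-number variation, indels/SVs, sample
contamination, or sequencing artifacts — recovery results on it bound what
the implementation can do under its own assumptions, not performance on
real tumors.

Benchmark problem sizes in the test suite are chosen for desk-scale
reproducibility: recovery uses 100-sample cohorts at burden scales
$\gamma \in \{1/4, 1, 4\}$ (about 13k–200k mutations), with three replicate
fits (best by pseudo-$R^2$) at the central burden and single fits at the
flanking burdens; ablations use ten replicate 25-sample cohorts; the ELBO
monotonicity check runs 50 full-batch epochs on a 15-sample cohort.

## Topotype analysis

Rate profiles from different models are compared by evaluating each
process's topography on a shared feature matrix and availability (the
marginal over channels), so tissue-specific feature landscapes do not
confound the comparison. Pairwise cosine similarities over the evaluation
bins (a held-out chromosome in practice) feed a symmetrized 10-NN graph;
communities come from Leiden at resolution 0.2. The 2-D view is a seeded
force-directed (Fruchterman–Reingold) layout of that same similarity
graph — a graph-layout embedding, chosen because the clustering itself
depends only on the kNN graph. Shapley attributions of the macro effects
use exact tree-path attribution with the bin feature matrix as background
(closed form for linear effects, seeded permutation sampling otherwise);
feature impact is the 0.97 quantile of absolute attributions and
directionality is the Pearson correlation between attributions and feature
values (0 on zero variance; Pearson because the quantity summarises the
strength of a linear relationship).

## Numerical choices and degenerate inputs

Distributions are normalized by log-sum-exp; zero-availability cells are
hard zeros. Ties in bin ordering are broken by discrete state key, then
chromosome order, then coordinate, making binning byte-reproducible. A
process that loses all responsibility mass is frozen with a warning rather
than refitted on an empty target. Empty samples refit to prior-mean
exposures with a flag. Degenerate held-out data (saturated score equal to
the null score) raises an error rather than returning 0/0. All randomness
— initialization jitter, bin subsampling, simulation, subsampled
benchmarks, layouts — flows from integer seeds recorded in configs and
outputs.

## Known limitations

The strand-adjustment tiering and the gene-relative grouping are this
package's own parameterizations of loosely specified designs. The guard
strategy trades occasional rejected M-steps for monotonicity; on pathological
data this can slow convergence. Exposure recovery for processes with very
low cohort mass is biased toward flatter rate profiles at finite burden
(responsibility smearing); replicate fits with selection by pseudo-$R^2$
mitigate but do not remove this. Indels, structural variants and
copy-number inference are out of scope.
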