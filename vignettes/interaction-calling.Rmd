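---
title: "Calling chromatin interactions from 4C-seq fragment counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling chromatin interactions from 4C-seq fragment counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopcall4c)
```

# The problem

Circular chromosome conformation capture (4C-seq) surveys, from one fixed
"bait" restriction fragment, which other genomic fragments were spatially
close to it in the nucleus. After digestion (here a 6-cutter primary
digest such as EcoRI), re-ligation, a secondary digest and inverse PCR,
sequencing reads land on the fragments the bait contacted. The analysis
question is: given unique-read counts over the genome-wide set of
restriction fragments, which fragments are the bait's reproducible,
strongly positive interaction partners?

The counting universe is the in-silico restriction-fragment library: the
intervals between consecutive top-strand cut positions, tiling every
chromosome exactly. Reads are unique-filtered, deduplicated by their
(chromosome, 5' position, strand) triple, and assigned to the fragment
containing their 5' end, because 4C reads start at ligation junctions.

# The estimator

The share of reads in any one fragment is tiny, so raw proportions
`n_i / N` are noisy and zero-inflated. We model the per-fragment counts as
independent Poisson variables; conditional on the total `N` the vector is
multinomial over the `K` unmasked fragments (the multinomial-Poisson
equivalence), and inference is done on the conditional multinomial. With a
symmetric Dirichlet prior of mass $\gamma$ per fragment the posterior is

$$ p \mid n \sim \mathrm{Dirichlet}(n_1 + \gamma, \ldots, n_K + \gamma). $$

Because fold change is the natural effect-size scale, the reported
statistic is the posterior expectation of the log2 proportion,

$$ \mathrm{E}[\log_2 p_i \mid n] =
   \frac{\psi(n_i + \gamma) - \psi(N + K\gamma)}{\ln 2}, $$

with $\psi$ the digamma function. For browser display the estimates are
mapped back to linear space and multiplied by an integer scaling factor
`S`: `round(S * 2^elog2p)`.

We use $\gamma = 0.5$ by default, a Jeffreys-style minimally informative
choice for the multinomial; $\gamma$ is a parameter of every estimation
function, and the closed form above covers any value, so the analysis is
easy to probe for prior sensitivity. Note that for an all-zero count
vector the expectation is *below* $-\log_2 K$ by the Jensen gap of the
logarithm — the prior-only estimate is the digamma value, not
$\log_2(1/K)$.

## Why Monte Carlo, and why a stratified sampler

The expectation has a closed form, but downstream users also want the
posterior spread of `log2 p_i` (reported as `mc_sd`) and the machinery
generalizes to functionals without closed forms (the binned profiles
reuse it unchanged). Estimation therefore draws `M` Dirichlet instances
and averages.

The sampler is a Latin-hypercube (stratified-quantile) construction: for
fragment `i`, a random permutation of the midpoint quantiles
$(k - \tfrac12)/M$ is pushed through the Gamma quantile function with
shape $n_i + \gamma$, and each instance (column) is normalized to a
proportion vector. This has three properties a plain `rgamma` sampler
lacks:

* **Exact ties and monotonicity.** The mean over the full quantile grid
  is permutation-invariant and strictly increasing in the Gamma shape, so
  fragments with equal counts get bit-identical estimates and larger
  counts always give strictly larger estimates — no Monte-Carlo rank
  noise in the call ordering.
* **Accuracy.** Per-fragment stratification removes almost all of the
  variance of the `log2 Gamma` term; at `M = 10^4` the mean absolute
  deviation from the digamma closed form is below `10^-3` log2 units
  across count vectors with `K <= 10`, `N <= 100` (the test suite asserts
  `< 0.01`).
* **Determinism.** Identical `(counts, gamma, M, seed)` give bit-identical
  output; the sampler also restores the caller's RNG state.

```{r estimator}
est <- posterior_log2_proportions(c(f1 = 9, f2 = 1), M = 1e4, seed = 1)
est$elog2p
elog2p_closed_form(c(9, 1))   # analytic reference
scale_linear(est, S = 1e6)$linear_scaled
```

# Calling rules

* **Universe.** "Interacting sites" are unmasked fragments with at least
  one read. Zero-count fragments carry prior-only estimates but are
  flagged out of the universe; the bait fragment and (with
  `mask_radius > 0`) its neighbourhood are masked because the
  self-ligation product and bait-proximal ligation noise dominate there.
  The default pipeline masks 100 kb around the bait, a standard
  viewpoint-exclusion choice.
* **Strong calls.** Exactly `floor(q * |universe|)` fragments with the
  highest `elog2p`, `q = 0.10`: the top decile of interacting sites. Ties
  at the boundary break by higher count, then lower genomic coordinate,
  so call sets are reproducible run to run.
* **cis/trans.** A call on the bait chromosome is cis, anything else
  trans.
* **Replicates.** The reproducible common set is the fragment-identity
  intersection across replicate call sets (all replicates share one
  fragment library). A proximity mode (`tolerance > 0`) is available for
  comparing call sets that should match within a genomic distance;
  identity is the default because it is symmetric, associative and
  idempotent.
* **Distance strata.** Cis calls are summarized by their genomic gap to
  the bait fragment: within 50 kb, within 1 Mb, beyond 1 Mb.
* **Binning.** For domain-scale views, fragment counts are summed into
  fixed-width bins (1 Mb default) by fragment midpoint — midpoint
  assignment avoids double-counting fragments that span a bin edge, and a
  midpoint exactly on a boundary goes to the right-hand (half-open) bin —
  and the same Dirichlet estimator is re-run on the binned counts.

# The synthetic-data generator

Every analysis stage is exercised end to end on generated data, so the
generator encodes the study conditions rather than convenience values.

* **Genome.** Uniform random bases with recognition sites planted as a
  Poisson process at density 1/4096 per base (the genome-average density
  of a 6-bp site); chance occurrences arising in the random background
  are mutated away so the recorded site list is exact. The demo genome is
  four chromosomes — a 1 Mb bait chromosome and three 0.45 Mb trans
  chromosomes (about 570 fragments). This size keeps a full two-replicate
  run in seconds while leaving a calling universe (~500 fragments after
  masking) an order of magnitude larger than the planted signal set.
* **Contacts.** Expected fragment weights follow the standard 3C contact
  model: a power-law distance decay `(1 + d/d0)^-alpha` in cis (defaults
  `alpha = 1`, `d0 = 10 kb`), a uniform trans background (0.01 relative
  weight), an inflated bait self-ligation weight (50), and planted strong
  contacts — 30 cis (at least 100 kb from the bait, i.e. distal contacts
  outside the masked zone) and 20 trans — at 20x their local baseline.
* **Replicate noise.** Counts are Dirichlet-multinomial around the
  weights: fragment `i` receives Gamma shape `w_i / phi` (`phi = 0.01`),
  so replicate agreement is good but imperfect, which is what makes the
  replicate-intersection logic non-trivial. Reads are placed uniformly
  within their fragment, and 5% extra multi-mapping reads exercise the
  unique filter.
* **qPCR.** `Ct = -log_E(quantity) + N(0, sd)`; at zero noise every
  quantification formula inverts the simulation exactly.
* **FISH.** Co-localized pairs get distances uniform below the threshold,
  separated pairs uniform on `(threshold, 5*threshold)`, so the realized
  frequency equals the request exactly.

What the generator does **not** emulate: real sequence composition and
mappability structure, fragment-length and GC biases of inverse PCR,
Ion-Torrent flow-space errors, undigested-template carry-over, and the
domain-scale contact correlations of real chromatin (TADs, compartments).
Passing the recovery tests therefore shows the pipeline's statistics and
bookkeeping are correct under the declared noise model — not that the
top-decile rule has any particular sensitivity on real tissue data, where
background is structured and replicate agreement is worse.

```{r pipeline, eval = FALSE}
res <- run_pipeline(default_config(seed = 1), out_dir = "run1")
mean(res$truth$planted$fragment_id %in% res$common$fragment_id)
```

At these conditions (two replicates of 1e5 unique reads) the
replicate-common set recovers 94–96% of the 50 planted contacts with 0–4%
unplanted members across seeds, and with no planted contacts the mean
intersection over 50 seeds matches the random-overlap expectation
`|calls|^2 / |universe|`.

# Ct-based quantification

All qPCR math reduces to `quantity ∝ E^-Ct` with per-cycle amplification
factor `E`:

* **Standard curves:** `E = 10^(-1/slope)` from the least-squares fit of
  Ct on log10 input; curves with a replicate spread above 2 Ct at equal
  input are flagged, and slopes shallower than 1 are rejected as
  non-exponential.
* **Digestion QC:** percent digested `= 100 (1 - E^{-\Delta Ct})` across
  amplicons spanning assayed cut sites; the run passes at >= 96% on every
  site.
* **3C frequencies:** `E_t^-Ct_t / E_r^-Ct_r` against a
  ligation-independent reference amplicon, with an optional per-primer
  correction divisor from a random-ligation control template.
* **Occupancy:** delta-delta-Ct against the arithmetic mean Ct of two
  reference genes (the geometric mean of their quantities — the natural
  combination on the exponential scale); fold > 1 means more nuclease
  protection, i.e. higher nucleosome occupancy. The allele-specificity of
  the McrBC step is summarized as maternal purity
  `m / (m + retention * p)`, flagged below 0.9.
* **Comparisons:** two-tailed Student t-tests (pooled variance by
  default — group sizes in these assays are 3–5, where pooling is the
  conventional choice; Welch by flag). Zero-variance degenerate groups
  report p = 1 (identical) or p = 0 (separated) instead of NaN. No
  multiple-testing correction is applied; per-site p-values are reported
  as such.

# 3D FISH co-localization

Signal centers are physical micrometre coordinates (`voxel_to_um`
converts pixel/slice triples with a configurable xy pixel size and a
0.3 um z step). A pair is interacting when the Euclidean center-to-center
distance is strictly below 1 um; the boundary is exact (distance = 1 um
is not co-localized). Genotype frequencies are compared with Fisher's
exact test by default — the counts are small and the test is exact —
with a chi-square alternative available.

# Numerical choices and limitations

* Coordinates are 0-based half-open throughout (BED convention); BED,
  TSV and bedGraph writers emit deterministic plain text, and a pipeline
  rerun with the same config is bit-identical (the run manifest records
  MD5 checksums).
* Duplicate cut positions from overlapping site occurrences are merged so
  no zero-length fragment exists; every inter-cut interval is a fragment.
* bedGraph values are rounded to 4 decimals; track mass conservation is
  exact up to clipping at position 0.
* The test suite runs the full study conditions once (about 5 s) and the
  null model at reduced depth (1e4 reads per replicate, 50 seeds); the
  estimator oracle sweep uses `M = 10^4`. These sizes are chosen so the
  whole suite runs in well under a minute on one core.
* Between-replicate shrinkage, hierarchical modelling and per-fragment
  significance testing are deliberately out of scope: calling is a
  quantile rule on the posterior point estimates, matching the top-decile
  definition the pipeline implements, and the replicate intersection is
  the reproducibility filter.
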