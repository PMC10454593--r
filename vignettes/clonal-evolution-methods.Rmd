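---
title: "Methods: multi-sample clonal deconvolution, clone trees and event timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-sample clonal deconvolution, clone trees and event timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`clonetrace` reconstructs the clonal history of a tumor from a small number
of related samples — longitudinal biopsies, or morphologically distinct
regions of one specimen. This vignette is the package's own account of the
statistics it implements: the models, the assumptions behind them, the
tunable parameters and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the known limits of
the approach.

```{r setup, message = FALSE}
library(clonetrace)
```

## 1. From read counts to cancer cell fractions

The quantity everything downstream consumes is the cancer cell fraction
(CCF): the proportion of *tumor* cells in a sample that carry a given
mutation. The observed variant allele frequency (VAF) underestimates it for
three reasons — normal-cell contamination, the local total copy number, and
the number of mutated copies — and the standard correction is built from
the expected VAF of a mutation at CCF $\varphi$, multiplicity $m$, in a
sample of purity $\rho$, with tumor total copy number $n_t$ and germline
copy number $n_n$ at the locus:

$$\mathrm{E[VAF]} \;=\; \frac{\varphi\,\rho\,m}{\rho\,n_t + (1-\rho)\,n_n}.$$

Multiplicity is not observable directly. We estimate it per variant *and
per sample* as the $m \in \{1,\dots,n_\mathrm{major}\}$ whose clonal
($\varphi = 1$) expected VAF is nearest the observed VAF, ties to the
smaller $m$. Capping at the major allele count encodes the assumption that
a point mutation arises on one parental haplotype and can only be
multiplied up to that haplotype's copy number — by a whole-genome doubling
or a focal gain. Estimating per sample matters because copy number differs
between samples (an amplified locus in a late sample may be unamplified in
an early one). The CCF is then the inversion of the formula at
$\hat m$. On male chrX and chrY, $n_n = 1$; this is load-bearing whenever
X-linked genes such as AR are in play.

Assumptions worth keeping in mind: copy number is clonal (every tumor cell
in a sample shares the segment profile), multiplicity is a single integer
per variant per sample, and purity is known. When a raw CCF exceeds 1 —
binomial noise, or a mis-specified copy state — we report the raw value,
clip to 1 for clustering, and flag values above `ccf_cap` (default 1.2).
Variants with depth below `min_depth` (default 10 reads) in any sample are
excluded: below that, the binomial likelihood is nearly flat and the
variant only adds noise. The default reflects exome data at roughly
100&times; median coverage.

Two properties of this construction are verified in the test suite: the
inversion is exact (machine precision) on noise-free expected VAFs over all
combinations of purity $\in \{0.3, 0.5, 0.8, 1\}$, copy states
$\{1{+}0, 1{+}1, 2{+}1, 2{+}2\}$ and valid multiplicities; and the mean CCF
error on binomially sampled counts shrinks as depth grows.

## 2. Dirichlet-process clustering of SNVs

Mutations accumulate in clones, so their CCF profiles across samples come
in a small, unknown number of groups. We cluster with a Dirichlet-process
mixture over partitions, with binomial emissions on the *observed counts*
rather than on point CCF estimates — at 100&times; depth a CCF point
estimate carries substantial, depth-dependent noise that the binomial
likelihood represents for free.

Cluster $k$ has a CCF $\varphi_{ks} \in [0,1]$ per sample $s$, discretised
to a grid of step `grid_step` (default 0.01 — about five times finer than
the CCF standard error at 100&times;, so the discretisation is not the
limiting error; halving it quadruples the phi-update cost for no visible
gain). Variant $i$ in cluster $k$ contributes
$\mathrm{alt}_{is} \sim \mathrm{Binomial}(\mathrm{depth}_{is},\,
\varphi_{ks}\, c_{is})$ with $c_{is}$ the coefficient from section 1.
Inference is collapsed Gibbs sampling: each sweep reassigns every variant
under the Chinese-restaurant prior (new clusters are opened against the
grid-uniform predictive), resamples every cluster's $\varphi_{ks}$ from its
grid conditional, and resamples the concentration $\alpha$ under a
Gamma(1,1) hyperprior via the Escobar–West auxiliary-variable move. The hot
loop is implemented in C++ (Rcpp), with all randomness drawn from R's RNG,
so a run is reproducible bit for bit given (inputs, configuration, seed).

Defaults are 2000 sweeps with 500 discarded as burn-in. On the package's
reference problems (300–400 SNVs, 2–4 samples) the occupied-cluster trace
stabilises within the first couple hundred sweeps; 2000 keeps a wide margin
at a few seconds' runtime. The final hard clustering is deliberately *not*
the last sweep's state: we accumulate the posterior co-clustering matrix
over post-burn-in sweeps and cut its average-linkage dendrogram at
dissimilarity 0.5 ("clustered together in at least half the posterior"),
which damps Monte-Carlo noise. Clusters smaller than `min_size` (default
`max(5, 2%)` of SNVs) are merged into the cluster with the nearest center:
over-dispersed counts occasionally shave off a few-variant satellite that
no analyst would call a clone. Labels are canonical — decreasing total CCF,
so the truncal cluster is always "A" — making summaries invariant to the
sampler's internal labelling.

## 3. Ploidy, whole-genome doubling, and copy-number events

Ploidy is the segment-length-weighted mean total copy number,
$\sum_i \ell_i (n_{\mathrm{major},i}+n_{\mathrm{minor},i}) / \sum_i \ell_i$
with $\ell = \mathrm{end}-\mathrm{start}+1$; it is invariant to splitting
segments, which the tests check by construction. Whole-genome doubling is
called when ploidy strictly exceeds 3: a doubled genome that has since shed
material still sits well above 3, a diploid genome with typical gains stays
below.

Event calls are *relative to sample ploidy*, which is the design decision
that matters most here. In a doubled genome, two copies of RB1 is a loss;
an absolute threshold would miss every post-WGD loss. Concretely, per gene:
LOH if the minor allele count is 0 across the span; loss if the minimum
total over the span falls below `round(ploidy)`; focal amplification if
some covering segment reaches `amp_factor × ploidy` (default 2) and spans
at most `focal_max_len` (default 10 Mb — "focal" in the sense of a narrow
spike against the genome-wide background; there is no community-standard
constant, so both knobs are configuration). Arm-level calls use the
length-weighted arm mean against `ploidy ± arm_gain_margin` (default 0.6,
i.e. more than half the genome-average copy number away) and arm LOH
requires minor copy 0 over `arm_frac` (default 0.9) of the covered length.
When a gene straddles segments in different states, the most extreme state
decides per event kind (minimum for loss/LOH, maximum for amplification),
with a warning.

One gate sits on top of these rules: on chromosomes where the germline is
hemizygous (chrX/chrY in a male genome), minor copy 0 is the normal state,
so LOH is never called there, and the loss/gain baseline is scaled to
$\mathrm{ploidy} \times n_n/2$. Without this, every male-X gene would be a
truncal LOH artifact. The focal-amplification threshold deliberately stays
at `amp_factor × ploidy` on all chromosomes: an X amplification competes
with genome ploidy for read share, and in practice real amplifications
(tens of copies) clear either version of the bar.

The shipped gene table (PTEN, RB1, TP53, AR) and arm table are small
editable hg38 BED-like TSVs; both are inputs, not constants.

## 4. Clone-tree construction with CNA precedence

Two constraints tie mutation clusters into a tree. The *sum rule*: in every
sample, a parent's CCF must be at least the sum of its children's (cells
are nested). The *presence-subset rule*: a child cannot be present in a
sample its parent is absent from. The root is the MRCA — the cluster with
CCF center at least `mrca_threshold` (default 0.9) in every sample. Several
qualifying clusters are statistically indistinguishable at this resolution
and are merged into one root, with a warning; if none qualifies the cluster
maximising its minimum center is used, with a prominent warning, because a
sample set without a shared clonal cluster usually means the samples are
not from one tumor or purity is badly wrong.

Construction is greedy: clusters in decreasing total-CCF order attach to
the *deepest* existing node satisfying both constraints, the sum rule
checked with tolerance `epsilon` (default 0.15 — roughly twice the CCF
standard error at 100&times; depth, so estimation noise alone rarely blocks
a legitimate attachment; raise it for shallower data). Copy-number events
take precedence in two ways: when several candidate parents tie at the same
depth, the one whose sample-presence pattern matches a CNA-defined branch
containing the cluster wins; and events decorate the tree afterwards —
shared-by-all events on the root (truncal), others on the node whose
presence pattern matches their sample set. A cluster satisfying the
constraints nowhere attaches to the root flagged
`unplaced-constraint-violation` rather than distorting the rest of the
tree. Both rules are re-asserted on the finished tree; a violation there is
a bug, not a data property.

Greedy attachment with deterministic ordering means the output is a single
reproducible tree, not a posterior over trees; uncertainty in the centers
is not propagated (see section 7).

## 5. Timing events across dated samples

Under the persistence assumption — a lineage that acquires an event never
loses it — presence/absence across dated samples brackets an event in time:
the interval runs from the latest sample lacking the event (among those
predating all carriers) to the earliest sample carrying it, left-open and
right-closed. An event in every sample predates the first sample: its
interval is (origin, first sample], where "origin" is tumor initiation,
rendered as an open left endpoint — no attempt is made at mutation-rate
chronology. Presence patterns that contradict persistence (absent at a
date strictly later than a presence) are flagged `non_persistent` and given
no interval; with same-date sibling regions, absence in a sibling does not
trigger the flag, but a region-private event that is absent at later dates
does — the flag is then a correct statement that cross-sample persistence
cannot time a region-restricted event.

## 6. The synthetic-data generator

`simulate_case()` emits exactly the formats the pipeline consumes (VCF with
per-sample allelic depths, ASCAT-style segment TSV, sample panel) plus the
generating truth. The generative model mirrors the analysis assumptions
deliberately: clone CCFs that satisfy the tree constraints exactly; clonal
integer copy-number profiles per sample (a CNA appears in a sample when its
carrying clone exceeds CCF 0.5 there); Poisson depth around a configured
mean (default 100&times;, typical of exome series); binomial alt counts at
the model's expected VAF; and multiplicity $n_\mathrm{major}$ for SNVs in
clones ancestral to a whole-genome doubling (doubling carries the mutated
haplotype along, which is what keeps truncal SNVs at CCF ≈ 1 afterwards),
1 for all later SNVs.

Three presets define the package's reference conditions. `case1_like`:
four dated samples over five years (one a ductal-morphology region),
truncal WGD, a truncal 53-SNV clone carrying a PTEN SNV, a focal chrX (AR)
amplification present in everything except the earliest sample, a
ductal-private clone with private CNAs (1p LOH, 6q gain), and a 34-SNV
clone private to the last sample — five clones. `case2_like`: two regions
of one specimen, a trunk carrying 13q LOH (hence RB1 loss), a
neuroendocrine branch with 3p gain, 4p LOH and 17p LOH (TP53), and an
adenocarcinoma-private clone. `null_single_clone`: one diploid clone, no
CNAs. Purities (0.65–0.75) and the subclonal CCF levels (0.5–0.85) are
chosen as realistic macrodissected-FFPE values; the 53 and 34 SNV counts
match the motivating case's truncal and private cluster sizes.

What the generator does **not** emulate — and therefore what passing tests
cannot certify on real data: sequencing error and FFPE artifacts (no false
positives; real VCFs need upstream filtering), subclonal copy number
(integer clonal states only), segmentation error in the copy-number input,
purity mis-estimation (the panel's purity is exact by construction),
overlapping/phased mutations, and mutation loss (deletions removing an SNV
violate persistence and would surface as `non_persistent` flags).

## 7. Problem sizes, performance, and limitations

The reference checks run at desk scale by design: three-cluster mixtures
with 100 SNVs per cluster at 100&times; depth and purity 0.7 (ten seeds)
for clustering recovery, and twenty five-clone, four-sample simulated
patients at 150&times; depth for end-to-end topology and MRCA recovery. On
one CPU the full test suite takes about three minutes and the acceptance
script about two; a single patient-scale run (a few hundred SNVs, four
samples, default 2000 sweeps) takes a few seconds.

Known limitations, beyond the simulator's scope above:

* **Few samples, exome scale.** With 2–4 samples, clones below ~10 SNVs or
  with CCF separation inside the noise floor merge; the motivating setting
  (whole-exome, ~90&times;) has low power for subclones, and heterogeneity
  visible by immunohistochemistry can be invisible here.
* **Single deterministic tree.** No posterior over topologies; near-ties in
  attachment are resolved by documented tie-breaks (CNA consistency, then
  lexicographic), not quantified.
* **Clonal copy number.** CCF correction and event calls assume one
  integer profile per sample; subclonal CNAs bias the CCFs of overlapping
  SNVs.
* **Timing is bracketing, not dating.** Intervals are bounded by sampling
  dates; nothing is said about where within an interval an event falls.
* **Purity is trusted.** Errors in the supplied purity propagate linearly
  into every CCF; the package does not re-estimate it.
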