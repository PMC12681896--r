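---
title: "Two-tier clonality classification of tumor pairs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-tier clonality classification of tumor pairs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

When a patient presents with two tumors, the therapeutic stakes of deciding
whether they are one clone (an intrapulmonary metastasis, stage IV) or two
independent primaries (two early-stage cancers) are high. `clonalpair`
implements the two-tier molecular workflow used to make that call: a
decision tree on a conventional panel of somatic mutations, backed by a
genome-wide copy-number classifier for the pairs the tree cannot resolve.
This vignette explains the models, the tunable parameters, the synthetic
data the package is tested on, and the known limits of both.

## Tier 1: the adapted IASLC decision tree

Both tumors' somatic variants are reduced to a 27-gene NSCLC panel (the five
guideline oncogenes *BRAF*, *EGFR*, *ERBB2*, *KRAS*, *MET*, plus *TP53* and
21 recurrently mutated genes; `panel_definition()` ships the set as editable
data). Sharing is decided at the DNA level — identical (chromosome,
position, ref, alt) — never at the gene level. The branches, in order:

1. **Two or more shared panel variants → clonal.** Identical somatic
   variants at two or more positions are essentially impossible by chance.
2. **Exactly one shared variant.** Clonal, *unless* the variant matches a
   cautious hotspot pattern (default: *KRAS* codons 12/13/61), in which case
   the call is inconclusive — recurrent hotspots are exactly the variants
   two independent tumors can share by coincidence.
3. **Nothing shared, both tumors informative.** If each tumor carries its
   own definitive driver (*EGFR*, *BRAF*, *ERBB2*, *MET* by default) the
   pair is nonclonal: these drivers are early, truncal events. If the
   discordance involves *KRAS* or *TP53* (subclonal or convergent in
   practice), or only non-definitive genes, the pair is only *probable*
   nonclonal.
4. **At least one tumor without panel variants → inconclusive.**

Hotspot matching uses the gene plus the codon parsed from the protein
change; a variant without protein annotation is never downgraded (the
evidence for the downgrade is missing, so the stronger default applies).

Against exome-wide calls the package also provides the gold-standard rule
(`gold_standard_class()`): clonal iff strictly more than two variants are
shared at the DNA level.

### Design choices in the tree

The branch topology of the published flowchart leaves two points open, both
resolved here as data rather than code. First, a single shared non-hotspot
panel variant counts as clonal evidence; only configured hotspot patterns
downgrade to inconclusive. This reconciles the shared-mutation branch with
the observed behavior that a pair sharing only a *KRAS* hotspot stays
ambiguous. Second, "nonclonal" (versus "probable nonclonal") requires a
definitive driver *in each tumor*; the definitive set is configurable so a
site can match its local guideline interpretation. Whether "different TP53
status" means different variants or presence/absence does not matter here:
both routes end in the same class.

## Tier 2: the two-metric CNA classifier

Pairs the tree leaves ambiguous (probable nonclonal or inconclusive) move
to genome-wide copy number, summarized by two deliberately different
metrics.

**PCC** — the sample Pearson correlation of bin-level log2 read-count
ratios over all bins usable in both profiles (default minimum 500 shared
bins). It sees the whole profile, including focal events and breakpoint
placement, but has no notion of how common an aberration is.

**LLR** — an arm-level log-likelihood ratio that knows exactly that. Arms
are reduced to states $s \in \{-1, 0, +1\}$ and each arm $k$ has reference
probabilities $P_k(+1) = p^{gain}_k$, $P_k(-1) = p^{loss}_k$ estimated from
an external cohort of the same histology. Under independence the pair's
likelihood is $L_0 = \prod_k P_k(s^a_k)\,P_k(s^b_k)$. Under the clonal
model one latent arm $j$, uniform over the $K$ informative arms, carries a
truncal event present in both tumors:

$$L_1 = \sum_j \frac{1}{K}\; \mathbb{1}\!\left[s^a_j = s^b_j \neq 0\right]
P_j(s^a_j) \prod_{k \neq j} P_k(s^a_k)\, P_k(s^b_k),$$

and the statistic is $\mathrm{LLR} = \log_{10}(L_1/L_0)$, which simplifies
to $\log_{10}\!\big(\tfrac{1}{K}\sum_{j\,\text{concordant aberrant}}
1/P_j(s_j)\big)$: a shared rare event is strong clonal evidence, a shared
common one is weak. When no arm is concordantly aberrant, $L_1 = 0$ and the
value is floored at −50 so downstream logic needs no infinities. Reference
probabilities are clipped into $[\varepsilon, 1-\varepsilon]$
(ε = 0.01) so a never-aberrant reference arm cannot contribute an infinite
weight; when the clipped gain and loss sum beyond 1 they are rescaled
proportionally with the floors preserved.

The classification uses fixed diagnostic cutoffs: **clonal** iff
PCC > 0.54 *and* LLR > 0; **nonclonal** iff PCC < 0.45 *and* LLR < −5;
anything else — the gray box and the two conflict quadrants — is
**inconclusive**. A correctness check of the LLR implementation against a
brute-force enumeration of the latent arm is part of the test suite; the
implementation uses the simplified form, the oracle multiplies the products
out.

### A known limitation: the LLR scale

The latent-single-arm mixture above is one concrete reconstruction of the
arm-frequency-weighted likelihood-ratio approach; the cutoffs, however,
come from diagnostic practice with a differently parameterized reference
statistic. The mixture LLR is bounded: with $K$ informative arms its
smallest non-floored value is about $-\log_{10} K$ (≈ −1.6 for 39 arms), so
the interval (−5, −1.6) is unreachable. Two consequences, both visible in
the package's own end-to-end simulations: pairs of independent tumors that
share even one concordant aberrant arm by chance — common in lung cancer,
where e.g. 3q gain runs at ~60% in LUSC — land in the gray zone rather
than below −5; and a clonal pair whose shared events are all *common* arms
can sit just below 0. Deep negative values arise only from the floor (no
concordance at all). The classifier therefore behaves asymmetrically on
simulated cohorts: definitive calls it makes are almost always correct,
but many truly nonclonal pairs remain inconclusive. An alternative would
be a per-arm product model in which discordant aberrations actively
penalize the clonal hypothesis; that model produces a continuous negative
range compatible with the −5 cutoff but is not the model specified for
this package, so it is noted here rather than implemented.

## Preprocessing: from read counts to arm states

* **Binning.** Read positions are tallied into fixed half-open bins
  (100 kb, 500 kb or 1 Mb; a position on a boundary belongs to the later
  bin). For exome material, `exclude_on_target()` first removes reads
  within a padded capture design, leaving the off-target reads whose
  density tracks copy number.
* **Filtering.** Blacklisted or low-mappability bins are flagged unusable,
  never deleted; counts are preserved.
* **Normalization.** $\log_2\!\big(\tfrac{c + 0.5}{\tilde{c} + 0.5}\big)$
  with $\tilde{c}$ the median usable count; the 0.5 pseudo-count keeps
  zero-count bins finite. A per-bin covariate (e.g. GC) can trigger a
  median-by-quantile-bucket correction, off by default because the
  synthetic data carries no such trend.
* **Segmentation.** A circular-binary-segmentation style recursive search
  (compiled in C++): per segment, the arc maximizing the standardized
  mean-difference statistic is tested against `n_perm` seeded permutations
  (default 1000) at `alpha` (default 0.01); accepted splits recurse.
  Segments narrower than `min_width` (default 3 bins) are merged into the
  neighbor with the closer mean. Segment means are plain means of member
  bins, so bin-weighted segment means conserve each chromosome's total
  log2 signal to machine precision — a tested invariant.
* **Arm reduction.** Per arm, the bin-weighted mean of segment values is
  thresholded at ±0.1 log2 units (configurable). The alternative
  "largest aberrant segment" rule was rejected as too sensitive to focal
  noise. Arms with less than half their bins covered (`min_coverage` 0.5)
  are *missing*, not neutral, and drop out of the LLR entirely.

The ±0.1 default is deliberately permissive: at the lowest admitted purity
(30%), a one-copy gain shifts the expected log2 ratio by
$\log_2(1.15) \approx 0.20$ and a loss by −0.23, both comfortably beyond
the threshold once averaged over an arm, while bin-level noise averages
out (standard error ~0.01–0.03 per arm at the default depth).

## The synthetic cohort generator

The controlled-access cohorts the workflow was developed on cannot ship
with a package, so `simulate_cohort()` generates pairs with the same
statistical structure, and every downstream claim is tested against it.

* **Arm landscape.** Per-histology arm-event priors follow the published
  lung landscape (LUAD: gains on 1q/5p/7/8q/20, losses on 6/9/17p/18;
  LUSC: gains on 3q/5p/8q, losses on 3p/5q/8p/9p/13; baseline 0.08
  elsewhere). `draw_reference_frequencies()` draws a cohort-specific table
  from Beta priors around those means (concentration 60), playing the role
  of the external reference cohort.
* **Clonal structure.** A clonal pair is two daughters of one simulated
  ancestor: each ancestral arm event is retained with probability 0.95,
  private arm events appear with probability 0.05, truncal variants are
  retained with probability 0.95, and private variants are added on top.
  Nonclonal pairs are two independent draws of the same histology.
* **Variants.** Truncal exome burden is Poisson with mean 480 (so clonal
  pairs share a median of ~435 variants after retention, matching the
  scale reported for real paired biopsies), private burden Poisson(75).
  Panel genes mutate with per-gene, per-histology probabilities (TP53 0.5;
  KRAS 0.3 in LUAD; others 0.02–0.10), drawing from weighted hotspot
  alleles where genes have them — which is what lets two independent
  tumors occasionally share an identical KRAS hotspot variant and
  exercise the tree's downgrade branch.
* **Counts.** Each bin's expected relative copy ratio is
  $r = \rho c/2 + (1 - \rho)$ for purity $\rho$ and local copy number
  $c$; counts are negative-binomial with mean `depth`·r and variance
  $\mu(1 + d)$ with dispersion $d = 0.05$ — a mild, FFPE-flavored excess
  over Poisson that corresponds to a bin-level log2 noise SD of ~0.15 at
  the default depth of 100 reads per bin. Purity is Uniform(0.3, 0.9),
  the floor matching the macrodissection target of diagnostic practice.

**Problem sizes.** End-to-end simulations in the tests and the acceptance
script use 50 clonal + 50 nonclonal pairs on 500-kb bins (~5,800 bins,
~580,000 reads per sample). At 100 reads per bin this is the bin size at
which a sample clears the 500,000-read QC gate — the same depth-driven
choice the diagnostic protocol itself makes between its 100/500/1000-kb
dialects. Segmentation-recovery checks run on the full 100-kb genome
(~29,000 bins).

**What the generator does not emulate:** GC/mappability waves and other
platform artifacts, subclonal (fractional) copy-number states, whole-genome
doubling, focal amplifications beyond ±1 copy effects, germline
contamination of the variant calls, and read-level data. Tests passing on
this generator therefore validate the *logic and statistics* of the
pipeline — calibration on real FFPE sWGS still requires real reference
material.

## QC and the workflow

Samples below 20% tumor cells or 500,000 total reads are excluded (strict
inequalities; unknown values fail with reason "unknown"). For passing
pairs, `classify_pair()` computes the mutation tier first; a definitive
call short-circuits the CNA tier entirely (a tested guarantee). Ambiguous
pairs get PCC, LLR and the CNA classification; a pair neither tier can
resolve ends inconclusive with the failure annotated. Cohort evaluation
(`crosstab_vs_truth()`) reports per-truth concordance, the mutation tier's
ambiguity rate, and how often the CNA tier rescued an ambiguous pair;
`fisher_exact_2x2()` supports the usual association checks on such
cross-tabulations by exact hypergeometric enumeration.

## Numerical and convention notes

* On-disk coordinates are 1-based inclusive (SEG/VCF convention); all
  internal arithmetic is 0-based half-open, converted at exactly one point.
* Chromosome names are "1".."22","X","Y"; a "chr" prefix is stripped on
  read and never written. The shipped hg19 arm table covers the 39
  autosomal arms; acrocentric p arms and sex chromosomes are excluded
  territory.
* Floats are serialized at 6 significant digits so outputs diff cleanly.
* Every stochastic operation takes a seed and is a pure function of
  (inputs, seed); cohort generation, segmentation and the full workflow
  reproduce byte-identically under a fixed seed.
* The permutation test inside segmentation stops early once the exceedance
  count can no longer reach significance, which changes no decision, only
  the runtime.
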