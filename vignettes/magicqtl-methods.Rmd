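---
title: "Models and methods behind magicqtl"
author: "magicqtl authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind magicqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`magicqtl` simulates and analyzes multiparent advanced generation
intercross (MAGIC) populations of doubled haploid (DH) maize lines and
compares three allelic models of QTL. This vignette explains the models,
the tunable parameters, the design choices made where the design was
genuinely open, and what the simulation-based validation does and does
not show about real data.

## The population and its simulator

A MAGIC population is built by crossing $2^k$ inbred founders through a
balanced funnel (pairs, then four-ways, and so on), intercrossing the
resulting synthetic population for several generations, and extracting
fully homozygous DH lines. Because a DH line is a doubled gamete, one
meiotic product specifies its whole genome; `simulate_magic()` therefore
models DH induction as a single additional meiosis whose gamete is the
line.

The simulator tracks ancestry mosaics — per chromosome, half-open bp
segments labelled with the founder of origin — rather than sequences.
Key modelling choices:

* **Recombination.** Crossovers are a Poisson process at 1 per Morgan on
  the genetic map (Haldane, no interference), drawn on the cM axis and
  mapped to bp by piecewise-linear interpolation between map anchors.
  No interference is the simplest defensible process and matches the
  Markov assumption of the downstream ancestry HMM.
* **Funnel.** The pairing tree is an arbitrary, seedable permutation of
  the founders (real designs pair founders by trait, e.g. early by late
  flowering; the default is a random balanced tree). Every intercross
  founder individual is produced by an independent run of the funnel.
* **Intercross.** Random pairing without selfing, parents drawn
  uniformly from the previous cycle. The cycle size is a design
  parameter (the real population used about 1,600 per cycle; the
  validation studies here use 120–300, which preserves all expectations
  and only increases drift).
* **Founders.** Synthetic founders draw 0/1 alleles independently with a
  marker frequency chosen so a founder pair differs at an expected
  fraction `divergence` of markers; the default 0.5 emulates
  array-ascertained common variants. For more than two founders the
  expected pairwise difference of exchangeable bi-allelic genotypes
  cannot exceed 1/2, so `divergence` is capped at 0.5 unless $f = 2$.
  Planted IBD tracts force founder groups to share alleles over a cM
  window (resolved transitively, so plans cannot contradict themselves)
  and are recorded as truth for recovery tests.
* **Phenotypes.** An observation is grand mean + QTL scores + polygenic
  value + environment effect + residual. Planted QTL are bi-allelic,
  founder-allelic, or haplotype-allelic; their line scores are
  standardized so each QTL explains exactly its requested fraction of
  the (unit) phenotypic variance, and the polygenic value is drawn as a
  multivariate normal with covariance proportional to the realized
  genomic relationship matrix.

What the simulator does *not* emulate: selection during the crossing
scheme (the mechanism the real population's diagnostics point to),
sex-specific maps, crossover interference, array ascertainment bias
beyond the common-variant allele frequency, genotype clustering
artefacts, and missing-data structure. Tests passing on simulated data
therefore validate the inference machinery under neutral random mating,
not the biological conclusions one might draw from a real population.

## Founder-ancestry HMM

For each DH line and chromosome the hidden state at a marker is the
founder of origin ($f$ states). Emissions: the observed allele matches
the hidden founder's allele with probability $1-\varepsilon$
(`error`, default 0.002); missing genotypes emit 1 for every state.
Transitions over a map distance of $d$ cM use the recombination fraction

$$ r = \tfrac{1}{2}\left(1 - e^{-2 g d / 100}\right), $$

with the new founder uniform over the other $f-1$ on a recombination.
The map-expansion factor $g$ (`gens`, default 7) approximates the number
of recombining meioses accumulated by the funnel + three intercross
generations + DH induction; it plays the role that a pre-baked cross
type plays in general-purpose HMM packages, and because the true scheme
never exactly matches any pre-baked type, the package validates the
choice by simulation (`benchmark_founder_assignment()`) instead of
deriving pedigree-exact transitions. Posteriors come from scaled
forward–backward, vectorized over lines; the maximum-a-posteriori
founder path breaks ties toward the lowest founder index.

Accuracy is scored as the fraction of (line, marker) cells whose argmax
founder equals the simulated truth, plus the fraction of cells called
with probability above 0.8. On the desk-scale validation genome (2
chromosomes, 2,000 markers each at 150 cM, 16 founders) accuracy is
around 99.7%; errors concentrate in the one or two markers flanking
each ancestry junction, so accuracy rises with marker density.

## Marker thinning

Scanning every array site is redundant: founder probabilities change
only at recombination breakpoints. A greedy left-to-right sweep keeps a
marker only if the squared Pearson correlation between its probability
matrix and the last *kept* marker's (both column-centered and
flattened) is at most 0.95. The matrix-$R^2$ definition is symmetric,
lies in $[0,1]$, and reduces to the squared allelic correlation when
$f=2$; a constant (uninformative) matrix is treated as perfectly
redundant. The sweep is idempotent. The haplotype variant applies the
same sweep within runs of consecutive blocks sharing the same number of
distinct haplotypes, so matrices of unequal width are never compared.
The "previous kept" reading of the filter (standard greedy pruning) was
chosen over "immediately preceding"; the alternative would allow chains
of small changes to pass unfiltered.

## IBD and ancestral haplotype blocks

Founders that descend from common ancestors share long identical
haplotypes, which makes founder identities partially confounded. The
package groups founders into ancestral haplotypes per genomic block:

1. **Pairwise IBD.** Either ingested from RefinedIBD-style files
   (`read_ibd_segments()`) or called internally: maximal runs of
   identical alleles are seeded, neighbouring runs merged while the
   allele identity over the merged span stays at or above 0.99 and the
   span stays within `window_cm` (10 cM), and merged segments shorter
   than 0.2 cM dropped. The run-merge design (rather than a literal
   sliding-window pass) is what lets a planted tract be recovered to
   within one marker interval. The probabilistic machinery of dedicated
   IBD callers (LOD scores, haplotype frequencies) is intentionally out
   of scope.
2. **Blocks.** Block boundaries are the sorted unique endpoints of all
   segments plus the chromosome ends, so a segment either covers a
   block entirely or not at all (a consequence of the construction, not
   an extra rule); zero-length blocks are dropped.
3. **Grouping.** Within a block, haplotype groups are the connected
   components of the graph whose edges are covering IBD pairs. This
   implements the transitive-closure assumption (if A–B and A–C are
   IBD, B and C are treated as IBD too); blocks where a component is
   not a clique are flagged `incomplete` and reported, because the
   haplotype label then hides residual variation between founders.
4. **Haplotype probabilities** sum member founders' posterior
   probabilities, conserving probability mass; with all-singleton
   groups the haplotype design reduces exactly to the founder design.

## The three allelic models and the mixed-model scan

All three scans fit, one locus at a time,

$$ y = \mu + X_i \beta_i + Z u + \epsilon, \qquad
   u \sim N(0, \sigma^2_u K), $$

where $y$ holds one record per line (BLUPs across environments, so $Z$
is the identity; `calc_blups()` is where a non-trivial design enters,
as a two-way REML model with environment fixed and line random), and
$X_i$ is

* **GWAS_SNP** — the $n \times 1$ allele dosage of SNP $i$;
* **QTL_F** — the $n \times (f-1)$ founder-probability matrix
  (first founder dropped as reference);
* **QTL_H** — the $n \times (h-1)$ haplotype-probability matrix.

$K$ is a leave-one-chromosome-out genomic relationship matrix: markers
on the tested chromosome are excluded so the polygenic term does not
absorb the tested locus. Writing
$h^2 = \sigma^2_u/(\sigma^2_u + \sigma^2_e)$, the covariance is
$\sigma^2 (h^2 K + (1-h^2) I)$; after one eigendecomposition of $K$ per
(chromosome, phenotype) the profiled ML log-likelihood is evaluated on a
fixed $h^2$ grid (step 0.01 by default) for the null and every marker
design, and maximized over the grid — the grid strategy trades a
negligible discretization error for reusing one set of rotated designs
across all markers and permutations; ML (rather than REML) keeps
likelihood-ratio comparisons between nested fixed-effect models
well-defined. Numerical choices: eigenvalues are clipped
at zero; residual sums of squares are floored at `1e-300` before logs;
weights are strictly positive, so a design's rank does not depend on the
grid point and collinear designs are detected once by a rank check and
skipped; zero-variance design columns (founders absent from the
population) are dropped per marker before fitting.

Two marker tests are available. The default is the likelihood-ratio
chi-squared with degrees of freedom equal to the number of marker
columns (the natural test for multi-column founder/haplotype designs).
`test = "f"` instead forms the GLS F statistic at the marker's
ML-optimal $h^2$ with the null refit at the same grid point; this route
reduces *exactly* to the ordinary-least-squares F test when
$\sigma^2_u = 0$, which is the package's fixed-model consistency check.
The two orderings agree closely at these sample sizes; permutation
thresholds calibrate either.

**Permutation thresholds.** For each model separately, the line labels
linking phenotype to genotype rows are shuffled (one shared shuffle per
permutation across all markers, preserving the marker designs and their
LD), the genome-wide maximum $-\log_{10} p$ recorded, and the
$(1-\alpha)$ quantile of the maxima returned. The same permutations are
evaluated for all markers in one compiled pass, so a 100-permutation
genome scan costs a few seconds at desk scale.

**Support intervals** span the left-most to right-most tested markers
within a 100 Mb window centered on the peak ($\pm 50$ Mb) whose $-\log_{10} p$ is within 2 units of the peak.
**Merging**: same-phenotype records whose intervals overlap by at least
1 bp are merged transitively with the union interval. **Conditional
scans** re-test interval markers with the peak design as a fixed
covariate; the peak itself is collinear with the covariate and is
skipped by the rank check. Interval bounds always come from the
unconditional scan.

**Effect sizes** are re-parameterized as deviations from the
population mean, $\hat\beta_k - \sum_j \bar p_j \hat\beta_j$ with
$\bar p_j$ the mean probability of level $j$ (the reference level's
coefficient being zero), with standard errors from the coefficient
covariance at the ML-optimal $h^2$. Levels carried by fewer than 5
lines at probability above 0.8 are masked: with so few confident
carriers the level's effect is not estimable in any stable way.

## Population diagnostics

* **Founder representation.** Per site, lines with posterior
  probability above 0.8 for a founder approximate carrier counts,
  tested against the equal-share expectation $n/f$ by a chi-squared
  statistic with $f-1$ df. The genome-wide 5% threshold comes from
  simulated null populations; the default is the 5th percentile of each
  null population's *minimum* per-site p-value (a family-wise min-p
  rule, which yields a single, appropriately stringent genome-wide
  cutoff), with the pooled per-site distribution available as a switch.
* **LD.** $R^2$ is the squared Pearson correlation of allele dosages.
  Interchromosomal pairs above 0.9 are counted, and runs of consecutive
  SNPs each having a high-LD partner on another chromosome are reported
  as regions with size classes (>5 Mb, 1–5 Mb, 100 kb–1 Mb). Under
  neutral random mating the simulator produces none, which is the null
  against which a real population's interchromosomal LD (a selection
  signature) would be judged.
* **Enrichment.** Focal genes overlapping a region set are counted
  against `n_perm` same-size random draws from a background set;
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_\text{perm}+1)$, so p
  is never zero.
* **Epistasis around a focal allele.** Carrier probability is the sum
  of carrier founders' posteriors at the marker nearest the focal site;
  lines with probability strictly between 0.05 and 0.95 are flagged
  uncertain and dropped: with a mixed allelic state the carrier label
  would be arbitrary. The scan
  fits carrier + SNP + carrier×SNP with the mixed model and tests the
  interaction by a 1-df LRT under a Bonferroni threshold; SNPs collinear
  with carrier status are skipped. A complementary carrier-only subset
  scan (`background_subset_scan()`) re-runs QTL_F on the confident
  carriers with kinship subset accordingly.

## Validation benchmarks and problem sizes

The package ships four end-to-end benchmarks (also exercised by
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`), with
sizes chosen so the whole suite runs on a single CPU in tens of
minutes:

1. `benchmark_founder_assignment()` — 3 populations x 110 DH lines on a
   2-chromosome, 4,000-marker genome (150 cM per chromosome, 16
   founders): mean per-SNP HMM accuracy, expected around 99.7–99.8%.
2. `benchmark_founder_share()` — 20 populations x 50 lines: each
   founder's mean genome share against the 1/16 = 6.25% expectation,
   judged against the across-population Monte-Carlo spread (drift at
   desk-scale cycle sizes dominates this error).
3. `benchmark_interchrom_ld()` — 5 neutral populations: the count of
   interchromosomal SNP pairs with $R^2 > 0.9$, expected 0.
4. `benchmark_qtl_power()` — 100 replicates of an 8-parent, 300-line
   MAGIC population on a maize-like genome (10 chromosomes x 150 cM,
   2,000 markers) with one founder-architecture QTL explaining 12% of
   phenotypic variance over a 0.3-heritability polygenic background,
   the carrier count cycling over 1–4 founders to vary the causal
   allele frequency. Power is the fraction of replicates whose QTL_F
   scan clears a 100-permutation 5% genome-wide threshold with a
   support interval covering the causal locus; expected in the low-to-
   mid 80s (%). Two designed-in choices matter here: the genome has the
   full maize chromosome count so the threshold carries a realistic
   multiple-testing burden (a 2-chromosome toy inflates power to ~95%),
   and the scan tests all 2,000 markers rather than the thinned set —
   thinning deliberately decorrelates adjacent markers, which collapses
   support intervals to near-zero width and would fail the coverage
   rule precisely for the strongest QTL. The benchmark uses the
   simulator's true ancestry as the founder design, isolating mapping
   power from ancestry-inference error (which benchmark 1 quantifies
   separately).

## Known limitations

* Transition probabilities are exchangeable across founders; real
  funnels induce mild founder-pair-specific patterns the HMM ignores
  (the accuracy benchmark shows the cost is small).
* The internal IBD caller is deterministic and threshold-based; it has
  no power model and its cutoffs are, as for any IBD caller, arbitrary.
* Exact REML, multi-kernel and GxE mixed models, Bayesian QTL models
  and fine-mapping are out of scope.
* The 100 Mb support-interval window is blind to multi-QTL peaks; the
  conditional scan is the provided (and only) remedy.
* Permutation thresholds assume exchangeability of lines under the
  null; strong population structure beyond what $K$ captures would
  violate this.
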