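---
title: "Models and methods behind OGlycoAtlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind OGlycoAtlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OGlycoAtlas)
```

This vignette explains the models and conventions the package implements,
the parameters that matter and their defaults, what the synthetic-data
generators do and do not emulate, and the design decisions taken where the
design was genuinely open. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## Cross-species glycosite projection

Mucin-type O-glycosites identified in rodent or porcine brain tissue are
transferred to human coordinates through a global pairwise alignment of the
full-length animal protein to its human ortholog. Ortholog pairs and
glycosite tables are *inputs*: orthology inference and glycosite
localization are upstream of this package.

The conservation rule is deliberately positional rather than
identity-based: an animal Ser/Thr/Tyr site is **conserved** when the
aligned human residue is any of Ser, Thr or Tyr (so S→Y is conserved), and
**non-conserved** when it aligns to any other residue or to a gap. GalNAc
transfer requires a hydroxyl acceptor, not a specific residue, which is why
the acceptor class — not the letter — is what must survive evolution for
the site to remain plausible in human.

### The aligner

`globalAlign()` is a Needleman–Wunsch/Gotoh implementation (compiled via
Rcpp) with:

- **Affine gaps**: a gap run of length $k$ costs
  $g_{open} + k\,g_{ext}$; defaults $g_{open} = -10$, $g_{ext} = -1$ on the
  Gonnet-1992 matrix scale. Both are configurable via
  `alignmentParams()`, which enforces $g_{open} \le g_{ext} \le 0$.
- **Terminal gap penalties**: true end-to-end alignment, appropriate for
  full-length ortholog pairs rather than domain fragments.
- **Deterministic tie-breaking** in the traceback (diagonal, then
  gap-in-b, then gap-in-a), so projected coordinates never depend on
  platform or library version.
- A **pluggable substitution matrix**. Gonnet 1992 is the default; a
  BLOSUM62 file ships alongside, and any symmetric matrix in the
  documented plain-text format can be supplied.

A design point worth stating plainly: published projection work in this
area typically calls Clustal Omega in pairwise mode with default
parameters. Clustal Omega's defaults are HMM-mediated and not recoverable
as a fixed scoring scheme, so this package does not promise to reproduce
any specific third-party alignment. What it promises is equivalent
*projection semantics* — an optimal global affine-gap alignment over the
same substitution family and the same S/T/Y conservation rule — with the
advantage of exact determinism. The test suite pins the aligner to an
exhaustive-enumeration oracle on short sequences (every global alignment of
pairs up to length 6 is enumerated recursively and the maximum compared),
and the conservation-label recovery test (below) checks the property the
pipeline actually relies on.

### Consolidation and summaries

`consolidateSites()` merges human-native observations with conserved
projected sites, keyed by (human accession, human position). Multiple
observations converging on one residue — several animal species, several
biosources, both glycoforms — merge into one expanded site whose sets are
unions; this matches per-residue accounting, where a site is a residue, not
an observation. Evidence is `human_native`, `animal_conserved` or `both`,
and the identity
$|expanded| = |human\_only| + |animal\_only| + |both|$
is asserted in tests together with idempotence of re-consolidation.
Conflicting residue letters at one key abort with an error: that situation
indicates a sequence-version mismatch between the site table and the loaded
proteome, and silently preferring one letter would corrupt every downstream
summary.

`speciesOverlap()` tabulates the 15 non-empty combinations of
{human, mouse, rat, pig} evidence (a four-set Venn layout);
`noveltyVsReference()` partitions sites by membership in an external
compilation; `siteDensity()` reports sites per 100 extracellular residues
given BED-like 1-based inclusive ranges (topology prediction is out of
scope); `predictionConcordance()` scores externally computed predictor
flags, excluding and counting unflagged sites rather than imputing them.

Isoform handling: accession suffixes (`-2` etc.) are stripped with a
warning and positions are interpreted on the canonical sequence, because
ortholog alignment is performed on canonical full-length sequences only.
Animal observations whose accession has no ortholog pair are excluded from
projection and returned separately — dropped data should be visible.

## TMT secretome quantification

The regulated-secretome design compares basal and depolarized secretomes
across genotypes, spread over several TMT 10-plexes that each carry one
pooled internal-reference channel. The processing chain is:

1. **`filterQuantifiable()`** removes proteins that lack a nonzero
   intensity in any channel of any plex or that carry fewer than 2 PSMs:
   single-PSM quantifications are too noisy to scale between batches.
   Removals are counted by reason in `filterLog()`.
2. **`normalizeSampleLoading()`** scales each channel by
   (mean channel total)/(channel total) within its plex, equalizing total
   loading. This is a per-channel scalar, so within-channel protein
   ordering is untouched (asserted in tests).
3. **`irsCombine()`** performs internal reference scaling. For protein $i$
   in plex $b$, let $r_{ib}$ be the geometric mean of that plex's
   reference channels and $g_i = (\prod_b r_{ib})^{1/B}$. Every channel of
   plex $b$ is multiplied by $g_i / r_{ib}$. Afterwards the per-protein
   reference summaries agree across plexes to within floating-point
   round-off (the defining post-condition, asserted at relative
   $10^{-9}$), and any per-plex multiplicative batch factor cancels
   exactly. Geometric means are the natural summary for multiplicative
   reporter-ion data. Proteins with a zero reference intensity in any plex
   cannot be scaled and are dropped with a warning; plexes are combined
   over the intersection of surviving proteins. The result is a
   `SummarizedExperiment` whose `colData` is the channel metadata and
   whose `metadata()$irs_factors` records the factors applied.
4. **`differentialSecretion()`** runs a two-sided Welch $t$ test on log2
   intensities per protein, with Benjamini–Hochberg adjustment by default
   and Bonferroni selectable for genotype contrasts. The default
   responsiveness threshold is adjusted $p < 0.1$ with a positive fold
   change (secretion increased on depolarization). Source material for
   this kind of experiment states the significance rule both ways around
   0.1; this package treats "adjusted $p$-value > 0.1" phrasings as
   typographical and uses `<`, with the threshold exposed as `alpha`.

The engine choice also deserves a plain statement. Count-model engines
(edgeR-style negative binomial) and contingency tests have both been used
on reporter intensities in the literature this pipeline serves. Reporter
intensities after IRS are continuous and multiplicative, a Welch test on
log2 values is the transparent default, and the package validates it by
*parameter recovery*: on synthetic two-plex experiments (200 proteins, 10 %
with a true one-unit log2 fold change, a 3× batch factor, 10 % CV
log-normal noise, 5 vs 5 channels), the mean per-seed signed bias of the
estimated fold changes over 20 seeds is below 0.1. No numerical equivalence
to any external package is claimed, and the engine is isolated behind the
function boundary.

Residual zeros after filtering indicate an upstream problem; rather than
crashing mid-pipeline they are replaced by half the smallest positive
intensity with a warning before the log transform.

## Mass arithmetic and GAG stubs

`monoisotopicMass()` sums IUPAC monoisotopic atomic masses (≥ 6 decimals,
shipped as a static table) over an elemental composition; the empty
composition is 0 (additive identity) and unknown symbols are errors naming
the symbol. `averageProteinMass()` uses the standard average residue-mass
table plus one water (18.01528 Da) and reports kDa to 3 decimals — the
convention under which a chromogranin A construct is quoted at 50.438 kDa.
The calculator is validated on short peptides with hand-computable masses;
reproducing a specific construct mass from an accession is not attempted
because residual tag residues after protease cleavage are not recoverable
from an accession alone.

The chondroitinase-resistant linkage-region hexasaccharide
(HexA(−H₂O)HexNAcHexAHexHexXyl-O-Ser) occurs unsulfated
(C₃₇H₅₅NO₃₀), mono-sulfated (C₃₇H₅₅NO₃₃S) and di-sulfated
(C₃₇H₅₅NO₃₆S₂). `gagStubClasses()` computes the three expected masses from
these compositions — so the SO₃ spacing of 79.9568 u is structural, not
hard-coded — and `classifyGagStub()` assigns an observed mass increment to
the class within a ppm tolerance (default 10 ppm, the usual
high-resolution precursor tolerance), choosing the closest class if several
match.

## Mass photometry, granules, uptake

**Calibration.** `fitContrastCalibration()` is ordinary least squares of
standard mass on contrast. When only a pooled, unlabeled ladder recording
exists, `calibrateFromMixture()` partitions the contrasts into one cluster
per standard (k-means seeded at evenly spaced quantiles, hence
deterministic), pairs sorted centers with sorted masses and fits through
the centers. The slope must be positive — a non-positive slope means the
ladder was mis-specified.

**Oligomer classes.** `oligomerProfile()` applies hard thresholds first
(> 10,000 kDa → XL, > 500 kDa → X) and assigns the rest to the nearest of
{1, 2, 4, 8} × monomer mass (I, II, IV, VIII), ties to the smaller
oligomer. Nearest-multiple assignment is symmetric and deterministic, and
the threshold-first order settles the ambiguous octamer-to-500 kDa band
(403.5–500 kDa for a 50.438 kDa monomer): those events are VIII, because
they are below the stated 500 kDa class boundary. Both thresholds are
arguments. `monomersToExceed(500, 50.438)` returns 10 — the arithmetic
behind annotating >500 kDa complexes as containing at least ten monomers.

**Granule morphometry.** `granuleSizeDistribution()` bins diameters into
half-open, lower-inclusive bins $[kw, (k+1)w)$ with default width
$w = 20$ nm — published frequency plots of dense-core-granule sizes use
bins of roughly this coarseness, and the value is configurable — and
compares per-clone fractions above a threshold (default 170 nm) between
genotypes with an unpaired two-sided $t$ test. The clone, not the granule,
is the replicate: granules within a clone are not independent.

**Uptake.** `normalizeUptake()` computes per-replicate vesicular uptake as
cpm/mg(untreated) − cpm/mg(reserpine): reserpine blocks the vesicular
monoamine transporter, so the treated condition measures the non-vesicular
background. Percent change versus the control genotype is summarized from
per-replicate ratios to the control mean (mean ± SEM across replicates),
matching the "+x ± y %" style of reporting with SEM error bars; an
error-propagation SEM would understate the replicate-to-replicate spread
the experiment actually exhibits. Genotypes are compared by one-way ANOVA
with Tukey HSD.

**Glycans per molecule.** `glycansPerMolecule(u, M) = u \cdot M / 100`
converts µmol glycan per 100 mg protein and a molar mass in mg/µmol into
glycans per molecule. For the literature inputs (5, 48) the computed value
is 2.4; prose summaries of that calculation sometimes round it to
"approximately 2.5". The function returns the computed value.

All statistical engines used here (t, ANOVA, Tukey, BH) are the standard
`stats` implementations; the package's tests pin their behaviour where the
pipeline depends on it (F = t² on two balanced groups, nominal type-I error
within Monte-Carlo bounds at α = 0.05 over 1000 null simulations).

## The synthetic-data generators

Every generator takes one integer seed, draws from its own named stream
(so adding a generator never shifts another's output), restores the
caller's RNG state, and emits a truth table.

- **`simOrthologProteomes()`** draws animal sequences uniformly over the
  20 residues, places glycosites on S/T/Y, then derives the human ortholog
  by per-residue substitution (uniform over the other 19 letters, so a
  substituted S/T/Y stays glycosylatable with probability 2/19 — an
  analytic expectation the tests check) and geometric-length indels kept
  at least `indel_site_buffer` (default 10) residues away from every
  site. The buffer makes the ground-truth label depend only on the residue
  substitution at the site itself, which is what a label-recovery test
  should isolate; alignment behaviour *near* indels is exercised
  separately by the oracle tests. Defaults (200 proteins, mean length 300,
  5 % substitution, 1 % indels, 3 sites/protein) give desk-scale runtimes
  while matching the divergence range of rodent–human ortholog pairs.
- **`simTmtExperiment()`** builds intensities as base abundance ×
  condition effect × per-plex batch factor × per-channel loading factor ×
  log-normal noise, with channel 1 of each plex the pooled reference. The
  noise is multiplicative log-normal with a CV parameter — qualitatively
  the right error structure for reporter ions, with no claim to any
  instrument's exact noise. The truth table records per-protein log2 fold
  changes.
- **`simLandingEvents()`** draws oligomer classes from stated weights,
  small classes at {1,2,4,8} × monomer ± Gaussian noise (default 5 kDa),
  X uniform on 600–5000 kDa and XL uniform on 10,500–30,000 kDa.
- **`simGranules()`** draws log-normal diameters per clone (defaults:
  WT meanlog log 130 nm, a truncated-glycan genotype at log 150 nm, both
  sdlog 0.25, 3 clones of 272–633 granules — the per-clone count range of
  typical TEM quantification).
- **`simUptake()`** models untreated cpm/mg as vesicular rate ×
  genotype multiplier plus a reserpine floor, with mean-one log-normal
  noise. Defaults (CV 0.3, 6 replicates, multipliers 1/1.66/2.06) produce
  percent-change SEMs of roughly 20 points, the scale typical of
  scintillation uptake experiments with a handful of biological
  replicates.

**What passing tests show — and do not.** The generators reproduce the
*statistical structure* each stage assumes: multiplicative batch and
loading effects, known conservation labels, known mixture weights. They do
not emulate peptide-level quantification, ambiguous site localization,
correlated proteins, heavy-tailed reporter noise, non-orthologous gene
relationships, or segmentation error in electron micrographs. Recovery on
synthetic data therefore validates the algorithms' contracts, not the
biological accuracy of any particular published dataset.

## Numerical choices and degenerate inputs

- IRS post-condition asserted at relative 1e-9; geometric means computed
  in log space.
- Welch test: rows with zero variance in both groups get $p = 1$ when the
  means agree and $p = 0$ otherwise, so constant fixtures behave sensibly.
- Alignment of an empty sequence is the all-gap alignment costing one
  affine run ($g_{open} + n\,g_{ext}$); two empty sequences score 0.
- Oligomer ties (exactly between two multiples) go to the smaller class;
  class fractions must sum to 1 within 1e-9 (validity-checked).
- `classifyGagStub` returns `NULL`, not an error, for a non-matching mass:
  unmatched deltas are expected in real searches.
- Histogram bins are lower-inclusive, so a diameter of exactly 150 nm
  falls in [140, 160) at 20 nm width.

Test problem sizes (200 ortholog pairs at mean length 300; 20 seeds × 200
proteins for fold-change recovery; 2000 landing events; 1000 null
simulations for test size) were chosen as the smallest sizes at which the
Monte-Carlo bounds in the tests are comfortably away from their thresholds;
all are package choices and scale linearly if enlarged.

## Known limitations

- The aligner is a stand-in with equivalent projection semantics, not a
  Clustal Omega reimplementation; site projections near indel-rich regions
  can differ from HMM-guided alignments.
- Ambiguous glycosite localization is assumed resolved upstream; the
  package treats input positions as exact single residues.
- The differential engine is a per-protein Welch test; it does not borrow
  strength across proteins (no empirical-Bayes moderation) and will be
  conservative at very small channel counts.
- `calibrateFromMixture()` assumes the ladder components are
  well-separated in contrast; overlapping components need per-standard
  labels.
- Extracellular ranges for site density are user-supplied; no topology
  prediction is performed.
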