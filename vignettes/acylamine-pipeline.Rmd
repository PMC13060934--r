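---
title: "From combinatorial mass libraries to operon-aware metagenomics: the acylamines pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From combinatorial mass libraries to operon-aware metagenomics: the acylamines pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acylamines)
```

# The scientific problem

Gut bacteria such as *Blautia wexlerae* synthesize N-acyl amides ("acyl
amines"): condensation products of a fatty acid and a biogenic amine, for
example oleoyl ethanolamide or oleoyl dopamine. These lipids act on host
receptors involved in appetite and glucose handling, so linking their
microbial production to host phenotypes requires three connected measurement
problems, which this package implements as one tested pipeline:

1. **Finding acyl amines in untargeted LC-MS data.** Because authentic
   standards exist for only a handful of conjugates, candidate ions are
   screened against an *in silico* combinatorial library of every amine ×
   fatty-acid amide, by exact mass at MS1 and by diagnostic fragments at MS2.
2. **Finding the biosynthetic machinery in genomes.** Acyl-amine synthesis
   in Clostridia is encoded by a three-gene operon — an acyl transferase
   (C), a small acyl carrier protein (T) and a fatty acyl-CoA ligase (A) —
   detected here by protein homology plus operon-structure rules.
3. **Measuring that machinery in stool metagenomes.** Cassette genes are
   quantified by translated read matching, normalized to reads per million,
   and compared between host groups with rank statistics.

A synthetic-data module generates all inputs with known ground truth, so
every stage is testable end to end without external downloads.

# The chemistry model

All mass arithmetic happens on molecular formulas (element-count maps,
rendered in Hill order). The mass scale is monoisotopic: carbon is exactly
12 Da and the other elements carry IUPAC most-abundant-isotope masses to at
least six decimals. Positive-mode electrospray observes the protonated
molecular ion, so predicted m/z is the neutral monoisotopic mass plus the
*proton* mass (1.007276 Da), not the hydrogen-atom mass — the 0.5 mDa
difference matters at the 5 ppm tolerances used here.

Amide condensation is element bookkeeping: amine + fatty acid − H₂O.
Exactly one water is removed per pair; polyfunctional amines (dopamine's
catechol hydroxyls, serine's alcohol) form only the N-acyl product, so an
*n*-amine × *m*-acid library has exactly *n·m* members. Each conjugate
carries two diagnostic fragments: the protonated free amine and the fatty
primary amide (fatty acid + NH₃ − H₂O, e.g. palmitamide C16H33NO from
palmitic acid).

```{r chemistry}
render_formula(condense_amide("C6H14N4O2", "C16H32O2")) # palmitoyl arginine
protonated_mz("C6H14N4O2")                              # arginine fragment ion
round(protonated_mz(condense_amide("C8H11NO2", "C18H34O2")), 1) # oleoyl dopamine
```

# MS1/MS2 annotation

`match_ms1()` reports every (feature, conjugate) pair within the MS1
tolerance; `annotate()` then screens MS2 spectra for the two diagnostic
fragments. Numerical conventions, chosen once and applied everywhere:

* ppm error is computed against the **theoretical** m/z, and the tolerance
  boundary is **inclusive** (a feature at exactly 5.0 ppm matches at 5 ppm).
* Defaults are 5 ppm at MS1 and 10 ppm at MS2, the tolerances of the
  high-resolution screen this pipeline models.
* A feature may carry several candidate conjugates; all are retained and
  ambiguity is resolved by the fragments, not by retention time (no RT
  model exists for unknown conjugates).
* Fragment evidence is tiered rather than collapsed: `confirmed` (both
  fragments), `partial` (exactly one), `ms1_only`. The underlying screen
  monitors both the amine-moiety and fatty-amide fragments but publishes no
  single decision rule, so the tiers preserve the evidence for the analyst.
* MS2 spectra are linked to features by feature id; when one feature has
  spectra at several collision energies their peak lists are pooled.

# Operon detection

`align_proteins()` performs optimal local (Smith–Waterman) alignment under
BLOSUM62 with affine gap costs (opening 11, extension 1, i.e. a gap of
length L costs 11 + L). Identity is matches over aligned columns, gap
columns counting against identity and `X` never counting as a match;
coverage is the fraction of the *reference* protein spanned by the
alignment — "80% of the protein sequence" is read as coverage of the
reference, the stricter and more common convention.

A gene is a C or A candidate when its best alignment to any reference of
that role reaches 70% identity over 80% coverage. The T protein is too
short for reliable homology calls at those cutoffs, so it is identified
*positionally*: a cassette hit is a C/A candidate pair on one contig and
strand with exactly one small ORF (≤ 120 aa) strictly between them and
intergenic gaps of at most 500 bp. The gap ceiling, T length ceiling, and
the acceptance of both gene orders (C→T→A and A→T→C) are package defaults
— "putative operon structure" is not quantified in the literature this
models, so all three are exposed as arguments, and raising either homology
cutoff can only shrink the hit set (a property the tests assert).

# Translated-read quantification

Each read is translated in six frames (codons containing N become X, stops
become `*`) and aligned locally against the cassette protein database. A
read counts when the best-scoring alignment for some frame and subject
contains a window of at least 30 aligned columns at ≥ 90% identity — the
window rule is evaluated *within* the single best-scoring alignment per
(frame, subject), matching how a translated aligner reports one alignment
per target rather than enumerating all sub-alignments. A read counts at
most once regardless of how many database genes it matches. Per-sample
abundance is reads per million: `aligned / total * 1e6`.

Two exact accelerations keep this tractable in pure R; neither can change
a result:

* **k-mer prefilter.** Any qualifying window has at most 10% non-match
  columns, so by pigeonhole it contains an ungapped exact run of at least
  ⌈0.9·30 / (0.1·30 + 1)⌉ = 7 residues. Reads sharing no exact 7-mer with
  the database (in any frame) are discarded before alignment.
* **Score prescreen.** The BLOSUM62 diagonal is ≥ 4 and the worst
  per-column cost of a non-match is 12 (a single-residue gap), so any
  qualifying window — and hence the optimal local score of a qualifying
  read — scores at least 30·(4·0.9 − 12·0.1) = 72. Frames are first scored
  with the alignment's score-only mode and only plausible ones are
  realigned with traceback.

# The supporting statistics

These are implemented from first principles because they *are* part of the
contract (exactness at small samples, tie handling), with base R's versions
used only as cross-checks in the test suite:

* **Mann–Whitney U**: U counts pairs with ties at half weight. Exact mode
  (default for n+m ≤ 12) builds the permutation null by a subset-sum count
  over doubled midranks — ties exact by construction — and doubles the
  smaller tail, capping at 1. Larger samples use the tie-corrected normal
  approximation with continuity correction.
* **Benjamini–Hochberg**: classical step-up minima on sorted p-values;
  Bonferroni is available where a stricter family-wise bound is wanted.
* **Hypergeometric enrichment**: the survival probability P(X ≥ k) of
  drawing k or more pathway metabolites among the n taxon-associated ones
  from N annotated with K in the pathway, summed in log space.
* **Spearman**: Pearson correlation of midranks; t approximation for
  n ≥ 10, full permutation enumeration below.
* **Trapezoidal AUC** for glucose-tolerance curves and **relative growth**
  (ratio of mean optical densities) round out the analysis endpoints, and
  `prevalence_filter()` applies the ≥ 20% prevalence pre-filter (inclusive
  at the boundary) before differential-abundance testing.

# What the generators emulate — and what they do not

The synthetic-data module reproduces the *statistical structure* each stage
assumes, with defaults frozen at the emulated study's conditions:

* **Compound lists** (460 amines, 53 fatty acids by default): random but
  chemically valid formulas, always including the real anchors (dopamine,
  ethanolamine, arginine; palmitic, oleic, linoleic, α-linolenic acid) so
  the literature mass anchors can be checked on generated data. The real
  460/53 lists are unpublished, so the printed 7,578 unique-formula count
  is not reproducible; formula deduplication is instead verified against
  brute-force set construction.
* **Feature tables**: 20 spiked conjugates with Gaussian mass error
  (SD 2 ppm) and 200 decoys placed at least 3× the MS1 tolerance from every
  library mass — an exclusion zone that makes the false-annotation count
  deterministically zero instead of a stochastic quantity.
* **Genomes**: background genes of 120–300 aa plus, in positive genomes, a
  planted C–T–A operon whose C and A proteins are mutated to target
  identities (100/85/75/65/60% by default, bracketing the 70% cutoff).
  Mutation is substitution-only so realized identity is exact to within
  rounding (verified to ±2 points); indel robustness is deliberately out of
  scope. Reference C/T/A proteins are synthetic stand-ins with the real
  cassette's size structure (T ≪ C, A).
* **Reads**: 150 nt, uniform positions, random strand, flat 0.5%/base
  substitution errors (no quality model, no indels), with ground truth
  recording ≥ 90 nt overlap with planted cassette genes. Cohort samples
  draw the cassette genome's abundance higher in group A than B with
  lognormal sample-to-sample noise (SD 0.25 on the log scale).

Every generator is a pure function of its configuration and seed (one
stream per generator, offset from the master seed, so adding a call never
perturbs another). Passing tests on these data demonstrate the pipeline's
correctness — recovery of planted signal at the stated tolerances — not
robustness to everything real data adds: chimeric reads, indel errors,
isotope interference, co-eluting isomers, or homologs at intermediate
identity with domain rearrangements.

# Problem sizes and numerical choices

The test suite exercises the full 460 × 53 = 24,380-conjugate library, 20
annotation replicates, a 10-replicate identity ladder for operon detection,
and read sets of 10⁵ for the exact reads-per-million check (the study-scale
rate of 250 per million appears as 25 reads in 10⁵) with a 2 × 10⁴-read
error-calibration run asserted at three binomial standard deviations.
Degenerate inputs fail loudly rather than silently: empty formulas, zero
counts, unknown elements, nonpositive reference OD, unsorted OGTT times,
constant vectors in rank correlation, and malformed TSV/MGF/FASTQ records
are all rejected with the offending record named where possible.

# Known limitations

* Only `[M+H]+` is predicted; negative-mode adducts, isotope patterns and
  retention-time modelling are out of scope.
* Operon-structure thresholds are heuristics standing in for an
  unquantified "putative operon structure"; they are arguments, not facts.
* The translated-read rule evaluates windows within the best-scoring local
  alignment per frame and subject; at exact score ties (e.g. a mismatch at
  a window's terminal column) the reported window can differ between
  co-optimal alignments.
* Percent "homology" is implemented as percent identity, the convention of
  the aligner being modelled; similarity-weighted scoring is not offered.
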