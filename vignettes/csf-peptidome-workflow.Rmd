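---
title: "Models and methods of the CSF peptidome biomarker workflow"
author: "CSFPeptidomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the CSF peptidome biomarker workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CSFPeptidomics)
```

# Scope

`CSFPeptidomics` implements a complete desk-scale version of a
cerebrospinal-fluid (CSF) peptidomics biomarker study: screening a
discovery cohort for differentially abundant endogenous peptides,
selecting candidates through a reviewed cascade of statistical and
analytical rules, and evaluating a small targeted panel in a validation
cohort by parallel reaction monitoring (PRM) with light/heavy
quantification and ROC classification. Every stage runs on data from the
package's own synthetic peptidome generator, so the statistical
machinery is testable end to end without access to instrument data.

This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic data do and do
not establish about behavior on real measurements.

# The quantification container

`PeptidomeExperiment` extends `SummarizedExperiment`: rows are peptides,
columns samples, the single assay `abundance` holds chromatographic peak
areas. Two conventions matter throughout:

* **Missing is `NA`, never zero.** An empty cell in a quantification TSV
  means "not detected"; a written zero is a measured value. Peptidomics
  intensity data are left-censored, and conflating the two corrupts both
  normalization totals and imputation.
* **Coordinates are 1-based inclusive**, the UniProt convention. A
  peptide record is valid iff `end - start + 1` equals its sequence
  length, the parent protein contains the sequence exactly at those
  coordinates, and any recorded flanking residues match the protein
  context (peptides at a protein terminus must record no flank on that
  side). `validatePeptideRecord()` reports each failed clause rather
  than erroring, because record validation is itself an analysis output.

A declared `normalizationState` (`raw` → `none`/`tic`/`stdpep` → `log2`)
prevents accidental double normalization or testing on raw areas.

# Normalization

Three strategies are compared in screening work and implemented in
`normalizeQuant()`:

* `none` — areas as exported.
* `tic` — divide each sample by its total observed signal and rescale by
  the mean total, preserving magnitudes. The total uses observed values
  only (missing is not zero). Whether the field's usual TIC variant
  rescales to a reference total is genuinely ambiguous; the mean-total
  rescale is this package's documented choice and affects nothing
  downstream of a log2 transform except an additive constant.
* `stdpep` — divide each sample by the median, over the five spiked
  non-human standard peptides (StdPep), of that standard's abundance in
  the sample relative to its mean across samples. The median (rather
  than the mean) tolerates one aberrant standard. Spike-in normalization
  is preferred as the primary strategy because it is independent of the
  most abundant endogenous peptides, which dominate a TIC.

Any data-driven reference makes the correction exact only up to one
global constant: multiplying a sample by a factor *f* changes the
per-standard means too, so the normalized matrix is reproduced up to a
single common rescale (the package's tests check exactly this
invariance).

# Differential analysis

The discovery statistics follow the Perseus-style pipeline that
practitioners run on peptide-level label-free quantification:

1. **Filtering** (`prepareMatrix()`): identification quality ≥ 5;
   spike-in standards removed; presence policy applied with `≥`
   semantics on the 70% bound (17 of 24 samples is 70.8% and is
   retained). Five policies are supported — at least 70% in each group,
   in either group, or overall, and at least 3 observations in each or
   either group — because the candidate-selection cascade (below) unions
   over them.
2. **log2 transform**, then **Gaussian down-shift imputation**
   (`imputeGaussian()`): per sample, missing entries are drawn from
   `N(mean − 1.8·sd, (0.3·sd)²)` computed on that sample's observed
   values. The defaults (width 0.3, down-shift 1.8) are the de facto
   standard for left-censored proteomics data. Columns with fewer than
   two observed values fall back to the global distribution and are
   flagged. The `min3` policies skip imputation and use the observed
   values only.
3. **s0-moderated two-sample statistic** (`s0TTest()`):
   `t = (mean_A − mean_B) / (se_pooled + s0)` with `s0 = 0.1` by
   default. The additive constant damps peptides whose tiny variance
   would otherwise make trivial differences significant; at `s0 = 0` the
   statistic is exactly the pooled-variance Student t (unit tests verify
   agreement with `t.test(var.equal = TRUE)` to 1e-10). The pooled
   (Student) form is the default; Welch is deliberately not silently
   substituted.
4. **Permutation-based FDR** (`permutationFDR()`): the null is built by
   re-drawing group labels (250 permutations by default; when the
   requested number exceeds the count of distinct arrangements, the full
   enumeration is used and logged). For peptide *i*,
   `q_i = [mean over permutations of #null |t| ≥ |t_i|] / [#observed |t| ≥ |t_i|]`,
   the pooled-null (SAM-style) estimator, followed by step-down
   monotonization so a more significant peptide never has a larger q,
   capped at 1. Significance is `q ≤ 0.05`. The s0 significance curve
   used for volcano-plot display is a visualization of the same
   statistic, not a second criterion.

Two behaviors of this pipeline are worth knowing. First, under a global
null the realized fraction of significant peptides is controlled at the
nominal level (the acceptance suite measures this by simulation).
Second, down-shift imputation is aggressive on a matrix spanning many
orders of magnitude: a single stochastically missing entry of a
well-quantified peptide is imputed near the censoring floor, which both
attenuates the estimated difference and inflates its variance. That is
faithful to the method, and it is why the power checks plant effects on
peptides clearly above the detection limit — the abundance class actual
candidates come from.

Nonparametric group comparisons mirror the validation-stage conventions:
two-sided Wilcoxon rank-sum for two groups, Kruskal–Wallis with Dunn's
tie-corrected post hoc z tests for more. The Dunn adjustment is Holm by
default — the multiple-comparison method is an open choice in the field,
so it is exposed as an argument. Spearman correlation matrices use
pairwise-complete observations and flag pairs with fewer than three
points.

`separationSummary()` standardizes peptide rows, clusters samples with
Ward (`ward.D2`) linkage on Euclidean distance, cuts at two clusters,
and reports specificity as the fraction of control samples in the
cluster whose majority label is the control label. Note a bias of this
convention: under randomly permuted labels the expected specificity is
not 50% (majority assignment conditions on the draw and ties break
against the control label), so the meaningful comparison is against the
aligned-label value, not against chance.

# Tryptic-like peptides

Endogenous peptides preceded by K/R in the precursor protein and ending
in K/R carry the signature of basic-residue-directed proteolysis (the
same specificity as trypsin, hence "tryptic-like"). The strict
both-sides definition is the default (`mode = "and"`); the permissive
either-side variant is available (`mode = "or"`) because both appear in
the field's usage, and by construction the or-set always contains the
and-set. A peptide at the protein N-terminus has no preceding residue
and fails the N-side condition. Observation in a sample means a
non-missing quantification; `trypticCounts()` reports per-sample counts
and percentages, compared between groups by Wilcoxon.

# Candidate selection

`runCriteriaUnion()` reruns the differential analysis once per presence
policy and unions the significant peptides, recording per-candidate
provenance (which criteria flagged it, in which direction; conflicting
directions are flagged for review, never silently resolved). The
rationale is inclusiveness at the screening stage: complete-data
effects are best caught by the no-imputation criteria, effects in
peptides present in only one group by the imputation criteria.

Exclusion rules (`applyExclusions()`) then remove candidates that are
analytically or biologically unusable, each removal logged with its rule
and value:

* freeze–thaw instability: variation above 100 percentage points of the
  recovery scale (recovery is `100 × treated / reference`; "variation"
  is `|recovery − 100|` — the metric is stated explicitly because usage
  in the field is loose);
* blacklisted proteins: albumin (blood-derived) and keratins
  (contamination), matched by accession/entry-name/gene patterns;
* explicit blood-derived annotation tags.

Assay acceptance uses `stabilityAssess()` (pass iff every recovery is
strictly within ±30%) and `dilutionLinearity()` (deviation
`100·|measured×factor − undiluted|/undiluted`, strict <20%). Strict
inequality at the bounds is a deliberate convention since boundary
semantics are rarely printed; at machine precision the choice is visible
only for integer-exact recoveries.

Targeted peak identity is scored by the normalized spectral contrast dot
product `dotp = Σ m·r / √(Σm²·Σr²)` between measured and reference
transition intensities. `peakQC()` passes a peak iff dotp is strictly
above 0.7 **and** at least 10 transitions are present **and** all
transition apexes co-elute within 0.1 min **and** the apex is within
1.0 min of the reference retention time. The RT default encodes the
field's practice of rejecting an identity whose standard elutes more
than a minute away; the co-elution default is a typical chromatographic
peak width at these gradients.

`assemblePanel()` applies a reviewed edit list (explicit removals and
additions with reasons) to the label-free candidates. Panel design
decisions — dropping redundant proteins, adding a second peptide for
coverage — are scientific judgments; encoding them as config rather than
inference keeps them auditable.

# PRM quantification and panel classification

`quantifyPRM()` sums retained transition areas per channel and reports
the light/heavy ratio per sample × peptide. Transitions with matrix
interference are excluded **symmetrically from both channels** — the
ratio must compare like with like. Interference is flagged
automatically when a transition's pooled log L/H deviates from the
other transitions' median by more than 3× their spread (median/MAD,
with a small floor so that noiseless data are not all flagged), or can
be excluded a priori by config. A sample without light peaks is missing
with reason "no peak" (the endogenous peptide is below the limit); a
missing heavy channel is an assay failure and an error, because the
isotope-labeled standard is always spiked.

`rocSingle()` computes the rank-based AUC (identical to Mann–Whitney
U/(n₁n₀), ties averaged — verified against brute-force pair counting on
exhaustive small label arrangements) with a DeLong 95% CI, oriented so
AUC ≥ 0.5 with the direction recorded. `rocCombined()` fits a binary
logistic regression by maximum likelihood on standardized log2 ratios —
a two-class multinomial model reduces to exactly this — and reports the
in-sample combined ROC from the fitted probabilities alongside the
per-peptide AUCs. On (quasi-)separation, a tiny ridge penalty (1e-6 on
the slopes, escalated tenfold as needed, never on the intercept)
stabilizes the Newton iterations; the penalty used is recorded in the
result. Standardization before the fit is a documented default — it
changes nothing about the ROC but makes coefficients comparable.
Missing ratios are handled by listwise deletion (reported), never
imputed for classification; peptides with more than 30% missingness are
refused. All AUCs are in-sample by design and labelled so — the package
deliberately makes no cross-validated claims at these cohort sizes.

`correlateExternal()` provides the tie-corrected Spearman correlation
against an external assay (e.g. an NFL immunoassay) on complete pairs.

# The synthetic peptidome generator

The generator (`SimConfig()`, `simulateProteome()`,
`simulatePeptidome()`, `simulateCohort()`, `simulatePRM()`,
`simulateClinical()`) emulates the statistical structure the analysis
relies on:

* **Proteome** — random sequences, 100–1500 residues, uniform over the
  20-letter alphabet; peptides are true substrings (length 7–40) with
  recorded flanks, so coordinate/flank validation is exercised for real.
* **Abundance law** — log10 true means uniform over the configured span
  (8 orders by default): rank-abundance curves of deep peptidome data
  are near-linear in log-abundance over most of their range, which a
  lognormal's tails would not reproduce.
* **Noise** — multiplicative lognormal per entry with CV 0.20 (typical
  replicate variation of label-free peptide areas), times a shared
  per-sample factor with CV 0.25 (loading/injection variation; this is
  what makes unnormalized spike-in CVs land in the realistic 30–35%
  band, and what StdPep normalization removes). The five standards
  additionally carry a shared per-sample run factor with CV 0.05
  (spiking/pipetting), which makes spike-in normalization non-trivial:
  its estimation noise propagates into every normalized value, a real
  cost of the method that the simulation preserves.
* **Missingness** — detection is Bernoulli with probability
  `plogis(steepness · (log10 abundance − midpoint))`, default midpoint
  1.5 and steepness 1.5 per decade: missing-not-at-random
  left-censoring, the regime the down-shift imputation assumes.
  Standards are always detected.
* **Effects** — fold changes per (peptide, group); group labels come
  from the closed clinical set. QC pool samples are drawn at fold 1.
* **Tryptic fraction** — catalog composition is controlled exactly by
  rejection sampling against the K/R flank rule. A per-group difference
  in the *observed* fraction is planted mechanistically: the
  lower-fraction group has a subset of tryptic-like peptides suppressed
  far below the detection curve, so the difference emerges through
  missingness, as a protease-activity difference would.
* **Clinical covariates** — a Gaussian copula against the target
  peptide's observed log2 abundance realizes a configured Spearman
  correlation (using the exact Pearson↔Spearman correspondence
  `ρ = 2 sin(π r_s/6)`), then maps onto realistic marginals (age ~
  N(62, 9); ALSFRS-r ~ N(40, 5) clipped to 0–48; disease duration
  lognormal with median 12 months; Qalb lognormal around 6). Functional
  scores and duration are only defined for ALS-spectrum samples.
* **PRM reports** — the heavy channel follows a fixed per-peptide
  transition-intensity pattern with small lognormal noise (CV 0.05);
  the light channel is the same pattern scaled by the sample's true
  ratio. Interference injection multiplies one named transition's light
  area; below-limit samples emit no light peaks. No spectra, m/z values
  or retention-time prediction are simulated — transition-level areas
  are the level at which the implemented analysis operates.

Determinism: one master seed; each stage derives its own stream by a
fixed labeled offset, and all generator outputs are byte-identical for
identical (config, seed).

What passing tests on this generator shows — and does not. The suite
establishes that the statistics are implemented correctly (oracle
equivalences), that error rates and power behave as designed under the
assumed noise model, and that the plumbing is lossless. It does not
establish robustness to structure the generator omits: correlated
peptides from shared precursors, batch drift and run-order effects,
ionization competition, chimeric identifications, or missingness
mechanisms beyond abundance censoring.

# Problem sizes

The shipped tests and the acceptance script run, by choice, at desk
scale: catalogs of 400–2000 peptides (the acceptance script's discovery
demo uses 2000), cohorts of 24 + 24 discovery and 42 + 67 validation
samples mirroring the study design the workflow addresses, 250
permutations, and 30–100 simulation replicates per property. These
sizes put Monte-Carlo standard errors comfortably inside the asserted
bounds; nothing in the implementation is specific to them, and the
generator defaults (10^4 peptides) reproduce full-scale matrices if
desired.

# Known limitations

* The permutation null re-draws labels without stratification;
  covariate-adjusted or paired designs are out of scope.
* The PEAKS-style identification "quality" score is carried as an
  opaque thresholdable number; its semantics are proprietary.
* Protein-level roll-up is deliberately absent: the workflow's premise
  is that individual peptide species carry signal that averaging across
  a protein's peptides would destroy.
* In-sample AUCs are reported as such; no external-cohort or
  cross-validated performance is claimed.
* One printed validation-panel record (PENK) is internally inconsistent
  (its sequence has 19 residues, its coordinates imply 18); the package
  keeps the record verbatim and the validator flags the mismatch — an
  example of why record validation is part of the workflow at all.
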