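---
title: "Shotgun lipidomics quantification and diet-response analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shotgun lipidomics quantification and diet-response analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shotgunlipidr)
```

# Scope and model

`shotgunlipidr` implements a direct-infusion (shotgun) lipidomics
quantification chain and the downstream muscle-lipidome diet-response
analysis for a five-strain, two-diet mouse cohort. Direct infusion resolves
lipid classes not by chromatography but by class-specific MS/MS channels:
precursor-ion scans (all precursors yielding a diagnostic fragment, such as
the phosphocholine fragment at *m/z* 184.1) and neutral-loss scans (all
precursors losing a fixed neutral, such as the 141 Da
phosphoethanolamine head group). Sphingolipids are read from a separately
hydrolyzed extract in which acyl-linked glycerolipids have been destroyed.
At unit resolution a channel delivers, per species, one centroided peak per
isotopologue; everything downstream is arithmetic on those peak lists.

The pipeline stages are: species database construction from shorthand
nomenclature; synthetic-cohort generation (the validation instrument);
spectral processing (smoothing, s/n filtering, matching, isotope
correction); internal-standard quantification with molecular-species
resolution; derived membrane metrics; and the screening statistics.

# Nomenclature and the species database

Species are named in the community shorthand: sum composition
(`"TAG 54:5"`: total acyl carbons and double bonds) or molecular species
(`"PC 16:0/22:6"`: both chains resolved, without sn-position or double-bond
localisation, which are out of scope). TAG, DAG and CE are carried at sum
level only — the acquisition cannot distinguish the individual chains of a
TAG. SM and CER names denote the N-linked acyl under the assumption of the
major d18:1 sphingoid backbone, since the 184.1 scan cannot separate
isobaric backbone variants.

Elemental compositions are assembled per class as head group + backbone +
chain contributions (ester and amide linkages contribute
C~c~H~2c−2d−2~O, alkyl ether linkages C~c~H~2c−2d~), and monoisotopic
masses from standard atomic masses; `PC 16:0/18:1` gives C42H82NO8P,
759.5778 Da, matching the published value for POPC. Precursor adducts are
configurable with community-standard defaults: [M+H]⁺ for the
phospholipids and sphingolipids, [M+NH₄]⁺ for the neutral lipids (TAG,
DAG, CE), [M−H]⁻ carboxylates and precursors in negative mode. The PS
channel fragment and the precise adducts are not documented for the
original acquisition, so these defaults are explicit assumptions, not
reconstructions.

Because shorthand cannot encode double-bond position, n-3/n-6 family
membership is a configurable lookup keyed by `C:D`. The default covers the
common mammalian PUFA (`18:2` n-6 … `22:6` n-3); `22:5` is genuinely
ambiguous and defaults to n-3 (docosapentaenoic acid, the dominant isomer
in rodent muscle). A PUFA is defined as a chain with at least two double
bonds — the standard convention; this threshold drives the "at least
one PUFA" and "double-PUFA" phospholipid categories, so it is a parameter
of record. The enumeration space is bounded (even-carbon chains 12–24,
double bonds capped per class) to keep the database at a few hundred
species; odd chains enter only as internal standards or via the
ether/odd-chain rule below.

# The synthetic cohort: what it emulates

No public raw data accompany the study the workflow targets, so the
generator is the package's instrument. It emulates:

* the design — 5 strains × 2 diets × n = 4 replicates, 25 mg tissue per
  sample;
* replicate variation — independent lognormal concentrations with
  `E[conc] = mean` and CV 0.15 by default (concentrations are positive and
  right-skewed, which is also why the statistics log-transform);
* the diet-effect structure — the high-fat diet doubles TAG species means
  in every strain; DAG, CER and SM means are unchanged; double-PUFA
  phospholipid means are multiplied by 0.6 in four strains but not in the
  protected strain (BALB/c); double-PUFA species make up ≈1.9% of the
  phospholipid pool at baseline, inside the 1.0–2.6% band reported for
  muscle;
* spectra — per-channel peaks at database target *m/z* with intensity =
  response × amount, M+0…M+4 isotope envelopes, internal standards at
  known nmol amounts, ether-PE emitted at 1/3.45 of the diacyl response in
  the neutral-loss channel, baseline peaks and additive Gaussian noise,
  and merging of centroids closer than 0.2 Th (unit resolution cannot
  separate a species' M+2 from the monoisotopic peak of the neighbour one
  double bond down, 0.009 Th away).

Default CHOW means anchor the class totals to the reference class-total
table shipped in `inst/extdata/table1_class_totals.csv` (TAG 7.81, PC
11.27, PE 3.15 nmol/mg, …). What the generator does **not** emulate — and
what passing tests therefore cannot certify about real data — includes
ion suppression, adduct competition, in-source fragmentation, response
drift, inter-species biological covariance (species are drawn
independently) and baseline structure beyond white noise. Negative-mode
fatty-acyl channels are synthesized without isotope envelopes: the
molecular-species fractions are intensity ratios at a single precursor
*m/z*, so a common envelope factor cancels; cross-species M+2 talk in
negative mode is a known omission.

# Spectral processing

**Smoothing** is a centred moving average with edge truncation; the
default window of 1 point is the identity, since the generator emits
centroids. **Peak filtering** keeps peaks with s/n *strictly* above the
threshold (default 10); "over 10" is read as `>`, and the boundary is
configurable. When a peak list carries no s/n column, the noise scale is
estimated robustly as 1.4826 × MAD of the intensity distribution, which is
dominated by the baseline.

**Matching** assigns each peak to the nearest database target within
0.3 Th (unit-resolution instruments; vendor-internal tolerances are not
documented, so this is explicit configuration). Exact ties break toward
the lower-*m/z* target and are logged. A peak whose window contains both
an ether-linked and a non-standard odd-chain interpretation — the two are
0.036 Th apart, far below unit resolution — is assigned to the ether
species, the field's convention for tissues where ether lipids dominate
odd-chain species.

**Isotope correction** is two-stage. Stage 1 walks each channel in
ascending *m/z* and subtracts, from each species' monoisotopic intensity,
the M+2 and M+4 contributions of species whose isotopologues land on its
peak: dominantly the same-class species with one (two) more double bonds,
but the landing site is computed from the *m/z* axis, so near-isobars of
other classes in the same channel (e.g. a PC M+2 falling on an ether-PC
target 0.05 Th away) are also handled. Coefficients are ratios of envelope
fractions, `a₂ = f₂/f₀`. Negative corrected intensities are clamped to
zero with a warning; values within floating-point residue of zero are set
to exactly zero so that pure-contamination targets do not surface as
phantom detections. Stage 2 divides by `f₀` so intensities represent whole
species.

Two envelope models are provided. The default carbon-only binomial
(¹³C = 0.0107) is the standard unit-resolution approximation. The full
multi-element convolution (¹³C, ²H, ¹⁵N, ¹⁷O/¹⁸O) is exact; tests
generate spectra under it and verify the correction inverts it to within
1%. The binomial underestimates the absolute M+0 fraction by ~3% for a
C42 phospholipid (the ²H/¹⁵N/¹⁸O terms), but quantification is a *ratio*
to a same-class internal standard, whose non-carbon isotope factors are
nearly identical, so the deficit cancels to well under 1% within a class
— the reason the binomial default is safe.

# Quantification

Concentrations are `corrected(i)/corrected(IS) × amount(IS)/tissue mass`
(nmol/mg). One internal standard per class is configuration (the original
standards are documented elsewhere and not public); the defaults are
non-endogenous odd- or short-chain species, flagged in the database and
exempt from the ether/odd rule. The ether classes are read against their
diacyl parent's standard: that is precisely why ether-PE needs the 3.45
response factor, which is applied at class quantification. Whether the
original workflow applied the factor before or after isobaric
fractionation is unstated; applied before, the result is identical because
fractional allocation is proportional.

Molecular-species resolution enumerates, for each quantified sum
composition of PC/PE/PS, the candidate chain pairs in the database. A
pair's evidence is the summed intensity of its distinct chains' precursor
channels at the species' [M−H]⁻ *m/z* (summing a repeated chain's single
channel once keeps evidence proportional to amount for both mixed and
identical-chain pairs; `min` is available as the conservative
alternative). Fractions are evidence over total evidence across detected
pairs, and they multiply the sum-level concentration, so mass is conserved
exactly. Evidence is read *at the m/z position* rather than via exclusive
peak assignment because one unresolved peak can legitimately support
near-isobaric targets of different classes. Sum species with no evidence
pass through unresolved and flagged — class totals never lose mass, but
unresolved species cannot enter the PUFA categories and are logged when
excluded.

# Derived metrics

Class totals sum member species at molecular level where resolved and sum
level otherwise; counting a species at both levels is a hard error. The
phospholipid pool is defined explicitly as PC + PC-O + PE + PE-O + PS (the
reference table's printed PL totals do not equal the sum of its subclass
rows; the package does not attempt to reproduce that discrepancy). The
PC/PE ratio defaults to diacyl totals with ether subclasses excluded —
the source analysis does not state the choice — and is configurable. A
species with one n-6 and one n-3 chain counts in both family sums (also
unstated in the source; exclusive assignment is a configuration away).
Diet deltas are arithmetic mean differences on raw concentrations, per
strain; the log transform exists for testing, not for effect reporting.

# Statistics

Per species: natural log transform (base unstated in the source; natural
log chosen), with zeros replaced by half the species' minimum positive
value (logged) and all-zero species dropped; then a one-way ANOVA. The
phrase "between CHOW and HFD in the different strains" is ambiguous
between one ANOVA across all 10 strain-by-diet cells and a per-strain
two-group ANOVA; the 10-cell omnibus is the default because *protected*
LSD reuses the pooled ANOVA error, which only exists in the omnibus
reading; `anova_mode = "per_strain"` provides the other. With zero
within-cell variance everywhere, p is 1 when the cell means are identical
and 0 otherwise, by logged convention.

The ranked p-value/normal-probability examination is implemented as a
diagnostic output only (`rank_pvalue_diagnostic()`); it gates nothing. The
operative screen is omnibus P < 0.05: only such species receive post-hoc
diet comparisons, Fisher's LSD with the pooled MSE and within-cell degrees
of freedom, two-sided, significant at p < 0.01, direction from the sign of
the raw mean difference. No multiplicity correction beyond the protection
is applied — that is the procedure's design. Under a complete null
(simulated: 1000 lognormal species, CV 0.2, identical means, 10 cells,
n = 4) the empirical per-comparison false-positive rate — significant
calls over *all* strain-wise comparisons the procedure adjudicates,
screened-out species counting as non-significant — is ≈0.005, below the
nominal 0.01. Conditioning instead on the post-hoc tests actually executed
would give ≈0.09 by selection, which is why the protection is reported on
the per-comparison scale.

# Numerical choices and degenerate inputs

* Matching tolerance 0.3 Th, peak-merge tolerance 0.2 Th, envelope
  truncation at M+4 — all configurable; merge < match so one target sees
  one peak.
* Tie-break in matching: lower *m/z*, logged; distances within 1e-9 Th are
  ties.
* Isotope-correction floor: |corrected| < 1e-9 × channel maximum is
  exactly zero; genuine negatives clamp to zero with a warning.
* Missing internal standard: a per-class, per-sample quantification error,
  flagged in the QC log and warned about — never silently dropped.
* An empty chain space yields an empty database; an empty spectrum yields
  an empty peak set; zero PE total makes the PC/PE ratio a hard error
  (PC = 0 returns 0).
* Replicates below 2 are refused at configuration time (group statistics
  need at least two samples per cell).

# Problem sizes

The shipped tests validate on deliberately small instances: a two-strain
zero-noise cohort for exact parameter recovery (machine precision with the
matched envelope model), the full 40-sample default cohort for the
qualitative diet-response pattern, 1000-species null simulations for the
type-I properties, and 25-instance brute-force comparisons for the
ANOVA/LSD algebra. These sizes make the whole suite run in about two
minutes while leaving every assertion at its stated tolerance.

# Known limitations

* Identification is nearest-target at unit resolution: true isomers
  sharing a sum composition are resolved only through fatty-acyl evidence,
  and near-isobars closer than the merge tolerance are fundamentally
  confounded (the ether/odd rule is a convention, not a measurement).
* The generator's independence assumption means cross-species covariance
  (shared regulation, batch effects) is untested.
* Response factors are flat per class; calibration curves and multi-IS
  designs are out of scope, as are lyso-lipids, mzML ingestion and
  profile-mode spectra.
* The statistics implement the study's procedure faithfully, including its
  lack of FDR control; users wanting error control across species should
  treat the per-species p-values accordingly.
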