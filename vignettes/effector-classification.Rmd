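---
title: "Classifying kinase effectors from triple-inhibitor SILAC phosphoproteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying kinase effectors from triple-inhibitor SILAC phosphoproteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosfx)
```

## The experimental design phosfx models

The RAF–MEK–ERK module is the canonical growth-signalling cascade; in
BRAF-V600E melanoma it is constitutively active and is targeted clinically
with small-molecule inhibitors of BRAF, MEK or ERK. If the module were
strictly linear, inhibiting any of the three kinases should silence the same
set of downstream phosphorylation events. phosfx implements the quantitative
reasoning behind testing that prediction: cells carrying the activated
pathway are treated with each inhibitor separately, in biological triplicate,
and phosphorylation changes are read out by SILAC mass spectrometry.

In each experiment the drug-treated cells are heavy-labelled, the
vehicle-control cells light-labelled, and a super-SILAC internal standard
(medium channel) is mixed in for search coverage. The medium channel is
parsed but excluded from all statistics. Each quantified phosphosite yields,
per replicate, a heavy/light intensity ratio; dividing by the matching
protein-level H/L ratio removes changes in protein abundance, and the log2
of this ratio of ratios — the *log2FC* — is the elementary observation:

$$\mathrm{log_2FC} = \log_2 \frac{(H/L)_{\text{phosphosite}}}{(H/L)_{\text{protein}}}$$

A log2FC of −1 is a 50% reduction in phosphorylation after treatment. A site
down-modulated by **all three** inhibitors is interpreted as a downstream
effector of ERK (the terminal kinase); a site responding to exactly one
inhibitor under a stricter significance cut is a candidate direct substrate
of that kinase — evidence of non-linearity in the module.

## Input filtering and normalization

Only *class I* sites enter the analysis: localization probability ≥ 0.75 and
localization score difference ≥ 5, both inclusive (`filter_class1()`). The
cutoffs are stated with mixed wording in the field ("a probability of 0.75",
"greater than or equal to 5"); we read both inclusively, which is the
consistent interpretation, and the boundary case is pinned in a test.

`normalize_sites()` computes per-replicate log2FC values. Two conventions
matter:

* an intensity of 0 means "not quantified" and becomes missing — a SILAC
  channel cannot truly be zero, and treating it as such would produce
  infinite ratios;
* a site whose protein is absent from the proteome table is normalized
  against a protein ratio of 1.0 and flagged (`protein_normalized = FALSE`)
  rather than dropped. Phospho-enriched proteins are often invisible in the
  unenriched proteome run, and silently dropping them would hide real
  effectors; the flag lets users filter if they prefer.

The per-site replicate summary is the median of the non-missing replicate
values (robust to a single outlying replicate); the statistical test below
consumes the per-replicate values themselves, never the summary.

## The moderated one-sample t-test

With three replicates per condition, per-site variance estimates are noisy;
the standard remedy is empirical-Bayes variance shrinkage. Each condition is
tested against a null mean log-ratio of zero, which is the intercept-only
special case of the limma linear model — the design has no covariates, so
nothing more general is needed. The machinery is implemented in closed form
in this package (`estimate_prior()`, `moderated_t()`, `bh_fdr()`); limma
itself is used only as an independent cross-check in the test suite.

The sample variance $s_g^2$ of site $g$ (residual df $d$) is assumed to
follow $s_g^2 \mid \sigma_g^2 \sim \sigma_g^2 \chi^2_d / d$ with a scaled
inverse-chi-square prior $1/\sigma_g^2 \sim \chi^2_{d_0}/(d_0 s_0^2)$. The
hyperparameters are fit by method of moments on the log scale: the mean and
variance of $\log s_g^2$ have closed forms in digamma/trigamma functions,
and the trigamma equation is inverted by Newton iteration. When the observed
spread of log-variances does not exceed the pure sampling floor
$\psi'(d/2)$, there is no evidence of heterogeneity: $d_0 = \infty$ and
$s_0^2$ is the mean variance. The posterior variance and moderated statistic
are

$$s^2_{\text{post}} = \frac{d_0 s_0^2 + d s^2}{d_0 + d}, \qquad
  t = \frac{\bar{x}}{\sqrt{s^2_{\text{post}}/n}} \sim t_{d_0 + d},$$

with the normal limit used when $d_0 = \infty$. Two-sided p-values are used
because both up- and down-modulation are called. Benjamini–Hochberg
adjustment is applied within each condition by default (each inhibitor's
volcano is its own family); a `global_fdr` switch pools all conditions, an
ambiguity we surface rather than hide.

Numerical choices worth noting:

* sites quantified in fewer than `min_reps = 2` replicates in a condition
  get an `NA` result there — one observation carries no variance
  information. The threshold is configurable.
* when replicate counts are mixed (some sites with 3, some with 2
  observations), the prior is estimated from the modal-df subset and applied
  with each site's own df. This avoids a multi-df moment fit for a marginal
  gain that the simulations show is negligible.
* p-values are clamped at the smallest positive double: with near-zero
  replicate noise $t$ diverges and `pt()` underflows to exactly 0, which
  would leave the BH domain $(0, 1]$.

`bait_enrichment_z()` covers the orthogonal AP-MS validation arm: enrichment
of a FLAG-tagged bait over control pulldowns as
$(\bar{x}_{\text{bait}} - \bar{x}_{\text{ctrl}})/\mathrm{sd}_{\text{ctrl}}$,
with missing intensities imputed at half the smallest observed value — a
conventional detection-floor surrogate.

## Threshold calibration and effector classification

Rather than choosing fold-change cutoffs a priori, the thresholds are
calibrated from positive controls: phosphosites known in advance to respond
to pathway inhibition (e.g. established ERK effectors on STMN1, TPR,
RPS6KA1, NUP153). `calibrate_thresholds()` takes the least-negative control
summary log2FC and the largest control FDR, rounded outward to one decimal
(the 0.1 grid explains round published thresholds such as −0.7 and 0.1), and
also reports the raw, unrounded maxima. The stricter specific-effector FDR
is set to half the call FDR, reproducing the 0.1/0.05 pair; the up-threshold
mirrors the down-threshold.

Calls are strict inequalities — `down` iff FDR < 0.1 **and** log2FC < −0.7 —
matching the "<" convention in which such thresholds are reported.
`classify_effectors()` then combines the three conditions:

* `shared_effector`: down in **all** conditions. A site with an `NA` call in
  any condition is excluded, never imputed — a site seen in one replicate
  of one condition must not be promoted to a shared effector on partial
  evidence.
* `specific:<condition>`: passes FDR < 0.05 and log2FC < −0.7 in one
  condition while not down-called in any other. The phrase "not modulated in
  the other conditions" could also mean "log2FC above the threshold
  regardless of significance"; we implement "not down-called" as the default
  and expose the stricter reading as `strict_other_condition = TRUE`.
* `partial`: down somewhere but not everywhere and not specific. This class
  keeps the partition exhaustive; such sites (e.g. known feedback sites that
  miss the threshold in one arm) are described narratively in the literature
  but deserve an explicit label.
* `none`: everything else.

The classifier is validated against an exhaustive enumeration of all
three-condition call combinations transcribed independently as per-site
if/else rules.

## The synthetic-data generator

`simulate_experiment()` emulates the statistical structure of the design so
that every stage is testable with known ground truth. Channel-level
intensities are generated, not ratios, because the pipeline consumes
intensities: light intensities are lognormal (meanlog `log(1e6)`, sdlog 1,
arbitrary instrument scale); each protein carries a per-condition,
per-replicate log2 drift (sd `protein_ratio_sd = 0.3`) representing true
protein-abundance change plus protein-level measurement error; a
phosphosite's heavy channel multiplies its protein's drift by
$2^{\text{effect} + \varepsilon}$, $\varepsilon \sim N(0, 0.25)$. Proteome
normalization cancels the drift exactly, so the normalized log2FC is
$N(\text{effect}, \text{noise\_sd})$ by construction.

Defaults define the simulated study conditions: 2000 sites on 800 proteins,
3 conditions × 3 replicates, 2% shared effectors and 1% per-condition
specific effectors at effect −1.5, replicate noise sd 0.25 (the study does
not report its empirical replicate sd; 0.25 in log2 units is typical of
SILAC phosphoproteomics triplicates and is exposed in the config), 10%
replicate-level missingness, 10% of sites failing class I, and 2% of
proteins withheld from the proteome table to exercise the flagged
normalization path. Missingness is completely at random at the replicate
level (the H/L pair vanishes together): no missingness mechanism is
reported for the real data, and MCAR is the minimal documented assumption —
real phosphoproteomics missingness is partly intensity-dependent, which the
generator deliberately does not model. Localization failures are planted
uniformly across effector classes. The medium channel is generated (as the
geometric mean of heavy and light) and ignored, mirroring its role as an
unused internal standard.

What passing the recovery tests shows — and what it does not: the pipeline
correctly inverts the generative model it was built for (planted effects,
Gaussian replicate noise, MCAR missingness). It does not certify behaviour
under intensity-dependent missingness, mislocalized sites, ratio
compression, or peptide-level interference, none of which the generator
emulates.

Recovery metrics (`evaluate_recovery()`) are computed over the analyzed
universe — sites that passed class I. The filter is a detection step: a site
the pipeline was told is unlocalizable cannot be recovered by any
classifier, so including it in the recall denominator would measure the
generator, not the method. Under the defaults, shared-effector recall is
about 0.9 (bounded by the ~3% of effectors that lose two or more replicates
in some condition to missingness) and the false-positive rate among null
sites is below 0.1%, well under the 2% design bound. With near-zero noise
and no missingness the classification equals the planted truth exactly;
`noise_sd = 1e-6` rather than 0 is used for that round trip because all-zero
variances are a degenerate input to the prior fit (the generator itself
accepts `noise_sd = 0` for checks that bypass the test).

## Kinase specificity from positional-scanning peptide arrays

For a kinase with no public substrate motif, specificity can be measured
directly with an arrayed positional-scanning peptide library: 180 peptide
mixtures on the template Y-A-x-x-x-x-x-**S/T**-x-x-x-x-A-G-K-K, where each
mixture fixes one of the nine "x" positions (−5..−1, +1..+4 relative to the
central acceptor) to one of the 20 amino acids while the other x positions
hold an equimolar mixture of 17 amino acids (no Cys/Ser/Thr, which would
introduce competing acceptors or cross-linking). `enumerate_library()`
reproduces this combinatorics from the template string.

`build_pssm()` converts the quantified radiolabel matrix into a specificity
matrix by normalizing each position column to mean 1 over the 20 residues
and taking log2 — so 0 means indifference, positive values preference.
Cys/Ser/Thr rows still receive values from their fixed-position mixtures; no
special-casing. Replicate assays are normalized first and then averaged on
the log2 scale (`average_pssms()`); averaging raw counts first would weight
assays by total incorporation, but the alternative order is available since
the convention is not universal.

`score_flank()` scores a 15-mer site window additively over the nine
variable positions — log-odds additivity is the standard PSSM model; the
array measures the matrix, not the combination rule, so additivity is this
package's documented choice. The acceptor position never contributes, S and
T acceptors are equivalent (the template admits both), terminal padding and
non-standard residues contribute 0, and tyrosine-centered windows are
rejected for an S/T-directed matrix. `rank_kinases()` orders kinases by
score with lexicographic tie-breaking so ranks are reproducible.

`simulate_peptide_array()` closes the loop: given a linear-scale truth
matrix it generates raw counts (each position column scaled to a total
signal) with multiplicative lognormal noise of chosen CV. At zero noise
`build_pssm()` inverts it exactly; at CV 0.1 the recovered matrix correlates
with the truth at r > 0.95.

## Problem sizes and runtime

The simulation-based checks use 2000-site experiments (5 seeds) for
end-to-end recovery, a 7000-site null experiment (~21,000 site-tests) for
the type-I error calibration, and 5000–10,000 draws for prior recovery —
sizes at which the Monte-Carlo error is comfortably inside the asserted
tolerances while the full suite runs in well under a minute.

## Known limitations

* The moderated test is intercept-only; contrasts, variance trends, weights
  and robust priors are out of scope.
* FDR families (per-condition vs global) change the calls near the
  threshold; we default to per-condition and flag the choice.
* The PSSM scorer is a pure linear motif model: no network context, no
  classifier ensemble, no cross-kinase score normalization beyond ranking.
* The generator's MCAR missingness and Gaussian replicate noise are
  idealizations; see above for what that implies about test evidence.
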