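---
title: "Blood-based DNA methylation marker discovery and verification with methylscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blood-based DNA methylation marker discovery and verification with methylscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylscreen)
```

## The problem

Aberrantly methylated tumor DNA leaks into the bloodstream, where it can be
detected against the overwhelming background of DNA shed by peripheral
blood leukocytes (PBL). A blood-based methylation marker for ovarian cancer
therefore has to satisfy two conditions at once: it must be methylated
consistently across tumors (sensitivity), and it must be unmethylated in
the blood of women without the disease (specificity). methylscreen
implements a discovery-and-verification pipeline built around that
contrast: candidate loci are ranked by how cleanly the *least* methylated
tumor separates from the *most* methylated normal leukocyte sample, then
survivors are pushed through a series of counter-screens on PCR-based
platforms, quantified molecule-by-molecule in serum, and finally judged by
whether their serum kinetics track CA-125, the established protein marker
of ovarian tumor burden.

## The selection cascade

The discovery input is a probe-by-sample matrix of Infinium-style beta
values — fractional methylation scores in $[0,1]$ per CpG — together with a
matching matrix of detection p-values, a probe annotation, and a sample
sheet distinguishing tumors from PBL samples. The cascade applies, in
order:

1. **Detection QC.** Any probe with detection $p > 0.05$ in *any* sample
   (tumors and each PBL replicate, before averaging) is removed. Survivors
   are complete by construction, which is why the ranking step later treats
   a missing beta as an error rather than imputing.
2. **Annotation exclusion.** Probes flagged as overlapping a SNP or a
   RepeatMasker repeat are removed; such probes report genotype or
   cross-hybridization artifacts rather than methylation. The flags are
   consumed as input — the package does not recompute overlaps from dbSNP
   or RepeatMasker tracks. A probe without an annotation record is an
   error, never a silent keep.
3. **Replicate averaging.** PBL subjects are assayed in technical
   duplicate; replicates are collapsed to the per-subject arithmetic mean
   beta. The collapsed detection p is the maximum over replicates — the
   conservative choice, since the original protocol does not say.
4. **PBL methylation filter.** A probe with averaged beta $\ge 0.2$ in any
   PBL subject is removed. The rule is inclusive at the boundary: a probe
   at exactly 0.2 falls. (The source protocol states the rule both as
   "$\ge 0.2$" and as "$> 0.2$" in different places; we follow the
   methods-section wording and expose the threshold as a parameter.)
5. **Separation ranking.** Per probe, $T_L$ is the beta of the least
   methylated tumor and $PBL_H$ the beta of the most methylated PBL
   subject; probes are ranked by $\Delta = T_L - PBL_H$ descending and
   those with $\Delta \le 0$ are eliminated. $\Delta > 0$ means *every*
   tumor is more methylated than *every* normal blood sample — a
   deliberately stringent, worst-case-first criterion. Ties in $\Delta$
   break by probe id so the ranking is reproducible; the original report
   does not specify a tie rule.
6. **Top-k selection.** The first $k$ (default 15) ranked probes move to
   verification. With `unique_genes = TRUE` only the best probe per gene
   symbol is kept before truncation; the collapse rule is ours, since the
   source reports both probe and unique-gene counts without stating one.

Each stage emits a `filter_report`, and `funnel_table()` reconciles the
counts end to end; permuting sample columns changes nothing.

```{r cascade, eval = FALSE}
gen <- generate_infinium_cohort(sim_config(seed = 1))
sel <- select_markers(gen$cohort, gen$annotation, top_k = 15)
funnel_table(sel$reports)
```

## MethyLight verification

MethyLight is methylation-specific real-time PCR: a reaction reports a
cycle threshold (Ct) when methylated template is present, and nothing
otherwise. methylscreen encodes "undetected" as `NA` — the distinguished
missing value that propagates through arithmetic — never as a large
pseudo-Ct that could silently enter a calculation.

The verification cascade is order-fixed and short-circuiting; a marker
that fails one stage records no outcomes for later stages:

* **Assay design** — some loci cannot support a MethyLight primer/probe
  design at all.
* **M.SssI gate** — the assay must amplify fully methylated
  (M.SssI-treated) control DNA; an assay that cannot see 100% methylation
  is invalid.
* **PBL counter-screen** — against an excess of normal PBL DNA, every
  control sample must show Ct above 35 (or no amplification). One sample
  at Ct 34 fails the marker.
* **Plasma screen** — every healthy control plasma must show PMR below 5.
* **Tumor positivity** — the fraction of tumors with PMR above 20; by
  default all tumors must be positive.

**PMR** (Percent of Methylated Reference) is double-delta-Ct
quantification normalized to an ALU repeat control and scaled to the
M.SssI reference:

$$\mathrm{PMR} = 100 \times
  2^{-\left[(Ct^{target}_{sample} - Ct^{ALU}_{sample})
        - (Ct^{target}_{ref} - Ct^{ALU}_{ref})\right]}$$

The formula is the standard one from the MethyLight literature; the
categorization bins (low $<10$, mid $10$–$50$ closed, high $>50$) treat
the boundaries as mid, and both boundaries are configurable. An undetected
target with a valid ALU control yields PMR 0 (no methylation detected); an
undetected ALU is an error, because normalization is impossible. Input DNA
quality is gated separately: only DNAs whose ALU reaction crosses below
Ct 21 (strict) are usable at all. The PCR cycle ceiling that defines
"undetected" is taken as 50 cycles.

## Digital molecule counting

Digital MethyLight distributes a serum DNA aliquot across the wells of a
plate at limiting dilution and counts wells that amplify. With $k$
positive wells of $N$, the naive estimate (one molecule per positive well)
undercounts as soon as two molecules land in one well. The
most-probable-number correction inverts the Poisson occupancy model:

$$\hat\lambda = -N \ln\!\left(1 - k/N\right)$$

which is also the maximum-likelihood estimate under binomial sampling of
positive wells. A fully positive plate ($k = N$) carries no upper-tail
information and is an error under this method. Corrections are applied
per plate and then summed — dilution into wells happens per plate — and
concentrations are scaled to molecules per ml serum via
$1000/\text{volume assayed in }\mu l$ (100 µl per analysis by default,
with 1 µl of converted DNA representing 1 µl of serum). Samples with more
than 15 positive wells per 96 (scaled proportionally for other plate
sizes) are flagged `saturated`: the raw count regime where multiple
molecules per well become likely. The package both flags (as the source
protocol does) and corrects (as the field's standard estimator does).

## Longitudinal concordance and ROC

The clinical verification logic asks whether the marker's serum
concentration behaves like a measure of tumor burden. Per patient, the
package computes the Pearson product-moment correlation between serial
CA-125 (U/ml) and marker (molecules/ml) measurements, with the two-sided
$t$ test of $r = 0$ on $n-2$ degrees of freedom and a significance cutoff
of 0.05. Pairs with a missing value in either channel are dropped
pairwise; series with fewer than three complete pairs or zero variance
are reported as untestable rather than silently excluded. Values are
correlated on their raw scales (the source is silent on transforms;
two-sided tests are the standard choice for this null).

A post-resection drop is called, independently per channel, when the first
post-surgery draw is strictly below the baseline (first) draw. Baselines
may precede or follow surgery; the `baseline_is_presurgery` flag carries
that distinction.

Case/control discrimination uses the midrank AUC
($U$-statistic scaled to $[0,1]$, ties at half credit) with a stratified
percentile bootstrap confidence interval: cases and controls are resampled
within group, 2000 times by default, deterministically under a seed.

## The synthetic-data generator

Every pipeline input can be generated with known ground truth, so each
stage is testable without any external download.

* **Discovery cohorts** (`generate_infinium_cohort`): 27,578 probes by
  default, 41 tumors, and 2 PBL subjects in technical duplicate —
  the dimensions of the screened study the pipeline targets. Beta values
  are drawn from beta distributions parameterized by (mean, precision),
  which maps directly onto how group-level contrasts are specified:
  planted markers use mean 0.70 in tumors versus 0.02 in PBL (precision
  50), background probes mean 0.08, and 30% of probes are "PBL-high"
  (mean 0.55) in all groups to exercise the leukocyte filter. 0.2% of
  probe-by-sample cells fail detection QC; 3% and 2% of probes carry SNP
  and repeat flags. The planted count (40) and these background fractions
  are the package's own choices of a realistic screening landscape — the
  source reports only its observed funnel counts, which depend on the
  actual array annotation. Planted probes are exempted from simulated QC
  failures and annotation flags: the recovery invariant ("a correct
  cascade retains every planted marker") is only well-defined when the
  planted truth is not itself destroyed by engineered artifacts.
* **Patient trajectories** (`generate_patient_series`): a latent tumor
  burden that is constant to surgery, decays exponentially afterwards
  (0.5/week by default — resection removes most burden within weeks), and
  regrows from an optional relapse week. Both observed channels share
  this latent: CA-125 is an affine function of burden (300 U/ml per
  burden unit over a 10 U/ml non-tumor floor) under multiplicative
  lognormal noise (CV 0.2 — CA-125 spans orders of magnitude, so noise is
  multiplicative), and molecule counts are Poisson in the assayed volume
  (200 molecules/ml per burden unit, 100 µl per draw, draws every 6 weeks
  for ~90 weeks). The zero-burden sanity case is exercised with the floor
  set to 0, since a floor of 10 U/ml otherwise represents healthy
  baseline CA-125 production.
* **Digital plates** (`generate_digital_plates`): Poisson molecule input,
  uniform assignment to wells, a well positive iff it received at least
  one molecule — exactly the model the MPN estimator inverts. Detection
  efficiency defaults to 1.0 but is exposed, because real bisulfite
  recovery is lossy.
* **MethyLight panels** (`generate_methylight_panel`): a 15-marker panel
  with 3 design failures, 1 M.SssI failure, 3 PBL-methylated and 7
  plasma-positive markers by default, so the default screen funnel is
  15 → 12 → 11 → 8 → 1.

What the generator does **not** emulate: raw two-channel array
intensities and their normalization, bisulfite conversion chemistry,
PCR amplification curves, batch effects, within-tumor subtype
heterogeneity (a histology label is carried but unused), assay-specific
Ct noise structure, and clinical relapse adjudication. Passing tests
therefore demonstrate that the *computational* pipeline is correct under
its stated statistical model — not that the model captures every feature
of real cohorts.

## The synthetic serial table

`synthetic_serial_table()` is a labelled synthetic stand-in for a
nine-patient longitudinal verification dataset whose published per-patient
correlations are known but whose raw measurements are not distributed
with this package. Six patients are constructed — by standardizing the
CA-125 trajectory, projecting out an orthogonal residual, and mixing with
weights $(r, \sqrt{1-r^2})$ — to have *exact* sample correlations 0.97,
0.81, 0.70, 0.97, 0.95 and 0.74; three more have small correlations that
do not reach significance. Because a positive affine map leaves Pearson's
$r$ untouched, the marker channel can be placed on a realistic
molecules/ml scale without disturbing the construction. The table
validates the concordance machinery against values known by construction;
it contains no real patient data.

## Numerical and design choices

* Thresholds are parameters with the protocol values as defaults (QC
  $p \le 0.05$; PBL beta $\ge 0.2$; top 15; ALU Ct $< 21$; PBL screen Ct
  $> 35$; plasma PMR $< 5$; tumor PMR $> 20$; 15 hits/96 wells; 2000
  bootstrap resamples; $\alpha = 0.05$), so none is a buried constant.
* Strictness at each boundary is pinned by tests: QC and the PBL beta
  rule are inclusive of their boundary on the failing side; ALU QC,
  counter-screen, plasma and tumor cutoffs are strict.
* All generators accept a seed and restore the caller's RNG state;
  identical seeds give bit-identical outputs, including across the
  end-to-end pipeline's files.
* Tumors are pooled across histological subtypes during ranking — the
  design maximizes sensitivity across subtypes; stratified ranking is
  deliberately not a default.
* Whether multiple plates per sample should be pooled before or after
  correction is not specified by the source; corrections are per plate,
  then summed, because well-dilution is a per-plate event.

## Problem sizes

The test suite runs the full cascade on cohorts of 50–2,000 probes (the
brute-force equivalence checks use ≤ 50 so exhaustive scanning stays
exact), estimator-recovery simulations on 300–500 replicate plates,
bootstrap comparisons at 500–2,000 resamples, and 20–100 seed sweeps for
the distributional invariants — sizes chosen so the whole suite gives
tight Monte-Carlo bounds while staying quick on a laptop. The
`scripts/acceptance.R` entry point recomputes the headline quantities on
a 5,000-probe cohort with 40 planted markers and 500-plate recovery runs.

## Known limitations

* The funnel counts of any real cohort depend on the array annotation
  version; the package reports per-stage counts and makes no claim of
  reproducing a specific published funnel.
* The MPN estimator is slightly biased upward at extreme occupancy
  (Jensen's inequality); tests bound it within Monte-Carlo error up to
  $k/N = 0.8$, and $k = N$ is refused.
* Percentile bootstrap CIs undercover at these small group sizes (16 vs
  8); the implementation is compared against an independent bootstrap
  oracle rather than against nominal coverage.
* The concordance test assumes independent draws within a patient series;
  serial autocorrelation beyond the shared burden trend is not modeled.
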