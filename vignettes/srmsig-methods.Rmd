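---
title: "srmsig: methods, modelling choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{srmsig: methods, modelling choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Targeted plasma proteomics panels (selected reaction monitoring, SRM)
quantify a few dozen candidate proteins — here, N-glycosite peptides
enriched from plasma — across hundreds of case–control subjects, one
LC-MS run per subject. The statistical task is to turn raw peak areas
into a small multivariate protein signature that separates disease from
control subjects and to evaluate that signature honestly on an
independent cohort. srmsig implements that pipeline end to end and, since
clinical raw data are not redistributable, ships a synthetic cohort
generator with planted ground truth so every stage can be scored.

## Intensity model and normalization

All intensities are log2 peak areas. The working assumption throughout is
additivity on the log2 scale:

```
y(subject s, protein p, peptide j) =
    baseline_p + peptide_pj + subject_sp + group_sp + batch_b(s) + run_r(s) + e
```

Two nuisance terms are removed by two pure shift operations, in this
fixed order:

1. **Reference normalization.** Every targeted peptide (including the
   peptides of the spiked standard proteins) has a heavy stable-isotope
   counterpart spiked just before acquisition. Heavies therefore carry
   acquisition drift (`run`) but no biology and no preparation bias. For
   each protein, the per-run shift `median(all heavy of p) − median(heavy
   of p in run r)` is applied to both channels of that protein in that
   run; afterwards each protein's per-run heavy median is constant across
   runs, and light-minus-heavy differences within a run are untouched.
2. **Standard-protein normalization.** Two bovine glycoproteins spiked at
   equal amounts into every sample *before* preparation carry the batch
   bias (`batch`) that heavies cannot see. Each standard is summarized to
   one value per run (see below) and screened for stability: Pearson
   correlation of its summaries with the per-run medians of the
   endogenous light intensities, stable iff r > 0.6 (strict; the cutoff
   and the median-vs-sum basis are parameters, because the underlying
   method description does not pin down "total intensities"). A stable
   standard defines per-run shifts applied to all light intensities;
   afterwards its summaries are constant across runs, which also makes
   the operation idempotent. An unstable standard is refused — the
   pipeline then proceeds without stage 2, logged.

Both stages are shifts, so they can reorder nothing within a run.
Cross-cohort comparability is restored by a single constant that
equalizes the validation cohort's grand median (over observed cells) with
the training cohort's.

**Why heavies must not carry batch.** If the references also tracked
preparation bias, stage 1 would remove batch and stage 2 would have
nothing left to do; worse, standards would retain acquisition drift that
stage 2 would then re-inject into the endogenous signal. During
development this exact mistake produced measurable miscalibration of the
null distribution of the downstream t-tests (spurious "significant"
proteins on effect-free cohorts), which is why the generator spikes heavy
references for the standard peptides as well — as the real 90-plex did.

## Summarization and differential abundance

Protein abundance per subject is the additive two-way fixed-effects least
squares fit `y ~ peptide + subject` on observed cells, reporting
intercept + subject effect with sum-to-zero peptide effects; on balanced
complete data this is exactly the per-subject mean across peptides. The
original analysis used a linear mixed model; with one biological
replicate per subject and no technical replicates the mixed model
degenerates toward this fixed-effects fit, which we adopt deliberately
(documented simplification). The same model with runs as units summarizes
the standard proteins.

Group comparison is a per-protein pooled-variance two-sample t on the
subject-level summaries (df = n1 + n2 − 2), Benjamini–Hochberg adjusted
across tested proteins only (proteins with fewer than two observed values
in a group are skipped and leave the BH family). Fold changes are
reported on the original scale by the Delta method: FC = 2^log2FC,
SE = SE_log2 · ln 2 · 2^log2FC. Two significance presets exist: *plasma*
(adjusted p ≤ 0.05 and FC outside [1/1.1, 1.1]) used as the per-fold
candidate filter, and *tissue* (adjusted p < 0.05 and |log2FC| ≥ 1.5)
matching the discovery-phase convention. The "±1.1" cutoff is read on the
original FC scale and "±1.5" on the log2 scale — exactly as each is
conventionally printed — and both are parameters.

Where the method description was ambiguous about whether the per-fold
filter used raw or adjusted p (its two statements differ), the default is
the adjusted p (`use_adjusted = TRUE`), the more conservative and more
precisely specified variant; the raw-p variant is one flag away.

## Signature discovery

Missingness in SRM plasma data is strongly left-censored, so masked cells
are imputed per cohort with the protein's minimal observed relative
quantification — its empirical limit of detection. Before imputation,
proteins missing in strictly more than 40% of subjects are dropped.

Discovery is k-fold (default 10) stratified consensus cross-validation:
per fold, the plasma differential filter on the k−1 training folds
proposes candidates; bidirectional stepwise selection minimizes AIC
(−2ℓ + 2·params) starting from the intercept-only model (the original
description does not state the start point; empty-start is conservative
and `start = "full"` is available); the held-out fold is scored by AUC.
The consensus keeps proteins selected in at least `min_count` folds —
default 5 of 10, following the explicit "at least 5 of the 10" statement
over the conflicting "more than five times" phrasing elsewhere; both are
one parameter away (the 8-fold variant uses `min_count` 4 or 5
accordingly). The final model is refit on the full training cohort and
its probability threshold chosen to maximize training accuracy over the
midpoints of consecutive sorted unique probabilities plus 0/1 sentinels,
ties toward the smaller threshold. An empty consensus returns an explicit
intercept-only "no stable signature" model rather than an error.

Logistic fits use IRLS capped at 30 iterations; any |linear predictor|
above 30, or non-convergence, raises a separation flag, and flagged fits
are excluded from stepwise moves instead of silently winning with
infinite coefficients.

The exhaustive search enumerates every subset of size 1–5, validates each
with B (default 100) class-stratified out-of-bag bootstrap rounds — the
same pre-drawn resamples for every model, so rankings are paired — and
ranks models by median out-of-bag AUC; proteins in the models tying the
best median AUC are ranked by frequency. At a realistic pool of 70
proteins this is about 13.1 million models, so pools above 15 proteins
are refused unless explicitly allowed.

## Evaluation

AUC is the Mann–Whitney statistic (ties half credit), identical to the
trapezoidal area under the empirical ROC. Confidence intervals are
class-stratified percentile bootstraps (default B = 2,000); two
signatures evaluated on the same subjects are compared with a paired
bootstrap (two-sided p = doubled tail proportion of the ΔAUC
distribution, capped at 1). Classification is "predict case iff
probability ≥ threshold" — the boundary convention is not specified by
the source description and is documented and configurable. Subgroup
evaluation discriminates each CRC stratum (clinical stage; tumor diameter
[0, 3.5), [3.5, 6), [6, ∞) cm — the "3.4–6" occasionally printed for the
middle bin is treated as a typo for 3.5, not silently, namely here; CEA
strictly > 5 ng/ml) against the full shared control group. Decile
response curves rank subjects into near-equal bins (sizes differ by at
most one, larger bins first; loess overlay is presentational only), and
heatmap ordering uses Ward clustering (`ward.D2`, Euclidean) on the
imputed matrix.

## The synthetic world

The generator's defaults state the emulated study: training cohort
100 CRC / 34 benign / 66 healthy, validation 202 / 17 / 50 with stage
proportions 43/58/49/52; 70 candidate proteins with 1–3 peptides each;
baselines uniform over 20 log2 units (≈ 6 orders of magnitude of
dynamic range); five planted markers, four up and one down
(log2FC 1.0, 0.8, 0.6, 0.5, −0.7, i.e. |log2FC| ∈ [0.4, 1.0]); two
markers (the strongest up and the down marker) respond to tumor diameter
at ±0.15 log2/cm around the median diameter; CEA lognormal with
stage-dependent location (controls lowest) so the 5 ng/ml rule is
exercisable; CRC ages shifted +5 years.

Noise defaults are assumptions, stated once and exposed in the config:
between-subject SD 0.5, peptide response offsets SD 0.7, acquisition
drift SD 0.3 per run, preparation bias SD 0.5 per batch (4 batches;
preparation bias plausibly dominates drift in multi-plate studies),
measurement noise SD 0.2 — all log2 units. Censoring below a limit of
detection of 10 (log2) plus 2% missing-completely-at-random; markers are
planted among proteins with baseline ≥ LOD + 4, mirroring the fact that
validated panels come from the consistently quantified proteins.
Ground truth includes the generative (Bayes-optimal, equal-covariance
Gaussian) logistic coefficients, so fitted models can be benchmarked
against the best achievable classifier on the same draw.

What the generator does **not** emulate: chromatogram- or
transition-level interference, retention-time drift, peptide-specific
censoring mechanisms beyond a global LOD, correlated protein modules,
non-Gaussian biological variation, and cohort recruitment artifacts.
A green simulation test therefore establishes that the statistics recover
a correctly specified additive world at realistic sizes and noise — not
that they would survive every pathology of real plasma data. Notably,
with the per-run *median* stability basis the realized standard-protein
correlation hovers around the 0.6 cutoff (as the real fetuin did, barely
passing); cohorts whose batch realization is weak legitimately fail the
screen and skip stage 2.

## Numerical conventions

Medians of even-length sets use the midpoint; degenerate t comparisons
(zero pooled variance) return p = 1 for equal means and p = 0 otherwise;
undefined stability correlations (zero variance) report the standard as
unstable with a warning rather than guessing; all bootstrap and
cross-validation randomness is seed-determined, with fold assignment
keyed to sorted subject identifiers so row order cannot change a result;
report bundles are byte-identical across reruns of one configuration.

## Known limitations

Stepwise AIC selection inherits the instability of greedy subset search —
the consensus-over-folds construction is the mitigation, not a cure; no
regularized selection is offered by design. The pooled t-test assumes
equal group variances. Percentile bootstrap CIs are first-order accurate
only (no BCa). The exhaustive search above 15 proteins is a compute
decision left explicitly to the caller. Configuration files are JSON (no
YAML parser among the declared dependencies).
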