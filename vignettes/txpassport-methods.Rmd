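---
title: "Methods: the transcriptomic athlete biological passport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the transcriptomic athlete biological passport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txpassport)
```

## The problem

Microdoses of recombinant human erythropoietin (rHuEpo) stimulate red-cell
production strongly enough to matter in sport but weakly enough to slip
past the haematological module of the Athlete Biological Passport (ABP).
Whole-blood transcripts tied to erythropoiesis — `ALAS2`, `BCL2L1`,
`SLC4A1`, `TRIM58` and their peers — respond to stimulation with large,
long-lasting log2 fold-changes, which makes them candidate passport
markers. `txpassport` implements the full analysis chain such markers
need: panel normalisation, longitudinal differential expression, the
haematological stimulation index, and the adaptive Bayesian model that
converts population variance components into individual reference ranges.
Because no raw data from the original microdose trial is publicly
deposited, the package ships a synthetic-data module that emulates that
trial's design, so every stage runs, and is tested, end to end.

## The synthetic crossover trial

The generator reproduces the microdose study (MDS) layout: 14
endurance-trained subjects crossing over between an rHuEpo arm and a
placebo arm, sampled at 3 baseline visits (days −14, −7, 0), weekly
during 7 weeks of administration (days 3–45) and for 3 post weeks (days
52, 59, 66) — 13 timepoints, 364 scheduled samples, panel assays run in
duplicate.

Expression follows the hierarchical Gaussian model the passport analysis
itself assumes. For marker $g$ and subject $j$,

$$x_{gjt} = \mu_g + b_{gj} + \delta_g(t)\,[\text{arm}=\text{rHuEpo}] +
\varepsilon_{gjt},\qquad
b_{gj}\sim N(0,\sigma^2_{b,g}),\ \varepsilon_{gjt}\sim N(0,\sigma^2_{w,g}),$$

with $b_{gj}$ drawn once per subject and shared across both crossover
arms (the same individual serves in both). The defaults are the published
cohort values: per-marker means and within/between-subject variances for
the 41 analysable transcripts, and the per-timepoint doping log2
fold-changes $\delta_g(t)$ for the 11 transcripts whose trajectories were
printed (rising through administration, suppressed below baseline
post-withdrawal). Effect trajectories are step functions keyed by
timepoint label; timepoints without a printed value (D1, D6, D7 and all
baselines) carry $\delta = 0$. No carryover is modelled between arms, as
the arms are analysed independently.

Fluorescence is $\mathrm{MFI} = L\cdot 2^{x} + B$ with scale
$L = 5000$ and additive background $B = 30$ MFI; duplicates jitter the
mean multiplicatively with mean-one log-normal noise. Three of these
calibrations were genuinely open and are the package's own choices,
decided once:

* **Scale and limit of detection.** $L = 5000$, $B = 30$ and an LOD rule
  of adjusted MFI $> 50$ in at least 80% of samples place all 41
  published transcripts above the LOD — including the least abundant
  (`GYPE`, mean log2 −4.87) — while four synthetic low-abundance
  placeholder probes (`LOWTX1–4`, standing in for the unpublished
  below-LOD targets) fall under it, reproducing the study's 41-of-45
  outcome. The assay's true background magnitude and LOD rule were never
  published; only the outcome was.
* **Duplicate noise.** The generator's `cv_dup = 0.133`. The study
  reported a mean duplicate CV of 10.6%, computed as sd/mean over
  duplicate pairs; that statistic under-estimates the true CV by the
  Gaussian small-sample factor $\sqrt{2/\pi} \approx 0.80$ at $n = 2$,
  so a true CV of 0.133 yields a measured mean CV of ≈10.6%, matching
  the study's printed statistic rather than its estimand.
* **Reference probes** sit at log2 = 0 with small variances, so the
  normalised scale coincides with the published cohort means.

Whole sample blocks (subject × arm × timepoint) are dropped
independently with probability 21/364, the study's observed attrition;
dropping acts per block, not per replicate, because samples — not
wells — went missing. Haematology (HGB g/L, HCT %, RET %) follows
trajectory multipliers encoding the qualitative course: HGB/HCT rise
gradually and peak one week after the last injection; RET% jumps during
administration weeks 1–4 and is suppressed throughout the post phase —
the rebound the OFF-score catches. RET% takes log-normal noise so it
stays positive; HGB/HCT take additive Gaussian components. Every
generator function takes an explicit seed; there is no hidden global
state.

What the generator does **not** emulate: assay drift and plate effects,
non-Gaussian heavy tails, correlated markers (each probe is simulated
independently), iron status, exercise biology or altitude physiology
(the `ATS-runners` and `MDS-exercise` presets only re-label the sampling
grid). Tests passing on this generator therefore demonstrate the
*estimators* are correct under the model's own assumptions, not that
real blood behaves this way.

## Normalisation

Technical replicates are averaged on the raw MFI scale first; background
is subtracted with a positive floor (default 0.5 MFI) so log2 stays
defined; each sample's targets are divided by the geometric mean of its
five reference probes and log2 transformed. The replicate-averaging
order was unstated in the source methodology; averaging on the MFI scale
matches how the duplicate CV is defined and is pinned by a test.
Normalisation is invariant to per-sample scaling, which is the point of
the reference-gene construction.

## Differential expression

The within-subject estimator is a randomised-block contrast: each
subject's baseline mean (all three baseline visits by default;
`baseline_mode = "single"` uses the final one) is subtracted from their
value at every later timepoint, and the coefficient is the average over
subjects. The crossover comparison is the paired difference of
differences between arms. This closed-form estimator replaces a full
mixed-model fit deliberately: it matches the "compared to the averaged
baseline" design, is exactly testable against a brute-force oracle, and
keeps the residual structure simple.

Residual variances are moderated with the standard empirical-Bayes
scaled-inverse-$\chi^2$ prior, estimated by the method of moments on log
variances (including the trigamma-inverse solve); the posterior variance
is $\tilde s^2_g = (d_0 s_0^2 + d\,s^2_g)/(d_0 + d)$ and moderated t/F
statistics use $d_0 + d$ degrees of freedom. The machinery is authored
here because it is the pipeline's inferential core; it reproduces
`limma::squeezeVar` to 10 decimal places on dispersed inputs (checked in
the suite). One numerical tie-break departs from that reference: when
the log-variances show no excess dispersion the prior degrees of freedom
are infinite, and the prior scale is taken as the geometric mean of the
sample variances, so that identical input variances are a fixed point of
moderation rather than being inflated by the log-scale bias correction.

Significance uses Benjamini–Hochberg FDR < 0.05 together with a signed
fold-change threshold of 1.5, where the signed fold is
$\mathrm{sign}(L)\,2^{|L|}$ (a halving prints as −2). The selection
cascade mirrors the staged published analysis: S1 overall moderated F
significant; S2 ⊂ S1 significant one week after the last injection (P1);
S3 ⊂ S2 with |FC| ≥ 1.5 ten days after the first injection (D2); S4 ⊂ S3
consistently up at D2–D5 and down at P1–P3. The threshold is applied to
the fold magnitude. Note that two published trajectories (`DCAF12` at
D2, `TMOD1` at D5) sit within 0.03 log2 units of the 1.5-fold line, so
exact recovery of all 11 published responders is intrinsically
noise-sensitive at any cohort size; the cascade-exactness test plants a
clearly separated trajectory instead, while the generator's defaults
keep the published values.

## Haematology

The OFF-score is fixed at $\mathrm{OFF} = \mathrm{HGB}\,[\text{g/L}] -
60\sqrt{\mathrm{RET}\%}$, the ABP's OFF-hr definition; the package
standardises on g/L internally and converts (`HGB_gL`) at the file
boundary. Per-timepoint blood comparisons are paired t tests of each
subject's departure from their own baseline mean, Holm-adjusted across
timepoints. This is a declared substitution for the original
mixed-model/post-hoc analysis, whose exact specification is not
reproducible; it preserves the within-subject pairing and the stated
family-wise correction, and its size is verified by simulation.

## The adaptive passport model

Variance components come from one-way random-effects ANOVA on undoped
data with subject as the random factor:
$\hat\sigma^2_w = \mathrm{MS}_\text{within}$,
$\hat\sigma^2_b = (\mathrm{MS}_\text{between} -
\mathrm{MS}_\text{within})/n_0$ with the unbalanced-design effective
group size $n_0$; negative between-components are clipped to zero with a
warning. "Universal components" means one $(\sigma^2_w, \sigma^2_b)$
pair per marker shared by all subjects.

Reference ranges are the conjugate Normal–Normal update. After $n$ prior
observations with mean $\bar x$,

$$m_n = \frac{\mu/\sigma^2_b + n\bar x/\sigma^2_w}
{1/\sigma^2_b + n/\sigma^2_w},\qquad
\tau^2_n = \frac{1}{1/\sigma^2_b + n/\sigma^2_w},$$

and the next observation's limits are $m_n \pm z\sqrt{\tau^2_n +
\sigma^2_w}$ with $z = \Phi^{-1}(1-(1-\text{specificity})/2)$ — the
two-sided convention at the passport's 99% level (a one-sided mode
exists but is off by default). With no history this is the population
prior predictive; as history accumulates the ranges individualise and
tighten towards $z\sigma_w$. The interval's predictive mass is verified
against an importance-sampling oracle that never touches the conjugate
algebra.

Profiles are evaluated **sequentially**: observation $t$ is tested
against limits built from observations $1..t{-}1$, and every observation
enters the history afterwards regardless of atypicality. This mirrors
ABP practice, where each new test is judged against the passport built
so far; a batch mode (all observations against the prior predictive) is
available for comparison. A subject is flagged on ≥ 1 atypical value.
Sensitivity is the percentage of doped subjects flagged; specificity the
percentage of undoped subjects not flagged. Leave-one-out
cross-validation is applied exactly where overfitting threatens: each
undoped subject is evaluated with components estimated from the *other*
undoped subjects, while doped subjects use components from the full
undoped set (they never contribute to it). Reported
sensitivity/specificity round to the nearest integer percent, matching
the convention of the published summary (13/14 → 93).

The ROC score is a documented interpretation rather than a verbatim
reconstruction: the published description ("percentiles at which ...
sequences were falling in the distribution of sequences") is ambiguous
between per-observation and per-profile readings. The package scores
each observation by its two-sided extremeness $|2F(x)-1|$ under the
sequential posterior-predictive CDF and takes the profile maximum; the
AUC is then Mann–Whitney with ties counted half. This choice is
monotone, bounded in $[0,1]$ and consistent with the flagging rule
(which is also max-driven), but other constructions would give somewhat
different areas — plausibly why a few low-signal published transcripts
show ROC areas below 0.5.

## Numerical choices and degenerate inputs

* Background subtraction floors at 0.5 MFI (configurable); the source
  floor was unstated.
* `estimate_components` errors on a single subject and on designs with
  no within-subject replication; all-constant data returns zero
  variances, which is informative, not an error.
* `predictive_limits` with $\sigma^2_b = 0$ ignores history (no
  individualisation is possible); both variances zero with a history
  inconsistent with $\mu$ is a degenerate-model error.
* An empty doped set reports sensitivity as `NA`, an explicit sentinel —
  never 0.
* BH/Holm go through `stats::p.adjust`; ties in ranking follow its
  stable ordering.
* All seeds are explicit arguments (`withr::with_seed`), so identical
  seeds give byte-identical pipeline outputs; this is asserted on whole
  output files.

## Scale of the shipped verification

The test suite's simulation sizes are the package's chosen compromise
between statistical resolution and a short default run: 20 study-scale
(14 × 2 × 13) null pipelines for the "final cascade stage empty under
the null" property; 600–2000 subjects for coverage checks of the 95% and
99% ranges; $10^6$-draw importance-sampling oracles for predictive
limits; 8 × 200-subject cohorts for variance-component recovery (the
between-component's sampling error at one 200 × 13 cohort is itself
≈10%, so the 10% recovery bound is tested on the mean); 300 replicates
for the haematology family-wise error simulation. The acceptance script
re-derives the headline coverage number at 2000 × 13 with the
cohort-average components ($\sigma^2_w = 0.13$, $\sigma^2_b = 0.21$).

## Known limitations

Markers are modelled and screened one at a time; no multivariate
combination, no heteroscedastic or non-Normal marker models, no Bayesian
network across the haematological and transcriptomic modules. The
published per-marker sensitivities/specificities of the original cohort
are not reproducible from scratch — they depend on raw data that was
never deposited — so the packaged summary of that cohort is a fixture
used to test aggregation code, while all other numbers in the test suite
are computed from synthetic data generated under stated assumptions.
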