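# txpassport

Whole-blood transcriptional markers of erythropoiesis respond to
recombinant human erythropoietin (rHuEpo) with large, long-lasting
expression changes — longer-lasting than the haemoglobin and reticulocyte
shifts the Athlete Biological Passport (ABP) currently monitors, which is
what makes them attractive for catching *microdose* blood doping.
`txpassport` is an R package for anti-doping and transcriptomics
researchers that implements the complete analysis chain for such markers:

* **Panel normalisation** — bead-panel MFI measurements are
  replicate-averaged, background-subtracted and log2-normalised to the
  geometric mean of five reference genes (`ACTB`, `ACTR10`, `MRFAP1`,
  `PPIB`, `RAB11A`), with a limit-of-detection marker filter.
* **Longitudinal differential expression** — within-subject
  baseline-corrected contrasts, empirical-Bayes variance moderation
  (moderated t/F), Benjamini–Hochberg FDR with a 1.5 fold-change
  threshold, and the staged selection cascade that isolates markers up
  during administration and suppressed post-withdrawal.
* **Haematology** — the ABP stimulation index
  `OFF = HGB[g/L] − 60·√RET%`, plus Holm-adjusted paired timepoint
  comparisons.
* **The adaptive passport model** — per-marker within/between-subject
  variance components from undoped data (random-effects ANOVA), conjugate
  Normal–Normal individual reference ranges at 99% specificity, sequential
  atypical-value flagging, leave-one-out sensitivity/specificity and
  Mann–Whitney ROC areas.
* **A synthetic-study generator** — emulates the randomised
  placebo-controlled crossover microdose trial (14 subjects × 2 arms × 13
  weekly timepoints; 45 target + 5 reference probes, duplicates, realistic
  attrition), so the whole pipeline runs with no external data.

The core statistical object is the adaptive reference range: for a marker
with population mean μ and variance components (σ²_b, σ²_w), a subject
with *n* prior observations of mean x̄ gets the posterior

    m_n  = (μ/σ²_b + n·x̄/σ²_w) / (1/σ²_b + n/σ²_w)
    τ²_n = 1 / (1/σ²_b + n/σ²_w)

and the next observation is atypical if it falls outside
`m_n ± z·√(τ²_n + σ²_w)`, `z = Φ⁻¹(1 − (1 − 0.99)/2)`. A subject is
flagged on at least one atypical value in their 13-point profile.

## Worked example

```r
library(txpassport)

cfg <- pipeline_config(seed = 1, out_dir = "readme_run")
res <- run_pipeline(cfg)
#> [simulate] 338 of 364 scheduled sample blocks retained (33800 records)
#> [normalise] 41 markers kept, 4 below LOD (LOWTX1, LOWTX2, LOWTX3, LOWTX4); mean assay CV 10.6%
#> [de] selection cascade: S1=12 S2=11 S3=10 S4=7 markers
#> [passport] 43 markers screened; median sensitivity 21%
#> [report] wrote 8 documents to readme_run
```

The log already tells a story: of 364 scheduled samples 338 survive the
simulated attrition; the four synthetic low-abundance probes drop below
the limit of detection leaving 41 analysable transcripts; the duplicate CV
averages 10.6%; and at this 14-subject scale the selection cascade ends
with 7 of the 11 planted responder transcripts (small-cohort power, not a
bug — at 120 subjects the suite shows the cascade recovers planted
responders exactly).

```r
subset(res$passport, marker %in% c("HGB", "OFF", "ALAS2", "BCL2L1", "TRIM58"))
#>  marker        kind   mean sigma2_within sigma2_between sensitivity specificity roc_area
#>     HGB haematology 149.29        28.603         24.112          50          71     0.72
#>     OFF haematology  91.31        32.680         54.196         100          93     1.00
#>   ALAS2  transcript   2.97         0.225          0.291          93          71     0.95
#>  BCL2L1  transcript   1.33         0.175          0.192          79          86     0.90
#>  TRIM58  transcript   2.16         0.181          0.134          79          79     0.93
```

Each row is one marker pushed through the adaptive model: the variance
components estimated from the placebo arm (compare `BCL2L1`'s 0.175/0.192
with its generator truth 0.159/0.202), then sensitivity (% of rHuEpo-arm
subjects flagged), specificity (% of placebo-arm subjects not flagged) and
the ROC area from profile extremeness scores. Responder transcripts like
`ALAS2` combine high sensitivity with a ROC area near 1; the OFF-score —
built to catch the post-withdrawal reticulocyte rebound — separates the
arms completely in this run.

Individual reference ranges are available directly:

```r
comps <- marker_components(mu = 1.33, sigma2_within = 0.159, sigma2_between = 0.202)
predictive_limits(comps, history = c(1.1, 1.5, 1.2), specificity_level = 0.99)
#> lower upper
#> 0.125 2.435
```

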