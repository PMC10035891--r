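# phasemeta

Dynamic functional-connectivity analysis of parcellated brain signals
through instantaneous phase-locking, for researchers studying how
large-scale coordination — not just where regions connect, but how
connectivity reorganizes in time — differs between clinical groups such as
people with schizophrenia and controls.

## What it computes

For band-limited (0.01–0.08 Hz) region×time signals with Hilbert phases
θ(n,t), the pipeline tracks the instantaneous phase-locking matrix

    iPL(n,p,t) = cos(θ(n,t) − θ(p,t))          (+1 in-phase, −1 antiphase)

and its per-timepoint leading eigenvector V₁(t) (LEiDA). Recurrent
phase-locking modes ψ₁…ψₖ come from spherical k-means on V₁(t) with cosine
silhouette guiding k; each mode's minority-sign pole defines a community
of oscillators. Per community ψ the package computes two metastability
proxies

    META_ψ = sd_t R_ψ(t),   R_ψ(t) = |⟨e^{iθ(m,t)}⟩|, m ∈ ψ
    VAR_ψ  = mean over pairs (n,p) ∈ ψ of var_t iPL(n,p,t)

plus chimerality CHI(t) = var_ψ R_ψ(t), magnetization M(t) (antiphase /
in-phase region ratio of V₁), global integration GINT (threshold-integral
of the largest-component fraction of the mean iPL graph), functional
segregation FSEG (Louvain–Newman modularity Q), and the metastability
index K = FSEG / GINT. VAR is the headline metric: being built on signed
phase-locking it registers antiphase reorganization that the Kuramoto
order parameter folds away.

Downstream layers implement the accompanying statistics (ICC(1,1) run
reliability, aligned-rank-transform 2×R mixed ANOVA with a staged
flowchart of Friedman/Wilcoxon follow-ups, permutation Welch t-tests with
the add-one estimator, Bonferroni correction, assumption checks) and a
deliberately austere single-feature Gaussian naive-Bayes classifier with
class balancing, repeated stratified k-fold cross-validation and
out-of-sample transfer.

Because the clinical datasets this methodology targets are
access-restricted, the package ships a generalized Haken–Kelso–Bunz
oscillator simulator (`sim_config()`, `generate_cohorts()`): phase
oscillators with first- and second-order coupling A sin Δθ + 2B sin 2Δθ
(B = bA; Kuramoto when b = 0), community-structured coupling templates
switching on an exponential dwell schedule, and a case cohort with a
down-scaled "subcortical" coupling block. Every downstream stage is
validated end-to-end against this stated world.

## Worked example

```r
library(phasemeta)

# simulate a two-cohort dataset: 15 subjects per group, 30 regions,
# 150 frames at TR 2 s; the case cohort's first 10 regions lose coupling
cfg <- sim_config(n_regions = 30, n_subjects_per_group = 15,
                  n_frames = 150, tr = 2,
                  coupling_templates = default_coupling_templates(30, 3),
                  case_block = 1:10, case_coupling_scale = 0.2, seed = 7)
cohort <- generate_cohorts(cfg)
cohort
#> cohort_dataset: 30 subject-runs, 30 regions, 150 frames @ TR 2 s
#>   groups: case=15, control=15

# band-pass + Hilbert phases, then modes from the control dataset only
phases <- lapply(cohort$subjects, function(s)
  analytic_signal(bandpass_fft(s$series, 0.01, 0.08))$phase)
grp <- vapply(cohort$subjects, `[[`, "", "group")
eigs <- do.call(cbind, lapply(which(grp == "control"),
                              function(i) eigen_series(phases[[i]])$vectors))
modes <- extract_modes(eigs, k_range = 2:4, reps = 30, max_iter = 100, seed = 1)
select_k_silhouette(modes)$table
#>   k silhouette
#> 2 2  0.1046533
#> 3 3  0.1066865
#> 4 4  0.1078845

# block-community VAR per subject: group test and classification
block_var <- vapply(phases, var_metric, 0, community = 1:10)
pt <- perm_welch_t(block_var[grp == "control"], block_var[grp == "case"],
                   n_perm = 9999, seed = 1)
sprintf("perm Welch t = %.2f, p = %.4f", pt$t, pt$p)
#> "perm Welch t = 3.26, p = 0.0025"

repeated_kfold(block_var, grp, k = 10, reps = 20, seed = 1)
#> perf_report: AUC 0.881 | bal.acc 0.918 | sens 0.970 | spec 0.867 | p 4.34e-07
```

Reading the numbers: the cases' weakened block drifts persistently while
control blocks alternate between locked and drifting epochs, so control
block-VAR is higher; the permutation Welch test detects that group
difference (p ≈ 0.0025), and the single-feature naive-Bayes classifier
separates the cohorts well above chance (AUC 0.88, binomial p ≈ 4e-7).
The low silhouettes (~0.1) are expected at the default second-order
coupling b = 0.5, where antiphase bistability blurs mode boundaries — see
the methods vignette (`vignettes/phasemeta-methods.Rmd`).

A one-shot orchestration of the whole chain (simulate → preprocess →
modes → metrics → statistics → classification, with artifacts and config
snapshots written to disk) is available as `run_pipeline()`, or from the
shell:

```sh
Rscript -e 'phasemeta::pm_cli()' pipeline --seed 1 --out out/ \
    --regions 30 --subjects 15 --frames 150 --k 3 --kmeans-reps 50
```

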