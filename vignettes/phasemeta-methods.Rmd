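---
title: "Phase-locking metastability: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-locking metastability: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasemeta)
```

## The problem

Resting-state fMRI signals of people with schizophrenia differ from
controls less in *where* regions are connected than in *how* connectivity
reorganizes over time. `phasemeta` implements a dynamic
functional-connectivity pipeline built on instantaneous phase-locking:
band-limited signals are turned into analytic phases, the phase-locking
pattern at every timepoint is summarized by the leading eigenvector of the
phase-locking matrix (LEiDA), recurrent patterns ("modes") are extracted by
clustering, and metastability is quantified two ways — the conventional
standard deviation of the Kuramoto order parameter (META) and the mean
temporal variance of pairwise instantaneous phase-locking (VAR). VAR is the
package's centerpiece: because phase-locking is signed, it registers
antiphase as well as in-phase reorganization, which the Kuramoto order
parameter cannot distinguish.

## The model chain

**Phase-locking.** For regions $n, p$ with Hilbert phases
$\theta(n,t)$, instantaneous phase-locking is
$\mathrm{iPL}(n,p,t) = \cos(\theta(n,t) - \theta(p,t))$: $+1$ in-phase,
$-1$ antiphase, $0$ at quadrature.

**LEiDA.** The $N \times N$ matrix $\mathrm{iPL}(t)$ equals
$cc^\top + ss^\top$ with $c = \cos\theta(t)$, $s = \sin\theta(t)$; it is
rank 2 and positive semi-definite, so `eigen_series()` solves a
$2 \times 2$ Gram problem per timepoint instead of a full decomposition
(verified against `eigen()` to $10^{-9}$). The leading eigenvector
$V_1(t)$ is put under a *majority-non-negative* sign convention (exact
ties broken by the sign of region 1), and the minority (negative) pole is
the pattern's antiphase community. The ratio of antiphase to in-phase
regions is the magnetization $M(t)$, a criticality proxy.

**Modes.** Leading eigenvectors of one dataset (never concatenated across
cohorts — per-dataset clustering avoids leakage) are clustered by
spherical k-means under cosine distance, best of `reps` restarts,
candidate $k = 2\dots10$, with mean cosine silhouette guiding the choice
of $k$ (a fixed `k_select = 5` is the conventional default for
comparability with the literature). Modes are reported with the global
(all-non-negative) mode first, then by descending occupancy.

**Metastability.** Per community $\psi$ (the antiphase pole of each mode;
the full region set for the global mode):

* META $= \mathrm{sd}_t\, R_\psi(t)$ where
  $R_\psi(t) = |\langle e^{i\theta(m,t)}\rangle|_{m\in\psi}$;
* VAR $=$ mean over distinct pairs in $\psi$ of the temporal variance of
  $\mathrm{iPL}(n,p,t)$;
* CHI$(t) = \mathrm{var}_\psi R_\psi(t)$ (population variance across
  communities), an instantaneous chimerality index.

Global META / global VAR are unweighted means across communities.
Temporal variances use the sample ($T-1$) denominator; the
cross-community CHI uses the population denominator. Both choices are
documented here because the definitions do not fix them.

**Integration, segregation.** From the time-averaged iPL matrix:
global integration GINT is the trapezoidal integral over binarization
thresholds $\tau \in \{0, 0.01, \dots, 1\}$ of the largest-connected-
component fraction (edges where the off-diagonal entry $\ge \tau$;
negative entries therefore drop out beyond $\tau = 0$); functional
segregation FSEG is the Newman modularity $Q$ of the best of 20 seeded
Louvain partitions of the same matrix with negative weights removed; the
metastability index is $K = \mathrm{FSEG}/\mathrm{GINT}$. GINT normalizes
the component size by $N$, so GINT $\in [0,1]$ and a graph with no
positive connectivity scores exactly $1/N$.

## The synthetic cohort generator

There is no public generative model for the restricted clinical datasets
the method was designed around, so `generate_cohorts()` states a world
with the features the analysis assumes and nothing more:

* $N$ phase oscillators with natural frequencies uniform in the
  0.01–0.08 Hz resting-state band, integrated by Euler–Maruyama with
  sub-steps $\le$ TR/10, observed as $\cos\theta$ plus white noise
  (the simplest signal whose Hilbert phase is the latent phase);
* generalized Haken–Kelso–Bunz pairwise coupling
  $A_{ij}\sin(\theta_i-\theta_j) + 2B_{ij}\sin 2(\theta_i-\theta_j)$ with
  $B = b\,A$ ($b = 0.5$ by default, i.e. $A = 2B$); with $b = 0$ the
  drift reduces exactly to the Kuramoto model (unit-tested);
* community-structured coupling templates switching along an
  exponential-dwell schedule (mean 20 s — state dwell times of tens of
  seconds are the norm in dynamic FC), producing recurrent modes;
* a "case" cohort whose designated subcortical block has its coupling
  rows/columns scaled down, mirroring a basal-ganglia
  dysconnectivity finding.

Numerical choices worth knowing:

* **Coupling normalization.** Template strengths are per-capita
  (Kuramoto $K/N$ convention): `within = 2` rad/s is the *total* pull a
  region feels from its block. Absolute per-pair strengths would put the
  effective coupling above the Euler stability limit for realistic block
  sizes, and a background above $\approx 0.26$ rad/s (the critical
  coupling for the band's frequency spread) would lock the whole network;
  the default background is a subcritical 0.1 rad/s total.
* **Antiphase bistability.** For $B > A/4$ ($b > 0.25$) the pair
  potential $V(\phi) = -A\cos\phi - B\cos 2\phi$ has a *stable* antiphase
  valley: each dwell segment then settles at random into in-phase or
  antiphase alignment. That is precisely the regime in which VAR carries
  information that META misses — but it also means the active template is
  not identifiable from $V_1(t)$ alone, so the planted-schedule recovery
  fixture runs at $b = 0.2$ (second-order coupling active, antiphase
  unstable), where mode recovery is clean (label agreement
  $\approx 0.95$). Asking for $>85\%$ schedule recovery at $b = 0.5$ is
  not a property any method can have.
* **Planted effect direction.** Scaling a block's coupling down makes the
  case block drift persistently, while control blocks alternate between
  locked (iPL $\approx 1$) and drifting epochs — a variance-rich mixture.
  The planted group difference in block VAR is therefore
  control $>$ case under this generator; tests assert that direction.
* The generator emulates band-limited oscillations, community-structured
  coupling, mode switching and cohort coupling differences. It does
  **not** emulate hemodynamics, measurement drift, head motion,
  anatomical connectomes, or subject-level heterogeneity beyond random
  frequencies and schedules — a green recovery test establishes that the
  pipeline detects the statistical structure it assumes, not that it
  would survive every artifact of real fMRI.

## Signal preparation

Band-passing is an ideal (brick-wall) DFT filter on demeaned rows with
the closed band $[f_{lo}, f_{hi}]$ kept; it is linear, idempotent, and
passband-power preserving, and errors out when the band collides with
Nyquist or no FFT bin falls inside it. No tapering or edge trimming is
applied by default. The Hilbert phase of an all-zero region is defined as
0 with amplitude 0. The Bedrosian/Carson report quantifies narrowband
validity per region as the fraction of amplitude-envelope spectral power
at or above $f_{lo}$, with a 0.05 tolerance — the empirical rule has no
standard numeric criterion, so the threshold is a package convention
stated in the report attributes, alongside the Carson bandwidth
$2(\Delta f_{peak} + f_{mod})$.

In validation tests, phase recovery is scored by circular concordance
$|\langle e^{i(\hat\theta-\theta)}\rangle|$ rather than the Fisher–Lee
circular correlation, which is degenerate for phases that sweep the
circle uniformly (as narrowband carriers do).

## Statistics

* **ICC(1,1)**: one-way random-effects single-rater agreement
  $(\mathrm{BMS}-\mathrm{WMS})/(\mathrm{BMS}+(k-1)\mathrm{WMS})$, with
  Landis–Koch band labels.
* **ART ANOVA**: for each effect of the 2 × R group-by-run design, the
  response is aligned (all other effects' cell-mean estimates removed),
  mid-ranked, and a split-plot `aov` on the ranks (subject as the error
  stratum for the between-subject effect; the within stratum for run and
  the interaction) supplies F, df and p for that effect only. The
  alignment diagnostic — every stripped effect's marginal means constant —
  is computed on each call and unit-tested at $10^{-9}$. Degrees of
  freedom follow this error-stratum derivation; printed df in the
  motivating literature are not reproducible from their description.
  Type-I error per effect is calibrated to $[0.035, 0.065]$ at
  $\alpha = 0.05$ over 1000 null simulations in the acceptance suite.
* **Wilcoxon** tests report a tie-corrected continuity-corrected Z, an
  exact p for $n \le 25$ without ties, and effect size
  $r = |Z|/\sqrt{N}$ ($N$: total observations for rank-sum, non-zero
  pairs for signed-rank) — the effect-size formula itself is a
  convention, flagged in reports.
* **Permutation Welch t-test**: Monte Carlo relabelings with the add-one
  estimator $p = (1 + \#\{|t^*| \ge |t_{obs}|\})/(n_{perm}+1)$, so
  $p \ge 1/(n_{perm}+1) > 0$.
* **Flowchart**: ART first; a significant interaction routes to
  per-group Friedman tests, paired Wilcoxon run drivers and per-run
  independent group contrasts; otherwise main-effect paths (Friedman +
  paired Wilcoxon for run; independent Wilcoxon on subject means for
  group). Family-wise Bonferroni throughout. Group contrasts are
  *retained* only when their effect size exceeds the largest run-driver
  effect size, so run (session) effects cannot masquerade as group
  differences. Single-run designs degrade to the independent contrast.

## Classification

A single-feature Gaussian naive Bayes (closed form, case = positive
class) with class balancing (down-sampling by default, 53 per class for
cross-dataset transfer), stratified repeated k-fold cross-validation
(k = 10, 20 repetitions; per-repetition pooled held-out metrics averaged
across repetitions), rank-based AUC, and a binomial upper-tail p for the
correct count against chance 0.5. No preprocessing beyond balancing and
no hyperparameters, matching the protocol's deliberate austerity. Note
that refitting the Gaussian on a monotone-transformed feature is *not*
rank-preserving in general; the monotone-invariance property holds for
the rank AUC of the feature itself (`rank_auc()`), and is tested there.

## Known limitations

* Half-switch label smoothing is a named technique without a published
  formula; the hysteresis rule implemented here (keep the previous label
  when the top-two centroid distances differ by less than `delta`) is a
  stand-in, off by default, and guaranteed never to increase the number
  of label switches.
* "Regional contribution" can mean the eigenvector element (default) or
  the mean iPL row; both are exposed.
* VAR averages pairwise temporal variances; a per-region row-variance
  variant is exposed as `by = "region"`.
* The acceptance-grade numbers of the motivating clinical study (effect
  sizes, AUCs on HCPEP/Cobre) derive from restricted data and are out of
  scope; the synthetic world demonstrates recoverability, calibration and
  determinism, not clinical performance.
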