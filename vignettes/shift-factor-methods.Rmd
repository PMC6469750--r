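---
title: "Shift-factor correction of ELISA batch effects: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shift-factor correction of ELISA batch effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elisashift)
```

## The problem

Research-use ELISA kits are not held to diagnostic-grade lot standardization.
In a long-running study, a new kit lot can arrive with a standard curve that
is systematically displaced from earlier lots — typically because the
concentration assigned to the kit's standards differs from the previous
lot's by some fold factor — while the optical-density (OD) readings of a
stable control sample barely change. Concentrations read off each plate's
own curve then drift lot by lot, and months of sample data stop being
comparable. `elisashift` treats this lot-to-lot variability as a fixed
batch effect on the calibration curve and removes it, putting every plate's
concentrations on a single reference scale.

## The model

Each standard curve is a four- or five-parameter logistic (4PL/5PL) in
natural-log concentration $x$:

$$Y = a + \frac{d - a}{\left(1 + e^{(xmid - x)/scal}\right)^{g}},$$

with lower/upper asymptotes $a, d$ (OD), midpoint $xmid$ (log pg/mL),
inverse slope $scal$ at the inflexion, and asymmetry $g > 0$; $g = 1$ gives
the 4PL. The equivalent non-log ("plate reader") form uses $C = e^{xmid}$
and $B = -1/scal$ (`to_exp_form()`). Plate-reader software sometimes labels
the asymptotes of this form in the opposite order; the package always
normalizes to the reading in which `a` is the low-concentration asymptote,
so an increasing sandwich-ELISA curve has `a < d`, `scal > 0`.

**Batch effect.** If a batch's standards are mislabelled by a common fold
factor $N$ — the labelled concentration is $N$ times the reference-scale
one — then on the log axis every nominal $x$ is displaced by $S = \ln N$.
All batches share $(a, d, scal, g)$ and differ only in the midpoint:

$$Y_{ijk} = a + \frac{d - a}{\left(1 + e^{(xmid + S_i - x_{ij})/scal}\right)^{g}} + \varepsilon_{ijk},$$

with batch $i$, standard level $j$, replicate well $k$. The reference
batch, whose labels are treated as accurate, is pinned at $S = 0$ for
identifiability. Within a batch, curves differ only by measurement error;
between batches, by their $S_i$.

**Sign convention.** With this parameterization, relabelling a batch's
standard concentrations by a factor $N$ moves its estimated shift by
exactly $+\ln N$; a positive $S$ means the batch's standards are weaker
than their labels claim (scale equivariance is enforced by a test). Users
comparing against other software should check the sign convention rather
than assume it.

**Correction.** A sample's OD is first inverted through its own batch's
shifted curve to give the raw log concentration $\hat x$, and then

$$\hat x_{\text{adj}} = \hat x - S_i$$

places it on the reference scale. In the noiseless limit this is identical
to reading the OD off the reference curve directly, but the two-step form
mirrors standard laboratory practice (each plate is quantified with its own
curve, the correction is applied afterwards) and allows $S$ to be applied
retrospectively to months of already-quantified plates.

## Estimation

Two modes, both exposed by `fit_shift_model()`:

* **`fixed_reference`** (default, the operational workflow): the reference
  curve is one pooled nonlinear least-squares fit over *all* standard wells
  of the designated reference batch's plates — individual wells, never
  replicate means, so every measurement contributes a residual. Each other
  batch's $S$ is then a one-dimensional least-squares fit with all curve
  parameters frozen. Pooling (rather than fitting each curve and averaging
  parameters) was chosen because the model's error term lives at the level
  of single wells.
* **`joint`**: all shared parameters and every $S_i$ are estimated
  simultaneously. Statistically cleaner, but it lets noisy non-reference
  batches influence the curve shape; the fixed-reference mode reproduces
  the workflow in which the reference is a frozen laboratory artifact.
  The two agree to $10^{-6}$ on noiseless data (tested).

Numerics: Levenberg–Marquardt trust-region least squares
(`minpack.lm::nls.lm`), cost tolerance $10^{-10}$, at most 500 iterations.
Starting values come from a self-start heuristic (asymptotes padded 5%
beyond the observed OD range, midpoint by interpolation at half-height,
slope from the central segment, $g = 1$); on non-convergence, up to 10
restarts perturb the start log-normally (factor 1.2) under a fixed internal
seed, so fits are deterministic. A gradient-zero stationary point on
perfect data is accepted as convergence. $g$ is estimated on the log scale
within $[0.1, 10]$ — unbounded asymmetry is not identifiable from 8-point
curves. The 1-D shift search first scans a coarse grid over $[-6, 6]$
(±400-fold mislabelling) before polishing, so a distant optimum cannot be
missed. Standard errors for $S$ use the linearized curvature at the
optimum, $se = \sqrt{\hat\sigma^2 / \sum_k (\partial\mu_k/\partial S)^2}$;
in 500-replicate simulations at OD noise sd 0.02, $\hat S \pm 2\,se$ covers
the truth in well over 90% of draws (tested).

Degenerate inputs fail loudly rather than silently: fewer than 4 (4PL) or
5 (5PL) distinct standard levels, all-equal ODs, non-finite ODs, and
batches whose ODs all sit outside the reference asymptotes are classed
errors, never clamped estimates. Zero-concentration/blank wells are carried
through I/O but excluded from every fit (their log concentration is
undefined); blank subtraction is deliberately not performed.

## Quantification and flags

Replicates are aggregated as mean OD with the sample-sd CV (a single well
reports CV 0). Replicate CV above 15% — the conventional plate-acceptance
gate — flags `high_cv` but the value is still reported: acceptance is a
review decision, not automated censoring. ODs at or beyond the asymptotes
cannot be inverted and are censored with `below_range`/`above_range`.
Adjusted concentrations outside the batch's standard range (LLOQ/ULOQ = its
lowest/highest standard) are flagged `below_lloq`/`above_uloq` but
retained. Concentrations are reported in pg/mL; logs are carried
internally.

## Quality control

`qc_report()` assembles the longitudinal monitoring quantities: per-batch
per-plate $S$ summaries (mean, min, max, N, CV of $S$), per-control OD and
raw-versus-adjusted concentration summaries, and flagged curves.
Inter-assay CVs are reported as integer percent, rounded half-up (12.5%
prints as 13%); fold ratios of an $S$ against its group mean round to one
decimal; $S$ itself to four. Outlying curves are flagged by a
leave-one-out rule — curve $i$ is flagged when
$|S_i - \bar S_{-i}| > k \cdot sd(S_{-i})$, default $k = 3$ — a
reproducible stand-in for what is otherwise a by-inspection judgment; with
very few curves per lot (3–4) the leave-one-out sd is itself noisy, so
flags there are prompts for review, not verdicts.

## The synthetic testbed

`sim_spec()`/`simulate_plates()` generate plates with known truth so the
whole pipeline is testable without laboratory data. Default conditions:
reference curve $a = -0.01$, $d = 3.20$ OD, midpoint 1300 pg/mL, inverse
slope $1/1.3$, $g = 1$ (the scale of a real sandwich ELISA); five lots with
true shifts $(0, 0.07, 0.55, 0.65, 0.70)$ and $(28, 19, 8, 4, 9)$ plates;
eight two-fold standard levels from 8000 pg/mL in triplicate wells; one
spiked control at 500 pg/mL per plate; additive homoscedastic Gaussian OD
noise, sd 0.02 — chosen to put replicate CVs in the single-digit-percent
range typical of a well-run plate.

Generative semantics: standard wells of batch $i$ are drawn on the curve
with midpoint $xmid + S_i$ *against their nominal labels* (the labels are
what is wrong); control and unknown wells respond at their true
concentration on the reference curve, independent of batch — which is
exactly why their raw read-backs drift across shifted batches and their
adjusted values do not.

What the generator does **not** emulate: spatial plate effects (edge wells,
gradients), operator and day effects, heteroscedastic or proportional OD
noise, freeze–thaw drift of controls, and within-lot curve-shape changes.
Passing tests therefore demonstrate that the estimator recovers the model's
own truth at realistic noise — not that real kit lots obey the
common-shape, label-shift-only assumption; that assumption must be judged
per assay (stable control ODs alongside drifting concentrations is the
signature).

## Validation sizes and what is checked

The test suite closes the loop at the study's own scale: a single
experiment with the five-lot structure above (68 plates) must recover every
lot-mean $S$ within 0.05; 200 replicated small experiments (5 lots × 3
plates) must reduce the across-batch CV of the control's adjusted
concentrations relative to raw in ≥99% of replicates (observed: 100%, with
adjusted CVs near the 1–2% within-noise floor versus ~30% raw); scale
equivariance must hold to $10^{-6}$ for relabel factors 0.5, 2 and 10;
forward/inverse curve roundtrips to $10^{-9}$; noiseless fits recover
parameters to $10^{-6}$ relative. `scripts/acceptance.R` recomputes all of
these from scratch against the installed package.

## Known limitations

* The reference batch is a judgment call; the package pins whatever batch
  it is told. Choosing a reference with few or atypical curves propagates
  that choice into every adjusted value.
* A single $S$ per batch assumes the entire displacement is a common fold
  mislabelling. Shape changes between lots (different asymptotes or slope)
  are not corrected and will surface as inflated per-batch RSS.
* `se_S` is a linearization and ignores uncertainty in the reference curve
  itself (fixed-reference mode); with many reference curves this is small.
* Persistence stores the model, not the data; a reloaded model quantifies
  and gates but cannot re-plot its training wells.
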