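---
title: "Models and methods behind tastemix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tastemix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tastemix)
```

This vignette is the package's own account of the science it implements:
the data model, the statistical procedures, the network model, the
synthetic generator that stands in for recorded sessions, and the
numerical choices made where the design was genuinely open.

## The task and the data model

A session is a sequence of two-alternative-choice trials. On each trial
the animal samples a sucrose/NaCl mixture — parameterized by its
%Sucrose $s \in \{0, 25, 35, 45, 55, 65, 75, 100\}$ — at a central spout
(first central lick, $T$), waits through a delay, and licks one of two
lateral spouts (first lateral lick, $D$). A choice is *correct* when it
matches the predominant component ($s > 50 \Rightarrow$ sucrose side).
`taste_session` stores the trial table and long-format spike times on a
per-trial clock; $T$ and $D$ are stored per trial so that raw data stay
alignment-agnostic. Choices are encoded semantically (sucrose side vs
NaCl side) rather than left/right, which abstracts away taste-side
counterbalancing across subjects. Only completed trials (with a lateral
lick) are representable; trials without one are excluded upstream by
construction.

## Event warping

Firing dynamics are analyzed against both $T$ and $D$ at once on a warped
axis: 20 fixed 50 ms bins before $T$, 77 bins dividing the trial-specific
inter-event interval $[T, D)$ equally, and 20 fixed 50 ms bins after $D$
— 117 bins in total, spanning 1 s before $T$ to 1 s after $D$. At the
dataset-scale mean interval of 3.85 s the middle bins average 50 ms, so
the warped axis is commensurate with the fixed margins. Binning is
half-open $[\mathrm{left}, \mathrm{right})$; a spike exactly at $T$ falls
in the first middle bin. Rates are counts divided by the actual bin
duration, so middle-bin rates integrate back to the exact spike count in
$[T, D)$ — the conservation property the tests assert pre-smoothing.

Smoothing uses an acausal Gaussian kernel 11 bins wide ($\pm 5$ bins).
The kernel SD is not dictated by the width alone; we fix it at 2 bins and
expose it as a parameter. At the edges the kernel is renormalized over
its in-range support so a constant signal is preserved exactly. PSTHs
average raw single-trial rates per (stimulus, outcome) condition and are
then smoothed; single-trial tensors are kept in both raw and smoothed
form because downstream consumers differ: tuning-curve classification
uses smoothed rates (matching the PSTH preprocessing), while decoding
defaults to raw rates (smoothing would leak information across bins of
the time course); both choices are flags.

## Per-unit statistics

The auROC between firing-rate distributions on correct
predominantly-sucrose vs predominantly-NaCl trials is computed as the
normalized Mann–Whitney U statistic with ties counted 1/2 — 0 means
sucrose trials always fire more, 1 means NaCl trials always fire more,
0.5 is complete overlap. The per-unit peak is the bin of maximal
$|auROC - 0.5|$; ties take the earliest bin and an everywhere-0.5 time
course is left unlabeled (both situations are measure-zero with real
rates; fixing them makes results deterministic).

Responsivity compares trial-wise mean rates in the sampling
($[T, T+0.5\,\mathrm{s}]$) and delay ($[D-0.5\,\mathrm{s}, D]$) windows
against baselines ($[T-3, T-2.5]$ and $[D-5.5, D-5]$ for experimental
data; $[T-0.5, T]$ for simulated data with short pre-stimulus epochs) by
two-sided Mann–Whitney tests at $\alpha = 0.01$, correct trials only.
Selectivity (sucrose vs NaCl within the window) is tested only among
responsive units, so the selective set is nested in the responsive set by
construction.

## Decoding

The decoder is a leave-one-out nearest-centroid classifier: hold out a
trial, recompute each label's mean population vector without it, assign
the held-out trial to the nearest centroid in Euclidean distance, and
score class-balanced accuracy (mean of per-label hit rates). Distance
ties — measure-zero in practice — go to the smallest label value.
Labels left with fewer than 2 trials are dropped because their centroid
is undefined after hold-out. The significance threshold is binomial:
$k/N$ with $k = \min x : P(Y \ge x) < \alpha$, $Y \sim B(N, p)$,
$p = 1/8$ for stimulus and $1/2$ for choice. Session summaries average
the chance-subtracted time course over the first 10 middle bins after
$T$ and the last 10 before $D$; the cross-session repeated-measures
ANOVA those summaries feed is deliberately delegated to standard
statistics routines.

## Demixed PCA

The condition tensor holds single-trial rates by (trial, unit, stimulus,
choice, bin). Conditions with one trial have it duplicated so split-based
procedures stay defined; conditions with none are imputed at the
condition-mean level from per-unit, per-bin linear regressions
$y = \beta_0 + \beta_1\,\mathrm{stim} + \beta_2\,\mathrm{choice} +
\beta_3\,\mathrm{stim \cdot choice}$ fitted to available trials (choice
coded 0/1). If the design is rank-deficient the fallback is the
condition-marginal mean, with a message.

The centered trial-averaged matrix $\tilde X$ (units $\times$ S·Q·T) is
decomposed exactly into four joined marginalizations — time; stimulus
(+ stimulus:time); choice (+ choice:time); stimulus:choice (+ the triple
term) — whose sum reconstructs $\tilde X$ to machine precision. Each
marginalization is approximated by a rank-$q$ map $F_\phi D_\phi$
minimizing
$\|\tilde X_\phi - F D \tilde X\|^2 + SQT\,\|F D \tilde C^{1/2}\|^2 +
\mu\,\|F D\|^2$. Writing $K = \tilde X \tilde X' + SQT\,\tilde C + \mu I$,
the exact solution is the rank-$q$ SVD truncation of
$B = \tilde X_\phi \tilde X' K^{-1/2}$ in the transformed coordinates,
with $K^{-1/2}$ a symmetric eigen-pseudo-square-root (rank-deficient
$K$ at $\mu = 0$ reduces to the minimum-norm solution, which the tests
pin against a reduced-rank least-squares oracle). The noise covariance
$\tilde C$ defaults to the average of
$\tilde X_\phi \tilde X_\phi'/SQT$ over the marginalizations; a
`noise = "none"` flag disables it (the single-trial residual variant was
considered; the average-over-marginalizations form is the one
implemented as the default because it is fully determined by the
condition means and therefore applies equally to pseudo-populations
without simultaneous trials).

The *principal* stimulus/choice axis is the decoder row of maximal
projected variance, sign-oriented so the stimulus projection correlates
positively with %Sucrose and sucrose-side choices project positive —
the decomposition itself fixes no sign, and the convention makes figures
reproducible. Regularization can be chosen by split-half trial
cross-validation over a $\mu$ grid (deterministic given a seed), falling
back to a documented default when conditions are empty.

## Tuning-curve classification

A response profile is the unit's window-averaged rate per stimulus over
correct trials. Two templates compete: a line $p_1 s + p_2$ constrained
to be nonnegative at every profile stimulus, and a step with inflection
$p_3 \in \{40, 50, 60\}$ whose levels are the side means. Because a line
on $[0, 100]$ is nonnegative at all 8 stimuli iff it is nonnegative at 0
and 100, the constrained line fit is an exact two-constraint quadratic
program: the unconstrained least-squares solution is accepted when
feasible, otherwise the two boundary solutions and the origin are
compared — no iterative optimizer, which matters for the $10^4$-repeat
calibration suites. Each template is scored against the mean-only null
with $F = \frac{SSE_1 - SSE_2}{SSE_2}\cdot\frac{N_d - N_p}{N_p - 1}$ and
the larger-$F$ template wins if its upper-tail $F(N_p-1, N_d-N_p)$
p value is below 0.005 ($\alpha = 0.01$ Bonferroni-corrected for two
templates); otherwise the profile is *other*.

Degenerate cases: a perfect template fit ($SSE_2 = 0$, $SSE_1 > 0$) is
accepted with $p = 0$; a constant profile ($SSE_1 = 0$) is *other* — the
F ratio is 0/0 there and "no improvement over the mean" is the faithful
reading.

Winning steps are sub-classified with error trials through
$\delta_x = \langle r_x(s)\rangle_{s>50} - \langle r_x(s)\rangle_{s<50}$
for $x \in \{\mathrm{correct}, \mathrm{error}\}$: inflection at 50 and
$\delta_{\mathrm{correct}}\delta_{\mathrm{error}} < 0$ means the unit
follows the *chosen side* (step-choice); otherwise, with error data
available, it follows the stimulus side (step-perception); with an error
side missing the step stays unresolved and counts as neither sub-type in
summaries. Note a consequence the tests acknowledge: in windows where
the tuning is weakly expressed, sampling noise can flip the sign of
$\delta_{\mathrm{error}}$, so sub-type confusion is a property of the
rule itself at low signal; the confusion guarantees are therefore stated
for strongly expressed windows.

The time course runs 4-bin (~200 ms) windows stepped by 4 bins — 29
full windows plus a final 1-bin window on the 117-bin axis — plus the
two fixed windows, which we map onto the warped axis as the 10 middle
bins adjacent to $T$ and $D$ (consistent with the decoding windows; the
alternative of unwarped 0.5 s spans differs only through trial-to-trial
interval variability).

## Psychometrics

Choice behavior is summarized by the 4-parameter logistic
$y(s) = p_4 + (p_1 - p_4)/(1 + e^{-p_2 (s - p_3)})$ fitted by bounded
least squares to the per-stimulus mean responses (not trial-wise
likelihood — the curve is always fitted to session- or model-averaged
points), with $0 \le p_1, p_4 \le 1$ and $15 \le p_3 \le 85$; the slope
is unbounded and a fixed multi-start grid over
$p_2 \in \{\pm 0.02, \pm 0.1, \pm 0.5\}$ makes the fit deterministic.
Curves are compared by the extra-sum-of-squares F-test (joint fit vs
separate fits, $df_1 = N - 4$, $df_2 = N - 4k$), Bonferroni-corrected by
$\binom{K}{2}$ for $K$ curves under consideration. Points are unweighted
by trial counts, as the mean-based formulation implies; a weighted
variant would be a straightforward extension.

## The constrained network

The rate network integrates, by forward Euler with
$\alpha = dt/\tau = 0.2$ ($dt = 50$ ms, $\tau = 250$ ms),

$$\tau \dot h = -h + m(x) + W^{\mathrm{rec}} f(h + b) + \eta, \qquad
  \tau \dot z = -z + w_z' f(h + b),$$

with $f(z) = \min(\max(z, 0), 80)$ read as a firing rate in Hz,
$m(x) = A^{(2)} \tanh(A^{(1)} x)$ embedding the mixture as
$x = (\%\mathrm{Suc}, \%\mathrm{NaCl})/100$, and per-step internal noise
$\eta \sim \mathcal N(0, 0.05/\alpha)$ — entering the discrete update
multiplied by $\alpha$, i.e., an effective per-step SD of 0.05, which we
apply literally as specified. The printed embedding dimensions are
internally inconsistent in the source description (a 100-row first layer
against a 300-column second layer), so the hidden width is a single
parameter $H$, default 100. Trials last 5.9 s (118 steps); the stimulus
is on from 1.0 s for 1.2 s; the decision window is the 0.1 s up to the
decision time at 4.9 s; the model's choice is the sign of the mean of
$c = \tanh z$ over that window (an exact 0 falls to the NaCl side, a
measure-zero convention).

$N_c$ constrained units are penalized toward the session's smoothed
correct-trial PSTHs; target bins 1..117 map directly onto model steps
1..117, placing $T$ at 1.0 s and $D$ at 4.9 s — exact when the session's
mean inter-event interval is 3.9 s and a sub-bin approximation
otherwise. $N_u = \mathrm{round}(5.88 N_c)$ unconstrained units add
degrees of freedom. The loss is $L = 150 L_{\mathrm{beh}} +
L_{\mathrm{neu}}$, both terms normalized by their number of summands;
the behavioral term pushes $c$ to 0 before the stimulus and to $\pm 1$
(by mixture side) in the decision window.

Training is backpropagation-through-time, written out analytically in
vectorized R and verified against central finite differences to
$<10^{-4}$ relative error (away from the rectifier kink, where the
subgradient is taken as 0). Adam runs at learning rate 0.01 with global
gradient-norm clipping at 1.0 for 2000 iterations or until $L < 1$; each
iteration presents all 8 mixtures once, noiseless stimulus, internal
noise active (training under the same intrinsic noise the simulations
use makes the fitted dynamics robust to it; a flag disables it). Initialization: $A$ entries
$\mathcal N(0,1)$, recurrent weights $\mathcal N(0, 0.1/N)$ with the
diagonal fixed at zero through every update (self-connections are
prohibited as a constraint, so the diagonal gradient is masked), readout
$\mathcal N(0, 1/N)$, bias and initial state at 0; the initial state
$h_0$ is a single trained vector shared across stimuli (a per-stimulus
$h_0$ would add capacity the behavioral task does not need).

## Simulations, calibration and ablations

Post-training simulations add persistent input noise: the stimulus
vector (zero when off) is perturbed per step by
$\epsilon \sim \mathcal N(0, \sigma)$ before the embedding. $\sigma$ is
calibrated per model so overall accuracy over 20 trials per mixture
falls within 5 percentage points of the target (the trained-on session's
accuracy): a grid over $[0.05, 1.5]$ in steps of 0.05 with a fixed seed
per candidate, first hit wins, bisection refines if no grid point lands
inside the tolerance.

Ablations clamp the rates of a labeled unit set to zero at every step —
the clamp acts on $f(h+b)$ before both the recurrent term and the
decision readout, and the reported rates. Sets are defined by the
response-profile classifier run on the *control* simulated batch (a unit
belongs to a coding set if labeled so in at least one moving window;
*other* units are never labeled), so no separate labeling logic exists
for model data. The report projects post-ablation condition means onto
the control-fit dPCA axes, re-fits axes per condition, tabulates
overlaps, accuracy and psychometric slope, and flags models lacking 2
trials of each chosen direction in any condition for exclusion.

## The synthetic generator

The generator defines the study conditions the package is tested under:
137 trials, 27 units, the 8-mixture set, inter-event intervals
truncated-normal with mean 3.85 s (floor 1 s), and choices drawn from a
4PL psychometric. Defaults chosen once and fixed: psychometric
$(0.95, 0.08, 50, 0.05)$ — the slope matches the behavioral value the
analyses were built around, and the implied overall accuracy is 77.3%;
interval SD 0.6 s (only the mean is dictated; 0.6 s is a realistic
trial-to-trial spread for a delay task); coding mix
25/25/20/15/15% linear / step-perception / step-choice /
other-responsive / flat, echoing the reported moving-window prevalences
with the remainder split between event-responsive and flat units;
baselines uniform 2–8 Hz; tuning gain 10 Hz (several times the standard
error of a window-mean rate estimate, so label recovery is attainable);
envelope width 0.8 s. Tuning is expressed through temporal envelopes —
a half-Gaussian decaying from $T$ (sampling) or a linear ramp rising
into $D$ (delay) — because only *where in the trial* tuning lives
matters for the analyses, not its exact shape. Error trials arise from
the stochastic psychometric rather than injection, so step-choice and
step-perception units are separable exactly as in recorded data.

Spiking is inhomogeneous Poisson, thinned on a 1 ms grid. This is a
modeling convention, not a claim about the recordings: real spike trains
have refractoriness, burstiness and shared variability the generator
omits, along with drift, unit loss and correlated noise. Passing tests
on synthetic sessions therefore demonstrates that the pipeline recovers
the structure it assumes, not that recorded data satisfy those
assumptions. Pre-trial epochs span 3.5 s before $T$ so the long
experimental baseline windows exist; 1 s is simulated after $D$.

## Problem sizes and determinism

Every stochastic step takes an explicit seed (sessions are bit-identical
given config + seed; the pipeline derives per-stage sub-seeds from one
global seed). The test suite and acceptance script run at deliberately
modest sizes — single sessions, a reduced network with $N_c = 10$
(hence $N = 69$), 20 trials per mixture in simulation batches,
$10^4$-repeat Monte-Carlo calibrations — chosen so the full validation
executes comfortably on one CPU while keeping every statistical check
well-powered.

## Known limitations

* The dPCA noise-covariance default is the average-over-marginalizations
  formula; with genuinely simultaneous recordings a single-trial
  residual estimate may be preferable.
* The constrained line fit enforces nonnegativity only at the observed
  stimulus values (equivalently the endpoints), as specified — not over
  all of $[0, 100]$ for profiles missing the extremes.
* Step sub-classification at weak expression inherits the sign-flip
  fragility of the $\delta$ rule (see above).
* The network is a rate model without Dale's law or biophysical spiking,
  and ablations are inference-time only.
* t-SNE embeddings of the pairwise-distance structure are out of the
  tested core; any off-the-shelf embedding can consume
  `pairwise_distances()` output.
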