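---
title: "Methods: similarity decomposition and network-based prediction of hormonal states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity decomposition and network-based prediction of hormonal states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbsconn)
```

## The scientific problem

Ovarian hormones fluctuate over the menstrual cycle — estradiol ([E2]) by
roughly eight-fold and progesterone ([P4]) by roughly eighty-fold — and
hormonal contraceptives (HCs) replace these endogenous rhythms with flat,
suppressed levels. Densely sampled ("precision imaging") designs scan the
same person daily or weekly across cycles, which makes it possible to ask
two questions that group-contrast designs cannot:

1. **How much of functional-connectome organization is attributable to
   shared group structure, dataset/scanner differences, contraceptive
   state, and the individual?** (similarity decomposition)
2. **Which functional connections track contraceptive use and hormone
   concentrations, and do those patterns generalize to other people?**
   (cross-validated network-based prediction with transfer evaluation)

`nbsconn` implements both analyses over region-by-region functional
connectomes (Pearson correlation matrices of confound-regressed,
parcellated BOLD time series), plus a synthetic-study generator that plants
known effects so every stage of the pipeline can be validated against
ground truth.

## Connectome estimation

`timeseries_to_connectome()` residualizes each region's time series against
a confound matrix by OLS (per run, with an intercept), standardizes the
residuals, and correlates them pairwise; the matrix is symmetrized by
averaging with its transpose and given a unit diagonal. The default
confound recommendation is the 16-column set used for connectivity
estimation in this literature: six motion parameters, CSF and WM mean
signals, and their temporal derivatives (backward differences padded with a
leading zero, the fMRIPrep `*_derivative1` convention). Grey-matter signal
is deliberately not included. Exactly collinear confound columns are
dropped with a warning rather than producing an unstable fit. An optional
0/1 censor vector can drop high-motion volumes before regression; it is off
by default because mean framewise displacement (FD) in the motivating
studies was well below typical censoring thresholds and volume censoring
during connectivity estimation is not part of the core procedure.

Edge vectors use one canonical total order everywhere: all pairs
$(i, j)$ with $i < j$, sorted by $i$ then $j$ (`edge_pairs()`), and
`vectorize()`/`unvectorize()` are exact inverses.

## Analysis 1: similarity decomposition

For every pair of sessions the Pearson correlation between edge vectors is
Fisher-transformed, $z = \operatorname{arctanh}(r)$, after clipping
$|r| \le 1 - 10^{-7}$ so that numerically identical connectomes give a
large but finite z. Each unordered pair is then assessed against four
*overlapping* category definitions:

* **individual** — same subject (any two sessions);
* **dataset** — different subjects, same dataset;
* **hc_use** — different subjects, same HC-use status;
* **group** — any pair of different subjects.

Because the definitions nest, `classify_pairs()` stores one membership
flag per definition (the default for summaries, matching the definitions
verbatim) *and* a mutually exclusive `primary` label with precedence
individual > dataset > hc_use > group, which is the labeling a bar plot
wants. Category means are contrasted with Welch (unequal-variance)
two-sample t-tests at $\alpha = 0.01$; Welch is used because category
sizes and variances differ by orders of magnitude and the choice of pooled
versus unpooled variance is otherwise open. Pairwise z values share
sessions and are therefore not independent observations; the t-tests
deliberately ignore this, following the convention of the analysis this
package implements, and the limitation is stated here rather than patched
with a permutation scheme (a non-goal).

The **normalized effect magnitude** of factor A over factor B is simply
the difference of mean z values, `normalized_effect_magnitude(z_A, z_B)`.
For example, with a group mean of $z = 0.59$, an HC-use mean of $z = 0.54$,
and a within-individual mean of $z = 1.07$, the individual-over-group
magnitude is $1.07 - 0.59 = 0.48$ and the individual-over-HC magnitude is
$1.07 - 0.54 = 0.53$.

## Analysis 2: network-based predictive modeling

`run_discovery()` embeds network-based-statistic edge selection inside a
resampled cross-validation loop. Per iteration (default 1000; a fresh
seeded shuffle each time) sessions are split into `n_folds` folds (default
5, i.e. 80%/20% train/test). Per fold, on training rows only:

0. confounds are regressed out by OLS — mean FD from every edge, and, for
   hormone outcomes, FD (and optionally HC use) from the outcome as well;
   held-out rows are residualized with the training-fitted coefficients,
   never refit (no leakage);
1. each edge gets a connection-wise F test against the outcome,
   $F = r^2(n-2)/(1-r^2)$ referred to $F(1, n-2)$ (for a binary outcome
   this is the two-group one-way ANOVA F); after residualization the
   reference distribution keeps $n-2$ degrees of freedom by contract, a
   slight liberality that is irrelevant at the edge-selection threshold;
2. edges with $p < 0.05$ are thinned to their **largest connected
   component** (the component containing the most edges; ties broken
   toward the component holding the smallest region index);
3. component edges, standardized on training rows, feed an L2-penalized
   model — logistic regression for HC use, ridge regression for hormone
   concentrations — with the penalty $\alpha$ chosen by inner
   cross-validation (3 inner folds) over a log-spaced grid of 20 points on
   $[10^{-4}, 10]$, scoring the same metric as the outer loop and breaking
   ties toward the smaller penalty;
4. the fitted model is scored on the held-out fold: classification
   accuracy for HC, Spearman correlation between actual and predicted
   concentrations for hormones (hormone predictions are mapped back to the
   outcome scale by adding the training-fitted confound contribution
   before comparison).

Hormone outcomes are min-max scaled to $[0, 1]$ *within dataset* before
modeling, which makes concentrations comparable across assay technologies
(serum versus saliva); mean squared errors are reported on that scale. The
fold count follows the five-fold description of the core procedure (a
ten-fold variant exists in the source literature's schematic; the fold
count is a config field). Ridge is solved in closed form through the SVD
of the centered design, so a whole penalty grid costs one decomposition;
penalized logistic regression uses damped Newton/IRLS. Linear-kernel
kernel ridge regression is mathematically equivalent to the ridge solution
used here.

**Edge weights.** An edge's weight in the discovered network is its
performance-weighted selection frequency: the sum over iterations of the
iteration's mean held-out performance when the edge entered at least one
fold's component, divided by the total number of iterations. Never-selected
edges are exactly 0; iterations with negative performance (possible for
Spearman) contribute negative weight, so consistently negatively related
edges are dropped by thresholding. Folds whose component is empty score
chance (0.5 accuracy / 0 correlation) and select nothing.

`threshold_network()` keeps the top $\lceil f \cdot n_{\text{nonzero}}
\rceil$ edges by weight among positively weighted edges (default
$f = 0.5$), ties broken by canonical edge index. `train_final_model()`
refits residualization, standardization, and the penalized model on the
full discovery study over the retained edges, and `transfer_predict()`
applies every *stored* parameter to an independent study — external edges
are cleaned with the discovery-fitted confound coefficients and
standardized with discovery statistics, so the external data contribute
nothing to the model. For HC the reported MSE is that of the 0/1 class
prediction, i.e. the misclassification rate.

`drop_cycle_window()` supports the sensitivity analysis of removing
ovulatory-window sessions (cycle days 12–16, inclusive) before discovery.

## The synthetic generator

`generate_study()` builds session edge weights as

$$w_{es} = \tanh\big(b_e + d_e^{(\text{dataset})} + u_e^{(\text{subject})}
 + \beta_{\text{hc}} \text{hc}_s m^{\text{hc}}_e
 + \beta_{e2} \tilde{e2}_s m^{e2}_e
 + \beta_{p4} \tilde{p4}_s m^{p4}_e
 + \beta_{\text{fd}} \text{fd}_s m^{\text{fd}}_e
 + \varepsilon_{es}\big)$$

with a sparse shared backbone $b$, Gaussian per-dataset and per-subject
offsets, planted effect masks $m$ that are connected subgraphs
(`plant_connected_component()`, so component-based selection can recover
them), hormone predictors min-max scaled within dataset, and i.i.d.
Gaussian edge noise. The `tanh` keeps weights in $(-1, 1)$; matrices are
exactly symmetric with unit diagonal.

Two seeds govern two levels of randomness. The **population seed** draws
everything that is a property of the population rather than of one study:
the backbone, the planted effect networks, and the dataset/subject offsets
(keyed to their ids, so a subject appearing in two studies keeps their
idiosyncrasies). The **design seed** draws a particular study's sessions,
hormone jitter, motion, and noise. Any transfer evaluation presumes a
shared population-level connectome, which is exactly what a shared
population seed provides.

Hormone trajectories (`simulate_hormone_cycle()`) are sums of Gaussian
bumps over a positive baseline: for naturally-cycling profiles an
ovulatory estradiol surge at $0.46 \times$ cycle length with a smaller
mid-luteal bump, and a luteal progesterone peak at $0.75 \times$ cycle
length, parameterized to give ~8-fold (E2) and ~80-fold (P4) dynamic
ranges; HC profiles are flat low baselines. Multiplicative log-normal
jitter (sd 0.04, chosen so the fold-change bands hold with margin)
emulates assay noise. Units are arbitrary since all modeling scales
within dataset. Cycle day is carried as metadata only — weekly sampling
wraps across cycles and self-reported cycle-day is unreliable — and no
model consumes it except the explicit sensitivity window.

The default study designs mirror the motivating two-study structure: one
subject scanned daily for 30 naturally-cycling and 30 HC-using sessions
(two datasets, so HC status is deliberately confounded with dataset, as in
the real design), and an independent weekly three-subject study with 10
sessions in total.

### What the generator does and does not emulate

It emulates the statistical skeleton the pipeline sees: design structure,
curvilinear hormone dynamics with realistic fold changes, connectome-level
effect topography, and motion coupling. It does **not** simulate BOLD time
series (no temporal autocorrelation; noise is i.i.d. at the connectome
level), assay measurement-error models, or spatial autocorrelation of
edges. Passing tests therefore demonstrate that the *pipeline* recovers
what was planted under its own assumptions — not that real neural
hormone effects are of any particular size. Planted effect magnitudes are
chosen for test power, not realism; within-subject hormone-connectivity
effect sizes are not available to calibrate them.

## Numerical choices and degenerate inputs

* arctanh clipping at $|r| \le 1 - 10^{-7}$; zero-variance edge vectors
  make a pair undefined (excluded from summaries) rather than erroring.
* Constant edges get $F = 0, p = 1$; a constant outcome is rejected.
* Constant covariates on training rows are dropped with a warning.
* Ridge/logistic ties in the penalty search resolve to the smaller
  penalty; degenerate inner folds (single class) are skipped.
* Empty components score chance and select no edges instead of aborting a
  run.
* All randomness flows through explicit integer seeds; identical configs
  give bit-identical outputs (including the full discovery loop).

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles:
union-find connectivity checks for component selection, per-edge `lm()`
fits for the F statistics, normal-equations OLS for the $\alpha \to 0$
ridge limit, `glm()` for lightly penalized logistic regression, and
brute-force loops for similarity categories and node/network aggregation.
End-to-end checks run the full discovery on generated studies of 60
sessions and 50 regions with 100 resampling iterations (1225 edges; large
enough for a giant random suprathreshold component to exist, small enough
to keep a full run in tens of seconds), verify chance-level calibration
under outcome permutation, recovery of a planted 15-edge HC component,
and transfer discrimination between an external cohort sharing the effect
and the same cohort without it.

One caveat the end-to-end checks make explicit: because discovery
iterations resample folds of the *same* sessions, edges whose noise
happens to correlate with the outcome in that one sample are selected in
nearly every iteration. The discovered nonzero set is therefore much
larger than the planted component, and a count-based 50% retention keeps
a correspondingly large edge set; overlap metrics computed on that set
measure the behavior of the procedure, not a defect of the
implementation. Relatedly, transfer of a shared planted effect succeeds
when edge noise dominates subject-level idiosyncrasy (the committed
fixture uses noise sd 0.2 against offset sd 0.1) and collapses toward
chance as idiosyncratic offsets grow — the within/between-individual
dissociation that motivates transfer evaluation in the first place.

## Known limitations

* The pair-level t-tests ignore the dependence structure of similarity
  values (by design, matching the implemented analysis).
* The F reference distribution ignores degrees of freedom spent on
  confound residualization.
* The weighted-network denominator (total iterations, selection = any
  fold) is one of several defensible conventions; it is the one that
  makes never-selected edges exactly 0.
* The generator operates at the connectome level; pipelines sensitive to
  BOLD-level artifacts need real data.
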