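---
title: "Methods: multi-subject effective connectivity by penalized greedy search and non-Gaussian orientation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-subject effective connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effconn)
```

## The problem

A blocked working-memory experiment (an n-back task at loads 1–3) yields,
for each subject, one BOLD-like time series per region of interest (ROI).
Seven experimental conditions interleave through the session: three
*preparation* periods (the instruction screen before each block), three
*task* periods, and *rest* periods separating blocks.  The scientific
question is which directed inter-regional influences are present in each
condition, and in particular which connections are present in *every*
condition including rest (a "default" sub-network) versus present only
during a load's preparation and task periods but absent at rest
("preparation-related" sub-networks).

`effconn` implements the full analysis pipeline plus a synthetic-data
generator with known ground truth, so every stage is testable end to end
without any recordings.

## Model

Within one condition, the joint activity of the $p$ ROIs is modelled as a
linear structural equation model (SEM) over a directed acyclic graph
(DAG): for each node $j$ with parent set $\mathrm{pa}(j)$,

$$x_j \;=\; \sum_{k \in \mathrm{pa}(j)} \beta_{kj}\, x_k + e_j,$$

with mutually independent, **non-Gaussian** innovations $e_j$.  Time
points within a condition are treated as i.i.d. draws; all data are
column z-scored first, and all regressions are intercept-free on that
standardized scale.

The pipeline has four stages.

### 1. Segmentation (`segment()`, `standardize()`)

Schedules use 0-based TR indices and half-open `[onset, onset + n)`
segments — fixed here to remove any off-by-one ambiguity.  All segments
with the same condition label are concatenated (the analysis pools them).
Rest is analysed starting 4 s after the preceding block, i.e. the first
$\lceil 4\,\mathrm{s} / \mathrm{TR} \rceil = 2$ TRs (at TR = 2 s) of each
rest segment are dropped, so 5–6-TR rests contribute their last 3–4 TRs.
Under the default design (10 blocks per load, 8-s instructions, 21+-TR
blocks, 10–12-s rests) each subject contributes exactly 40 data points
per preparation condition, at least 210 per task condition and at least
90 at rest — small by single-subject standards, which is why every later
stage pools across subjects rather than concatenating their time series.

### 2. Structure search (`greedy_search()`, `find_first_nontriangular()`)

The skeleton shared across subjects is found by a greedy equivalence
search maximizing a penalized Gaussian likelihood *averaged over
per-subject datasets* (equal weights; the score never concatenates
subjects).  The local score of node $j$ with parents $P$ in one dataset
of $n$ rows is

$$\mathrm{score}_j = -\,n \ln \hat\sigma^2_{j|P} \;-\; c\,(|P|+1)\ln n,$$

with $\hat\sigma^2$ the maximum-likelihood (divisor $n$) residual
variance of the intercept-free regression and $c \ge 1$ the *penalty
discount*; the decomposable total score is the sum over nodes of the
across-subject averages.  This is the standard BIC up to constants
common to all models, written out because published descriptions rarely
state the convention.

The search itself operates on Markov equivalence classes (CPDAGs): the
forward phase repeatedly applies the best strictly score-improving edge
insertion operator (with the usual clique and semi-directed-path
validity conditions), the backward phase the best deletion, and after
every move the graph is re-closed via a consistent extension,
v-structure pattern and Meek-rule completion.  An earlier iteration of
this package used a plain DAG-space hill climb (add/delete, then
add/delete/reverse); it systematically locked in arbitrary orientation
ties and compensated with spurious edges that no single move could
repair, inflating triangle counts and forcing destructive penalties.
Equivalence-class search eliminates that failure mode and is the design
the score's Markov-equivalence invariance calls for, so it is the one
implemented.

Because the ROI signals are noisy aggregates of latent neural causes,
three mutually adjacent nodes ("triangulation") are treated as a symptom
of spurious connections: `find_first_nontriangular()` re-runs the search
at $c = c_\mathrm{start}, c_\mathrm{start}+c_\mathrm{step}, \dots$
(default 1, 1, up to 20) and returns the first triangle-free skeleton,
recording `c_used`.  The penalty actually used is therefore an *output*
of the analysis, not a tuning knob.

Numerical choices: strict-improvement threshold $10^{-9}$ on the
averaged score (suppresses floating-point churn); equal-score candidate
moves resolved in a fixed lexicographic enumeration order (by target
label, then source, then operator subset) so results are deterministic;
operator subsets capped at size 3 (`max_subset`), ample for the sparse
graphs searched here; near-collinear candidate parent sets fall back to
a ridge-stabilized solve.

### 3. Orientation (`anderson_darling()`, `orient_edges()`)

With the skeleton fixed, each adjacency is oriented by exploiting
non-Gaussianity: among linear models, the regression residuals of the
*incorrect* direction are closer to Gaussian than those of the correct
one.  Departure from normality is measured by the Anderson–Darling
statistic on standardized residuals,

$$A^2 = -n - \frac{1}{n}\sum_{i=1}^{n} (2i-1)\left[\ln F(z_{(i)}) +
\ln\!\big(1 - F(z_{(n+1-i)})\big)\right],$$

with CDF values clipped to $[10^{-10}, 1-10^{-10}]$.  Standardization
uses the sample SD (divisor $n-1$), the usual estimated-parameters form.
For an edge $\{X, Y\}$, each candidate direction implies local
regressions of $X$ and $Y$ on their adjacent-node parent sets (the
receiving node keeps all its adjacencies as parents, the sending node
all but the receiver); the direction score sums $A^2$ over both
endpoints and over subjects (summing is monotone-equivalent to averaging
with equal $n$), and the higher score wins — logged as rule
"pairwise-AD".  Ties go to the lexicographically smaller (source,
target).  If the oriented graph contains a cycle, the edge on a cycle
with the smallest score margin is flipped first (least-confident
decisions disturbed first), repeating until acyclic.  With Gaussian
innovations the margin is centred at zero by construction — orientation
is then uninformative, which the test suite checks as a negative
control.

### 4. SEM estimation and classification (`fit_subject()`, `classify_connections()`)

For a DAG with independent errors the maximum-likelihood SEM estimate
factorizes into node-wise OLS, so path coefficients are computed in
closed form per subject — exact, and equivalent to an iterative SEM
optimizer for this model class — then summarized as across-subject mean
(SD), sample SD with divisor $n-1$.  A single subject yields SD 0 with
an explicit degenerate flag rather than a missing value.

Classification is pure set algebra over connections across the seven
condition tables: *default* = present in all seven; *preparation-related
(load k)* = present in prep-k and task-k but absent at rest;
*preparation+rest-only (k)* = present in prep-k and rest but absent in
all three task conditions.  Presence is direction-blind; a
`direction_variable` set records the pairs whose orientation flips
between conditions.  Connection identity is normally the unordered ROI
pair; transcribed published tables occasionally print the two
orientations of one pair as distinct rows, so table entries carry the
printed row label as their identity and the classifier honours it (for
pipeline-built tables the two notions coincide).  In the packaged
transcriptions (`inst/extdata/`), a cell prefixed `<` marks a reversed
direction relative to the row label, a row written `A-B` (no arrow) has
unresolved direction, and a printed mean of 0.00 still counts as
present.

## The synthetic-data generator

`sample_graph_set()` draws the ground truth the classifier must recover:
a default edge set shared by all seven conditions plus per-load extras
shared by prep-k and task-k and absent at rest (the "paired" scenario).
Defaults mirror the study's Increase network: 18 ROIs, 11 default edges,
1/2/5 extras for loads 1/2/3, path coefficients drawn uniformly from
0.5–0.9 on the standardized scale.  All edges are oriented along one
hidden topological order (so every condition graph is acyclic) and every
condition skeleton is kept triangle-free: the search is *designed* to
reject triangulated solutions, so a triangulated truth would be
unrecoverable by construction, and the recovery claims are stated under
triangle-free truth.

`simulate_subject()` emits i.i.d. SEM rows per schedule segment.  There
is deliberately no hemodynamic convolution: the analysis consumes raw
segment samples, and modelling temporal autocorrelation is out of scope
(an AR(1) flag exists for robustness experiments only).  Innovations
default to uniform — strongly sub-Gaussian, which the orientation stage
requires; Gaussian noise is reserved for negative controls.
Between-subject variability is a ±10% multiplicative jitter on every
coefficient, drawn once per subject per edge — exactly the heterogeneity
the across-subject score averaging is meant to absorb.  Task-block
lengths are drawn uniformly on [21, 27] TRs to emulate the self-paced
design; rest durations on 10–12 s in whole TRs.

What the generator does *not* emulate: hemodynamic lag and smoothing,
physiological and scanner noise spectra, motion, spatial ROI overlap,
non-stationarity within blocks.  Passing recovery tests therefore show
the algorithms are correct under the stated model, not that real fMRI
data satisfy that model.

`simulate_benchmark()` is the single-condition counterpart used for
accuracy claims: 50 variables, 10 subjects, ~200 time points each,
edge density 0.05 (~61 edges), uniform innovations, coefficients
0.5–0.9.  Session lengths, density and noise family are exposed as
parameters because the published simulation benchmark this emulates does
not pin them down.  At these settings the pipeline recovers well over
95% of adjacencies and orients essentially all correctly discovered
edges; problem sizes for tests were chosen so the full suite and the
acceptance script each run in minutes on one core.

## Worked example

```{r example, eval = FALSE}
gs <- sample_graph_set(seed = 1)
study <- simulate_study(gs, n_subjects = 16, seed = 1)
datasets <- segment_study(study)

res <- find_first_nontriangular(datasets$prep3)
oriented <- orient_edges(res$skeleton, datasets$prep3)
estimate_edges(oriented, datasets$prep3)
```

Running the search per condition, building one edge table per condition
with `build_edge_table()` and calling `classify_connections()` closes
the loop back to the generating `gs` via `compare_to_truth()`.

## Known limitations

* The i.i.d.-within-segment assumption ignores BOLD autocorrelation;
  with strongly colored noise the effective sample size is smaller than
  the nominal data-point counts.
* Orientation accuracy degrades gracefully toward chance as innovations
  approach Gaussianity; the package reports margins but no significance
  test for individual edge directions.
* No latent-variable search: a common unobserved cause of two ROIs can
  appear as a (possibly mis-oriented) edge between them.
* The penalty escalation returns the *first* triangle-free solution;
  when the data genuinely contain a triangle of strong effects, edges
  are sacrificed by design.
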