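---
title: "Methods: pipeline engine, step library and benchmark metrics"
author: "fcspipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pipeline engine, step library and benchmark metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcspipe)
```

## Why a pipeline engine

Pre-processing of flow cytometry data — removing saturated margin events,
compensating fluorescence spillover, discarding unstable acquisition-time
segments, doublets, debris and dead cells, and rescaling fluorescence for
display — is a sequence of filtering and transformation steps whose order
and parameters materially change the events that survive. Comparing two
candidate pipelines therefore requires (a) declaring each pipeline in one
place rather than in ad hoc scripts, (b) keeping every intermediate result
inspectable, and (c) a stable per-event identity so that outputs of
different steps, parameterizations or pipelines can be compared event by
event and scored against a reference gating.

`fcspipe` addresses exactly this. A pipeline is a JSON document with two
ordered step lists: `scaleTransformProcessingSteps`, run once per
experiment to estimate per-channel scale transformations, and
`flowFramesPreProcessingSteps`, run independently per FCS file. Each step
names a registered function and its arguments; at run time each step
receives the previous step's output as an implicit first argument. The
engine caches every step output on disk before the next step starts, so a
run can be monitored, resumed, partially invalidated and mined for
diagnostics after the fact. The same engine code executes any step order;
two pipelines differ only in their JSON.

## Event identity

Every event carries the 0-based row index it had in its raw FCS file, and
no step ever renumbers events. Identifiers survive serialization through a
custom FCS keyword (`CYTOPIPE_EVENT_IDS`, a compact range encoding), so a
cached output read back from disk still knows which raw events it holds.
This is the join key for everything downstream: step-to-step diffs,
retention profiles, and benchmark metrics. Identity is only meaningful
within one sample; cross-sample comparisons are restricted to distribution
views by design.

## The step library

All steps consume and produce an event table and preserve identifiers.
Robust statistics use the MAD with the 1.4826 normal-consistency constant
throughout.

**Margin removal.** Per-channel bounds `(low, high)` in data units; events
outside the bounds on any bounded channel are removed. Bounds are
*inclusive* by default (an event exactly at a bound is removed) because
saturated events pile up exactly at the detector range `$PnR`.

**Compensation.** The spillover matrix $S$ (rows = source dyes, columns =
detectors, row-normalized to unit diagonal) mixes true fluorescence into
observed fluorescence, $X_{raw} = X_{true} S$. Compensation
right-multiplies the fluorescence sub-matrix by $S^{-1}$. $S$ is taken
from the FCS keywords (`$SPILLOVER`, then `SPILL`, then `SPILLOVER`) or
supplied explicitly; singular matrices are rejected.

**Time QC.** Events are ordered by the Time channel and cut into
consecutive bins of `bin_size` events (default 100; the trailing partial
bin joins its predecessor). For each monitored channel the per-bin median
is computed; bin $j$ is flagged when

$$\frac{\lvert m_j - \mathrm{median}(m) \rvert}{1.4826\,\mathrm{MAD}(m)} > \texttt{mad\_cutoff}$$

for any channel (default cutoff 6), and all its events are removed. When
the MAD of bin medians is zero (constant signal) nothing is flagged. This
is deliberately a simple location-shift monitor: it detects the dominant
instability mode (fluidics drift, clogs) and is not a re-implementation of
peak-based or multi-flag QC methods. With fewer than `min_bins` bins the
step warns and passes the data through unchanged — too little data to
judge stability is not a failure.

**Doublet removal.** Doublets have elevated pulse area for their height.
With $r = \mathrm{FSC\text{-}A}/\mathrm{FSC\text{-}H}$, events are kept
when $r \le \mathrm{median}(r) + n_{mad}\cdot 1.4826\cdot\mathrm{MAD}(r)$,
default $n_{mad} = 4$. The rule is one-sided (low ratios are harmless) and
degenerates gracefully: identical ratios give MAD 0 and nothing is
removed. The threshold rule and its default are this package's own choice,
exposed as a parameter.

**Debris removal.** A Gaussian mixture model (EM, full covariances) with a
user-chosen number of clusters is fitted on the (FSC-A, SSC-A) plane,
standardized per axis to unit variance so the two scatter scales
contribute comparably. The cluster whose centroid — mapped back to
original units — has the smallest Euclidean norm from the origin is
removed. "Nearest to the origin" is implemented as the minimal centroid
norm because the componentwise reading ("smallest FSC-A *and* smallest
SSC-A") is ambiguous when clusters are not ordered on both axes; the
Euclidean rule always yields a unique answer (ties broken by cluster
index, which cannot occur with continuous data). Clustering is delegated
to `mclust` with a seeded, deterministic initialization; two runs with the
same seed remove the same events.

**Scale transformation.** The logicle, a biexponential display scale that
is logarithmic at high intensity and linear around zero, with parameters
$T$ (top of scale), $M$ (display width in decades), $W$ (linearization
width in decades) and $A$ (extra negative decades). Internally, display
decades $y \in [-A, M]$ map to $s = (y+A)/(M+A) \in [0,1]$ and the data
value is

$$S(s) = a e^{b s} - c e^{-d s} - f,$$

extended by odd symmetry about $s_1 = (A + W)/(M+A)$, with coefficients
fixed by $S(s_1) = 0$, $S(1) = T$, $c/a = e^{(b+d)(A+2W)/(M+A)}$,
$b = (M+A)\ln 10$ and $d$ the root of $2\ln(b/d) = w(b+d)$,
$w = W/(M+A)$. The inverse (display to data) is this closed form; the
forward direction is evaluated by bisection on it (100 halvings of a
bracket that always encloses the solution, i.e. converged far below the
1e-10 display-unit tolerance the package promises). Automatic estimation
per channel follows the reference heuristic: $T$ from `$PnR` (observed
maximum as fallback), $A = 0$, and
$W = \max\!\big(0, (M - \log_{10}(T/\lvert r\rvert))/2\big)$ with $r$ the
5% quantile of the channel's non-positive values; channels with no
non-positive values fall back to $W = 0.5$. The defaults $M = 4.5$ and
$q = 0.05$ are declared package defaults. Estimation runs once per
experiment on an aggregated table (4 randomly selected files by default,
margin-filtered and compensated), giving one transform set for all
samples; per-channel parameters — typically the display width, the
"positive decimals" of the display — can be adjusted manually and the set
re-serialized to JSON.

**Dead-cell removal.** Dead cells are bright in the viability
(Live & Dead) channel. On the *transformed* intensities — raw-scale
densities are spike-shaped and unusable for mode finding, which is why the
transform set is an explicit argument — a Gaussian KDE (Silverman
bandwidth, 512 grid points) is computed, the two highest prominent modes
are located, and the threshold is the density minimum between them. A mode
counts as a population only if it reaches 5% of the top density, and the
valley must dip below half the lower mode; otherwise the distribution is
treated as unimodal (no dead population), the threshold falls back to the
0.99 quantile and a warning is raised. The prominence rules exist because
a naive "two highest local maxima" reading picks up KDE summit jitter on
unimodal data and would then remove half the sample.

## The engine's caching model

Each step output is stored under
`<cache>/<experiment>/<sample|GLOBAL>/<NN_stepname>.<fcs|json>` (event
tables as FCS 3.1 float, transform sets as JSON) together with a status
record. Cache validity is decided by a chained SHA-256 hash over the
canonicalized step definition plus the previous step's hash, with the
scale-transform pipeline's final hash feeding the per-file chain; editing
any upstream step therefore invalidates everything downstream of the edit,
and nothing else. On re-run the longest valid prefix is skipped untouched;
a re-run over a fully valid cache performs zero computation and zero
writes.

Two details guarantee reproducibility:

* **Serialized-form chaining.** A step's input is always the *cached* form
  of its predecessor's output (float32 through FCS), never the in-memory
  double-precision object, so a resumed run is bit-identical to an
  uninterrupted one.
* **Derived seeds.** The experiment seed is declared once; each sample
  derives its own seed from it and the sample name, so results are
  independent of the number of parallel workers and of scheduling order.

A step failure records an error for that sample and stops that sample
only; completed steps always form a prefix, which is what the workflow
view renders (completed / error / pending nodes in step order).

## Benchmarking against a ground truth

Ground truth is a CSV of retained ("good") event identifiers per sample;
bad events are the complement within the raw file. With $G$/$B$ the
truth partition and $F_G$/$F_B$ the pipeline's retained/removed partition:

$$\text{sensitivity} = \frac{\lvert F_B \cap B\rvert}{\lvert B\rvert},\quad
\text{specificity} = \frac{\lvert F_G \cap G\rvert}{\lvert G\rvert},\quad
\text{precision} = \frac{\lvert F_B \cap B\rvert}{\lvert F_B\rvert},\quad
\text{recall} = \frac{\lvert F_G \cap G\rvert}{\lvert F_G\rvert}.$$

Metrics with an empty denominator (a pipeline that removes nothing has no
$F_B$) are reported as missing, never as zero. Summaries are per-metric
quartiles; figures are per-metric box plots and per-sample A-versus-B
scatters with the identity line.

## The synthetic generator

Every test and the acceptance run operate on generated samples with known
per-event labels, so recovery rates are measurable exactly. One sample
contains, by default, 10,000 events split as target 70%, debris 12%, dead
10%, doublets 5%, margin 3%:

* **Target** events are multivariate Gaussian in (FSC-A, SSC-A) around
  (50000, 30000) with correlated spread, a lymphocyte-like cluster.
* **Debris** sits near the scatter origin (mean (8000, 5000)).
* **Doublets** have FSC-A multiplied by `doublet_area_factor` (default 2)
  with FSC-H untouched, doubling the area/height ratio.
* **Dead** cells share the target scatter distribution but have viability
  intensity multiplied by $10^{1.5}$ (1.5 decades, `dead_shift`), giving
  the bimodal viability density the dead-cell step assumes.
* **Margin** events are an over-dispersed FSC-A tail clipped at the
  detector maximum (262,144), so they sit exactly at `$PnR` like real
  saturated events.
* **Fluorescence** is log-normal per channel and mixed by a 3x3 spillover
  matrix (off-diagonals 0.03–0.10) before storage, with the matrix
  serialized into the file's keywords.
* **Acquisition time** is uniform over 300 s (monotone in the file); the
  default unstable window shifts FL1-A by 6 per-event standard deviations
  over t in [100, 130) s.

Good = target population outside the unstable window; everything else is
bad. Per-population counts are deterministic (rounded fractions, target
absorbs the remainder), and a fixed seed reproduces files byte for byte.
Dataset generation jitters per-sample population means (5% relative) for
inter-sample variability.

What this emulates — and what it does not: populations are clean
parametric clusters with no autofluorescence, no spectral overspill beyond
the linear mixing model, no debris/dead continuum, no rare populations,
and instrument noise is limited to the planted location shift. Passing the
recovery criteria on this data shows the algorithms implement their
declared rules and separate well-separated populations; it does not show
robustness on low-quality real samples, where e.g. mixture clustering is
known to fail when the target population is a small minority.

## Shipped pipelines and study conditions

Two pipeline descriptions ship with the package, differing in where time
QC runs — after compensation and scale transformation
(`qc_transformed.json`) or directly on raw data (`qc_raw.json`) — which
also forces different step orders around compensation, mirroring the two
families of QC methods in use. Both share the scale-transform pipeline
(aggregate 4 files, remove margins, compensate, estimate logicle
parameters).

Problem sizes used by the test suite and the acceptance script: recovery
properties on single 10,000-event samples; engine semantics on 3 samples
of 2,000 events; the end-to-end dual-pipeline benchmark on 6 samples of
10,000 events, on which both pipelines score every metric well above 0.8
against the generator's truth and the oracle filter (keep exactly the true
good events, run through the same engine) scores exactly 1.0 — the
built-in consistency check of the whole benchmark path.

## Numerical choices and degenerate inputs

* Logicle forward evaluation: vectorized bisection, 100 iterations from a
  bracket derived from the data magnitude; mutual-inverse error is below
  1e-8 everywhere tested, including randomized parameter draws.
* `d` in the logicle coefficients: `uniroot` on $(0, b)$ at
  `.Machine$double.eps^0.75` tolerance; $W = 0$ short-circuits to
  $d = b$.
* Written FCS files are float32; round trips are exact to single
  precision, and all equality checks across the cache compare that form.
* Empty tables write and read back as 0-event files; zero-channel tables
  are refused.
* MAD = 0 situations (constant signal, identical ratios) never divide:
  time QC flags nothing, doublet threshold collapses to the median.
* Events with non-positive pulse height cannot enter a ratio and are
  removed with a warning.

## Known limitations

* FCS support covers single-dataset list-mode 3.0/3.1 files (integer,
  float, double); FCS 2.0, multi-dataset files and TEXT-segment escape
  sequences are out of scope.
* The time-QC method is a location-shift detector; slow monotone drift
  within a bin-median tolerance band or variance-only instability will
  pass.
* Debris identification assumes the origin-nearest mixture component is
  debris; samples dominated by debris can defeat it, as any
  cluster-count-based rule.
* Cross-sample event diffs are impossible in principle and refused; only
  distribution comparisons are offered there.
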