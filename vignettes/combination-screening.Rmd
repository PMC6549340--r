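---
title: "Higher-order drug combination screening with combiscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Higher-order drug combination screening with combiscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combiscreen)
library(dplyr)
```

# The problem

An *exhaustive* drug combination screen evaluates every non-empty subset of a
fixed drug panel, each drug at one fixed concentration, up to a chosen
combination order. For a panel of $N_d$ drugs screened up to order $c$ the
number of treated wells is

$$N_w(N_d, c) = \sum_{i=1}^{c} \binom{N_d}{i},$$

so a 9-drug screen up to order 4 needs 255 treated wells and a fully
exhaustive 8-drug screen needs $2^8 - 1 = 255$ — either fits on one 384-well
plate alongside 40 or more untreated control wells. `combiscreen` covers the
full workflow of such a screen: randomized plate design, label-free
quantification of time-lapse phase-contrast images, matched-filter counting
of apoptotic-like objects, two-stage quality control, end-point Bliss
synergy scoring, and mining of the fused temporal responses into groups
explained by their lowest-order drivers.

# Plate design

`design_spec()` + `randomize_layout()` place every condition (plus untreated
controls) at uniformly random wells, re-randomized independently per
replicate plate, so spatially correlated noise decorrelates between
replicates and averages out on merging. Design choices:

* **Untreated wells.** Feasibility requires at least `min_untreated`
  (default 40) control wells; when space allows, `untreated_target`
  (default 53) are placed. Remaining wells become BLANK and serve as assay
  blanks for the survival index.
* **Seeding.** One master seed; replicate $r$ draws its permutation from
  stream `seed + r`. Identical inputs reproduce layouts byte for byte.
* **Edge wells.** An optional `edge_exclude` flag keeps the evaporation-prone
  outer rim empty; off by default, since full-plate layouts are the norm.
* **Specification file.** A line-oriented `key=value` header plus
  tab-separated `drug  concentration  unit` lines; `read_design_spec()` and
  `write_design_spec()` round-trip it. The exported destination CSV holds one
  row per (well, compound) transfer for acoustic liquid handlers, with
  explicit marker rows for untreated and blank wells so the file round-trips
  losslessly.

# Image quantification

Frames are grayscale matrices on a $[0,1]$ intensity scale; a well is a
time-ordered list of frames (the reference recording schedule is 17 frames
at 4 h intervals, the first frame 4 h after treatment). All per-frame
computations are independent, so frames can be processed in any order or in
parallel without changing any result (a map/reduce contract that the tests
assert).

**Segmentation.** The global background level $\mu_b$ is the median
intensity — background dominates phase-contrast frames of adherent cultures.
The pixel population is split at $\mu_b$ and Otsu's threshold is applied
independently to each side, giving a background interval $[lo, hi]$; pixels
outside it are foreground. This catches both dark (cell body) and bright
(halo, apoptotic ring) foreground without a user-set threshold. A side with
fewer than two distinct intensities cannot be split and extends to the frame
extreme (a constant frame degenerates to $[v, v]$ with a warning).

**Confluence.** The foreground *fraction* (invariant to crop size), tracked
as the relative change to the first frame,
$\Delta C_w(t_i) = (c_w(t_i) - c_w(t_0)) / c_w(t_0)$.

**Morphology.** Hierarchical pixel histograms (PHHC): an image pyramid
(default 3 levels, antialiased local-average downsampling by 2 per level for
frames, nearest-neighbor for masks) with a 16-bin foreground intensity
histogram per level, concatenated. The change measure is the L1 distance to
the first frame normalized by the first frame's L1 mass,
$\Delta M_w(t_i) = \lVert h_w(t_i) - h_w(t_0)\rVert_1 / \lVert h_w(t_0)\rVert_1$,
which starts at 0 and compensates for seeding-density differences. The
histogram bin range is fixed per plate from the global intensity range of
every well's first frame so vectors are comparable across wells. Note that
because PHHC entries are raw foreground counts, $\Delta M$ responds to
growth as well as to texture change; the readouts are interpreted jointly,
not in isolation.

# Matched-filter object counting

A linear matched filter detects prototype-like (apoptotic-like) objects: for
a user-selected prototype patch $s$ (the reference case uses 33×32 px) and a
scalar background level $b$, the coefficients are $w = s - b$ (white-noise
covariance; $b$ is scalar because phase-contrast backgrounds are flat — the
per-frame median or a training-set mean serves as the estimate). The
response is the valid sliding dot product — no padding, brute-force
equivalent, which the tests verify against an independent double-loop oracle
to 1e-9.

Two counters run on the thresholded response and their mean is the per-frame
count:

* **Taboo counting** greedily accepts the largest remaining response,
  then taboos the patch-footprint neighborhood around it (even patch
  dimensions round the center toward the top-left) until the maximum falls
  below the threshold.
* **Position counting** projects the supra-threshold set onto columns,
  finds maximal contiguous column intervals, then counts maximal contiguous
  row intervals within each; the counts are summed. The two-pass reading is
  cross-checked against a connected-component oracle in the tests; on
  touching objects the two counters can legitimately disagree, which is why
  their mean is reported.

**Threshold tuning.** The threshold is in raw response units and is tuned
per prototype by supervised learning against manually annotated frames
(at least 8 recommended, each containing both ordinary cells and
apoptotic-like objects). The loss is the mean absolute difference between
observed and predicted counts. Per cross-validation fold (4 folds, repeated
twice by default) the loss is minimized over 11 starting thresholds at the
deciles of the pooled supra-background response values, then refined by 20
golden-section iterations on the bracketing interval, ties breaking toward
the larger threshold (fewer detections, since the loss is piecewise
constant). If the median held-out loss exceeds 5 counts the tuning aborts as
overfitted and asks for more data; otherwise the final threshold is the
median of the fold optima.

# Quality control

**Intra-plate.** At the earliest (ideally pre-effect) frame all wells should
look alike, so each well's first-frame PHHC vector is compared with every
other well's by relative L1 distance ($\lVert h_i - h_j \rVert_1$ over the
mean of their masses; 2 for disjoint histograms). Wells whose median
distance exceeds `median + 3 * MAD` of all wells' medians are excluded from
everything downstream. The MAD rule is this package's automatic cutoff: it
is robust, parameter-free, and flags exactly the "deviating feature vector"
wells the procedure targets; the multiplier is configurable. With very tight
plates the MAD collapses and the rule can be strict — excluded wells are
reported, never silently dropped, and a condition left with a single
replicate simply skips inter-plate QC (its variability is undefined).

**Inter-plate.** For a condition replicated across plates, the variability
estimate is the area between the replicate growth curves:
$V_w = \sum_t \left(\Delta C_w^{\max}(t) - \Delta C_w^{\min}(t)\right)$,
with the max/min taken per time point. Its null distribution is obtained by
resampling: each of $N$ = 10000 simulations draws one untreated well per
plate (with replacement) and computes $V$; the 95th percentile $\tau_{95}$
of the simulated values is the threshold, so a true null condition is
flagged with 5% probability (both $N$ and the percentile are user
parameters). Conditions strictly above $\tau_{95}$ are outliers and are not
replicate-merged; survivors are merged by per-time mean with the standard
deviation and contributing replicate count recorded.

`qc_false_alarm_rate()` measures this operating characteristic end to end:
it simulates independent 4-plate experiments of untreated-model growth
curves (exponential growth, rate 0.02/h — about a 3.6-fold confluence gain
over the 64 h window — plus i.i.d. Gaussian noise, sd 0.05 on the
relative-change scale), builds the resampling null per experiment, and
tests held-out null conditions. Because a single experiment's threshold is
itself an estimate from a finite untreated pool, the reported rate averages
over 20 experiments (384-well untreated pools, 250 held-out conditions
each, 5000 in total) so its uncertainty is dominated by the binomial error
of the number tested. `scripts/acceptance.R` recomputes exactly this.

# Survival and synergy

The survival index normalizes end-point fluorescence per plate,
$S = (f - \tilde f_{blank}) / (\tilde f_{control} - \tilde f_{blank})$
with medians over blank and untreated wells. $S$ is deliberately not clamped
to $[0,1]$: growth stimulation can exceed 1, and scores computed from
out-of-range survivals carry a quality warning rather than being censored.

For a combination of $n$ drugs the Bliss index compares the observed
survival with the independence expectation,
$B = \prod_{i=1}^n S(c_i) - S(\mathbf c_n)$; positive values indicate
synergy. Because one $B$ value can arise from very different
(expected, observed) pairs, the scaled index
$B_S = B \cdot \left[1 - \min\{\textstyle\prod_i S(c_i), S(\mathbf c_n)\}\right]$
suppresses synergy claimed at high observed survival and antagonism
predicted at high expected survival; $|B_S| \le |B|$ with equality only when
the suppressing survival is 0.

Significance uses replicate resampling: a percentile bootstrap CI for $B_S$,
and a two-sided p value against a Bliss-independent null in which the
combination's replicates are replaced by products of independently resampled
single-drug replicate draws. This resampling design is this package's
construction (the choice of null ensemble is otherwise open), and
Benjamini-Hochberg FDR is reported across the combination family since a
9-drug order-4 screen scores 246 combinations. The table-level default of
1000 bootstrap draws keeps full-plate scoring interactive; raise `n_boot`
for publication-grade p values.

# Response mining

Per condition, four readouts — $\Delta C$, $\Delta M$, object counts (all
length $n$, the number of frames) and the scalar survival index expanded to
a constant $n$-vector — are each normalized by their own standard deviation
(a zero-spread block passes through unscaled) and concatenated into one
profile of length $N = 4n$. Only replicate-merged, QC-passed curves enter.

Profiles are grouped by top-down multilevel K-means: at each node,
K-means++ initialization with Lloyd iterations, best of $R = 10$ restarts,
for each candidate $K \in \{1, \dots, 10\}$; the selected $K$ is the
smallest whose SSE drop versus $K-1$,
$\Delta\hat E_{K-1\to K} = (\hat E_K - \hat E_{K-1}) / \hat E_{K-1} \cdot 100,$
falls below $-20\%$ (none → $K = 1$; a zero SSE stops the scan). The
"smallest K with a >20% drop" reading is the literal one; at the top level
it typically yields two main behavior groups, with recursion (default depth
2, minimum split size 8) supplying finer structure. $R$ is user-set; 10
restarts make the best-of-$R$ SSE stable on problems of this size.

Each group is summarized by its **smallest non-redundant representative
set**: iteratively take the lowest-order remaining combination (lexicographic
tie-break), keep it, and remove every remaining combination containing it.
The result is exactly the subset-minimal members (an antichain, verified
against a brute-force oracle), so a group driven by one drug collapses to
that single drug — this is what disentangles higher- from lower- and
single-drug effects. Group reports de-normalize the average blocks back to
original units for display.

# The synthetic-data generator

Every stage is testable without microscope data. The generator emulates:

* **Backgrounds:** a flat field plus Gaussian sensor noise quantized to
  8-bit gray levels (default sd 0.002, about half a gray level), matching
  the flat, low-noise background of phase-contrast wells; a pure-background
  frame then segments to well under 5% foreground.
* **Objects:** a bright elliptical ring with darker core (sizes around the
  33×32 px reference prototype), planted additively at known centers with
  exact ground truth; `random_centers()` enforces a minimum separation.
* **Wells:** seeded cell blobs growing exponentially (untreated rate 0.02/h
  from 1000 cells/well-like seeding of 12 blobs), with per-drug effect
  models (growth factor, progressive intensity drift driving morphology
  change, a linear apoptotic-object ramp, terminal viability). A
  combination inherits the most severe member effect on each axis unless an
  explicit higher-order boost is configured — exactly the
  "single drug explains the group" structure the subset search must detect.
  Note the planted apoptotic rings contribute foreground, so arrested wells
  show a small residual confluence rise, as debris does in real wells.
* **End points:** fluorescence proportional to terminal viability with
  multiplicative log-normal noise; replicate plates share effect models but
  re-draw all noise.

What passing on these fixtures does **not** show: robustness to optics
(PSF, vignetting, focus drift), to dense confluent textures, or to real
apoptotic morphology variation — the fixtures are geometric proxies. The
pipeline's statistical machinery (QC thresholds, synergy resampling,
K-selection) is exercised faithfully; the image models are deliberately
simple.

# Problem sizes and numerical choices

The test suite runs everything at fixture scale chosen for thorough yet
quick verification: 64–128 px frames, 3–17 frame series, 9×8–15×14
prototypes for oracle checks, 2-replicate end-to-end screens, 10000-draw
resampling nulls, and a 12-experiment (3000-condition) false-alarm
measurement; the acceptance script uses 20 experiments (5000 conditions).
Other conventions: intensities are finite doubles (NaN pixels are an input
error); quantile type is R's default (type 7); `V = tau` passes QC (strict
inequality flags); K-means uses 100 Lloyd iterations maximum; all random
draws derive from one master seed via fixed per-stream offsets.

# Limitations

Single fixed concentration per drug (no dose-response surfaces, by design);
Bliss-type end-point scoring only (no Loewe/therapeutic-window reference
model); no spatial plate-effect modeling beyond randomization; counting is
"sufficiently good localization", not per-cell accuracy — the matched filter
is linear and its threshold transfers only within a prototype/instrument
setting.
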