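---
title: "Models and methods behind punctacall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind punctacall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctacall)
```

# The measurement problem

Multiplexed fluorescent in situ hybridization (RNAscope) renders individual
transcripts as discrete puncta. To decide whether a cell expresses a probe
(*Chat*, *Vglut2*, *Fos*), a per-cell decision rule is needed that accounts
for non-specific background puncta; to decide whether a treatment changes
the fraction of expressing cells, an inference layer is needed that respects
the fact that ROIs (left/right PPN or LDT fields from one section) from the
same mouse are correlated. punctacall implements both, plus the image
processing in between and a synthetic-data generator that makes the whole
chain testable against known ground truth.

# The binomial positivity model

The calling statistic treats every pixel of a cell as an independent
Bernoulli trial under the null hypothesis that the cell contains no real
signal, only background. With

* $n$ — the cell's pixel area (DAPI-derived component dilated by 2 px),
* $p$ — the per-pixel background rate, estimated as the fraction of
  *non-cell* pixels that are puncta-positive for that probe,
* $k$ — the puncta-positive pixel volume inside the cell,

the p-value is the exact upper tail $P(X \ge k)$ for
$X \sim \mathrm{Binomial}(n, p)$, computed without normal approximation.
A cell is positive when $p\text{-value} < \alpha / n_{\text{cells}}$ with
$\alpha = 0.01$: a Bonferroni correction whose divisor is the number of
segmented cells in that ROI (not cells × probes — each probe is its own
family). Two parametrizations were genuinely open:

* **pixels vs punctum objects** — the default tests puncta-positive
  *pixels* against a per-pixel background rate, which keeps the numerator
  and the background estimate in the same units; an object-count variant is
  available via `call_cells(..., statistic = "objects")`.
* **%Fos transcript averaging** — `fos_transcript_pct` is
  $100 \cdot \text{Fos pixel volume} / \text{cell pixel volume}$ (clipped to
  the cell, hence in $[0, 100]$). ROI summaries average it over *activated*
  (Fos+) cells of each type by default, matching how the metric is reported
  for activated populations; `fos_pct_over = "all"` switches to all cells of
  the type.

Under the null the test is exact and conservative (discreteness), so the
per-ROI family-wise positive rate is at most $\alpha$; the acceptance suite
verifies this on 500 simulated null ROIs.

# Segmentation choices

* Background subtraction is a morphological white top-hat with a disc
  (default radius 50 px for full-size micrographs; the pipeline uses 15 px
  on its 256 px synthetic frames). A constant or tilted-plane background
  maps to (near) zero; features narrower than the disc survive.
* Grayscale conversion takes the HSV value component (per-pixel channel
  maximum), the natural reduction for fluorescence composites.
* The Otsu threshold is an exhaustive search over all 256-bin histogram
  cuts for the maximizer of between-class variance, with disjoint classes
  (bins $\le t$ vs $> t$). This is implemented in the package directly: the
  installed image library's Otsu routine includes the candidate bin in both
  classes and can return a threshold far from the true maximizer, which the
  property test against an independent plain-loop oracle rejects.
* Connected components default to 8-connectivity (4 available); components
  under `min_area = 20` px are discarded as debris; labels are assigned in
  raster-scan order of each component's first pixel so segmentation is
  fully deterministic and rotation-equivariant.
* Touching nuclei are *not* split (no watershed); the synthetic generator
  spaces nuclei accordingly. Registration across serial sections is treated
  as identity: ROIs enter pre-cropped.
* Cell area = nucleus dilated by 2 px (configurable), approximating
  cytoplasmic capture; probe intensity plays no role in cell-area
  definition.

# Puncta quantification

Puncta are connected supra-threshold components (Otsu or fixed threshold,
`min_size` default 1 px). A punctum belongs to the cell containing its
centroid — containment, not any-overlap, so nothing is double counted; the
per-cell *pixel volume* is clipped at the cell boundary. Puncta whose
centroids fall on background feed the background-rate estimate
$\hat p = \text{puncta-positive background px} / \text{background px}$,
the same per-pixel units the binomial null uses. Total detected puncta
always equal per-cell puncta plus background puncta. Note one subtlety the
tests spell out: total puncta-positive *volume* is monotone in the
detection threshold, but component *counts* need not be (a blob can split);
counts are monotone once spots are isolated.

# ROI quality control

Two screens run in a fixed order. First the cell-count bounds: an ROI is
kept iff its cholinergic count lies in $[20, 250]$ (IHC) or $[20, 300]$
(RNAscope) — "fewer than 20 or more than 300" read literally, so boundary
counts stay. Then, on the survivors only, the outlier rule: a value is
excluded only when it is outside the $1.5\times$IQR fences (type-7 linear
interpolation quartiles) **and** $|z| > 2.68$, with $z$ computed from the
stratum mean and SD including the candidate. Two consequences worth
knowing:

* With the candidate included, $|z|$ cannot exceed $(n-1)/\sqrt{n}$, so in
  strata of $n \le 9$ the conjunctive rule can never fire; a leave-one-out
  z variant is available behind `qc_config(leave_one_out = TRUE)`.
* The conjunction excludes a subset of what either rule alone would; the
  screen runs exactly once (no iterative re-screening after removal).

The stratum is sex × treatment × region × day (the comparison cell), and
the screened metric defaults to the percent of activated cholinergic
neurons — both configurable, since neither is dictated by the procedure
itself. The quartile method and the one-pass policy are recorded in the
exclusion log.

# Nested and mixed statistics

ROIs within a mouse share the mouse: treating them as independent inflates
type-I error. The nested one-way ANOVA therefore uses the mouse-within-group
mean square as the error term, $F = MS_{\text{group}} / MS_{\text{mouse}}$
with $(k-1,\ M-k)$ degrees of freedom ($M$ = mice). On balanced data this
is computed from expected mean squares and is *identical* to an ordinary
one-way ANOVA on mouse means (enforced to $10^{-6}$ in the tests);
unbalanced data fall back to a linear mixed model with a random mouse
intercept and Satterthwaite denominator df — one coherent contract covering
both. The nested t-test is the $k = 2$ special case,
$t = \mathrm{sign}(\Delta)\sqrt{F}$, $t^2 = F$ to $10^{-9}$. Tukey HSD
post-hocs use the studentized range on mouse means with the pooled
within-group mouse-mean variance and mouse-level df (Tukey–Kramer SEs when
group sizes differ); planned pairwise comparisons use a pooled error with
Bonferroni correction over the requested pairs.

The sex × treatment layer fits
`outcome ~ sex * treatment + (1 | mouse)` with sum-to-zero contrasts and
Type III F tests (Satterthwaite, hence the fractional denominator df
typical of such reports; Kenward–Roger would be the alternative — the
choice is documented, not asserted as canonical). A *qualitative* sex
difference — significant interaction with opposite-sign simple effects in
males and females — flags that downstream analyses should run separately by
sex, which the pipeline then does. Singular fits (zero random-effect
variance) are reported, not hidden; an all-constant outcome short-circuits
to $F = 0,\ p = 1$. Significance is 0.05 two-sided throughout; no
additional FDR layer is applied.

Calibration under a correlated-ROI null (ICC 0.3, 4 mice × 4 ROIs per
group) keeps the nested test at the nominal 0.05 while the naive ROI-level
ANOVA runs near 0.17 — the acceptance suite demonstrates both on 800
replicates.

# The synthetic generator

What it emulates: the group structure (sex, treatment, dose, day), mice
within groups, ROIs within mice, four latent cell types, treatment- and
type-dependent activation, Poisson per-cell signal puncta over a per-pixel
Bernoulli background — the simplest model consistent with the binomial
test — and a logit-normal mouse random effect inducing within-mouse
correlation. Nuclei are non-overlapping discs (radius 6–8 px) with the cell
area a 2 px dilation; puncta are single bright pixels; all randomness flows
through one explicit seed, and identical seeds give bit-identical output.

Defaults and where they come from:

* **Type mixture** (0.16, 0.46, 0.06, 0.32 for chat-only / vglut-only /
  co-label / neither): solved from two observed co-label shares — co-labeled
  cells ≈ 27% of Chat+ cells and ≈ 11.5% of Vglut2+ cells.
* **Activation probabilities**: chronic-study group means per type
  (cholinergic 0.507/0.668 saline/ethanol, glutamatergic 0.417/0.631,
  co-labeled ≈ 0.88 in both — constitutively active); the `neither` class
  (0.30) is unreported and a free choice.
* **Signal rates**: marker probes 30 puncta/cell; *Fos* 12 puncta ≈ 4% of
  the ~250 px default cell area, putting %Fos transcript in the reported
  few-percent range. No study reports these microscopic quantities; they
  are free parameters, chosen so signal is clearly separable from the
  5e-4/px background (also a free parameter).
* **Mouse random effect** (`mouse_sd = 0.2`, logit scale): back-solved from
  the scale of reported nested t statistics (~3.8 for a 16-point effect at
  4–5 mice/group). The implied total per-mouse SD is ≈ 6.3 percentage
  points; subtracting the within-mouse binomial ROI-sampling component
  (≈ 4 points at 25–50 cholinergic cells/ROI × 4 ROIs) leaves ≈ 4.9 points
  for the random effect, ≈ 0.2 on the logit scale at p ≈ 0.6.

What it does **not** emulate: point-spread optics, autofluorescence,
z-stacks, tissue morphology beyond packed discs, touching or overlapping
nuclei, segmentation errors correlated with cell type, or chromatic
registration error. Passing tests therefore certify the *computational*
chain — segmentation recovers well-separated nuclei, the caller is exact,
the statistics are calibrated — not robustness to every optical artifact of
real micrographs.

# Problem sizes and numerical choices

The validation suite uses 256–320 px frames with 10–50 cells for image
runs, and table-mode studies (the same latent model without rendering) for
the replicated simulations: 500 null ROIs for error control, 100 replicate
studies of 5 mice/group × 4 ROIs × 150–300 cells for recovery and power,
800 replicates for the ICC calibration. These sizes give stable Monte Carlo
estimates while keeping a full run in tens of seconds; the generator scales
to larger frames by raising `image_size`/`n_cells` together (packing is
rejected past 50% area occupancy). Ties in the Otsu search break to the
first maximizer; degenerate inputs fail loudly (constant images have no
Otsu threshold, empty cells yield p = 1, a group with one mouse has no
error term, zero-SD strata produce no z-exclusions).

# Known limitations

* Touching nuclei are merged (no watershed), so dense tissue needs either
  spacing or an upstream splitter.
* Background rates are per-ROI and per-probe scalars; spatially varying
  background is only handled through the top-hat subtraction.
* The greedy centroid matcher used for validation assumes spacing ≥ the
  gate diameter (true for the generator); it is a validation tool, not a
  tracking algorithm.
* The IHC arm shares the activation logic via an intensity threshold
  (`ihc_activated`) rather than a stain-specific model.
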