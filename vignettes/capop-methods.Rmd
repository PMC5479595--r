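---
title: "From fluorescence movies to neuronal assemblies: the capop methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From fluorescence movies to neuronal assemblies: the capop methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capop)
```

capop is a scriptable pipeline for population calcium imaging: it takes a
raw fluorescence movie and produces registered frames, single-neuron ROIs,
neuropil-corrected ΔF/F0 traces, statistically significant calcium
transients, event-locked tuning maps, and non-exclusive neuronal
assemblies validated against surrogate nulls. This vignette explains the
models and the numerical choices behind each stage, what the synthetic
generator does and does not emulate, and the limitations a user should
keep in mind.

## Registration and artifact flagging

Rigid in-plane drift is estimated per frame by FFT cross-correlation
against a template (by default the mean of the 100 frames with the highest
mutual correlation, which is robust to calcium transients). The
correlation peak is refined to sub-pixel precision by parabolic
interpolation, and the raw displacement series is smoothed with a centered
moving average (default width 1 s) — frame-to-frame jitter in the
*estimate* is noise, while true drift is slow. Frames are re-sampled with
bilinear interpolation; pixels pulled in from outside the field are marked
invalid (`NA`) and ignored by all trace statistics.

A frame is flagged as a motion artifact when its correlation with the
template falls below `median - max(3*MAD, 0.05)` (the 0.05 floor prevents
flagging immaterial fluctuations on very stable recordings) or when the
residual displacement left after smoothing exceeds 5 px. Flagged frames
are masked, not dropped, so frame indices and event times stay aligned.
Only rigid x–y translation is modeled; rotation, non-rigid deformation and
axial (z) motion are out of scope — z-artifacts are expected to be caught
by the quality flag instead.

## Segmentation

Segmentation operates on the time-averaged image after local-contrast
normalization: `(I - local_min) / (local_range + eps)` over a disc
neighborhood (`local_contrast` pixels, typically 10–40 depending on cell
size). Min/max filters commute with increasing affine maps, so the result
is exactly invariant to global gain and offset changes, and slow
illumination gradients are flattened.

Two labeling regimes are supported:

* **labeled_nuclei** (filled bright somata, e.g. synthetic dyes or
  nuclear-localized reporters): threshold at `thr_soma`, split touching
  cells with a distance-transform watershed, then exclude pixels below the
  neuropil border threshold `thr_neuropil`.
* **unlabeled_nuclei** (cytosolic reporters excluded from the nucleus,
  giving a bright ring around a dark center): nucleus seeds are connected
  components below `thr_soma` whose dilated shell is mostly above
  `thr_neuropil`; seeds grow onto the surrounding ring by geodesic
  propagation, so touching cells stay disjoint. The `roi_size_opt`
  presets ("bigger"/"smaller") set the growth radius (3 vs 1.5 µm,
  converted through the pixel size).

Candidate ROIs are then filtered on area, mean normalized intensity, and
perimeter circularity `P²/(4πA)` (1 for a circle; useful bounds bracket
1, e.g. 0.5–1.7). The filter is idempotent. Where single-cell resolution
is not available, `hexagonal_grid()` tiles the field (or a mask) with
pointy-top hexagons of a given diameter; border hexagons are kept only if
at least half of their nominal area survives clipping — a convention
chosen so that grid statistics are not dominated by slivers.

## Traces, neuropil correction and ΔF/F0

A ROI trace is the plain mean over its pixels (no weighting — the mask is
already the shape estimate). Limited optical resolution mixes diffuse
neuropil fluorescence into somatic signals, `F_measured = F_soma +
α·F_neuropil`. The local neuropil signal of each ROI is measured in a
perisomatic disk (default radius 20 µm) centered on the ROI, minus the
pixels of *all* detected ROIs, and subtracted as `F - α·F_np`. The default
α = 0.9 reflects common practice for dense cortical tissue, but the right
value is preparation-dependent and deliberately exposed; `sanity_check()`
flags over-subtraction (negative fluorescence), saturation, and flat
traces.

F0 can be a windowed mean (typically the seconds before each stimulus) or
the slow baseline `F_smooth`: a running 8th percentile over a sliding
window (default 30 s, validated against the indicator decay constant —
the window must dominate τ or transients leak into the baseline), smoothed
by a moving average of the same width. A low percentile sits
`qnorm(p)·σ` below the true baseline under Gaussian noise; capop adds that
offset back (with σ estimated robustly from the residuals by MAD), so
transient-free ΔF/F0 is centred on zero rather than biased positive.

## Significant transients

The noise scale σ of each ROI is estimated from the *negative* ΔF/F0
fluctuations, which contain no calcium signal: locate the distribution
mode (kernel-density mode, ties to the lower mode), reflect the
sub-mode samples about it, and take the SD — equivalent to fitting a
Gaussian to the negative side. The alternative `trimmed_sd` discards the
top 10% of samples and divides by the SD of a correspondingly truncated
unit normal, so it too is unbiased on pure noise.

The **static** detector marks `dff - mu > k·σ` (default k = 3): simple and
fast, with the Gaussian-tail false-positive rate you would expect.

The **dynamic** detector imposes two conditions. (i) A candidate rise: a
transition between frames (over one or two frames, for events straddling a
frame boundary) exceeding the one-sided noise-transition quantile at the
requested confidence — under independent Gaussian noise, transitions have
scale σ√2. (ii) A decay compatible with the indicator: from the peak
(which, under the instantaneous-rise model, sits within two frames of the
rise), the expected decay lasts until `amp·exp(-Δ/τ)` re-enters the z·σ
band around baseline; over that window the odds ratio between the
exponential-decay transient model and pure baseline noise must exceed
`confidence/(1-confidence)`. The window is truncated before the next
candidate rise on a fixed (95% quantile) segmentation of the trace — this
prevents a later genuine event from vouching for an unrelated earlier
noise rise, and keeping the segmentation fixed makes specificity monotone
in the confidence parameter. Events mark frames significant from the rise
to the envelope's return to baseline; `masked_dff` zeroes everything else.

Numerical notes: noise is assumed independent between frames (σ√2
transition scale) — strongly autocorrelated noise would need a wider
quantile; the single-exponential kernel ignores the indicator rise time
(≈45 ms for GCaMP6f), adequate at frame periods above ~15 ms; τ defaults
to 0.25 s (GCaMP6f) and must be supplied for other indicators. A spike is
"associated" with a calcium event when significant fluorescence occurs
within 40 ms after it — an ongoing summating transient counts, which is
why burst spikes are easier to detect than isolated single spikes.

## Event-locked responses and HSV maps

Peri-event windows `[t-pre, t+post)` are grouped by stimulus value. The
scalar response per trial is the mean ΔF/F0 over the post-event window
(configurable to the peak); by default responses are taken from
`masked_dff`, so only statistically significant fluorescence contributes.
A ROI counts as responsive only if some stimulus value reaches at least 2
significant trials: a single significant trial is indistinguishable from a
spontaneous transient landing in the window. Unresponsive ROIs get tuning
width equal to the grid span, hence zero map saturation (whitish).

Tuning width is the full width at half maximum of the trial-averaged
curve above its minimum, linearly interpolated between grid points and
clamped to the grid span; the preferred value `v_peak` is the grid argmax
(lowest value on ties). The HSV map encodes `v_peak` as hue (scaled onto
[0, 0.75] of the wheel so the two grid extremes are not confusably
similar — the variable must be continuous and parametric; cyclic
variables such as motion direction wrap and are unsupported), selectivity
`1 - width/span` as saturation, and `peak_amp / max(peak_amp)` as value,
each after a monotone clip/offset rescale that handles heavily skewed
response distributions; optionally amplitude also drives transparency so
weak noisy responses fade.

## Non-exclusive assemblies: PCA-promax

Each ROI's activity (raw ΔF/F0 or significant transients only) is
z-scored over valid frames, and the ROI×ROI correlation matrix is
eigen-decomposed. Components are retained when their eigenvalue exceeds

λ_max = (1 + √(N/T))² + N^(−2/3),

the Marčenko–Pastur upper edge of the eigenvalue spectrum of an N×T
random matrix plus a Tracy–Widom-scale finite-size correction. Below this
bound an eigenvalue is indistinguishable from noise; on i.i.d. data
essentially nothing is retained, and each genuinely correlated group
contributes one component. The correction term is configurable off.

Retained loadings are rotated: Kaiser-normalized varimax followed by a
promax oblique rotation of power κ = 4 (the conventional default; larger
κ gives sparser, more correlated components). Obliqueness is the point:
assemblies may share neurons, which no orthogonal basis can express.
Component signs are set so the dominant loading is positive. Loadings are
z-scored per component (across ROIs, so maxima are comparable between
components) and a ROI joins an assembly when its z-scored loading exceeds
zMax. The automatic zMax is the first local minimum of the kernel density
of per-ROI maximal loadings after its leftmost mode — the valley
between the non-member bulk and the member tail (bandwidth = Silverman's
rule times a user `smooth` factor); if the density is unimodal the
package refuses to guess and asks for a manual value.

Assemblies whose unit components have dot product > 0.6 are merged
(union of members, renormalized mean component; the scan restarts after
each merge, taking the largest dot product first with ties to the lower
index pair — a deterministic order). Finally, each assembly must beat
membership-shuffled nulls on *both* statistics: mean pairwise member
correlation, and peak count of co-active members per frame (co-active =
z > 2), with empirical p-values `(1 + #{null ≥ obs})/(1 + n_shuffle)` and
p < 0.05 on each. The shuffle keeps every ROI's activity intact and only
randomizes membership, so it tests the grouping, not the signals.
k-means (10 restarts, best inertia, seeded) and hierarchical clustering
(correlation distance, average linkage) are provided as exclusive
baselines; by construction they cannot assign a neuron to two assemblies.

## Surrogate assembly nulls

Two membership nulls are built, both preserving the recorded dynamics of
every ROI. **RSA** (random surrogate assemblies) draw the same number of
ROIs uniformly. **TSA** (topographical surrogate assemblies) re-place the
original constellation under a random rigid transform (rotation, optional
reflection, translation constrained to the span of the ROI centroids),
snap each point to the nearest unused ROI centroid, and accept the
replicate only if the two-sample Kolmogorov–Smirnov distance between
original and surrogate pairwise-distance distributions is ≤ 0.1, so
every emitted TSA preserves the spatial statistics of the original.
`pool_compare()` pools any per-ROI or per-pair feature (mean activity,
pairwise correlation, pairwise distance, or user-supplied) over original
vs surrogate assemblies, returning shared-bin Freedman–Diaconis
histograms and a KS p-value. The canonical use: assemblies should group
*correlated* ROIs far beyond RSA, while showing no bias in mean activity
relative to TSA.

## The synthetic generator, and what passing tests mean

`make_cells()` places non-overlapping disk (nucleus-labeled) or ring
(cytosol-labeled) somata by dart throwing with a minimal gap.
`make_activity()` superimposes background Poisson spiking, assembly
events (rate per assembly; each event recruits each member with
probability `within_prob`, default 0.3), and optionally stimulus-locked
spiking with Gaussian tuning around per-cell preferred values; spikes are
convolved with an instantaneous-rise, exponential-decay kernel
(`amplitude·exp(-t/τ)`, computed by an exact recursive filter), then
multiplicative drift and Gaussian noise are added. `render_movie()`
composites cells over a background with a shared low-passed
population-mean neuropil signal (scaled by 0.9 inside cells to emulate
partial-volume contamination), per-frame rigid jitter and pixel noise.
Everything is bit-reproducible from its seed.

The benchmark conditions used by the test suite and the acceptance script
are fixed once: 500 ROIs with 8 planted assemblies of 20–40 members (two
sharing 5 ROIs, event rate 0.3 Hz, recruitment 0.3, background 0.02 Hz,
600 s at 5 Hz) for assembly recovery; 60 Hz, τ = 250 ms, 4σ-amplitude
events for transient inference; 50 cells per labeling regime on a
160×160 µm field for segmentation; a −45°…45° stimulus grid in 5° steps
with 3 trials per value for tuning maps. These sizes keep every check
under a few tens of seconds on one CPU while leaving the statistics
well-resolved.

The generator emulates the features each stage depends on — it does not
emulate real tissue. Missing, deliberately: indicator saturation and
nonlinearity (Hill kinetics), finite rise time, photobleaching beyond a
linear drift, shot (Poisson) noise statistics, overlapping cells in
depth, dendritic/axonal signal, and non-rigid motion. Passing the
closed-loop tests therefore shows the algorithms are correct under their
own model assumptions and calibrated noise; it does not certify
performance on any particular microscope or indicator, for which the
exposed parameters (α, τ, thresholds, windows) exist.

## Known limitations

* Registration is rigid and in-plane only.
* The transient model assumes instantaneous rise and independent Gaussian
  noise; heavily autocorrelated noise inflates the false-positive rate.
* The eigenvalue threshold assumes T ≥ N (warned otherwise); very short
  recordings cannot support assembly detection.
* The automatic zMax requires a bimodal loading-maxima distribution; on
  structureless data it deliberately errors rather than guessing.
* Cyclic stimulus variables are not supported by the HSV mapping.
* Multi-plane volumes are handled one plane at a time (one `movie_stack`
  and `roi_map` per plane) with ROIs concatenated for assembly analysis;
  there is no axial ROI fusion.
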