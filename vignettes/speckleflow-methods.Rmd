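---
title: "Models and methods behind speckleflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind speckleflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

speckleflow implements three quantification pipelines used in cortical
hemodynamic imaging of rodents — resting-state cerebral blood flow (CBF)
mapping by laser speckle contrast imaging, stimulus-evoked
neurovascular-coupling (NVC) quantification, and confocal vessel
morphometry — together with synthetic-data generators that carry exact
ground truth. This vignette explains the models, the tunable parameters,
the numerical choices, and what the synthetic validation does and does not
establish about real data.

## Speckle flowmetry

### The contrast model

Coherent light backscattered from moving red blood cells forms a speckle
pattern that decorrelates with a field correlation time $\tau_c$ inversely
related to scatterer speed. Integrating the intensity over a camera
exposure $T$ blurs the pattern, reducing the speckle contrast
$K = s/m$ (standard deviation over mean). For an exponentially
decorrelating field (Lorentzian spectrum) the squared contrast is

$$K^2(T, \tau_c) = \beta\,\frac{e^{-2x} - 1 + 2x}{2x^2},
  \qquad x = T/\tau_c,$$

implemented in `speckle_contrast_theory()`. $\beta \in (0, 1]$ is the
speckle-averaging factor (pixel/speckle size mismatch, polarization,
coherence). The package reports the conventional relative flow index

$$\mathrm{CBF} = \frac{\beta}{2\,T\,K^2},$$

which is proportional to $1/\tau_c$ in the strong-blurring regime but is
*not* an absolute perfusion; no attempt is made to calibrate it to
physical units.

### Temporal contrast and its estimator

`temporal_contrast()` computes $K$ per pixel over the frame axis, which
suppresses static scattering (e.g. from the intact skull): a static
contribution has no temporal variance. The sample standard deviation uses
the $n-1$ denominator — at the default 60 frames the distinction is small
but the unbiased variance is the defensible default. Pixels with zero
temporal mean are flagged invalid rather than mapped to infinite contrast,
and stay excluded from all downstream medians.

Motion-artifact frames are rejected before contrast estimation
(`reject_motion_frames()`): a frame is dropped when its global mean
intensity deviates from the median of all frame means by more than
`k_mad` (default 5) robust standard deviations (MAD $\times$ 1.4826).
This concrete criterion is this package's choice — published protocols
reject motion frames but do not fix a rule — and it is configurable. Note
a robust rule can flag at most half the frames by construction; a
separate `min_frames` guard (default 10) aborts when too few survive.

### Beta calibration

A static scene has near-zero *temporal* contrast, so $\beta$ cannot be
estimated temporally. `estimate_beta()` therefore uses the *spatial*
contrast of the time-averaged frame of a static phantom: $(s/m)^2$ over
every `window`-sized region fully inside the image, summarized by the
median across windows (robust to dust and slow illumination gradients).
The window statistic is right-skewed, and its median under-reads
$\beta$ by about 7% for 7 x 7 windows on fully developed speckle; the
default `window = 15` keeps that skew bias below ~2% while remaining
local. Estimates above 1.05 or at 0 raise calibration errors.

### Synthetic dynamic speckle

`simulate_dynamic_speckle()` evolves a complex circular-Gaussian field
per pixel as an Ornstein-Uhlenbeck process (exact discrete transitions,
so $g_1(\tau) = e^{-\tau/\tau_c}$ holds at any step size) and integrates
$|E|^2$ over the exposure with at least 10 sub-steps per frame and at
least 10 sub-steps per correlation time. $\beta < 1$ is realized
physically — by averaging $m = \mathrm{round}(1/\beta)$ independent
speckle intensities per pixel, the pixel/speckle mismatch mechanism — so
the dynamic closed form remains valid; realizable targets are $1/m$ and
the truth records the realized value.

One subtlety governs the validation design: the closed form predicts the
contrast of a *single* exposure, while the temporal estimator uses the
sample variance across frames. When frames are spaced closer than
$\tau_c$, their intensities are correlated and the sample variance is
biased low (about 8% at $\tau_c = 10T$ with 60 fps spacing). The
generator therefore exposes `frame_interval`, and the package's
validation simulations space frames at $\ge 10\,\tau_c$ so successive
exposures are effectively independent draws; the acquisition-realistic
60 fps spacing remains the default for ordinary use.

Validation sizes: the simulator-versus-theory comparison uses
$100 \times 100$ pixels $\times$ 60 frames at
$\tau_c/T \in \{0.1, 0.5, 1, 2, 10\}$ (agreement within 5%, typically
within 2%), and the parameter-recovery sweep uses $60 \times 60$ pixels
over $\tau_c/T \in \{0.5, 1, 2, 5, 10\}$, checking that ROI-median CBF
decreases strictly in $\tau_c$ and that CBF ratios between $\tau_c$ and
$2\tau_c$ match the closed-form prediction within 10%.

## Neurovascular coupling

The stimulation protocol (`stim_protocol()`) defaults to forty 15-s
trials — 2 s baseline, 2 s stimulation, 11 s recovery — imaged at 50 fps.
Frame $k$ carries time $t = (k-1)/\mathrm{rate}$ from trial start;
**baseline** frames are $t < t_\mathrm{on}$ and **stimulation** frames
are $t_\mathrm{on} \le t \le t_\mathrm{off}$ (closed interval). The
closed convention is deliberate: it makes the trapezoidal integral of a
plateau response over the stimulation window exactly
$\mathrm{amplitude} \times \mathrm{stim\_s}$, removing an off-by-one-frame
bias from the AUC.

The pipeline is: `downsample_windows()` (non-overlapping 15 x 15 *pixel*
tiles, each replaced by its mean; the alternative reading — a 15 x 15
output *grid* — was rejected as the tile size is what controls
signal-to-noise; partial edge tiles are dropped), `segment_trials()`
(trigger-aligned blocks; incomplete trials rejected whole and logged,
never padded), `select_responders()` and `average_response()`.

Responder selection ranks windows by the baseline-normalized mean CBF
increase during stimulation, $(\bar{x}_\mathrm{stim} -
\bar{x}_\mathrm{base})/\bar{x}_\mathrm{base}$, and keeps the top
$\lceil \mathrm{fraction} \cdot n \rceil$ windows (default fraction
0.10), with ties broken by row-major window index so selection is
deterministic. The ranking metric is a package choice — "largest
response" is not otherwise defined — and since ranking by raw
$\Delta$CBF differs only by a per-window monotone factor, the
percent-based metric was fixed as the default.

Per trial, the selected windows' raw courses are averaged first, then
normalized to percent change against the trial's own 2-s baseline mean
(so each per-trial course has exactly zero baseline mean); trials are
then averaged unweighted. The companion $\Delta$CBF course subtracts the
baseline mean without dividing; on a uniform baseline $b$ it equals
$b/100$ times the percent course identically, which the tests assert.
Metrics: the peak is searched over the whole trial (responses can peak
just after stimulus offset), AUC is the trapezoidal integral over the
stimulation window only, and time-to-peak is measured from stimulus
onset.

The synthetic generator (`generate_nvc_trials()`) emits a continuous
windowed recording with known responder set, amplitude, and i.i.d.
Gaussian noise, with two response shapes: a plateau (amplitude held over
the stimulation window) and a gamma-variate transient
$A\,(t'/t_p)^\alpha e^{\alpha(1 - t'/t_p)}$ with $\alpha = 3$, onset
0.2 s after stimulus start and peak 1.5 s after it — fixed, plausible
hemodynamic values; the response model is otherwise unconstrained.
Validation: with 15% amplitude, 2% noise and 40 trials the recovered
peak is within 1 percentage point; across amplitudes 5–20% recovery is
within 10% relative and strictly ordered.

## Vessel morphometry

`make_mips()` partitions a confocal z-stack into slabs of
$\lfloor \mathrm{slab}/\Delta z \rfloor$ slices (default 70 um) and takes
pixelwise maxima; a trailing remainder shorter than half a slab is
discarded, otherwise kept as a thin MIP, either way logged.
`consensus_roi()` implements the strict-majority reader vote (2-of-3),
guaranteed to lie between the intersection and union of the reader masks.

Binarization uses the iterative-selection (Ridler–Calvard/ISODATA)
threshold within the consensus ROI only. Iteration of
$t \leftarrow (\mu_{<t} + \mu_{\ge t})/2$ stops when the induced
below/above partition stops changing; since the midpoint depends only on
the partition, the returned $t$ is then an exact fixed point of the
update map (a stop on the step size alone can exit one step early, which
the tests caught against an exhaustive integer-threshold oracle).
Foreground is `image >= t`.

All component operations use 8-connectivity (standard for thin
structures). The size filter removes components *strictly* smaller than
51 um^2 — an exactly-51 component is kept. Skeletonization is iterative
Zhang–Suen-type thinning; it preserves component count and produces
centerlines free of 2 x 2 blocks, at the cost of the usual end-effect:
a bar of width $w$ loses roughly $w$ pixels of centerline at its two
ends combined, a bias that is negligible for vessels much longer than
wide (the validation phantoms use full-canvas vessels, where the density
error stays near 1%). `segment_skeleton()` splits the skeleton at pixels
with three or more neighbours into branch-free polylines whose length
sums 1 per axial and $\sqrt 2$ per diagonal step.

Local diameter at a skeleton point is estimated from the Euclidean
distance transform as $2d - 1$ pixels, where $d$ is the distance from
the skeleton pixel center to the nearest background pixel center: for a
bar of odd pixel width this is exact, and for even widths it is 1 px
low — inside the 1-px validation tolerance. Each segment contributes a
single value, its mean diameter, so long vessels do not dominate the
distribution. Vessel density pools the `n_select = 5` MIPs with the
longest total skeleton length (matching the 7–12 MIPs available per
animal) as total length over total ROI area. Diameter histograms use
1-um bins on $(0, 12]$ um — the microvascular display range — and are
normalized to the modal bin, so the maximum normalized count is exactly
1 for any nonempty input.

The vessel phantom generator draws straight capsules (centerline plus
round caps) of known width, length and intensity, with optional Gaussian
blur and noise. Curved or branching vessels, intensity falloff along
vessels, depth-dependent blur and labelling dropouts are *not* modelled;
recovery on these phantoms therefore validates the raster geometry,
thresholding, thinning and distance-transform logic, not robustness to
the full variability of lectin-labelled tissue.

## Group statistics

`two_sample_t()` is the Welch unequal-variance test ("t-test" alone does
not fix a variant; Welch is the safer default), with fixed conventions
for zero-variance degeneracies. `ks_two_sample()` defaults to the
two-sample Kolmogorov–Smirnov test on raw per-segment diameter samples —
the statistically faithful comparison — and offers a `histogram` mode
that compares mode-normalized binned curves for figure parity, using the
asymptotic Kolmogorov distribution with effective size
$n_a n_b/(n_a + n_b)$.

One calibration fact is worth stating plainly: with $n = 20$ per group
the KS statistic lives on the lattice $k/20$, and the smallest
attainable rejection region at $\alpha = 0.05$ is $D \ge 0.45$, whose
exact null mass is about 0.034 (`psmirnov`). The test is therefore
conservative at this sample size — its empirical null rejection rate is
~0.034, not 0.05 — for *any* implementation; the suite checks the
empirical rate against this exact lattice value. The Welch test is
calibrated to 0.05 within Monte-Carlo error.

`fit_log_trend()` fits $\mathrm{CBF} = a + b \ln(\mathrm{age})$ by least
squares through per-group means. It is a descriptive guide-the-eye
summary only; no inference is attached.

## Reproducibility and I/O

Every generator takes an explicit seed and is a pure function of its
spec: outputs are bit-identical across calls and the global RNG state is
restored afterwards. Image data travel as multi-page TIFF with a YAML
sidecar; because the TIFF container stores samples in $[0,1]$, float
maps are max-scaled on write with the scale factor recorded in the
sidecar (round trips are lossless to 32-bit float precision). Tables are
CSV with shortest round-trip numeric formatting, so identical runs
produce byte-identical files; each `write_outputs()` run also records
its resolved configuration and an MD5 manifest.

## Known limitations

- The flow index is relative; comparisons across instruments or optical
  configurations require a shared beta phantom and identical exposure.
- The speckle simulator models a single dynamic scattering population;
  there is no static-plus-dynamic mixture, no skull/tissue layering, and
  no point-spread function beyond the beta averaging mechanism.
- The motion-rejection rule is a stand-in for unpublished protocol
  details and should be tuned (`k_mad`) per acquisition.
- Thinning end-effects shorten centerlines by about one vessel width per
  vessel; density is slightly underestimated for short, thick segments.
- The KS comparison is conservative at small group sizes (see above).
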