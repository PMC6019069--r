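---
title: "Methods: circuit bridges, calcium phenotypes and the behavioural balance point"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circuit bridges, calcium phenotypes and the behavioural balance point}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthgauge)
```

This vignette documents the models, parameters and numerical choices
behind `depthgauge`, and what the synthetic generators do and do not
emulate.

## The scientific setting

Planktonic larvae of marine annelids carry two photoreceptor systems with
antagonistic behavioural outputs. Pigmented rhabdomeric photoreceptors
(rPRCs, in eyespots and adult eyes) compare light across body sides and
drive directional phototaxis — upward swimming toward downwelling light.
Non-pigmented, UV-sensitive ciliary photoreceptors (cPRCs) in the brain
drive a non-directional avoidance response — downward swimming — that
engages with a latency of roughly one minute. Because UV-violet light
attenuates faster with depth than blue light, the UV/blue photon ratio
encodes depth; the fraction at which the two drives cancel is the larva's
*balance point*, and the whole arrangement acts as a ratio-chromatic depth
gauge. The package provides the computational chain for studying this
system at three levels: wiring (connectome bridge paths), physiology
(calcium-imaging phenotypes) and behaviour (vertical-swimming analysis).

## Bridge-path search

The connectome is a square nonnegative-integer matrix of directed synapse
counts, rows presynaptic and columns postsynaptic, aligned to a
cell-annotation table with a controlled vocabulary of cell classes. The
two circuits are defined as class sets: the cPRC circuit is the four
cPRCs plus everything directly postsynaptic to them (RGW and NOS
interneurons, flask sensory neurons, Ser-h1, MC), the rPRC circuit is the
eyespot and adult-eye photoreceptors with their interneurons (IN_pro,
IN_sn) and ventral motoneurons.

`findBridgePaths()` enumerates every directed path of at most two edges
from a source-circuit cell to a target-circuit cell. Three choices shape
the search:

* **Intermediary eligibility.** The middle cell of a two-hop path must
  belong to *neither* circuit. Without this restriction every
  within-circuit hop followed by a crossing edge would be counted as a
  separate "bridge", inflating the tally with paths that add no new site
  of contact. A one-hop edge whose endpoints sit in the two circuits
  (RGW → IN_sn) is reported as a *direct* bridge keyed by its target
  class.
* **Edge threshold.** An edge exists when its synapse count is at least
  `minSynapses` (default 1). The search definition itself carries no
  stricter threshold, so the cut-off is exposed as a parameter rather
  than hard-coded; users wanting to ignore weak (1–2 synapse)
  connections can raise it.
* **Determinism.** Paths are returned in lexicographic order of their
  cell identifiers, so downstream tallies and diffs are reproducible.

Bridge classes aggregate paths by the intermediary's class. The two
median mechanosensory cells (MS1, MS2) form a single bridge class even
though they contact both motoneurons and IN_pro cells — the class is
keyed by the intermediary, not by the output target.

The implementation is a direct double/triple loop over the class-filtered
index sets; the test suite checks it against an independent exhaustive
enumeration on random annotated graphs of up to 12 nodes.

## Membrane morphometrics

Each ciliary branch is modelled as an open cylinder: area
$\sum_i \pi d_i L_i$ with diameters in nm and lengths in µm. End caps are
omitted because branch tips contribute a negligible fraction of the
lateral surface at a 130 nm calibre, and the open-cylinder form is the
one consistent with the aggregate morphometry (one branch of 130 nm ×
677 µm gives 276.5 µm²). Basal-body counts carry a configurable
plausibility range (default 12–15 per cell) enforced at construction.

## Radiometry and duty-cycle mixtures

Photon flux uses fixed CODATA constants
($h = 6.62607015\times10^{-34}$ J·s, $c = 2.99792458\times10^8$ m/s) so
results are bit-reproducible; comparisons against printed flux values use
two significant figures with round-half-even. Duty-cycle schedules keep
epoch durations as real milliseconds — no quantization to a device
switching grid, since none is part of the schedule definition — and
`timeAveragedRatio()` inverts the construction exactly on all fractions.
The imaging-to-stimulus area ratio is the exact geometric formula
$WH/(\pi r^2)$; with a 254 × 254 px frame the 18 px ROI gives 253.5,
marginally above the often-quoted upper bound of 250, and we report the
exact value rather than forcing agreement with a rounded range.

## Spectrum peaks

`spectrumPeak()` takes the global maximum after optional moving-average
smoothing (a full window in nm, centred, truncated at the grid edges);
ties break toward the shorter wavelength so the result is deterministic
on plateaus. The synthetic opsin generator uses a log-normal-in-wavelength
bump — a behavioural stand-in chosen for smoothness and a single
controllable peak, not a claim about opsin photochemistry. The bleached
spectrum is the dark curve minus a depletion bump centred at the desired
difference-spectrum peak (clamped at zero), so the dark − light
difference peaks at the configured wavelength by construction. With the
default 1% noise and a 10 nm smoothing window, the dark peak (384 nm) is
recovered within ±2 nm in ≥95% of seeds.

## Calcium traces and response classes

ΔF/F₀ supports two baselines. The fixed mode divides by the mean of a
pre-stimulus window. The time-dependent mode divides by a simultaneously
recorded reference-region series (an area with no calcium activity),
which makes the result *exactly* invariant to any positive per-frame
multiplicative artefact hitting both regions — the property that matters
when a stimulation laser bleeds into the detector. The invariance is
asserted in the tests as an identity, not a tolerance.

Response detection works on thresholds in ΔF/F₀ units. Defaults are 3×
the pre-stimulus standard deviation of the trace — the phenomenology is
described qualitatively, so a noise-scaled threshold is the defensible
default — floored at 0.05 for noise-free traces whose pre-stimulus s.d.
is zero. An excursion counts only if sustained for ≥3 consecutive frames
(2.4 s at 1.25 frames/s), rejecting single-frame noise. The decision
table: dip then rise → `biphasic_cPRC`; dip without rise →
`hyperpolarizing_only`; rise within 10 s of onset without a dip →
`onset_depolarizing`; later rise → `delayed_depolarizing`; otherwise
`none`. The rise is searched to the end of the trace, so depolarizations
after stimulus offset are counted — the biphasic response completes even
when the UV stimulus is switched off during the dip.

Joint 405/488 nm classification maps response pairs onto cell types:
`cPRC_like` (biphasic at 405, dip-only at 488), `RGW_follower` (tracks
the cPRC response at 405, silent at 488), `SN_early` (prompt
depolarization at 405 only) and `SN_late` (delayed depolarization at
405, weak-or-none at 488). The weak-vs-none boundary is a configurable
amplitude ratio (default 0.5, i.e. a 488 nm peak under half the 405 nm
peak still counts as weak); no quantitative boundary is established for
real data, so this parameter is flagged as unvalidated.

Correlation maps assign 0 (not NA) to zero-variance pixels so the
two-colour [−1, 1] rendering needs no special casing.

## Behavioural analysis

Vertical displacement uses z increasing upward; video rows increase
downward, so the tracker negates rows at calibration time
(`z = (rows − row) · mmPerPx`). Binned displacement excludes larvae not
present for the entire bin — inclusion of partial residences would bias
bins toward the displacement of whichever larvae happen to enter or
leave. Per-bin displacements telescope: their sum equals the window net
displacement for larvae present throughout.

Net displacement offers two estimators: per-larva (default; mean of
individual z-differences over larvae spanning the window) and
centre-of-mass (difference of population mean depth between the window
edges, tolerating track turnover). They coincide exactly on full tracks,
which the tests assert; the per-larva form is the default because it has
a clean per-animal interpretation and a standard error.

Analysis windows ship as presets: `fig3E`/`methods_action` (90–210 s, the
last two minutes of a 3.5-min stimulus), `cuvette` (last 45 s of a 60-s
stimulus) and `ratio` (last two minutes of a 4-min mixture condition).

The balance point interpolates linearly between the two grid fractions
bracketing the sign change of the ratio-response curve; with several
crossings the one following the largest positive response is used, since
the curve's global shape (upward at low UV, downward at high UV) makes
that the physiologically meaningful crossing. A curve that never changes
sign — as with UV/red mixtures, where no red-driven phototaxis exists —
is an error, not a number.

Group comparisons use Welch t-tests (the variance assumption is not part
of the comparison's definition, and unequal variances are the safe
default), with Holm–Šidák (step-down, adjusted
$\alpha_i = 1-(1-\alpha)^{1/(m-i+1)}$) or Šidák–Bonferroni (single-step)
correction implemented in-package since `p.adjust` offers neither Šidák
variant. Step-down rejections are a superset of single-step rejections
on any p-vector, which the tests check; family-wise error control is
verified by simulation (10,000 null replicates at m = 10).

Tracking uses greedy nearest-neighbour linking: closest pair first, ties
toward the lower track id, within a maximum link distance; no gap
bridging and no global assignment. This is adequate at the low densities
of column assays but will split or swap crossing tracks — a documented
limitation, and the reason the synthetic tracking benchmarks use
non-crossing lanes.

## The synthetic generators

**Connectome fixture.** Cell counts fix the reconstructed circuit's known
classes (4 cPRCs, 4 RGW, 6 IN_preMN, 2 MS, 2 Ser-h1); other class sizes
are configurable above minima. Edges are realized exactly along the
described pathways — including the flask neurons' lack of outputs and
the absence of any rPRC-to-cPRC feedback, so the reverse bridge search is
empty by construction — with synapse counts drawn uniformly from a
per-edge range (2–10) or pinned to the midpoint in deterministic mode
for exact tests.

**Movies.** Cells are Gaussian blobs on a uniform background; cPRCs get a
3× elevated resting amplitude (their high resting calcium makes them
identifiable without stimulation), and wavelength-conditional kernels
reproduce the four response classes. A 16 s dip at −0.4 ΔF/F₀ followed by
a saturating rise to +2 approximates the biphasic time course at the
0.8 s frame interval. Noise is Gaussian with s.d. proportional to
√intensity (Poisson-like). The knockout mode lowers the cPRC resting
amplitude five-fold and flattens its kernels. Not emulated: motion,
anatomy-shaped ROIs, bleaching, or detector nonlinearity — so passing
classification tests demonstrates the decision logic, not robustness to
registration artefacts.

**Swimming model.** Vertical position follows a drift–diffusion process
$dz = [v_{pt} S_{pt}(\lambda_{eff}) - v_{uv} S_{uv}(\lambda_{eff})
\cdot \mathbb{1}(t > \tau)]\,dt + \sigma\,dW$, with reflecting boundaries
at the column floor and surface (160 mm water height) and the effective
sensitivities computed from the schedule's time-averaged wavelength
fractions. The sensitivity curves are raised cosines — behavioural
stand-ins, not opsin spectra — anchored to the observed wavelength
boundaries: phototaxis centred at 490 nm with 130 nm half-support (so it
spans ~360–620 nm and is weakly positive at 380–400 nm, producing the
initial upward swim under UV), avoidance centred at 380 nm with 60 nm
half-support (zero above 440 nm, quarter-strength at 420 nm where the
net response is near neutral). The avoidance latency τ defaults to a
hard switch at 60 s; a smooth 20 s ramp is available behind
`smoothLatency`. The avoidance speed is not free: it is calibrated by
solving the zero-drift condition
$v_{pt} S_{pt}^{eff}(b) = v_{uv} S_{uv}^{eff}(b)$ at the configured
balance fraction $b = 0.40$ of the 380/480 nm mixture, so the balance
point is a generator ground truth that the analysis chain must recover.
Because no quantitative swimming speeds or displacement magnitudes are
established in text, the drift scale (0.3 mm/s) and diffusion scale
(0.5 mm/√s) are realistic placeholders for mm-scale larvae, and all
magnitude-sensitive tests are sign- or ratio-based, never absolute. The
generator's expected drift has a closed form, which the tests compare
with the empirical mean over 1,000 larvae in a tall arena (2,000 mm) —
in the 160 mm column, boundary reflections compress displacements near
the floor and surface, which is also why recovered balance points can
deviate by a percentage point or two from the calibrated truth.

**Videos.** Gaussian blobs with additive sensor noise at the trajectory
positions. Blob radius, amplitude and threshold interact: two particles
closer than roughly 7 px (at the defaults) merge into one connected
component, which is the greedy tracker's documented failure mode.

## Problem sizes

The shipped tests run the full chain at desk scale: 41-cell connectomes,
64 × 64 px movies of 150 frames, 8 × 8 × 50 oracle movies, 20-larva
tracking videos, 40–60 larvae per behavioural condition, 1,000 larvae for
the drift identity, 10,000 replicates for the family-wise error
simulation, and 200 larvae per UV fraction (2,200 total) for the
balance-point recovery. These sizes give stable statistics while keeping
the whole suite fast; all scale up linearly through the exported
parameters.

## Known limitations

* The tracker has no gap closing or global assignment; crossing or
  merging larvae fragment tracks.
* Response classification assumes registered movies and supplied ROIs;
  there is no segmentation of real anatomy.
* The raised-cosine sensitivities and the hard latency switch are
  deliberately minimal; they reproduce sign structure and the balance
  point, not full displacement time courses.
* The weak-response boundary (`weakRatio = 0.5`) in cell classification
  is unvalidated against real recordings.
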