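---
title: "Detecting and quantifying dense-core vesicle fusion with dcvfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying dense-core vesicle fusion with dcvfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement

Neuropeptides are released from dense-core vesicles (DCVs). Tagging a vesicle
cargo (NPY or BDNF) with super-ecliptic pHluorin makes single fusion events
optically visible: pHluorin is quenched in the acidic vesicle lumen and lights
up the instant a fusion pore neutralizes it, producing a step increase of
typically 1.5-3 dF/F0 at a ~3 px punctum, followed by a decay over seconds.
At the end of a recording, superfusion with NH4Cl-containing Tyrode's
neutralizes every labeled vesicle, revealing the total labeled pool so that
the number of fusion events can be normalized to a release fraction.

The canonical acquisition this package targets: 2 Hz imaging; 30 s baseline;
16 trains of 50 APs at 50 Hz delivered every 1.5 s (24 s of stimulation,
i.e. 48 frames, entered as a 50-frame window after rounding up to a multiple
of 10); 26 s post-stimulus; NH4Cl from 80 s, i.e. frame 160 of 200. In code:

```{r, eval = FALSE}
library(dcvfusion)
paradigm <- acquisition_paradigm(
  frame_rate_hz = 2, baseline_frames = 30,
  stim_start_frame = 61,
  stim_len_frames = round_stim_window(frames_for_duration(16 * 1.5, 2)),
  nh4_start_frame = 160
)
```

`baseline_frames` is a *parameter* (the rolling-window length, 30 frames =
15 s), distinct from the 30 s hardware baseline delay; both follow the
reference acquisition.

## Detection model

Events are localized on the temporal standard deviation of the stimulation
window: a transient step-and-decay at a pixel inflates its SD well above the
shot-noise floor, and — unlike a mean or maximum projection — the SD image
does not over-represent constitutively bright regions (soma, bright debris).
The pipeline is:

1. **Normalization.** Either "B&W opening" (per frame: maximum filter, then
   minimum filter, then Gaussian blur, all with one radius — the verbatim
   filter order of the reference tool, which is a grayscale closing plus
   blur; it suppresses dark shot noise and smooths while using only local
   information, so it tolerates uneven illumination), or baseline
   subtraction (subtract the per-pixel mean of the first `baseline_frames`
   frames; better for very noisy images but sensitive to uneven
   illumination). Outputs are kept signed; nothing is clipped.
2. **SD projection** of the stimulation window (sample SD, n-1). Multiple
   stimulation blocks are projected per block and combined by pixel-wise
   maximum; candidate search is not re-run per block (cheaper, and
   equivalent for localization).
3. **Spot calling by prominence.** The SD image is min-max rescaled to 0-255
   (the 8-bit semantics of the "SNR" knob) and local maxima are kept when
   their topographic prominence — height above the highest saddle to a
   higher maximum — reaches `snr`. Plateau maxima collapse to their rounded
   centroid; equal-height twin peaks are both kept; score ties break by
   (row, col) so detection is fully reproducible.
4. **ROI placement.** Square ROIs (default 3 x 3) are accepted greedily in
   score order; a candidate sharing more than `max_overlap_px` pixels
   (default: a third of the ROI area, 3 px for 3 x 3) with an accepted ROI
   is dropped, so one event cannot be reported twice.
5. **Event-start assignment.** Each ROI's mean trace is measured on the
   *raw* movie, and the start is the first frame in
   `[stim_start, nh4_start)` exceeding the trailing rolling mean plus
   `cleaning_threshold_sd` rolling SDs (window = `baseline_frames`). ROIs
   that never cross are discarded and the survivors renumbered from "0000".

Two choices here were genuinely open and are worth stating. Traces are
measured on the raw movie rather than the normalized one, so dF/F0 keeps its
physical meaning; normalization is used only to localize events. And the
rolling statistics use a trailing (causal) window, so an event cannot inflate
its own detection threshold.

In baseline-subtraction mode an additional gate applies (the "detection
threshold"): a candidate's peak intensity during stimulation must exceed the
normalized movie's mean plus `detection_threshold_sd` SDs. The reference
tool's exact interaction between this gate and the prominence knob is not
documented; the two are applied conjunctively.

### Parameter defaults

| parameter | default | meaning |
|---|---|---|
| `snr` | 15 | prominence on the 0-255 rescaled SD image |
| `cleaning_threshold_sd` | 5 | rolling-SD multiples for the event start |
| `detection_threshold_sd` | 2 | extra intensity gate (baseline-subtraction only) |
| `roi_size_px` | 3 | matches the ~3 px event footprint |
| `max_overlap_px` | `floor(roi^2/3)` | one-third-area overlap cap |
| `smoothing_radius_px` | 1 | rank-filter radius and Gaussian sigma |
| `pool_snr` | 0 (automatic) | prominence for NH4 punctum counting |

The reference workflow treats the SNR and cleaning knobs as per-image tuning
(adjust prominence "until the majority of puncta are selected without
selecting background noise"). The package ships fixed defaults instead,
calibrated once on the simulator's clean and event-free scenes so that all
planted 1.5-3 dF/F0 events are recovered while an event-free movie yields at
most one spurious ROI: because the SD image is min-max rescaled, an
event-free movie amplifies its noise texture to full scale and produces many
low-prominence candidates, and it is the causal rolling-statistics gate at 5
SD (one-sided tail ~3e-7 per frame) that keeps them out. Real events cross
that gate with enormous margin (a 1.5 dF/F0 step is ~50 trace SDs here).

## Per-event quantification

For each retained ROI: `start_time_s = (start_frame - 1) / frame_rate`;
`F0` and `SD0` are the mean and sample SD of the trace over frames
1..`baseline_frames`; the duration is the run of consecutive frames above
`F0 + duration_sd * SD0` (default `duration_sd = 2`; the reference names the
inputs but not the return-to-baseline rule, so the rule is ours and the
multiplier is exposed); the amplitude is `(peak - F0) / F0` over the event
window. Events still above threshold at NH4 onset are capped there and
flagged `persistent` rather than discarded, since dequenching would
contaminate the decay. The peak dF/F0 is the primary intensity measure; the
summed dF/F0 over the event (`dff_integral`) is also emitted because
"fusion intensity" is ambiguous between peak and integral. Distances to the
nearest other event and to the nearest synapse pixel are Euclidean, in
pixels; a lone event has no nearest-event distance (reported missing, not 0).

## Pool estimation

The NH4 response is projected as the per-pixel maximum over the NH4 window
minus the per-pixel baseline mean, after the same movie normalization as
detection (mirroring the reference pool dialog, which carries the same
normalization options). Three estimates of the labeled pool:

* **raw pool** — the count of prominence maxima in the projection. With
  `pool_snr = 0` the prominence is estimated from the NH4 response itself as
  mean + 3 SD of the projection's background (pixels below its Triangle
  threshold) — a documented heuristic, since the reference statistic is
  unstated.
* **fused-corrected** — total integrated punctum intensity divided by the
  mean integrated intensity of the detected fusion events.
* **puncta-corrected** — the same total divided by the median integrated
  intensity of isolated single puncta (puncta within +/-50% of the modal
  punctum intensity, the mode taken from a kernel density over punctum
  integrals).

The reference names these corrections without formulas; the reconstructions
above follow its selection advice (use fused-corrected when single-event and
single-punctum intensities are comparable). Integration is deliberately
symmetric so the ratios are unbiased vesicle counts: every integral is a
window sum (default 7 x 7, covering a ~3 px punctum with its Gaussian tails)
over a background-corrected image — the projection minus the mean of its
sub-Triangle-threshold pixels on one side, the normalized event-peak frame
minus the baseline image and its own background level on the other.
Clipping each pixel at the threshold instead would lose the Gaussian tails
of every punctum but not of the event unit, biasing the fused-corrected
estimate systematically low.

Vesicle clusters that fuse optically into one punctum are counted once by
the raw pool but contribute their full intensity to the corrected estimates,
which is exactly the failure mode the corrections exist for.

Two degenerate cases need explicit handling. Prominence is a *relative*
measure: after min-max rescaling, the global maximum of any image — even
pure noise — is maximally prominent, so a noise-only projection would always
yield at least one "punctum". Counted puncta must therefore also clear a
detectability floor (`min_punctum_sd`, default 10 background SDs above the
projection background; real dequenched puncta sit ~50 SDs up), and the
no-puncta QC flag additionally fires when the frame-mean intensity fails to
rise by at least 1% at NH4 onset — no dequenching response means no
detectable puncta, whatever the spot caller picks out of the noise.

Saturation QC: any pixel at the bit-depth maximum during the NH4 window
*outside the soma* flags the recording. The soma mask is the dilated largest
connected component above the Triangle threshold of the *baseline mean
image* — the soma is the brightest structure before stimulation (trans-Golgi
pHluorin) — rather than of the NH4 projection, where a saturating artifact
would itself dominate and masquerade as the soma, defeating the check. The
release fraction is the number of detected events divided by a chosen pool
estimate.

## Synapse mask and localization

The synapsin-mCherry marker image is segmented by a morphological top-hat:
open the bright-punctum working image (minimum filter, maximum filter,
Gaussian blur, one radius of about the synapse size), subtract the opening
from the working image, Triangle-threshold the difference. Opening erases
puncta no larger than the radius while following the smooth background, so
the difference isolates the puncta and cancels illumination gradients.
`objects = "dark"` accepts inverted-contrast input (black puncta on white)
by inverting first — the black-object-on-white convention some workflows
use. The reference chain's subtraction operand is ambiguous in prose; the
implementation fixes the chain by its function (top-hat on the
bright-object image), which is the only reading that yields a punctum mask,
and exposes the polarity switch. Manual deletion of stray objects is
replaced by a connected-component size filter with explicit
`[min_area, max_area]` bounds. An event is synaptic when its ROI center lies
within `tolerance_px` (default 1) of the mask.

The Triangle threshold itself uses 256 equal-width bins over the intensity
range, draws the line from the histogram peak to the far end of the longer
tail, and takes the bin maximizing perpendicular distance to that line; ties
in the peak go to the first bin, a side tie goes right, and the returned
threshold is the selected bin's midpoint. These conventions are fixed so
masks are bit-stable.

## The simulator

`simulate_movie()` renders a single autaptic neuron: a bright soma, 16
smooth-curve neurites, faint diffuse signal; `n_vesicles` quenched puncta
(Gaussian sigma ~1 px, i.e. ~3 px footprint) at 5% of their dequenched
brightness; `n_events` stimulus-locked fusion events with instantaneous rise
and exponential decay (tau 2 s); a global dequenching step completing within
2 frames at NH4 onset; a smooth multiplicative illumination field (+/-20%);
and mixed Poisson-Gaussian camera noise on a constant offset of 100 counts
(gain 2 counts/e-, read noise 3 counts — EMCCD-like). Scene brightnesses
(diffuse 30, neurite 150, soma 600, vesicle 300 counts) were chosen once as
realistic for this preparation and are not tuned per test. Event amplitudes
are drawn from 1.5-3 dF/F0 and calibrated against the local baseline
*including* the camera offset, because measured dF/F0 on real traces
includes it too; the programmed amplitude is therefore recoverable from the
rendered movie. Default counts (60 events, 150 vesicles) sit inside the
reported 30-200 events per cell, with the pool desk-scaled from the reported
1,400-18,000 so tests stay fast (256 x 256 x 200 frames; unit tests use a
96 x 96 x 120 variant, and the multi-seed recall check a 160 x 160 one).

What the simulator does *not* emulate — vesicle trafficking during NH4
(available as an option, off by default), photobleaching, focus drift, cell
debris, kiss-and-run kinetics — bounds what green tests mean: they certify
the algorithmic chain against exact ground truth under realistic noise, not
performance on drifting or contaminated recordings, which the QC flags are
designed to catch and annotate (never delete).

Fused vesicles are assumed to retain their label and dequench during NH4
(`fused_retain = TRUE`), so the rendered pool equals `n_vesicles`.

## Numerical conventions

Pixel coordinates are (row, col), 1-based, origin top-left, matching R
matrices; frame indices are 1-based everywhere, honoring the
`(FusionStart - 1) / F` convention with no hidden conversions. Movies are
stored (row, col, time) so one frame is a contiguous matrix. Rank and
Gaussian filters use reflect padding; Gaussian kernels are truncated at
`ceil(3 sigma)` and normalized to unit sum. Frame rate and paradigm always
come from arguments or a config file — TIFF metadata dialects are too
unreliable to guess from. Stacks are written as 8/16-bit unsigned TIFF and
round-trip exactly after rounding.

## Known limitations

* Events that start after the stimulation window contribute nothing to the
  SD projection and are only found if a post-stimulus tail is searched; the
  event-start search runs to NH4 onset, but localization is
  stimulation-locked. Post-stimulus-heavy protocols should split the
  recording into multiple stimulation blocks.
* The corrected pool estimators assume puncta are sparse at the integration
  scale (7 x 7); heavily overlapping puncta double-count intensity.
* QC criteria that are visual judgments in the bench protocol (focus drift,
  hovering debris, pre-NH4 bright vesicles) are numeric proxies with
  explicit thresholds; they annotate and never exclude silently.
* Statistical comparison across conditions (t-tests, ANOVA and friends) is
  intentionally out of scope; the two output tables are tidy input for any
  stats environment.
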