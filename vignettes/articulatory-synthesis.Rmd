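---
title: "Articulatory speech synthesis with emasynth: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Articulatory speech synthesis with emasynth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(emasynth)
```

## The problem

A speech neuroprosthesis needs a synthesizer that turns *motor* commands
into audible speech in real time. A practical stepping stone is an
articulatory synthesizer: electromagnetic articulography (EMA) tracks
small coils glued to the tongue, lips, jaw and velum, and a learned
mapping converts those positions, frame by frame, into acoustic
parameters that a vocoder renders as sound. Because every speaker's vocal
tract and coil placement differ, a lightweight calibration stage maps a
new speaker's articulatory space onto the reference speaker's, so one
trained synthesizer can be driven by many speakers — including in silent
speech, where no glottal activity is available and the voice source must
be artificial.

`emasynth` implements this whole chain — vocoder, EMA preprocessing,
articulatory-to-acoustic network, cross-speaker calibration, causal
streaming — plus a synthetic corpus generator and the evaluation metrics,
so that every stage can be exercised and verified without any recorded
data.

## The vocoder

### Mel-cepstral analysis

Audio sampled at 22,050 Hz is analyzed with a 512-sample (23 ms) Blackman
window every 220 samples (the closest integer hop to 10 ms, giving a
nominal 100 Hz frame rate that pairs with the articulatory frames by
index). Each frame is described by 25 mel-cepstral coefficients
$c_\alpha(m)$, $m = 0..24$, defining a spectral envelope model

$$H(z) = \exp \sum_{m=0}^{24} c_\alpha(m)\,\tilde z^{-m}, \qquad
\tilde z^{-1} = \frac{z^{-1} - \alpha}{1 - \alpha z^{-1}},$$

with warp coefficient $\alpha = 0.455$, which approximates the mel scale
at this sampling rate. The coefficients are estimated per frame by
minimizing the log-spectral matching criterion
$\bar E = \mathrm{mean}_k\,[e^{R_k} - R_k - 1]$, where
$R_k = \log I_k - \log |H(e^{j\omega_k})|^2$ compares the frame's
periodogram with the model on an FFT grid. This criterion is convex in
the coefficients with an everywhere positive-definite Hessian, so a
damped Newton iteration (at most 30 steps, stopping when the criterion
decreases by less than $10^{-6}$) converges in a handful of steps from a
weighted least-squares initial fit. Two consequences the tests rely on:
scaling the audio by $k$ moves only $c_\alpha(0)$, by $\ln k$; and at
$\alpha = 0$ the procedure coincides with plain (unwarped) cepstral
envelope fitting.

### MLSA synthesis and inverse filtering

The exponential transfer function is realized by the standard Mel Log
Spectrum Approximation (MLSA) digital filter: coefficients are first
converted to the filter basis by the linear recursion
$b(M) = c(M)$, $b(m) = c(m) - \alpha\,b(m+1)$, and the exponential is
split into gain, first-coefficient and higher-coefficient stages, each
approximated by an order-5 Padé rational $R_5(F) = P(F)/P(-F)$ built on a
cascade of warped all-pass sections. We compute the true order-5 Padé
coefficients of the exponential in closed form. With
$\lVert c \rVert_\infty \le 1$ the realized magnitude response is within
a millidecibel of the analytic envelope over 0–8 kHz.

Because the inverse filter uses the same rational structure with negated
coefficients (stages in reverse order), inversion is exact up to
rounding, not merely approximate: synthesizing an excitation and inverse
filtering the result recovers it to machine precision, which the test
suite asserts at a relative RMS of $10^{-3}$ and observes at $10^{-15}$.

Filter coefficients are interpolated linearly per sample from the
*previous* frame's values to the current frame's. The alternative
(interpolating toward the next frame) would need one frame of lookahead
and break causality; holding coefficients constant per frame would
introduce audible steps.

### Excitation

Two sources drive the filter. The pitch-driven source uses a per-frame
fundamental-frequency contour: voiced frames contribute a pulse train via
phase accumulation (a pulse whenever the accumulated normalized phase
crosses an integer), unvoiced frames unit-variance white noise; pulses
have amplitude $\sqrt{\mathrm{rate}/f_0}$ so both regimes have unit
average power. The fixed-template source tiles a single glottal period
end to end — the silent-speech mode, where no glottal activity exists and
all sounds come out voiced at a constant pitch. The package ships a
*synthetic* template (`glottal_template()`): a Rosenberg-style glottal
flow derivative whose spectrum is flattened to unit magnitude, because a
residual obtained by inverse filtering a real vowel is approximately
spectrally flat; an un-whitened template would tilt every synthesized
spectrum. How a real template period would be selected from a recording
is left to the user — the template is an explicit input everywhere.

Pitch extraction (needed only for analysis-synthesis work, not the silent
loop) uses frame-wise normalized autocorrelation over a 1024-sample
window with a 50–400 Hz search range, voicing decided by a 0.3 peak
threshold plus an energy gate, and parabolic peak refinement.

## Articulatory preprocessing

EMA gives nine coil positions at 400 Hz plus a 6-DOF reference-coil pose.
Head movement is removed by re-expressing every coil in the reference
coil's rigid frame (inverse rotation, then translation). Trajectories are
down-sampled to 100 Hz through a 4th-order Butterworth low-pass at the
new Nyquist run forward and backward — zero phase, an 8th-order magnitude
response, and constant trajectories pass unchanged — followed by
decimation. Four parameterizations are supported: the raw 27 coordinates;
14 midsagittal parameters (lip-corner coils dropped, lateral coordinate
discarded — after head correction the midsagittal plane is taken to be
the x–y plane of the reference frame, the simplest defensible convention
since the plane-fitting method is otherwise unconstrained); and 10 or 7
PCA scores. PCA is fit on z-scored 27-dimensional data; scaling first
keeps millimetre-scale tongue coils from dominating the sub-millimetre
velum coil. Silence frames (from the phone segmentation) are removed
before any model fitting.

The network input stacks each frame with its 4 predecessors (50 ms of
context at 100 Hz) — past frames only, so the representation is usable
in a real-time stream. At utterance start the first frame is replicated,
which keeps the frame count constant and the stream causal.

## The articulatory-to-acoustic network

A fully connected feed-forward network, 3 hidden layers of 200 leaky
rectified linear units (negative slope 0.01, configurable) maps the
stacked, z-scored articulatory context to the 25 z-scored mel-cepstral
coefficients; normalizers are fitted on training items only. Weights are
initialized from zero-mean Gaussians with standard deviation $1/N$ ($N$ =
fan-in), biases at zero.

Training adds layers successively: stage 1 trains input–hidden–output;
each later stage keeps the trained hidden layers, inserts a fresh hidden
layer and a fresh output layer, and fine-tunes everything. Each epoch
shuffles the training frames into 100 blocks and minimizes each block's
MSE with Polak–Ribière conjugate gradient capped at 3 line searches
(quadratic/cubic interpolation with extrapolation, Armijo acceptance,
warm-started step sizes across blocks). We interpret "3 line searches"
as a per-block cap rather than running CG to convergence — the cap is a
`train_config` knob (`line_searches`) for anyone preferring otherwise.
Items are split 90/5/5 (train/validation/test) at the *item* level, so
frames of one utterance never straddle subsets; ties in the remainder go
to validation. A stage stops when validation MSE has not improved for 20
epochs, and the best-validation weights are restored. Two numerical
choices worth flagging: improvements smaller than `min_delta` $= 10^{-4}$
do not reset the patience counter (block-stochastic validation noise
otherwise produces micro-improvements indefinitely), and `max_epochs`
(default 500) is a safety bound only — in the shipped acceptance runs we
set it to 45 per stage, which the patience rule undercuts in practice.

## Cross-speaker calibration

A new speaker silently repeats reference utterances; the calibration maps
their articulatory frames into the reference space with a single affine
transform, frame by frame, no temporal context. A global integer frame
delay (speaker + system latency) is first estimated by grid search over
−30..+30 frames (±300 ms; the range is configurable since nothing pins it
down): for each candidate the sequences are shifted and trimmed, silence
frames dropped, an ordinary-least-squares fit computed, and the delay
with minimal MSE wins, ties toward zero. Shifting happens on the intact
time axis *before* silence removal — removing frames first would corrupt
the axis the delay is defined on. The fit itself is plain OLS with
intercept (an optional ridge exists for rank-deficient inputs but is off
by default). Per-sensor calibration quality is summarized as the mean
Euclidean distance between predicted and reference midsagittal positions
over speech frames.

## Streaming and the real-time claim

One streaming step consumes one articulatory frame and produces one hop
(220 samples) of audio: calibration, context-buffer push, network
forward pass, MLSA filtering of the next template-excitation chunk. The
state is a 5-frame buffer, the filter delay lines and the excitation
phase — all of constant size, so per-frame work is O(1), which a test
asserts through an operation counter rather than wall-clock (hardware
latency is out of scope here). Offline synthesis drives the *same*
per-frame core in a loop, so batch and streaming output are identical by
construction; the test suite verifies both the sample-exact equivalence
and causality under future-frame perturbation. Closed-loop (silent
speech) synthesis always uses the fixed-template excitation.

## The synthetic corpus

The generator emulates the structure of a reference articulatory-acoustic
corpus so that every stage has inputs with *known answers*. Its defaults
are the package's study conditions, chosen once:

- 17 pseudo-phones (10 "vowels", 7 "consonants"), each a fixed
  articulatory target drawn from a zero-mean Gaussian with 5 mm spread in
  the 14-dimensional midsagittal space — comparable to real articulator
  excursions (tongue ~3 cm range, velum < 1 cm). A separate rest posture
  holds during silences.
- Items: 15% isolated vowels (0.3–0.5 s), 25% vowel–consonant–vowel
  triplets, 60% pseudo-sentences of 11–17 phones (0.08–0.2 s each), with
  0.15–0.35 s silence margins — a mean item of roughly 2 s, mixing the
  item types a real corpus would contain.
- Trajectories: piecewise-constant target tracks smoothed by a 50 ms
  raised-cosine kernel at 400 Hz (a stand-in for articulator dynamics —
  real coarticulation is richer than target interpolation), plus 0.2 mm
  low-passed Gaussian jitter; then down-sampled to 100 Hz by the package's
  own decimator.
- Acoustics: a fixed random shallow network (50 tanh units) maps the
  stacked trajectory to 25 mel-cepstral coefficients — smooth,
  Lipschitz-bounded, reproducible from its seed; observation noise is
  added at 40% of each coefficient's signal spread, so the z-scored noise
  floor of any regression is known. Audio, when requested, is MLSA
  synthesis with a 120 Hz pulse excitation.
- New speakers: $x_{new}(t) = A\,x_{ref}(t-\delta) + b + \varepsilon$
  with $A = I + 0.15R$ (seed-drawn), $b \sim N(0, 2\,\mathrm{mm})$,
  $\delta = 5$ frames and $\varepsilon$ of 0.3 mm by default — sensor
  noise and session-to-session placement differences in miniature.

What passing tests on this corpus do show: the estimators recover known
transformations, the network reaches the known noise floor, the streamed
cascade preserves phonetic identity. What they do not show: performance
on real coarticulated speech, real EMA dropout/drift, or human
intelligibility — those require recorded data and listeners.

### Problem sizes used in the shipped runs

The recovery and closed-loop checks train on a 150-item corpus
(~21,000 speech frames), a size at which the network reliably reaches
within 20% of the observation-noise floor; calibration recovery uses
60-item corpora (~10,000 frames) and the calibration-noise setting
$\sigma = 0.01 \times$ signal sd, inside the small-noise regime where
affine recovery to 5% is informative (at several percent of signal sd the
anisotropy of target-based trajectories inflates entrywise parameter
error even though prediction MSE stays excellent). Delay recovery is
exact across the whole regime.

## Evaluation metrics

Identification accuracy is $R/N$; the chance level of a balanced
$C$-alternative test is $1/C$ (10 offline vowel classes → 10%, 16 VCV
classes → 6.25%, 7 closed-loop classes → ~14.3%). Confusion matrices are
row-normalized with a per-row error column, and can be *seriated*:
rows/columns reordered (same permutation both ways) to maximize
$\sum_{ij} p_{ij}/(1+|i-j|)$, concentrating confusions near the diagonal
— exactly by exhaustive search up to 8 categories, greedy insertion plus
2-opt beyond. Word accuracy is $(N - S - D - I)/N$ from a unit-cost
minimum-edit alignment (ties prefer substitutions; tokenization
lowercases, strips punctuation, splits on whitespace). Objective spectral
fidelity uses the mel-cepstral distortion
$\frac{10}{\ln 10}\sqrt{2\sum_{m\ge1}(a_m-b_m)^2}$ averaged over frames —
gain-invariant since $m = 0$ is excluded.

Human listeners are replaced, at desk scale only, by a nearest-centroid
classifier: class templates are steady-state mel-cepstra of
analysis-synthesis renditions of the reference items (the vocoder's
quality ceiling), and a stimulus is assigned the class with minimal
mel-cepstral distortion to its template mean, ties broken by label order.

## Known limitations

- The synthesizer's naturalness is bounded by the MLSA + fixed-template
  source model: constant pitch, fully voiced, "robotic" by design.
- The corpus generator does not model coarticulation dynamics, palate
  contact, sensor dropout, or phonetically faithful articulation.
- The seriation objective fixes one reasonable band weighting; other
  weightings can prefer different orders for near-tied structures.
- Training is CPU-bound, deterministic, single-threaded; no
  regularization beyond early stopping is implemented.
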