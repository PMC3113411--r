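---
title: "neuroring: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{neuroring: models, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`neuroring` is a headless, deterministic implementation of the classic
three-engine brain-machine-interface (BMI) architecture: an *acquisition*
engine produces one frame of multichannel neural data every 33.3 ms, a
*signal-processing* engine turns it into band-power features and a decoded
velocity, and an *application* engine runs a center-out cursor task and
feeds target information back to the acquisition engine. The three engines
form a closed ring: frame *k*'s task feedback must arrive at the
acquisition engine before frame *k + 1* is emitted, which guarantees that
every block of data is fully processed and a system output generated
before the next block enters the system. Every frame carries a *packet
index*, and everything the system saves — per-frame sampled variables and
change-logged parameters alike — is keyed by it, so an entire session can
be replayed offline, bit for bit.

This vignette explains the science inside each stage, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic-data tests do and do not establish about real recordings.

## The synthetic ECoG model

Each simulated channel is built from a pink-noise process $S_1$ with a
$1/f$ power spectral density and its high-gamma (70–120 Hz) component
$S_2$, combined as

$$S = S_1 + d\,\cos(\theta - \mathrm{PD}_i)\,S_2,$$

where $d \in [0, 1]$ is the modulation depth, $\theta$ the drive direction
(toward the cursor target), and $\mathrm{PD}_i$ the channel's preferred
direction; the 32 default channels have preferred directions uniformly
spaced over the circle. When the drive is inactive (baseline) or $d = 0$,
the output is exactly $S_1$.

Two design points matter here and both are deliberate:

* **$S_2$ is derived from $S_1$, not drawn independently.** If $S_2$ were
  an independent band-limited noise, the *expected* band power would be
  $P_1 + d^2\cos^2(\theta-\mathrm{PD})\,P_2$: quadratic in the cosine,
  symmetric under a 180° flip of the drive, and with *no linear component*
  for a regression on $(\cos\theta, \sin\theta)$ to find — preferred
  directions would be unidentifiable by the decoder-training procedure the
  package implements. Deriving $S_2$ from $S_1$ makes the in-band
  amplitude gain $1 + d\cos(\theta - \mathrm{PD})$, hence band power
  $\approx (1 + d\cos)^2 P_1$, monotone in $\cos$ for $d < 1$. That is
  the cosine-tuned population model the decoder assumes, and it is what
  makes the end-to-end parameter-recovery tests meaningful.
* **The band-pass is zero-phase.** $S_2$ is extracted with a linear-phase
  windowed-sinc FIR filter (241 taps at 1200 Hz, ≈16 Hz transition width)
  whose group delay (120 samples, 0.1 s) is compensated by delaying $S_1$
  by the same amount. In-band, $S_1$ and $S_2$ then add coherently. A
  causal IIR band-pass is tempting for a streaming simulator but wrong:
  its phase rotates $S_2$ against $S_1$'s in-band component and most of
  the amplitude modulation cancels, leaving tuning barely detectable.
  The price of the FIR is a fixed 0.1 s output latency, irrelevant for a
  signal generator.

Pink noise itself comes from a cascade of six first-order pole–zero
shelving sections, log-spaced over 1–300 Hz and bilinear-transformed with
prewarping, driven by white Gaussian noise. The cascade's white-noise RMS
gain is computed from its impulse response and divided out, and the
default output scale is 50 µV RMS — a typical subdural ECoG amplitude.
The generator is streaming: filter states persist between frames, so two
40-sample calls equal one 80-sample call bit for bit. Its log–log PSD
slope over 2–300 Hz is −1.0 ± 0.2 (checked by a Welch periodogram and a
least-squares fit in the acceptance suite).

The simulator synthesizes directly at the 1200 Hz acquisition rate. The
default modulation depth is 0.3 — strong enough that three minutes of
training data recover all preferred directions, weak enough that single
frames remain noisy; closed-loop demonstrations use 0.5.

## Features: AR band power and pseudo-Z scores

Every frame, the trailing 0.5 s window of each channel (600 samples; the
window advances one 33.3 ms frame per step, ≈93 % overlap) is fitted with
a 15th-order autoregressive model using Burg's recursion, which is stable
on short windows. The model's one-sided spectral density is evaluated on
a fine grid (16 trapezoid sub-intervals per bin) and integrated over
10 Hz bins from 0 to 200 Hz, giving a 32 × 20 feature matrix per frame.
We integrate the density over each bin rather than sampling it at bin
centers: AR spectra are sharply peaked and the integral is the quantity
with Parseval meaning (total band power over the full range tracks the
window variance). The Burg implementation is compiled (it runs once per
channel per frame) and is verified against `stats::ar.burg` to 1e-10 in
the test suite; the first 600-sample window is complete at the 15th frame,
and earlier frames return a flagged warm-up outcome.

Raw band powers are standardized to pseudo-Z scores,
$f_{\mathrm{norm}} = (f - \bar f)/\sigma$, with $\bar f$ and $\sigma$
estimated from a ~3-minute no-task baseline by a streaming Welford
update ($n-1$ denominator). Normalizing the baseline frames by their own
statistics must give per-feature mean 0 and sd 1 up to floating point;
the acceptance suite runs the full pipeline at ≈5400 baseline frames and
asserts $|\text{mean}| < 0.05$ and sd in $[0.9, 1.1]$ — a pipeline
consistency check, not a statistical one.

## Decoder training, the shuffle null, and the population vector

During training the application engine presents targets in balanced
shuffled blocks and the decoder buffers, per frame, the pseudo-Z feature
vector together with the *unit vector toward the current target*
$(m_x, m_y)$ — the desired-movement regressor. (Instantaneous cursor
velocity would be an alternative regressor; the target vector is constant
within a trial, which matches how the scripted simulator drives the
signals.) Each feature is then fitted by ordinary least squares,

$$f_i = b_{0,i} + b_{x,i} m_x + b_{y,i} m_y,$$

with plain (unadjusted) $R^2$ and preferred direction
$C_i = (b_{x,i}, b_{y,i})/\lVert\cdot\rVert$. The fit is vectorized
across all 640 features via one QR decomposition.

Feature selection compares each $R^2_i$ with percentiles of a *null*
distribution obtained by refitting after shuffling the target labels:
1000 iterations, each permuting whole kinematics rows (which preserves
the marginal target distribution), pooled across features. The default
threshold is the pooled 95th percentile and is a live parameter — it can
be changed mid-run and the selection recomputed without refitting.
Numerically, permuting design rows leaves $X'X$ unchanged, so each
refit needs only $X'Y$; the implementation batches all permutations of a
chunk into a single matrix product and reconstructs per-iteration $R^2$
exactly (the test suite checks bit-agreement with naive refitting).
Calibration on genuinely untuned data is part of acceptance: the fraction
of iid-noise features exceeding the pooled p95 is 5 % ± 2 %.

Two caveats, stated openly. First, with overlapping windows the training
frames are autocorrelated while the row-shuffle null assumes
exchangeability, so on simulator data the null is anti-conservative:
many out-of-band features also clear the p95 threshold. The package keeps
the row-shuffle because it is the classic procedure this architecture
ships with; selecting those extra weakly-tuned features barely affects
the population vector (their activity excess is near zero on average),
but a block-wise (per-trial) shuffle would be the statistically stricter
variant. Second, $R^2$ is the plain coefficient of determination, not
adjusted; with three regressors and thousands of frames the difference is
negligible.

The control signal is the population vector over selected features,
$P = \sum_i (d_i - b_{0,i}) C_i$, scaled by a live gain. The gain is
auto-calibrated at fit time so that the mean decoded speed over the
training buffer equals a cruise speed of 0.4 screen-units/s — the cursor
crosses the 0.8-unit target distance in about two seconds — and can be
adjusted live afterwards. A generic linear decoder (`v = W d + w0`) is
provided, and the population vector is algebraically a special case of
it (tested). For one-dimensional control the push-pull decoder
$c_y = a(s_1 - s_2) - b$ uses the 70–110 Hz power of two channels, with
$a$ and $b$ calibrated on baseline data so the control has zero mean and
unit variance.

## The center-out task

Coordinates: screen origin at center, workspace clamped to
$[-1, 1]^2$, angles counter-clockwise from screen right. Targets sit at
distance 0.8, target and cursor radii 0.1 (the source architecture
states no geometry; these are round numbers that make the task neither
trivial nor impossible at the default gain). Control is velocity:
`cursor <- cursor + v * dt`, with 1-D control moving the vertical axis
only, positive up. A trial succeeds on overlap (no hold time by
default), fails at the 10 s timeout, and is followed by a 2 s
inter-trial interval with cursor and target hidden and control input
ignored (whether the original study zeroed or ignored control during the
interval is unstated; we freeze the cursor). Targets are scheduled in
balanced shuffled blocks.

During closed-loop control the simulator's drive angle points from the
*current cursor position* toward the target — a scripted stand-in for a
subject's corrective intent (during training it points center→target,
matching the scripted presentation). This matters for honesty about what
the closed-loop acceptance shows: with depth 0.5 and corrective intent,
the full scripted session reaches ≥80 % success with mean first-second
headings within 30° of the target. That demonstrates the *pipeline* —
features, normalization, training, selection, decoding, task, recording —
is wired correctly end to end; it says nothing about human
performance, learning, or non-stationary real signals.

## Engine runtime and determinism

R is single-threaded, so the ring is a deterministic cooperative
scheduler driving the three engines in order within one process. Each
frame, an engine executes exactly: receive upstream bundle → apply
pending parameter updates → run its processing hook → send downstream →
enqueue a visualization snapshot → enqueue a save record. Parameter
updates are applied atomically at the start of the main sequence, each
stamped with the index of the first frame whose processing saw the new
value, and forwarded to the recorder (last writer wins within a gap;
every update is logged). Visualization queues are bounded (8 frames,
drop-oldest with a counter) so a stalled consumer can never back-pressure
the ring; in-flight visualization data is discarded on suspend. Decoder
(re)fits are triggered by a parameter and publish the new model between
frames, never blocking a frame in progress — mid-session retraining shows
up in the run file as a new weights record at the frame where it took
effect.

The clock has two modes. `"sim"` advances a virtual clock exactly one
frame period per frame: runs are deterministic given seeds, display
refresh intervals are exactly one frame period, and the timing benches
become closed-form checks. `"wall"` sleeps to the frame boundary and is
what a live deployment would use. Every stochastic component (each
simulator channel, the target scheduler, the shuffle null, the latency
probe) owns a private, resumable RNG stream derived from the master
seed, so results do not depend on what else draws from R's global
generator. Two runs with identical seeds and configuration produce
byte-identical sampled-variable streams — asserted in acceptance by
comparing re-encoded record bytes.

Suspending closes the current run file; resuming opens a fresh one with
packet indices restarting at 0, while engine in-memory state — decoder
weights, baseline statistics, filter states — survives, so a model
trained with one application can be reused with another. Any engine can
be hot-swapped for another of its kind with the remaining engines' state
preserved.

## Wire protocol and the ring transport

Bundles (ordered name–value collections; the unit of all traffic)
serialize to a little-endian, self-describing, length-prefixed binary
format: a 1-byte protocol version, a 4-byte payload length, then the
packet index, item count, and per item its name, a type tag (float64,
int32, logical, UTF-8 text), rank, dimensions, and payload. Scalars are
rank 0; arrays carry their shape per message, so array-valued variables
may change size between packets. The decoder on partial input reports
exactly how many bytes it still needs, which makes reassembly on a TCP
stream trivial; a version mismatch is a framing error with a byte
offset. Received items overwrite same-named local variables; unknown
names are retained and flagged.

The three-hop TCP ring (acquisition → signal processing → application →
acquisition) uses a compiled POSIX socket layer because two transport
requirements are not reachable from base R: Nagle's algorithm must be
disabled (messages leave immediately; batching happens at the
application layer — all of a frame's variables travel in one bundle per
link), and the raw-binary reader needs UDP datagrams. Links re-form
after a drop with exponential backoff capped at 2 s and re-send the
in-flight message; because every message carries its packet index,
re-delivery is idempotent. The scheduler runs with either the in-memory
transport or the TCP loopback transport; both produce identical record
streams (tested), which is the single-process stand-in for the
architecture's single-host/distributed equivalence.

The UDP dialect for external senders is fixed: one datagram per frame =
4-byte little-endian frame counter, 2-byte channel count, 2-byte
samples-per-channel, then channel-major IEEE float32 samples. Malformed
datagrams are dropped and counted; counter gaps are logged.

## Run files, replay, and MAT export

A run file is a plain concatenation of framed codec messages: one header
record (subject, session, investigators, date, engine names), then
*sampled* records (all saved per-frame values of one engine at one
packet index) and *control* records (one parameter change each, keyed by
the index where it took effect; initial values are logged at index 0).
This reuses the wire codec as the on-disk format — one binary layout to
document and test instead of two. An HDF5 container would be the
conventional alternative; no R HDF5 binding is available in this
package's dependency set, and the framed stream has a property HDF5
would not give for free: a crash leaves a file readable up to the last
flushed record (tested by truncating mid-record). The saving path is a
bounded FIFO (1024 bundles, drop-with-counter on overflow — loss is
logged, never silent) drained outside the main sequence, flushed every
64 records or every second.

Replay merges, per packet index, every engine's sampled values with the
piecewise-constant control values in effect, reconstructing the full
system state; records that arrived out of order are index-sorted on
read. `export_mat()` writes MATLAB v5 files — one struct per engine and
record group, each variable carrying its values and its packet-index
vector, variable-size arrays as cell arrays — through a minimal MAT
writer included in the package and verified against `scipy.io.loadmat`
as an independent reader.

## Timing benches

Three measurements mirror the classic real-time validation of this
architecture. *Processing time* is the span from block arrival to ring
completion, per frame; frames exceeding the 33.3 ms budget are counted
as overruns (pass-through engines overrun zero times; load grows with
channel count). *Refresh* is the interval between application display
updates: in simulated clock, exactly one frame period with zero jitter,
by construction. *Latency* feeds a 10 Hz zero-offset sine through one
channel and flips a response flag at the display update of the frame in
which a zero crossing (either edge — the detector's edge convention is
otherwise unstated) is detected; with crossing phases uniform over the
frame, mean latency is frame/2 plus the processing time and the standard
deviation is frame/√12. One subtlety: against an ideal simulated clock a
probe at exactly 10 Hz locks to just two crossing phases (50 ms is 1.5
frames), so the bench's oscillator re-draws its phase every cycle
(seeded) — this realizes, in simulation, the uniform-phase condition
that independent hardware clocks produce through drift. With an injected
processing delay δ the measured mean matches frame/2 + δ within 2 % over
5000 events. Absolute wall-clock milliseconds are hardware-specific and
are reported but never asserted.

## Problem sizes used by the test and acceptance suites

The acceptance suite runs the study conditions end to end: 60 s of pink
noise for the spectral check; a 180 s baseline (≈5400 frames) for
normalization; 24 training trials at depth 0.3 with the full
1000-iteration null for preferred-direction recovery; 2000 untuned
features for null calibration; a complete scripted session at depth 0.5
with 40 control trials for closed-loop performance; 5000 frames and 5000
probe events for the ring and latency checks. Determinism and replay are
exercised on an 8-channel session — byte-identity does not become more
convincing with more channels. Module tests use smaller versions of the
same constructions.

## Known limitations

* The simulator emulates stationary, artifact-free, perfectly
  cosine-tuned signals with independent channels. Real ECoG is
  non-stationary, spatially correlated, and contaminated by movement and
  line artifacts; passing tests here validate the machinery, not
  robustness to any of that.
* The row-shuffle null is anti-conservative under the autocorrelation
  induced by overlapping windows (see above).
* The cooperative scheduler serializes engines in one process; it
  preserves the architecture's ordering and determinism guarantees but
  cannot measure genuine multi-host parallel speedups.
* The optimal-linear-estimator and Kalman-type decoders, threshold
  crossing, circle-drawing, and biofeedback applications are extension
  points, not implementations.
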