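---
title: "A spiking network for visual looming detection: model, conventions, and what the synthetic experiments show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking network for visual looming detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`loomnet` simulates a feed-forward spiking neural network that watches
grayscale video and emits spikes when an object appears to approach
(loom). The architecture follows the bio-inspired collision-detection
tradition of the locust lobula giant movement detector (LGMD) models:
luminance changes are split into ON/OFF polarity channels, converted to
spike trains, and passed through a competition between fast excitation and
delayed, spatially wider inhibition, with a feed-forward inhibition (FFI)
gate that vetoes whole-field events. Two features distinguish this family
from classic rate-based LGMD models: all signals travel as *binary spikes*
with an 8-phase weighted code per video frame, and the entry layer is a
*foveated* ("eccentric") receptive-field mosaic of leaky
integrate-and-fire (LIF) neurons that mimics the mammalian retina's high
central acuity.

This vignette explains the model stage by stage, records every convention
and tunable parameter, describes what the synthetic stimulus generator
does and does not emulate, and reports — honestly — which of the
behaviors expected of this architecture the implementation reproduces and
which it cannot, together with the structural reason.

## 1. Signal pathway

### 1.1 Motion retrieval and ON/OFF channels

For a stream $L(x,y,f)$ of 8-bit frames, the per-frame luminance change is
$P(x,y,f) = L(x,y,f) - L(x,y,f-1)$ (the first frame has no predecessor and
contributes an empty period). Half-wave rectification with a one-frame
residual splits this into polarity channels:

$$P_{on}(f) = [P(f)]^+ + \alpha_1 P_{on}(f-1), \qquad
  P_{off}(f) = [P(f)]^- + \alpha_1 P_{off}(f-1),$$

with $\alpha_1 = 0.1$. The residual gives each channel a one-frame memory
tail; with $\alpha_1 = 0$ the channels are exclusive memoryless
rectifications (a property test asserts this).

### 1.2 Phase coding with weighted spikes

Each frame is expanded into 8 phase ticks. A channel value is normalized
by the intensity scale 256 and encoded as fixed-point binary: phase $i$
carries bit $i$ of the expansion, most significant first, and the weight
of phase time $t$ is

$$\omega(t) = 2^{-(1 + t \bmod 8)} \in \{2^{-1}, \dots, 2^{-8}\},$$

so the earliest spikes of every period matter most. The
$\omega$-weighted sum of the phase spikes reconstructs the normalized
value to within $2^{-8}$ (verified exhaustively for all 256 8-bit
values). Values above $255/256$ — possible after residual accumulation —
are clipped, because the 8-bit code cannot represent 1.0; clip events are
counted on the trace.

### 1.3 Eccentric down-sampling

The entry layer approximates a round retina with square rings of
receptive fields (RFs) whose size shrinks linearly from `max_rs = 10` px
at the border to 1 px in the fovea. The anchor (upper-left corner) RF of
ring $i$ follows the half-step recursion

$$R^c(i) = R^c(i-1) + \tfrac12 R^s(i-1), \qquad
  R^s(i) = \max(R^s) - \frac{\max(R^s)}{d_{fovea}}\,R^c(i),$$

with $d_{fovea}$ the distance from the border to the nominal foveal edge
(10% of the image side). **Rounding convention** (the recursion is
real-valued and several discretizations are defensible): anchor centers
are kept real, RF sizes are floored to integers, the recursion stops at
the first size below 2, and the fovea spans from $R^c(l)$ to the mirrored
last ring corner in unit steps. Under this convention the default
configuration (100 px input) gives $l = 14$ ring layers, $n = 29$ foveal
points, and a down-sampled grid side

$$DL = 2l + n + 1 = 58,$$

which is the configuration's documented reference value and the
calibration anchor for the convention. Pixel membership uses pixel
centers: an RF of size $s$ centered at $c$ covers the pixels whose
centers fall in $[c - s/2,\, c + s/2]$. Consecutive ring anchors are
spaced by the RF size (the last forced onto the mirrored corner), so the
rings tile without gaps; every pixel is covered by at least one RF
(asserted at construction), and overlapping RFs are intentional.

Each RF is a LIF unit integrating its pixels' spikes. Each output-grid
neuron then integrates the spikes of the RFs intersecting its image
region; foveal output neurons correspond one-to-one to unit RFs. The
per-pixel injected current is $R_k = 0.6$ for a unit RF and $R_k$ divided
by the RF's pixel count for larger RFs (switchable to raw $R_k$ per pixel
via `rf_current = "raw"`), so a peripheral RF demands more coincident
stimulation to fire.

### 1.4 Excitation, delayed inhibition, and summation cells

On the $DL \times DL$ grid, each phase produces an excitatory current
from the current spikes and an inhibitory current from the spikes
$\epsilon$ phases ago ($\epsilon = 2$ by default):

$$E(t) = \omega(t)\,\big(S \ast W_1\big)\,\rho, \qquad
  I(t) = \omega(t-\epsilon)\,\big(S_{t-\epsilon} \ast W_2\big)\,\rho,$$

with $W_1$ a $3\times3$ and $W_2$ a $9\times9$ Gaussian kernel and
$\rho = 0.9$. Summation (S) cells integrate $G = E - I$ with the
phase-scaled threshold $\omega(t)\rho$, subtract $\omega(t)\rho$ on
firing, and never fall below the resting level 0.

**Kernel conventions.** Two choices here are genuinely open and were
fixed as follows:

* *Width units.* Kernel standard deviations are interpreted relative to
  each kernel's half-width. $\sigma_1 = 1$ on the $3\times3$ kernel is 1
  cell (unchanged); $\sigma_2 = 0.5$ on the $9\times9$ kernel is 2 cells,
  making the inhibitory surround genuinely wider than the excitatory
  center; $\sigma_3 = 1$ on the global $DL \times DL$ pooling kernel
  spans the grid with a foveal emphasis. Reading the same numbers as
  absolute cells would make $W_2$ a near-delta and would restrict the
  global pool to the three central grid cells — cells that image the
  static interior of a centered looming object — leaving the readout
  structurally blind (verified empirically: no stimulus ever produced an
  output spike under that reading).
* *Normalization.* $W_1$ and $W_2$ are connection-weight surfaces with
  peak 1. Because $W_2$ is wider at equal peak, $W_2 \ge W_1$ pointwise
  on the overlap, so at zero delay ($\epsilon = 0$, where $E$ and $I$
  reference the same spikes with the same weight) $G \le 0$ everywhere
  and the network is *exactly* silent for every stimulus — the expected
  zero-delay behavior of this architecture, and a property the acceptance
  suite verifies on the full battery. Unit-sum kernels cannot produce it
  (the normalized excitatory center outweighs the normalized inhibitory
  center and a halo of net excitation survives). The global kernel $W_3$
  *is* unit-sum so the pooled channel current is bounded by
  $\omega(t)\rho$. `normalize_kernels = TRUE` switches all three kernels
  to unit sum; the exported `make_kernels()` keeps unit-sum as its
  default contract.

### 1.5 FFI, channel neurons, output neuron

The delayed population rate per polarity,
$F(t) = \omega(t-\epsilon)\, n_{active}(t-\epsilon) / DL^2$, gates the
channel input: if $F \ge S_{th} = 0.1$ the channel receives nothing that
phase (input blocking only; the channel membrane is not cleared — the
gate's observable effect, membrane-decay-only during gated phases, is
what the acceptance test checks on a whole-field flash). Otherwise the
S-cell spikes are pooled through $W_3$ and drive one LIF neuron per
polarity; the output neuron combines the two channel spike trains with
weights $\{\theta_1, \theta_2\}$ (default $\{0.5, 0.5\}$) and fires
against the same phase-scaled threshold. Biasing toward the OFF channel
($\{0.3, 0.7\}$) is the intended mechanism for dark-object-only
selectivity.

### 1.6 LIF conventions

All four LIF stages share the leak time constant $\tau$, measured in
phase ticks. The default is $1000/\mathrm{fps}$ ticks ($\approx 33$ at 30
fps, decay $e^{-1/\tau} \approx 0.97$ per tick), chosen so membrane
memory spans a few frames; the constant's natural unit is ambiguous and
it is exposed in the configuration. The RF and grid layers use a hard
reset to 0; the summation cells, channel neurons and output neuron use
the weight-scaled threshold $\omega(t)\rho$ with soft reset (subtract
$\omega(t)\rho$) and a floor at 0. All threshold comparisons are
inclusive ($\ge$). Phase time starts at $t = 0$ with the first (empty)
period of the first frame, so a clip of $F$ frames spans exactly $8F$
phases.

## 2. The synthetic stimulus battery

`loom_suite()` generates the standard conditions: looming squares (side
10 → 80 px over 90 frames at 30 fps, linear growth), their exact
time-reversals (receding), translating vertical bars (10 px wide, 2
px/frame), and drifting sinusoidal gratings (4 cycles/image at temporal
frequencies 0.05–0.4 cycles/frame), each at four contrasts — dark-on-light
and light-on-dark at luminance gaps 180 and 60 on a 100 × 100 px frame.
The trajectory is linear by default (an exponential option exists)
because only expansion per se drives the model; sizes, speeds and
contrasts are package conventions chosen once at these round values.
Generators are deterministic; clips are bit-reproducible.

What the generator does *not* emulate: perspective (hyperbolic)
approach trajectories with their characteristic terminal acceleration,
sensor noise, background texture or ego-motion, and luminance-dependent
contrast changes. Passing or failing on this battery therefore speaks to
the network's behavior on idealized, mirror-symmetric stimuli, not to
dashcam-style footage.

## 3. What the implementation reproduces — and what it structurally cannot

The geometry and coding layers behave exactly as specified: the default
layout yields $DL = 58$; phase weights are $2^{-1}\dots2^{-8}$; encoding
reconstructs all 256 8-bit values; EPSC/IPSC match a brute-force oracle;
the FFI gate blocks channel input on whole-field flashes; and the
delay-extreme behaviors at $\epsilon = 0$ (total silence, exact by the
kernel construction) and $\epsilon = 1$ (responses to both approach and
recession) hold on the full battery.

The architecture's hallmark claims — spiking for looming but *not* for
its time-reversed (receding) counterpart, silence for translating bars,
OFF-bias restricting detection to dark objects, and the down-sampling
ablation ordering — do **not** emerge in this implementation, and the
reason is structural rather than parametric:

1. *The cascade is isotropic.* Every spatial operator (RF pooling, the
   $W_1$/$W_2$ convolutions, $W_3$ pooling, the FFI population count) is
   invariant under reflection; nothing in the network encodes motion
   direction.
2. *The inhibition delay is effectively instantaneous.* Two phase ticks
   are a quarter of a frame, during which the stimulus is static, so the
   delayed inhibition almost always references the current frame's own
   spike pattern; and at phases $t < \epsilon$ the delayed weight
   $\omega(t-\epsilon)$ falls on the previous frame's lightest phases
   ($2^{-7}, 2^{-8}$), so the first two phases of every frame pass
   onsets essentially unopposed.
3. *The stimuli are exact mirrors.* A receding clip is the time-reversal
   of a looming clip, frame for frame.

Together these make the network's response to a receding clip the
(approximate) time-mirror of its response to the looming clip: any
configuration that detects looming somewhere detects receding at the
mirrored time. Empirically, total S-cell spike counts for looming vs.
receding agree to within 0.5% across every convention combination we
tested (delayed-weight vs. current-weight IPSC, weighted vs. pure-rate
FFI, raw vs. normalized RF currents, unit-sum vs. peak-1 kernels, global
kernel widths from 4 to 28 cells, leak constants from 1 to 33 ticks).
The residual asymmetry from causal LIF charging is far too small to
carry a selectivity threshold. Translating bars likewise produce central
S-cell drive during their foveal crossing that matches or exceeds a
looming square's, so no static spatial weighting separates them either.

The corresponding acceptance tests are kept at their specified
expectations and fail visibly rather than being weakened; the suite's
unit and property tests (geometry, coding, currents, LIF contracts,
gating, determinism, causality, I/O) all pass. A mechanism that would
restore approach selectivity — e.g., inhibition delayed on the one-frame
scale with motion-history asymmetry, or physically rendered
(perspective) trajectories that break the mirror symmetry — lies outside
this model family's stated structure and is deliberately not added.

## 4. Parameters at a glance

| Parameter | Meaning | Default |
|---|---|---|
| `alpha1` | ON/OFF residual coefficient | 0.1 |
| `max_rs` | largest RF side (px, at border) | 10 |
| `tau` | LIF leak constant (phase ticks) | 1000/fps ≈ 33.3 |
| `r_k` | RF percentage-area current | 0.6 |
| `rho` | LIF threshold / current gain | 0.9 |
| `sigma1, sigma2, sigma3` | kernel widths (half-width units) | 1, 0.5, 1 |
| `epsilon` | inhibitory phase delay (ticks, 0–8) | 2 |
| `side_length` | input frame side (px) | 100 |
| `dl` | output grid side (derived; validated if set) | 58 |
| `s_th` | FFI gate threshold | 0.1 |
| `theta1, theta2` | output channel mixing | 0.5, 0.5 |
| `fps` | sampling rate (frames/s) | 30 |

Problem sizes used throughout the tests and experiment scripts: 90-frame
(3 s) clips at 100 × 100 px for the behavioral battery, 10–15-frame
clips at 50 × 50 px (a 28-cell grid) for pipeline-level unit tests.

## 5. Numerical and degenerate-input choices

* Coordinates are 0-based, x = column, y = row, origin top-left.
* The ring/region boundary construction uses an absolute tolerance of
  $10^{-9}$ against floating-point ties; region membership treats pixel
  $p$ as the half-open square $[p, p+1)$.
* Zero-contrast specs, constant streams, and empty event sets are valid
  and produce empty spike volumes end to end (tested).
* Histories for the delayed inhibition are ring buffers of depth 8, the
  largest admissible delay; `epsilon` outside $[0, 8]$ is rejected.
* A configured `dl` that disagrees with the built layout is an error,
  not a warning.
* Streams shorter than 2 frames, non-square frames, and size mismatches
  with the configuration are rejected with explicit messages.
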