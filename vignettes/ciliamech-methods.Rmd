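---
title: "Methods: synthetic-data-driven analysis of ciliary transport, antennal mechanics and ciliary protein levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ciliamech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`ciliamech` re-implements, as a tested and reproducible pipeline, three
quantitative analyses used to study how fully assembled sensory cilia in
*Drosophila* chordotonal neurons are maintained:

1. **IFT train kinematics** — kymograph analysis of intraflagellar
   transport (IFT) trains imaged live along the proximal ciliary segment:
   directional separation, track extraction, velocities, train lengths,
   stalls and encounter outcomes.
2. **Antennal mechanics** — the antennal sound receiver treated as a
   damped harmonic oscillator: displacement power spectral density (PSD),
   oscillator fit, fluctuation energy in $k_BT$ units, and the mechanical
   sensitivity gain from pure-tone stimulus sweeps.
3. **Ciliary intensity quantification** — marker-gated segmentation of
   ciliary regions in two-channel volumes, per-antenna intensity
   averages, control normalisation, and Mann–Whitney group comparison.

No microscopy or vibrometry recordings are distributed with the package.
Instead, every analysis stage is driven by a synthetic-data generator
with a known ground truth, so recovery can be measured exactly. What a
passing test shows, and what it does not, is discussed per module below.

# Synthetic IFT movies

`simulate_ift_movie()` renders bidirectional trains on a straight 1D
ciliary track. Each train is a boxcar of its physical length convolved
with a Gaussian point-spread function (PSF), carrying a fixed photon
budget per frame, spread transversely with the same Gaussian. Poisson
photon noise and Gaussian read noise are applied on top of a constant
background.

Key defaults and their rationale:

* **Frame interval 0.12 s** — the spinning-disc acquisition interval used
  for live imaging of larval chordotonal cilia.
* **Pixel size 0.13 µm** — typical for a 100x spinning-disc configuration;
  the live-imaging pixel size is a free parameter of the generator.
* **PSF σ = 0.11 µm** (FWHM ≈ 260 nm) — a realistic emission PSF for GFP
  on a high-NA spinning-disc system.
* **Speeds 0.22 / 1.2 µm/s** (anterograde / retrograde) and mean train
  lengths 358 / 237 nm with 80 / 50 nm spreads — the study conditions;
  the spreads are consistent with the reported min–max ranges
  (152–650 and 115–433 nm).
* **Injection rates 0.15 trains/s per direction** — yields a handful of
  concurrently visible trains on a 5 µm proximal segment, matching the
  visual density of published kymographs.
* **Pause behaviour**: retrograde trains pause with probability 0.76 at
  encounters with anterograde trains; anterograde trains never pause.
  The pause duration (1.0 s default) is not constrained by published
  measurements and is exposed as a free parameter.
* **Photometry**: 1000 photons per train per frame over a background of
  20 counts (read noise σ = 2) gives peak SNR well above 5.

Encounter semantics: a *decision point* is recorded when a retrograde
train moves into a crossing with an anterograde train. Crossings that
occur while the retrograde train is already paused are not decision
points — the train cannot visibly pause again — and are neither drawn nor
recorded in the truth. Each (retrograde, anterograde) pair produces at
most one event.

What the generator does **not** emulate: photobleaching, motion blur
within the 100 ms exposure, curved or 3D ciliary paths, intensity
differences between anterograde and retrograde trains, and
non-stationary backgrounds. Passing recovery tests therefore demonstrate
the correctness of the analysis chain under controlled optics, not
robustness to every property of real recordings.

# Kymograph analysis

`build_kymograph()` samples the movie along the ciliary path at 1 px arc
spacing, taking the **maximum** over a 3 px transverse profile (maximum
rather than mean, so dim trains survive the reduction). Row = frame,
column = arc position, with arc 0 at the ciliary base; anterograde motion
means increasing arc coordinate.

`separate_directions()` implements directional separation by 2D Fourier
quadrant filtering, the principle behind the kymograph-clearing macro
toolsets: remove the static component (per-column temporal median), FFT,
and split the frequency plane by `sign(f_time) * sign(f_space)`;
zero-frequency and Nyquist lines are shared equally. Two numerical
choices matter:

* **Boundary handling.** The kymograph is mirror-padded (reflected) in
  both dimensions before the FFT and cropped afterwards. A tapering
  window (e.g. Hann) would suppress trains near the first and last
  frames to invisibility — on a 60 s recording with 23 s anterograde
  transit times that loses a third of the data — while plain periodic
  wrap-around produces spurious cross artifacts. Reflection keeps the
  signal continuous at the boundaries with no amplitude loss. The
  space-flip symmetry (flipping the space axis swaps the anterograde and
  retrograde outputs exactly) holds to machine precision.
* **Negative clipping.** After the inverse transform, negative
  intensities are clipped to zero; the three components reconstruct the
  input up to that clipping and the boundary padding.

`extract_tracks()` thresholds each directional kymograph at
`mean + 1.5 SD`, with the statistics pooled over both directional
channels: in a channel with little traffic, per-channel statistics
collapse and leakage from the busy channel would masquerade as tracks.
Connected components in the (time, space) plane become tracks, with
per-frame subpixel positions from intensity-weighted centroids. A
component must also be brighter over its own pixels than the opposite
channel is over the same pixels — the abrupt ends of a bright streak leak
a small symmetric echo into the opposite quadrants, and this dominance
test removes those ghosts. The default threshold factor 1.5 was chosen
for streak continuity: at 2 SD the retrograde streak (whose peak is
lower than the anterograde one at matched photon budget) fragments at
noise dips.

**Velocity** (`track_velocity()`): least-absolute-deviations (LAD) slope
of arc position against time over the *non-stalled segments* of a track,
combined as a segment-length-weighted mean. A single regression through
a pause-offset trajectory underestimates the moving speed, since each
pause shifts the subsequent segment; per-segment slopes do not. On
image-extracted retrograde tracks, stalls are detected with a 0.5 µm/s
threshold on positions smoothed by a 5-frame running median: the
centroid jitter of a subpixel streak corresponds to apparent frame-to-
frame speeds of several tenths of a µm/s, so the clean-trajectory
default (0.05 µm/s) would never fire, while 0.5 µm/s sits well below the
1.2 µm/s retrograde speed. Anterograde trains are not scanned for stalls
(they do not pause in this system, and their 0.22 µm/s speed is below
any noise-robust stall threshold).

**Train length** (`train_length()`): per frame, the full width at half
maximum (FWHM) of the background-subtracted spatial profile through the
track position, averaged over the track lifetime. The profile is
upsampled with a cubic spline before the crossings are located, because
the raw sampling (~2 px per PSF FWHM) makes linear interpolation
systematically wide. Two properties of this measure should be kept in
mind: it reports the *convolved* width (true length ⊗ PSF), exactly as a
manual line measurement does on real images, and at the resolution limit
it still reads up to ~8% wide from pixelation. Comparisons across
conditions and the length ranking are unaffected. Lengths are best
measured on the separated directional kymographs, where opposite-
direction crossings do not contaminate the profile. `particles_per_train()`
converts lengths to IFT-B particle counts with the 6.17 nm longitudinal
repeat spacing observed in *Chlamydomonas* anterograde trains
(358 nm → 58 particles, 237 nm → 38).

**Encounters** (`find_encounters()`): interpolated trajectory crossings
of (retrograde, anterograde) pairs within 2 px / 2 frames. The outcome is
`pause` when a stall *starts* within the time tolerance of the crossing —
requiring the stall to begin at the encounter attributes causality
correctly when several anterograde trains pass a halted train — and
crossings that happen while the retrograde train is already mid-stall
are skipped, mirroring the generator's decision-point semantics. On
noise-free trajectories the classifier recovers the configured pause
probability within two standard errors over 20 seeds; on image-extracted
tracks it is conservative, because a pausing train often drops below the
extraction threshold and the track breaks at exactly the frames that
prove the pause.

# Antennal mechanics

`simulate_thermal_trace()` integrates the underdamped Langevin equation

$$ m\ddot x = -K_s x - \gamma \dot x + a\,F_{th}(t), \qquad
   K_s = m\omega_0^2,\quad \gamma = m\omega_0/Q, $$

with white thermal force noise of one-sided PSD $4\gamma k_BT$ scaled by
the active force factor $a$ ($a=1$: passive equilibrium; $a>1$: active
amplification by the mechanosensory neurons, multiplying the stationary
displacement variance by $a^2$). The integrator is semi-implicit
(symplectic) Euler at an internal step of at most $1/(50 f_0)$,
implemented as the algebraically identical driven AR(2) recursion for
speed; a transient of ten relaxation times is discarded. The defaults —
mass 50 ng, $f_0 = 300$ Hz, $Q = 2$, 298 K, 60 s at 6 kHz — describe the
antennal receiver under study. At these settings the sample variance
matches $k_BT/K_s$ within 5%.

`displacement_psd()` is a Welch estimate (Hann window, 50% overlap,
segment length chosen for ≤ 2 Hz resolution, one-sided scaling). A
velocity trace — what a laser-Doppler vibrometer delivers — is converted
by dividing the PSD by $\omega^2 = (2\pi f)^2$, with the zero-frequency
bin excluded. The analysis band defaults to 100–1500 Hz.

`fit_sho()` fits the log-PSD over the band with the harmonic-oscillator
model

$$ S(\omega) = \frac{F_0^2}{m^2\left[(\omega_0^2-\omega^2)^2 +
   (\omega\,\omega_0/Q)^2\right]} $$

for $(F_0, f_0, Q)$ by Levenberg–Marquardt least squares on
log-transformed parameters (mass fixed). Initial values: $f_0$ at the
spectral maximum, $Q$ from the half-power width, $F_0$ from the peak
height. Fitting in log space balances the decades of dynamic range
between the resonance peak and the tails. Derived quantities:
$\gamma = m\omega_0/Q$ and $K_s = m\omega_0^2$.

**Fluctuation energy.** With the effective stiffness defined through
equipartition, $K = k_BT/\langle X^2\rangle$, the receiver's fluctuation
energy is $E = (K_s/K)\,k_BT = K_s\langle X^2\rangle$, reported in
$k_BT$ units ($k_B = 1.380649\times10^{-23}$ J/K). `fluctuation_energy()`
computes $\langle X^2\rangle$ two ways:

* from the **full-band integral of the fitted model**,
  $\langle X^2\rangle = F_0^2 Q/(4 m^2 \omega_0^3)$ in closed form — the
  primary `energy_kBT`;
* from the **trapezoid integral of the measured PSD over the analysis
  band** — reported as `energy_kBT_band`.

The fit-based value is primary because the 100–1500 Hz band holds only
~89% of the variance of a 300 Hz, $Q=2$ oscillator (11% sits below
100 Hz), so a band-limited $\langle X^2\rangle$ systematically
underestimates the energy of a receiver whose stiffness is derived from
the fit; the fitted model extrapolates the missing tails consistently.
At passive equilibrium `energy_kBT` is 1 within 10% at the stated
simulation settings, and scales as $a^2$ for active simulations.

**Gain.** For pure-tone stimulation at the antennal eigenfrequency, the
mechanical gain per sound particle velocity (SPV) level is
$\mathrm{gain} = X \cdot 2\pi f_{eigen} / \mathrm{SPV}$ (dimensionless),
and the mechanical sensitivity of a fly is
$\mathrm{gain}_{max}/\mathrm{gain}_{min}$ across the sweep.
`simulate_forced_responses()` emulates the standard 17-level sweep
spanning 96 dB in 6 dB steps; its gain profile interpolates along a
normalised sigmoid in log-SPV between the configured end gains, so the
configured sensitivity is met exactly at the endpoints. The sweep is
deterministic; measurement noise on displacement amplitudes is not
modelled, so recovery tests check the analysis arithmetic, not
robustness to spectral estimation error of forced responses.

# Ciliary intensity quantification

`simulate_quant_volume()` builds two groups of two-channel volumes
(16×64×64 voxels at 0.4×0.13×0.13 µm): the marker channel defines ~10
capsule-shaped ciliary regions per volume laid out on a jittered grid
(disjoint and in-bounds by construction), and the target channel carries
the signal to be quantified. In the knockdown group the whole in-region
staining is scaled by $(1-r)$, so the group mean ratio equals the
configured reduction exactly; a per-volume lognormal staining factor
(CV 3%) models antenna-to-antenna variability and voxel noise (σ = 10 on
a background of 20, signal 100–150) models the camera. The 3% CV was
chosen so that a 9% median reduction at $n = 10$ antennae per group is
detectable but not trivial, similar to the spread of published
normalised box plots.

The analysis chain replaces interactive surface segmentation with a
deterministic one: Otsu threshold on the marker channel, 26-connected
3D components, minimum size filter (`segment_marker_regions()`), then
mean target intensity per region and per-volume ("per antenna") averages
(`region_intensity_stats()`), normalisation to the **median** of the
control group per experiment batch (`normalize_to_control()`; the median
is used for robustness at small $n$), and a two-sided Mann–Whitney U
comparison (`compare_groups()`: exact for both $n \le 8$ without ties,
normal approximation with tie correction otherwise; verified against
brute-force enumeration for all group sizes ≤ 6).

`dilation_positive_fraction()` scores each cilium's dilation sub-region
as positive when its mean target intensity exceeds the background mean
by more than 2 background SDs; the positivity threshold is a package
default, not a published value. `bending_angle()` fits principal axes to
the dendrite and cilium point sets and reports the deviation from
collinear continuation folded to [0°, 90°], invariant under rotation and
reflection; the reference-axis convention (deviation from the dendrite's
continuation) is the package's choice.

# Reproducibility plumbing

Movies are written as 16-bit multi-page TIFF with a JSON sidecar for the
calibration (pixel size, frame interval) — explicit arguments override
the sidecar on read. Traces and stimulus tables are plain CSV; ground
truth is JSON. `run_pipeline()` executes configured stages from a single
validated configuration (unknown keys are rejected by name), expands one
user seed into independent per-stage seeds so adding a stage never
perturbs another stage's random stream, and writes a manifest with MD5
hashes of every output; identical configuration and seed reproduce
hash-identical tables.

# Problem sizes

The shipped analyses and tests use 60 s movies (500 frames) of a 5 µm
segment, 3–8 movies per question; 60 s mechanical traces at 6 kHz; and
10–20 volumes per group for quantification. These sizes put every
recovered quantity comfortably inside its statistical tolerance while a
full run of the test suite and the analysis scripts completes in a few
minutes on a single core.

# Known limitations

* Retrograde streak widths read ~10% above the boxcar⊗PSF expectation:
  the steeper streak slope and residual crossing contamination broaden
  the per-frame profile. Anterograde lengths match the convolution
  oracle closely.
* Image-level pause-fraction estimates are conservative (see above); the
  calibrated estimate uses the trajectory-level classifier.
* The Fourier separation assigns diffusive or direction-reversing
  particles to both channels; the generator does not produce such
  particles, and the package makes no claim about them.
* All generators are stationary in time; drift, focus loss and
  photobleaching in real recordings require pre-correction upstream of
  this package.
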