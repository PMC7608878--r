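---
title: "Simulating foliage echoes: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating foliage echoes: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echoscape)
```

`echoscape` chains three models: a Lindenmayer-system tree generator, an
inhomogeneous Poisson process (IPP) forest sampler, and a frequency-domain
foliage-echo synthesizer for a monostatic, bat-like sonar. This vignette
explains each model, its assumptions and tunable parameters, the numerical
choices behind the implementation, and what the package's tests do and do
not establish about real-world echoes.

## The tree model

A grammar `lsys_grammar(variables, axiom, rules)` is rewritten in parallel:
every variable with a production is replaced simultaneously at each
iteration, the standard L-system semantics. The canonical two-variable
grammar (`default_grammar()`) uses `g` for a starting/end branch (a leaf is
simplified as an end branch), `d` for a trunk or inner branch, and the
production `g → d(g)[g)+g)`:

```{r}
lsys_expand(default_grammar(), 1)
lsys_expand(default_grammar(), 2)
```

Two conventions deserve explanation.

**End-branch tokens.** The closing marker `)` belongs to the end branch it
terminates, so the token `g)` is rewritten atomically. Rewriting `g` and
`)` independently would double the end markers at every iteration and the
second-iteration string above would not come out as printed.

**Branch markers form a stack, and the strings are lossy.** `(` opens a
child branch (push), the `)` carried by `g)` closes the current branch
(pop), `+` opens a branch at the mirror azimuth of the previous child with
its attachment raised by a random fraction, and `[` advances the
attachment point up the parent axis before opening a branch. Because each
expanded block `d(g)[g)+g)` internally balances its own markers, the pop
owed to the opener that enclosed the original `g` is lost in the printed
string. No local rule can recover the enclosing structure from the flat
string (the grammar is genuinely ambiguous there), so under stack
semantics later blocks chain onto the preceding branch instead of
returning to the trunk. Token and segment counts are unaffected; the
resulting morphology is vine-like at depth rather than perfectly
self-similar, which we judged acceptable for a generator whose purpose is
natural-looking variation.

Turtle geometry is controlled by `geometry_params()`:

| parameter | default | meaning |
|---|---|---|
| `initial_length`, `initial_radius` | 1 m, 0.05 m | trunk dimensions |
| `length_ratio`, `radius_ratio` | 0.7, 0.6 | per-level contraction |
| `branch_angle` | 35° | child divergence from the parent axis |
| `ratio_noise_sd`, `angle_noise_sd` | 0.05 | per-branch Gaussian jitter |
| `raise_fraction_range` | (0.2, 0.5) | attachment raise for `+` and `[` |
| `azimuth_rule` | golden-angle | azimuth of successive children |

None of these are dictated by the underlying branching model; the defaults
were chosen once for natural appearance (golden-angle azimuths mimic
phyllotaxis; contraction ratios near 0.7 give plausible crowns) and every
one is configurable. Ratio noise is truncated by redraw so contractions
stay in (0,1). With all noise standard deviations zero and a degenerate
raise interval, interpretation is exactly seed-independent.

Branch and sub-branch detail beyond the first level comes from mesh
templates. Real CAD tree assets are commercial, so the package ships a
procedural generator (`make_branch_template()`): a tapered tube swept
along a curving axis, a few thinner sub-branches, and triangular leaf
facets scattered near the tips, all deterministic per seed. Any user STL
(binary or ASCII) can be substituted; leaf faces in user meshes are tagged
by an explicit index vector, since mesh formats carry no leaf semantics.
Templates are attached at the first-level attachment points: placed
rigidly one-to-one when template and branch counts match (with optional
jitter), otherwise by randomly selecting a template and applying a random
similarity transform — isotropic scale drawn log-uniformly from
(0.8, 1.25) so up- and down-scaling are symmetric on the log scale, and a
uniform spin about the attachment axis.

Each triangular leaf facet becomes a disc reflector: centre at the
triangle centroid, normal along the face normal, radius from a normal
distribution (default mean 4 cm, sd 8 mm) truncated positive by redraw.

## The forest model

Tree locations follow an IPP whose intensity is a mixture of squared
exponentials,
`λ(s) = Σ Cᵢ exp{−(sₓ−aᵢ)²/hᵢ² − (s_y−bᵢ)²/lᵢ²}` — note the
denominators `h²`, `l²` carry no factor 2, so `h` and `l` are not standard
deviations. Infinite scales give a spatially constant component, i.e. a
homogeneous process. The expected count `∫_D λ` factorizes per component
into 1-D Gaussian integrals and is evaluated in closed form with the error
function; a component wholly interior to the domain approaches `C·π·h·l`.

Sampling uses thinning with the global bound `λ_max = Σ Cᵢ`: always valid,
mildly conservative (a numerical supremum over the domain would reject
fewer candidates but adds failure modes for no benefit at these problem
sizes). The retained points are an exact draw of the process, which the
tests verify against Poisson count statistics and the closed-form marginal
CDF.

Species are sampled independently and merged. The spacing restriction —
two trees of different species must be at least `min_spacing` (default
1 m) apart — is resolved by deleting the member of an offending
cross-species pair that belongs to the later-sampled species, with
deletions reported. This is one admissible choice; the underlying model
does not prescribe a deletion rule, and same-species pairs are never
thinned (clustering within a species is a feature of the intensity).

## The echo model

The sonar is monostatic: emitter and receiver co-located, sensible when
the sensor is small relative to target range. For a pose, the echo is
assembled per frequency bin and inverted to the time domain.

**Beampattern.** A 2-D Gaussian in beam-frame azimuth and elevation
approximates the mainlobe: `S = A₀ exp{−[az²/(2σ_az²) + el²/(2σ_el²)]}`.
Beamwidths are stated as full −3 dB widths read on the amplitude gain in
dB (`20 log₁₀ S/A₀`), giving `σ = (width/2)/√(0.3 ln 10)` and a gain of
`10^(−3/20) ≈ 0.708·A₀` at half the width off axis. The mainlobe used for
culling is the closed ellipse on which that −3 dB level is attained,
`az²/(2σ_az²) + el²/(2σ_el²) ≤ (3/20) ln 10`, whose on-axis crossings are
exactly ±width/2. Reflectors behind the sonar (`|az| > π/2`) are excluded
regardless of beamwidth. A₀ is taken constant over the band; an emitter
spectrum shape could be folded in multiplicatively if needed.

**Disc scattering.** The disc beampattern uses the fitted cosine
approximation `L = P1(c)·cos(P2(c)·β)`, `c = 2πaf/v`, with
`P1(c) = 0.5003c² + 0.6867` and `P2(c) = 0.3999c^(−0.9065) + 0.9979` —
closed-form stand-ins for numerically evaluated spheroidal-wave-function
scattering. `c = 0` is excluded (P2 diverges), and the validity range of
the fits is not documented: very large `c` (leaf much larger than the
wavelength) is extrapolation. Beyond the first zero of the cosine the fit
goes negative; the package clamps the gain at zero by default (no
unphysical sign flips), with the unclamped form switchable. The incident
angle is folded to [0, π/2] via the absolute normal projection: discs are
two-sided.

**Superposition and inversion.** Each in-band bin superposes the `m`
in-mainlobe reflectors with amplitude `A = S·L·(v/f)/(2πr²)` and
round-trip phase `φ = 2πf(2r)/v`. The spectrum stores `A e^{−jφ}`: the
negative sign matches the forward-DFT kernel so that the inverse FFT
places each arrival at its physical delay `2r/v` (with the opposite sign
the echo train would appear time-reversed at the end of the record).
Negative-frequency bins are filled by conjugate symmetry before the
inverse FFT; the imaginary residue must stay below 1e-10 of the peak, and
DC/Nyquist bins are forced real. Shading between leaves is neglected, so
the synthesis is exactly linear in the disc set — a property the tests
check to machine precision.

**Grid defaults.** `fs = 400 kHz`, `n_fft = 4096` (a 10.24 ms record,
about 1.76 m of unambiguous round-trip range per ms of record), band
60–80 kHz, `v = 343 m/s`. A reflector at 2 m already wraps a 4096-sample
record; use `n_fft = 8192` for ranges beyond ~1.75 m. The emission
weighting is flat across the band (matching the in-band-only assumption);
an optional raised-cosine edge taper (off by default) trades range
resolution for sidelobe suppression.

## Scenarios and reproducibility

Scenario I (static sonar, varying beamwidth) and scenario II (figure-eight
fly-through) are composed with `scenario_config()` + `run_scenario()`. The
figure-eight is a closed-form Gerono lemniscate
(`x = A sin t, y = A sin t cos t`) rather than a dynamically controlled
flight path: only pose samples matter for echo generation. Aiming
"at the trees" is realized as aim-at-nearest-canopy-centroid, overridable
with explicit aim points. Every random quantity derives from one master
seed through the fixed counter mapping `derive_seed()` (per species, per
tree, per pose), so runs are bit-identical per seed and per-pose results
are independent of evaluation order.

## What the tests show, and what they do not

The synthetic scenes are the package's own generator output: statistics
verified there (Poisson counts, marginal CDFs, delay/attenuation laws,
superposition, beam symmetry, mainlobe monotonicity) validate the
sampler and the signal chain, not the realism of any particular tree
species. Real foliage differs in ways the generator does not emulate:
leaves are not circular discs, shading and multiple scattering between
leaves are real, trunks, branches and ground contribute echoes,
atmospheric absorption attenuates high frequencies with range, and a
moving sensor incurs Doppler shifts. All of these are out of scope by
design; the disc/beam/superposition model is the deliberate simplification
that makes scene-conditioned echo synthesis fast and fully labelled.

Problem sizes in the test-suite and acceptance runs were chosen to keep a
desk-scale run comfortable: 2000 replicates for count statistics, ~2000
pooled points for goodness of fit, trees of 13–61 segments with 15–25
leaf discs, and a 12-pose scenario over a two-species forest of order ten
trees. All scale linearly if larger studies are needed.
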