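---
title: "Methods: ensemble analyses of bathy phytochrome photoactivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble analyses of bathy phytochrome photoactivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and modelling stance

`hulatwist` implements the statistical layer of a multiscale photoactivation
study of a bathy bacteriophytochrome: the ensemble analyses that sit on top
of nonadiabatic (surface-hopping) excited-state dynamics, ground-state
relaxation MD, and enhanced-sampling free-energy runs. The electronic
structure and force-field engines themselves are out of scope; in their
place the package ships generators that emulate the *statistical structure*
of those ensembles. Every analysis is therefore exercised against inputs
whose ground truth is known by construction, and the test suite closes the
loop: generators advertise windows, labels, and injected events that the
analysis functions must recover exactly.

Units are fixed package-wide: angstrom, picosecond, degree, kcal/mol,
kelvin.

## Bridge geometry and the hula twist

Dihedrals are signed torsions in the IUPAC convention, computed with the
atan2 form (numerically stable at 0° and 180°); the test suite checks a
thousand random quadruples against an independent projection formula at
1e-9° and verifies rigid-motion invariance and reflection antisymmetry.
Time series are unwrapped by minimal-step continuation, valid when the true
per-frame change stays below 180° — a precondition of the frame spacing,
not something the code can detect.

Stereochemistry codes follow the field's six-letter convention: double
bonds (D2, D4, D6 by default, configurable) map to Z below 90° absolute
wrapped value and E at or above it; single bonds map to s/a the same way.
The 90° boundary tie-breaks to E and a. Pfr reads ZZEssa, the Pr
photoproduct ZZZssa; only the D6 letter distinguishes them.

Isomerization detection finds the first crossing of unwrapped D6 through
the ±90° + 360k family, interpolating linearly between frames. Rotation
sense is the sign of the net change over a ±1 ps neighborhood of the
crossing (shorter than the fast decay lifetime, long enough to measure the
partner's rotation); by this package's convention a *negative* change
viewed from the C-ring side is counterclockwise (ccw). The hula-twist flag
requires the adjacent single-bond dihedral D5 to rotate at least 30°
(configurable) with the *opposite* sense over the same neighborhood — the
volume-conserving concerted motion that lets the double bond flip without
sweeping the D ring through the pocket. The sense labels are a fixed
convention: absolute handedness would require a viewing direction the
analysis cannot know, so only consistency (D6 ccw with D5 cw) is
meaningful.

## Surface-hopping ensemble and its generator

The preset `agp2-sh` encodes the study conditions of the nonadiabatic
ensemble: 3028 trajectories, censoring horizon 20 ps, hop-time lifetimes
0.71 ps (fast) and 4.25 ps (slow), a 61/3028 long-lived subpopulation still
excited at the horizon, and a 28% reactive fraction of the whole ensemble.
Two generator choices deserve explanation:

* **Fixed-count composition.** Those numbers are *realized counts* of one
  reported ensemble, so the preset reproduces them as exact counts (a quota
  design): exactly 61 trajectories censored, exactly round(0.28 × 3028) =
  848 reactive, fast/slow membership likewise rounded, with randomness in
  the hop times, the assignment shuffle, and the geometry noise.
  `composition = "binomial"` switches to fully independent per-trajectory
  draws for users who want sampling variability in the composition itself.
* **Truncated component draws.** Hopped trajectories draw their hop time
  from their component's exponential conditioned on t < 20 ps (inverse-CDF
  truncation), so the censored count is exactly the long-lived
  subpopulation. The discarded tail mass is at most 0.9% of the slow
  component; the empirical survival stays within Kolmogorov–Smirnov
  distance 0.004 of the nominal mixture-plus-plateau law, checked at
  n = 50,000 in the suite.

The biexponential amplitudes are not part of the reported conditions; the
preset uses a fast fraction of 0.60 (fast-dominant decay, the typical
situation when most of an ultrafast photoreceptor ensemble decays through
the short channel) and this choice is fixed once here, not tuned.

Reactive trajectories carry the hula-twist kinematics: D6 ramps smoothly
(raised-cosine) from 180° to 0° over a 1.5 ps window centred on the hop,
crossing the Z/E boundary at the hop time, while D5 counter-rotates by 60°;
relaxation later completes D5 into the Pr window only for BV–Pr members.
Non-reactive trajectories make a sub-threshold 45° excursion and return to
the E region. Gaussian jitter (sd 1.5°) is added to all dihedral channels;
at the ramp's ~19°/frame crossing slope this moves the detected crossing by
well under one frame.

## Censored decay kinetics

The survival model is a k-component exponential mixture with right
censoring and an explicit long-lived plateau:

S(t) = Σⱼ aⱼ exp(−t/τⱼ) + π,  Σⱼ aⱼ + π = 1.

Uncensored records contribute the mixture density, censored records
S(censor time). The plateau term is estimated only when censored records
are present and matters: a two-exponential tail alone cannot place 2% of
the mass beyond 20 ps when the slow lifetime is ~4 ps, so omitting π forces
the slow lifetime upward by tens of percent (the numerical pseudo-true MLE
without the plateau is biased +43% on the slow and +14% on the fast
lifetime under the preset conditions, while the plateau model is exact to
four decimals). This is the package's resolution of a genuine modelling
gap: survivors at the horizon are a subpopulation, not tail mass.

Numerics: amplitudes live on a floored simplex (`min_amplitude = 0.02`
each) scaled by 1 − π, lifetimes are log-parameterized, and the optimizer
runs BFGS with a Nelder–Mead polish from 8 quantile-spaced, seeded starts
(mixture likelihoods are multimodal). The floor removes the classic
degenerate solutions in which a vanishing component spikes on the smallest
observations — without it, AIC selection on genuinely monoexponential data
is corrupted by spurious two-component fits. The k = 1 uncensored case
uses the closed form (the sample mean). Model selection minimizes
AIC = 2p − 2logL with p = (k − 1) + k + [π estimated]; AIC rather than BIC
because the component count is small and the cost of missing a real slow
component is higher than the cost of an occasional extra parameter.
Lifetimes are reported as 1/e decay constants of each component.

The quantum yield is n_reactive / n_total with censored survivors in the
denominator (they absorbed a photon and formed no photoproduct), and a 95%
Wilson score interval — better centred than the Wald interval at small
counts, and verified in the suite against the closed form and by exact
binomial coverage enumeration.

## Photoproduct relaxation and classification windows

The relaxation generator partitions its ensemble into the three outcomes
and drives each member from a freshly isomerized bridge geometry (D6 ≈ 12°,
D5 ≈ 170°) to its population's endpoint along a smooth ramp with small
(0.8° sd) noise. The classification windows are package constants shared
with the generator, and they had to be *chosen* — the taxonomy is
qualitative in origin:

* Synthetic D5 references: Pfr at +120°, Pr at −120°, half-width 25°. The
  hula-twist travel is then a +120° net cw rotation passing through the
  180° region, which becomes the *intermediate* D5 window (within 35° of
  180°, i.e. the gap between the two named windows).
* D6 is Pr-like (Z) below 90° absolute value — the same boundary as the
  stereocode letter.
* Planarity (BV–Pr″): D4, D5 and D6 all within 20° of 0° or 180°. D4 is
  what separates a planar bridge from a BV–Pr′ member whose D5 happens to
  sit near 180°: BV–Pr′ endpoints keep D4 ≈ 30°, planar members D4 ≈ 5°,
  and BV–Pr members carry the ~15° D4 relaxation shift.
* BV–Pr additionally requires a D-ring carbonyl hydrogen bond to His278 or
  Tyr165 (geometric criterion 3.5 Å, with a 120° D–H⋯A angle when
  hydrogens are modelled — the standard MD-analysis definition; no
  energetic scoring).

Classification precedence is BV–Pr, then BV–Pr″ (planarity), then BV–Pr′,
else Pfr-like. The Meta-F signature is an overlay, not a fourth class: it
scores three pocket criteria (carbonyl–His278 bond; Gln190 displaced more
than 4 Å from its Pfr-frame reference; Trp440 farther than 6 Å from Gln190,
the open gate) and is true only when all three hold. The 4 Å and 6 Å
thresholds are declared package defaults — the source taxonomy gives no
numbers — and are exposed as arguments.

## Pocket clustering

Distance features default to eight D-ring pairs (ring N and carbonyl O
against Asp196, Gln190, His278, Tyr165, and the nearest water oxygen).
Columns are z-scored before PCA — the pairs span different magnitudes, and
centring-only is one flag away. Clustering is Ward's minimum-variance
criterion (`ward.D2` on Euclidean distances) in the PC space retaining at
least 90% of the variance; k is fixed to 3 by default with silhouette
widths at k−1, k, k+1 reported as diagnostics rather than automatic
selection — the cluster count is a modelling commitment the user should
see, not a hidden optimum. The suite checks Ward against an exhaustive
bipartition search on six grouped points (Ward is greedy, so the equality
oracle is run on data with genuine group structure) and PCA against a
power-iteration eigendecomposition.

Lifetime stratification groups hop records by a per-trajectory interaction
pattern and reports Kaplan–Meier medians per group, so censored records are
handled rather than dropped; the median is NA when a group's survival never
reaches one half.

## Spine tilt

Each helix axis is the leading principal axis of its C-alpha cloud; the
tilt is the angle between axes folded to [0°, 90°], making it symmetric and
rigid-motion invariant. The generator builds ideal α-helical traces
(rise 1.5 Å, 100°/residue, radius 2.3 Å, 25 residues, 0.05 Å jitter); at
that length the principal-axis estimate recovers constructed tilts of 0°,
10°, 30° and 60° within 0.5°.

## Proton-transfer model surface and adaptive bias

The keto↔enol proton transfer is modelled in one dimension on the
collective variable q = d(N–H) − d(O–H). The surface is the quartic whose
gradient factors as c·(q − q_keto)(q − q_barrier)(q − q_enol): the two
minima sit *exactly* at the configured positions with U(enol) − U(keto)
equal to the configured ΔE (default 27 kcal/mol) and the barrier solved by
root-finding on the enol side of the midpoint. With those four constraints
the per-well stiffnesses are derived quantities (reported on the object),
not free inputs. The default barrier is ΔE + 5 kcal/mol — the smallest
qualitative choice that keeps a genuine double well; any barrier above ΔE
can be configured.

Sampling is overdamped Langevin (Euler–Maruyama):
dx = −μ U′(x) dt + sqrt(2 μ k_BT dt) ξ, with mobility μ = 1/(m·γ),
friction γ = 5 ps⁻¹ and an effective CV mass of 50 amu (friction alone
does not fix an overdamped mobility, so the mass is explicit; the pair
gives a diffusion constant of ~1 Å²/ps at 300 K, a typical condensed-phase
scale). The integrator refuses time steps with μ·U″_max·dt > 1 and
suggests a stable one; walls at the simulation range are reflective. The
compiled core uses R's RNG, so runs are reproducible under a seed. The
default dt is 1 fs; the stiff ΔE = 27 surface needs 0.2 fs, which the
stability check enforces.

The adaptive bias deposits Gaussian kernels (bandwidth 0.05 Å, every 500
steps, initial height 1.2 kcal/mol) with the well-tempered attenuation
e^(−V(x)/((γ−1)k_BT)), accumulating V on a 1200-point grid that the
integrator reads by linear interpolation (grid spacing ≪ bandwidth, so the
interpolation error is negligible); γ = ∞ is the standard-metadynamics
limit. At convergence V ≈ −(1 − 1/γ)·F, so
ΔF = −γ/(γ−1)·(V(q_enol) − V(q_keto)), cross-checked by an
exp(V/k_BT)-reweighted histogram split at the barrier top and, in the
tests, against direct quadrature of the basin partition functions. The
estimate errors out rather than reporting zero when the kernels never
reached both basins. For the 27 kcal/mol surface the package uses γ = 20
(residual barrier ≈ barrier/γ ≈ 1.6 kcal/mol ≈ 2.7 k_BT, enough for
repeated recrossings within a few million steps); γ = 10 remains the
general default.

The physical conclusion the model carries: at 300 K an unbiased run of
10⁶ steps never visits the enol basin — the transfer is uphill by ~45 k_BT
— while the biased run recovers the constructed ΔF within 1.5 kcal/mol.

## Problem sizes and determinism

The suite runs at the study-condition scales where the quantities are
defined (3028-trajectory kinetics ensembles, the 63-member relaxation
fixture, 300-frame pocket sets) and uses 10⁵–4×10⁶-step Langevin runs and
n = 50,000 draws for distributional checks; the full suite and the
acceptance script each complete in a few minutes on one core. All
generators are pure functions of (config, seed) and restore the caller's
RNG state; the pipeline writes reports with sorted keys and no timestamps,
so identical configs and seeds give byte-identical files.

## What the synthetic ensembles do and do not show

The generators reproduce the statistical skeleton the analyses assume:
mixture-with-plateau hop kinetics, anticorrelated D5/D6 kinematics,
endpoint windows with hydrogen-bond partners, separated Gaussian pocket
arrangements, ideal helix pairs, and a parameterized double well. Passing
tests therefore demonstrate that the *analysis chain* is correct and
self-consistent at the reported ensemble scales — not that the underlying
dynamics of the real protein are as constructed. Real trajectory data
bring features the generators deliberately omit: anharmonic dihedral
fluctuations and transient recrossings, water exchange on the same
timescale as the H-bond criteria, correlated pocket/backbone motion,
non-exponential short-time decay from the initial-condition distribution,
and force-field-dependent absolute geometries. Conclusions about real
ensembles should rest on the analysis functions applied to real
trajectories; the synthetic layer exists to keep those functions honest.

## Known limitations

* The hula-twist sense labels are convention-relative (see above).
* The censored-mixture fit assumes censoring only at the common horizon;
  staggered censoring works in the likelihood but the plateau
  interpretation is cleanest with a single horizon.
* The Meta-F thresholds (4 Å displacement, 6 Å gate) and the D5 window
  centers are declared defaults, not fitted quantities.
* The 1-D proton-transfer model has no second coordinate, so it cannot
  describe relay mechanisms except as separate surface presets.
* PDB support is a minimal coordinate dialect, not a general parser.
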