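---
title: "Methods: hierarchical structure and mechanics of silk fibres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical structure and mechanics of silk fibres}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silkstruct)
```

## Scope and model

`silkstruct` implements the quantitative analysis chain used to characterise
strong, hierarchically ordered protein fibres such as bagworm silk: a
semicrystalline fibre whose β-sheet crystallites and amorphous segments
alternate along the fibre axis in a lamellar stack, bundle into ~nm-scale
nanofibrils, and derive from a heavy-chain fibroin (H-Fib) built of tandem
PAB + NPAB repeat motifs (polyalanine block + non-polyalanine block).

Five measurement domains are covered, each with a forward model
(`generate_*`) whose ground truth is recorded, so every analysis operation is
validated by parameter recovery rather than against irreproducible physical
specimens:

1. **WAXD** (wide-angle diffraction, Å scale): crystallinity by Gaussian
   deconvolution, rectangular unit cell from three reflections, crystal
   strain from the 002 spacing, azimuthal orientation index.
2. **Meridional SAXS** (nm scale): Kratky transform, harmonic long-period
   detection, one-dimensional electron-density correlation function K(z).
3. **Equatorial SAXS**: nanofibril-bundle size via the Scherrer equation with
   instrumental-broadening correction.
4. **Tensile mechanics**: tilt-corrected elliptical cross-sections,
   force-to-stress conversion, modulus/strength/extensibility/toughness,
   crystal modulus, deformation-stage segmentation.
5. **Sequence**: polyalanine-block detection, tandem-motif segmentation, and
   the residue-count → phase-length arithmetic connecting primary structure
   to the SAXS phase thicknesses.

## The lamellar stack and its scattering

The stack is an ideal two-phase square wave of period $L_p$ (default
38.5 nm) with phase-I fraction $\phi_1$ (default $15.7/38.5$). Its
meridional scattering consists of harmonics at $q_n = 2\pi n / L_p$. The
paper-level source for this geometry reports only peak *positions*; the
relative intensities are an open modelling choice. We use the ideal
square-wave Fourier envelope $[\sin(n\pi\phi_1)/(n\pi)]^2$ applied to the
**Lorentz-corrected** (Kratky, $q^2 I$) peak areas, i.e. $I(q)$ carries a
$1/q^2$ factor. This is the one convention under which the analysis-side
correlation function

$$K(z) \propto \int_0^\infty q^2 I(q) \cos(zq)\, dq$$

of the noiseless profile equals the self-correlation triangle of the
generating density — which is exactly what the package's dual-route test
demands (cosine-transform route vs direct real-space autocorrelation of
η(z)). Had the envelope been placed on $I(q)$ directly, the $q^2$ weight
would rescale order $n$ by $n^2$ and no two-phase decomposition could
recover the stated thicknesses.

K(z) extraction follows the standard triangle construction: a line fitted
over the 20–80 % portion of the drop from the invariant $Q = K(0)$ to the
first (negative) minimum; its intersection with the flat first-minimum
baseline gives the core thickness $d_{pI}$, its zero crossing divided by the
majority-phase fraction (from $K_{min}/Q = -\phi_1/\phi_2$) the mean
thickness $\langle d_{pI}\rangle$; the long period is the dominant local
maximum beyond the minimum. Two numerical guards matter: truncated harmonic
content puts small ripples on K(z), so the first minimum must reach negative
values and the maximum is taken as the *highest* post-minimum peak; and the
baseline is averaged over a ±5 % $L_p$ neighbourhood of the minimum to
suppress ripple. Low-$q$ intensities are extrapolated to $q=0$ with a
quadratic through the first points and the high-$q$ tail is tapered with a
half-Hann window — both standard, both exposed as arguments.

With sharp interfaces, core and mean thickness coincide
($d_{pI} \approx \langle d_{pI}\rangle \approx \phi_1 L_p$). In measured
silk the two differ (e.g. 12.5 vs 15.7 nm) because interfaces are diffuse
and thicknesses polydisperse; the generator does not model interface
gradients (a stated non-goal), so a green dual-route test establishes
correctness of the transform and constructions, *not* fidelity to diffuse
interfaces.

The φ-recovery leg of the dual-route test is run at 8 harmonic orders and
peak width σ = 0.004 nm⁻¹ rather than the 5-order default: with 5 orders the
truncated Fourier series itself biases the baseline ratio by ~0.03 (closed
form, independent of implementation). This choice was made from the closed
form before running the test.

## WAXD conventions

- All Bragg arithmetic uses the profile's own wavelength metadata. The
  static-generator default is Cu-Kα (0.15418 nm) because at Mo-Kα the (200)
  reflection of the silk cell (a = 9.39 Å) would fall below the stated
  10–37° window; time-resolved profiles use the 0.0709 nm synchrotron
  wavelength.
- Crystallinity fitting fixes the six crystalline centres ((200), (210),
  (211), (002), (102)+(300) composite, (202)) at positions computed from the
  cell; widths are bounded (crystalline 0.05–1.5°, amorphous 1–8°, scaled by
  wavelength), areas are solved linearly with non-negativity by active-set
  column dropping, and the amorphous centre floats inside a d-spacing window
  (5.91–3.56 Å, i.e. 15–25° at Cu). The background is a jointly fitted
  linear baseline (switchable to constant/none). The (102)+(300) composite
  is one Gaussian at the midpoint of its component angles.
- The orientation index (180 − FWHM)/180 uses the azimuthal profile sampled
  on the 200 ring by bilinear interpolation; FWHM by linear interpolation at
  half maximum above the ring's minimum. Arcs broader than ~90° overlap
  their mirror images, so recovered FWHM saturates below the nominal value —
  the index remains strictly monotone in the generated spread, which is the
  tested property.
- d002 during deformation is taken from a Gaussian fit (log-quadratic
  regression) in a ±1° window, giving the sub-bin precision that 0.5 %-level
  crystal strains require.

## Fibre-diagram rendering

Each reflection is placed on its 2θ ring with a Gaussian radial profile and
a periodic Gaussian azimuthal arc (FWHM = `orientation_fwhm`) centred on the
equator or meridian per its index; the amorphous halo is isotropic. Arcs are
normalised to unit circular mean so that an azimuthal-*mean* radial scan
reproduces the generating 1D profile including relative crystalline/
amorphous areas — a synthetic-world convention, not detector physics. The
round-trip test uses a 1024² detector at 0.075 mm pixels because the radial
bin width must exceed the per-pixel 2θ pitch near the equator, where the
oriented arcs concentrate intensity; coarser instruments alias.

## Scherrer sizing

The equatorial peak is fitted as a Gaussian; its q-space FWHM converts to
the angular broadening $\beta = \Delta q\,\lambda/(2\pi\cos\theta)$, the
instrumental width (silver-behenate-style calibration, supplied as a
number) is removed in quadrature, and $d = K\lambda/(\beta\cos\theta)$ with
K = 0.9. In q units the chain collapses to $d = 2\pi K/\Delta q$, which is
also how the generator computes the size broadening — the inverse pair is
exact, so recovery error measures only the peak-fitting step.

## Mechanics conventions

- Cross-section: per-filament area $\pi L'^2_a/(4R\cos^2\theta)$ with
  defaults R = 1.70, θ = 10.37°, and two filaments per fibre.
- The elastic-fit window (strain 0.2–1.5 %) is not stated in the source
  material; it sits well below the ~3.3 % stage-I boundary. A tangent-at-
  origin mode is provided as the alternative reading.
- Yield is located by the 0.2 %-offset construction (the source never
  defines its criterion); fracture is the last sample at ≥95 % of the global
  stress maximum, which also handles the gradual post-peak decay of fibre
  bundles.
- Toughness converts as 1 GPa·strain = 1000 MJ m⁻³.
- The synthetic stress–strain law is piecewise linear (elastic slope E to
  the yield strain, then linear hardening to fracture) with defaults
  E = 28.1 GPa, yield 3.3 %, strength 2.0 GPa at extensibility 0.32 — the
  fibre averages the package emulates; the hardening slope follows from
  those four numbers. The strain grid always contains the yield breakpoint
  so the recorded closed-form toughness equals trapezoidal integration
  exactly.

## Sequence model and motif detection

Each tandem unit is PAB (22 Ala) + NPAB; the NPAB is 45 residues of Gly-X
dipeptide (X = Ala:Ser 60:40), a 6-residue insert drawn from Ser/Val/Tyr,
and 87 residues mixing Gly-X and Gly-Gly-X tiles (GGX X = Ala:Tyr 60:40) —
160 residues per unit, five units by default, Gly+Ala fraction ≈ 0.80. The
composition ratios are free parameters chosen once to echo the stated
dipeptide/tripeptide chemistry. Two guards keep ground truth exactly
recoverable: the residue adjacent to the insert is never Ser/Val/Tyr, and
the post-insert stretch never ends in Ala (which would fuse with the next
polyalanine block).

Detection: maximal Ala runs ≥ 10 (between the >20-residue blocks of this
fibroin and the 5–8-residue runs of spidroins); motifs span PAB start to
next PAB start, so n blocks give n−1 complete motifs and an incomplete tail
reported separately; the insert is the best 4–10-residue window with ≥70 %
Ser/Val/Tyr (leftmost, then longest, on ties). The crystal-forming NPAB
segment is defined as PAB-end → insert-start; with the 0.35 nm/residue
β-sheet rise, 22 + 45 = 67 residues map to 23.5 nm (displayed half-up from
23.45), and a 90-residue amorphous remainder against a 15.7 nm phase
thickness shrinks by 50 %.

## Orchestration and reproducibility

`run_static_analysis()`, `run_deformation_analysis()` and
`run_sequence_analysis()` wrap the stages behind JSON-configurable runs
that record the fully resolved configuration and package version; reruns
with identical config and seed are bit-identical. The deformation run
re-measures every frame's SAXS harmonics and 002 centre from synthetic
profiles (an honest per-frame round trip); the orientation-index series is
injected directly rather than rendering dozens of 2D images per run — a
runtime choice, so the deformation report does not test the 2D orientation
path (the static tests do). Stage tables follow the stage I / II / total
layout with per-stage d002, crystal-strain, long-period and
long-period-strain columns.

All randomness flows through explicit seeds; seeded runs are
bit-reproducible and seeds alter only noise, never recorded ground truth.

## Worked example

```{r example}
g <- generate_saxs_meridional(lamellar_params(long_period = 38.5,
                                              phase1_fraction = 15.7 / 38.5))
hp <- find_harmonic_peaks(kratky_transform(g$profile))
hp
cf <- correlation_function(g$profile)
cf
```

## Known limitations

- No paracrystalline disorder, interface gradients, or 3D packing in the
  stack model; no desmearing or absolute-intensity calibration.
- The crystallinity model is Gaussian-only with a single amorphous halo, as
  in the emulated workflow; no Rietveld or texture analysis.
- The fibre-diagram renderer has no polarisation/Lorentz pixel corrections
  (a stated non-goal) and its azimuthal normalisation is chosen for
  round-trip identity, not detector realism.
- Sequence validation is against the parametric generator; real fibroin
  transcripts (the deposited read sets) are out of scope, with the counted
  quantities (22 / 45 / ~160 / 5–8) as fixed points.
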