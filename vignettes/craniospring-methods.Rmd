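---
title: "Modelling spring-assisted cranioplasty: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spring-assisted cranioplasty: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Sagittal craniosynostosis — premature fusion of the sagittal suture —
produces a long, narrow head (scaphocephaly, cranial index CI = BPD/OFD
well below normal).  In spring-assisted cranioplasty (SAC) two parasagittal
osteotomies free the fused strip and compressed metallic springs are
inserted across it; over the following weeks the springs expand and widen
the skull.  `craniospring` is a desk-scale computational laboratory for
this procedure: a parametric synthetic calvarium, a quasi-static
viscoelastic finite-element (FE) solver with spring distractor conditions,
craniometric outcome measures, a five-parameter design-of-experiments (DoE)
sensitivity study, and a synthetic clinical cohort generator for trend
comparison.  This vignette explains the model, its assumptions, the
tunable parameters, and the design decisions taken where the problem was
genuinely open.

## The synthetic calvarium

`generate_skull()` builds a bilaterally symmetric half-superellipsoid vault
shell with the population-average dimensions of a scaphocephalic cohort at
SAC age (about five months):

* outer length OFD = 152.6 mm, outer width BPD = 108.3 mm (baseline
  CI ≈ 0.71),
* uniform shell thickness 2.02 mm,
* coronal and lambdoid suture planes at 81.5° and 70.9° to the reference
  plane (the nasion–meatus analogue, the `z = 0` equator of the generator),
* suture bands 2 mm wide.

The published population table lists OFD and BPD values that would imply a
cranial index of about 1.41; scaphocephaly requires CI < 1, so the
generator assigns the larger printed value (152.6 mm) to the length and the
smaller (108.3 mm) to the width.

Geometry choices worth knowing about:

* **Superellipse exponent (default 2.5).**  A pure ellipsoid (exponent 2)
  has an unrealistically pointed vertex; 2.5 flattens the crown the way
  infant skulls are.
* **Parietal eminence (`eminence_frac = 0.05` at 0.3 of the vault
  height).**  Real calvaria are widest at the parietal eminences, well
  above the skull base.  Without this bulge the widest point of the
  generated vault lies exactly on the fully constrained base rim and the
  BPD cannot respond to expansion at all — a boundary artifact, not
  biomechanics.  The small bulge puts the measured width on free bone; the
  width calibration keeps the generated BPD at its requested value.
* **Vault height (66 mm).**  Not reported for the study population; 66 mm
  (≈ 0.43·OFD) is a plausible vault height above the nasion–meatus plane
  for this age.
* **Suture placement.**  The suture planes are anchored by arc fraction
  along the midsagittal outer curve (coronal at 0.30, lambdoid at 0.79 of
  the front-to-back arc) and inclined at the population angles.  The
  lambdoid anchor is chosen so the parietal arc accommodates the entire
  surgical design space of spring positions, whose posterior extreme
  reaches 62% of OFD behind the coronal suture.
* **Suture material (`suture_modulus_scale = 0.1`).**  Patent sutures in a
  five-month infant are fibrous tissue, an order of magnitude softer than
  the mineralised bone around them; suture-band elements carry a 0.1
  stiffness multiplier by default (set 1 for bone-stiff sutures).
* **Mesh.**  Structured grid of linear tetrahedra (Kuhn subdivision), two
  element layers through the shell thickness, with the left half the exact
  mirror image of the right half so that symmetric loads produce
  mirror-symmetric solutions to solver precision.  The default target edge
  length is 9 mm; `refine_skull()` regenerates the same geometry at a
  finer resolution (the generator is parametric, so regeneration *is* the
  natural conforming refinement).

`apply_osteotomies()` introduces the two parasagittal cuts as zero-width
duplicated-node cracks spanning the parietal region between the suture
bands, and places the two spring notch sets at arc distances A and A+B from
the coronal suture along the cut.  The mediolateral mesh stations are
smoothly remapped so the cut planes are exact mesh planes; a corrective
second pass calibrates the notch-pair separation to LAT within 1%.

**Spring topology.**  Each spring spans the freed central strip
wall-to-wall: its feet sit in notches on the *lateral* (parietal-wall)
faces of the two cuts, so its initial opening equals LAT (≈ 18 mm) and its
expansion pushes the two parietal walls apart.  This is the only reading
consistent with the clinical spring constants — free lengths of 55–61 mm
against an osteotomy separation of ~18 mm — and it gives the osteotomy
distance its observed mechanical role (wider LAT ⇒ less initial spring
compression ⇒ less driving force).

## The viscoelastic finite-element solver

The calvarium is a small-strain isotropic solid whose shear modulus relaxes
by a two-term Prony series,

$$\frac{G(t)}{G_0} = \alpha_\infty + \sum_i \alpha_i e^{-t/\tau_i},
\qquad \alpha_1 = 0.73213,\ \tau_1 = 6720.4\ \mathrm{s},\quad
\alpha_2 = 0.25708,\ \tau_2 = 40322\ \mathrm{s},$$

with $\alpha_\infty = 0.01079$ by the unit-sum constraint.  The time
constants are interpreted in seconds, consistent with distraction forces
dissipating over days.  The bulk response is elastic (relaxation acts on
the deviatoric operator only); volumetric relaxation is not modelled.

`solve_expansion()` integrates the quasi-static equilibrium equations on a
log-spaced time grid (default ≥ 40 implicit steps from 1 s to 5 days)
with the standard recursive internal-variable (exponential-integrator)
update of the hereditary integral.  Because the material is homogeneous up
to a per-element stiffness scale, the update operates on two global sparse
operators — one volumetric, one deviatoric — assembled once per mesh in
compiled code; each step solves one sparse Cholesky system whose symbolic
factorization is reused across steps.

Each spring is a linear compression element between the centroids of its
notch pair: force $F = K(OP_\infty - \text{opening})$, clamped at zero
(a distractor cannot pull itself closed), applied as equal-and-opposite
follower forces along the current centroid line and linearised into the
system matrix, which keeps the spring-dominated late-time plateau
unconditionally stable.  Within each step the follower direction and force
are updated by fixed-point iteration until the true nonlinear equilibrium
residual falls below the solver tolerance (default 10⁻⁶ relative).

**Elastic constants.**  The instantaneous modulus is deliberately an
*effective structural* value, `youngs_modulus_inst = 22` MPa (ν = 0.3).
It was calibrated once so that the simulated spring opening of the
population-mean configuration follows the clinically observed exponential
opening with a time constant of ≈ 1.16 days; it simultaneously reproduces
the other system-level observations — openings plateau within ~5 days,
exceed 90% of the spring free length within three weeks, and the
distraction forces largely dissipate within ~10 days.  Calibrated
effective moduli of tens of MPa (far below quasi-static cortical-bone
values) are standard in validated SAC models; the stiff-bone literature
value (hundreds of MPa) makes the simulated expansion an order of
magnitude too slow against every one of those observations.  Because
$\alpha_\infty \approx 0.011$, late-time openings are spring-dominated and
insensitive to the exact choice.

**Formulation limits.**  Small-strain, small-displacement kinematics with
openings of tens of millimetres on a ~150 mm skull is a stretch — accepted
because the reference framework (linear spring conditions in a commercial
solver) shares it and all conclusions are trend-based.  There is no
contact across the crack faces, no self-contact, no bone growth or
remodelling, and no helmet or gravity loading.

## Craniometric outcomes

BPD and OFD are the maximal mediolateral and anteroposterior extents of
the deformed *outer* surface on or above the reference plane, axis-aligned
in the anatomical frame (the base is fully constrained, so no
re-registration is needed).  On generator meshes the discrete nodal
extremum is refined by one-dimensional parabolas along the two surface
grid directions; this sub-grid estimate makes the diameters evolve
smoothly in time instead of jumping when the winning node changes, which
matters when differencing CI values a few hundredths of a point apart.
CI = BPD/OFD; changes are reported in percentage points,
ΔCI(t) = 100·(CI(t) − CI(0)).  Surgical parameters are normalized as
LAT% = 100·LAT/BPD, A% = 100·A/OFD, B% = 100·B/OFD, with
(A+B)% = A% + B% and K_TOT = K_ANT + K_POST.

## The design-of-experiments study

`build_design()` draws a maximin-optimized Latin hypercube (the stand-in
for the proprietary "optimal space-filling" design of the reference
workflow) over five inputs, by default 79 points in:

| input | range | source |
|---|---|---|
| LAT% | 14.8 – 19.0 | population mean ± sd |
| A% | 24.9 – 37.9 | population mean ± sd |
| B% | 10.3 – 24.1 | population mean ± sd |
| K_ANT, K_POST | 0.17 – 0.68 N/mm | clinical spring range |

`run_design()` executes the FE pipeline per design point and records ΔCI
at 1 s (immediate post-operative), day 1 and day 5 (follow-up).
A full quadratic response surface (21 terms in coded variables, ordinary
least squares) is fitted per output; signed local sensitivities are
one-at-a-time range sweeps normalized by the mid-range output,
$S_i = 100\,[f(x_i{=}\text{up}) - f(x_i{=}\text{low})]/f(\text{mid})$,
with non-monotone sweeps flagged.  An alternative normalization was
considered (by the output range over the design) but the mid-range
normalization is the straightforward reading of "rate of output change";
either way only signs, orderings and time trends are interpreted.

**Stiffness-to-spring mapping.**  The clinical spring table couples
stiffer wires to slightly shorter free lengths.  Imposing that inverse
coupling on the continuous stiffness input confounds the stiffness
sensitivity with a free-length effect that cancels it at follow-up; since
the reference study reports clearly positive follow-up stiffness
sensitivities, the default `"continuous"` mode holds the free length at
the clinical mid-range value and isolates the stiffness effect.  The
`"interpolated"` (table-coupled) and `"discrete"` (snap to S10/S12/S14)
modes remain available; the long-term-plateau analysis uses the discrete
clinical models.

## The synthetic clinical cohorts

`synthesize_cohort()` emulates the two retrospective imaging groups:
an X-ray group (n = 42, spring models recorded, no positions, ΔCI at
day 1 = 3.4 ± 2.5 and follow-up = 4.4 ± 2.5 points) and a 3D-scan group
(n = 20, positions recorded, no spring models, follow-up
ΔCI = 3.7 ± 1.7 points).  Surgical parameters are truncated-normal draws
at the population moments (bounds ± 3 sd); spring models are uniform over
the clinical table; each patient's ΔCI is a linear effect of the
modality's available predictors plus Gaussian noise, with the residual
standard deviation chosen so the *marginal* ΔCI standard deviation matches
the clinical value exactly.  Effect slopes default to the clinically
observed signs (positive combined stiffness, +3.0 points per N/mm;
negative LAT%, −0.3 points per percent; positive (A+B)%, +0.1 points per
percent); their magnitudes are free generator parameters — none are
reported clinically — chosen so that single-predictor R² stays low
(≈ 0.1–0.3), as in the clinical scatter, while the slope signs remain
statistically recoverable from cohorts of the clinical size.  BPD/OFD
pairs are back-solved from each patient's CI trajectory (width change at
fixed length), so the records are internally consistent.  The follow-up
time point of the 3D-scan group is spring removal (~4 months), treated as
the plateaued end-of-expansion state since CI change after 3–4 weeks is
negligible.

What the generator does *not* emulate: anatomical shape variability,
measurement error structure of planar X-rays vs surface scans, age
effects, or any nonlinear dose–response; passing the recovery tests
therefore shows that the analysis pipeline is consistent and well-powered
for cohorts like these, not that the clinical effects are linear.

## Numerical choices and degenerate inputs

* Time grid: log-spaced from 1 s; ≥ 40 steps to 5 days (the step-density
  convergence of day-5/day-20 differences was verified to three
  significant figures at double density).
* Follower direction at the first step is the notch centroid line of the
  undeformed mesh (wall-to-wall, so never degenerate).
* A spring whose opening reaches its free length carries zero load but
  stays in the sparsity pattern with vanishing stiffness.
* Osteotomies with `b_mm = 0` (coincident springs), notch sites beyond the
  lambdoid suture, cuts wider than the vault, meshes too coarse to carry a
  cut (fewer than three parietal stations), and degenerate (non-positive
  volume) elements all raise errors naming the offending input.
* The response-surface fit refuses rank-deficient bases and names the
  collinear terms; sensitivity normalization refuses a ~0 mid-range
  output.
* Cohort slopes that would explain more variance than the target marginal
  standard deviation are rejected.

## Study sizes used in the shipped analyses

The package defaults are a 9 mm target edge length (≈ 1 700 nodes,
≈ 6 200 tetrahedra, two through-thickness layers) for study runs, with the
79-point design completing in a few minutes on one core; the test suite
exercises the same pipeline at a 13 mm edge length.  The mesh-sensitivity
criterion (< 5% change in spring expansion) is met between the 13 mm and
9 mm resolutions for the spring openings; craniometric *differences* a few
hundredths of a point in size remain resolution-sensitive, which is why
the long-term plateau quantity is reported with its design-point spread.

## Known limitations

* The vault is a smooth proxy, not a CT-derived template: absolute ΔCI
  levels (ours ≈ 3.5 points at follow-up for the mean configuration) sit
  within the clinical bands, but quantities tied to the authors' template
  geometry — notably the absolute size of the spring-position effect and
  the few-hundredths-of-a-point CI drift between day 5 and day 20 — are
  reproduced in order of magnitude, not digit-for-digit.  Our model's
  day-5→day-20 mean CI change is slightly *negative* (≈ −0.02 points):
  at pinned spring opening the eminence bulge partially tracks the
  still-decaying spring force, outweighing the small positive opening-lag
  component (≈ +0.05 points) that would otherwise match the published
  value.
* Sutures are straight bands; the wavy in-vivo suture morphology and its
  local strain effects are not represented.
* No cranial growth during distraction; justified by the separation of
  time scales (reshaping in days, growth in months).
* The solver is validated against closed-form one-dimensional and patch
  oracles and by its internal equilibrium/symmetry invariants — not
  against patient-specific imaging.
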