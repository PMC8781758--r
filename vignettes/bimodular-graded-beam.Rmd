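---
title: "A bimodular functionally graded beam model of cortical bone under bending fatigue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bimodular functionally graded beam model of cortical bone under bending fatigue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Cortical bone is a bimodular material: its effective elastic modulus differs
in tension and compression, so the neutral axis of a bent bone beam does not
sit at mid-depth. Under cyclic four-point bending the two sides also damage
differently — linear microcracks accumulate on the compressed side, diffuse
damage on the stretched side — so the modulus becomes graded through the
thickness and the neutral axis migrates over fatigue life. The measurable
signature of this process is the pair of surface strain magnitudes
$(\varepsilon_C, \varepsilon_T)$ recorded at a fixed measurement stress at
intervals through the life of the specimen.

`bimodbeam` turns each such strain pair into a quantitative description of
the graded section, and verifies the resulting analytical model against an
independently implemented finite-element solution.

## The model

Heights $y$ are measured from the *current* neutral axis, positive toward
the compression (upper) side. The modulus is anchored at the axis value
$E_0$, assumed constant over life, and graded logarithmically on each side:

$$E(y) = E_0\left[1 - \ln\!\left(1 - \alpha_C\, y / h_{\mathrm{ref}}\right)\right],
\qquad 0 \le y \le h_C,$$
$$E(y) = E_0\left[1 - \ln\!\left(1 + \alpha_T\, y / h_{\mathrm{ref}}\right)\right],
\qquad -h_T \le y < 0,$$

with $h_C + h_T = h$ the beam height and $h_{\mathrm{ref}}$ a reference
length (default 6 mm, the nominal specimen height). Both sides use the same
orientation: positive $\alpha$ stiffens the material away from the axis,
negative $\alpha$ softens it, and $\alpha_C = \alpha_T$ gives a
mirror-symmetric section with the axis exactly at mid-depth. The logarithmic
argument must stay positive and $E > 0$ must hold across the section, which
bounds each gradient to
$-(e-1)\,h_{\mathrm{ref}}/d < \alpha < h_{\mathrm{ref}}/d$ for side depth
$d$.

A note on orientation: with the source equations printed in two opposite
sign conventions for the compression side, this package adopts the form used
consistently inside the force/moment balance (above). In the opposite
convention the compression gradient is $-\alpha_C$; a *decreasing*
$\alpha_C$ here is the same physical statement as an *increasing* plotted
compression gradient there, namely progressive softening of the compressed
side.

Plane sections give $\varepsilon(y) = y/\rho$, so the measured strain pair
fixes the kinematics directly:

$$h_C = h\,\frac{\varepsilon_C}{\varepsilon_C + \varepsilon_T}, \qquad
h_T = h\,\frac{\varepsilon_T}{\varepsilon_C + \varepsilon_T}, \qquad
\rho = \frac{h}{\varepsilon_C + \varepsilon_T}.$$

The stress profile is $\sigma(y) = E(y)\, y / \rho$ — continuous and zero at
the neutral layer, which is precisely the property the graded (rather than
bilinear) model buys. Force and moment balance of the section then read

$$A_{FC}(\alpha_C) + A_{FT}(\alpha_T) = 0, \qquad
A_{MC}(\alpha_C) + A_{MT}(\alpha_T) = \frac{M \rho}{w E_0},$$

where $A_{FC}, A_{FT}$ are first moments and $A_{MC}, A_{MT}$ second moments
of the dimensionless modulus shape over each side. These two equations
determine the two unknown gradients at every life fraction. The bending
moment in the inner span is $M = \sigma w h^2/6$ at the measurement stress
$\sigma$ (the machine load is $F = \sigma w h^2/(3a)$).

## Closed-form integrals and the solvers

Substituting $y \to -y$ shows that the tension-side integrals reduce to the
compression-side kernel, so only two antiderivatives are needed. With
$c = \alpha/h_{\mathrm{ref}}$ and $x = c\,d$:

$$\int_0^d [1 - \ln(1 - c y)]\, y\, \mathrm{d}y =
\tfrac34 d^2 + \frac{d}{2c} + \left(\frac{1}{2c^2} - \frac{d^2}{2}\right)\ln(1 - x),$$

and the analogous $y^2$ form for the moment kernel. Both cancel
catastrophically as $c \to 0$, so for $|x| < 0.05$ the implementation
switches to the exact series
$d^2[\tfrac12 + \sum_k x^k/(k(k+2))]$ (16 terms; truncation error below
$10^{-22}$ relative at the switch point). The closed forms are validated
against adaptive quadrature to $10^{-10}$ relative over a grid of more than
100 admissible $(\alpha, d)$ pairs in the test suite.

Both balance equations are strictly monotone in the right variables, which
makes the two solvers simple and deterministic (no randomness anywhere):

* **Forward** (`forward_strains`): given $(\alpha_C, \alpha_T)$, force
  balance is strictly increasing in $h_C$, so `uniroot` on the admissible
  interval yields the unique split; the moment balance then gives $\rho$ and
  the surface strains.
* **Inverse** (`solve_alphas`): given a strain pair, $(h_C, h_T, \rho)$ are
  known. For fixed $\alpha_C$, force balance is strictly increasing in
  $\alpha_T$ (inner 1-D root); substituting into the moment balance gives a
  strictly increasing outer function of $\alpha_C$ (the outer bracket is
  located by an 81-point scan of the admissible interval before the root
  polish). Root tolerances are $10^{-13}$ on the parameter, which leaves
  balance residuals near machine precision — orders of magnitude inside the
  acceptance thresholds of $10^{-9} h^2$ and $10^{-9} h^3$.

The round trip `forward_strains` then `solve_alphas` recovers gradients to
better than $10^{-12}$ on a $20 \times 20$ grid spanning
$\alpha \in [-0.5, 1]$ on both sides (run by `scripts/acceptance.R`).

### Anchoring E0

The source study fixes $E_0$ but never states how. The package default,
`homogeneous_initial`, chooses the homogeneous-beam value
$E_0 = 2\sigma_{\mathrm{meas}}/(\varepsilon_{C0} + \varepsilon_{T0})$, which
makes the pre-fatigue state exactly homogeneous ($\alpha_C = \alpha_T = 0$
up to the measured 2819/2807 asymmetry). On the averaged initial strains
this gives $E_0 \approx 23.5$ GPa, physiologically plausible for bovine
cortical bone along the long axis. A `fixed` mode accepts any externally
measured value; all downstream gradients scale with this choice, a known
identifiability limit of the model (only $M/E_0$ enters the moment balance).

## Trajectory analysis and the segmented fits

`analyze_trajectory` inverts the model at every life fraction and reports
the neutral-axis offset $h_T - h/2$ (negative once the axis has migrated
toward the tension side, which happens exactly when
$\varepsilon_C > \varepsilon_T$), the gradient series, and the extreme-fibre
stresses.

The compressive strain evolution is two-phase linear. `fit_two_segments`
fits two independent least-squares lines over every interior partition with
at least two points per side, selects the partition with the smallest pooled
residual sum of squares, and reports the breakpoint as the *intersection* of
the two lines, clamped to the gap between the partitions (gap midpoint if
the lines are parallel). The intersection refinement matters: with eleven
uniformly spaced observations the 28%-of-life kink falls between samples,
yet noiseless data still returns the breakpoint exactly. The pooled
$r^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ uses one total sum of squares about
the global mean; which convention produced the published value is not
stated, so the simplest one is used. A constant response (zero SST) is
reported as $r^2 = 1$ with a degeneracy flag.

## The synthetic generator

No raw strain data is deposited ("available on request"), so the package
ships a generator that emulates the *reported structure* of the
measurements:

| parameter | default | source |
|---|---|---|
| initial strains | 2819 / 2807 με | printed averaged pre-fatigue pair |
| compressive breakpoint | 0.28 of life | reported two-phase transition |
| tensile total rise | 4% | reported increment |
| samples | 11 | reported number of strain groups |
| phase rises | 400 / 150 με | shape choice (see below) |
| noise | 20 με (Gaussian, i.i.d.) | stand-in for DIC resolution |

The phase-1/phase-2 compressive rises are not printed anywhere; 400 and
150 με were chosen once as a "rapid then slow" shape that keeps the
breakpoint clearly identifiable, and are exposed as parameters. The noise
model is a stand-in — no measurement uncertainty is reported for the DIC
strains — with the magnitude set to the order of DIC strain resolution.
What the generator does *not* emulate: inter-specimen variance structure,
serially correlated measurement error, and any nonlinearity of the true
strain evolution within a phase. Passing tests therefore demonstrate
correctness of the inversion and estimation machinery under the stated
structure, not robustness to every pathology of real DIC data.

Exact fixtures (`generate_forward_fixture`) bypass the piecewise-linear
shape entirely: strains are generated by the forward model from prescribed
gradient paths, so inverse recovery can be checked against ground truth to
solver precision.

### What the model implies for the gradient directions

On the paper-shaped trajectory the recovered $\alpha_C$ falls monotonically
(the compressed side softens ever deeper — the two-phase signature of the
compressive strain appears in $|\alpha_C|$), and the neutral axis migrates
monotonically toward tension. The tension-side gradient is *not* monotone:
force balance links the three quantities, and because
$A_{FC}(\alpha_C; h_C) = |A_{FT}|(\alpha_T; h_T)$ with both kernels
increasing in $\alpha$ and depth, a deepening compression zone ($h_C$ up,
$h_T$ down) forces $\alpha_T$ *upward* whenever the asymmetry grows faster
than the moment target $M\rho/(wE_0)$ shrinks. During the rapid phase-1
compressive rise that is exactly what happens — $\alpha_T$ rises until the
breakpoint and declines thereafter, for every $E_0$ anchor we examined
(12–40 GPa). A monotone tension-side decline over the whole life would
require a phase-1 compressive rise too gentle to produce the reported
two-phase behaviour; the package reports what the balance equations imply
rather than forcing the pattern.

## The finite-element verification

An independent plane-stress solver rebuilds the graded beam with 4-node
bilinear quadrilaterals (2×2 Gauss quadrature, sparse assembly) and checks
that the zero-strain line *emerges* at the analytically predicted height —
the neutral axis is never prescribed in the FE model. Design choices:

* **Plane stress with thickness w**, matching the thin side-face
  idealisation of the beam.
* **Poisson's ratio** is not stated in the source; default $\nu = 0.3$,
  a common value for cortical bone FE, exposed in the config.
* **Material sampling**: per-element constant modulus evaluated at the
  element-centroid height relative to the analytical neutral axis,
  mirroring the per-element material assignment of commercial workflows.
* **Supports and loads at single nodes** (vertical restraints at the outer
  contacts, one horizontal restraint, F/2 down at each inner contact). The
  2 mm contact radius of the physical fixture is not modelled; strains are
  extracted at mid-span, far from the contacts by Saint-Venant's principle.
* **Mesh**: structured grid over the outer span × height; `ny` even so a
  node row lies at mid-depth, and the contact x-positions must land on node
  columns (a multiple of 21 elements along the default 42 mm span).
  Reference mesh 126 × 24; a patch test, an equilibrium check
  ($10^{-8}$ relative), and a convergence sweep (42×8 → 168×32, observed
  order ≈ 2 in the surface strain) back the discretisation. Strain is
  recovered from the bilinear shape functions on the mid-span line, where
  $\varepsilon_{xx}$ is constant within an element column; the neutral axis
  is interpolated between node rows.

At the reference mesh the emergent FE neutral axis agrees with the
analytical $h_T$ to well under 0.1% of the beam height along the whole
demo trajectory (the verification scripts compute the exact figures), far
inside the 2% consistency band the workflow asserts. The published
FEM-vs-experiment offset (6–11%) is *not* reproducible here — it measures
model-vs-measurement discrepancy on raw data that was never deposited — so
FEM-vs-analytical consistency on synthetic trajectories stands in for it.

## Problem sizes and runtimes

The shipped workflow uses the study-scale problem throughout: 11-point
trajectories, a $20\times20$ gradient grid for round-trip validation, 100
seeded replicates for the breakpoint study, and the 126 × 24 reference mesh
(≈ 6,400 degrees of freedom) for the FE cross-check. The complete test
suite runs in under a minute on one core; `scripts/acceptance.R` in a few
seconds.

## Known limitations

* Isotropic, linear-elastic, 2-D plane stress only; no orthotropy,
  porosity, contact mechanics or geometric nonlinearity.
* $E_0$ constant over life by assumption; a time-dependent axis modulus is
  outside the model class.
* The gradient magnitudes depend on the $E_0$ anchor (see above); only the
  neutral-axis kinematics are anchor-free.
* No fatigue-life prediction: the model describes the section state at each
  measured instant, not damage-rate laws.
* Measured strains are taken as given (the DIC step is upstream of this
  package); strain pairs are assumed positive magnitudes at a common
  measurement stress.
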