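---
title: "Implicit membrane geometries: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Implicit membrane geometries: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imembrane)
```

# The hydration field

An implicit membrane replaces explicit lipids by a scalar hydration field
$f_{hyd}(\mathbf{x}) \in [0,1]$: 0 means a fully hydrophobic environment
(bilayer core), 1 fully aqueous. Membrane-dependent energy terms weight their
per-atom contributions by this field; the burial term implemented here is

$$\Delta G_{memb} \;=\; \sum_{r=1}^{N_{res}} \sum_{a=1}^{N^r_{atom}}
  \bigl(1 - f_{hyd}\bigr)\, \Delta G^{atom}_{w,l},$$

so an atom in bulk water ($f_{hyd}=1$) contributes exactly zero and a buried
atom contributes its full water-to-bilayer transfer energy.

All structures are assumed to be in *membrane coordinates*: membrane normal
along $z$, membrane center (the bilayer mid-plane, or mid-surface for curved
geometries) through the origin. The package does not reposition proteins;
placement is the job of dedicated tools and databases.

## One transition family

Every geometry uses the same rational sigmoid
$g(s) = s^n/(1+s^n)$ on a normalised distance $s \ge 0$, with two shared
parameters:

* `halfThickness` $t$ (Å, default **15**) — the hydrophobic half-thickness;
  the field crosses $0.5$ at depth $|z| = t$, giving a 30 Å hydrophobic
  core, the textbook value for a phospholipid bilayer.
* `steepness` $n$ (dimensionless, default **10**) — sharpness of the
  hydrophobic–aqueous transition; $n = 10$ gives a transition zone of a few
  Ångström on either side of the half-depth, matching the qualitative
  published fields for this model family.

Using one family everywhere is a deliberate choice: the literature on this
model class prints the functional form only for the ellipsoid radial factor,
and production energy functions use closely related but differently
parameterised depth sigmoids whose constants are not published. Internal
consistency across geometries (slab limits, composition identities) is worth
more here than chasing unpublished constants, and both $t$ and $n$ are
user-settable if a different calibration is needed.

## Geometries

**Slab.** $f_{thk}(z) = g(|z|/t)$. Depends only on depth.

**Ellipsoid (micelle / bicelle).** A bicelle is modelled as a planar disc of
radius $a$ (`innerRadius`) capped by a hemispherical rim. We define an
effective radial coordinate

$$r \;=\; a + \sqrt{\max(0, \rho - a)^2 + z^2}, \qquad
  \rho = \sqrt{x^2+y^2},$$

i.e. distance is measured from the *edge* of the planar disc, and compose the
radial factor $h = g(r/R_{out})$ with the depth term by the soft union
$f = f_{thk} + h - f_{thk} h$. Design notes:

* The printed form of this model family says only that $r$ is "distance from
  the center of the ellipsoid" without defining the metric for $a > 0$; the
  edge-referenced metric above reproduces the intended field — a flat
  30 Å-thick core over the disc and a hemispherically capped rim — with a
  single formula, and reduces *exactly* to the spherical micelle when
  $a = 0$. Inside the disc ($\rho \le a$) it is bit-for-bit the slab
  composition, since $r = a + |z|$ there.
* The outer radius is derived, not free: $R_{out} = a + t$. We read "inner
  radius + membrane thickness" with the *half*-thickness so that the rim cap
  transitions on the same 15 Å scale as the flat membrane; taking the full
  bilayer thickness would make the rim twice as soft as the face, which has
  no physical rationale for a detergent rim.
* The micelle is therefore not a separate geometry: `ellipsoidGeometry(0)`.

**Vesicle.** $f = g(|d|/t)$ with signed radial depth
$d = \lVert \mathbf{x} - \mathbf{c} \rVert - R$ about the sphere center
$\mathbf{c} = (0,0,\mp R)$. The embedding origin always lies on the
mid-surface, so a structure positioned for the slab is also positioned for
any vesicle radius. `curvature = "down"` (center below, the default) curves
the membrane away underneath the protein; `"up"` mirrors it.

**Double vesicle.** Two concentric spheres *centered at the origin* (unlike
the single vesicle — here the origin is the common sphere center, not a
membrane point) with mid-surface radii $R_1$ (`innerRadius`) and
$R_2 = R_1 + 2t + d$, where `distance` $d$ is the gap from the outer edge of
the inner membrane to the inner edge of the outer membrane. Defining the
parameter edge-to-edge makes overlapping membranes unrepresentable. The
fields combine by the product rule $f = f_1 f_2$: a point is hydrophobic if
it is inside *either* membrane. The combination rule is not printed in the
literature for this model class; the product is the De Morgan dual of the
pore's union rule and the only symmetric choice that is 0 on each
mid-surface and 1 far from both. At large $R_1$ the field converges to the
product of two parallel slabs (verified to $10^{-4}$ in the tests at
$R_1 = 10^6$ Å).

## The aqueous pore

$f_{cavity} = 1/(1 + (\rho/\rho_0)^m)$ around an axis parallel to $z$
through $(x_0, y_0)$: 1 on the axis, 0.5 at the pore radius $\rho_0$, 0 far
away, with steepness $m$ (default 10). Published pore models for this family
are more elaborate (per-slab ellipses fitted to the structure); the radial
sigmoid keeps the two contracts that everything downstream relies on — the
composition algebra and the pore-facing classification — while staying
closed-form and geometry-independent. The pore composes with *every*
geometry through

$$f_{hyd} = f_{thk} + f_{cavity} - f_{thk} f_{cavity}
  = 1 - (1-f_{thk})(1-f_{cavity}),$$

the probabilistic union of the two aqueous regions: commutative, identity 0,
absorbing 1, never smaller than either input.

## Gradients

Every geometry implements its analytic gradient (`transitionGradient`,
composed with the pore by `gradientFHyd`), as force-based protocols require.
The tests compare them against central finite differences
($h = 10^{-4}$ Å) at 1000 random points per geometry with the criterion
$|\nabla_{analytic} - \nabla_{FD}| \le 10^{-6}\max(1, |\nabla_{FD}|)$ — a
relative bound with a unit floor, because slab gradients have exactly-zero
lateral components for which a pure ratio is 0/0.

Degenerate points are handled explicitly: at a sphere center (vesicle,
double vesicle, micelle center) the field has a removable radial singularity
and the gradient is defined as the zero vector with a warning; on the pore
axis the field has a smooth maximum for $m > 1$ and the gradient is zero
without comment. The sigmoid and its derivative are evaluated through
overflow-safe forms ($s^{-n}$ rearrangements for $s > 1$) so huge radii
(e.g. $R = 10^6$ Å slab-limit checks) stay finite. The soft union is guarded
so that its algebraic identities (identity 0, absorbing 1, bounds) hold
*exactly* in floating point rather than to within an ulp.

# Scoring

**Energy table.** The transfer energies $\Delta G_{w,l}$ are pluggable
(`energyTable()`, `readEnergyTable()`) with a three-level lookup: exact
(residue, atom) rows, residue-level rows spread evenly over side-chain heavy
atoms (backbone scored 0; for traces without side chains — glycine or
CA-only synthetic structures — the residue value rides on the CA so the
mechanics remain testable), and element-level fallbacks. Unmatched atoms
score 0 with a warning. The shipped `defaultEnergyTable()` is a
**demonstration scale** (aliphatics/aromatics negative, charged residues
positive, in the style of published side-chain hydrophobicity scales); it is
deliberately *not* presented as the parameterization of any production
energy function, whose per-atom values are not published.

**Classification.** Residues are labelled at a representative atom (CA by
default; a side-chain-centroid mode is available): `pore_facing` iff
$f_{cavity} > 0.1$ and $f_{thk} < 0.75$ (the established rule for this model
family), then `lipid_facing` if $f_{hyd} < 0.25$, `aqueous` if
$f_{hyd} > 0.75$, else `interface`. The 0.25/0.75 cut-offs are our choice —
the benchmark literature uses these categories without printing thresholds —
placed symmetrically about 0.5 and exposed as arguments.

# Parameter estimation

`defaultBicelleRadius()` implements the standard heuristic: the largest
CA–CA distance within 3 Å of the membrane center, halved, times three —
an estimate that keeps the mimetic larger than the protein's transmembrane
cross-section. `checkBicelleSize()` warns when the inner radius is smaller
than half the maximal atom-pair cross-section in that slice.

`optimizeGeometryParams()` grid-searches the kind-specific parameters
(ellipsoid: inner radius 10–100 Å step 5; vesicle: $R \in \{80..600$ step
$20, 1000, 10^6\}$ Å × both curvature signs, mirroring the 80–600 Å range
over which curvature predictions are typically run; double vesicle: gap
10–300 Å step 10 at $R_1 = 1000$ Å). The objective — not specified in the
literature beyond "match the hydrophobic residues to the spanfile" — is the
Jaccard index between $\{$residues with CA $f_{hyd} < 0.5\}$ and the
spanfile residues: symmetric, bounded, and indifferent to residue ordering.
Balanced accuracy is available as an alternative. Ties break
deterministically toward the smallest parameters (grid order). As the
sensitivity caveat in the source material warns, the optimum can move when
span boundaries shift by a few residues; the tests cover this as a
robustness (non-crash) property, not a value assertion.

# Ensemble metrics

**Enrichment**: with $k = \lceil 0.1\,N \rceil$, the overlap
$|S \cap R|/(k \cdot 0.1)$ between the $k$ lowest-score and $k$ lowest-RMSD
models — 10 for complete overlap, 0 for none. Ties are broken by a stable
sort on model id, making the statistic platform-deterministic.

**Pnear**: the formula is cited but not printed in the source material for
this model family; we use the standard Boltzmann-weighted convention

$$P_{near} = \frac{\sum_i e^{-r_i^2/\lambda^2} e^{-E_i/kT}}
  {\sum_i e^{-E_i/kT}},$$

with defaults $\lambda = 2$ Å (a typical backbone/interface RMSD similarity
scale) and $kT = 1$ energy unit, both exposed on the API and CLI. Energies
are shifted by their minimum before exponentiation — mathematically a no-op,
numerically essential.

**Design metrics**: sequence recovery (fraction of native residues recovered
over masked positions), per-amino-acid recovery relative to the $1/20$
random background, and the KL divergence $D(p_{designed}\,\|\,p_{native})$
over the 20 amino acids with pseudocount $10^{-4}$ (direction and smoothing
are our choices; the source material states neither).

# Synthetic study conditions

The generators emulate the *geometric* situations the methods are designed
for, with known ground truth:

* `makeTMHelix(n)` — ideal α-helical CA trace (rise 1.5 Å/residue, helix
  radius 2.3 Å, 100°/residue), centered at the origin, span = residues with
  $|z| \le 15$ Å.
* `makePoreBundle(nHelices, poreRadius)` — vertical helices on a circle of
  radius $\rho_0 + 3$ Å so inward-pointing CAs (within 0.3 Å of closest
  approach) are ground-truth pore-facing and outward CAs are lipid-facing.
* `makeCurvedBundle(R)` — straight CA traces along local sphere normals with
  midpoints on the sphere of radius $R$ centered $(0,0,-R)$; default lateral
  extent 200 Å, chosen so curvature is informative (at 120 Å radius the
  outer helices tilt far enough that a slab misplaces them badly, which is
  exactly the regime where curved refinement matters for large channels).
* `makeFunnelEnsemble(n, q)` — RMSDs $\sim |N(0, 5\,\text{Å})|$ and scores
  $q \cdot \text{slope} \cdot r + (1-q) N(0, 5)$: $q = 1$ is a perfect
  funnel (enrichment exactly 10), $q = 0$ uncorrelated (expected enrichment
  1, the random-overlap value).

All generators are byte-deterministic given a seed and restore the caller's
RNG state. What they do **not** emulate: side-chain packing, sequence
diversity beyond poly-alanine, experimental coordinate error, or the
energetics of real decoy ensembles. Passing tests therefore certify the
*geometry, composition, estimation and metric machinery* — not predictive
accuracy on real membrane proteins, which additionally depends on the energy
function used around this field.

Problem sizes in the shipped tests were chosen to make the suite fast while
keeping the statistics meaningful: $10^5$ random positions for range
invariants, 1000 points per geometry for gradient checks, 50 Å boxes at
$R = 10^6$ Å for slab limits, $10^4$ random ensembles for metric bounds, and
100 seeds × $10^4$ models for the random-overlap expectation.

# Known limitations

* The ellipsoid is isotropic in $x,y$ (a disc, not a general triaxial
  ellipsoid); elongated nanodiscs are out of scope.
* The pore is a single straight cylinder-like field; branched or tilted
  channels and per-depth pore profiles are not modelled.
* The default energy table is a demonstration scale; quantitative burial
  energies require loading a calibrated table.
* No repositioning: structures must already be in membrane coordinates.
* Curvature sign conventions assume a single protein embedding at the
  origin; multi-copy systems on one vesicle are not supported.
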