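---
title: "Correcting dynamical scattering in electron diffraction data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting dynamical scattering in electron diffraction data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynred)
```

## The error model

Crystallographic refinement treats the measured intensity of a Bragg
reflection as kinematic, $I \propto |F|^2$.  In electron diffraction a
second elastic scattering event inside the crystal adds a contribution
that is, to a good approximation, uncorrelated with the kinematical
structure factor of the reflection it lands on: intensity scattered
*out of* strong beams arrives *in* other reflections with effectively
arbitrary phase.  Modelling that contribution as a complex-valued
dynamical component $F_{dyn}$ with $\mathrm{E}|F_{dyn}|^2 =
\varepsilon_{dyn}^2$, added to the kinematical structure factor, the
expected observed power obeys

$$\mathrm{E}\,|F_{obs}|^2 = |F_{kin}|^2 + \varepsilon_{dyn}^2 ,$$

so in a plot of observed against calculated amplitudes the data follow
a hyperbola $\left(|F_{calc}|^2 + \varepsilon_{dyn}^2\right)^{1/2}$
that intercepts the $y$ axis at $\varepsilon_{dyn}$: weak reflections
are systematically overestimated, strong ones barely touched.
`fit_epsilon()` estimates $\varepsilon_{dyn} \ge 0$ by unweighted
least squares on amplitudes,

$$\hat\varepsilon = \arg\min_{\varepsilon}\sum_i
  \left(|F_{obs,i}| - \sqrt{|F_{calc,i}|^2 + \varepsilon^2}\right)^2 ,$$

and `fit_epsilon_scaled()` alternates this with the closed-form
observed-to-calculated scale $k = \sum |F_o| m_i / \sum m_i^2$,
$m_i = (|F_{c,i}|^2+\varepsilon^2)^{1/2}$, to a relative tolerance of
$10^{-8}$ (at most 50 rounds; the two parameters are nearly separable,
so convergence takes a handful of iterations).

The resolution dependence of the error is captured by refitting
$\varepsilon$ inside ten resolution bins holding equal numbers of
reflections — low-resolution bins collect any remainder — and then
either fitting a continuous form to the per-bin values (a line
$\varepsilon(d) = a d + b$ or a two-term exponential
$a e^{bd} + c e^{ed}$) or keeping the per-bin step function.
Evaluation clamps $\varepsilon(d)$ below at zero and clamps $d$ to the
fitted bin range: both continuous forms misbehave when extrapolated,
and a correction evaluated outside the data that defined it is not
meaningful.

## The correction

In the absence of dynamical scattering, observed and calculated
intensities are linearly related.  The expected inflation of a
reflection with kinematic intensity $I_{kin}$ at resolution $d$ is

$$k_{dyn}(I_{kin}, d) = \frac{I_{kin} + \varepsilon(d)^2}{I_{kin}} ,$$

the reciprocal of a generalized Wiener filter $S/(S+N)$ with
signal-dependent weighting.  `correct_intensities()` multiplies each
intensity *and its sigma* by $1/k_{dyn}$, evaluated with the plug-in
estimate $\tilde I = \max(I_{obs}, \sigma)$ for the unknown kinematic
intensity:

$$I_{corr} = I_{obs}\,\frac{\tilde I}{\tilde I + \varepsilon(d)^2}.$$

Design points, in decreasing order of consequence:

* **Plug-in estimate.**  The kinematic intensity is unknown at
  correction time; using the observation itself is standard Wiener
  practice and keeps the correction model-independent once
  $\varepsilon(d)$ is fitted (it can be applied as a stream transform
  of an HKL file).  The $\sigma$ floor keeps the factor defined for
  zero and negative weak measurements.
* **Negative intensities are retained**, never zeroed or deleted —
  downstream French–Wilson-style treatments expect the full
  distribution.  They receive the factor evaluated at the floor, i.e.
  the strongest down-weighting.
* **Sigmas co-scale exactly**, so $I/\sigma$ is invariant to machine
  precision; the correction changes relative weights *between*
  reflections, not the internal consistency of one.
* **Factors lie in $(0, 1]$** and, with a per-bin (constant within
  bin) $\varepsilon$, are monotone in $I$, so intensity ordering
  within a resolution bin is preserved.

For data refined against amplitudes (the protein convention) a
discrete per-bin correction is applied in the amplitude domain:
$F_{corr} = F_{obs}\,\tilde F / (\tilde F^2 + \varepsilon_b^2)^{1/2}$
with $\tilde F = \max(F_{obs}, \sigma_F)$ — the square root of the
intensity-domain factor, so squaring corrected amplitudes reproduces
the intensity route.  A step function is preferred over a continuous
fit here because the $\varepsilon(d)$ curves of macromolecular data
are non-monotonic (secondary structure and solvent impose their own
resolution dependence) and a low-parameter form would be misspecified.

The error term is fitted on amplitudes, matching the observed-versus-
calculated amplitude plots it summarizes; intensities are converted by
$F = \sqrt{\max(I, 0)}$ *for fitting only*.  All fits are unweighted
least squares.

## What the simulator emulates — and a bias it exposes

`simulate_observed()` generates every symmetry-unique reflection to a
resolution limit, computes kinematic structure factors from a model,
applies an arbitrary overall amplitude scale (real integrated data
carry the detector/scaling pipeline's scale), and adds the dynamical
component exactly as the error model assumes: independent Gaussian
real and imaginary parts with standard deviation
$\varepsilon(d)/\sqrt2$ each, so $\mathrm{E}|F_{dyn}|^2 =
\varepsilon(d)^2$, followed by optional Gaussian or Poisson counting
noise.  Weak reflections are then overestimated on average and
`mean(I_obs) - |F_kin|^2 \to \varepsilon^2`, both of which the test
suite verifies.

One property of this generator deserves emphasis because it bounds
what "parameter recovery" can mean.  Under a complex-Gaussian
perturbation the observed amplitude is **Rice distributed**, and the
Rice mean does *not* lie on the quadrature hyperbola: for
$|F_{kin}| \gg \varepsilon$ a second-order expansion gives

$$\mathrm{E}|F_{obs}| \approx |F_{kin}| +
  \frac{\varepsilon^2}{4|F_{kin}|}
  \approx \sqrt{|F_{kin}|^2 + \varepsilon^2/2} ,$$

because the component of $F_{dyn}$ parallel to $F_{kin}$ averages out
of the mean amplitude — only half the dynamical power survives.  At
$F_{kin} = 0$ the mean is $\varepsilon\sqrt{\pi}/2 \approx
0.886\,\varepsilon$.  Consequently the amplitude-domain least-squares
fit estimates between $\varepsilon/\sqrt2$ and $0.886\,\varepsilon$
depending on the signal mix — about $0.8\,\varepsilon$ under this
package's study conditions, in *every* signal regime.  The expected
*power* identity is exact ($\mathrm{E}|F_{obs}|^2 = |F_{kin}|^2 +
\varepsilon^2$); only the mean-amplitude hyperbola is approximate.
The package fits the amplitude hyperbola as the method defines it and
documents the bias rather than silently switching to an
intensity-domain fit; tests of the fit's correctness therefore use
exactly-constructed hyperbolic data (where recovery is exact to
$10^{-6}$), while simulation-based tests assert the properties that do
hold: positivity, monotone resolution dependence, expected-power
conservation, and strict contraction of the refitted $\varepsilon$
after correction (the contraction factor is about 1.6–1.7 under these
conditions; larger published reductions additionally re-refine the
model between the two fits, which is outside this package's scope).

The generator draws the dynamical component independently per
reflection — the minimal model consistent with the uncorrelatedness
assumption.  Real dynamical scattering couples neighbouring
reflections through the excitation geometry, depends on crystal
thickness and orientation, and conserves intensity globally; none of
that is modelled, which is precisely why passing these tests
demonstrates the statistical machinery, not the physics of any
particular crystal.

**Study conditions** used by the simulation-based tests and the
acceptance script, chosen once to resemble a small-molecule data set:
orthorhombic P2~1~2~1~2~1~ cell $15 \times 18 \times 19$ Å, 16-atom
C/O toy structure with $U_{iso} \in [0.01, 0.05]$ Å$^2$, resolution
limit 0.8 Å (5815 unique reflections under *mmm*), amplitude scale 10
(so $\varepsilon^* = 2$ perturbs mainly the weak tail, as in real
data), no counting noise for recovery checks, Poisson noise at 5–20
counts per intensity unit where uncertainties are needed.

## Supporting computations

**Kinematic structure factors.**  $F(h) = \sum_{sym}\sum_{atoms}
occ\, f(s)\, T(h)\, e^{2\pi i\, h\cdot(Rx+t)}$ with $s =
\sin\theta/\lambda = 1/(2d)$ throughout (stated prominently because
$1/d$ and $1/(2d)$ conventions coexist in the field), isotropic
Debye–Waller factor $e^{-8\pi^2 U_{iso} s^2}$ and anisotropic
$e^{-2\pi^2 \sum U_{ij} h_i h_j a^*_i a^*_j}$.  Symmetry copies are
handled by index transformation ($h' = hR$ plus a translation phase),
which applies the correct rotated ADP without expanding atoms.  The
engine is checked against a pre-expanded plain-loop direct summation
to $10^{-10}$ relative on random triclinic models.

**Electron form factors.**  The built-in table parameterizes the
elastic electron scattering factors of H, C, N, O and S as five
Gaussians over $s \in [0, 2]$ Å$^{-1}$.  Refinement programs expect
the nine-coefficient Cromer–Mann form (four Gaussians plus a
constant); `fit_cromer_mann9()` refits by Levenberg–Marquardt on a
0.01-spaced grid, initialized from the four largest-amplitude source
Gaussians with the fifth amplitude as the constant and widths bounded
at zero.  The refit reproduces the source curves to better than
$10^{-2}$ (max absolute, carbon: $1.8 \times 10^{-3}$) and the
forward value at $s = 0$ to 0.5%.  The $s$ range and unweighted
objective are this module's choices; they match the resolution range
of atomic-resolution data.

**Unit-cell refinement.**  In electron diffraction the cell and the
detector distance are nearly perfectly correlated, so the lattice is
refined against idealized interatomic distances instead (DFIX 1–2 and
DANG 1–3 restraints, the latter deliberately treated as distances,
not angles).  With fractional coordinates fixed, the weighted residual
$\sum ((d_{model}(cell) - t_i)/\sigma_i)^2$ is minimized over the free
cell parameters (orthorhombic default: axes free, angles fixed at
90°) by a Nelder–Mead simplex restarted until the residual change
falls below $10^{-12}$ relative — three smooth parameters, so
robustness was preferred over gradient speed.  Distances are taken to
the nearest symmetry/lattice image, since bonded pairs may straddle
cell boundaries.  Alternating this with coordinate re-refinement is
the natural extension and is deliberately not included; a single
fixed-coordinate cell refinement is the deliverable, and callers can
iterate externally.

**Merging statistics.**  $R_{merge} = \sum_{hkl}\sum_i |I_i -
\langle I\rangle| / \sum_{hkl}\sum_i I_i$ over multiply-observed
uniques; $R_{meas}$ adds $\sqrt{n/(n-1)}$; CC½ is the Pearson
correlation of random half-dataset means (seeded split, isolated from
the global RNG).  With no multiply-observed reflections the R factors
are reported absent (`NA`), never zero.  Completeness counts
theoretical reflections by direct enumeration under the Laue group
without subtracting systematic absences (documented convention —
absences are space-group-specific and the count is used
comparatively).  High-resolution cutoff diagnostics report the first
bin failing $I/\sigma > 1$ and the first failing CC½ > 50%
separately; because the walk rule is convention-dependent, neither is
applied automatically.

## Numerical choices

* `fit_epsilon()` brackets the 1-D minimum on a 201-point grid over
  $[0, \max|F_{obs}|]$ then refines with golden-section/parabolic
  search; the boundary $\varepsilon = 0$ is compared explicitly so an
  error-free data set returns exactly zero.
* The two-exponential $\varepsilon(d)$ fit is multi-start (nine
  sign/rate combinations plus a near-linear start); if no start beats
  the flat model it falls back to the per-bin step function with a
  warning rather than returning an unstable curve.
* Binning sorts by $d$ descending with a stable sort, so ties keep
  input order and results are deterministic; the per-bin
  representative resolution is the arithmetic mean of member
  $d$-spacings, which serves as the abscissa for $\varepsilon(d)$
  fitting.
* HKLF4 reading accepts both terminator-ended and EOF-ended files and
  ignores batch columns; writing refuses values that overflow the
  fixed 8-column fields instead of silently mangling them.
* All simulation entry points require an explicit seed and restore the
  caller's RNG state (`withr::with_seed`).

## Limitations

* The correction needs calculated amplitudes, i.e. an initial model;
  amplitude accuracy matters more for refinement than phasing, so this
  is rarely binding, but the package offers no model-free mode.
* $\varepsilon(d)$ is heuristic: no predictive theory links it to
  crystal thickness or orientation here.  For plate- or needle-shaped
  crystals the error should also be examined per rotation-angle group;
  the data structures carry per-crystal ids for that purpose, but no
  angle-resolved fit is provided.
* Full dynamical treatments (Bloch-wave or multislice refinement) are
  out of scope, as are frame integration, scaling across frames,
  phasing and model refinement.
* The protein amplitude route computes atoms-only calculated
  amplitudes if structure factors are made with this package's engine
  (no bulk-solvent model), which inflates the apparent low-resolution
  error; per-bin correction absorbs most, but not all, of that
  misfit.
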