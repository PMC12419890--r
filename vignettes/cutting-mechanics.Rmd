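---
title: "Cutting mechanics of thin leaves: model, measurements and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cutting mechanics of thin leaves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cutmech)
```

## The model and its assumptions

Steady-state blade cutting of a thin sheet is treated as a fracture
process: advancing the cut by `dx` creates new crack surface of area
`t dx`, at an energetic cost `G_c t dx`, where `t` is the sheet thickness
and `G_c` the tearing energy. Equating this with the work of the external
load gives the lower bound

$$F \ge G_c\,t.$$

No tool property appears: an ideally sharp razor and a blunt tool share
the same bound. Real tools dissipate extra energy near the crack tip.
Parametrizing the tool by a single length, its cutting-edge radius $R$,
dimensional analysis gives this extra cost as $C\,\sigma_c R\,t\,dx$, with
$\sigma_c$ a characteristic stress of the cut material and $C$ a
dimensionless contact constant of order one. Hence

$$F_f = G_c\,t\,(1+\Omega), \qquad
  \Omega = \frac{C\,\sigma_c\,R}{G_c},$$

so the normalized force $F_f/(G_c t) = 1 + \Omega$ depends only on the
ratio of the edge radius to the *material length scale* $G_c/\sigma_c$.

Assumptions worth keeping in mind:

- the sheet is thin enough that bending and buckling contributions are
  negligible (the experimental pre-cut wedge exists precisely to suppress
  them);
- rate effects are ignored — cutting-speed sensitivity is weak (tripling
  the speed raises forces by roughly a fifth), and all measurements are
  taken at one speed;
- a single length scale characterizes the tool. For a complex tooth this
  is a modelling choice; the edge radius is the most natural one, but not
  the only candidate;
- $\sigma_c$ is identified with the ultimate tensile strength. This is
  appropriate for elastomer pseudoleaves; for real leaf laminae the right
  stress measure (yield, shear, modulus, critical energy density) is an
  open question, and since $R_{crit} = \text{tol}\cdot G_c/(C\sigma_c)$
  is linear in $1/\sigma_c$, the critical radius below which a blade can
  be called sharp shifts proportionally. For a nominal tropical-leaf
  parameter set ($\sigma_c$ = 3 MPa, $G_c$ = 400 J m⁻²) the 5% critical
  radius evaluates to 3.3 µm; order-of-magnitude statements of ~10 µm
  require either a smaller effective $\sigma_c$ or a looser force
  tolerance. The package implements the formula as stated and leaves the
  choice of $\sigma_c$ to the caller.

`classify_sharpness()` labels a blade *ideally sharp* for
$\Omega < 0.05$ (strictly below — at exactly the threshold the blade is
transitional), *geometry dominated* for $\Omega \ge 1$, and
*transitional* in between. The 0.05 cut-off is the empirical level at
which measured fracture forces become indistinguishable from the lower
bound; both it and $C$ (default 2) live in `cut_model_config()`.

Uncertainty on derived quantities ($G_c t$, $G_c/\sigma_c$) is
first-order Gaussian propagation with independent errors; covariances are
not modelled because the dispersions entering the model (material
characterization, thickness mapping) come from separate measurements.

## Measurement definitions

**Force traces.** A trial is two passes at constant stage speed
(0.3 mm s⁻¹ over 5 mm by default): the first cuts intact material and
measures the total cutting force $F_c$; the second re-runs the open cut
and measures the spacing force $F_s$ (sidewall friction plus elastic
sheet deformation). The fracture force is $F_f = F_c - F_s$. Forces are
averaged over a 2 mm steady-state window after the initiation peak.
Biological laminae vary in thickness between samples, so their forces are
rescaled to the substrate mean thickness,
$F \cdot \bar t_1 / t_1$; elastomer sheets vary by under 5% and are not
corrected.

**Edge geometry.** The wedge angle is the interior angle between two
lines fitted along the straight parts of the tip cross-section; the edge
radius is the radius of the smallest circle tangent to both lines that
still fits inside the cross-section. Both definitions are implemented
literally (see *Numerical choices*).

**Materials.** Young's modulus is the least-squares slope of the initial
linear region (default strain window 0–5%, configurable — stiff
materials whose linearity ends earlier need a narrower window, and very
compliant elastomers benefit from a wider one); the UTS is the stress
maximum; the tearing energy uses the classical pure-shear relation
$G_c = W(\lambda_c)\, h_0$, with $W$ the strain energy density of the
unnotched specimen at the critical stretch of its notched twin and $h_0$
the unstrained specimen height. Engineering stress and strain are used
throughout, consistent with defining the UTS as force over initial area.

**Allometry.** Scaling exponents are OLS slopes on log10-transformed
data, with a standard t-interval on the slope. The t-interval is a
deliberate, documented choice; it is exact under lognormal scatter and
the generator produces exactly that.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `C` | 2 | – | near-tip contact constant |
| `omega_sharp_threshold` | 0.05 | – | ideal-sharpness cut-off |
| `window_length` | 2e-3 | m | steady-state averaging window |
| `settle_fraction` | 0.1 | – | post-peak settling tolerance |
| `straightness_deg` | 2 | deg/step | flank straightness threshold |
| `n_resample` | 150 | points | uniform resampling of a contour |
| `tol_px` | 0.05 | px | bisection tolerance on the radius |
| `containment_window` | 7 | points | outline smoothing for containment |
| `strain_window` | 0–0.05 | – | modulus fit window |

## The synthetic study

`synthetic_study_config()` fixes the study conditions; its defaults *are*
the emulated experiment:

- two groups of 15 workers, body masses evenly spaced in log10-space over
  1.9–55.5 mg (callow) and 2.3–54.8 mg (forager);
- pristine edge radii drawn size-invariant from a truncated normal with
  mean 162 nm and sd 120 nm; forager radii follow
  $R_f = a\,m^{-0.87}$ with lognormal scatter (sdlog 0.5) clamped to the
  attainable range 89–11712 nm. The prefactor $a$ maps the geometric
  mid-mass onto the geometric centre of that range; the scatter
  magnitude is an assumption, since the true wear distribution at a given
  mass is unknown;
- wedge angles 77 ± 15° (callow) and 93 ± 9° (forager);
- substrates: 4:1 PDMS ($G_c$ 98 ± 9 J m⁻², UTS 6.0 ± 2 MPa, E 4.1 ±
  0.3 MPa) and 10:1 PDMS ($G_c$ 197 ± 25 J m⁻², UTS 5.5 ± 2 MPa, E 1.6
  ± 0.3 MPa) at 200 and 400 µm with 5% relative thickness dispersion,
  matching the measured 210 ± 10 / 420 ± 15 µm sheets;
- per-trial true $G_c$ is drawn with the material's stated dispersion
  (specimen-level heterogeneity); $\sigma_c$ enters the ground truth at
  its nominal value — the crack-tip stress scale is treated as a material
  constant while sheet-to-sheet toughness varies. This choice keeps the
  parameter-recovery regression's error structure interpretable;
- traces: initiation peak at 0.8 mm with 1.3× overshoot, exponential
  settling over 0.05 mm, additive Gaussian noise of 1 mN at 300 Hz,
  5 mm travel; spacing forces drawn uniformly at 12–22% of the total
  (pseudoleaf profile; plant substrates use 9–14%).

The generator emulates plateau statistics, wear allometry and material
dispersion. It does **not** emulate: venation or any spatial
heterogeneity within a sheet, mechanistic abrasion (wear is sampled, not
accumulated), sensor drift or calibration error, rate dependence, or
correlated errors between $G_c$ and $\sigma_c$. Passing tests therefore
demonstrate that the pipeline recovers known ground truth under realistic
dispersion — not that real leaves obey the model; the initiation-peak
shape is invented and only the plateau it settles onto matters
downstream.

Problem sizes in the tests and analysis scripts (two groups × 15 workers
× 4 substrates, 300 Hz traces, 8 material replicates, 50 contours) mirror
the emulated study design; replicate counts for distributional checks
(e.g. 20 studies for toughness recovery, 5 for slope recovery) were
chosen to hold Monte-Carlo error well below the tolerances being
asserted.

## Numerical choices

- **Settling rule.** The published record leaves "after the initial
  peak" unspecified. The rule here: the initiation peak is the global
  force maximum; the window starts at the first later sample whose force
  lies within `settle_fraction` (10%) of the median force over the final
  2 mm of travel, and spans the window length. Earliest valid window
  wins — a deterministic tie-break. Traces whose post-peak travel is
  shorter than the window raise an "insufficient steady state" error,
  which the study pipeline converts into the short-steady-state validity
  exclusion. With the default generator shapes this rule recovers
  plateaus with < 1% bias; on an instantaneous-settle trace it is exact.
- **Second-pass alignment.** The spacing window is aligned to the same
  displacement interval as the first-pass window, keeping the two means
  comparable.
- **Negative fracture forces** (spacing above total) are flagged, never
  clipped or discarded — exclusion is a pipeline policy, not a
  measurement one.
- **Thickness correction** refuses to run twice unless explicitly told
  to (`allow_recorrect`), which also provides the exact inverse
  (swap the two thicknesses).
- **Flank detection.** The contour is resampled to 150 points uniform in
  arc length, so the straightness criterion (turning angle < 2° per
  step, after a 5-point moving average) is independent of digitization
  density and pixel scale. The two longest straight runs, trimmed by two
  points at each end, are fitted by total least squares (principal axis).
  Fewer than two runs raises a "no flanks" error; runs within 1° of
  parallel raise a degenerate-geometry error (a rectangle does exactly
  this).
- **Edge radius.** Circle centres are constrained to the interior
  bisector (bitangency is enforced exactly); containment requires the
  centre inside the polygon — the open contour closed by its bounding
  cut edge — and every edge at distance ≥ radius minus a slack. The
  slack (default `max(0.01 px, 2× flank-fit residual)`) and a light
  7-point smoothing of the outline absorb digitization jitter; on a
  noiseless outline the smoothing displaces the tip arc by < 0.01 px.
  For wedge-plus-tangent-arc tips containment is monotone in the radius,
  so bisection (tolerance 0.05 px) finds the smallest contained circle; a
  brute-force 0.1 px grid search is kept as an independent oracle. A tip
  finer than the pixel scale returns the resolution floor rather than
  zero.
- **Energy integration.** Strain energy density uses trapezoidal
  integration with linear interpolation of the final partial segment;
  the generator solves its critical stretch against the same quadrature,
  making zero-noise tearing-energy recovery exact rather than
  discretization-limited. The estimate is stable to within 0.5% under a
  ~7× change in sampling density.
- **Statistical checks.** "Callow forces consistent with the minimum" is
  assessed the way the study frames it: the group mean normalized force
  must fall inside the propagated lower-bound uncertainty band, with a
  pooled one-sample t-test as a secondary guard at the 1% level (the
  generator's truth has $\Omega > 0$ by construction, so an
  ever-larger sample would eventually reject equality at any fixed
  level — the band, not the p-value, is the scientific claim). The
  $C\sigma_c$ slope in the parameter-recovery regression is limited by
  how many heavily worn blades a single population draws, so recovery is
  asserted on replicate-averaged estimates.

## Limitations

- The edge-radius estimator assumes the tip region is reasonably
  described by two straight flanks joined by a convex tip; strongly
  concave or multi-faceted tips violate bitangency and will be reported
  at the smallest circle consistent with the fitted lines.
- Contour extraction from real micrographs (thresholding, segmentation)
  is out of scope; the reader ingests ordered coordinate lists.
- The pure-shear relation assumes ideal pure-shear kinematics; real
  leaf tissue violates the homogeneity this rests on, and toughness from
  free-running-crack tests can differ substantially from cutting-based
  estimates — the model itself predicts cutting assays bounded below by
  $G_c t$, which is one way to detect inflated toughness values.
- The recovery regression treats the measured edge radius as error-free;
  with noisy radius estimates its slope would attenuate.
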