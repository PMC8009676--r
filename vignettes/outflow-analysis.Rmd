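---
title: "Quantifying conventional aqueous outflow: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying conventional aqueous outflow: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`outflowr` implements the quantitative core of a study design that is common
in glaucoma pharmacology: a treatment (here, prototypically, a rho-kinase
inhibitor) is hypothesised to lower intraocular pressure (IOP) by acting on
the trabecular meshwork (TM), and the hypothesis is interrogated through a
chain of measurements — clinical before/after IOP tables, ex vivo perfusion
of enucleated eyes, Goldmann-equation bookkeeping, in vivo imaging of
Schlemm's canal (SC) collapse with inverse finite-element estimation of TM
stiffness, atomic force microscopy (AFM) on cryosections, and electron- and
fluorescence-microscopic morphometry. This vignette documents the models
each stage assumes, the tunable parameters and their defaults, the numerical
choices, and the limits of what the synthetic-data tests demonstrate.

## Clinical cohort statistics

Cohort tables hold integer IOPs (mmHg) before and within a month after
treatment. `cohort_summary()` reports arithmetic means and SDs;
`paired_t_one_tailed()` applies the paired one-tailed t-test appropriate for
a directional (lowering-only) hypothesis on normally distributed IOPs.

Outlier screening (`tukey_flags()`) is the Tukey upper fence
`Q3 + 1.5 IQR` with linear-interpolation quartiles. Only the upper fence is
applied by default, because screening asks whether an implausibly *high*
pressure distorts the cohort mean. Exclusion is always an explicit flag of
`cohort_summary()`, never silent: published tables sometimes print means
that include an eye their own footnote flags (the bundled first cohort
does), so reproducing a printed number requires control over inclusion.

The zero-variance degenerate case (every pair unchanged) errors rather than
returning `p = 0.5`: a paired t-test is undefined without variance in the
differences, and silently fabricating a p-value would hide a data problem.

## Outflow facility from stepped perfusion

An enucleated eye is perfused at a sequence of pressure steps (default
4.5–21 mmHg, nine steps). Because flow needs time to stabilise after each
step change, `average_step()` averages pressure and flow over only the final
4 minutes (240 s) of each step; the flow coefficient of variation over that
window is the step's quality metric. `qc_steps()` implements the rule that a
poor step invalidates everything after it — once an eye misbehaves
(CV > 0.10, or mean pressure more than 0.5 mmHg off target), later steps are
not trusted. Both thresholds are package defaults, exposed as arguments;
they are deliberately strict because facility enters downstream analyses in
log scale, where a single corrupted step leverages the fit.

`fit_facility()` fits the power-law pressure–flow model

\[ Q = C_r \left(\frac{P}{P_r}\right)^{\beta} P, \qquad P_r = 8\ \text{mmHg}, \]

with \(C_r\) the outflow facility (nl/min/mmHg) at the reference pressure
and \(\beta \in [-1, 1]\) a mild pressure-nonlinearity. \(\beta = 0\)
recovers the strictly linear Goldmann picture, and the fit falls back to it
when the nonlinear solve fails. The fit is parameterised in \(\log C_r\)
because facility is log-normally distributed across eyes; the standard error
of \(\log C_r\) comes from the nonlinear-least-squares covariance
(Levenberg–Marquardt via `minpack.lm`). Ex vivo, the downstream (episcleral
venous) pressure is zero, so the full perfusion pressure drives flow.

`compare_facilities()` tests group differences on \(\log C_r\) with
inverse-variance weights \(1/\mathrm{se}^2\); with equal weights it reduces
exactly to the ordinary (Welch) t-test on log values, which the tests
verify. Percent differences between group means are reported in *both*
conventions found in the literature — \((\bar a/\bar b - 1)\) and
\((\bar a - \bar b)/\bar a\) — and always labeled, because the two can
differ by tens of percentage points (e.g. 84% vs 46% for the same pair of
means) and published texts switch between them.

## Goldmann accounting of IOP changes

At steady state, aqueous inflow balances outflow:
\(Q = C\,(\mathrm{IOP} - \mathrm{EVP}) + F_U\), with EVP the episcleral
venous pressure and \(F_U\) the pressure-independent (unconventional)
outflow. Assuming treatment leaves EVP and \(F_U\) unchanged and suppresses
inflow by a fraction \(x\), the treated-eye IOP predicted from facility
changes alone is

\[ \mathrm{IOP}_{pred} = -\,x\,\frac{Q_{PL}}{C_{NT}}
   + \frac{C_{PL}}{C_{NT}}\,(\mathrm{IOP}_{PL} - \mathrm{EVP})
   + \mathrm{EVP}. \]

Two accounting ratios are computed by `percent_accounted()`: the predicted
IOP *drop* over the observed drop (`diff_ratio`), and the predicted over the
measured treated-eye IOP *level* (`level_ratio`). Neither EVP nor \(x\) is
usually measured, so `goldmann_sweep()` evaluates the accounting over an
EVP grid (default 4–10 mmHg by 0.5, spanning plausible rodent and human
values) and \(x \in \{0, 0.10, 0.15\}\), reporting an envelope rather than a
point. Since \(d\,\mathrm{IOP}_{pred}/d\,\mathrm{EVP} =
1 - (1 - x)\,C_{PL}/C_{NT} > 0\) whenever treatment increases facility,
`diff_ratio` falls and `level_ratio` rises monotonically with assumed EVP —
a useful analytic check that the sweep verifies numerically. \(F_U\)
cancels identically when \(x = 0\), which the tests confirm on random
inputs. Default \(F_U = 0\).

## TM stiffness from SC collapse (forward and inverse model)

As IOP rises, SC collapses — more readily the softer the TM. The package
quantifies this with a deliberately idealised pseudo-2D plane-strain
section: an elliptical SC lumen (default semi-axes 90 × 5 µm — a wide, flat
slit, as the canal appears in cross-section), a TM band of 30 µm around it,
soft TM/uveal tissue on the anterior-chamber side, and a stiff shell
(default 3 MPa) representing sclera/cornea on the scleral side, with outer
radius 200 µm. The scleral half of the outer boundary is clamped; the
chamber side is a free surface. That last choice is load-bearing: tissues
are modeled as nearly incompressible, and if the section were fully
enclosed by the stiff shell, conservation of area would force any lumen
change to shear the shell, making the computed collapse almost independent
of TM stiffness. Letting tissue displace toward the anterior chamber — as
it does anatomically — restores TM-dominated compliance.

Materials are Mooney–Rivlin, `E = 6 (c1 + c2)` in the incompressible
small-strain convention, with the neo-Hookean special case `c2 = 0` as
default and near-incompressibility imposed as a penalty (Poisson ratio
0.4995, bulk/shear ≥ 1000). The solver is a total-Lagrangian 4-node
quadrilateral code with selective reduced integration (the volumetric
penalty term at the element centroid only) to avoid locking, Newton
iteration with automatic load-step halving, and a dead (reference
configuration) pressure load. The load at each clamped IOP is the
transmural pressure `IOP - P_SC`, with the SC luminal pressure from a
series-resistance divider `P_SC = IOP - r (IOP - EVP)` (defaults `r = 0.7`,
`EVP = 7` mmHg: most outflow resistance resides in the TM/inner wall).
Verification: the solver matches the analytic thick-walled-cylinder (Lamé)
solution within 0.4% in the small-strain limit, for both a clamped
compressible case and a traction-free nearly incompressible case.

`invert_stiffness()` estimates TM stiffness by sweeping a grid (default
20–240 kPa in 10 kPa steps), solving the forward model once per grid value
(solutions are cached), and minimising the sum of squared differences
between model and observed SC areas *normalised to the 10 mmHg level* over
the IOP range 10–20 mmHg. Normalisation removes the unknown absolute lumen
size; the default geometry was fixed, once, so that the normalised collapse
curves span the informative mid-range over this stiffness grid (roughly
0.17 at 20 kPa to 0.92 at 240 kPa at the 20 mmHg level), giving the
inverse problem usable sensitivity everywhere on the grid. Optional
golden-section refinement between the bracketing grid points is available.

Numerical caveats, stated plainly: mesh-refinement convergence is better
than 1% in normalised area at moderate deformation (e.g. 100 kPa TM at the
default mesh of 48 × 8 elements), but near-complete collapse (soft TM at
20 mmHg) converges more slowly (~3% at the default mesh). The inverse
procedure is unaffected by this as a *calibration-consistent* comparison —
observed and model curves are compared on the same mesh — but absolute
stiffness values from any idealised geometry should be read as
model-referenced, not anatomical, quantities. Wall self-contact after full
collapse is outside scope; the load stepping simply terminates near zero
area.

## AFM stiffness extraction and hierarchical aggregation

Spherical-indenter force curves follow the Hertz law
\(F = \tfrac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2}\) (probe
radius default 5 µm, i.e. a 10 µm sphere; \(\nu = 0.5\) for incompressible
soft tissue; with E in kPa and lengths in µm the force is in nN).
`fit_hertz()` fits \(E\) and the contact point *jointly* by least squares
on the approach segment below the 7 nN force cap — for soft, rough samples
the contact point is not identifiable by thresholding, and treating it as a
free parameter is the robust choice. Curves that cannot be fitted (or fit
with non-positive modulus) are flagged invalid and excluded from
aggregation rather than raising errors, since batch AFM data always contain
junk curves.

`aggregate_eye_stiffness()` averages unweighted at every level of the
sampling hierarchy: repeats → location → cryosection → quadrant → eye. For
unbalanced designs this is *not* the grand mean — each quadrant counts
equally however many curves it contributed — and the tests pin this down on
hand-computed unbalanced examples. The canonical balanced design (3 repeats
× 5 locations × 9 cryosections) yields 135 curves per eye. Off-tissue
locations identified post hoc are handled as a boolean mask column, not an
automated classifier.

## Morphometry

`bmm_ratio()` computes the fraction of SC inner wall underlain by basement
membrane material: attached segment lengths summed and divided by total
wall length, with segments flagged as optically offset from the wall
excluded, and overlapping segments merged (with a warning) so the ratio is
bounded by 1. `aggregate_grades()` averages discordant graders (half grades
allowed), takes per-eye means over images, and runs both the parametric
(ANOVA + pairwise t) and non-parametric (Kruskal–Wallis + rank-sum) routes,
since ordinal 0–2 grades sit on the boundary of both traditions.
`roi_mean_intensity()` is the mean grayscale value under a mask;
z-stacks are mean-projected first (the projection choice is a package
decision — maximum projection would bias toward bright slices).
`roi_group_test()` handles the non-independence of multiple images per eye
with a seeded cluster bootstrap over eyes (1999 resamples by default)
instead of an estimating-equations correction; its output is labeled as
bootstrap inference.

## Synthetic data: what it emulates, and what passing tests do not show

Every input class has a generator with the statistical structure the
analyses assume: log-normal facilities over eyes with multiplicative
(CV-parameterised) flow noise, since perfusion flow scales with pressure;
Hertzian force curves with contact offset, additive force noise and the
7 nN cap; monotone SC collapse curves with multiplicative log-normal area
noise; integer-rounded before/after cohorts with the post-treatment floor
at 5 mmHg; longitudinal mouse IOP series on the twice-weekly day grid
{0,1,3,7,10,14,17,21,24,28} with steroid elevation (default PL 5.94 ± 0.57
mmHg, treated 0.23 ± 0.45 mmHg, baseline ≈ 19.4 mmHg) — the defaults are
the conditions of the studies these analyses serve; and random wall-segment
layouts of known coverage. All generators are bit-deterministic given a
seed.

Passing round-trip and recovery tests on these inputs demonstrates that the
estimators are consistent under their own assumptions — not that real data
satisfy those assumptions. Real perfusion traces drift and leak; real force
curves have baseline tilt and adhesion; real OCT segmentations carry
correlated, not i.i.d. log-normal, errors; real SC geometry differs from
any ellipse. The synthetic layer is the test harness, not evidence about
tissue.

## Problem sizes and reproducibility

The shipped checks use: 1000 synthetic perfusion records for the facility
bias property (median |bias| < 2%), 200 noisy AFM curves for the Hertz
accuracy property (mean within 5% at 0.2 nN noise), a 23-point stiffness
grid with 200 replicates of 8 curves at 5% area noise for inverse-model
recovery (≥ 95% within one grid step), and 48 × 8 elements for the default
forward mesh — sizes chosen so the full battery reruns comfortably on a
single CPU. `scripts/acceptance.R` recomputes the package's headline
quantities from scratch for a given `--seed` and writes them as JSON.
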