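---
title: "From lipid-protein forces to conformational state: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From lipid-protein forces to conformational state: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fdapls` asks a narrow question about mechanosensitive membrane proteins:
can the conformational state of the protein be read off from nothing but
the forces the surrounding lipids exert on it, and if so, which residues
carry that signal? This vignette documents the models the package
implements, the assumptions behind them, the tunable parameters, and the
design decisions that were genuinely open.

```{r setup}
library(fdapls)
```

## The force model

The elementary quantity is the short-range nonbonded force between one
protein atom and one lipid atom at minimum-image separation $r$ in an
orthorhombic box:

* **Coulomb**, $f_C(r) = k_e\, q_a q_b / r^2$ with
  $k_e = 138.935458\ \mathrm{kJ\,mol^{-1}\,nm\,e^{-2}}$, plainly truncated
  at $r_\mathrm{cut} = 1.2$ nm. Truncation leaves a discontinuity of the
  Coulomb term at the cutoff; this is a deliberate approximation — the
  reciprocal-space (PME) part of the electrostatics is out of scope, and
  only force *differences* between conformational states enter the
  downstream regression.
* **Lennard-Jones** with a *force switch* between
  $r_\mathrm{switch} = 1.0$ nm and $r_\mathrm{cut} = 1.2$ nm. Each
  inverse-power force term $\alpha/r^{p+1}$ ($p = 6, 12$) is augmented on
  the switching interval by $A(r-r_1)^2 + B(r-r_1)^3$, with $A$ and $B$
  fixed by requiring the force and its derivative to vanish at
  $r_\mathrm{cut}$. The switched force is continuous everywhere and decays
  smoothly to zero at the cutoff, which the test suite verifies on a radial
  scan. Whether the original force-field settings used a force switch or a
  potential switch is not decidable from the information at hand; the
  force-switch convention is recorded as an assumption.
* **Combination rule**: Lorentz–Berthelot (arithmetic $\sigma$, geometric
  $\epsilon$). Units are fixed to nm, elementary charge and kJ/mol
  throughout, matching the conversion factor above.

Only protein–lipid pairs are ever evaluated; intra-protein and intra-lipid
forces are not part of the model. Triclinic boxes are rejected rather than
approximated.

For residue $i$ and lipid molecule $j$, $\mathbf{F}_{ij}$ is the vector sum
over the atom-pair Cartesian product, and the punctual stress is
$\mathrm{PS}_i = \sum_j |\mathbf{F}_{ij}|$. The order of operations
matters: vector sum within one residue–lipid pair, magnitude, then scalar
sum across lipids. Two lipids pulling a residue in opposite directions
yield $2F$, not $0$ — punctual stress measures how hard the membrane
squeezes a residue, not the net pull. `stress_trajectory()` evaluates this
per frame (default stride 40 ps between stored frames) to build the
frames × residues feature matrix.

The implementation vectorises over all atom pairs; the test suite pins it
against an independent quadruple-loop evaluation (residues × lipids ×
atoms × atoms) whose switch coefficients are obtained by numerically
solving the boundary conditions rather than from the closed form, on
twenty random toy systems at relative tolerance $10^{-10}$.

## The conformational observable

Two reference conformations, "down" and "up", define a difference vector
on backbone atoms. Every frame is first superposed onto the *down*
reference by the Kabsch construction (rotation + translation, reflection
excluded via the sign of the determinant); then

$$x(t) = \sum_i \left(\mathbf{r}_i(t) - \mathbf{r}_i^\mathrm{avg}\right)
\cdot \left(\mathbf{r}_i^\mathrm{up} - \mathbf{r}_i^\mathrm{down}\right),
\qquad
\mathbf{r}_i^\mathrm{avg} = \tfrac12\left(\mathbf{r}_i^\mathrm{up} +
\mathbf{r}_i^\mathrm{down}\right).$$

Substituting the endpoints gives $x = \pm\tfrac12\sum_i
|\mathbf{r}_i^\mathrm{up} - \mathbf{r}_i^\mathrm{down}|^2$, so $x$ is
antisymmetric about the midpoint and $0$ is the natural state separatrix;
`label_states()` uses threshold $x > 0$ by default (configurable). $x$ is
reported unnormalized, in nm²; a normalization flag divides by
$\sum|\Delta \mathbf{r}|^2$ for plotting, mapping down/up to $\mp 1/2$.
Whether to normalize was an open choice; the unnormalized form is the
primary one because the closed-form identities above hold in it directly.

Two geometric facts shape the implementation and tests:

* The post-superposition identities hold *exactly* only when the up
  reference carries no net rigid-body component relative to the down
  reference. `reference_pair()` therefore superposes up onto down at
  construction (switchable off), and the synthetic transition generator
  removes the rigid part of its random displacement field before scaling
  it to the requested RMS magnitude.
* At the exact midpoint $x = 0$, the state label is floating-point
  ambiguous by construction; tests avoid placing a frame exactly on the
  separatrix.

Degenerate fits (fewer than three selected atoms, collinear selections)
are refused with explicit errors rather than silently producing an
arbitrary rotation.

## PLS-FMA

The regression is single-response PLS1 by the NIPALS recursion: each
weight vector is proportional to the covariance of the current feature
residuals with the observable residuals, followed by score computation and
deflation. SIMPLS was rejected in favour of NIPALS to keep each component
interpretable as a covariance-maximizing force mode. The composed
coefficient vector $\beta = W(P^\top W)^{-1} q$ is stored for every
truncation $1..K$, so truncated predictions need no refitting.

Key choices:

* **Centering, no scaling.** Features are mean-centered (this also absorbs
  the nonzero resting stress every residue feels) but never
  variance-scaled: coefficients remain comparable across residues in
  physical force units, which is what makes cross-residue and cross-chain
  coefficient comparisons meaningful.
* **Component count.** The default policy fits up to 20 components and
  keeps the last $K$ whose leave-one-replica-out mean Pearson correlation
  improved by at least 0.01 over $K-1$. On data dominated by a single
  latent transition this typically selects $K = 1$; the cap and tolerance
  are arguments, not constants.
* **Rank exhaustion** truncates $K$ with a warning instead of failing;
  a zero-variance observable is a hard error.
* **Contribution of component $k$** is defined as
  $R^2_{1..k} / R^2_{1..K}$ on the evaluation data. The quantity is
  model-internal ("how much of what the model explains does one collective
  mode explain"); other definitions (e.g. covariance shares) exist, and
  this one is an assumption documented here.
* **Sign convention.** PLS1 orients predictions to correlate positively
  with the observable by construction, so positive coefficients mean more
  lipid force on the down side of the transition, negative ones more force
  on the up side.

At $K = \mathrm{rank}(X)$ the PLS solution coincides with ordinary least
squares; the suite asserts this against the normal equations, asserts
score orthogonality, and checks exact recovery on noiseless data.

## Validation

`cross_validate()` holds out each replica in turn. For held-out replicas
containing a transition it reports the ROC AUC of per-frame state
prediction — computed by the Mann–Whitney pair formulation (midranks, ties
half) — and the Pearson correlation between predicted and observed
observable. Controls, where AUC is undefined, report the per-frame
false-positive fraction (frames whose predicted $x$ exceeds the
threshold); per-frame rather than per-trajectory, so the number is
directly comparable to a percentage of misclassified frames. AUC is
computed per held-out replica, never pooled across replicas.

Per-fold coefficient vectors are sign-aligned against the first fold and
averaged; their pairwise cosine matrix is kept as a consistency
diagnostic. `chain_symmetry()` takes an explicit two-column residue
pairing (no automatic alignment) and reports paired coefficients, their
correlation, and partner ranks of the top residues of each sign;
`top_residues()` ranks hotspots with ties broken by residue position,
ascending, so output is deterministic.

## What the synthetic data emulate — and what they do not

`generate_force_ensemble()` reproduces the *statistical shape* of a
tension-driven gating study: 10 replicas (7 transitioning, 3 control) of
500 frames; a 521-dimensional per-residue feature vector; 20 hotspot
residues with coefficients $\pm 1$ (mixed signs, mirroring stronger force
before vs after the transition); per-feature resting baselines drawn from
$\mathcal{N}(10, 2)$; i.i.d. Gaussian feature noise of sd 2.0; a latent
coordinate $s(t)$ that is $-1$ for controls and follows a logistic ramp of
width 20 frames centered uniformly in the central 30–70% of each
transitioning trajectory (transitions in the emulated regime occur over
tens of nanoseconds at 40 ps stride, i.e. sharp but smooth on the frame
axis). The observable is $s(t)$ plus Gaussian noise (sd 0.1); labels are
$s(t) > 0$. Every generator is a pure function of its spec including the
seed.

The per-frame noise level of real force signals is not known from the
emulated study; sd 2.0 is a calibration choice, exposed in the spec, under
which the reported quality bounds are met with margin but not trivially
(the per-feature signal-to-noise is 0.5, and only the 20-of-521
hotspot structure makes the transition recoverable). Real punctual-stress
data differ in ways the generator deliberately ignores: noise is
temporally autocorrelated and non-Gaussian, hotspot magnitudes are
heterogeneous, feature noise is correlated across neighbouring residues,
and lipid exchange introduces slow drifts. Passing tests therefore
demonstrate the correctness and calibration-regime behaviour of the
estimator chain, not performance guarantees on any particular simulation
dataset.

One consequence worth stating plainly: with a single latent mode, the
component-selection policy keeps one component and the first-component
contribution is 100% by construction. The synthetic regime can show that a
dominant collective mode *is found*; it cannot reproduce the 67–70%-style
partial contributions that arise when real data contain secondary force
modes.

A note on estimator choice for hotspot recovery: adding components beyond
the selected one dilutes the cosine between the estimated and true
coefficient vectors (pure-noise directions enter the composition; the
effect is frozen in a regression test and was cross-checked against an
independent NIPALS implementation). The package's headline estimate is
therefore the ensemble-averaged per-fold vector at the policy-selected
$K$.

## Problem sizes and numerics

The test suite and the acceptance script run entirely on generated data:
toy systems of at most ~40 atoms for force oracles, 25-atom reference
pairs for the observable identities, and the calibrated
10 × 500 × 521 ensemble (and nine reseedings of it) for the regression and
validation checks. These sizes were chosen so the full chain — including
ten leave-one-replica-out fits at the component cap — completes in minutes
on one CPU while keeping every statistical check well away from
small-sample artifacts.

Numerical tolerances follow the quantity being tested: $10^{-10}$ relative
for force-kernel equivalence, $10^{-12}$ for pairwise antisymmetry,
$10^{-8}$ for geometric identities after superposition, $10^{-6}$ for the
PLS–OLS limit. Singular geometries (coincident atoms within the cutoff)
and degenerate regressions are errors, not NaNs.

## Limitations

* No reciprocal-space electrostatics, bonded terms, virials or pressure;
  the force model is the short-range nonbonded slice relevant to
  lipid–protein punctual stress only.
* Binary trajectory formats (XTC/DCD) are not parsed; the core reads
  PDB/GRO and multi-model PDB, and delimited matrices for features.
* No statistical testing of coefficient significance and no bootstrap
  intervals; the validation is predictive (cross-validation) and
  structural (chain symmetry).
* The "principal component" between two reference structures is exactly
  the two-structure difference vector — no PCA or essential dynamics is
  performed, and Cartesian-coordinate functional mode analysis is out of
  scope.
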