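# fdapls

Lipid–protein force distribution analysis coupled to partial-least-squares
functional mode analysis (PLS-FMA), in R.

Mechanosensitive channels such as the two-pore-domain potassium channel
TREK-2 respond to membrane tension with a conformational transition between
a "down" and an "up" state. `fdapls` implements the inference chain that
connects the forces lipids exert on a membrane protein to that
conformational state:

1. **Punctual stress.** For protein residue *i* and lipid molecule *j*, the
   net short-range nonbonded force **F**<sub>ij</sub> is the vector sum over
   all atom pairs (truncated Coulomb at 1.2 nm plus Lennard-Jones with a
   force switch between 1.0 and 1.2 nm, Lorentz–Berthelot combination,
   orthorhombic minimum image). The per-residue punctual stress is the
   scalar sum of magnitudes across lipids,

   PS<sub>i</sub> = Σ<sub>j</sub> |**F**<sub>ij</sub>| ,

   so opposing pulls add instead of cancelling. A trajectory becomes a
   frames × residues stress matrix — the feature space.

2. **Difference-vector observable.** Conformational state is measured by
   projecting each frame, after least-squares (Kabsch) superposition onto
   the down reference over the backbone, onto the up-minus-down
   displacement:

   x(t) = Σ<sub>i</sub> ( **r**<sub>i</sub>(t) − **r**<sub>i</sub><sup>avg</sup> ) · ( **r**<sub>i</sub><sup>up</sup> − **r**<sub>i</sub><sup>down</sup> ),
   with **r**<sub>i</sub><sup>avg</sup> = ½(**r**<sub>i</sub><sup>up</sup> + **r**<sub>i</sub><sup>down</sup>).

   x is negative on the down side, positive on the up side; frames are
   labelled by sign.

3. **PLS-FMA.** A single-response NIPALS PLS regression of x(t) on the
   stress vector finds the collective force mode with maximal covariance
   with the transition. Features are mean-centered but never
   variance-scaled, so coefficients stay comparable across residues in
   physical force units. Positive coefficients mean more lipid force in the
   down state, negative ones more force after the transition to up.

4. **Validation.** Leave-one-trajectory-out cross-validation reports, per
   held-out replica, the ROC AUC (Mann–Whitney pair count) of per-frame
   state prediction, the Pearson correlation between predicted and observed
   x, and — for control replicas without a transition — the per-frame
   false-positive fraction. Per-fold coefficient vectors are sign-aligned
   and averaged; chain-symmetry comparison and hotspot ranking identify the
   force-sensing residues.

Because suitable microsecond trajectory data are rarely at hand, the
package ships a first-class synthetic-data module: toy membrane–protein
systems with known nonbonded parameters (for exact force oracles), toy
down→up transition trajectories, and replica ensembles of force features
with a known latent transition and known ground-truth coefficients.

## Worked example

```r
library(fdapls)

# toy membrane-protein system and its per-residue punctual stress
sys <- generate_toy_system(n_protein_residues = 6, n_lipids = 8,
                           atoms_per_residue = 3, seed = 42)
round(punctual_stress(sys), 2)
#>      1      2      3      4      5      6
#>  20.31  51.84 428.19 416.33  98.54 197.23
```

Residues sitting next to "near" lipids feel hundreds of kJ mol⁻¹ nm⁻¹ of
summed lipid force; residues whose lipids lie beyond the 1.2 nm cutoff feel
none.

```r
# a noisy down-to-up transition and its difference-vector observable
tr <- generate_transition_trajectory(sys, displacement_magnitude = 0.3,
                                     n_frames = 50, seed = 42)
refs <- reference_pair(tr$r_up, tr$r_down,
                       backbone_selection = tr$protein_atoms, fit = FALSE)
difference_series(tr$frames, refs)
#> Difference-vector series: 50 frames; x in [ -0.8255 , 0.8673 ] nm^2
#>   frames on up side: 25 / 50
```

The observable runs from −½Σ|Δr|² (down) to +½Σ|Δr|² (up) and crosses zero
at the midpoint, labelling each frame's conformational side.

```r
# calibrated synthetic ensemble: 7 transitioning + 3 control replicas,
# 500 frames x 521 residue features, 20 hotspots, feature noise sd 2.0
ens <- generate_force_ensemble(synthetic_ensemble_spec(seed = 1))
rep <- cross_validate(ens)
rep
#> Leave-one-trajectory-out validation ( 1 PLS components )
#>   transition replicas: AUC 0.996-0.999, Pearson r 0.887-0.903
#>   control replicas: false-positive fractions 0.8%, 1.4%, 1.2%
#>   first-component contribution: 97.9% (mean over folds)

head(top_residues(rep$ensemble_vector, k = 5)$positive)
#>   residue coefficient
#> 1     263  0.04238006
#> 2     277  0.04051324
#> 3     307  0.04036585
#> 4     165  0.03997912
#> 5     330  0.03967442
```

Held out one at a time, every transitioning replica is predicted almost
perfectly from force features alone (AUC ≥ 0.996), predicted and observed
observables correlate at r ≥ 0.887, and the quiescent controls produce
around 1% false positives. The top-ranked residues recover the generator's
planted hotspots; `chain_symmetry()` compares coefficients across the two
chains of a dimer given an explicit residue pairing.

`run_pipeline(pipeline_config(...), output_dir)` executes the whole chain
and writes every intermediate table, the validation report (JSON + TSV) and
a run log keyed by a configuration hash.

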