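# spinemorph

3D morphometry and synaptic connectivity of dendritic spines from
volume electron microscopy (FIB/SEM) stacks.

Serial block-face imaging of DAB-labeled neurons yields anisotropic
image stacks (typically 3.7 nm/px in XY, 25 nm steps in Z) in which a
traced dendrite, its spines, their synaptic junctions and the
presynaptic boutons can be reconstructed voxel by voxel.  `spinemorph`
implements the full quantitative workflow for neuroanatomists working
with such data:

* **stack preparation** — translation-only slice alignment (exhaustive
  integer search, normalized cross-correlation), robust across-slice
  intensity normalization, and the Gaussian-blurred companion stack used
  for seeding;
* **segmentation** — absolute-intensity seeded region growing
  (26-connected, no smoothing), import of painted junction labels, and
  spine isolation from the parent shaft by a skeleton-path inscribed
  tube with a minimal-cross-section neck cut;
* **morphometry** — volume `V = n_vox · s_x s_y s_z`, voxel-face and
  marching-tetrahedra surface area, Wadell sphericity
  `Ψ = π^{1/3} (6V)^{2/3} / A` (1 for a ball, lower for complex shapes),
  sphere-equivalent diameter `(6V/π)^{1/3}`, and branched-spine
  splitting at the shared-neck isthmus;
* **classification** — thin / filopodial / stubby / mushroom / branched,
  as a documented decision cascade over skeleton-and-distance-transform
  features (length, neck and head diameter, head count);
* **connectivity** — the spine–synapse–bouton graph by label adjacency,
  the synaptic bouton index SBi (number of distinct postsynaptic
  elements per bouton), SSB/MSB fractions, head/neck synapse location,
  non-synaptic spine flags;
* **statistics** — Spearman and Mann–Whitney tests, fixed-width binned
  averaging (default 5.0e6 nm³ bins, single-point bins excluded), and
  the two-regime threshold regression: the dependent variable rises
  linearly with spine volume up to a threshold chosen by maximizing the
  lower-range R², and stays flat above it;
* **a phantom generator** — parametric dendrite + spine + synapse +
  bouton scenes rendered on the anisotropic grid with exact ground
  truth, plus an acquisition-artifact model (per-slice jitter, drift,
  noise), so every stage is testable against known geometry.

## Worked example

Simulate a small acquisition (one thin, one mushroom, one stubby spine
at 8 × 8 × 25 nm voxels), corrupt it with jitter/drift/noise, and run
the full pipeline:

```r
library(spinemorph)

spec <- phantom_spec(spacing = c(8, 8, 25),
                     n_spines_per_type = c(thin = 1, mushroom = 1, stubby = 1),
                     sbi_distribution = c(.5, .5, rep(0, 8)),
                     slice_jitter_px = 2, intensity_drift = 0.08,
                     rng_seed = 5)
report <- run_pipeline(pipeline_config(spec), "out")
report
#> <pipeline_report> out
#>   config 7b2020c6 seed 5
#>   spine types (%): thin 34, filopodial 0, stubby 33, mushroom 33, branched 0
#>   SSB 67% / MSB 33% of 3 boutons

report$features[, c("spine", "length_nm", "neck_diam_nm", "head_diam_nm", "type")]
#>   spine length_nm neck_diam_nm head_diam_nm     type
#> 1     1  974.3319    157.13262     442.5381 mushroom
#> 2     2  284.2637    252.91808     208.0000   stubby
#> 3     3 1282.7639     61.22432     216.3053     thin

report$graph$boutons
#>   bouton_id sbi class n_synapses synapse_ids
#> 1         3   1   SSB          1           4
#> 2         6   2   MSB          2         7;9
#> 3        11   1   SSB          1          12
```

All three simulated spines are recovered from the corrupted stack and
assigned their true class; the middle bouton is a multi-synaptic bouton
(SBi = 2: it contacts the labeled spine plus one unlabeled element), so
the SSB/MSB split is 67%/33% of 3 boutons.  The report bundle on disk
(`out/`) holds the ground truth, alignment table (applied vs recovered
shifts), per-object morphometry, features, composition, connectivity
tables and a JSON summary, all stamped with the config hash and seed;
rerunning with the same config reproduces the files byte for byte.

Morphometry of a digitized ball (radius 200 nm, 10 nm voxels)
illustrates the two surface estimators:

```r
measure_object(digitize_ball(200, c(10, 10, 10)))
#>   volume_nm3 surface_area_nm2 sphericity eq_diameter_nm     method
#>     33401000           754200  0.6650239       399.5645 voxel_face
measure_object(digitize_ball(200, c(10, 10, 10)), method = "mesh")
#>   volume_nm3 surface_area_nm2 sphericity eq_diameter_nm method
#>     33113807           501117  0.9951405       398.4161   mesh
```

The raw voxel-face area overestimates a smooth sphere by ~1.5× (a bias
shared by every object at fixed voxel size, so comparisons stay valid),
while the mesh estimator converges to the analytic `4πr² ≈ 502655 nm²`
within half a percent and scores the ball's sphericity at ≈ 1.

See `vignettes/spinemorph-methods.Rmd` for the full account of the
models, parameter defaults and numerical choices.

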