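# cardiocap3d

Quantification of 3D coronary microvascular architecture and capillary
pruning from multi-channel confocal stacks.

During postnatal remodeling of the heart's microvasculature, poorly
perfused capillary segments regress ("pruning"), each leaving a transient
**empty sleeve**: a basement-membrane tube (collagen IV⁺) with no
endothelium inside (ICAM2⁻). This package implements, as reusable R
functions, the full measurement pipeline for thick-section (35 µm, 2 µm
z-steps) fluorescence volumes:

* **Synthetic ground truth** — a seeded generator of 3D capillary networks
  (`generate_vascular_tree()`, `plant_empty_sleeves()`, `rasterize()`,
  `simulate_voi()`) that renders six channels (ICAM2, COL IV, ERG nuclei,
  i.v. IB4, dextran, pimonidazole hypoxia) with exact per-segment truth,
  so every downstream stage is testable without microscope data.
* **Vessel segmentation** — multi-scale multilevel (exhaustive Otsu)
  thresholding with anisotropy-aware smoothing
  (`multiscale_multilevel_segment()`), vascular volume density.
* **Angio-architecture** — homotopic 3D skeletonization
  (`skeletonize_mask()`), graph extraction with junction clustering
  (`build_graph()`, `prune_spurs()`, `merge_close_junctions()`), and
  per-segment length, chord, tortuosity = length/chord, and diameter from
  the exact euclidean distance transform (`compute_metrics()`).
* **Network heterogeneity** — grid box-counting fractal dimension
  (`box_count_fd()`; fd = −slope of log N(r) vs log r) and gliding-box
  lacunarity (`gliding_box_lacunarity()`; Λ(r) = ⟨M²⟩/⟨M⟩²), per-VOI
  spread statistics (`extract_vois()`, `heterogeneity_sd()`).
* **Pruning events** — automated empty-sleeve detection as connected
  components of `COLIV ∧ ¬dilate(ICAM2)` passing capillary-scale geometry
  filters (`detect_empty_sleeves()`), with density per mm³ and percentage
  of segments (~4% in the postnatal heart: 100–150 events among
  2,000–3,000 segments per 350 × 350 × 35 µm volume).
* **Endothelial density maps** — MIP over a 6 µm slab, mean-filter +
  Otsu + watershed nucleus segmentation, neighbour counts within 32 µm and
  their histogram/colour code (`mip_over_planes()`, `segment_nuclei()`,
  `neighbor_counts()`, `density_histogram()`).
* **Perfusion and oxygenation** — perfusion percentage
  (IB4-occupied fraction of ICAM2 vasculature), extravascular dextran
  percentage, hypoxia MFI and histogram on the 0–4095 scale, diffusion
  distances to the nearest vessel, PAS-positive area
  (`perfusion_percentage()`, `extravascular_dextran_percentage()`,
  `hypoxia_stats()`, `diffusion_distance_stats()`,
  `pas_area_percentage()`).
* **Physiology formulas** — LV wall strain
  `100·(sys−dia)/sys`, rate-corrected intervals
  `QRSc = QRS + 0.0125·(1−RR)` and `QTc = QT + 0.0154·(1−RR)` (all in
  seconds), stage differentials, Pearson correlation reports
  (`lv_strain()`, `qrs_corrected()`, `qt_corrected()`,
  `stage_differential()`, `pearson_report()`).

Voxel-level primitives (exact anisotropic euclidean distance transform,
26-connected labeling, homotopic thinning, capsule rasterization,
exhaustive multilevel Otsu) are implemented in C++ via Rcpp.

## Worked example

```r
library(cardiocap3d)

# a 280 x 280 x 35 um myocardial volume of interest with ~220 capillary
# segments, 4% of them planted as empty sleeves, imaged at 0.7 x 0.7 x 2 um
# voxels with 10% gaussian noise
voi <- simulate_voi(seed = 1, preset = "pruning", sleeve_fraction = 0.04)
#> <synthetic_dataset> 6 channels, 18 x 400 x 400 voxels
#> <vascular_graph_truth> 221 nodes, 220 segments (9 empty sleeves) in 35 x 280 x 280 um

res <- quantify_voi(voi)
res$metrics
#> <network_metrics> 212 segments, 67 bifurcations, 19 trifurcations, 127 end nodes
#>   vascular volume density 0.0179 | mean diameter 3.22 um | mean tortuosity 1.053
#>   total skeleton length 4553.0 um | EC per um 0.0551

res$n_pruning_events      # empty sleeves detected in the COL IV / ICAM2 channels
#> [1] 8
res$pruning_percent       # percentage of vascular segments, ~4% regime
#> [1] 3.773585
pruning_density(res$sleeves, prod(dim(voi$channels$endothelium)) *
                               prod(voi$params$voxel_size_um))
#> [1] 2834.467            # events per mm^3 of myocardium

head(as.data.frame(res$sleeves)[, c("centroid_x_um", "centroid_y_um",
                                    "length_um", "max_inscribed_diameter_um")])
#>   centroid_x_um centroid_y_um length_um max_inscribed_diameter_um
#> 1      177.0889      86.02873  16.94498                  3.959798
#> 2      203.7905     108.52072  18.77317                  4.237924
#> 3      207.3152     147.83232  20.37107                  3.130495
#> ...

box_count_fd(res$ec_mask$values)
#> <fractal_result> fd = 1.838 (R^2 = 0.999) over box sizes 4, 2, 1
gliding_box_lacunarity(res$ec_mask$values, c(2, 4, 8))
#> <lacunarity_result> mean Lambda = 18.0198 over box sizes 2, 4, 8

hypoxia_stats(voi$channels$hypoxia)$mfi   # mean hypoxyprobe intensity, 0-4095
#> [1] 1266.03
lv_strain(2.0, 1.4)                       # % systolic wall thickening
#> [1] 30
qt_corrected(0.048, 0.11)                 # QTc (s) at a mouse RR of 0.11 s
#> [1] 0.061706
```

The 212 measured segments, 67 bifurcations and 19 trifurcations are read
off the skeleton graph of the segmented ICAM2 channel; the 8 detected
sleeves (of 9 planted) are basement-membrane components lacking
endothelium that pass the capillary-scale geometry filters, giving 3.8% of
segments and ~2,800 events per mm³ in this volume. The fractal dimension
and lacunarity summarise the space-filling complexity and gap
heterogeneity of the same mask.

See the methods vignette (`vignettes/cardiocap3d-methods.Rmd`) for the
models, parameter choices and their rationale.

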