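# stentml

Simulation-driven machine learning for predicting stent expansion in
calcified coronary arteries.

Stent underexpansion — a deployed stent failing to reach roughly 80% of
its target lumen area — is a major complication of stenting heavily
calcified lesions, and it is driven by per-cross-section geometry: the
angle the calcification subtends at the lumen centroid, its thickness,
and how much compliant fibrotic tissue is left to stretch. `stentml` is
an R package for studying whether those pre-stenting geometric features
predict the post-stenting lumen area. It is aimed at researchers in
vascular biomechanics and medical image analysis who want a fully
reproducible, end-to-end testbed: a synthetic vessel generator and a
reduced mechanical surrogate replace patient imaging and large
finite-element runs, while the constitutive laws, feature definitions,
regression models, and evaluation protocol are implemented in full.

## What is inside

* **Constitutive laws** (`tissue_preset()`, `strain_energy()`,
  `uniaxial_nominal_stress()`, `elastoplastic_uniaxial_response()`):
  reduced third-order polynomial hyperelasticity
  `U = Σ C_ij (I1−3)^i (I2−3)^j` for artery, fibrotic plaque and
  calcification (coefficients in MPa), incompressible kinematics, and
  perfect plasticity for fibrotic plaque with a nominal yield stress of
  0.07 MPa at 34% engineering strain. The fibrotic law's nominal stress
  at stretch 1.34 evaluates to 0.0702 MPa, so the printed yield pair and
  the hyperelastic curve are mutually consistent.
* **Synthetic vessels** (`vessel_gen_config()`, `generate_vessel()`,
  `rasterize_section()`): seeded, axially correlated 120-slice segments
  (0.1 mm spacing) with sector-shaped calcification deposits seated on
  the lumen boundary; labeled contours and raster masks.
* **Expansion surrogate** (`stent_params()`, `expand_section()`): a
  per-slice composite-ring tension balance. Loading drives the lumen
  toward the 3.3 mm balloon circumference with equal membrane tension
  across the calcified arc (stretch capped at 2%) and the elastoplastic
  fibrotic arc (plastic flow up to a lock-up stretch); recoil unloads
  the scaffold against the residual tissue tension. The calcification-free
  reference recoils to the nominal 3.0 mm stent size (7.07 mm² lumen).
* **Features** (`extract_features()`, `neighbor_average()`): the eight
  standard per-slice features — Area_A, Area_F, Area_C, Area_L, Angle_C,
  Thickness_C, ArcLength_C, ArcLength_F — measured about the lumen
  centroid, plus eight-neighbor averaging.
* **Regression and evaluation** (`fit_lr()`, `fit_svr()`,
  `evaluate_model()`, `segment_split()`, `subgroup()`,
  `compare_groups()`): ordinary least squares and ε-insensitive SVR
  (linear / polynomial / RBF kernels), the 90-train / 30-test segment
  protocol, stretch vs calcification feature subgroups, signed
  percentage errors with bias and range, one-way ANOVA and pooled
  t-tests.
* **Pipeline** (`pipeline_config()`, `run_pipeline()`,
  `make_fixture()`): one call from seed to report bundle, with plain
  CSV/JSON outputs.

See the vignette (`vignettes/stent-expansion-pipeline.Rmd`) for the
model details, parameter meanings and limitations.

## Worked example

```r
library(stentml)

# one cross section: 1 mm lumen, 0.85 mm wall, 120 deg deposit, 0.3 mm thick
sec <- cross_section(0, circle_contour(1, 96), circle_contour(1.85, 96),
                     list(sector_annulus_contour(1.01, 1.31, 0, 120)))
extract_features(sec)
#>      area_a      area_f      area_c      area_l     angle_c thickness_c
#>  10.7444261   6.8764676   0.7286083   3.1393502 120.0000000   0.2999999
#> arclength_c arclength_f
#>   2.0940213   4.1880426

expand_section(sec, stent_params())
#> <expansion_result> lumen 3.139 -> 6.994 mm^2 (recoil 9.6%)
#>   stretches: fibrotic 1.965, calcified 1.0200
```

The 120° deposit stretches by at most 2%, the fibrotic arc carries the
expansion (stretch 1.97), and after scaffold recoil the slice ends at
6.99 mm² — just under the 7.07 mm² target and well above the 5.65 mm²
underexpansion threshold (`target_lumen_area(3)`,
`underexpansion_threshold(3)`).

The full protocol on a default synthetic vessel:

```r
res <- run_pipeline(pipeline_config(seed = 1))
subset(res$summary, condition == "individual" & features == "all")
#>    condition features   model      bias   err_min  err_max max_area_diff n_test
#>  individual      all      lr  2.093249 -5.882198 8.641551     0.6246692     30
#>  individual      all   svr_l -3.104865 -9.049944 2.710544     0.6352615     30
#>  individual      all   svr_p -1.380171 -4.885674 1.948580     0.3521351     30
#>  individual      all svr_rbf -1.279921 -5.122312 2.609245     0.3598054     30
```

Each row is one model fitted on the first 90 slices and evaluated on the
last 30: `bias` is the mean signed percentage error of the predicted
post-stenting lumen area, `err_min`/`err_max` its range, and
`max_area_diff` the largest absolute area error in mm². The nonlinear
SVR kernels give the smallest bias magnitudes and area errors here;
`res$summary` also holds the stretch-only and calcification-only
subgroup experiments and the neighbor-averaged condition, and
`res$model_comparison` the ANOVA across the four models.

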