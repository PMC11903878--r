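# turcorg

Spatial organization and conformational analysis of gamma-tubulin ring
complexes (gamma-TuRCs) at human centrosomes.

## The problem

The gamma-TuRC is the 14-spoke, cone-shaped template that nucleates
microtubules. At interphase centrosomes it occupies two compartments: a
broad pool in the pericentriolar material (PCM) and a condensed cluster
inside the centriole lumen, held near the wall of nine microtubule
triplets (MTTs). Characterizing this organization quantitatively requires
several analyses that sit downstream of subtomogram averaging and MINFLUX
nanoscopy but upstream of interpretation, and `turcorg` packages them for
structural biologists working with oriented particle tables and
single-molecule localization recordings:

* **Distance pools.** For each particle the center-to-center distance to
  the nearest MTT B-tubule centerline, `d_i = min_j d(p_i, L_j)`, signed
  negative for the centriole-lumenal pool and positive for the
  pericentriolar pool, summarized by median-unbiased (Hyndman–Fan type 8)
  percentiles: `h = p (n + 1/3) + 1/3` interpolated between order
  statistics.
* **Pair configurations.** Each gamma-TuRC and its nearest accepted MTT
  segment reduced to a rigid-motion-invariant 7D feature
  `( R(q_turc)^T (p_seg - p_turc) / s , q_turc^{-1} q_seg )`
  (local-frame shift over scale `s` = 60 nm, plus the canonicalized
  relative quaternion), filtered to 60–120 nm center-of-mass distance and
  clustered with seeded k-means; the main cluster's share, mean
  configuration, and wall-facing spoke sector are reported.
* **MINFLUX post-processing.** Keep 9th-iteration localizations, rescale
  z by 0.7, drop EFO >= 100 kHz, drop traces with < 4 surviving
  localizations; average traces to emitter centers; fit each structure's
  central axis (total-least-squares line refined by a cylinder fit that
  minimizes the variance of radial distances) and profile the radial
  distribution.
* **Ring-geometry deviations.** Kabsch superposition of a gamma-TuRC
  model onto a closed microtubule-capping reference over spokes 2–8 (or
  3–8), then per-spoke Euclidean deviations of the gamma-tubulin centers.

Because the particle coordinates and localization tables behind the
published centrosomal gamma-TuRC organization are not deposited in
reusable form, the package ships synthetic-data generators that plant
every parameter the analyses recover — the wall geometry, the distance
laws, the preferred pair configuration, the MINFLUX cylinder — so the
whole chain is validated offline. See the methods vignette
(`vignettes/turc-organization.Rmd`) for the model, parameter defaults and
design rationale.

## Worked example

```r
library(turcorg)

cfg   <- sim_config(seed = 1)
model <- simulate_centriole(cfg)
particles <- validate_particle_table(rbind(
  as.data.frame(simulate_lumenal_turcs(model, cfg)),
  as.data.frame(simulate_pericentriolar_turcs(model, cfg))))

labeled <- classify_pools(particles, model)
res     <- signed_mtt_distances(labeled, model)
attr(res, "summary")$lumenal
#> n = 300, median = 75.88, 90% between 63.81 and 85.16
attr(res, "summary")$pericentriolar
#> n = 500, median = 84.82, 90% between 44.51 and 132.34

nn <- nearest_neighbor_distances(labeled)
summarize_distribution(nn$nn_nm[nn$pool == "lumenal"])
#> n = 300, median = 29.00, 90% between 19.29 and 44.54

mf <- minflux_pipeline(simulate_minflux(cfg))
mf$radial_pooled
#> n = 3238, median = 35.01, 90% between 31.98 and 38.37
sprintf("sigma_xy = %.2f nm, sigma_z = %.2f nm",
        mf$precision$sigma_xy_nm, mf$precision$sigma_z_nm)
#> "sigma_xy = 5.73 nm, sigma_z = 4.82 nm"
```

The lumenal pool recovers its planted 75 nm B-tubule distance and dense
~25–30 nm nearest-neighbor packing; the pericentriolar pool recovers the
broad 85 nm truncated-Gaussian law; the MINFLUX stage recovers the 35 nm
cylinder radius and the planted localization precisions from ~36,000
noisy, decoy-laden localization rows.

A config-driven end-to-end run (simulation, pools, pairs, MINFLUX,
ring deviations, JSON report with per-step filter counts):

```r
run_pipeline(pipeline_config(seed = 1), out_dir = "turcorg_out")
```

or from a shell via the thin wrapper
`inst/scripts/turcorg-pipeline.R --stage all --seed 1 --out-dir out`.

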