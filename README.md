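# attenquant

Quantification of soft-tissue attenuation artifacts in myocardial perfusion
SPECT, with a digital cardiac phantom simulator for verifying every stage of
the pipeline without clinical data.

## The problem

In myocardial perfusion imaging (MPI), photon absorption by the abdomen,
breasts and lateral chest wall depresses counts in parts of the left
ventricle and mimics true perfusion defects. When images are read without
CT-based attenuation correction — the common situation on dedicated cardiac
CZT cameras, which usually lack a CT — the reader must know where the
artifact sits, how much of the myocardium it covers, and how deep it is.
These patterns differ between camera geometries (multi-pinhole CZT with a
static gantry vs. a rotating parallel-hole NaI camera), so the artifact must
be quantified per camera.

`attenquant` implements the sector-wise NAC/AC comparison used for this
purpose. For a paired study — the same acquisition reconstructed without
(NAC) and with (AC) attenuation correction — it:

1. selects a fixed number of short-axis slices counted from the base
   (20 for the CZT profile at 4 mm voxels, 12 for the conventional profile
   at 6.4 mm);
2. divides each slice into 12 equal 30° sectors about the LV centre and
   normalizes each segment's counts by the grand total, giving a
   slice × sector grid *n* for each volume;
3. forms the per-segment ratio *R = n_NAC / n_AC*, which is ≈ 1 where there
   is no attenuation and < 1 inside the artifact;
4. delineates the artifact as all segments with *R* strictly below a
   per-camera threshold (0.90 CZT, 0.85 conventional) and reports

   - **extent** = (number of artifact segments) / (total segments),
   - **localization** = circular mean of the artifact segments'
     sector-centre angles (0° anterior, 90° lateral, 180° inferior,
     270° septal),
   - **depth** = mean NAC counts in the artifact segments / mean counts in
     the 30% of segments with the highest counts.

A true perfusion defect scales the *same* voxels in NAC and AC and therefore
cancels in *R* — the built-in control separating artifact from disease.

The package also ships a digital LV phantom (`generate_study()`,
`generate_cohort()`): a sector-equalized cylindrical myocardial shell with
injectable multiplicative attenuation zones, solid defects and Poisson
noise, so recovered metrics can be compared against injected ground truth.

## Worked example

```r
library(attenquant)

study   <- reference_phantom("czt")   # noiseless digital phantom, CZT profile
metrics <- quantify_study(study)
metrics
#> <artifact_metrics (czt, threshold 0.90)>
#>   extent       68/240 segments = 28.3%
#>   localization 150.0 deg
#>   depth        73.0% of the top-30% count level
```

The phantom carries an inferolateral artifact (sectors centred 105°–195°
over the 17 most basal slices, transmission 0.70–0.76). The pipeline finds
68 of the 240 analyzed segments below the 0.90 ratio threshold (extent 28%),
centred at 150° (inferolateral wall), with counts inside the artifact at 73%
of the brightest-30% reference level. `tidy(metrics)` returns the same
numbers as a one-row tibble; `autoplot()` on the sector grid, ratio map or
mask draws the corresponding bullseye plot.

Simulated cohorts chain the same way:

```r
spec <- cohort_spec(6, 23, 5, 72, 3, 155, 17, camera_profile("czt"),
                    noise = TRUE, seed = 42)
quantify_cohort(generate_cohort(spec)) |>
  dplyr::select(acquisition, extent_injected_pct, extent_pct, depth_pct,
                localization_deg)
#> # A tibble: 6 × 5
#>   acquisition extent_injected_pct extent_pct depth_pct localization_deg
#>         <int>               <dbl>      <dbl>     <dbl>            <dbl>
#> 1           1                30         30        75.3             145.
#> 2           2                26.2       26.2      67.6             138.
#> 3           3                30.4       30.4      69.2             145.
#> 4           4                22.5       22.5      70.9             162.
#> 5           5                16.2       16.2      71.0             150.
#> 6           6                26.2       26.2      73.4             138.
```

Even with Poisson noise the recovered extent matches the injected extent
exactly (the artifact is far from the threshold), while depth and
localization scatter around their injected values (72% and 155°).
`summarize_cohort()` builds the per-camera mean ± SD table and paired t
tests between cameras (circular differences for localization).

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/attenquant.R simulate --camera czt --seed 7 --noise --out out/
Rscript inst/cli/attenquant.R quantify --nac out/study_nac.nii.gz \
    --ac out/study_ac.nii.gz --sidecar out/study_sidecar.json --out metrics.json
```

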