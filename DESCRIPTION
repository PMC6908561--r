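Package: attenquant
Title: Quantification of Attenuation Artifacts in Myocardial Perfusion SPECT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sector-wise quantification of soft-tissue attenuation artifacts in
    myocardial perfusion SPECT from paired non-attenuation-corrected (NAC) and
    attenuation-corrected (AC) short-axis volumes. Segments the left-ventricular
    myocardium into basal-to-apical slices and 12 angular sectors, normalizes
    segment counts, forms the NAC/AC ratio map, delineates the attenuation
    artifact by a per-camera ratio threshold, and reports its extent (fraction
    of segments), localization (circular mean angle) and depth (count reduction
    relative to the brightest 30% of segments). Includes a digital
    left-ventricular phantom generator with injectable attenuation zones, solid
    perfusion defects and Poisson noise for both a CZT (4 mm, 20 slices) and a
    conventional (6.4 mm, 12 slices) camera profile, cohort simulation, paired
    camera comparisons, NIfTI/CSV/JSON input and output, polar-map plotting,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
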