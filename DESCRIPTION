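Package: spotlag
Title: Spot-Assay Image Quantification and Antifungal Tolerance Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies time-lapse photographs of agar-plate spot assays used to
    screen Brettanomyces bruxellensis for cycloheximide tolerance. Plate frames
    are realigned to a reference template by a four-corner homography, colony
    foreground is separated from agar background by a two-component Gaussian
    mixture on pixel intensities, and per-drop growth areas (pixels) are
    assembled into kinetics. From the kinetics the package extracts the
    day-resolution lag phase (with right censoring at the end of incubation),
    the maximum growth area (Amax), control-normalized lags for both YPD and
    wine-residence designs, and a three-class tolerance profile, then compares
    groups by Kruskal-Wallis tests with Dunn post hoc comparisons and a
    compact-letter display and partitions normalized-lag variance by factorial
    ANOVA. A synthetic plate-image generator with known ground truth emulates
    the assay design (dose series, inoculum densities, imaging schedule,
    inter-frame jitter) so that every stage is testable end to end. Wine
    stress conditions are characterized by their molecular SO2 fraction
    computed from the sulfite dissociation equilibrium.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    png,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    mclust,
    tiff,
    withr
Config/testthat/edition: 3
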