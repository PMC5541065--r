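Package: benthoscan
Title: Underwater Hyperspectral Transect Analysis for Benthic Habitat Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing push-broom underwater hyperspectral transect
    surveys of shallow benthic habitats such as coral reefs. Reads and writes
    ENVI image cubes, renders colour imagery, performs in-scene gray-board
    reflectance correction, computes smoothed spectral-derivative photopigment
    and substrate index maps, fuses diver depth and echosounder altitude logs
    into seafloor topographic profiles with arc-chord rugosity, and trains
    supervised pixel classifiers (multi-layer perceptron, Mahalanobis
    distance, linear support vector machine) from sparse polygon annotations
    to produce full-transect benthic composition maps with accuracy, precision
    and recall reporting. Includes a parametric synthetic reef-scene simulator
    (class layouts, pigment-feature endmember spectra, water-column
    attenuation, sensor tracks and a reference board) so that every stage of
    the pipeline can be exercised and validated without field data, plus
    survey-geometry planning arithmetic linking altitude, swath, speed and
    data volume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    grDevices,
    jsonlite,
    png,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
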