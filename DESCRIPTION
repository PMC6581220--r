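Package: awakepet
Title: Awake-Animal PET with Radioactive Point-Source Head Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for brain PET of awake,
    freely moving mice. Provides a list-mode coincidence simulator with a
    digital mouse-head phantom carrying four radioactive fiducial markers,
    point-source head tracking in 32-ms short-frame reconstructions with
    geometric marker matching and rigid (Kabsch) pose estimation, list-mode
    OSEM reconstruction with image-space resolution modelling, event-by-event
    rigid motion correction, body-outline attenuation maps, behavioural
    readouts (head speed, distance travelled, position heat maps), and the
    quantification statistics used in test-retest and pharmacological
    challenge studies (regional SUV, coefficient of variation, intraclass
    correlation, Bland-Altman agreement, time-activity-curve slope tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
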