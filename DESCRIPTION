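Package: photonpixel
Title: Parallel Electrical-Signal Acquisition via LED-Array Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for photon-pixel coupling: parallel conversion of many
    electrical sensor channels into LED luminance, camera frames, per-LED
    pixel values and calibrated percentage matrices. Includes a forward-model
    simulator of the sensor/LED/camera rig (gain spread, point-spread and
    diffuser blur, camera noise, geometric jitter, slow signal dynamics),
    automated LED spot detection into a vector map of pixel coordinates,
    frame-to-matrix decoding, additive per-sensor gain calibration from a
    common-signal session, average-encoded-matrix heatmaps with invertible
    three-colour encoding, and a small feed-forward classifier with a 50
    percent decision threshold. A command-line interface unifies the stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    nnet,
    png,
    stats,
    tools,
    utils
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
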