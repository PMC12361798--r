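Package: echomvp
Title: Diagnosis and Saliency Heatmap Agent for Mitral Valve Prolapse in
    Cine Echocardiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage analysis agent for cine echocardiography of the
    mitral valve: confidence-gated dual-network recognition of systolic
    frames with cardiac-cycle parsing, segmentation-based diagnosis of
    mitral valve prolapse (MVP) with severe-zone localization from the
    spatial relationship of the anterior leaflet, posterior leaflet and
    prolapse area, and edge-belt-guided saliency heatmaps of the prolapse
    with learnable frequency-domain attention. Includes a synthetic
    echocardiography phantom generator with ground-truth phase labels and
    leaflet/prolapse masks so the full pipeline is trainable and testable
    on CPU, plus the complete evaluation metric suite (precision, recall,
    macro-F1, accuracy, cycle-level AccSys, end-diastole/end-systole frame
    errors, Dice and IoU).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
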