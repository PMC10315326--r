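Package: rvsb
Title: Single-Beat Estimation of Right Ventricular Pressure-Volume Loop Parameters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates right-ventricular pressure-volume-loop parameters from
    right-heart-catheterization data alone, using the single-beat method: the
    theoretical isovolumic peak pressure (Pmax) is obtained by sine-curve
    fitting of the isovolumic contraction and relaxation segments of the RV
    pressure waveform, end-systolic and end-diastolic volumes follow in closed
    form from Pmax, end-systolic pressure and stroke volume under a zero
    volume-intercept assumption, and the diastolic stiffness coefficient (beta)
    and end-diastolic elastance (Eed) are obtained from an exponential
    end-diastolic pressure-volume relationship anchored at the estimated
    volumes and the normalized RV end-diastolic pressure. Includes waveform
    CSV input/output, beat segmentation and fiducial landmark detection on
    dP/dt, a synthetic waveform generator with known ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
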