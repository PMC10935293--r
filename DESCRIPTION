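Package: fpmflow
Title: Fourier Ptychographic Microscopy Simulation and Wirtinger-Flow
    Pupil Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the forward imaging process of a Fourier
    ptychographic microscope (LED-array illumination, coherent-transfer-
    function low-pass filtering, intensity detection) and reconstructs
    high-resolution complex object fields from stacks of low-resolution
    intensity images. Two reconstruction engines are provided: the
    classical alternating-projection spectrum-stitching algorithm, and an
    aberration-correcting optimizer that parameterizes the pupil phase
    with Zernike polynomials and minimizes a spectral self-consistency
    loss by Wirtinger-Flow gradient descent with alternating sample/pupil
    updates. Includes defocus-to-Zernike calibration, synthetic phantom
    and benchmark generators, PSNR/SSIM image-quality metrics, and
    TIFF/JSON/CSV input-output for acquisition stacks and reconstructions.
License: MIT
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
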