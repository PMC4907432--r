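Package: cbctpano
Title: Panoramic Radiograph Synthesis from Dental Cone-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesizes panoramic dental radiographs from cone-beam CT
    (CBCT) volumes by curved planar reformation. An axial maximum-intensity
    projection is segmented by seeded k-means++ clustering, the dental arch
    is isolated with a spatial quadrangle, a parabola is fitted and turned
    into a Hermite cubic spline arch curve; oblique sagittal sections along
    the curve's normals are segmented and a polynomial long-axis curve is
    fitted per section; the resulting 3D panoramic curved surface is
    developed isometrically into single-slice or thickened (slab-averaged)
    panoramic radiographs. Includes a cylinder-projection baseline and a
    synthetic jaw phantom with closed-form ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    png,
    tiff,
    jsonlite,
    yaml,
    EBImage,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
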