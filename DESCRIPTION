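Package: hdrcheck
Title: Independent Second-Check Dose Calculation for HDR Brachytherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Volumetric independent dose calculation for verifying
    high-dose-rate (HDR) image-guided adaptive brachytherapy plans. Computes
    TG-43U1 line-source dose at arbitrary points and on 3D grids, derives
    stepping-source orientations in ring applicators by a tangent method
    (with a chained-chord baseline), rasterizes structure contours and
    computes dose-volume histogram metrics (D100%, D90%, D10cc, D2cc,
    D0.1cc) with or without applicator-volume exclusion, converts doses to
    biologically effective dose (BED) and equivalent dose in 2-Gy fractions
    (EQD2), and compares dose distributions with the gamma index. Includes a
    deterministic synthetic fixture generator (tandem-and-ring plan,
    ellipsoidal target and organ-at-risk phantom) so the full verification
    workflow runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), pracma, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
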