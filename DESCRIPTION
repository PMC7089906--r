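Package: impingemap
Title: Pre-Operative Mapping of Prosthetic and Bony Impingement for Hip
    Arthroplasty Planning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies and visualises bone-to-bone (BTBI) and
    implant-to-bone (ITBI) impingement areas on native bone geometry for
    total hip arthroplasty planning.  For every posture of a hip activity
    the conical clearance angle (CCA) before prosthetic impingement is
    found by nested angular sweeps; bony contacts occurring within
    fractions of that clearance are located with Moller-Trumbore
    segment-triangle intersection tests, extracted as connected mesh
    patches by seed/child region growing, ranked into severity bands and
    exported as colour-coded surface meshes (PLY) and area tables (CSV).
    Includes parametric test fixtures (cup, ball-and-neck stem, bone
    proxies with prominence bumps) whose contact angles have closed forms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, yaml, jsonlite, utils, stats, grDevices, graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
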