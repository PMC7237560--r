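Package: celldosim
Title: Cellular Electron Dosimetry for Beta and Auger Emitters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo cellular dosimetry for electron-emitting
    radionuclides used in targeted radionuclide therapy. Computes absorbed
    doses to the nuclei of single tumour cells, of cells in a 19-cell
    micrometastasis cluster, and of water spheres, for terbium-161 and
    lutetium-177 under different subcellular source distributions (cell
    surface, cytoplasm, nucleus, whole cell). Electron transport uses
    continuous-slowing-down dose point kernels built from a collision
    stopping-power table for liquid water, with a stepped track mode for
    cross-validation. Doses are normalized to a fixed electron energy
    release per unit volume so that radionuclides with different energies
    per decay can be compared, and are decomposed into self-dose and
    cross-dose with batch statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    optparse,
    ggplot2
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
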