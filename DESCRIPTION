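Package: capop
Title: Calcium Imaging Analysis of Neuronal Population Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable pipeline for the analysis of neuronal population
    calcium imaging: rigid movie registration with motion-artifact flagging,
    morphology-based segmentation of single-neuron ROIs (nucleus-labeled and
    cytosol-labeled modes, plus hexagonal grids), perisomatic neuropil
    decontamination and dF/F0 computation, noise-model based inference of
    significant calcium transients constrained by indicator decay kinetics,
    event-locked tuning curves with HSV topographic response maps, detection
    of non-exclusive neuronal assemblies by PCA with promax oblique rotation
    and a Marchenko-Pastur eigenvalue threshold, and validation of assembly
    features against random and topography-preserving surrogate assemblies.
    Includes a synthetic-data generator producing ground-truth movies, traces
    and planted assemblies for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
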