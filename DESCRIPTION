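Package: oisi
Title: Analysis of Sensory-Evoked Optical Intrinsic Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for widefield multispectral optical intrinsic signal (OIS)
    imaging of evoked cortical responses. Provides a forward simulator for
    trial-structured multispectral frame stacks (hemodynamic and
    light-scattering components, illumination drift, shot-like noise),
    preprocessing (Gaussian spatial filtering, reference-region illumination
    correction, trial averaging), OIS activation mapping and region-of-interest
    time-course extraction, spectral decomposition of multi-band signals into
    oxy-/deoxy-hemoglobin and a scattering pseudo-chromophore via the modified
    Beer-Lambert law, and evoked-response metrics (peak amplitude and position,
    half-recovery time, average LFP) with exact nonparametric statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
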