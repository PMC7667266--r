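Package: chelscreen
Title: Screening Metal-Ion Chelating Agents by Conditional Stability Constants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the pragmatic screening of chelating agents for metal
    scavenging (e.g. soil-washing remediation). From cumulative ligand
    protonation constants and 1:1 metal-ligand formation constants the package
    computes the proton side-reaction polynomial D(H), conditional (effective)
    stability constants, the required constant for a target complexed
    fraction, F(H) screening curves, pH windows of complexation, and full
    pH-stepped speciation of one metal / one ligand systems with optional
    mononuclear metal hydrolysis. Ships a curated database of amino
    carboxylic chelators (NTA, EDTA, EDDS, GLDA, ...) and a command-line
    interface for batch screening and soil-contamination scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ggplot2,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
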