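Package: trackmc
Title: Event-by-Event Track-Structure Monte Carlo for Charged Particles in
    Liquid Water
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semiempirical inelastic cross-section models for electrons,
    protons and heavy ions in liquid water (Rudd and Seltzer ionisation,
    Kutcher-Green and Kaplan-Sukhonosov excitation, first Born approximation
    with a pluggable dielectric response, Z-squared heavy-ion scaling with
    Booth-Grant effective charge), organised as two switchable model chains
    mirroring the RITRACKS and Geant4-DNA physics lists, plus an
    event-by-event Monte Carlo transport loop that counts ionisation events
    produced by a single primary and its secondary-electron cascade in a
    bounded water volume.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
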