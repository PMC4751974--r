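Package: heterospec
Title: Design of Heterospecific Coiled-Coil Peptide Sets by Interactome
    Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving sets of mutually orthogonal (heterospecific)
    parallel dimeric coiled-coil peptides. Expands degenerate peptide or
    degenerate-codon templates into explicit libraries, enumerates heptad
    core (a-a') and electrostatic (g-e') interhelical pairings for parallel
    and antiparallel dimer geometries, scores every pairwise interaction in
    the resulting interactome with an additive free-energy decomposition and
    a linear predicted melting temperature (Tm) model, filters promiscuous
    sequences (stable homodimers, antiparallel fully complementary
    homodimers) at import, and searches the stored interactions for groups
    of two and four coiled coils predicted to pair correctly while all
    off-target interactions are disfavoured. Also includes utilities to
    simulate and fit two-state thermal denaturation curves of dimeric coiled
    coils and to quantify dimer-exchange excess helicity from circular
    dichroism spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
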