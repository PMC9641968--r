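Package: ancsr
Title: Marginal Ancestral Sequence Reconstruction and Active-Site
    Combination Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Marginal ancestral sequence reconstruction on a fixed
    protein phylogeny (Felsenstein pruning under empirical amino-acid
    substitution models with discrete-gamma or free-rate heterogeneity),
    detection of ancestrally variable sites within a structural site
    panel, enumeration of ancestral residue combinations with joint
    posterior probabilities, physicochemical recoding of residues, and
    classification of each combination against extant sequence
    diversity. Ships the 24-site nitrogenase substrate-channel panel and
    the posterior profile of the Nif/Vnf/Anf ancestor as a worked
    reference data set, plus a sequence simulator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
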