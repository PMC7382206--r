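Package: tunarflp
Title: In-Silico PCR-RFLP Identification of Tuna and Tuna-Substitute Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Virtual PCR-RFLP toolkit for authenticating raw tuna products
    from the mitochondrial cytochrome b (Cytb) marker. Amplifies a 357-bp
    Cytb fragment in silico with a universal primer pair, digests it with a
    five-enzyme restriction panel (Eco147I, HinfI, MboI, XagI, HindII),
    and calls the species by matching the fragment-length fingerprint
    against a bundled eight-species reference panel using a staged key in
    which HindII resolves the bigeye tuna / skipjack tuna pair. Includes
    tolerance-aware gel-band matching, exhaustive diagnostic-panel
    minimization, a Kimura 2-parameter + neighbor-joining verification
    phylogeny with bootstrap supports, and a constructive synthetic-sequence
    generator that reproduces every reference fingerprint without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
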