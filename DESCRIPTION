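Package: uvr8scan
Title: Functional-Site Conservation Scanning for UVR8-Like UV-B Photoreceptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-anchored scanning of candidate protein sequences for the
    functional sites of the plant UV-B photoreceptor UVR8: the GWRHT
    pentapeptide motifs of beta-propeller blades 5-7, the tryptophan triad
    (W233/W285/W337) responsible for UV-B perception, the salt-bridge residues
    maintaining the homodimer (R286, R338, E43, D44, D96, D107) and the VP core
    of the C-terminal C27 region. Candidates are globally aligned to a
    reference with affine gap penalties, annotated sites are projected through
    the induced coordinate map and called on an
    exact/conservative/degraded/absent ladder, and sequences are classified
    into homology tiers. The package also aggregates conservation percentages
    and per-species copy numbers, builds a reference-anchored pseudo-alignment
    with gap/entropy column filtering, neighbor-joining trees and bootstrap
    supports, and simulates UVR8-like protein families along known trees with
    ground-truth knockouts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
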