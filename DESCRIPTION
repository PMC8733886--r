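Package: mapseqid
Title: Protein Sequence Identification and Assignment from Density Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Identifies proteins and assigns sequence register in main-chain-only
    models built into crystallographic (2Fo-Fc) or cryo-EM density maps. Map
    density around each traced residue is sampled on a backbone-aligned masked
    grid, a small neural classifier predicts 20-way residue-type probabilities,
    and the resulting positional probabilities are used either to query a FASTA
    sequence database through a profile hidden Markov model (HMMER) or to score
    whole-fragment sequence alignments with Z-scores and extreme-value p-values.
    Includes a synthetic-data generator (Gaussian-atom maps, ideal side-chain
    libraries, decoy sequence databases) so the full pipeline can be trained and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
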