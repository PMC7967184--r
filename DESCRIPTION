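Package: flexrank
Title: Rank-Based Analysis of Backbone Heavy-Atom Flexibility in Structural Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting atom-type patterns in backbone heavy-atom
    flexibility across multi-model protein structures. Reads multi-model PDB
    ensembles (NMR models or molecular-dynamics snapshot stacks) and
    crystallographic B-factor columns, superimposes ensemble models by
    least-squares, variance-weighted, or core-restricted schemes, computes
    per-atom coordinate variances, ranks backbone atom types (amide N, C-alpha,
    carbonyl C, carbonyl O) within each residue, and fits a tie-corrected
    Friedman mean-rank test with a three-standard-error post-hoc comparison
    rule.  A per-residue F-score quantifies how anomalously variable each
    carbonyl oxygen is relative to its amide-nitrogen baseline.  Includes a
    synthetic-ensemble generator (ideal backbone geometry, additive Gaussian
    noise, and a peptide-plane rocking motion model) so every stage of the
    pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
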