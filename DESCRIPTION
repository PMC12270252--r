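Package: crisprOutcomes
Title: Interpretable Prediction of CRISPR-Cas9 Template-Free Repair Outcome Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates the template-free repair outcome space of a
    CRISPR-Cas9 target (deletions up to 30 bp grouped by microhomology-driven
    product identity, plus 21 insertion outcomes), predicts per-outcome
    frequency profiles with a compact three-submodel architecture (a 5-feature
    sigmoid neural network for deletions and softmax regressions for
    insertions and the deletion-insertion ratio), adapts pre-trained models to
    new cellular domains via transfer learning with optional layer freezing,
    and explains predictions with exact Shapley-value feature attributions.
    Includes a synthetic-screen generator, Jensen-Shannon distance based
    evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
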