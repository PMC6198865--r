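Package: recphylo
Title: Read, Write, Validate, Produce and Draw Reconciled Gene Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phylogenetic reconciliations between gene trees and
    species trees stored as recPhyloXML, the XML interchange grammar in which
    each gene-tree clade carries an ordered sequence of evolutionary events
    (speciation, duplication, loss, lateral transfer in its two-step
    donor/recipient representation, and bifurcation in unsampled lineages).
    Provides a bit-faithful reader and writer including geographic
    annotations, a two-level validator (event grammar and semantic consistency
    against the species tree), conversion to and from Newick/NHX, event
    censuses, document combination and extraction, a most-parsimonious
    duplication-loss (LCA) reconciler that emits the format, a
    duplication-transfer-loss simulator along a dated species tree, and an
    SVG visualizer drawing gene trees embedded in species-tree tubes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
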