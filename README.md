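# recphylo

Gene trees rarely match the species tree they evolved in: genes are
duplicated, lost, and laterally transferred. A *reconciliation* annotates
every gene-tree node with such an evolutionary event and maps it onto the
species tree, and recPhyloXML is the community XML grammar for exchanging
reconciliations between inference programs, simulators and viewers.
`recphylo` is an R toolkit for that grammar, aimed at anyone who produces,
checks, converts, simulates or draws reconciled gene trees.

Each gene-tree clade carries an `<eventsRec>` sequence built from seven
event tags. `transferBack` (a lineage re-entering a sampled species branch)
is the only non-terminal tag and may repeat; every sequence ends in exactly
one terminal tag, either bifurcating — `speciation`, `duplication`,
`branchingOut`, `bifurcationOut` — giving the clade two children, or
lineage-ending — `leaf`, `loss`. A lateral transfer is written in two
steps: the donor-side `branchingOut` (one gene copy stays resident, the
other exits the sampled tree) and the recipient-side `transferBack`;
`bifurcationOut` represents a gene bifurcating while it evolves in an
unsampled or extinct lineage absent from the species tree. A document
(`<recPhylo>`) packages at most one species tree with one or more rooted
reconciled gene trees; `<geography>`/`<area>` annotations (with verbatim
KML payloads) are carried through.

The package provides:

* **I/O** — `read_recphylo()` / `write_recphylo()` (strict or lenient,
  byte-stable output), `read_plain_tree()` for Newick/NHX.
* **Validation** — `validate_structure()` for the event grammar and
  document cardinality, `validate_semantics()` for consistency against the
  species tree (unknown species, speciation/duplication/transfer child
  rules, orphan or self transfers, timeSlice monotonicity), and
  `build_reconciliation_map()` for the gene-to-species assignment with an
  explicit unsampled sentinel.
* **Conversion** — `to_newick()` (plain or an NHX dialect that encodes the
  full event sequence), `from_nhx()`, event censuses
  (`rp_count_events()`), `rp_combine()` and `rp_extract()`.
* **Production** — `lca_reconcile()`, the classical most-parsimonious
  duplication–loss reconciliation under the LCA mapping
  M(g) = lca(M(left), M(right)), with g a duplication iff M(g) equals a
  child image and explicit `LOST` leaves on every skipped species branch;
  and `simulate_dataset()`, a seeded duplication–transfer–loss simulator
  along a dated species tree whose native output is the document model.
* **Visualization** — `rp_render_svg()` draws the species tree as nested
  tubes with the gene tree embedded, one restylable glyph per event.
* **CLI** — the installed `exec/recphylo` script exposes `validate`,
  `convert`, `count`, `combine`, `extract`, `reconcile`, `simulate` and
  `draw` subcommands over files or pipes (exit codes: 0 valid/success,
  1 invalid document, 2 usage error, 3 I/O or parse failure).

## Worked example

Reconcile a four-gene family against a dated three-species tree, using the
`species_gene` leaf-naming convention:

```r
library(recphylo)
doc <- lca_reconcile("((A_1,B_1),(A_2,C_1));", "((A:1,B:1)AB:1,C:2)root;")
rp_count_events(doc)
#> event census over 1 gene tree(s):
#>   leaf            4
#>   speciation      4
#>   loss            2
#>   duplication     1
validate_semantics(doc, "strict")
#> VALID (0 error(s), 0 warning(s))
```

The census reads: the family's root is a duplication (the two (A,B)-shaped
subtrees are paralogous copies), and making the copies fit the species
tree demands two losses — copy 1 was lost in C, copy 2 in B. Two of the
four speciation events are pass-through nodes inserted to carry those
`LOST` leaves. The same history as NHX (`Ev` = event sequence, `S` =
species, `G` = gene name):

```r
to_newick(doc$gene_trees[[1]], "nhx")
#> (((A_1[&&NHX:Ev=leaf:S=A:G=A_1],B_1[&&NHX:Ev=leaf:S=B:G=B_1])
#>    [&&NHX:Ev=speciation:S=AB],LOST[&&NHX:Ev=loss:S=C])
#>    [&&NHX:Ev=speciation:S=root], ...)[&&NHX:Ev=duplication:S=root];
```

`write_recphylo(doc, "family.xml")` serializes it, and
`rp_render_svg(doc, "family.svg")` draws it. A simulated multi-family
dataset with transfers comes from:

```r
sim <- simulate_dataset("((A:1,B:1)AB:1,C:2)root;",
                        rp_sim_params(n_families = 2, seed = 7,
                                      transfer_rate = 0.4))
rp_count_events(sim)
#> event census over 2 gene tree(s):
#>   leaf            10
#>   speciation      4
#>   duplication     1
#>   branchingOut    3
#>   transferBack    3
```

Every `branchingOut` is balanced by a `transferBack` — the two-step
transfer representation.

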