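---
title: "Reconciled gene trees in recphylo: model, validation, parsimony and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciled gene trees in recphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recphylo)
```

## The event grammar and its object model

A reconciliation annotates each gene-tree clade with the sequence of
evolutionary events that happened along the branch leading to it, plus a
mapping onto a species tree. The grammar has seven event types. Six are
*terminal*: they close the sequence and fix the clade's arity —
`speciation`, `duplication`, `branchingOut` and `bifurcationOut` bifurcate
the gene tree (two children), `leaf` and `loss` end the lineage (no
children). `transferBack` is the single *non-terminal* type: it records a
lineage re-entering a sampled species branch and may occur any number of
times before the terminal event. Attribute rules follow the tag
semantics: every located event carries a `speciesLocation`;
`transferBack` instead carries a `destinationSpecies`; `bifurcationOut`
carries neither, because it happens in a lineage absent from the species
tree; `geneName` belongs to `leaf` only.

`recphylo` enforces these rules at three layers. Constructors
(`rp_event()`, `rp_gene_node()`, `rp_document()`) reject violations at
build time, so programmatically produced objects are correct by
construction. The reader enforces them while parsing. The structural
validator re-checks everything from scratch, so that hand-patched or
deliberately malformed objects (built with `check = FALSE`) can be
diagnosed rather than merely refused.

Design choices worth making explicit:

* **Binary trees only.** Every bifurcating event is binary and the two
  lineage-ending events terminate; a polytomy has no event that could
  label it, so clades with other child counts are rejected.
* **Sibling order** is preserved as read but carries no meaning:
  `rp_equal()` and the species-tree comparison in `rp_combine()` try both
  orderings.
* **Names** need not be unique in gene trees (`LOST` is an ordinary
  name, following the convention of the format's published examples);
  species names must be unique since `speciesLocation` resolves by exact,
  case-sensitive string match.
* **The unsampled sentinel** `rp_unsampled()` is `"@UNSAMPLED@"`; a
  leading `@` cannot start an XML name, so it can never collide with a
  species identifier.
* **confidence** is stored unconstrained; values outside [0, 1] draw a
  validator warning (`W_CONFIDENCE`) rather than a model error, since the
  grammar only promises "a support value".
* Several `transferBack`s in one sequence are syntactically legal; the
  package interprets them as successive species changes in listed order.
  Whether a `speciesLocation` denotes a species-tree node or its incoming
  branch is left open by the grammar; the model stores the name and the
  consumers (validator, renderer) treat it as the branch ending in that
  node.

## Two-level validation

Level 1 (`validate_structure()`) is purely local: exactly one terminal
event per sequence and in last position (`E_NO_TERMINAL`,
`E_EARLY_TERMINAL`, `E_MULTI_TERMINAL`), arity matching the terminal
(`E_ARITY`), attribute presence (`E_ATTR`), and document cardinality — at
most one species tree, at least one gene tree, unique species names
(`E_DOC`).

Level 2 (`validate_semantics()`) checks the reconciliation against the
species tree. The grammar itself never formalizes cross-node consistency,
so the rule set here is derived from the event definitions and is
deliberately split by level:

* **lenient** checks only what any consumer must rely on: resolvable
  species references (`E_SPECIES_UNKNOWN`) and `timeSlice` monotonicity
  along root-to-leaf paths (`W_TIMESLICE`, a warning — slices are
  facultative per event).
* **strict** adds the child-consistency rules. Define the *starting
  species* of a branch as the destination of its first `transferBack` if
  it begins with one, else the `speciesLocation` of its terminal event
  (unsampled for `bifurcationOut`). Then: speciation children must start
  in the two distinct child species of the speciation's location
  (`E_SPECIATION_CHILDREN`); duplication children must start in the
  duplication's species (`E_DUP_CHILDREN`); a `branchingOut` needs
  exactly one resident child and one emigrant — a child beginning with
  `transferBack` or ending in `bifurcationOut`
  (`E_BRANCHINGOUT_CHILDREN`); `bifurcationOut` children must all be
  emigrants in that sense (`E_BIFOUT_CHILDREN`); a `transferBack` start
  requires a donor-side `branchingOut`/`bifurcationOut` parent
  (`E_ORPHAN_TRANSFERBACK`); and a transfer may not re-enter the species
  it currently occupies (`E_TRANSFER_SELF`), where "currently occupies"
  means the previous destination in a `transferBack` chain, or the donor
  species for the first reception after a `branchingOut`.

Two conventions resolve questions the grammar leaves open. A *root*
beginning with `transferBack` is downgraded to a warning
(`W_ROOT_TRANSFERBACK`): the family may simply originate outside the
sampled tree. And under a `branchingOut`, a `loss` child is accepted only
on the resident side — the emigrant side is by definition outside the
sampled tree, where a located loss is not expressible.

The strict rules are tested against an independent brute-force oracle
that enumerates, per node, the legal child-descriptor pairs. The suite
compares the two implementations exhaustively over every event/species
assignment (with up to one `transferBack` prefix per node) of small gene
trees over two- and three-leaf species trees — tens of thousands of
documents — and on thousands of sampled assignments of gene trees up to 7
nodes over four-leaf species trees. Full exhaustion over the 7-node space
is combinatorially impossible (the assignment space exceeds 10^12), which
is why sampling takes over beyond the enumerable sizes.

## LCA duplication–loss parsimony

`lca_reconcile()` implements the classical most-parsimonious
transfer-free reconciliation. Each gene node g gets
M(g) = lca(M(left(g)), M(right(g))) in the species tree; g is a
*duplication* iff M(g) equals a child's image, else a *speciation*.
Losses are made explicit so that the output is a complete, strictly valid
document: on the edge from g to child c, the lineage demonstrably crossed
every species node between its entry branch and M(c), and at each such
node a pass-through speciation with a `LOST` child is inserted. Charging
is the standard convention:

```
speciation at s, child mapped to m:  losses = depth(m) - depth(s) - 1
duplication at s, child mapped to m: losses = depth(m) - depth(s)
```

so a duplication at s whose child lives strictly below s pays one more
loss (the copy lost in s's other descendant) than a speciation would.
The test suite certifies minimality by exhaustive enumeration of all
ancestry-respecting assignments on hundreds of random instances (gene
trees up to 9 nodes, species trees up to 4 leaves) and checks the
zero-cost ⇔ congruence equivalence. The output is deterministic:
identical inputs serialize byte-identically.

Leaf mappings come either as a two-column TSV (`gene TAB species`) or via
the `species_gene` name-prefix rule. Tree indices in `rp_extract()` and
the CLI are 1-based throughout, the R convention.

## The duplication–transfer–loss simulator

`simulate_dataset()` exists so that every tag of the grammar — including
the transfer tags — can be exercised on arbitrarily many valid documents.
It is a top-down birth–death–transfer process along a dated, ultrametric
species tree (tolerance 1e-9 on leaf contemporaneity; a root branch
length, when given, acts as a stem):

* Rates `dup_rate`, `transfer_rate`, `loss_rate` are per unit branch
  length — equivalently per unit time — with default 0.1 each: on the
  bundled depth-2 trees this yields families with a handful of events,
  which is what fixtures should look like. No rate heterogeneity across
  branches; the simplest model that exercises the grammar.
* A transfer emits the donor-side `branchingOut`; the emigrant copy
  spends an Exp(`transfer_rate`) time in an undated unsampled
  compartment, capped at the time remaining, then re-enters a recipient
  drawn uniformly among the branches alive at the re-entry time,
  excluding the branch it came from (matching the self-transfer rule;
  hence transfers require at least two species). With probability
  `unsampled_bifurcation_prob` (default 0.1) it instead bifurcates there
  (`bifurcationOut`), each daughter re-entering independently; nesting
  depth defaults to one level (`max_unsampled_bifurcations`). The
  compartment is a single pool, not an explicit extinct-species tree —
  it honors the observation that most transfers pass through unsampled
  lineages without modelling their phylogeny.
* `timeSlice` attributes (on by default) are the 0-based rank, oldest
  first, of the inter-node time interval containing each event, so the
  validator's monotonicity rule is exercised by every simulated file.
* `condition_on_survival` (default on) redraws families with no extant
  leaf. All draws flow from one seed through R's RNG in a fixed
  recursion order, so equal seeds give byte-identical documents.

What passing the simulator-based tests does *not* show: real
reconciliations have rate heterogeneity, dated transfers constrained by
explicit extinct lineages, non-contemporaneous sampling and
multifurcations from unresolved gene trees. The simulator's closure
property (every output passes strict validation, checked on 1000 random
parameter draws) validates the package's internal consistency, not any
biological model. Its analytic anchors: at all-zero rates the gene tree
is an exact copy of the species tree, and on a single branch of length T
with only duplication at rate δ the mean leaf count is e^(δT) (pure birth
process), checked at 10000 replicates within 3 Monte-Carlo standard
errors.

## Text formats

The XML writer is a deterministic serializer: UTF-8, two-space
indentation, fixed attribute order (`speciesLocation` /
`destinationSpecies` first), optional attributes only when present,
species tree before gene trees, `rooted="true"` on every gene-tree
phylogeny. This makes write→read→write byte-stable, which the suite
asserts on the whole example corpus. The reader accepts documents with or
without a namespace; the writer emits none unless asked. Curly
typographic quotes seen in typeset examples of the format are treated as
an artifact; the format uses plain XML quotes. Unknown phyloXML-style
clade children (e.g. `<description>`) are errors in strict mode and
opaque pass-through blobs in lenient mode with `keep_unknown = TRUE`.
`timeSlice` must be an integer in strict mode.

The NHX dialect written by `to_newick(tree, "nhx")` uses keys `Ev`
(semicolon-separated event types, in order), `S` (terminal species), `D`
(transferBack destinations, comma-separated), `T` (timeSlices), plus `C`
(confidences), `G` (leaf gene name) and `B` (clade support) so that
`from_nhx()` restores the tree exactly — geography annotations are the
one thing the dialect does not carry. Event codes are the tag names
verbatim, avoiding collision with other tools' one-letter codes. Values
are percent-encoded, and labels containing a Newick metacharacter
(`, : ( ) ; [ ]`) are single-quoted with `''` escaping, so arbitrary
names round-trip.

## Rendering

`rp_layout()` computes plain coordinates first; `rp_svg()` only
serializes them, so the geometric invariants are asserted numerically.
Time runs left to right with the root at the left. Species tubes are
rectangles: a leaf tube's height grows with the number of gene lineages
anchored in it, an internal tube's vertical band spans its children's
bands (which is what makes parent-to-child gene routes provably stay
inside the tubes), and horizontal extent comes from topological depth
with leaf tubes flush right. Gene nodes get anchor lanes evenly spaced
inside their tube, ordered by tree index and preorder — a deterministic
tie-break. Routes are L-shaped inside tubes; transfer edges are straight,
dashed, and explicitly tagged as inter-tube segments. `bifurcationOut`
lineages live in a reserved margin band above the species tubes,
truncated-tube style. Glyphs: star for the start of a gene lineage,
square duplication, cross loss, diamond transfer departure, triangle
transfer arrival; the published figure conventions leave speciation and
extant-leaf glyphs unspecified, so the package uses an open circle and a
small dot, and an outline diamond for `bifurcationOut`. Every glyph
carries a stable id and an `event-<type>` CSS class, so recoloring an
SVG afterwards is a one-line stylesheet edit.

## Problem sizes and limitations

The shipped suite uses: exhaustive validator/oracle enumeration at 3-node
gene trees (≈23 000 documents) plus 1000–1500 sampled larger instances;
500 LCA instances against exhaustive minimization; 1000 simulator draws
for closure; 10 000 pure-birth replicates; 100 rendered documents. These
sizes give sub-minute module tests while leaving the combinatorial claims
exhaustive wherever exhaustion is tractable.

Known limitations: no dated-consistency check against real branch lengths
(only ordinal timeSlice monotonicity); no auto-repair of invalid files;
no parsing of third-party reconciliation dialects (ALE, NOTUNG, ecceTERA,
PrIME, RANGER-DTL); no transfer inference in the reconciler (DL only, by
design — transfer-bearing documents come from the simulator or external
tools); no ILS, gene conversion or transfer-with-replacement events; and
the renderer aims for convention-compatible, deterministic output rather
than reproducing any particular viewer's layout.
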