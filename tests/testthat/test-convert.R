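test_that("plain Newick conversion keeps topology and drops events", {
  single <- rp_gene_node(list(ev("leaf", species_location = "C")),
                         name = "gene_seq_1")
  expect_identical(to_newick(single), "gene_seq_1;")

  doc <- read_recphylo(fixture("listing-speciation-loss.xml"))
  nwk <- to_newick(doc$gene_trees[[1L]])
  expect_identical(nwk, "(gene_seq_1,LOST)n1;")
  expect_false(grepl("NHX", nwk))
})

test_that("NHX conversion encodes events; forbidden labels are quoted", {
  doc <- read_recphylo(fixture("listing-speciation-loss.xml"))
  nhx <- to_newick(doc$gene_trees[[1L]], "nhx")
  expect_match(nhx, "LOST\\[&&NHX:Ev=loss:S=B\\]")
  expect_match(nhx, "Ev=speciation:S=A")

  odd <- rp_gene_node(list(ev("leaf", species_location = "C")),
                      name = "a(1)")
  out <- to_newick(odd, "nhx")
  expect_match(out, "^'a\\(1\\)'", fixed = FALSE)
  back <- from_nhx(out)
  expect_equal(back$name, "a(1)")
})

test_that("NHX round-trip restores full event sequences", {
  doc <- read_recphylo(fixture("listing-transfer.xml"))
  t <- doc$gene_trees[[1L]]
  back <- from_nhx(to_newick(t, "nhx"))
  expect_true(rp_equal(back, t))
  tb_node <- back$children[[2L]]
  expect_equal(vapply(tb_node$events, `[[`, "", "type"),
               c("transferBack", "leaf"))
  expect_equal(tb_node$events[[1L]]$destination_species, "B")
})

test_that("NHX round-trip is exact over simulated trees (property)", {
  set.seed(11)
  for (i in 1:40) {
    doc <- simulate_dataset(random_dated_species(4),
                            rp_sim_params(n_families = 1, seed = 500 + i,
                                          transfer_rate = 0.5,
                                          dup_rate = 0.3, loss_rate = 0.2))
    t <- doc$gene_trees[[1L]]
    back <- from_nhx(to_newick(t, "nhx"))
    expect_true(rp_equal(back, t))
    # census preserved through the text format
    d2 <- rp_document(list(back), species_tree = doc$species_tree)
    expect_identical(rp_count_events(d2)$total, rp_count_events(doc)$total)
  }
})

test_that("plain Newick without annotations is rejected with guidance", {
  expect_error(from_nhx("((a,b),c);"), "lca_reconcile")
  root <- "[&&NHX:Ev=duplication:S=A]"
  expect_error(from_nhx(paste0(
    "(a[&&NHX:Ev=whoops:S=A],b[&&NHX:Ev=leaf:S=B])", root, ";")),
    "unknown event code")
  expect_error(from_nhx(paste0(
    "(a[&&NHX:Ev=leaf],b[&&NHX:Ev=leaf:S=B])", root, ";")),
    "missing S")
})

test_that("event censuses count every event exactly once", {
  loss_doc <- read_recphylo(fixture("listing-speciation-loss.xml"))
  cen <- rp_count_events(loss_doc)$total
  expect_identical(cen[["speciation"]], 1)
  expect_identical(cen[["leaf"]], 1)
  expect_identical(cen[["loss"]], 1)
  expect_identical(sum(cen), 3)

  tr <- read_recphylo(fixture("listing-transfer.xml"))
  cet <- rp_count_events(tr)$total
  expect_identical(cet[["transferBack"]], 1)   # non-terminal counted too
  expect_identical(cet[["branchingOut"]], 1)
  expect_identical(cet[["leaf"]], 2)
})

test_that("census identity: bifurcations = endings - #trees, per document", {
  set.seed(21)
  for (i in 1:15) {
    doc <- simulate_dataset(random_dated_species(4),
                            rp_sim_params(n_families = 3, seed = 700 + i,
                                          transfer_rate = 0.4,
                                          dup_rate = 0.3, loss_rate = 0.3))
    cen <- rp_count_events(doc)$total
    bif <- cen[["speciation"]] + cen[["duplication"]] +
      cen[["branchingOut"]] + cen[["bifurcationOut"]]
    expect_identical(bif, cen[["leaf"]] + cen[["loss"]] -
                       length(doc$gene_trees))
  }
})

test_that("combine concatenates gene trees and adds censuses", {
  a <- read_recphylo(fixture("recphylo-skeleton.xml"))   # 2 gene trees
  b <- read_recphylo(fixture("listing-speciation-loss.xml"))
  ab <- rp_combine(list(a, b))
  expect_length(ab$gene_trees, 3L)
  expect_identical(rp_count_events(ab)$total,
                   rp_count_events(a)$total + rp_count_events(b)$total)

  # species tree kept when only one input carries one
  no_sp <- rp_document(a$gene_trees)
  with_sp <- rp_combine(list(no_sp, b))
  expect_true(rp_equal(with_sp$species_tree, b$species_tree))
  d2 <- read_recphylo(write_recphylo(with_sp))
  expect_true(rp_equal(with_sp, d2))

  # conflicting species trees are rejected, naming the divergence
  other <- rp_document(b$gene_trees,
                       species_tree = rp_species_node(
                         "A", list(rp_species_node("C"),
                                   rp_species_node("D"))))
  expect_error(rp_combine(list(b, other)), "conflicting species trees")
})

test_that("extract selects by index and unambiguous name", {
  doc <- read_recphylo(fixture("recphylo-skeleton.xml"))
  doc5 <- rp_combine(list(doc, doc, rp_extract(doc, 1L)))
  expect_length(doc5$gene_trees, 5L)

  two <- rp_extract(doc5, c(1L, 3L))
  expect_length(two$gene_trees, 2L)
  expect_true(rp_equal(two$species_tree, doc$species_tree))

  byname <- rp_extract(doc, "m1")
  expect_equal(byname$gene_trees[[1L]]$name, "m1")
  expect_error(rp_extract(doc5, "n1"), "ambiguous")
  expect_error(rp_extract(doc, "nope"), "no gene tree")
  expect_error(rp_extract(doc, 99L), "out of range")

  # extracting everything in order is the identity
  expect_true(rp_equal(rp_extract(doc5, 1:5), doc5))
})

test_that("census serializes to TSV rows and JSON", {
  doc <- read_recphylo(fixture("listing-speciation-loss.xml"))
  tsv <- rp_census_tsv(rp_count_events(doc))
  expect_match(tsv, "event_type\ttree_index\tcount")
  expect_match(tsv, "speciation\t1\t1")
  expect_match(tsv, "loss\ttotal\t1")
  js <- jsonlite::fromJSON(rp_census_json(rp_count_events(doc)))
  expect_identical(js$total$leaf, 1L)
})

test_that("plain conversion of an LCA output re-reconciles to the same census", {
  set.seed(31)
  prune_lost <- function(n) {
    if (!length(n$children)) return(if (n$name == "LOST") NULL else n)
    kept <- Filter(Negate(is.null), lapply(n$children, prune_lost))
    if (length(kept) == 1L) return(kept[[1L]])
    n$children <- kept
    n
  }
  for (i in 1:10) {
    sp <- as_named_species(random_topology(c("A", "B", "C", "D")))
    genes <- paste0(sample(c("A", "B", "C", "D"), 5, replace = TRUE),
                    "_", 1:5)
    g <- random_topology(genes)
    doc <- lca_reconcile(g, sp)
    nwk <- to_newick(doc$gene_trees[[1L]], "plain")
    replain <- prune_lost(read_plain_tree(nwk))
    redoc <- lca_reconcile(replain, sp)
    expect_identical(rp_count_events(redoc)$total,
                     rp_count_events(doc)$total)
  }
})
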