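test_that("printed-example documents pass both validators strictly", {
  for (f in fixture_files()) {
    doc <- read_recphylo(f)
    expect_true(validate_structure(doc)$valid, label = basename(f))
    rep <- validate_semantics(doc, "strict")
    expect_true(rep$valid, label = paste("semantics of", basename(f)))
  }
})

test_that("structural flags fire on malformed event sequences", {
  # terminal not last
  n <- rp_gene_node(list(ev("leaf", species_location = "C"),
                         ev("loss", species_location = "C")),
                    check = FALSE)
  rep <- validate_structure(rp_document(list(n), check = FALSE))
  expect_true("E_EARLY_TERMINAL" %in% rep$issues$code)
  expect_true("E_MULTI_TERMINAL" %in% rep$issues$code)
  expect_false(rep$valid)

  # no terminal at all
  n2 <- rp_gene_node(list(ev("transferBack", destination_species = "B")),
                     check = FALSE)
  rep2 <- validate_structure(rp_document(list(n2), check = FALSE))
  expect_true("E_NO_TERMINAL" %in% rep2$issues$code)

  # bifurcating terminal without children
  n3 <- rp_gene_node(list(ev("speciation", species_location = "A")),
                     check = FALSE)
  rep3 <- validate_structure(rp_document(list(n3), check = FALSE))
  expect_true("E_ARITY" %in% rep3$issues$code)

  # attribute rules (events forged without the constructor)
  bad <- structure(list(type = "bifurcationOut", species_location = "A",
                        destination_species = NULL, confidence = NULL,
                        time_slice = NULL, gene_name = NULL),
                   class = "rp_event")
  n4 <- rp_gene_node(list(bad), children = list(gn_leaf("A"), gn_leaf("A")),
                     check = FALSE)
  rep4 <- validate_structure(rp_document(list(n4), check = FALSE))
  expect_true("E_ATTR" %in% rep4$issues$code)

  # document-level cardinality
  rep5 <- validate_structure(rp_document(list(), check = FALSE))
  expect_true("E_DOC" %in% rep5$issues$code)
})

test_that("semantic flags: unknown species, orphan transfers, self transfers", {
  sp <- sp_ABC()
  # unknown species reference
  d1 <- rp_document(gn_leaf("Z"), species_tree = sp)
  expect_true("E_SPECIES_UNKNOWN" %in%
                validate_semantics(d1, "strict")$issues$code)
  # lenient also flags unresolved references
  expect_true("E_SPECIES_UNKNOWN" %in%
                validate_semantics(d1, "lenient")$issues$code)

  # transferBack under a duplication parent is orphaned
  emi <- rp_gene_node(list(ev("transferBack", destination_species = "B"),
                           ev("leaf", species_location = "B")))
  d2 <- rp_document(rp_gene_node(
    list(ev("duplication", species_location = "C")),
    children = list(gn_leaf("C"), emi)), species_tree = sp)
  rep2 <- validate_semantics(d2, "strict")
  expect_true("E_ORPHAN_TRANSFERBACK" %in% rep2$issues$code)
  expect_true(validate_semantics(d2, "lenient")$valid)

  # transfer back into the donor branch
  d3 <- rp_document(rp_gene_node(
    list(ev("branchingOut", species_location = "C")),
    children = list(gn_leaf("C"),
                    rp_gene_node(list(
                      ev("transferBack", destination_species = "C"),
                      ev("leaf", species_location = "C"))))),
    species_tree = sp)
  expect_true("E_TRANSFER_SELF" %in%
                validate_semantics(d3, "strict")$issues$code)

  # a root may start with transferBack (warning only)
  d4 <- rp_document(rp_gene_node(
    list(ev("transferBack", destination_species = "B"),
         ev("leaf", species_location = "B"))), species_tree = sp)
  rep4 <- validate_semantics(d4, "strict")
  expect_true(rep4$valid)
  expect_true("W_ROOT_TRANSFERBACK" %in% rep4$issues$code)
})

test_that("speciation children must start in the two child species", {
  sp <- sp_ABC()   # (B,C)A
  mk <- function(l, r) rp_document(rp_gene_node(
    list(ev("speciation", species_location = "A")),
    children = list(gn_leaf(l), gn_leaf(r))), species_tree = sp)
  expect_true(validate_semantics(mk("B", "C"), "strict")$valid)
  expect_true(validate_semantics(mk("C", "B"), "strict")$valid)
  expect_true("E_SPECIATION_CHILDREN" %in%
                validate_semantics(mk("C", "C"), "strict")$issues$code)
  expect_true("E_SPECIATION_CHILDREN" %in%
                validate_semantics(mk("A", "B"), "strict")$issues$code)
  # lenient mode does not police cross-node consistency
  expect_true(validate_semantics(mk("C", "C"), "lenient")$valid)
})

test_that("timeSlice monotonicity along root-to-leaf paths is a warning", {
  sp <- sp_ABC()
  mk <- function(ts_root, ts_leaf1) {
    rp_document(rp_gene_node(
      list(ev("speciation", species_location = "A", time_slice = ts_root)),
      children = list(
        rp_gene_node(list(ev("leaf", species_location = "B",
                             time_slice = ts_leaf1))),
        gn_leaf("C"))), species_tree = sp)
  }
  expect_true(validate_semantics(mk(0L, 2L), "strict")$valid)
  rep <- validate_semantics(mk(2L, 0L), "strict")
  expect_true(rep$valid)                       # warning, not error
  expect_true("W_TIMESLICE" %in% rep$issues$code)
  expect_true("W_TIMESLICE" %in%
                validate_semantics(mk(2L, 0L), "lenient")$issues$code)
})

test_that("documents without a species tree skip semantics with a warning", {
  d <- rp_document(gn_leaf("anything"))
  rep <- validate_semantics(d, "strict")
  expect_true(rep$valid)
  expect_identical(rep$issues$code, "W_NO_SPTREE")
})

test_that("single invalidating mutations flip a valid fixture to invalid", {
  doc <- read_recphylo(fixture("listing-speciation-loss.xml"))
  expect_true(validate_semantics(doc, "strict")$valid)

  # swap a child's species
  m1 <- doc
  m1$gene_trees[[1L]]$children[[1L]]$events[[1L]]$species_location <- "B"
  expect_false(validate_semantics(m1, "strict")$valid)

  # delete the terminal event
  m2 <- doc
  m2$gene_trees[[1L]]$children[[1L]]$events <- list()
  expect_false(validate_structure(m2)$valid)

  # retype the speciation as a duplication (children differ in species)
  m3 <- doc
  m3$gene_trees[[1L]]$events[[1L]] <- ev("duplication",
                                         species_location = "A")
  expect_false(validate_semantics(m3, "strict")$valid)
})

test_that("validator agrees with the brute-force oracle exhaustively", {
  # exhaustive: all 3-node gene trees, every event/species assignment with
  # at most one transferBack prefix per node, over every species-tree shape
  # with two leaves; plus the no-prefix assignments over three-leaf shapes
  run_exhaustive <- function(sp, with_tb) {
    topo <- all_topologies(c("g1", "g2"))[[1L]]
    S <- rp_species_names(sp)
    int_flags <- preorder_is_internal(topo)
    choices <- lapply(int_flags, function(int)
      assignment_choices(int, S, with_tb = with_tb))
    idx <- rep(1L, length(choices))
    n_checked <- 0L; n_mismatch <- 0L
    repeat {
      assignment <- mapply(function(ch, i) ch[[i]], choices, idx,
                           SIMPLIFY = FALSE)
      g <- build_assigned_tree(topo, assignment)
      doc <- rp_document(list(g), species_tree = sp, check = FALSE)
      n_checked <- n_checked + 1L
      if (impl_semantic_valid(doc) != oracle_semantic_valid(doc))
        n_mismatch <- n_mismatch + 1L
      k <- length(idx)
      while (k >= 1L) {
        idx[k] <- idx[k] + 1L
        if (idx[k] <= length(choices[[k]])) break
        idx[k] <- 1L
        k <- k - 1L
      }
      if (k < 1L) break
    }
    c(checked = n_checked, mismatch = n_mismatch)
  }
  sp2 <- rp_species_node("r", list(rp_species_node("X"),
                                   rp_species_node("Y")))
  r1 <- run_exhaustive(sp2, with_tb = TRUE)
  expect_gt(r1[["checked"]], 20000)
  expect_identical(r1[["mismatch"]], 0L)

  sp3 <- sp_ABC()
  sp3$children[[2L]] <- rp_species_node("C", list(rp_species_node("D"),
                                                  rp_species_node("E")))
  r2 <- run_exhaustive(sp3, with_tb = FALSE)
  expect_gt(r2[["checked"]], 1000)
  expect_identical(r2[["mismatch"]], 0L)
})

test_that("validator agrees with the oracle on sampled larger instances", {
  set.seed(101)
  sp4 <- as_named_species(random_topology(c("A", "B", "C", "D")))
  S <- rp_species_names(sp4)
  for (rep_i in 1:1500) {
    n_leaves <- sample(2:4, 1L)     # gene trees of 3, 5, 7 nodes
    topo <- random_topology(paste0("g", seq_len(n_leaves)))
    int_flags <- preorder_is_internal(topo)
    assignment <- lapply(int_flags, function(int) {
      ch <- assignment_choices(int, S, with_tb = TRUE,
                               extra_species = "Zmissing")
      ch[[sample.int(length(ch), 1L)]]
    })
    g <- build_assigned_tree(topo, assignment)
    doc <- rp_document(list(g), species_tree = sp4, check = FALSE)
    expect_identical(impl_semantic_valid(doc), oracle_semantic_valid(doc))
  }
})

test_that("reconciliation maps are total and use the unsampled sentinel", {
  doc <- read_recphylo(fixture("listing-leaf.xml"))
  m <- build_reconciliation_map(doc)
  expect_identical(m$species, "C")
  expect_identical(m$node_name, "gene_seq_1")

  bif <- read_recphylo(fixture("listing-bifurcationout.xml"))
  mb <- build_reconciliation_map(bif)
  expect_identical(nrow(mb), 5L)               # total over all gene nodes
  expect_true(rp_unsampled() %in% mb$species)

  bad <- rp_document(gn_leaf("Z"), species_tree = sp_ABC())
  expect_error(build_reconciliation_map(bad), "not in the species tree")
  expect_error(build_reconciliation_map(rp_document(gn_leaf("C"))),
               "species tree is required")
})

test_that("reports serialize to TSV and JSON", {
  doc <- rp_document(gn_leaf("Z"), species_tree = sp_ABC())
  rep <- validate_semantics(doc, "strict")
  tsv <- rp_report_tsv(rep)
  expect_match(tsv, "code\tseverity")
  expect_match(tsv, "E_SPECIES_UNKNOWN")
  js <- jsonlite::fromJSON(rp_report_json(rep))
  expect_false(js$valid)
  expect_identical(js$issues$code[[1L]], "E_SPECIES_UNKNOWN")
})
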