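test_that("zero-rate limit reproduces the species tree exactly", {
  params <- rp_sim_params(dup_rate = 0, transfer_rate = 0, loss_rate = 0,
                          n_families = 1, seed = 1)
  doc <- simulate_dataset("((A:1,B:1)AB:1,C:2)root;", params)
  cen <- rp_count_events(doc)$total
  expect_identical(cen[["speciation"]], 2)     # both internal species nodes
  expect_identical(cen[["leaf"]], 3)           # one gene per species leaf
  expect_identical(sum(cen), 5)                # nothing else
  leaves <- Filter(function(w) rp_terminal_event(w$node)$type == "leaf",
                   recphylo:::rp_walk(doc$gene_trees[[1L]]))
  expect_setequal(vapply(leaves, function(w)
    rp_terminal_event(w$node)$species_location, ""), c("A", "B", "C"))
})

test_that("transfer-free simulations contain no transfer tags", {
  doc <- simulate_dataset("((A:1,B:1)AB:1,C:2)root;",
                          rp_sim_params(dup_rate = 0.5, transfer_rate = 0,
                                        loss_rate = 0.3, n_families = 10,
                                        seed = 2))
  cen <- rp_count_events(doc)$total
  expect_identical(cen[["branchingOut"]], 0)
  expect_identical(cen[["transferBack"]], 0)
  expect_identical(cen[["bifurcationOut"]], 0)
})

test_that("same seed gives byte-identical documents", {
  p <- rp_sim_params(n_families = 4, seed = 33, transfer_rate = 0.4)
  x1 <- write_recphylo(simulate_dataset("((A:1,B:1)AB:1,C:2)r;", p))
  x2 <- write_recphylo(simulate_dataset("((A:1,B:1)AB:1,C:2)r;", p))
  expect_identical(x1, x2)
  x3 <- write_recphylo(simulate_dataset(
    "((A:1,B:1)AB:1,C:2)r;", rp_sim_params(n_families = 4, seed = 34,
                                           transfer_rate = 0.4)))
  expect_false(identical(x1, x3))
})

test_that("n_families controls the number of gene trees", {
  doc <- simulate_dataset("(A:1,B:1)r;",
                          rp_sim_params(n_families = 5, seed = 3))
  expect_length(doc$gene_trees, 5L)
})

test_that("simulated documents pass strict validation (closure property)", {
  set.seed(9)
  n_docs <- 300
  for (i in seq_len(n_docs)) {
    sp <- random_dated_species(sample(2:5, 1L))
    p <- rp_sim_params(dup_rate = stats::runif(1, 0, 0.6),
                       transfer_rate = stats::runif(1, 0, 0.6),
                       loss_rate = stats::runif(1, 0, 0.6),
                       unsampled_bifurcation_prob = stats::runif(1, 0, 0.5),
                       n_families = 1,
                       condition_on_survival = FALSE)
    doc <- rp_document(list(simulate_family(sp, p)), species_tree = sp)
    expect_true(validate_structure(doc)$valid)
    rep <- validate_semantics(doc, "strict")
    expect_true(rep$valid)
    # timeSlice annotations must never warn either
    expect_false("W_TIMESLICE" %in% rep$issues$code)
  }
})

test_that("every transferBack has a donor-side branching parent", {
  set.seed(13)
  doc <- simulate_dataset(random_dated_species(5),
                          rp_sim_params(transfer_rate = 0.8,
                                        unsampled_bifurcation_prob = 0.4,
                                        n_families = 30, seed = 77))
  cen <- rp_count_events(doc)$total
  expect_gt(cen[["transferBack"]], 0)          # transfers were exercised
  check <- function(node, parent_term) {
    if (node$events[[1L]]$type == "transferBack")
      expect_true(parent_term %in% c("branchingOut", "bifurcationOut"))
    for (ch in node$children)
      check(ch, rp_terminal_event(node)$type)
  }
  for (g in doc$gene_trees) check(g, NA_character_)
  # two-step bookkeeping: each branchingOut feeds one unsampled lineage and
  # each bifurcationOut turns one into two, all of which re-enter
  expect_identical(cen[["transferBack"]],
                   cen[["branchingOut"]] + cen[["bifurcationOut"]])
})

test_that("recipients are alive at the re-entry time", {
  set.seed(17)
  doc <- simulate_dataset("((A:1,B:1)AB:1,C:2)r;",
                          rp_sim_params(transfer_rate = 1.0,
                                        n_families = 20, seed = 5))
  # with timeSlices on, a reception in a species must not predate the
  # species' origin: slice of the transferBack <= slice of later events,
  # and the destination exists — already covered by strict validity — so
  # check directly against node times: transferBack into AB only in slices
  # where AB is alive (slice 0..1 for this dated tree)
  ok <- TRUE
  walk <- function(n) {
    for (e in n$events)
      if (e$type == "transferBack" && e$destination_species == "AB" &&
          !is.null(e$time_slice) && e$time_slice > 1L)
        ok <<- FALSE
    for (ch in n$children) walk(ch)
  }
  for (g in doc$gene_trees) walk(g)
  expect_true(ok)
})

test_that("pure-duplication growth matches the closed-form mean", {
  # single species branch of length T: a birth process with rate delta has
  # expected population e^(delta T) at the end
  set.seed(23)
  delta <- 1.0; T_len <- 1.0; n_rep <- 10000
  p <- rp_sim_params(dup_rate = delta, transfer_rate = 0, loss_rate = 0,
                     condition_on_survival = FALSE,
                     emit_time_slices = FALSE)
  counts <- vapply(seq_len(n_rep), function(i) {
    fam <- simulate_family("A:1;", p)
    rp_count_events(rp_document(list(fam)), check = FALSE)$total[["leaf"]]
  }, 0)
  expected <- exp(delta * T_len)
  se <- stats::sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("heavy loss without survival conditioning still validates", {
  # the root branch length acts as a stem, so whole-family loss is possible
  doc <- simulate_dataset("(A:1,B:1)r:1;",
                          rp_sim_params(loss_rate = 5, dup_rate = 0.1,
                                        transfer_rate = 0.1,
                                        n_families = 20, seed = 41,
                                        condition_on_survival = FALSE))
  expect_true(validate_structure(doc)$valid)
  expect_true(validate_semantics(doc, "strict")$valid)
  # at least one family should be a bare root loss under rate 5
  root_loss <- vapply(doc$gene_trees, function(g)
    rp_terminal_event(g)$type == "loss" && length(g$children) == 0L, NA)
  expect_true(any(root_loss))
})

test_that("survival conditioning guarantees extant leaves", {
  doc <- simulate_dataset("(A:1,B:1)r;",
                          rp_sim_params(loss_rate = 2, dup_rate = 0.2,
                                        transfer_rate = 0, n_families = 30,
                                        seed = 51,
                                        condition_on_survival = TRUE))
  cen <- rp_count_events(doc)
  expect_true(all(cen$per_tree["leaf", ] >= 1))
})

test_that("parameter validation rejects impossible settings", {
  expect_error(rp_sim_params(dup_rate = -1), "non-negative")
  expect_error(rp_sim_params(unsampled_bifurcation_prob = 2), "\\[0, 1\\]")
  expect_error(rp_sim_params(n_families = 0), "positive")
  expect_error(simulate_family("A:1;", rp_sim_params(transfer_rate = 1)),
               "at least two leaves")
  expect_error(simulate_family("(A:1,B:2)r;", rp_sim_params()),
               "ultrametric")
  expect_error(simulate_family("(A,B)r;", rp_sim_params()),
               "positive branch lengths")
})
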