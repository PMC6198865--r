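# Duplication-transfer-loss simulator along a dated (ultrametric) species
# tree. Its native output is the reconciliation document model, so every
# simulated family exercises the full event vocabulary and passes strict
# validation by construction; the test fixtures of the package are drawn
# from it.
#
# Model: a single gene lineage starts at the species root (plus optional
# stem given by the root branch length). Along each species branch,
# exponential waiting times with total rate dup + transfer + loss choose
# the next event. A transfer is donor-side `branchingOut`; the emigrant
# copy evolves in an undated unsampled compartment for an Exp(transfer
# rate) duration capped at the time remaining, may bifurcate there
# (`bifurcationOut`) with a fixed probability, and re-enters a uniformly
# chosen recipient branch alive at the re-entry time, excluding the branch
# it currently occupies, as `transferBack`. Species-tree nodes yield
# `speciation`; the present yields `leaf`.

#' Simulation parameters
#'
#' @param dup_rate,transfer_rate,loss_rate event rates per unit branch
#'   length (equivalently per unit time on an ultrametric tree); all
#'   non-negative.
#' @param unsampled_bifurcation_prob probability that a transferred lineage
#'   bifurcates in the unsampled compartment before re-entering.
#' @param n_families number of gene families in a dataset.
#' @param seed integer seed used by [simulate_dataset()]; `NULL` leaves the
#'   RNG state untouched.
#' @param condition_on_survival reject and redraw families with no
#'   surviving extant leaf.
#' @param emit_time_slices annotate every event with the integer rank of
#'   the species-tree time interval it falls in (0 = oldest).
#' @param max_unsampled_bifurcations nesting depth allowed for
#'   bifurcations inside the unsampled compartment.
#' @return a list of class `rp_sim_params`.
#' @export
rp_sim_params <- function(dup_rate = 0.1, transfer_rate = 0.1,
                          loss_rate = 0.1,
                          unsampled_bifurcation_prob = 0.1,
                          n_families = 1L, seed = NULL,
                          condition_on_survival = TRUE,
                          emit_time_slices = TRUE,
                          max_unsampled_bifurcations = 1L) {
  rates <- c(dup_rate, transfer_rate, loss_rate)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("rates must be finite and non-negative", call. = FALSE)
  if (unsampled_bifurcation_prob < 0 || unsampled_bifurcation_prob > 1)
    stop("unsampled_bifurcation_prob must lie in [0, 1]", call. = FALSE)
  if (n_families < 1L)
    stop("n_families must be a positive integer", call. = FALSE)
  structure(list(dup_rate = dup_rate, transfer_rate = transfer_rate,
                 loss_rate = loss_rate,
                 unsampled_bifurcation_prob = unsampled_bifurcation_prob,
                 n_families = as.integer(n_families), seed = seed,
                 condition_on_survival = isTRUE(condition_on_survival),
                 emit_time_slices = isTRUE(emit_time_slices),
                 max_unsampled_bifurcations =
                   as.integer(max_unsampled_bifurcations)),
            class = "rp_sim_params")
}

# node ages (time before present) and ultrametry check
.dated_tree <- function(species_tree, tol = 1e-9) {
  sp <- .as_species_tree(species_tree)
  rel <- .sp_relations(sp)
  age <- stats::setNames(rep(NA_real_, length(rel$names)), rel$names)
  bl <- stats::setNames(rep(NA_real_, length(rel$names)), rel$names)
  walk <- function(node) {
    bl[[node$name]] <<- node$branch_length %||% NA_real_
    if (!length(node$children)) { age[[node$name]] <<- 0; return(0) }
    a <- vapply(node$children, function(ch) {
      sub <- walk(ch)
      if (is.null(ch$branch_length) || ch$branch_length <= 0)
        stop("dated species trees require strictly positive branch lengths",
             call. = FALSE)
      sub + ch$branch_length
    }, 0)
    if (abs(a[1L] - a[2L]) > tol)
      stop("species tree is not ultrametric at node '", node$name,
           "' (child ages ", a[1L], " vs ", a[2L], ")", call. = FALSE)
    age[[node$name]] <<- mean(a)
    age[[node$name]]
  }
  walk(sp)
  root <- sp$name
  stem <- if (!is.na(bl[[root]]) && bl[[root]] > 0) bl[[root]] else 0
  start_age <- stats::setNames(
    ifelse(is.na(rel$parent), age[[root]] + stem, age[rel$parent]),
    rel$names)
  list(tree = sp, rel = rel, age = age, start_age = start_age,
       root = root, root_start = age[[root]] + stem)
}

# rank (0-based, oldest first) of the time interval containing t
.time_slice <- function(dt, t) {
  bounds <- sort(unique(c(dt$root_start, dt$age)), decreasing = TRUE)
  max(0L, sum(bounds > t + 1e-12) - 1L)
}

#' Simulate one gene family
#'
#' Runs the birth-death-transfer process once along the dated species tree
#' and returns the reconciled gene tree. Uses (and advances) the current
#' RNG state; seed management lives in [simulate_dataset()].
#'
#' @param species_tree a dated species tree: Newick string with branch
#'   lengths, `rp_plain_node`, or [rp_species_node]; binary, ultrametric.
#' @param params an [rp_sim_params()] object.
#' @return an [rp_gene_node] root.
#' @export
simulate_family <- function(species_tree, params = rp_sim_params()) {
  stopifnot(inherits(params, "rp_sim_params"))
  dt <- .dated_tree(species_tree)
  if (params$transfer_rate > 0 && length(dt$rel$leaves) < 2L)
    stop("transfers require a species tree with at least two leaves",
         call. = FALSE)
  attempts <- 0L
  repeat {
    attempts <- attempts + 1L
    st <- new.env(parent = emptyenv())
    st$leaf_count <- integer()
    st$n_leaves <- 0L
    fam <- .sim_branch(dt, params, st, dt$root, dt$root_start)
    if (!params$condition_on_survival || st$n_leaves > 0L) return(fam)
    if (attempts >= 10000L)
      stop("no surviving family in 10000 draws; lower the loss rate",
           call. = FALSE)
  }
}

.sim_ev <- function(dt, params, type, t, ...) {
  ts <- if (params$emit_time_slices) .time_slice(dt, t) else NULL
  rp_event(type, time_slice = ts, ...)
}

.sim_branch <- function(dt, params, st, sp, t) {
  # evolve one gene lineage in species branch `sp` from age t to the branch
  # end; returns an rp_gene_node
  total <- params$dup_rate + params$transfer_rate + params$loss_rate
  end <- dt$age[[sp]]
  repeat {
    wait <- if (total > 0) stats::rexp(1L, total) else Inf
    if (t - wait <= end + 1e-12) {
      t <- end
      kids <- dt$rel$children[[sp]]
      if (!length(kids)) {                       # present: extant leaf
        st$n_leaves <- st$n_leaves + 1L
        k <- (st$leaf_count[sp] %||% 0L)
        k <- if (is.na(k)) 1L else k + 1L
        st$leaf_count[sp] <- k
        gn <- paste0(sp, "_", k)
        return(rp_gene_node(
          list(.sim_ev(dt, params, "leaf", t, species_location = sp,
                       gene_name = gn)), name = gn))
      }
      children <- lapply(kids, function(ch)
        .sim_branch(dt, params, st, ch, t))
      return(rp_gene_node(
        list(.sim_ev(dt, params, "speciation", t, species_location = sp)),
        children = children))
    }
    t <- t - wait
    u <- stats::runif(1L) * total
    if (u < params$dup_rate) {
      children <- list(.sim_branch(dt, params, st, sp, t),
                       .sim_branch(dt, params, st, sp, t))
      return(rp_gene_node(
        list(.sim_ev(dt, params, "duplication", t, species_location = sp)),
        children = children))
    }
    if (u < params$dup_rate + params$loss_rate) {
      return(rp_gene_node(
        list(.sim_ev(dt, params, "loss", t, species_location = sp)),
        name = "LOST"))
    }
    # transfer: donor-side branchingOut; resident copy continues here
    emigrant <- .sim_unsampled(dt, params, st, donor = sp, t = t,
                               depth = 0L)
    resident <- .sim_branch(dt, params, st, sp, t)
    return(rp_gene_node(
      list(.sim_ev(dt, params, "branchingOut", t, species_location = sp)),
      children = list(resident, emigrant)))
  }
}

# branches alive at age t (start_age > t >= age), optionally excluding one
.alive_branches <- function(dt, t, exclude = NULL) {
  alive <- names(dt$age)[dt$start_age > t + 1e-12 & dt$age <= t + 1e-12]
  setdiff(alive, exclude)
}

.sim_unsampled <- function(dt, params, st, donor, t, depth) {
  # the emigrant copy drifts in the unsampled compartment, may bifurcate
  # there, and re-enters a sampled branch as transferBack
  stay <- stats::rexp(1L, params$transfer_rate)
  t_re <- max(t - stay, 0)
  if (depth < params$max_unsampled_bifurcations &&
      stats::runif(1L) < params$unsampled_bifurcation_prob) {
    children <- list(
      .sim_unsampled(dt, params, st, donor, t_re, depth + 1L),
      .sim_unsampled(dt, params, st, donor, t_re, depth + 1L))
    return(rp_gene_node(
      list(.sim_ev(dt, params, "bifurcationOut", t_re)),
      children = children))
  }
  cand <- .alive_branches(dt, t_re, exclude = donor)
  if (!length(cand)) {
    t_re <- 0
    cand <- .alive_branches(dt, t_re, exclude = donor)
  }
  recipient <- cand[[sample.int(length(cand), 1L)]]
  node <- .sim_branch(dt, params, st, recipient, t_re)
  node$events <- c(list(.sim_ev(dt, params, "transferBack", t_re,
                                destination_species = recipient)),
                   node$events)
  node
}

#' Simulate a multi-family reconciliation document
#'
#' Draws `n_families` independent gene families on the same species tree
#' and packages them with it. Fully reproducible: with `params$seed` set,
#' identical calls serialize to byte-identical recPhyloXML.
#'
#' @inheritParams simulate_family
#' @return an [rp_document].
#' @examples
#' doc <- simulate_dataset("((A:1,B:1):1,C:2)root;",
#'                         rp_sim_params(n_families = 2, seed = 1))
#' @export
simulate_dataset <- function(species_tree, params = rp_sim_params()) {
  stopifnot(inherits(params, "rp_sim_params"))
  dt <- .dated_tree(species_tree)
  if (!is.null(params$seed)) set.seed(params$seed)
  fams <- lapply(seq_len(params$n_families), function(i)
    simulate_family(dt$tree, params))
  rp_document(fams, species_tree = dt$tree)
}
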