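# shared builders for tests: tiny trees, fixtures, random topologies

ev <- rp_event  # shorthand

gn_leaf <- function(sp, name = paste0(sp, "_x")) {
  rp_gene_node(list(ev("leaf", species_location = sp)), name = name)
}

fixture <- function(name) {
  system.file("extdata", name, package = "recphylo")
}

fixture_files <- function() {
  list.files(system.file("extdata", package = "recphylo"),
             pattern = "\\.xml$", full.names = TRUE)
}

# species tree ((B,C)A) used by most printed examples
sp_ABC <- function() {
  rp_species_node("A", list(rp_species_node("B"), rp_species_node("C")))
}

# all rooted binary topologies over the given (ordered) leaf names,
# as rp_plain_node trees
all_topologies <- function(leaves) {
  if (length(leaves) == 1L)
    return(list(structure(list(name = leaves, branch_length = NULL,
                               support = NULL, nhx = list(),
                               children = list()),
                          class = "rp_plain_node")))
  out <- list()
  n <- length(leaves)
  # splits: first leaf always in the left block to avoid mirror duplicates
  for (mask in 0:(2^(n - 1) - 1)) {
    left_sel <- c(TRUE, as.logical(bitwAnd(mask, 2^(0:(n - 2)))))
    if (all(left_sel)) next
    left <- leaves[left_sel]
    right <- leaves[!left_sel]
    for (L in all_topologies(left))
      for (R in all_topologies(right))
        out[[length(out) + 1L]] <- structure(
          list(name = "", branch_length = NULL, support = NULL,
               nhx = list(), children = list(L, R)),
          class = "rp_plain_node")
  }
  out
}

# random rooted binary topology over the given leaves (uses current RNG)
random_topology <- function(leaves) {
  nodes <- lapply(leaves, function(l) structure(
    list(name = l, branch_length = NULL, support = NULL, nhx = list(),
         children = list()), class = "rp_plain_node"))
  while (length(nodes) > 1L) {
    i <- sample.int(length(nodes), 2L)
    joined <- structure(
      list(name = "", branch_length = NULL, support = NULL, nhx = list(),
           children = nodes[i]), class = "rp_plain_node")
    nodes <- c(nodes[-i], list(joined))
  }
  nodes[[1L]]
}

# name the clades of a plain topology and convert to a species tree
as_named_species <- function(topo, prefix = "s") {
  k <- 0L
  rec <- function(n) {
    if (!length(n$children)) return(rp_species_node(n$name))
    k <<- k + 1L
    rp_species_node(paste0(prefix, k), children = lapply(n$children, rec))
  }
  rec(topo)
}

# ultrametric random species tree over n leaves (named A, B, ...) for the
# simulator; total depth fixed to `depth`
random_dated_species <- function(n, depth = 2) {
  topo <- random_topology(LETTERS[seq_len(n)])
  k <- 0L
  build <- function(node, age) {
    if (!length(node$children)) {
      return(rp_species_node(node$name, branch_length = age))
    }
    k <<- k + 1L
    child_age <- stats::runif(1L, 0.1 * age, 0.9 * age)
    rp_species_node(paste0("anc", k),
                    children = lapply(node$children, build,
                                      age = child_age),
                    branch_length = age - child_age)
  }
  root <- build(topo, depth)
  root$branch_length <- NULL
  root
}
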