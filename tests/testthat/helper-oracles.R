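# Independent oracles, deliberately implemented with different strategies
# than the package code they check (enumeration instead of direct rules).

# ---------------------------------------------------------------------------
# Brute-force duplication-loss cost: minimize over ALL species assignments
# of the internal gene nodes that respect ancestry, deriving events and
# losses from the assignment.  Independent of the LCA mapping shortcut.

sp_info <- function(sp_root) {
  parent <- character(); depth <- integer(); children <- list()
  rec <- function(node, par, d) {
    parent[[node$name]] <<- par
    depth[[node$name]] <<- d
    children[[node$name]] <<- vapply(node$children, `[[`, "", "name")
    for (ch in node$children) rec(ch, node$name, d + 1L)
  }
  rec(sp_root, NA_character_, 0L)
  anc <- lapply(names(parent), function(n) {
    path <- n
    while (!is.na(parent[[path[1L]]])) path <- c(parent[[path[1L]]], path)
    path
  })
  names(anc) <- names(parent)
  list(parent = parent, depth = depth, children = children,
       ancestors = anc, names = names(parent))
}

is_anc_or_self <- function(info, a, b) a %in% info$ancestors[[b]]

# which child subtree of `a` contains `b` (NA if b == a or not below)
child_branch_of <- function(info, a, b) {
  if (a == b) return(NA_character_)
  path <- info$ancestors[[b]]
  i <- match(a, path)
  if (is.na(i) || i == length(path)) return(NA_character_)
  path[i + 1L]
}

oracle_dl_cost <- function(gene_plain, sp_root, mapping) {
  info <- sp_info(sp_root)
  # collect postorder internal nodes and leaves
  nodes <- list(); parent_of <- integer(); leaf_sp <- character()
  collect <- function(n) {
    ids <- integer()
    for (ch in n$children) ids <- c(ids, collect(ch))
    nodes[[length(nodes) + 1L]] <<- list(node = n, children = ids)
    length(nodes)
  }
  collect(gene_plain)
  n_nodes <- length(nodes)
  is_leaf <- vapply(nodes, function(x) length(x$children) == 0L, NA)
  fixed <- rep(NA_character_, n_nodes)
  for (i in which(is_leaf))
    fixed[i] <- unname(mapping[[nodes[[i]]$node$name]])
  internal <- which(!is_leaf)
  if (!length(internal)) return(0L)

  best <- Inf
  assign_next <- function(k, M) {
    if (k > length(internal)) {
      cost <- 0L
      for (i in internal) {
        ch <- nodes[[i]]$children
        m <- M[i]; m1 <- M[ch[1L]]; m2 <- M[ch[2L]]
        b1 <- child_branch_of(info, m, m1)
        b2 <- child_branch_of(info, m, m2)
        spec <- !is.na(b1) && !is.na(b2) && b1 != b2
        if (!spec) cost <- cost + 1L            # duplication
        for (mc in c(m1, m2))
          cost <- cost + (info$depth[[mc]] - info$depth[[m]]) -
            (if (spec) 1L else 0L)
      }
      best <<- min(best, cost)
      return(invisible(NULL))
    }
    i <- internal[k]
    ch <- nodes[[i]]$children
    for (s in info$names) {
      ok <- all(vapply(ch, function(c2)
        is_anc_or_self(info, s, M[c2]), NA))
      if (!ok) next
      M[i] <- s
      assign_next(k + 1L, M)
    }
  }
  assign_next(1L, fixed)
  best
}

impl_dl_cost <- function(doc) {
  cen <- rp_count_events(doc)$total
  unname(cen[["duplication"]] + cen[["loss"]])
}

# ---------------------------------------------------------------------------
# Independent semantic consistency checker.  For every internal gene node it
# ENUMERATES the legal (first-event, start-species) descriptor pairs of the
# two children given the node's terminal event and the species tree, then
# tests membership; transfer-orphan and self-transfer legality is checked by
# walking annotated paths.  Returns TRUE iff no error-level rule is broken.

oracle_semantic_valid <- function(doc) {
  if (is.null(doc$species_tree)) return(TRUE)
  info <- sp_info(doc$species_tree)
  S <- info$names
  ok <- TRUE

  descr <- function(node) {
    first <- node$events[[1L]]$type
    start <- rp_start_species(node)
    term <- rp_terminal_event(node)$type
    list(first = first, start = start, term = term)
  }

  legal_pairs <- function(term_type, s) {
    # enumerate all (descriptor1, descriptor2) the rules admit, as strings
    d_res <- paste0("resident:", s)                  # starts in s, no tb
    d_tb  <- paste0("tb:", S)                        # starts with transferBack
    d_bif <- "bifout"                                # stays unsampled
    if (term_type == "speciation") {
      kids <- info$children[[s]]
      if (length(kids) != 2L) return(character())
      c(paste(paste0("resident:", kids[1L]), paste0("resident:", kids[2L])),
        paste(paste0("resident:", kids[2L]), paste0("resident:", kids[1L])))
    } else if (term_type == "duplication") {
      paste(d_res, d_res)
    } else if (term_type == "branchingOut") {
      emi <- c(d_tb, d_bif)
      c(paste(d_res, emi), paste(emi, d_res))
    } else if (term_type == "bifurcationOut") {
      emi <- c(d_tb, d_bif)
      as.vector(outer(emi, emi, paste))
    } else character()
  }

  node_descr_string <- function(node) {
    d <- descr(node)
    if (d$first == "transferBack") paste0("tb:", d$start)
    else if (d$term == "bifurcationOut" && d$first == "bifurcationOut")
      "bifout"
    else paste0("resident:", d$start)
  }

  check <- function(node, parent_term, parent_loc) {
    for (e in node$events) {
      for (ref in c(e$species_location, e$destination_species))
        if (!is.null(ref) && !ref %in% S) ok <<- FALSE
    }
    first <- node$events[[1L]]$type
    if (first == "transferBack" && !is.null(parent_term) &&
        !parent_term %in% c("branchingOut", "bifurcationOut"))
      ok <<- FALSE
    # self transfer: chain of destinations, seeded by a branchingOut donor
    types <- vapply(node$events, `[[`, "", "type")
    dests <- vapply(node$events[types == "transferBack"], `[[`, "",
                    "destination_species")
    cur <- if (identical(parent_term, "branchingOut") &&
               first == "transferBack") parent_loc else NULL
    for (d in dests) {
      if (!is.null(cur) && identical(d, cur)) ok <<- FALSE
      cur <- d
    }
    term <- rp_terminal_event(node)
    if (length(node$children) == 2L && term$type != "leaf") {
      pair <- paste(node_descr_string(node$children[[1L]]),
                    node_descr_string(node$children[[2L]]))
      if (!pair %in% legal_pairs(term$type, term$species_location %||% ""))
        ok <<- FALSE
    }
    for (ch in node$children)
      check(ch, term$type, term$species_location)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  for (g in doc$gene_trees) check(g, NULL, NULL)
  ok
}

impl_semantic_valid <- function(doc) {
  validate_semantics(doc, "strict")$valid
}

# ---------------------------------------------------------------------------
# Enumerator / sampler of structurally valid event assignments over a gene
# topology: every internal node gets a bifurcating terminal, every leaf
# position a lineage-ending one, each optionally prefixed by one
# transferBack.  Used to compare the semantic validator with the oracle.

assignment_choices <- function(internal, species, with_tb = TRUE,
                               extra_species = character()) {
  S <- c(species, extra_species)
  terms <- list()
  if (internal) {
    for (s in S) for (t in c("speciation", "duplication", "branchingOut"))
      terms[[length(terms) + 1L]] <- list(type = t, loc = s)
    terms[[length(terms) + 1L]] <- list(type = "bifurcationOut", loc = NULL)
  } else {
    for (s in S) for (t in c("leaf", "loss"))
      terms[[length(terms) + 1L]] <- list(type = t, loc = s)
  }
  prefixes <- list(NULL)
  if (with_tb) for (s in S)
    prefixes[[length(prefixes) + 1L]] <- s
  out <- list()
  for (p in prefixes) for (t in terms)
    out[[length(out) + 1L]] <- list(tb = p, term = t)
  out
}

build_assigned_tree <- function(topo, assignment) {
  # assignment: list indexed in preorder of topo nodes
  i <- 0L
  rec <- function(n) {
    i <<- i + 1L
    a <- assignment[[i]]
    events <- list()
    if (!is.null(a$tb))
      events[[1L]] <- rp_event("transferBack", destination_species = a$tb)
    events[[length(events) + 1L]] <-
      if (is.null(a$term$loc)) rp_event(a$term$type)
      else rp_event(a$term$type, species_location = a$term$loc)
    rp_gene_node(events, children = lapply(n$children, rec),
                 name = n$name, check = FALSE)
  }
  rec(topo)
}

preorder_count <- function(topo) {
  1L + sum(vapply(topo$children, preorder_count, 0L))
}

preorder_is_internal <- function(topo) {
  out <- logical()
  rec <- function(n) {
    out[[length(out) + 1L]] <<- length(n$children) > 0L
    for (ch in n$children) rec(ch)
  }
  rec(topo)
  out
}
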