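#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Event grammar -------------------------------------------------------------

#' Event-type vocabulary
#'
#' The seven evolutionary event tags a reconciled gene-tree clade may carry.
#' `transferBack` is the only *non-terminal* event (it marks a lineage
#' re-entering the species tree and may be repeated); every event sequence
#' ends in exactly one *terminal* event. Terminal events are either
#' *bifurcating* (the clade has two children) or *lineage-ending* (no
#' children).
#'
#' @return `rp_event_types()` returns the character vector of all seven
#'   event-type names.
#' @export
rp_event_types <- function() {
  c("leaf", "speciation", "loss", "duplication",
    "branchingOut", "transferBack", "bifurcationOut")
}

.RP_TERMINAL    <- c("leaf", "speciation", "loss", "duplication",
                     "branchingOut", "bifurcationOut")
.RP_BIFURCATING <- c("speciation", "duplication", "branchingOut",
                     "bifurcationOut")
.RP_ENDING      <- c("leaf", "loss")
# event types with an obligatory speciesLocation attribute
.RP_LOCATED     <- c("leaf", "speciation", "loss", "duplication",
                     "branchingOut")

#' @rdname rp_event_types
#' @param type event-type name.
#' @export
rp_is_terminal <- function(type) type %in% .RP_TERMINAL

#' Sentinel species identifier for unsampled/extinct lineages
#'
#' Gene nodes whose terminal event is `bifurcationOut` evolve in a lineage
#' absent from the species tree; the reconciliation map assigns them this
#' sentinel. It starts with `"@"` so it can never collide with an XML name
#' used as a species identifier.
#'
#' @return a length-one character string.
#' @export
rp_unsampled <- function() "@UNSAMPLED@"

#' Construct an evolutionary event
#'
#' Builds one event of a clade's event sequence, enforcing the attribute
#' rules of the grammar: `species_location` is obligatory for located events
#' (`leaf`, `speciation`, `loss`, `duplication`, `branchingOut`) and
#' forbidden on `transferBack` and `bifurcationOut`; `destination_species`
#' is obligatory on `transferBack` and forbidden elsewhere; `gene_name` is
#' allowed only on `leaf`; `time_slice` must be a non-negative integer.
#' `confidence` is stored unconstrained (range checks are a validator
#' warning, not a model error).
#'
#' @param type one of [rp_event_types()].
#' @param species_location species name where the event takes place.
#' @param destination_species recipient species of a `transferBack`.
#' @param confidence optional numeric support value.
#' @param time_slice optional non-negative integer time slice.
#' @param gene_name optional extant-gene identifier (leaf events only).
#' @return an object of class `rp_event`.
#' @examples
#' rp_event("leaf", species_location = "C")
#' rp_event("transferBack", destination_species = "B")
#' @export
rp_event <- function(type, species_location = NULL, destination_species = NULL,
                     confidence = NULL, time_slice = NULL, gene_name = NULL) {
  if (length(type) != 1L || !type %in% rp_event_types())
    stop("unknown event type: ", paste(type, collapse = "/"), call. = FALSE)
  if (type %in% .RP_LOCATED) {
    if (is.null(species_location))
      stop("event '", type, "' requires a speciesLocation", call. = FALSE)
  } else if (!is.null(species_location)) {
    stop("event '", type, "' must not carry a speciesLocation", call. = FALSE)
  }
  if (type == "transferBack") {
    if (is.null(destination_species))
      stop("transferBack requires a destinationSpecies", call. = FALSE)
  } else if (!is.null(destination_species)) {
    stop("event '", type, "' must not carry a destinationSpecies",
         call. = FALSE)
  }
  if (!is.null(gene_name) && type != "leaf")
    stop("geneName is only allowed on leaf events", call. = FALSE)
  if (!is.null(time_slice)) {
    if (length(time_slice) != 1L || is.na(time_slice) ||
        time_slice < 0 || time_slice != floor(time_slice))
      stop("timeSlice must be a single non-negative integer", call. = FALSE)
    time_slice <- as.integer(time_slice)
  }
  if (!is.null(confidence)) confidence <- as.numeric(confidence)
  structure(
    list(type = type,
         species_location = species_location,
         destination_species = destination_species,
         confidence = confidence,
         time_slice = time_slice,
         gene_name = gene_name),
    class = "rp_event")
}

#' @export
print.rp_event <- function(x, ...) {
  loc <- if (!is.null(x$species_location)) paste0(" @", x$species_location)
         else if (!is.null(x$destination_species))
           paste0(" ->", x$destination_species)
         else ""
  cat("<", x$type, loc, ">\n", sep = "")
  invisible(x)
}

#' Arity of a terminal event
#'
#' Bifurcating events (`speciation`, `duplication`, `branchingOut`,
#' `bifurcationOut`) have arity 2; lineage-ending events (`leaf`, `loss`)
#' have arity 0. `transferBack` is non-terminal and has no arity.
#'
#' @param event an [rp_event].
#' @return integer 0 or 2.
#' @export
rp_arity <- function(event) {
  stopifnot(inherits(event, "rp_event"))
  if (!rp_is_terminal(event$type))
    stop("non-terminal event '", event$type, "' has no arity", call. = FALSE)
  if (event$type %in% .RP_BIFURCATING) 2L else 0L
}

#' Terminal event of a gene node
#'
#' The unique last event of the node's event sequence.
#'
#' @param node an [rp_gene_node].
#' @return an [rp_event].
#' @export
rp_terminal_event <- function(node) {
  stopifnot(inherits(node, "rp_gene_node"))
  node$events[[length(node$events)]]
}

.check_event_sequence <- function(events) {
  if (!is.list(events) || length(events) == 0L)
    stop("event sequence must be a non-empty list of events", call. = FALSE)
  for (e in events)
    if (!inherits(e, "rp_event"))
      stop("event sequence elements must be rp_event objects", call. = FALSE)
  n <- length(events)
  types <- vapply(events, `[[`, "", "type")
  if (!rp_is_terminal(types[n]))
    stop("event sequence must end with a terminal event, not '",
         types[n], "'", call. = FALSE)
  if (n > 1L && any(types[-n] != "transferBack"))
    stop("only transferBack events may precede the terminal event",
         call. = FALSE)
  invisible(events)
}

# ---------------------------------------------------------------------------
# Geography -----------------------------------------------------------------

#' Geographic annotation of a clade
#'
#' An area with optional description, support value, source (for instance
#' `"observed"` or an inference method) and an opaque KML payload carried
#' verbatim for GIS consumers.
#'
#' @param area_name name of the area.
#' @param description,value,source optional metadata.
#' @param kml_payload optional raw inner XML, preserved byte-verbatim.
#' @return an object of class `rp_geography`.
#' @export
rp_geography <- function(area_name, description = NULL, value = NULL,
                         source = NULL, kml_payload = NULL) {
  stopifnot(is.character(area_name), length(area_name) == 1L)
  structure(
    list(area_name = area_name, description = description,
         value = if (is.null(value)) NULL else as.numeric(value),
         source = source, kml_payload = kml_payload),
    class = "rp_geography")
}

# ---------------------------------------------------------------------------
# Tree nodes ----------------------------------------------------------------

#' Construct a reconciled gene-tree clade
#'
#' A gene node carries its event sequence (ending in one terminal event) and
#' either two children (bifurcating terminal) or none (lineage-ending
#' terminal). Child order is preserved as given but carries no semantic
#' meaning. Names may be empty and need not be unique.
#'
#' @param events list of [rp_event] objects (the `<eventsRec>` content).
#' @param children list of 0 or 2 `rp_gene_node` children.
#' @param name clade name (may be `""`).
#' @param branch_length optional non-negative branch length.
#' @param support optional numeric support value of the clade.
#' @param geography optional list of [rp_geography] annotations.
#' @param extra_xml character vector of opaque pass-through XML fragments
#'   (unknown clade children kept in lenient parsing).
#' @param check validate invariants (set `FALSE` only to build deliberately
#'   malformed nodes for the structural validator).
#' @return an object of class `rp_gene_node`.
#' @examples
#' leafC <- rp_gene_node(list(rp_event("leaf", "C")), name = "gene_seq_1")
#' @export
rp_gene_node <- function(events, children = list(), name = "",
                         branch_length = NULL, support = NULL,
                         geography = list(), extra_xml = character(),
                         check = TRUE) {
  if (inherits(events, "rp_event")) events <- list(events)
  node <- structure(
    list(name = as.character(name)[1L],
         branch_length = if (is.null(branch_length)) NULL
                         else as.numeric(branch_length),
         support = if (is.null(support)) NULL else as.numeric(support),
         events = events,
         geography = geography,
         extra_xml = extra_xml,
         children = children),
    class = "rp_gene_node")
  if (check) {
    .check_event_sequence(events)
    if (!is.null(branch_length) && branch_length < 0)
      stop("branch length must be non-negative", call. = FALSE)
    arity <- rp_arity(rp_terminal_event(node))
    if (length(children) != arity)
      stop("terminal event '", rp_terminal_event(node)$type, "' requires ",
           arity, " children, got ", length(children), call. = FALSE)
    for (ch in children)
      if (!inherits(ch, "rp_gene_node"))
        stop("children must be rp_gene_node objects", call. = FALSE)
  }
  node
}

#' Construct a species-tree clade
#'
#' Species nodes are binary (0 or 2 children); names must be unique within
#' one species tree so that `speciesLocation` references resolve (uniqueness
#' is checked at document construction and by the validator).
#'
#' @param name species name.
#' @param children list of 0 or 2 `rp_species_node` children.
#' @param branch_length optional non-negative branch length.
#' @param geography optional list of [rp_geography] annotations.
#' @param extra_xml opaque pass-through XML fragments.
#' @param check validate invariants.
#' @return an object of class `rp_species_node`.
#' @export
rp_species_node <- function(name, children = list(), branch_length = NULL,
                            geography = list(), extra_xml = character(),
                            check = TRUE) {
  node <- structure(
    list(name = as.character(name)[1L],
         branch_length = if (is.null(branch_length)) NULL
                         else as.numeric(branch_length),
         geography = geography,
         extra_xml = extra_xml,
         children = children),
    class = "rp_species_node")
  if (check) {
    if (!length(children) %in% c(0L, 2L))
      stop("species clades must have 0 or 2 children", call. = FALSE)
    for (ch in children)
      if (!inherits(ch, "rp_species_node"))
        stop("children must be rp_species_node objects", call. = FALSE)
    if (!is.null(branch_length) && branch_length < 0)
      stop("branch length must be non-negative", call. = FALSE)
  }
  node
}

#' Construct a reconciliation document
#'
#' The `<recPhylo>` unit: at most one species tree and one or more rooted
#' reconciled gene trees.
#'
#' @param gene_trees list of [rp_gene_node] roots (length >= 1); a single
#'   node is accepted and wrapped.
#' @param species_tree optional [rp_species_node] root.
#' @param check validate invariants.
#' @return an object of class `rp_document`.
#' @export
rp_document <- function(gene_trees, species_tree = NULL, check = TRUE) {
  if (inherits(gene_trees, "rp_gene_node")) gene_trees <- list(gene_trees)
  doc <- structure(
    list(species_tree = species_tree, gene_trees = gene_trees),
    class = "rp_document")
  if (check) {
    if (length(gene_trees) < 1L)
      stop("a document requires at least one gene tree", call. = FALSE)
    for (g in gene_trees)
      if (!inherits(g, "rp_gene_node"))
        stop("gene trees must be rp_gene_node objects", call. = FALSE)
    if (!is.null(species_tree)) {
      if (!inherits(species_tree, "rp_species_node"))
        stop("species_tree must be an rp_species_node", call. = FALSE)
      nm <- rp_species_names(species_tree)
      dup <- nm[duplicated(nm)]
      if (length(dup))
        stop("duplicated species names: ", paste(unique(dup), collapse = ", "),
             call. = FALSE)
    }
  }
  doc
}

#' @export
print.rp_document <- function(x, ...) {
  cat("<recPhylo> document\n")
  cat("  species tree: ",
      if (is.null(x$species_tree)) "none"
      else paste0(length(rp_species_names(x$species_tree)), " clades"),
      "\n", sep = "")
  cat("  gene trees:   ", length(x$gene_trees), "\n", sep = "")
  cns <- rp_count_events(x, check = FALSE)$total
  cns <- cns[cns > 0]
  if (length(cns))
    cat("  events:       ",
        paste(names(cns), cns, sep = ":", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
print.rp_gene_node <- function(x, ...) {
  rec <- function(n, depth) {
    ev <- paste(vapply(n$events, function(e) {
      loc <- e$species_location %||% e$destination_species
      if (is.null(loc)) e$type else paste0(e$type, "(", loc, ")")
    }, ""), collapse = ", ")
    cat(strrep("  ", depth),
        if (nzchar(n$name)) n$name else "<unnamed>", " [", ev, "]\n", sep = "")
    for (ch in n$children) rec(ch, depth + 1L)
  }
  rec(x, 0L)
  invisible(x)
}

#' @export
print.rp_species_node <- function(x, ...) {
  rec <- function(n, depth) {
    cat(strrep("  ", depth), if (nzchar(n$name)) n$name else "<unnamed>",
        "\n", sep = "")
    for (ch in n$children) rec(ch, depth + 1L)
  }
  rec(x, 0L)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Traversal helpers ---------------------------------------------------------

#' All names in a species tree, preorder
#' @param node an [rp_species_node].
#' @return character vector.
#' @export
rp_species_names <- function(node) {
  out <- node$name
  for (ch in node$children) out <- c(out, rp_species_names(ch))
  out
}

# preorder list of (node, path) pairs for a gene or species tree;
# path is a dot-separated child-index string, "" for the root
rp_walk <- function(node, path = "") {
  out <- list(list(node = node, path = path))
  if (length(node$children))
    for (i in seq_along(node$children)) {
      sub <- if (nzchar(path)) paste0(path, ".", i) else as.character(i)
      out <- c(out, rp_walk(node$children[[i]], sub))
    }
  out
}

#' Starting species of a gene branch
#'
#' The species in which a gene lineage begins: the destination of the first
#' `transferBack` if the sequence starts with one, else the
#' `speciesLocation` of the terminal event, or the unsampled sentinel for a
#' `bifurcationOut`.
#'
#' @param node an [rp_gene_node].
#' @return species name string.
#' @export
rp_start_species <- function(node) {
  e1 <- node$events[[1L]]
  if (e1$type == "transferBack") return(e1$destination_species)
  if (e1$type == "bifurcationOut") return(rp_unsampled())
  e1$species_location
}

# ---------------------------------------------------------------------------
# Structural equality -------------------------------------------------------

.eq_opt <- function(a, b, tol = 1e-9) {
  if (is.null(a) && is.null(b)) return(TRUE)
  if (is.null(a) || is.null(b)) return(FALSE)
  if (is.numeric(a)) return(is.numeric(b) && abs(a - b) <= tol)
  identical(a, b)
}

.eq_event <- function(a, b) {
  a$type == b$type &&
    .eq_opt(a$species_location, b$species_location) &&
    .eq_opt(a$destination_species, b$destination_species) &&
    .eq_opt(a$confidence, b$confidence) &&
    .eq_opt(a$time_slice, b$time_slice) &&
    .eq_opt(a$gene_name, b$gene_name)
}

.eq_geo <- function(a, b) {
  identical(a$area_name, b$area_name) &&
    .eq_opt(a$description, b$description) &&
    .eq_opt(a$value, b$value) &&
    .eq_opt(a$source, b$source) &&
    .eq_opt(a$kml_payload, b$kml_payload)
}

.eq_geos <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!length(a)) return(TRUE)
  all(mapply(.eq_geo, a, b))
}

#' Structural equality of model objects
#'
#' Compares two gene nodes, species nodes or documents field by field,
#' treating sibling order as semantically unordered (both orderings of the
#' children are tried) and numeric fields up to a small tolerance.
#'
#' @param a,b objects of the same model class.
#' @return logical.
#' @export
rp_equal <- function(a, b) {
  if (inherits(a, "rp_document")) {
    if (!inherits(b, "rp_document")) return(FALSE)
    if (is.null(a$species_tree) != is.null(b$species_tree)) return(FALSE)
    if (!is.null(a$species_tree) &&
        !rp_equal(a$species_tree, b$species_tree)) return(FALSE)
    if (length(a$gene_trees) != length(b$gene_trees)) return(FALSE)
    for (i in seq_along(a$gene_trees))
      if (!rp_equal(a$gene_trees[[i]], b$gene_trees[[i]])) return(FALSE)
    return(TRUE)
  }
  if (inherits(a, "rp_gene_node")) {
    if (!inherits(b, "rp_gene_node")) return(FALSE)
    if (!identical(a$name, b$name)) return(FALSE)
    if (!.eq_opt(a$branch_length, b$branch_length)) return(FALSE)
    if (!.eq_opt(a$support, b$support)) return(FALSE)
    if (length(a$events) != length(b$events)) return(FALSE)
    for (i in seq_along(a$events))
      if (!.eq_event(a$events[[i]], b$events[[i]])) return(FALSE)
    if (!.eq_geos(a$geography, b$geography)) return(FALSE)
    return(.eq_children(a$children, b$children))
  }
  if (inherits(a, "rp_species_node")) {
    if (!inherits(b, "rp_species_node")) return(FALSE)
    if (!identical(a$name, b$name)) return(FALSE)
    if (!.eq_opt(a$branch_length, b$branch_length)) return(FALSE)
    if (!.eq_geos(a$geography, b$geography)) return(FALSE)
    return(.eq_children(a$children, b$children))
  }
  stop("rp_equal: unsupported classes", call. = FALSE)
}

.eq_children <- function(ca, cb) {
  if (length(ca) != length(cb)) return(FALSE)
  if (length(ca) == 0L) return(TRUE)
  (rp_equal(ca[[1L]], cb[[1L]]) && rp_equal(ca[[2L]], cb[[2L]])) ||
    (rp_equal(ca[[1L]], cb[[2L]]) && rp_equal(ca[[2L]], cb[[1L]]))
}
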