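# Interchange utilities: recPhyloXML <-> Newick/NHX, event censuses,
# document combination and extraction.
#
# The NHX key vocabulary is this library's own documented dialect:
#   Ev  semicolon-separated event-type names, in sequence order
#   S   speciesLocation of the terminal event (absent for bifurcationOut)
#   D   transferBack destination species, comma-separated, in order
#   T   timeSlice per event, comma-separated, empty where absent
#   C   confidence per event, comma-separated, empty where absent
#   G   geneName of a leaf event
#   B   clade support value
# Values are percent-encoded so names containing NHX metacharacters
# round-trip.

.nhx_encode <- function(x) {
  for (p in c("%", ":", "=", "[", "]", ",", ";", "(", ")"))
    x <- gsub(p, sprintf("%%%02X", utf8ToInt(p)), x, fixed = TRUE)
  x
}

.nhx_decode <- function(x) {
  m <- gregexpr("%[0-9A-Fa-f]{2}", x)
  regmatches(x, m) <- lapply(regmatches(x, m), function(hits)
    vapply(hits, function(h)
      intToUtf8(strtoi(substr(h, 2L, 3L), 16L)), ""))
  x
}

#' Convert a reconciled gene tree to Newick or NHX
#'
#' `plain` mode keeps only topology, names and branch lengths; `nhx` mode
#' additionally encodes each node's full event sequence in an NHX comment
#' (see the package's format notes for the key vocabulary). Labels
#' containing Newick-forbidden characters are single-quoted.
#'
#' @param tree an [rp_gene_node] root.
#' @param mode `"plain"` or `"nhx"`.
#' @return a single Newick/NHX string terminated by `";"`.
#' @examples
#' leafC <- rp_gene_node(list(rp_event("leaf", "C")), name = "gene_seq_1")
#' to_newick(leafC)
#' to_newick(leafC, mode = "nhx")
#' @export
to_newick <- function(tree, mode = c("plain", "nhx")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "rp_gene_node"))
  paste0(.nwk_node(tree, mode), ";")
}

.nwk_node <- function(node, mode) {
  inner <- if (length(node$children))
    paste0("(", paste(vapply(node$children, .nwk_node, "", mode = mode),
                      collapse = ","), ")") else ""
  lab <- if (nzchar(node$name)) newick_quote(node$name) else ""
  bl <- if (!is.null(node$branch_length))
    paste0(":", .fmt_num(node$branch_length)) else ""
  com <- if (mode == "nhx") .nhx_comment(node) else ""
  paste0(inner, lab, bl, com)
}

.nhx_comment <- function(node) {
  ev <- node$events
  types <- vapply(ev, `[[`, "", "type")
  kv <- c(Ev = paste(types, collapse = ";"))
  term <- ev[[length(ev)]]
  if (!is.null(term$species_location))
    kv["S"] <- .nhx_encode(term$species_location)
  dests <- vapply(ev[types == "transferBack"], `[[`, "",
                  "destination_species")
  if (length(dests)) kv["D"] <- paste(.nhx_encode(dests), collapse = ",")
  slices <- vapply(ev, function(e)
    if (is.null(e$time_slice)) "" else as.character(e$time_slice), "")
  if (any(nzchar(slices))) kv["T"] <- paste(slices, collapse = ",")
  confs <- vapply(ev, function(e)
    if (is.null(e$confidence)) "" else .fmt_num(e$confidence), "")
  if (any(nzchar(confs))) kv["C"] <- paste(confs, collapse = ",")
  if (!is.null(term$gene_name)) kv["G"] <- .nhx_encode(term$gene_name)
  if (!is.null(node$support)) kv["B"] <- .fmt_num(node$support)
  paste0("[&&NHX:", paste(names(kv), kv, sep = "=", collapse = ":"), "]")
}

#' Rebuild a reconciled gene tree from this library's NHX dialect
#'
#' Inverse of `to_newick(tree, mode = "nhx")`: reconstructs the full event
#' sequence of every node, so `from_nhx(to_newick(t, "nhx"))` is
#' structurally equal to `t`.
#'
#' @param source NHX text or a file path.
#' @return an [rp_gene_node] root.
#' @export
from_nhx <- function(source) {
  plain <- read_plain_tree(source)
  .plain_to_gene(plain, path = "root")
}

.split_keep_empty <- function(x, sep) {
  if (is.null(x)) return(character())
  strsplit(paste0(x, "\001"), sep, fixed = TRUE)[[1L]] -> parts
  parts[length(parts)] <- sub("\001$", "", parts[length(parts)])
  parts
}

.plain_to_gene <- function(node, path) {
  nhx <- node$nhx
  if (is.null(nhx$Ev))
    stop("node '", path, "' has no Ev annotation: this looks like plain ",
         "Newick without reconciliation data; reconcile it first ",
         "(see lca_reconcile)", call. = FALSE)
  types <- strsplit(nhx$Ev, ";", fixed = TRUE)[[1L]]
  bad <- setdiff(types, rp_event_types())
  if (length(bad))
    stop("unknown event code(s) in NHX annotation: ",
         paste(bad, collapse = ", "), call. = FALSE)
  dests <- .nhx_decode(.split_keep_empty(nhx$D, ","))
  slices <- .split_keep_empty(nhx$T, ",")
  confs <- .split_keep_empty(nhx$C, ",")
  di <- 0L
  events <- lapply(seq_along(types), function(i) {
    t <- types[i]
    dest <- NULL
    if (t == "transferBack") {
      di <<- di + 1L
      if (di > length(dests))
        stop("missing transferBack destination in NHX annotation at '",
             path, "'", call. = FALSE)
      dest <- dests[di]
    }
    loc <- if (t %in% .RP_LOCATED) .nhx_decode(nhx$S %||% "") else NULL
    if (!is.null(loc) && !nzchar(loc))
      stop("missing S (species) key for event '", t, "' at '", path, "'",
           call. = FALSE)
    ts <- if (i <= length(slices) && nzchar(slices[i]))
      as.integer(slices[i]) else NULL
    cf <- if (i <= length(confs) && nzchar(confs[i]))
      as.numeric(confs[i]) else NULL
    gn <- if (t == "leaf" && !is.null(nhx$G)) .nhx_decode(nhx$G) else NULL
    rp_event(t, species_location = loc, destination_species = dest,
             confidence = cf, time_slice = ts, gene_name = gn)
  })
  children <- lapply(seq_along(node$children), function(i)
    .plain_to_gene(node$children[[i]], paste0(path, ".", i)))
  support <- if (!is.null(nhx$B)) as.numeric(nhx$B) else NULL
  rp_gene_node(events, children = children, name = node$name,
               branch_length = node$branch_length, support = support)
}

# ---------------------------------------------------------------------------
# Event census ---------------------------------------------------------------

#' Count events in a document
#'
#' Tallies every event of every sequence — including non-terminal
#' `transferBack` events — once, per gene tree and totaled.
#'
#' @param doc an [rp_document].
#' @param check verify structural validity first.
#' @return an object of class `rp_event_census`: list with `per_tree`
#'   (event-type x tree integer matrix) and `total` (named integer vector).
#' @examples
#' leafC <- rp_gene_node(list(rp_event("leaf", "C")))
#' rp_count_events(rp_document(leafC))$total
#' @export
rp_count_events <- function(doc, check = TRUE) {
  stopifnot(inherits(doc, "rp_document"))
  if (check) {
    rep <- validate_structure(doc)
    if (!rep$valid)
      stop("document fails structural validation; see validate_structure()",
           call. = FALSE)
  }
  types <- rp_event_types()
  per_tree <- matrix(0L, nrow = length(types),
                     ncol = length(doc$gene_trees),
                     dimnames = list(types, NULL))
  for (ti in seq_along(doc$gene_trees))
    for (w in rp_walk(doc$gene_trees[[ti]]))
      for (e in w$node$events)
        per_tree[e$type, ti] <- per_tree[e$type, ti] + 1L
  structure(list(per_tree = per_tree,
                 total = rowSums(per_tree)[types]),
            class = "rp_event_census")
}

#' @export
print.rp_event_census <- function(x, ...) {
  cat("event census over", ncol(x$per_tree), "gene tree(s):\n")
  tot <- x$total[x$total > 0]
  for (nm in names(tot)) cat(sprintf("  %-15s %d\n", nm, tot[[nm]]))
  invisible(x)
}

#' Serialize an event census
#'
#' @param census an `rp_event_census`.
#' @param file optional output path.
#' @return TSV text with columns event_type, tree_index, count (plus
#'   `total` rows), or JSON.
#' @export
rp_census_tsv <- function(census, file = NULL) {
  rows <- c("event_type\ttree_index\tcount")
  for (ti in seq_len(ncol(census$per_tree)))
    for (t in rownames(census$per_tree))
      rows <- c(rows, paste(t, ti, census$per_tree[t, ti], sep = "\t"))
  for (t in names(census$total))
    rows <- c(rows, paste(t, "total", census$total[[t]], sep = "\t"))
  txt <- paste(rows, collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' @rdname rp_census_tsv
#' @export
rp_census_json <- function(census, file = NULL) {
  obj <- list(total = as.list(census$total),
              per_tree = lapply(seq_len(ncol(census$per_tree)), function(i)
                as.list(census$per_tree[, i])))
  txt <- as.character(jsonlite::toJSON(obj, auto_unbox = TRUE))
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

# ---------------------------------------------------------------------------
# Combine / extract ----------------------------------------------------------

.first_sp_divergence <- function(a, b, path = "root") {
  if (!identical(a$name, b$name))
    return(sprintf("%s ('%s' vs '%s')", path, a$name, b$name))
  if (length(a$children) != length(b$children))
    return(sprintf("%s (arity %d vs %d)", path, length(a$children),
                   length(b$children)))
  if (!length(a$children)) return(NULL)
  # try matching in given order, then swapped (sibling order is unordered)
  for (perm in list(c(1L, 2L), c(2L, 1L))) {
    ok <- TRUE
    for (i in 1:2)
      if (!rp_equal(a$children[[i]], b$children[[perm[i]]])) ok <- FALSE
    if (ok) return(NULL)
  }
  for (i in 1:2) {
    d <- .first_sp_divergence(a$children[[i]], b$children[[i]],
                              paste0(path, ".", i))
    if (!is.null(d)) return(d)
  }
  sprintf("%s (children differ)", path)
}

#' Combine several documents into one
#'
#' Concatenates the gene trees of all inputs in order. Species trees, where
#' present, must be structurally identical (same topology and names,
#' sibling order ignored); a single available species tree is kept when the
#' other inputs have none.
#'
#' @param docs list of [rp_document] objects (or several documents as
#'   `...`).
#' @param ... documents, if `docs` is not a list.
#' @return an [rp_document].
#' @export
rp_combine <- function(docs, ...) {
  if (inherits(docs, "rp_document")) docs <- c(list(docs), list(...))
  stopifnot(length(docs) >= 1L)
  sp <- NULL
  for (d in docs) {
    stopifnot(inherits(d, "rp_document"))
    if (is.null(d$species_tree)) next
    if (is.null(sp)) { sp <- d$species_tree; next }
    if (!rp_equal(sp, d$species_tree)) {
      where <- .first_sp_divergence(sp, d$species_tree)
      stop("conflicting species trees; first divergence at ", where,
           call. = FALSE)
    }
  }
  rp_document(do.call(c, lapply(docs, `[[`, "gene_trees")),
              species_tree = sp)
}

#' Extract gene trees from a document
#'
#' Selects gene trees by 1-based index or by root-clade name; each selector
#' must match exactly one tree. The species tree is retained and the
#' selected trees appear in selector order.
#'
#' @param doc an [rp_document].
#' @param selectors vector or list of integer indices and/or name strings.
#' @return an [rp_document].
#' @export
rp_extract <- function(doc, selectors) {
  stopifnot(inherits(doc, "rp_document"))
  if (!is.list(selectors)) selectors <- as.list(selectors)
  pick <- vapply(selectors, function(s) {
    if (is.numeric(s)) {
      if (length(s) != 1L || is.na(s) || s < 1 || s > length(doc$gene_trees)
          || s != floor(s))
        stop("index selector out of range: ", s, call. = FALSE)
      return(as.integer(s))
    }
    hits <- which(vapply(doc$gene_trees, function(g)
      identical(g$name, as.character(s)), NA))
    if (length(hits) == 0L)
      stop("no gene tree with root name '", s, "'", call. = FALSE)
    if (length(hits) > 1L)
      stop("ambiguous selector '", s, "': matches ", length(hits),
           " gene trees", call. = FALSE)
    hits
  }, 0L)
  rp_document(doc$gene_trees[pick], species_tree = doc$species_tree)
}
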