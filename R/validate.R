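# Two-level validation: level 1 (structure) re-checks the event grammar and
# document cardinality from scratch, so it also works on objects built with
# check = FALSE or patched by hand; level 2 (semantics) checks the
# reconciliation against the species tree. The cross-node semantic rules are
# not formalized by the format itself, so they are split into a strict set
# (derived from the event definitions) and a lenient set (reference
# resolution and time monotonicity only).

.report_env <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env
}

.flag <- function(env, code, severity, tree = NA_integer_, path = "",
                  message = "") {
  env$rows[[length(env$rows) + 1L]] <-
    list(code = code, severity = severity, gene_tree_index = tree,
         node_path = path, message = message)
  invisible(NULL)
}

.report_finish <- function(env) {
  if (length(env$rows)) {
    issues <- data.frame(
      code = vapply(env$rows, `[[`, "", "code"),
      severity = vapply(env$rows, `[[`, "", "severity"),
      gene_tree_index = vapply(env$rows, `[[`, NA_integer_,
                               "gene_tree_index"),
      node_path = vapply(env$rows, `[[`, "", "node_path"),
      message = vapply(env$rows, `[[`, "", "message"),
      stringsAsFactors = FALSE)
  } else {
    issues <- data.frame(code = character(), severity = character(),
                         gene_tree_index = integer(),
                         node_path = character(), message = character(),
                         stringsAsFactors = FALSE)
  }
  structure(list(issues = issues,
                 valid = !any(issues$severity == "error")),
            class = "rp_validation_report")
}

#' @export
print.rp_validation_report <- function(x, ...) {
  cat(if (x$valid) "VALID" else "INVALID",
      sprintf(" (%d error(s), %d warning(s))\n",
              sum(x$issues$severity == "error"),
              sum(x$issues$severity == "warning")), sep = "")
  if (nrow(x$issues)) {
    for (i in seq_len(nrow(x$issues)))
      cat(sprintf("  [%s] %s tree=%s %s: %s\n", x$issues$severity[i],
                  x$issues$code[i],
                  ifelse(is.na(x$issues$gene_tree_index[i]), "-",
                         x$issues$gene_tree_index[i]),
                  x$issues$node_path[i], x$issues$message[i]))
  }
  invisible(x)
}

#' Serialize a validation report
#'
#' @param report an `rp_validation_report`.
#' @param file optional path; when `NULL` the text is returned.
#' @return TSV text (columns code, severity, tree index, node path,
#'   message) or JSON, invisibly when written to a file.
#' @export
rp_report_tsv <- function(report, file = NULL) {
  hdr <- "code\tseverity\tgene_tree_index\tnode_path\tmessage"
  d <- report$issues
  rows <- paste(d$code, d$severity, d$gene_tree_index, d$node_path,
                d$message, sep = "\t")
  txt <- paste(c(hdr, rows), collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' @rdname rp_report_tsv
#' @export
rp_report_json <- function(report, file = NULL) {
  obj <- list(valid = report$valid, issues = report$issues)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, dataframe = "rows")
  if (is.null(file)) return(as.character(txt))
  writeLines(as.character(txt), file)
  invisible(as.character(txt))
}

# ---------------------------------------------------------------------------
# Level 1: structure --------------------------------------------------------

#' Validate the event grammar and document structure
#'
#' Checks, independently of the constructors, that every event sequence is
#' non-empty with exactly one terminal event in last position
#' (`E_NO_TERMINAL`, `E_EARLY_TERMINAL`, `E_MULTI_TERMINAL`), that clade
#' arity matches the terminal event (`E_ARITY`), that event attributes obey
#' the presence rules (`E_ATTR`), and document cardinality plus species-name
#' uniqueness (`E_DOC`).
#'
#' @param doc an [rp_document].
#' @return an `rp_validation_report`.
#' @export
validate_structure <- function(doc) {
  env <- .report_env()
  if (!inherits(doc, "rp_document")) {
    .flag(env, "E_DOC", "error", message = "not an rp_document")
    return(.report_finish(env))
  }
  if (length(doc$gene_trees) < 1L)
    .flag(env, "E_DOC", "error",
          message = "document must contain at least one gene tree")
  if (!is.null(doc$species_tree)) {
    nm <- rp_species_names(doc$species_tree)
    dup <- unique(nm[duplicated(nm)])
    if (length(dup))
      .flag(env, "E_DOC", "error",
            message = paste0("duplicated species name(s): ",
                             paste(dup, collapse = ", ")))
    for (w in rp_walk(doc$species_tree))
      if (!length(w$node$children) %in% c(0L, 2L))
        .flag(env, "E_DOC", "error", path = w$path,
              message = "species clades must have 0 or 2 children")
  }
  for (ti in seq_along(doc$gene_trees))
    for (w in rp_walk(doc$gene_trees[[ti]]))
      .check_node_structure(env, w$node, ti, w$path)
  .report_finish(env)
}

.check_node_structure <- function(env, node, ti, path) {
  ev <- node$events
  if (!is.list(ev) || length(ev) == 0L) {
    .flag(env, "E_NO_TERMINAL", "error", ti, path,
          "empty event sequence")
    return(invisible(NULL))
  }
  types <- vapply(ev, `[[`, "", "type")
  term_idx <- which(rp_is_terminal(types))
  if (length(term_idx) == 0L)
    .flag(env, "E_NO_TERMINAL", "error", ti, path,
          "event sequence has no terminal event")
  if (length(term_idx) > 1L)
    .flag(env, "E_MULTI_TERMINAL", "error", ti, path,
          "event sequence has more than one terminal event")
  if (length(term_idx) >= 1L && term_idx[1L] != length(types))
    .flag(env, "E_EARLY_TERMINAL", "error", ti, path,
          paste0("terminal event '", types[term_idx[1L]],
                 "' is not the last of the sequence"))
  for (i in seq_along(ev)) {
    e <- ev[[i]]
    t <- e$type
    if (t %in% .RP_LOCATED && is.null(e$species_location))
      .flag(env, "E_ATTR", "error", ti, path,
            paste0("event '", t, "' lacks its speciesLocation"))
    if (!t %in% .RP_LOCATED && !is.null(e$species_location))
      .flag(env, "E_ATTR", "error", ti, path,
            paste0("event '", t, "' must not carry a speciesLocation"))
    if (t == "transferBack" && is.null(e$destination_species))
      .flag(env, "E_ATTR", "error", ti, path,
            "transferBack lacks its destinationSpecies")
    if (t != "transferBack" && !is.null(e$destination_species))
      .flag(env, "E_ATTR", "error", ti, path,
            paste0("event '", t, "' must not carry a destinationSpecies"))
    if (!is.null(e$gene_name) && t != "leaf")
      .flag(env, "E_ATTR", "error", ti, path,
            "geneName is only allowed on leaf events")
    if (!is.null(e$time_slice) && e$time_slice < 0)
      .flag(env, "E_ATTR", "error", ti, path, "negative timeSlice")
  }
  if (length(term_idx) >= 1L) {
    term <- types[term_idx[length(term_idx)]]
    want <- if (term %in% .RP_BIFURCATING) 2L else 0L
    if (length(node$children) != want)
      .flag(env, "E_ARITY", "error", ti, path,
            sprintf("terminal event '%s' requires %d children, found %d",
                    term, want, length(node$children)))
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Level 2: semantics --------------------------------------------------------

.species_index <- function(sp_root) {
  nodes <- rp_walk(sp_root)
  nm <- vapply(nodes, function(w) w$node$name, "")
  children <- lapply(nodes, function(w)
    vapply(w$node$children, `[[`, "", "name"))
  names(children) <- nm
  list(names = nm, children = children)
}

#' Validate reconciliation semantics against the species tree
#'
#' Level-2 validation. In both levels: every `speciesLocation` /
#' `destinationSpecies` must name a species clade (`E_SPECIES_UNKNOWN`) and
#' `timeSlice` values must be non-decreasing along root-to-leaf gene paths
#' (`W_TIMESLICE`, warning). In strict level additionally: speciation
#' children must start in the two distinct child species
#' (`E_SPECIATION_CHILDREN`); duplication children must start in the same
#' species (`E_DUP_CHILDREN`); under a `branchingOut` exactly one child is
#' resident while the other emigrates (`E_BRANCHINGOUT_CHILDREN`); a
#' `transferBack` start requires a donor-side `branchingOut` /
#' `bifurcationOut` parent (`E_ORPHAN_TRANSFERBACK`; at the root this is
#' only a warning `W_ROOT_TRANSFERBACK`); `bifurcationOut` children must
#' re-enter by `transferBack` or stay unsampled (`E_BIFOUT_CHILDREN`); and a
#' transfer may not re-enter the species it currently occupies
#' (`E_TRANSFER_SELF`). Without a species tree all rules are skipped with
#' `W_NO_SPTREE`.
#'
#' @param doc an [rp_document] that passes [validate_structure()].
#' @param level `"strict"` or `"lenient"`.
#' @return an `rp_validation_report`.
#' @export
validate_semantics <- function(doc, level = c("strict", "lenient")) {
  level <- match.arg(level)
  env <- .report_env()
  if (is.null(doc$species_tree)) {
    .flag(env, "W_NO_SPTREE", "warning",
          message = "no species tree: semantic rules skipped")
    return(.report_finish(env))
  }
  idx <- .species_index(doc$species_tree)
  strict <- level == "strict"
  for (ti in seq_along(doc$gene_trees))
    .check_semantics_node(env, doc$gene_trees[[ti]], ti, "", idx, strict,
                          parent_term = NULL, last_slice = -Inf)
  .report_finish(env)
}

.known_species <- function(env, name, idx, ti, path) {
  if (name %in% idx$names) return(TRUE)
  .flag(env, "E_SPECIES_UNKNOWN", "error", ti, path,
        paste0("species '", name, "' is not in the species tree"))
  FALSE
}

.check_semantics_node <- function(env, node, ti, path, idx, strict,
                                  parent_term, last_slice) {
  types <- vapply(node$events, `[[`, "", "type")
  n <- length(types)
  term <- node$events[[n]]

  # reference resolution + confidence range + timeSlice monotonicity
  for (e in node$events) {
    if (!is.null(e$species_location))
      .known_species(env, e$species_location, idx, ti, path)
    if (!is.null(e$destination_species))
      .known_species(env, e$destination_species, idx, ti, path)
    if (!is.null(e$confidence) && (e$confidence < 0 || e$confidence > 1))
      .flag(env, "W_CONFIDENCE", "warning", ti, path,
            paste0("confidence ", e$confidence, " outside [0, 1]"))
    if (!is.null(e$time_slice)) {
      if (e$time_slice < last_slice)
        .flag(env, "W_TIMESLICE", "warning", ti, path,
              sprintf("timeSlice %d after %s on the same path",
                      e$time_slice, format(last_slice)))
      last_slice <- max(last_slice, e$time_slice)
    }
  }

  starts_tb <- types[1L] == "transferBack"
  if (starts_tb) {
    if (is.null(parent_term)) {
      .flag(env, "W_ROOT_TRANSFERBACK", "warning", ti, path,
            "root lineage begins with a transferBack (origin outside tree)")
    } else if (strict &&
               !parent_term$type %in% c("branchingOut", "bifurcationOut")) {
      .flag(env, "E_ORPHAN_TRANSFERBACK", "error", ti, path,
            paste0("transferBack reception without a donor-side branching ",
                   "event (parent ends with '", parent_term$type, "')"))
    }
  }

  if (strict) {
    # self-transfers: re-entering the currently occupied species
    dests <- vapply(node$events[types == "transferBack"],
                    `[[`, "", "destination_species")
    occupied <- if (!is.null(parent_term) &&
                    parent_term$type == "branchingOut" && starts_tb)
      parent_term$species_location else NULL
    for (d in dests) {
      if (!is.null(occupied) && identical(d, occupied))
        .flag(env, "E_TRANSFER_SELF", "error", ti, path,
              paste0("transferBack into the occupied species '", d, "'"))
      occupied <- d
    }
  }

  if (strict && length(node$children) == 2L) {
    st <- vapply(node$children, rp_start_species, "")
    emigrant <- vapply(node$children, function(ch)
      ch$events[[1L]]$type == "transferBack" ||
        rp_terminal_event(ch)$type == "bifurcationOut", NA)
    tt <- term$type
    s <- term$species_location
    if (tt == "speciation") {
      want <- idx$children[[s]] %||% character()
      if (length(want) != 2L || !setequal(st, want) || st[1L] == st[2L])
        .flag(env, "E_SPECIATION_CHILDREN", "error", ti, path,
              sprintf(paste0("speciation at '%s': children start in [%s], ",
                             "expected its two child species [%s]"),
                      s, paste(st, collapse = ", "),
                      paste(want, collapse = ", ")))
    } else if (tt == "duplication") {
      if (!all(st == s))
        .flag(env, "E_DUP_CHILDREN", "error", ti, path,
              sprintf("duplication at '%s': children start in [%s]",
                      s, paste(st, collapse = ", ")))
    } else if (tt == "branchingOut") {
      resident <- !emigrant & st == s
      if (sum(resident) != 1L || sum(emigrant) != 1L || any(resident & emigrant))
        .flag(env, "E_BRANCHINGOUT_CHILDREN", "error", ti, path,
              sprintf(paste0("branchingOut at '%s': expected one resident ",
                             "child in '%s' and one emigrant child"), s, s))
    } else if (tt == "bifurcationOut") {
      if (!all(emigrant))
        .flag(env, "E_BIFOUT_CHILDREN", "error", ti, path,
              paste0("bifurcationOut children must re-enter via ",
                     "transferBack or stay unsampled"))
    }
  }

  for (i in seq_along(node$children)) {
    sub <- if (nzchar(path)) paste0(path, ".", i) else as.character(i)
    .check_semantics_node(env, node$children[[i]], ti, sub, idx, strict,
                          parent_term = term, last_slice = last_slice)
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Reconciliation map ---------------------------------------------------------

#' Materialize the gene-node to species assignment
#'
#' Assigns every gene node to the species of its terminal event;
#' `bifurcationOut` nodes map to the unsampled sentinel ([rp_unsampled()]).
#'
#' @param doc an [rp_document] with a species tree, passing
#'   [validate_structure()].
#' @return a data frame of class `rp_reconciliation_map` with columns
#'   `gene_tree_index`, `node_path`, `node_name`, `species`.
#' @export
build_reconciliation_map <- function(doc) {
  stopifnot(inherits(doc, "rp_document"))
  if (is.null(doc$species_tree))
    stop("a species tree is required to build a reconciliation map",
         call. = FALSE)
  known <- rp_species_names(doc$species_tree)
  rows <- list()
  for (ti in seq_along(doc$gene_trees)) {
    for (w in rp_walk(doc$gene_trees[[ti]])) {
      term <- rp_terminal_event(w$node)
      sp <- if (term$type == "bifurcationOut") rp_unsampled() else
        term$species_location
      if (sp != rp_unsampled() && !sp %in% known)
        stop("species '", sp, "' is not in the species tree (tree ", ti,
             ", node '", w$path, "')", call. = FALSE)
      rows[[length(rows) + 1L]] <-
        list(gene_tree_index = ti, node_path = w$path,
             node_name = w$node$name, species = sp)
    }
  }
  out <- data.frame(
    gene_tree_index = vapply(rows, `[[`, 0L, "gene_tree_index"),
    node_path = vapply(rows, `[[`, "", "node_path"),
    node_name = vapply(rows, `[[`, "", "node_name"),
    species = vapply(rows, `[[`, "", "species"),
    stringsAsFactors = FALSE)
  class(out) <- c("rp_reconciliation_map", class(out))
  out
}
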