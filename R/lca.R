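# Most-parsimonious duplication-loss reconciliation by LCA mapping.
#
# Each gene node g is assigned M(g), the lowest common ancestor in the
# species tree of the species of its descendant leaves. g is a duplication
# when M(g) equals the image of one of its children, else a speciation.
# Explicit loss leaves (named "LOST") are inserted for every species branch
# the lineage demonstrably passed through without leaving descendants. The
# resulting duplication + loss count is the classical parsimony minimum
# among all reconciliations without transfers.

#' Read a gene-leaf to species mapping from a two-column TSV
#'
#' @param file path to a headerless two-column TSV
#'   (`gene_name<TAB>species_name`).
#' @return named character vector: `mapping[gene] == species`.
#' @export
read_leaf_mapping <- function(file) {
  m <- utils::read.table(file, sep = "\t", header = FALSE,
                         colClasses = "character", quote = "",
                         comment.char = "")
  if (ncol(m) != 2L)
    stop("leaf mapping must have exactly two tab-separated columns",
         call. = FALSE)
  stats::setNames(m[[2L]], m[[1L]])
}

#' Derive a leaf mapping from a name-prefix convention
#'
#' Gene leaves named `"<species><sep><gene id>"` are mapped to the species
#' given by the part before the first separator.
#'
#' @param gene_names character vector of gene-leaf names.
#' @param sep separator (default `"_"`).
#' @return named character vector suitable for [lca_reconcile()].
#' @export
leaf_mapping_from_names <- function(gene_names, sep = "_") {
  no_sep <- !grepl(sep, gene_names, fixed = TRUE)
  if (any(no_sep))
    stop("gene name(s) without '", sep, "' separator: ",
         paste(gene_names[no_sep], collapse = ", "), call. = FALSE)
  sp <- vapply(strsplit(gene_names, sep, fixed = TRUE), `[[`, "", 1L)
  stats::setNames(sp, gene_names)
}

.as_species_tree <- function(x) {
  if (inherits(x, "rp_species_node")) return(x)
  if (inherits(x, "rp_plain_node")) return(plain_to_species(x))
  if (is.character(x)) return(plain_to_species(read_plain_tree(x)))
  stop("cannot interpret species tree input", call. = FALSE)
}

.as_plain_tree <- function(x) {
  if (inherits(x, "rp_plain_node")) return(x)
  if (is.character(x)) return(read_plain_tree(x))
  stop("cannot interpret gene tree input", call. = FALSE)
}

# name-indexed species relations: parent, children, depth
.sp_relations <- function(sp_root) {
  parent <- character()
  children <- list()
  depth <- integer()
  rec <- function(node, par, d) {
    parent[[node$name]] <<- par
    depth[[node$name]] <<- d
    children[[node$name]] <<-
      vapply(node$children, `[[`, "", "name")
    for (ch in node$children) rec(ch, node$name, d + 1L)
  }
  rec(sp_root, NA_character_, 0L)
  list(parent = parent, children = children, depth = depth,
       names = names(parent),
       leaves = names(children)[!vapply(children, length, 0L)])
}

.sp_lca <- function(rel, a, b) {
  while (a != b) {
    if (rel$depth[[a]] >= rel$depth[[b]]) a <- rel$parent[[a]]
    else b <- rel$parent[[b]]
  }
  a
}

# species names on the path from `from` down to `to`, both inclusive
.sp_path_down <- function(rel, from, to) {
  path <- to
  while (path[1L] != from) {
    p <- rel$parent[[path[1L]]]
    if (is.na(p)) stop("'", from, "' is not an ancestor of '", to, "'",
                       call. = FALSE)
    path <- c(p, path)
  }
  path
}

#' Most-parsimonious duplication-loss reconciliation
#'
#' Reconciles a plain rooted binary gene tree against a rooted binary
#' species tree under the LCA mapping, producing a reconciliation document
#' with explicit `speciation`, `duplication`, `loss` and `leaf` events that
#' passes strict validation. The duplication + loss count is minimal among
#' all transfer-free reconciliations. Deterministic: identical inputs give
#' byte-identical serialized output.
#'
#' @param gene_tree Newick string, file path or `rp_plain_node`; must be
#'   rooted and binary.
#' @param species_tree Newick string, `rp_plain_node` or
#'   [rp_species_node]; rooted and binary.
#' @param mapping named character vector mapping every gene-leaf name to a
#'   species-leaf name (see [read_leaf_mapping()]); `NULL` applies the
#'   `"species_gene"` name-prefix rule of [leaf_mapping_from_names()].
#' @return an [rp_document] with the species tree and one reconciled gene
#'   tree.
#' @examples
#' doc <- lca_reconcile("((A_1,B_1),(A_2,B_2));", "(A,B)root;")
#' rp_count_events(doc)$total
#' @export
lca_reconcile <- function(gene_tree, species_tree, mapping = NULL) {
  g <- .as_plain_tree(gene_tree)
  sp <- .as_species_tree(species_tree)
  rel <- .sp_relations(sp)

  leaves <- character()
  walk_leaves <- function(n) {
    k <- length(n$children)
    if (k == 0L) {
      if (!nzchar(n$name))
        stop("gene-tree leaves must be named", call. = FALSE)
      leaves <<- c(leaves, n$name)
    } else if (k != 2L) {
      stop("gene tree must be binary (found a clade with ", k,
           " children)", call. = FALSE)
    } else for (ch in n$children) walk_leaves(ch)
  }
  walk_leaves(g)

  if (is.null(mapping)) mapping <- leaf_mapping_from_names(leaves)
  missing <- setdiff(leaves, names(mapping))
  if (length(missing))
    stop("leaf mapping is not total; unmapped gene leaves: ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- setdiff(unname(mapping[leaves]), rel$leaves)
  if (length(bad))
    stop("mapped species absent from the species tree (or not a leaf): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)

  build <- function(node) {
    # returns list(rec = rp_gene_node, m = species image)
    if (!length(node$children)) {
      m <- unname(mapping[[node$name]])
      rec <- rp_gene_node(
        list(rp_event("leaf", species_location = m, gene_name = node$name)),
        name = node$name, branch_length = node$branch_length)
      return(list(rec = rec, m = m))
    }
    L <- build(node$children[[1L]])
    R <- build(node$children[[2L]])
    m <- .sp_lca(rel, L$m, R$m)
    dup <- (m == L$m) || (m == R$m)
    if (dup) {
      kids <- list(.wrap_losses(L$rec, m, L$m, rel),
                   .wrap_losses(R$rec, m, R$m, rel))
      ev <- rp_event("duplication", species_location = m)
    } else {
      kids <- lapply(list(L, R), function(side) {
        entry <- .sp_path_down(rel, m, side$m)[2L]  # child branch of m
        .wrap_losses(side$rec, entry, side$m, rel)
      })
      ev <- rp_event("speciation", species_location = m)
    }
    rec <- rp_gene_node(list(ev), children = kids, name = node$name,
                        branch_length = node$branch_length)
    list(rec = rec, m = m)
  }

  root <- build(g)
  rp_document(list(root$rec), species_tree = sp)
}

# Insert loss-bearing speciation nodes along the species path from `from`
# (inclusive) down to `to` (exclusive): at each intermediate species node
# the lineage speciates and the off-path copy is lost.
.wrap_losses <- function(rec, from, to, rel) {
  if (from == to) return(rec)
  path <- .sp_path_down(rel, from, to)
  for (i in rev(seq_len(length(path) - 1L))) {
    v <- path[i]
    on_path <- path[i + 1L]
    off <- setdiff(rel$children[[v]], on_path)
    lost <- rp_gene_node(
      list(rp_event("loss", species_location = off)), name = "LOST")
    rec <- rp_gene_node(
      list(rp_event("speciation", species_location = v)),
      children = list(rec, lost))
  }
  rec
}
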