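# Newick / NHX text parsing and writing.
#
# A small recursive-descent parser is used because the NHX comment maps and
# quoted-label semantics needed here are not exposed by the usual phylo
# readers; plain-Newick topologies are cross-checked against ape in the test
# suite. Forbidden characters in unquoted labels —  , : ( ) ; [ ]  — are
# honored: labels containing them must be single-quoted (with '' escaping
# embedded quotes).

.NWK_FORBIDDEN <- c(",", ":", "(", ")", ";", "[", "]")

#' Quote a Newick label when needed
#'
#' Labels containing a forbidden character (`, : ( ) ; [ ]`), whitespace or
#' a quote are wrapped in single quotes, doubling embedded quotes.
#'
#' @param x character vector of labels.
#' @return character vector of safely writable labels.
#' @export
newick_quote <- function(x) {
  needs <- grepl("[][(),:;'[:space:]]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Read a plain rooted tree from Newick or NHX text
#'
#' Returns a plain (unreconciled) tree as nested lists of class
#' `rp_plain_node` with fields `name`, `branch_length`, `support`, `nhx`
#' (named list of NHX key/value strings) and `children`. Purely numeric
#' internal labels are also interpreted as support values. Multifurcations
#' are parsed; consumers that require binary trees (the LCA reconciler)
#' check arity themselves.
#'
#' @param source file path or Newick/NHX string (detected by the presence
#'   of a `(` or `;`).
#' @return an `rp_plain_node` root.
#' @examples
#' tr <- read_plain_tree("((a:1.5,b:2.0)ab,c);")
#' @export
read_plain_tree <- function(source) {
  txt <- if (length(source) == 1L && !grepl("[(;]", source) &&
             file.exists(source))
    paste(readLines(source, warn = FALSE), collapse = "") else
    paste(source, collapse = "")
  st <- new.env(parent = emptyenv())
  st$s <- txt
  st$i <- 1L
  st$n <- nchar(txt)
  .nwk_ws(st)
  node <- .nwk_subtree(st)
  .nwk_ws(st)
  if (.nwk_peek(st) != ";")
    stop("expected ';' at position ", st$i, " of Newick input",
         call. = FALSE)
  st$i <- st$i + 1L
  .nwk_ws(st)
  if (st$i <= st$n)
    stop("trailing characters after ';' in Newick input", call. = FALSE)
  node
}

.nwk_peek <- function(st) {
  if (st$i > st$n) "" else substr(st$s, st$i, st$i)
}

.nwk_ws <- function(st) {
  while (st$i <= st$n && grepl("[[:space:]]", substr(st$s, st$i, st$i)))
    st$i <- st$i + 1L
}

.nwk_label <- function(st) {
  .nwk_ws(st)
  ch <- .nwk_peek(st)
  if (ch == "'") {
    st$i <- st$i + 1L
    buf <- character()
    repeat {
      if (st$i > st$n) stop("unterminated quoted label", call. = FALSE)
      ch <- substr(st$s, st$i, st$i)
      st$i <- st$i + 1L
      if (ch == "'") {
        if (.nwk_peek(st) == "'") { buf <- c(buf, "'"); st$i <- st$i + 1L }
        else break
      } else buf <- c(buf, ch)
    }
    return(paste(buf, collapse = ""))
  }
  start <- st$i
  while (st$i <= st$n) {
    ch <- substr(st$s, st$i, st$i)
    if (ch %in% .NWK_FORBIDDEN || grepl("[[:space:]]", ch)) break
    if (ch == "'")
      stop("quote inside unquoted label at position ", st$i, call. = FALSE)
    st$i <- st$i + 1L
  }
  substr(st$s, start, st$i - 1L)
}

.nwk_comment <- function(st) {
  # returns NULL or the comment body (without brackets)
  .nwk_ws(st)
  if (.nwk_peek(st) != "[") return(NULL)
  st$i <- st$i + 1L
  start <- st$i
  depth <- 1L
  while (st$i <= st$n) {
    ch <- substr(st$s, st$i, st$i)
    if (ch == "[") depth <- depth + 1L
    if (ch == "]") {
      depth <- depth - 1L
      if (depth == 0L) {
        body <- substr(st$s, start, st$i - 1L)
        st$i <- st$i + 1L
        return(body)
      }
    }
    st$i <- st$i + 1L
  }
  stop("unterminated '[' comment in Newick input", call. = FALSE)
}

.parse_nhx_body <- function(body) {
  if (is.null(body) || !startsWith(body, "&&NHX")) return(list())
  body <- sub("^&&NHX:?", "", body)
  if (!nzchar(body)) return(list())
  parts <- strsplit(body, ":", fixed = TRUE)[[1L]]
  out <- list()
  for (p in parts) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 0) next
    out[[substr(p, 1L, eq - 1L)]] <- substr(p, eq + 1L, nchar(p))
  }
  out
}

.nwk_subtree <- function(st) {
  .nwk_ws(st)
  children <- list()
  if (.nwk_peek(st) == "(") {
    st$i <- st$i + 1L
    repeat {
      children[[length(children) + 1L]] <- .nwk_subtree(st)
      .nwk_ws(st)
      ch <- .nwk_peek(st)
      if (ch == ",") { st$i <- st$i + 1L; next }
      if (ch == ")") { st$i <- st$i + 1L; break }
      stop("expected ',' or ')' at position ", st$i, " of Newick input",
           call. = FALSE)
    }
  }
  name <- .nwk_label(st)
  branch_length <- NULL
  .nwk_ws(st)
  if (.nwk_peek(st) == ":") {
    st$i <- st$i + 1L
    num <- .nwk_label(st)
    branch_length <- suppressWarnings(as.numeric(num))
    if (is.na(branch_length))
      stop("invalid branch length '", num, "'", call. = FALSE)
  }
  nhx <- .parse_nhx_body(.nwk_comment(st))
  support <- NULL
  if (length(children) && nzchar(name) &&
      grepl("^[-+]?[0-9.]+([eE][-+]?[0-9]+)?$", name))
    support <- as.numeric(name)
  structure(list(name = name, branch_length = branch_length,
                 support = support, nhx = nhx, children = children),
            class = "rp_plain_node")
}

#' Convert a plain tree to a species tree
#'
#' Unnamed internal nodes receive generated names (`spN`) so that every
#' species clade can be referenced by `speciesLocation`.
#'
#' @param tree an `rp_plain_node` (from [read_plain_tree()]).
#' @return an [rp_species_node] root.
#' @export
plain_to_species <- function(tree) {
  counter <- new.env(parent = emptyenv())
  counter$k <- 0L
  used <- character()
  collect <- function(n) {
    if (nzchar(n$name)) used <<- c(used, n$name)
    for (ch in n$children) collect(ch)
  }
  collect(tree)
  fresh <- function() {
    repeat {
      counter$k <- counter$k + 1L
      nm <- paste0("sp", counter$k)
      if (!nm %in% used) return(nm)
    }
  }
  rec <- function(n) {
    # internal purely-numeric labels are supports, not usable names
    nm <- if (nzchar(n$name) && (is.null(n$support) || !length(n$children)))
      n$name else ""
    if (!nzchar(nm)) nm <- fresh()
    rp_species_node(nm, children = lapply(n$children, rec),
                    branch_length = n$branch_length)
  }
  rec(tree)
}
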