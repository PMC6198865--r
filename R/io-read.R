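# Reader for recPhyloXML / recGeneTreeXML / recSpeciesTreeXML documents.
# XML well-formedness and tree walking are delegated to xml2; this file owns
# the mapping from elements to model objects and the issue bookkeeping.

#' Parsing options
#'
#' @param strict in strict mode every deviation from the grammar is an
#'   error; in lenient mode recoverable deviations (unknown clade children,
#'   nameless areas, malformed optional attributes) become warnings.
#' @param keep_unknown keep unknown clade children as opaque pass-through
#'   fragments re-emitted on write (lenient mode only).
#' @return a list of class `rp_parse_options`.
#' @export
rp_parse_options <- function(strict = TRUE, keep_unknown = !strict) {
  structure(list(strict = isTRUE(strict), keep_unknown = isTRUE(keep_unknown)),
            class = "rp_parse_options")
}

# compact, unformatted serialization of one element (verbatim content)
.xml_node_string <- function(node) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  xml2::write_xml(node, con, options = "no_declaration")
  rawToChar(rawConnectionValue(con))
}

.issue_collector <- function() {
  env <- new.env(parent = emptyenv())
  env$issues <- list()
  env
}

.add_issue <- function(col, severity, path, message) {
  col$issues[[length(col$issues) + 1L]] <-
    list(severity = severity, xml_path = path, message = message)
  invisible(NULL)
}

.issues_df <- function(col) {
  if (!length(col$issues))
    return(data.frame(severity = character(), xml_path = character(),
                      message = character(), stringsAsFactors = FALSE))
  data.frame(
    severity = vapply(col$issues, `[[`, "", "severity"),
    xml_path = vapply(col$issues, `[[`, "", "xml_path"),
    message  = vapply(col$issues, `[[`, "", "message"),
    stringsAsFactors = FALSE)
}

#' Parse issues attached to a document
#'
#' @param doc a document returned by [read_recphylo()].
#' @return a data frame with columns severity, xml_path, message.
#' @export
rp_issues <- function(doc) {
  attr(doc, "issues") %||%
    data.frame(severity = character(), xml_path = character(),
               message = character(), stringsAsFactors = FALSE)
}

#' Read a recPhyloXML document
#'
#' Parses a `<recPhylo>` document into the in-memory model, checking the
#' local tag grammar on the way: at most one `<spTree>`, at least one
#' `<recGeneTree>`, every `<eventsRec>` a run of `transferBack` events
#' closed by exactly one terminal event, and clade arity matching the
#' terminal event. Grammar violations are errors in both modes; cosmetic
#' deviations are warnings in lenient mode. Warnings are attached to the
#' result (see [rp_issues()]).
#'
#' @param source a file path, connection, or a length-one character string
#'   containing XML.
#' @param options an [rp_parse_options()] object.
#' @return an [rp_document] with an `issues` attribute.
#' @examples
#' xml <- paste0(
#'   '<recPhylo><recGeneTree><phylogeny rooted="true"><clade>',
#'   '<name>gene_seq_1</name>',
#'   '<eventsRec><leaf speciesLocation="C"></leaf></eventsRec>',
#'   '</clade></phylogeny></recGeneTree></recPhylo>')
#' doc <- read_recphylo(xml)
#' @export
read_recphylo <- function(source, options = rp_parse_options()) {
  stopifnot(inherits(options, "rp_parse_options"))
  x <- tryCatch(xml2::read_xml(source),
                error = function(e) stop("malformed XML: ",
                                         conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(x)
  col <- .issue_collector()
  if (xml2::xml_name(x) != "recPhylo")
    stop("root tag must be <recPhylo>, found <", xml2::xml_name(x), ">",
         call. = FALSE)
  kids <- xml2::xml_children(x)
  names_k <- xml2::xml_name(kids)
  sp_idx <- which(names_k == "spTree")
  gt_idx <- which(names_k == "recGeneTree")
  other  <- setdiff(seq_along(kids), c(sp_idx, gt_idx))
  if (length(other)) {
    msg <- paste0("unexpected element(s) under <recPhylo>: ",
                  paste(unique(names_k[other]), collapse = ", "))
    if (options$strict) stop(msg, call. = FALSE)
    .add_issue(col, "warning", "/recPhylo", msg)
  }
  if (length(sp_idx) > 1L)
    stop("a document may contain at most one <spTree>", call. = FALSE)
  if (length(gt_idx) < 1L)
    stop("a document must contain at least one <recGeneTree>", call. = FALSE)

  species_tree <- NULL
  if (length(sp_idx) == 1L) {
    phy <- .single_phylogeny(kids[[sp_idx]], "/recPhylo/spTree")
    species_tree <- .parse_species_clade(
      .root_clade(phy, "/recPhylo/spTree/phylogeny"),
      "/recPhylo/spTree/phylogeny/clade", options, col)
  }
  gene_trees <- lapply(seq_along(gt_idx), function(i) {
    base <- sprintf("/recPhylo/recGeneTree[%d]", i)
    phy <- .single_phylogeny(kids[[gt_idx[i]]], base)
    rooted <- xml2::xml_attr(phy, "rooted")
    if (is.na(rooted) || tolower(rooted) != "true") {
      msg <- "reconciled gene trees must be rooted (phylogeny rooted=\"true\")"
      if (options$strict) stop(msg, " at ", base, call. = FALSE)
      .add_issue(col, "warning", paste0(base, "/phylogeny"), msg)
    }
    .parse_gene_clade(.root_clade(phy, paste0(base, "/phylogeny")),
                      paste0(base, "/phylogeny/clade"), options, col)
  })

  doc <- rp_document(gene_trees, species_tree)
  attr(doc, "issues") <- .issues_df(col)
  doc
}

.single_phylogeny <- function(el, path) {
  phys <- xml2::xml_find_all(el, "./phylogeny")
  if (length(phys) != 1L)
    stop("expected exactly one <phylogeny> under ", path, call. = FALSE)
  phys[[1L]]
}

.root_clade <- function(phy, path) {
  clades <- xml2::xml_find_all(phy, "./clade")
  if (length(clades) != 1L)
    stop("expected exactly one root <clade> under ", path, call. = FALSE)
  clades[[1L]]
}

.parse_num_attr <- function(el, name, path, options, col, integer = FALSE) {
  v <- xml2::xml_attr(el, name)
  if (is.na(v)) return(NULL)
  n <- suppressWarnings(as.numeric(v))
  bad <- is.na(n) || (integer && n != floor(n))
  if (bad) {
    msg <- paste0("attribute ", name, "='", v, "' is not a valid ",
                  if (integer) "integer" else "number")
    if (options$strict) stop(msg, " at ", path, call. = FALSE)
    .add_issue(col, "warning", path, paste0(msg, "; dropped"))
    return(NULL)
  }
  if (integer) as.integer(n) else n
}

.parse_events <- function(ev_el, path, options, col) {
  kids <- xml2::xml_children(ev_el)
  if (!length(kids))
    stop("<eventsRec> must contain at least one event at ", path,
         call. = FALSE)
  lapply(seq_along(kids), function(i) {
    el <- kids[[i]]
    type <- xml2::xml_name(el)
    epath <- paste0(path, "/", type)
    if (!type %in% rp_event_types())
      stop("unknown event tag <", type, "> at ", epath, call. = FALSE)
    args <- list(
      type = type,
      species_location = {
        v <- xml2::xml_attr(el, "speciesLocation"); if (is.na(v)) NULL else v
      },
      destination_species = {
        v <- xml2::xml_attr(el, "destinationSpecies"); if (is.na(v)) NULL else v
      },
      confidence = .parse_num_attr(el, "confidence", epath, options, col),
      time_slice = .parse_num_attr(el, "timeSlice", epath, options, col,
                                   integer = TRUE),
      gene_name = {
        v <- xml2::xml_attr(el, "geneName"); if (is.na(v)) NULL else v
      })
    tryCatch(do.call(rp_event, args),
             error = function(e) stop(conditionMessage(e), " at ", epath,
                                      call. = FALSE))
  })
}

.parse_geography <- function(geo_el, path, options, col) {
  areas <- xml2::xml_find_all(geo_el, "./area")
  lapply(seq_along(areas), function(i) {
    a <- areas[[i]]
    apath <- sprintf("%s/area[%d]", path, i)
    nm <- xml2::xml_find_first(a, "./name")
    if (inherits(nm, "xml_missing")) {
      msg <- "<area> without a <name>"
      if (options$strict) stop(msg, " at ", apath, call. = FALSE)
      .add_issue(col, "warning", apath,
                 paste0(msg, "; placeholder name assigned"))
      area_name <- sprintf("unnamed_area_%d", i)
    } else area_name <- xml2::xml_text(nm)
    txt_or_null <- function(xp) {
      n <- xml2::xml_find_first(a, xp)
      if (inherits(n, "xml_missing")) NULL else xml2::xml_text(n)
    }
    val <- txt_or_null("./value")
    kml <- xml2::xml_find_first(a, "./kml")
    kml_payload <- if (inherits(kml, "xml_missing")) NULL else
      paste(vapply(xml2::xml_children(kml), .xml_node_string, ""),
            collapse = "")
    rp_geography(area_name,
                 description = txt_or_null("./description"),
                 value = if (is.null(val)) NULL
                         else suppressWarnings(as.numeric(val)),
                 source = txt_or_null("./source"),
                 kml_payload = kml_payload)
  })
}

#' Read the geographic annotations of a clade element
#'
#' Low-level access to the `<geography>` child of a clade: one annotation
#' per `<area>` in document order; the KML payload, when present, is kept
#' byte-verbatim.
#'
#' @param clade_el an `xml2` node for a `<clade>` element.
#' @param options an [rp_parse_options()] object.
#' @return list of [rp_geography] (empty when the clade has no geography).
#' @export
read_geography <- function(clade_el, options = rp_parse_options()) {
  col <- .issue_collector()
  geo <- xml2::xml_find_first(clade_el, "./geography")
  if (inherits(geo, "xml_missing")) return(list())
  .parse_geography(geo, "clade/geography", options, col)
}

.KNOWN_GENE_TAGS <- c("name", "branch_length", "confidence", "eventsRec",
                      "geography", "clade")
.KNOWN_SP_TAGS   <- c("name", "branch_length", "confidence", "geography",
                      "clade")

.unknown_tags <- function(el, known, path, options, col) {
  kids <- xml2::xml_children(el)
  unk <- kids[!xml2::xml_name(kids) %in% known]
  if (!length(unk)) return(character())
  nms <- unique(xml2::xml_name(unk))
  msg <- paste0("unknown clade element(s): ", paste(nms, collapse = ", "))
  if (options$strict) stop(msg, " at ", path, call. = FALSE)
  if (options$keep_unknown) {
    .add_issue(col, "warning", path, paste0(msg, "; kept verbatim"))
    vapply(unk, .xml_node_string, "")
  } else {
    .add_issue(col, "warning", path, paste0(msg, "; dropped"))
    character()
  }
}

.clade_basics <- function(el, path, options, col) {
  nm <- xml2::xml_find_first(el, "./name")
  name <- if (inherits(nm, "xml_missing")) "" else xml2::xml_text(nm)
  bl <- .parse_num_attr(el, "branch_length", path, options, col)
  if (is.null(bl)) {
    bel <- xml2::xml_find_first(el, "./branch_length")
    if (!inherits(bel, "xml_missing"))
      bl <- suppressWarnings(as.numeric(xml2::xml_text(bel)))
  }
  conf <- xml2::xml_find_first(el, "./confidence")
  support <- if (inherits(conf, "xml_missing")) NULL else
    suppressWarnings(as.numeric(xml2::xml_text(conf)))
  geo <- xml2::xml_find_first(el, "./geography")
  geography <- if (inherits(geo, "xml_missing")) list() else
    .parse_geography(geo, paste0(path, "/geography"), options, col)
  list(name = name, branch_length = bl, support = support,
       geography = geography)
}

.parse_gene_clade <- function(el, path, options, col) {
  b <- .clade_basics(el, path, options, col)
  extra <- .unknown_tags(el, .KNOWN_GENE_TAGS, path, options, col)
  ev <- xml2::xml_find_all(el, "./eventsRec")
  if (length(ev) != 1L)
    stop("each gene clade requires exactly one <eventsRec> at ", path,
         call. = FALSE)
  events <- .parse_events(ev[[1L]], paste0(path, "/eventsRec"), options, col)
  sub <- xml2::xml_find_all(el, "./clade")
  children <- lapply(seq_along(sub), function(i)
    .parse_gene_clade(sub[[i]], sprintf("%s/clade[%d]", path, i),
                      options, col))
  tryCatch(
    rp_gene_node(events, children = children, name = b$name,
                 branch_length = b$branch_length, support = b$support,
                 geography = b$geography, extra_xml = extra),
    error = function(e) stop(conditionMessage(e), " at ", path,
                             call. = FALSE))
}

.parse_species_clade <- function(el, path, options, col) {
  b <- .clade_basics(el, path, options, col)
  extra <- .unknown_tags(el, .KNOWN_SP_TAGS, path, options, col)
  sub <- xml2::xml_find_all(el, "./clade")
  children <- lapply(seq_along(sub), function(i)
    .parse_species_clade(sub[[i]], sprintf("%s/clade[%d]", path, i),
                         options, col))
  tryCatch(
    rp_species_node(b$name, children = children,
                    branch_length = b$branch_length,
                    geography = b$geography, extra_xml = extra),
    error = function(e) stop(conditionMessage(e), " at ", path,
                             call. = FALSE))
}
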