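# Deterministic serializer for recPhyloXML. Output is plain UTF-8 with
# two-space indentation and a fixed attribute order
# (speciesLocation/destinationSpecies first), so identical documents always
# serialize to identical bytes and write->read->write is byte-stable.

.xml_escape <- function(x, attr = FALSE) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  if (attr) x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

.fmt_num <- function(x) {
  format(x, digits = 15, trim = TRUE, scientific = FALSE)
}

#' Write a recPhyloXML document
#'
#' Serializes a document to recPhyloXML: the species tree first (when
#' present), then the gene trees in document order, each gene-tree
#' `<phylogeny>` carrying `rooted="true"`. Optional attributes are emitted
#' only when present. Output from this writer re-parses to a structurally
#' equal document and is byte-stable under write/read cycles.
#'
#' @param doc an [rp_document].
#' @param file output path or connection; `NULL` returns the XML as a
#'   single character string.
#' @param namespace optional namespace URI to declare on the root element
#'   (none by default).
#' @return the XML string, invisibly when written to a file.
#' @export
write_recphylo <- function(doc, file = NULL, namespace = NULL) {
  stopifnot(inherits(doc, "rp_document"))
  out <- character()
  push <- function(...) out[[length(out) + 1L]] <<- paste0(...)
  push('<?xml version="1.0" encoding="UTF-8"?>')
  push('<recPhylo',
       if (!is.null(namespace))
         paste0(' xmlns="', .xml_escape(namespace, attr = TRUE), '"'),
       '>')
  if (!is.null(doc$species_tree)) {
    push('  <spTree>')
    push('    <phylogeny>')
    out <- c(out, .ser_species_clade(doc$species_tree, 6L))
    push('    </phylogeny>')
    push('  </spTree>')
  }
  for (g in doc$gene_trees) {
    push('  <recGeneTree>')
    push('    <phylogeny rooted="true">')
    out <- c(out, .ser_gene_clade(g, 6L))
    push('    </phylogeny>')
    push('  </recGeneTree>')
  }
  push('</recPhylo>')
  xml <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(file)) return(xml)
  if (is.character(file)) {
    con <- file(file, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(xml), con)
  } else {
    writeLines(xml, file, sep = "")
  }
  invisible(xml)
}

.ser_event <- function(e, ind) {
  attrs <- character()
  if (!is.null(e$species_location))
    attrs <- c(attrs, paste0('speciesLocation="',
                             .xml_escape(e$species_location, TRUE), '"'))
  if (!is.null(e$destination_species))
    attrs <- c(attrs, paste0('destinationSpecies="',
                             .xml_escape(e$destination_species, TRUE), '"'))
  if (!is.null(e$confidence))
    attrs <- c(attrs, paste0('confidence="', .fmt_num(e$confidence), '"'))
  if (!is.null(e$time_slice))
    attrs <- c(attrs, paste0('timeSlice="', e$time_slice, '"'))
  if (!is.null(e$gene_name))
    attrs <- c(attrs, paste0('geneName="',
                             .xml_escape(e$gene_name, TRUE), '"'))
  paste0(strrep(" ", ind), "<", e$type,
         if (length(attrs)) paste0(" ", paste(attrs, collapse = " ")),
         "></", e$type, ">")
}

.ser_geography <- function(geos, ind) {
  sp <- strrep(" ", ind)
  out <- paste0(sp, "<geography>")
  for (g in geos) {
    out <- c(out, paste0(sp, "  <area>"))
    out <- c(out, paste0(sp, "    <name>", .xml_escape(g$area_name),
                         "</name>"))
    if (!is.null(g$description))
      out <- c(out, paste0(sp, "    <description>",
                           .xml_escape(g$description), "</description>"))
    if (!is.null(g$value))
      out <- c(out, paste0(sp, "    <value>", .fmt_num(g$value), "</value>"))
    if (!is.null(g$source))
      out <- c(out, paste0(sp, "    <source>", .xml_escape(g$source),
                           "</source>"))
    if (!is.null(g$kml_payload))
      out <- c(out, paste0(sp, "    <kml>", g$kml_payload, "</kml>"))
    out <- c(out, paste0(sp, "  </area>"))
  }
  c(out, paste0(sp, "</geography>"))
}

.ser_clade_open <- function(node, ind) {
  sp <- strrep(" ", ind)
  bl <- if (!is.null(node$branch_length))
    paste0(' branch_length="', .fmt_num(node$branch_length), '"') else ""
  out <- paste0(sp, "<clade", bl, ">")
  if (nzchar(node$name))
    out <- c(out, paste0(sp, "  <name>", .xml_escape(node$name), "</name>"))
  out
}

.ser_gene_clade <- function(node, ind) {
  sp <- strrep(" ", ind)
  out <- .ser_clade_open(node, ind)
  if (!is.null(node$support))
    out <- c(out, paste0(sp, "  <confidence>", .fmt_num(node$support),
                         "</confidence>"))
  out <- c(out, paste0(sp, "  <eventsRec>"))
  for (e in node$events) out <- c(out, .ser_event(e, ind + 4L))
  out <- c(out, paste0(sp, "  </eventsRec>"))
  if (length(node$geography))
    out <- c(out, .ser_geography(node$geography, ind + 2L))
  for (frag in node$extra_xml) out <- c(out, paste0(sp, "  ", frag))
  for (ch in node$children) out <- c(out, .ser_gene_clade(ch, ind + 2L))
  c(out, paste0(sp, "</clade>"))
}

.ser_species_clade <- function(node, ind) {
  sp <- strrep(" ", ind)
  out <- .ser_clade_open(node, ind)
  if (length(node$geography))
    out <- c(out, .ser_geography(node$geography, ind + 2L))
  for (frag in node$extra_xml) out <- c(out, paste0(sp, "  ", frag))
  for (ch in node$children) out <- c(out, .ser_species_clade(ch, ind + 2L))
  c(out, paste0(sp, "</clade>"))
}
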