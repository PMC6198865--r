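# SVG visualization: the species tree drawn as nested tubes (time running
# left to right, root at the left), the gene tree embedded inside with one
# glyph per event. Layout is computed first as plain coordinates so that
# geometric properties (anchor containment, tube nesting) can be asserted
# numerically without parsing SVG.

.RP_GLYPH_CLASS <- function(type) paste0("event-", type)

#' Compute a deterministic layout for a reconciliation document
#'
#' Species leaves are evenly spaced vertically; each species tube's
#' vertical band spans the bands of its children, and its height grows
#' with the number of gene lineages it hosts. Horizontal positions come
#' from topological depth (leaf tubes extend to the right margin);
#' `bifurcationOut` lineages live in a reserved margin band above the
#' species tubes. Every gene node receives an anchor point inside its
#' species tube and a polyline route to each child, with inter-tube
#' transfer segments tagged as such.
#'
#' @param doc an [rp_document] with a species tree, passing strict
#'   validation.
#' @param lane_height vertical pixels per gene lane.
#' @param slice_width horizontal pixels per species-tree depth unit.
#' @return an object of class `rp_layout` with components `species`
#'   (tube rectangles), `anchors`, `events` (glyph positions) and `routes`
#'   (segments with a `kind` of `"intra"` or `"transfer"`).
#' @export
rp_layout <- function(doc, lane_height = 14, slice_width = 90) {
  stopifnot(inherits(doc, "rp_document"))
  if (is.null(doc$species_tree))
    stop("layout requires a species tree; draw plain gene trees with an ",
         "ordinary phylogram instead", call. = FALSE)
  rep1 <- validate_structure(doc)
  if (!rep1$valid)
    stop("document fails structural validation; layout refused",
         call. = FALSE)
  rel <- .sp_relations(doc$species_tree)
  rmap <- build_reconciliation_map(doc)

  # gene nodes per species, deterministic (tree index, preorder) order
  per_sp <- split(seq_len(nrow(rmap)), rmap$species)
  lanes_of <- function(s) length(per_sp[[s]] %||% integer())

  # vertical bands: leaves stacked, internals span their children
  depth <- rel$depth
  max_depth <- max(depth)
  band <- list()
  y_cursor <- 0
  gap <- lane_height
  assign_band <- function(name) {
    kids <- rel$children[[name]]
    if (!length(kids)) {
      h <- lane_height * (1 + max(1L, lanes_of(name)))
      band[[name]] <<- c(y_cursor, y_cursor + h)
      y_cursor <<- y_cursor + h + gap
    } else {
      for (k in kids) assign_band(k)
      lo <- min(vapply(kids, function(k) band[[k]][1L], 0))
      hi <- max(vapply(kids, function(k) band[[k]][2L], 0))
      band[[name]] <<- c(lo, hi)
    }
  }
  margin_h <- lane_height *
    (2 + sum(rmap$species == rp_unsampled()))   # reserved unsampled band
  y_cursor <- margin_h + gap
  assign_band(rel$names[1L])

  x_node <- vapply(rel$names, function(s) {
    if (!length(rel$children[[s]])) (max_depth + 1) * slice_width
    else (depth[[s]] + 1) * slice_width
  }, 0)
  x_start <- vapply(rel$names, function(s) {
    p <- rel$parent[[s]]
    if (is.na(p)) 0 else x_node[[p]]
  }, 0)

  species <- data.frame(
    name = rel$names,
    x0 = unname(x_start[rel$names]),
    x1 = unname(x_node[rel$names]),
    y0 = vapply(rel$names, function(s) band[[s]][1L], 0),
    y1 = vapply(rel$names, function(s) band[[s]][2L], 0),
    stringsAsFactors = FALSE)
  rownames(species) <- species$name
  width <- (max_depth + 1) * slice_width + slice_width / 2
  unsampled_rect <- c(0, width, 0, margin_h)

  # anchors: lane y within the species band; x by position along the branch
  node_tab <- rmap
  node_tab$lane <- NA_integer_
  for (s in names(per_sp)) {
    idx <- per_sp[[s]]
    node_tab$lane[idx] <- seq_along(idx)
  }
  # within-branch rank: count ancestors of the node mapped to the same
  # species in the same gene tree (chained duplications/transfers spread out)
  anchor_xy <- function(i) {
    s <- node_tab$species[i]
    lane <- node_tab$lane[i]
    if (s == rp_unsampled()) {
      n <- length(per_sp[[s]])
      x <- unsampled_rect[1L] +
        (unsampled_rect[2L] - unsampled_rect[1L]) * lane / (n + 1)
      y <- unsampled_rect[3L] +
        (unsampled_rect[4L] - unsampled_rect[3L]) / 2
      return(c(x, y))
    }
    r <- species[s, ]
    n <- length(per_sp[[s]])
    y <- r$y0 + (r$y1 - r$y0) * lane / (n + 1)
    ti <- node_tab$gene_tree_index[i]
    path <- node_tab$node_path[i]
    node <- .node_at(doc$gene_trees[[ti]], path)
    tt <- rp_terminal_event(node)$type
    x <- if (tt %in% c("speciation", "leaf")) r$x1
         else r$x0 + (r$x1 - r$x0) * lane / (n + 1)
    c(x, y)
  }
  xy <- t(vapply(seq_len(nrow(node_tab)), anchor_xy, c(0, 0)))
  node_tab$x <- xy[, 1L]
  node_tab$y <- xy[, 2L]

  key <- paste(node_tab$gene_tree_index, node_tab$node_path)
  lookup <- stats::setNames(seq_len(nrow(node_tab)), key)

  events <- list()
  routes <- list()
  for (ti in seq_along(doc$gene_trees)) {
    for (w in rp_walk(doc$gene_trees[[ti]])) {
      i <- lookup[[paste(ti, w$path)]]
      ax <- node_tab$x[i]; ay <- node_tab$y[i]
      evs <- w$node$events
      nvs <- length(evs)
      for (k in seq_len(nvs)) {
        off <- (nvs - k) * 10        # leading transferBacks sit left
        events[[length(events) + 1L]] <- list(
          tree = ti, path = w$path, seq_index = k, type = evs[[k]]$type,
          x = ax - off, y = ay)
      }
      for (ci in seq_along(w$node$children)) {
        cp <- if (nzchar(w$path)) paste0(w$path, ".", ci)
              else as.character(ci)
        j <- lookup[[paste(ti, cp)]]
        cx <- node_tab$x[j]; cy <- node_tab$y[j]
        child <- w$node$children[[ci]]
        is_transfer <-
          child$events[[1L]]$type == "transferBack" ||
          rp_terminal_event(child)$type == "bifurcationOut" ||
          rp_terminal_event(w$node)$type == "bifurcationOut"
        segs <- if (is_transfer) {
          data.frame(x0 = ax, y0 = ay, x1 = cx, y1 = cy,
                     kind = "transfer", stringsAsFactors = FALSE)
        } else {
          data.frame(x0 = c(ax, ax), y0 = c(ay, cy),
                     x1 = c(ax, cx), y1 = c(cy, cy),
                     kind = "intra", stringsAsFactors = FALSE)
        }
        segs$tree <- ti
        segs$parent_path <- w$path
        segs$child_path <- cp
        routes[[length(routes) + 1L]] <- segs
      }
    }
  }
  ev_df <- data.frame(
    tree = vapply(events, `[[`, 0L, "tree"),
    path = vapply(events, `[[`, "", "path"),
    seq_index = vapply(events, `[[`, 0L, "seq_index"),
    type = vapply(events, `[[`, "", "type"),
    x = vapply(events, `[[`, 0, "x"),
    y = vapply(events, `[[`, 0, "y"),
    stringsAsFactors = FALSE)
  structure(
    list(species = species, anchors = node_tab, events = ev_df,
         routes = if (length(routes)) do.call(rbind, routes) else
           data.frame(),
         unsampled_rect = unsampled_rect,
         width = width,
         height = y_cursor + lane_height),
    class = "rp_layout")
}

.node_at <- function(root, path) {
  if (!nzchar(path)) return(root)
  for (i in as.integer(strsplit(path, ".", fixed = TRUE)[[1L]]))
    root <- root$children[[i]]
  root
}

.rp_default_theme <- function() {
  list(
    tube_fill = "#222222", tube_opacity = "0.15",
    line_color = "#1f6fb4", line_width = 1.6,
    glyph_size = 6,
    colors = c(leaf = "#1b7837", speciation = "#1f6fb4",
               loss = "#c51b1b", duplication = "#e08b00",
               branchingOut = "#7b3294", transferBack = "#7b3294",
               bifurcationOut = "#5e5e5e"))
}

#' Render a layout as SVG
#'
#' Glyph conventions: star = start of a gene lineage, square =
#' duplication, cross = loss, diamond = transfer departure
#' (`branchingOut`), triangle = transfer arrival (`transferBack`), circle =
#' speciation (a library convention: the format's figures leave the
#' speciation glyph unspecified), dot = extant leaf, open diamond =
#' `bifurcationOut`. Every glyph carries a stable `id` and a CSS class
#' `event-<type>`, so the color scheme can be restyled after the fact.
#'
#' @param layout an `rp_layout`.
#' @param theme named list overriding [.rp_default_theme()] entries
#'   (colors, stroke widths, glyph size).
#' @return a single SVG 1.1 string.
#' @export
rp_svg <- function(layout, theme = list()) {
  stopifnot(inherits(layout, "rp_layout"))
  th <- utils::modifyList(.rp_default_theme(), theme)
  g <- th$glyph_size
  out <- character()
  push <- function(...) out[[length(out) + 1L]] <<- paste0(...)
  push(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                      'width="%s" height="%s" viewBox="0 0 %s %s">'),
               .fmt_num(layout$width), .fmt_num(layout$height),
               .fmt_num(layout$width), .fmt_num(layout$height)))
  css <- c(
    sprintf(".species-tube{fill:%s;fill-opacity:%s;}", th$tube_fill,
            th$tube_opacity),
    sprintf(".gene-edge{stroke:%s;stroke-width:%s;fill:none;}",
            th$line_color, .fmt_num(th$line_width)),
    ".gene-edge-transfer{stroke-dasharray:4 3;}",
    vapply(names(th$colors), function(t)
      sprintf(".event-%s{stroke:%s;fill:%s;}", t, th$colors[[t]],
              th$colors[[t]]), ""),
    ".event-bifurcationOut{fill:none;}",
    ".lineage-start{fill:#000000;}")
  push("<style>", paste(css, collapse = ""), "</style>")

  sp <- layout$species
  for (i in seq_len(nrow(sp)))
    push(sprintf(paste0('<rect class="species-tube" id="tube-%s" x="%s" ',
                        'y="%s" width="%s" height="%s"/>'),
                 .svg_id(sp$name[i]), .fmt_num(sp$x0[i]),
                 .fmt_num(sp$y0[i]), .fmt_num(sp$x1[i] - sp$x0[i]),
                 .fmt_num(sp$y1[i] - sp$y0[i])))
  # species labels at tube top-right corner
  for (i in seq_len(nrow(sp)))
    push(sprintf('<text x="%s" y="%s" font-size="11">%s</text>',
                 .fmt_num(sp$x1[i] - 4), .fmt_num(sp$y0[i] + 11),
                 .xml_escape(sp$name[i])))

  r <- layout$routes
  if (nrow(r))
    for (i in seq_len(nrow(r)))
      push(sprintf(paste0('<line class="gene-edge%s" x1="%s" y1="%s" ',
                          'x2="%s" y2="%s"/>'),
                   if (r$kind[i] == "transfer") " gene-edge-transfer"
                   else "",
                   .fmt_num(r$x0[i]), .fmt_num(r$y0[i]),
                   .fmt_num(r$x1[i]), .fmt_num(r$y1[i])))

  ev <- layout$events
  for (i in seq_len(nrow(ev))) {
    id <- sprintf("evt-%d-%s-%d", ev$tree[i],
                  if (nzchar(ev$path[i])) .svg_id(ev$path[i]) else "root",
                  ev$seq_index[i])
    push(.glyph_svg(ev$type[i], ev$x[i], ev$y[i], g, id))
    if (!nzchar(ev$path[i]) && ev$seq_index[i] == 1L)
      push(.star_svg(ev$x[i] - 2.2 * g, ev$y[i], g,
                     sprintf("start-%d", ev$tree[i])))
  }
  push("</svg>")
  paste0(paste(out, collapse = "\n"), "\n")
}

.svg_id <- function(x) gsub("[^A-Za-z0-9_-]", "_", x)

.glyph_svg <- function(type, x, y, g, id) {
  cls <- .RP_GLYPH_CLASS(type)
  h <- g / 2
  switch(type,
    duplication = sprintf(
      '<rect class="%s" id="%s" x="%s" y="%s" width="%s" height="%s"/>',
      cls, id, .fmt_num(x - h), .fmt_num(y - h), .fmt_num(g), .fmt_num(g)),
    loss = sprintf(
      '<path class="%s" id="%s" d="M %s %s L %s %s M %s %s L %s %s"/>',
      cls, id, .fmt_num(x - h), .fmt_num(y - h), .fmt_num(x + h),
      .fmt_num(y + h), .fmt_num(x - h), .fmt_num(y + h), .fmt_num(x + h),
      .fmt_num(y - h)),
    branchingOut = ,
    bifurcationOut = sprintf(
      '<polygon class="%s" id="%s" points="%s,%s %s,%s %s,%s %s,%s"/>',
      cls, id, .fmt_num(x), .fmt_num(y - h), .fmt_num(x + h), .fmt_num(y),
      .fmt_num(x), .fmt_num(y + h), .fmt_num(x - h), .fmt_num(y)),
    transferBack = sprintf(
      '<polygon class="%s" id="%s" points="%s,%s %s,%s %s,%s"/>',
      cls, id, .fmt_num(x - h), .fmt_num(y - h), .fmt_num(x + h),
      .fmt_num(y), .fmt_num(x - h), .fmt_num(y + h)),
    speciation = sprintf(
      '<circle class="%s" id="%s" cx="%s" cy="%s" r="%s" fill="none"/>',
      cls, id, .fmt_num(x), .fmt_num(y), .fmt_num(h)),
    leaf = sprintf(
      '<circle class="%s" id="%s" cx="%s" cy="%s" r="%s"/>',
      cls, id, .fmt_num(x), .fmt_num(y), .fmt_num(h * 0.7)))
}

.star_svg <- function(x, y, g, id) {
  h <- g / 2
  pts <- vapply(0:9, function(k) {
    r <- if (k %% 2 == 0) h else h / 2.5
    a <- pi / 2 + k * pi / 5
    paste0(.fmt_num(round(x + r * cos(a), 3)), ",",
           .fmt_num(round(y - r * sin(a), 3)))
  }, "")
  sprintf('<polygon class="lineage-start" id="%s" points="%s"/>',
          id, paste(pts, collapse = " "))
}

#' Draw a reconciliation document as SVG
#'
#' Convenience wrapper: [rp_layout()] then [rp_svg()].
#'
#' @param doc an [rp_document] with a species tree.
#' @param file optional output path; `NULL` returns the SVG string.
#' @param theme,lane_height,slice_width passed through.
#' @return the SVG string, invisibly when written to a file.
#' @export
rp_render_svg <- function(doc, file = NULL, theme = list(),
                          lane_height = 14, slice_width = 90) {
  svg <- rp_svg(rp_layout(doc, lane_height = lane_height,
                          slice_width = slice_width), theme = theme)
  if (is.null(file)) return(svg)
  writeLines(svg, file, sep = "")
  invisible(svg)
}
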