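# geometric checks on layouts and glyph counting in SVG text

count_glyphs <- function(svg, type) {
  lengths(regmatches(svg, gregexpr(sprintf('class="event-%s"', type),
                                   svg, fixed = TRUE)))
}

seg_in_rect <- function(x0, y0, x1, y1, r, eps = 1e-6) {
  inside <- function(x, y)
    x >= r$x0 - eps & x <= r$x1 + eps & y >= r$y0 - eps & y <= r$y1 + eps
  inside(x0, y0) && inside(x1, y1)
}

layout_containment_ok <- function(doc) {
  lay <- rp_layout(doc)
  sp <- lay$species
  anchors_ok <- all(vapply(seq_len(nrow(lay$anchors)), function(i) {
    a <- lay$anchors[i, ]
    if (a$species == rp_unsampled()) {
      u <- lay$unsampled_rect
      a$x >= u[1L] && a$x <= u[2L] && a$y >= u[3L] && a$y <= u[4L]
    } else {
      r <- sp[a$species, ]
      a$x >= r$x0 - 1e-6 && a$x <= r$x1 + 1e-6 &&
        a$y >= r$y0 - 1e-6 && a$y <= r$y1 + 1e-6
    }
  }, NA))
  routes_ok <- TRUE
  if (nrow(lay$routes)) {
    for (i in seq_len(nrow(lay$routes))) {
      s <- lay$routes[i, ]
      if (s$kind == "transfer") next          # declared inter-tube segment
      in_any <- any(vapply(seq_len(nrow(sp)), function(j)
        seg_in_rect(s$x0, s$y0, s$x1, s$y1, sp[j, ]), NA))
      if (!in_any) routes_ok <- FALSE
    }
  }
  anchors_ok && routes_ok
}
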