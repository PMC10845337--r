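# Deterministic 2D geometry for the three layout encodings of one contact.
#
# All coordinates live in the unit square [0,1]^2 (y up); the SVG writer
# flips y. Fills are category labels only ("light_gray", "dark_gray",
# "green", "none"); the concrete colors live in .layout_palette.

.layout_palette <- c(light_gray = "#d3d3d3",
                     dark_gray  = "#808080",
                     green      = "#2ca02c",
                     none       = "none")

# alternating diagonal shading: segment 1 light, segment 2 dark, ...
.diag_fill <- function(i) ifelse(i %% 2L == 1L, "light_gray", "dark_gray")

.new_geometry <- function(layout, n_segments, primitives) {
  structure(list(layout = layout, n_segments = n_segments,
                 primitives = primitives),
            class = "layout_geometry")
}

#' @export
print.layout_geometry <- function(x, ...) {
  fills <- vapply(x$primitives, function(p) p$fill, character(1))
  cat(sprintf("<layout_geometry: %s, %d segments, %d primitives (%d green)>\n",
              x$layout, x$n_segments, length(x$primitives),
              sum(fills == "green")))
  invisible(x)
}

# square cell primitive in grid coordinates (row i from top, column j);
# carries its matrix indices so layouts can be compared cell-for-cell
.cell <- function(i, j, n, fill, shape = "cell") {
  s <- 1 / n
  list(shape = shape, fill = fill, i = i, j = j,
       x = (j - 1) * s, y = 1 - i * s, w = s, h = s)
}

#' Full adjacency-matrix geometry of one contact
#'
#' An n-by-n grid with rows and columns indexed by segment. The two symmetric
#' cells (a, b) and (b, a) of the contact are green; diagonal cells carry the
#' alternating light/dark segment shading (light gray at segment 1);
#' remaining cells are unfilled outlines. Intrasegment contacts are not
#' represented, which is why the diagonal is available for the shading.
#'
#' @param ct One-row contact data frame (see [contact()]).
#' @param n_segments Chain length.
#' @return A `layout_geometry` object.
#' @export
matrix_geometry <- function(ct, n_segments = 8L) {
  stopifnot(nrow(ct) == 1L, ct$a >= 1L, ct$b <= n_segments, ct$a < ct$b)
  prim <- list()
  for (i in seq_len(n_segments)) {
    for (j in seq_len(n_segments)) {
      fill <- if (i == j) .diag_fill(i)
              else if ((i == ct$a && j == ct$b) || (i == ct$b && j == ct$a))
                "green"
              else "none"
      prim[[length(prim) + 1L]] <- .cell(i, j, n_segments, fill)
    }
  }
  .new_geometry("matrix", n_segments, prim)
}

#' Half-matrix geometry of one contact
#'
#' The upper triangle of the adjacency matrix, drawn as a 45-degree-rotated
#' triangle resting on a horizontal base row: the base row holds the
#' n alternately shaded segment cells (the rotated diagonal), and each pair
#' (i, j), i < j, becomes one diamond cell above the base, centred between
#' segments i and j at height proportional to their separation. Exactly the
#' contact's cell is green; the redundancy of the symmetric half is gone.
#'
#' @inheritParams matrix_geometry
#' @return A `layout_geometry` object.
#' @export
half_matrix_geometry <- function(ct, n_segments = 8L) {
  stopifnot(nrow(ct) == 1L, ct$a >= 1L, ct$b <= n_segments, ct$a < ct$b)
  n <- n_segments
  s <- 1 / n            # base cell width; diamond half-diagonal = s/2
  prim <- list()
  for (i in seq_len(n)) {  # shaded base: rotated diagonal cells
    prim[[length(prim) + 1L]] <-
      list(shape = "cell", fill = .diag_fill(i), i = i, j = i,
           x = (i - 1) * s, y = 0, w = s, h = s / 2)
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      fill <- if (i == ct$a && j == ct$b) "green" else "none"
      cx <- (i + j - 1) * s / 2          # midpoint between base cells i and j
      cy <- s / 2 + (j - i) * s / 2      # height grows with separation
      prim[[length(prim) + 1L]] <-
        list(shape = "triangle_cell", fill = fill, i = i, j = j,
             x = cx, y = cy, w = s, h = s)   # diamond centre + diagonals
    }
  }
  .new_geometry("half_matrix", n, prim)
}

# clockwise-from-top angle (radians) -> unit-circle point centred at (.5,.5)
.circ_point <- function(theta, r = 0.5) {
  c(x = 0.5 + r * sin(theta), y = 0.5 + r * cos(theta))
}

#' Circular layout geometry of one contact
#'
#' The n segments become equal arcs of an annulus on the unit circle,
#' alternately shaded, with segment 1 starting at twelve o'clock and the
#' numbering proceeding clockwise. The contact is drawn as a single green
#' chord joining the midpoints of its two arcs, and the two contact arcs are
#' themselves filled green.
#'
#' @inheritParams matrix_geometry
#' @return A `layout_geometry` object.
#' @export
circular_geometry <- function(ct, n_segments = 8L) {
  stopifnot(nrow(ct) == 1L, ct$a >= 1L, ct$b <= n_segments, ct$a < ct$b)
  n <- n_segments
  width <- 2 * pi / n
  r_outer <- 0.5
  r_inner <- 0.40
  prim <- list()
  for (i in seq_len(n)) {
    fill <- if (i == ct$a || i == ct$b) "green" else .diag_fill(i)
    prim[[length(prim) + 1L]] <-
      list(shape = "node_arc_segment", fill = fill, i = i, j = i,
           theta0 = (i - 1) * width, theta1 = i * width,
           r_inner = r_inner, r_outer = r_outer)
  }
  p1 <- .circ_point((ct$a - 0.5) * width, r_inner)
  p2 <- .circ_point((ct$b - 0.5) * width, r_inner)
  prim[[length(prim) + 1L]] <-
    list(shape = "chord", fill = "green", i = ct$a, j = ct$b,
         x1 = p1[["x"]], y1 = p1[["y"]], x2 = p2[["x"]], y2 = p2[["y"]])
  .new_geometry("circular", n, prim)
}

#' Layout geometry dispatcher
#'
#' @param layout One of `"circular"`, `"half_matrix"`, `"matrix"`.
#' @inheritParams matrix_geometry
#' @return A `layout_geometry` object.
#' @export
layout_geometry <- function(layout, ct, n_segments = 8L) {
  switch(match.arg(layout, c("circular", "half_matrix", "matrix")),
         circular = circular_geometry(ct, n_segments),
         half_matrix = half_matrix_geometry(ct, n_segments),
         matrix = matrix_geometry(ct, n_segments))
}

.svg_num <- function(x) {
  out <- formatC(x, format = "f", digits = 4)
  sub("^(-?\\d+)\\.0000$", "\\1", out)
}

.svg_primitive <- function(p, size) {
  fill <- .layout_palette[[p$fill]]
  stroke <- ' stroke="#555555" stroke-width="0.6"'
  flipy <- function(y) size * (1 - y)
  if (p$shape == "cell") {
    sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"%s/>',
            .svg_num(size * p$x), .svg_num(flipy(p$y + p$h)),
            .svg_num(size * p$w), .svg_num(size * p$h), fill, stroke)
  } else if (p$shape == "triangle_cell") {
    cx <- size * p$x; cy <- flipy(p$y)
    dx <- size * p$w / 2; dy <- size * p$h / 2
    pts <- sprintf("%s,%s %s,%s %s,%s %s,%s",
                   .svg_num(cx), .svg_num(cy - dy),
                   .svg_num(cx + dx), .svg_num(cy),
                   .svg_num(cx), .svg_num(cy + dy),
                   .svg_num(cx - dx), .svg_num(cy))
    sprintf('<polygon points="%s" fill="%s"%s/>', pts, fill, stroke)
  } else if (p$shape == "node_arc_segment") {
    pt <- function(theta, r) {
      q <- .circ_point(theta, r)
      c(size * q[["x"]], flipy(q[["y"]]))
    }
    o0 <- pt(p$theta0, p$r_outer); o1 <- pt(p$theta1, p$r_outer)
    i1 <- pt(p$theta1, p$r_inner); i0 <- pt(p$theta0, p$r_inner)
    large <- if ((p$theta1 - p$theta0) > pi) 1L else 0L
    d <- sprintf(paste0("M %s %s A %s %s 0 %d 1 %s %s L %s %s ",
                        "A %s %s 0 %d 0 %s %s Z"),
                 .svg_num(o0[1]), .svg_num(o0[2]),
                 .svg_num(size * p$r_outer), .svg_num(size * p$r_outer), large,
                 .svg_num(o1[1]), .svg_num(o1[2]),
                 .svg_num(i1[1]), .svg_num(i1[2]),
                 .svg_num(size * p$r_inner), .svg_num(size * p$r_inner), large,
                 .svg_num(i0[1]), .svg_num(i0[2]))
    sprintf('<path d="%s" fill="%s"%s/>', d, fill, stroke)
  } else if (p$shape == "chord") {
    sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="2.5"/>',
            .svg_num(size * p$x1), .svg_num(flipy(p$y1)),
            .svg_num(size * p$x2), .svg_num(flipy(p$y2)), fill)
  } else stop("unknown primitive shape: ", p$shape, call. = FALSE)
}

#' Write a layout geometry as SVG
#'
#' Serializes a geometry to a standalone SVG file. The output carries no
#' timestamps or random identifiers, so identical geometries always produce
#' byte-identical files.
#'
#' @param geometry A `layout_geometry`.
#' @param path Output file path.
#' @param size Canvas side length in SVG user units.
#' @return `path`, invisibly.
#' @export
write_svg <- function(geometry, path, size = 300) {
  stopifnot(inherits(geometry, "layout_geometry"))
  size <- as.integer(size)
  body <- vapply(geometry$primitives, .svg_primitive, character(1),
                 size = size)
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                            'width="%d" height="%d" viewBox="0 0 %d %d">'),
                     size, size, size, size),
             sprintf('<rect width="%d" height="%d" fill="#ffffff"/>',
                     size, size),
             body,
             '</svg>')
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
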