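#' Area enclosed by a closed polyline (shoelace formula)
#'
#' @param contour two-column matrix (x, y) of polygon vertices in order;
#'   the closing edge back to the first vertex is implied. Units mm.
#' @param check_simple verify the contour is non-self-intersecting
#'   (O(n^2) segment test) before computing.
#' @return Absolute enclosed area, mm^2, independent of orientation.
#' @export
polygon_area <- function(contour, check_simple = FALSE) {
  contour <- as_contour(contour)
  if (check_simple && !is_simple_polygon(contour))
    stop("contour is self-intersecting", call. = FALSE)
  x <- contour[, 1]; y <- contour[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' Area centroid of a closed polyline
#'
#' Centroid of the enclosed region (not the vertex mean), via the standard
#' shoelace moments.
#'
#' @inheritParams polygon_area
#' @return Numeric length-2 `(x, y)` in mm.
#' @export
polygon_centroid <- function(contour) {
  contour <- as_contour(contour)
  x <- contour[, 1]; y <- contour[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cross <- x * ys - xs * y
  a <- sum(cross) / 2
  if (abs(a) < 1e-14)
    stop("degenerate (zero-area) contour", call. = FALSE)
  c(sum((x + xs) * cross), sum((y + ys) * cross)) / (6 * a)
}

#' Perimeter of a closed polyline
#' @inheritParams polygon_area
#' @return Total edge length, mm.
#' @export
polygon_perimeter <- function(contour) {
  contour <- as_contour(contour)
  d <- rbind(diff(contour), contour[1, ] - contour[nrow(contour), ])
  sum(sqrt(rowSums(d^2)))
}

as_contour <- function(contour) {
  contour <- as.matrix(contour)
  if (ncol(contour) != 2 || nrow(contour) < 3)
    stop("a contour needs >= 3 vertices and 2 columns (x, y)", call. = FALSE)
  if (any(!is.finite(contour))) stop("non-finite contour coordinates", call. = FALSE)
  # drop a duplicated closing vertex if present
  n <- nrow(contour)
  if (all(abs(contour[1, ] - contour[n, ]) < 1e-12)) contour <- contour[-n, , drop = FALSE]
  unname(contour)
}

# Segment-pair intersection test for polygon simplicity. Adjacent edges
# (sharing a vertex) are skipped.
is_simple_polygon <- function(contour) {
  p <- as_contour(contour)
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    j <- seq.int(i + 2, n)
    j <- j[!(i == 1 & j == n)]  # edges n and 1 are adjacent
    if (!length(j)) next
    if (any(segments_cross(a[i, ], b[i, ], a[j, , drop = FALSE], b[j, , drop = FALSE])))
      return(FALSE)
  }
  TRUE
}

# Does segment p1-p2 properly cross any of the segments q1[k,]-q2[k,]?
segments_cross <- function(p1, p2, q1, q2) {
  d1 <- orient2d(q1, q2, p1)
  d2 <- orient2d(q1, q2, p2)
  d3 <- orient2d_single(p1, p2, q1)
  d4 <- orient2d_single(p1, p2, q2)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

orient2d <- function(a, b, p) {
  (b[, 1] - a[, 1]) * (p[2] - a[, 2]) - (b[, 2] - a[, 2]) * (p[1] - a[, 1])
}

orient2d_single <- function(p1, p2, q) {
  (p2[1] - p1[1]) * (q[, 2] - p1[2]) - (p2[2] - p1[2]) * (q[, 1] - p1[1])
}

# Vectorized point-in-polygon (pracma even-odd test).
points_in_polygon <- function(x, y, contour) {
  contour <- as_contour(contour)
  pracma::inpolygon(x, y, contour[, 1], contour[, 2], boundary = TRUE)
}

#' Circular contour helper
#'
#' @param r radius, mm.
#' @param n number of vertices.
#' @param center numeric length-2 center, mm.
#' @return An `n x 2` counter-clockwise contour matrix.
#' @export
circle_contour <- function(r, n = 96, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

#' Annular-sector contour helper
#'
#' Builds the closed polygon of an annular sector (the typical shape of a
#' calcification deposit in this package): inner arc from `theta0` to
#' `theta1` degrees at radius `r_in`, outer arc back at `r_out`.
#'
#' @param r_in,r_out inner/outer radii, mm (`r_out > r_in`).
#' @param theta0,theta1 start/end angles, degrees, counter-clockwise.
#' @param n_arc vertices per arc.
#' @param center numeric length-2 center, mm.
#' @return Contour matrix (counter-clockwise).
#' @export
sector_annulus_contour <- function(r_in, r_out, theta0, theta1,
                                   n_arc = 48, center = c(0, 0)) {
  stopifnot(r_out > r_in, r_in > 0, theta1 > theta0)
  th <- seq(theta0, theta1, length.out = n_arc) * pi / 180
  inner <- cbind(center[1] + r_in * cos(th), center[2] + r_in * sin(th))
  outer <- cbind(center[1] + r_out * cos(rev(th)), center[2] + r_out * sin(rev(th)))
  rbind(inner, outer)
}

#' Labeled cross-section geometry of one vessel slice
#'
#' Container for one planar slice: the lumen contour, the outer wall
#' contour, and zero or more calcification polygons lying in the wall
#' annulus; everything between lumen and outer wall that is not
#' calcification is fibrotic plaque. Coordinates in mm, contours
#' counter-clockwise in a slice-local frame.
#'
#' @param z axial position, mm.
#' @param lumen_contour,outer_contour closed contour matrices (x, y), mm.
#' @param calc_regions list of closed calcification polygons.
#' @param slice_index optional ordinal of the slice within its vessel.
#' @param validate check contour validity and containment of the lumen in
#'   the outer wall (vertex-wise).
#' @return Object of class `cross_section`.
#' @export
cross_section <- function(z, lumen_contour, outer_contour,
                          calc_regions = list(), slice_index = NA_integer_,
                          validate = TRUE) {
  lumen_contour <- as_contour(lumen_contour)
  outer_contour <- as_contour(outer_contour)
  calc_regions <- lapply(calc_regions, as_contour)
  if (validate) {
    if (!all(points_in_polygon(lumen_contour[, 1], lumen_contour[, 2], outer_contour)))
      stop("lumen contour is not inside the outer contour", call. = FALSE)
    for (k in seq_along(calc_regions)) {
      cr <- calc_regions[[k]]
      if (!all(points_in_polygon(cr[, 1], cr[, 2], outer_contour)))
        stop("calcification region ", k, " extends beyond the outer wall",
             call. = FALSE)
    }
  }
  structure(list(z = as.numeric(z), lumen_contour = lumen_contour,
                 outer_contour = outer_contour, calc_regions = calc_regions,
                 slice_index = slice_index),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> z = %.3f mm, lumen area %.3f mm^2, %d calcification region(s)\n",
              x$z, polygon_area(x$lumen_contour), length(x$calc_regions)))
  invisible(x)
}

#' Rasterize a cross section into a labeled mask
#'
#' Samples pixel centers on a regular grid covering the outer-wall bounding
#' box (one pixel of padding) and labels each pixel `0` background,
#' `1` lumen, `2` fibrotic, `3` calcification. With a pixel size larger
#' than the section the grid degenerates to a handful of pixels and may be
#' all background; no error is raised.
#'
#' @param section a [cross_section()].
#' @param pixel_size pixel edge length, mm (e.g. 0.0125).
#' @return Integer matrix of class `vessel_mask` with attributes `origin`
#'   (mm coordinates of the center of pixel `[1,1]`), `pixel_size`, and
#'   `palette` documenting the labels. Rows index x, columns y.
#' @export
rasterize_section <- function(section, pixel_size) {
  stopifnot(inherits(section, "cross_section"), pixel_size > 0)
  bb <- apply(section$outer_contour, 2, range)
  x0 <- bb[1, 1] - pixel_size; x1 <- bb[2, 1] + pixel_size
  y0 <- bb[1, 2] - pixel_size; y1 <- bb[2, 2] + pixel_size
  xs <- seq(x0 + pixel_size / 2, x1, by = pixel_size)
  ys <- seq(y0 + pixel_size / 2, y1, by = pixel_size)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  lab <- integer(length(gx))
  in_outer <- points_in_polygon(gx, gy, section$outer_contour)
  lab[in_outer] <- 2L
  io <- which(in_outer)
  if (length(io)) {
    in_lumen <- points_in_polygon(gx[io], gy[io], section$lumen_contour)
    lab[io[in_lumen]] <- 1L
  }
  for (cr in section$calc_regions) {
    cb <- apply(cr, 2, range)
    cand <- io[gx[io] >= cb[1, 1] & gx[io] <= cb[2, 1] &
               gy[io] >= cb[1, 2] & gy[io] <= cb[2, 2]]
    cand <- cand[lab[cand] == 2L]
    if (length(cand)) {
      inc <- points_in_polygon(gx[cand], gy[cand], cr)
      lab[cand[inc]] <- 3L
    }
  }
  m <- matrix(lab, nrow = length(xs), ncol = length(ys))
  structure(m, class = "vessel_mask",
            origin = c(xs[1], ys[1]), pixel_size = pixel_size,
            palette = c(background = 0L, lumen = 1L, fibrotic = 2L,
                        calcification = 3L))
}

#' Label areas of a rasterized mask
#'
#' Pixel-count areas (mm^2) per tissue label; used to cross-check
#' polygon-based areas.
#'
#' @param mask a `vessel_mask` from [rasterize_section()].
#' @return Named numeric vector (`lumen`, `fibrotic`, `calcification`).
#' @export
mask_areas <- function(mask) {
  px <- attr(mask, "pixel_size")^2
  c(lumen = sum(mask == 1L) * px,
    fibrotic = sum(mask == 2L) * px,
    calcification = sum(mask == 3L) * px)
}
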