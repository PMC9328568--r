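#' @keywords internal
"_PACKAGE"

FEATURE_NAMES <- c("area_a", "area_f", "area_c", "area_l",
                   "angle_c", "thickness_c", "arclength_c", "arclength_f")

# --- angular interval machinery ------------------------------------------

# Angle (degrees in [0, 360)) of points about an origin.
angle_deg <- function(x, y, origin) {
  (atan2(y - origin[2], x - origin[1]) * 180 / pi) %% 360
}

# Subtended angular intervals of one polygon about `origin`, as the union
# of per-edge spans (each edge contributes the shorter arc between its
# endpoint angles). Valid for radially compact regions that do not wrap
# more than 180 degrees per edge, which holds for any densely sampled
# deposit contour.
polygon_angular_intervals <- function(poly, origin) {
  poly <- as_contour(poly)
  a <- angle_deg(poly[, 1], poly[, 2], origin)
  a2 <- c(a[-1], a[1])
  d <- ((a2 - a + 180) %% 360) - 180
  lo <- ifelse(d >= 0, a, a2)
  len <- abs(d)
  cbind(start = lo, end = lo + len)
}

# Merge intervals (start, end) on the circle, degrees. Returns a matrix of
# disjoint non-wrapping intervals within [0, 360].
merge_circular_intervals <- function(iv, tol = 1e-9) {
  if (is.null(iv) || nrow(iv) == 0) return(matrix(numeric(), ncol = 2))
  # split wrapping intervals at 360
  keep <- iv[, 2] <= 360 + tol
  wrap <- iv[!keep, , drop = FALSE]
  iv <- rbind(iv[keep, , drop = FALSE],
              if (nrow(wrap)) cbind(wrap[, 1], 360),
              if (nrow(wrap)) cbind(0, wrap[, 2] - 360))
  iv[, 2] <- pmin(iv[, 2], 360)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1]) {
    last <- nrow(out)
    if (iv[k, 1] <= out[last, 2] + tol) {
      out[last, 2] <- max(out[last, 2], iv[k, 2])
    } else {
      out <- rbind(out, iv[k, ])
    }
  }
  # merge across the 0/360 seam
  if (nrow(out) > 1 && out[1, 1] <= tol && out[nrow(out), 2] >= 360 - tol) {
    out[1, 1] <- out[nrow(out), 1] - 360
    out <- out[-nrow(out), , drop = FALSE]
  }
  colnames(out) <- c("start", "end")
  out
}

# Union of the angular intervals subtended by all calcification regions at
# the lumen centroid. Matrix (start, end) in degrees; start may be negative
# for an interval crossing 0.
calc_angular_union <- function(section) {
  if (!length(section$calc_regions)) return(matrix(numeric(), ncol = 2))
  origin <- polygon_centroid(section$lumen_contour)
  iv <- do.call(rbind, lapply(section$calc_regions,
                              polygon_angular_intervals, origin = origin))
  merge_circular_intervals(iv)
}

angle_in_union <- function(theta, union_iv) {
  if (nrow(union_iv) == 0) return(rep(FALSE, length(theta)))
  hit <- rep(FALSE, length(theta))
  for (k in seq_len(nrow(union_iv))) {
    s <- union_iv[k, 1]; e <- union_iv[k, 2]
    th <- theta
    if (s < 0) th <- ifelse(th >= s %% 360, th - 360, th)
    hit <- hit | (th >= s - 1e-12 & th <= e + 1e-12)
  }
  hit
}

#' Calcification angle of a cross section
#'
#' Total angular measure (degrees) of the union of the angular intervals
#' subtended at the lumen centroid by all calcification regions. Multiple
#' deposits contribute the measure of the union of their (possibly
#' overlapping) intervals; a slice without calcification scores 0.
#'
#' @param section a [cross_section()].
#' @return Angle in degrees, within `[0, 360]`.
#' @export
calcification_angle <- function(section) {
  stopifnot(inherits(section, "cross_section"))
  u <- calc_angular_union(section)
  if (nrow(u) == 0) return(0)
  min(360, sum(u[, 2] - u[, 1]))
}

# Chord lengths of centroid rays through the calcification regions.
# Returns max over the sampled rays of the summed in-calcification length.
ray_calc_chords <- function(section, thetas) {
  origin <- polygon_centroid(section$lumen_contour)
  total <- numeric(length(thetas))
  dx <- cos(thetas * pi / 180); dy <- sin(thetas * pi / 180)
  for (poly in section$calc_regions) {
    poly <- as_contour(poly)
    p <- poly
    q <- poly[c(2:nrow(poly), 1), , drop = FALSE]
    rx <- q[, 1] - p[, 1]; ry <- q[, 2] - p[, 2]
    px <- p[, 1] - origin[1]; py <- p[, 2] - origin[2]
    # solve origin + t*d = p + s*r   (outer over rays x edges)
    denom <- outer(dx, ry) - outer(dy, rx)              # cross(d, r)
    tnum <- matrix(px * ry - py * rx, nrow = length(dx),
                   ncol = nrow(p), byrow = TRUE)        # cross(p - o, r)
    snum <- outer(dx, py) - outer(dy, px)               # cross(d, p - o) -> sign
    ok <- abs(denom) > 1e-14
    tt <- tnum / denom
    ss <- -snum / denom
    valid <- ok & ss >= 0 & ss < 1 & tt > 1e-12
    valid[is.na(valid)] <- FALSE
    tm <- tt
    tm[!valid] <- NA_real_
    cnt <- rowSums(valid)
    # fast path: a convex-along-the-ray region crossed exactly twice
    two <- cnt == 2
    if (any(two)) {
      td <- as.data.frame(tm[two, , drop = FALSE])
      lo <- do.call(pmin, c(td, na.rm = TRUE))
      hi <- do.call(pmax, c(td, na.rm = TRUE))
      total[two] <- total[two] + (hi - lo)
    }
    for (i in which(cnt > 2)) {
      ts <- sort(tm[i, !is.na(tm[i, ])])
      if (length(ts) %% 2 == 1) ts <- ts[-length(ts)]
      total[i] <- total[i] + sum(ts[seq(2, length(ts), by = 2)] -
                                 ts[seq(1, length(ts), by = 2)])
    }
  }
  total
}

#' Maximum radial calcification thickness
#'
#' Maximum, over a dense grid of rays from the lumen centroid, of the total
#' chord length of the ray's intersection with the calcification regions
#' (radial thickness convention, consistent with the centroid-based angle).
#'
#' @param section a [cross_section()].
#' @param n_rays number of rays spread over the calcified angular union.
#' @return Thickness in mm; 0 for a slice without calcification.
#' @export
max_calc_thickness <- function(section, n_rays = 3600) {
  stopifnot(inherits(section, "cross_section"))
  u <- calc_angular_union(section)
  if (nrow(u) == 0) return(0)
  spans <- u[, 2] - u[, 1]
  per <- pmax(8L, ceiling(n_rays * spans / sum(spans)))
  thetas <- unlist(lapply(seq_len(nrow(u)), function(k)
    seq(u[k, 1], u[k, 2], length.out = per[k])))
  max(ray_calc_chords(section, thetas %% 360))
}

#' Lumen-boundary arc lengths inside/outside the calcified span
#'
#' Partitions the lumen contour length by whether each boundary segment's
#' centroid angle lies within the calcification angular union. The two
#' parts sum to the lumen perimeter exactly, by construction.
#'
#' @param section a [cross_section()].
#' @return Named numeric: `arclength_c`, `arclength_f` (mm).
#' @export
inner_arc_lengths <- function(section) {
  stopifnot(inherits(section, "cross_section"))
  lum <- as_contour(section$lumen_contour)
  n <- nrow(lum)
  nxt <- c(2:n, 1)
  seg_len <- sqrt(rowSums((lum[nxt, ] - lum)^2))
  u <- calc_angular_union(section)
  if (nrow(u) == 0)
    return(c(arclength_c = 0, arclength_f = sum(seg_len)))
  origin <- polygon_centroid(lum)
  mid <- (lum + lum[nxt, ]) / 2
  th <- angle_deg(mid[, 1], mid[, 2], origin)
  inc <- angle_in_union(th, u)
  c(arclength_c = sum(seg_len[inc]), arclength_f = sum(seg_len[!inc]))
}

#' Extract the eight pre-stenting features of a cross section
#'
#' Computes, per slice: artery area (region enclosed by the outer contour,
#' lumen included), fibrotic area (artery minus lumen minus calcification),
#' calcification area, lumen area, calcification angle, maximum radial
#' calcification thickness, and the lumen-boundary arc lengths inside and
#' outside the calcified angular span.
#'
#' @param section a [cross_section()].
#' @return Object of class `feature_vector`: named numeric of the eight
#'   features (`area_a`, `area_f`, `area_c`, `area_l`, `angle_c`,
#'   `thickness_c`, `arclength_c`, `arclength_f`), with attributes
#'   `slice_index` and `z`.
#' @export
extract_features <- function(section) {
  stopifnot(inherits(section, "cross_section"))
  area_a <- polygon_area(section$outer_contour)
  area_l <- polygon_area(section$lumen_contour)
  area_c <- if (length(section$calc_regions))
    sum(vapply(section$calc_regions, polygon_area, numeric(1))) else 0
  arcs <- inner_arc_lengths(section)
  fv <- c(area_a = area_a,
          area_f = area_a - area_l - area_c,
          area_c = area_c,
          area_l = area_l,
          angle_c = calcification_angle(section),
          thickness_c = max_calc_thickness(section),
          arclength_c = unname(arcs["arclength_c"]),
          arclength_f = unname(arcs["arclength_f"]))
  structure(fv, class = "feature_vector",
            slice_index = section$slice_index, z = section$z)
}

#' Feature table of a whole vessel
#'
#' @param sections list of [cross_section()] objects (a generated vessel).
#' @return `data.frame` with `slice_index`, `z` and the eight feature
#'   columns, one row per slice.
#' @export
extract_features_vessel <- function(sections) {
  stopifnot(length(sections) >= 1)
  rows <- lapply(seq_along(sections), function(i) {
    fv <- tryCatch(extract_features(sections[[i]]),
                   error = function(e) stop("feature extraction failed at slice ",
                                            i, ": ", conditionMessage(e),
                                            call. = FALSE))
    data.frame(slice_index = i, z = sections[[i]]$z, t(unclass(fv)))
  })
  do.call(rbind, rows)
}

#' Neighbor-averaged feature table
#'
#' Replaces each feature value by its mean over the slice itself plus up to
#' `window/2` immediately preceding and following slices (the window
#' truncates at the ends of the segment). Only input features are averaged;
#' any non-feature columns (e.g. labels) are left untouched.
#'
#' @param features a feature `data.frame` from [extract_features_vessel()]
#'   (or any data frame containing the eight canonical feature columns).
#' @param window total number of neighbors (default 8: four before and four
#'   after).
#' @return Data frame of the same shape with smoothed feature columns.
#' @export
neighbor_average <- function(features, window = 8) {
  stopifnot(is.data.frame(features), nrow(features) >= 1, window >= 0)
  half <- floor(window / 2)
  cols <- intersect(FEATURE_NAMES, names(features))
  if (!length(cols)) stop("no canonical feature columns found", call. = FALSE)
  n <- nrow(features)
  out <- features
  for (cl in cols) {
    v <- features[[cl]]
    out[[cl]] <- vapply(seq_len(n), function(i) {
      idx <- max(1, i - half):min(n, i + half)
      mean(v[idx])
    }, numeric(1))
  }
  out
}
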