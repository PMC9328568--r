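#' Configuration of the synthetic vessel generator
#'
#' Defines the study conditions the generator emulates: a stented segment
#' sampled as `n_sections` cross sections at `spacing` mm, with per-slice
#' lumen radius, wall thickness, calcification angular span and deposit
#' thickness drawn from configured distributions and smoothed along the
#' axis with a Gaussian kernel of width `axial_correlation_length`.
#'
#' Defaults mirror the reference setting of the pipeline: 120 sections at
#' 0.1 mm spacing, a lumen of radius about 1 mm, and a calcification angle
#' distribution whose spans range roughly 0-180 degrees (180 degrees being
#' the critical angle of the usual OCT-based calcium score).
#'
#' @param n_sections number of slices (>= 1).
#' @param spacing axial spacing, mm.
#' @param lumen_radius_mean,lumen_radius_sd lumen radius distribution, mm.
#' @param wall_thickness_mean,wall_thickness_sd wall (outer minus lumen)
#'   thickness distribution, mm.
#' @param calc_angle_mean,calc_angle_sd total calcification angular span
#'   distribution, degrees; negative draws are truncated to 0 (slice
#'   without calcification).
#' @param calc_thickness_mean,calc_thickness_sd radial deposit thickness
#'   distribution, mm; must stay below the wall thickness.
#' @param n_deposits_max maximum number of deposits per slice (1 or 2).
#' @param axial_correlation_length smoothing length along the axis, mm.
#' @param contour_points vertices per lumen/outer contour.
#' @param lumen_ellipticity relative amplitude of the second-harmonic lumen
#'   shape perturbation (0 = circular lumen).
#' @param seed integer seed governing all randomness.
#' @return Object of class `vessel_gen_config`.
#' @export
vessel_gen_config <- function(n_sections = 120,
                              spacing = 0.1,
                              lumen_radius_mean = 1.0,
                              lumen_radius_sd = 0.10,
                              wall_thickness_mean = 0.85,
                              wall_thickness_sd = 0.06,
                              calc_angle_mean = 90,
                              calc_angle_sd = 55,
                              calc_thickness_mean = 0.30,
                              calc_thickness_sd = 0.06,
                              n_deposits_max = 2,
                              axial_correlation_length = 0.6,
                              contour_points = 96,
                              lumen_ellipticity = 0.04,
                              seed = 1L) {
  cfg <- list(n_sections = as.integer(n_sections), spacing = spacing,
              lumen_radius_mean = lumen_radius_mean,
              lumen_radius_sd = lumen_radius_sd,
              wall_thickness_mean = wall_thickness_mean,
              wall_thickness_sd = wall_thickness_sd,
              calc_angle_mean = calc_angle_mean,
              calc_angle_sd = calc_angle_sd,
              calc_thickness_mean = calc_thickness_mean,
              calc_thickness_sd = calc_thickness_sd,
              n_deposits_max = as.integer(n_deposits_max),
              axial_correlation_length = axial_correlation_length,
              contour_points = as.integer(contour_points),
              lumen_ellipticity = lumen_ellipticity,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_sections >= 1, spacing > 0,
              lumen_radius_mean > 0, wall_thickness_mean > 0,
              calc_thickness_mean > 0, calc_angle_mean >= 0,
              lumen_radius_sd >= 0, wall_thickness_sd >= 0,
              calc_angle_sd >= 0, calc_thickness_sd >= 0,
              n_deposits_max >= 1, contour_points >= 16,
              axial_correlation_length >= 0, lumen_ellipticity >= 0)
  })
  if (cfg$calc_thickness_mean >= cfg$wall_thickness_mean)
    stop("infeasible configuration: mean calcification thickness must be below the mean wall thickness",
         call. = FALSE)
  structure(cfg, class = "vessel_gen_config")
}

# Standardized axially correlated field: white noise smoothed with a
# Gaussian kernel (sd = correlation length in slices) and re-standardized,
# so the configured mean/sd are realized exactly. Returns zeros when the
# smoothed draw is degenerate (e.g. n = 1).
smooth_field <- function(n, corr_slices) {
  x <- stats::rnorm(n)
  if (n > 1 && corr_slices > 0) {
    half <- ceiling(3 * corr_slices)
    k <- stats::dnorm(seq(-half, half), sd = corr_slices)
    k <- k / sum(k)
    # reflective padding so the smoothed field is defined at the ends
    pad_l <- x[pmax(1, pmin(n, seq.int(half, 1) + 1))]
    pad_r <- x[pmax(1, pmin(n, n - seq_len(half)))]
    xp <- c(pad_l, x, pad_r)
    x <- as.numeric(stats::filter(xp, k, sides = 2))[half + seq_len(n)]
  }
  if (n == 1 || stats::sd(x) < 1e-12) return(rep(0, n))
  (x - mean(x)) / stats::sd(x)
}

#' Generate a synthetic calcified-vessel segment
#'
#' Produces an ordered list of labeled cross sections whose lumen radius,
#' wall thickness, calcification angular span and deposit thickness vary
#' smoothly along the axis. Deposits are annular sectors seated on the
#' lumen boundary so that the calcification angle is controlled by
#' construction; the total span is split between up to `n_deposits_max`
#' deposits placed on roughly opposite sides of the lumen. Identical
#' configuration and seed give bit-identical output.
#'
#' @param cfg a [vessel_gen_config()].
#' @return List of [cross_section()] objects of class `stent_vessel`, with
#'   the configuration stored in `attr(, "config")`.
#' @export
generate_vessel <- function(cfg) {
  stopifnot(inherits(cfg, "vessel_gen_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  n <- cfg$n_sections
  cs <- cfg$axial_correlation_length / cfg$spacing
  r_lum <- cfg$lumen_radius_mean + cfg$lumen_radius_sd * smooth_field(n, cs)
  t_wall <- cfg$wall_thickness_mean + cfg$wall_thickness_sd * smooth_field(n, cs)
  a_tot <- cfg$calc_angle_mean + cfg$calc_angle_sd * smooth_field(n, cs)
  t_calc <- cfg$calc_thickness_mean + cfg$calc_thickness_sd * smooth_field(n, cs)
  phi2 <- 180 * smooth_field(n, cs)              # lumen shape orientation, deg
  c1 <- stats::runif(1, 0, 360) + 40 * smooth_field(n, cs)  # deposit 1 center
  dc2 <- 20 * smooth_field(n, cs)                # deposit 2 offset jitter
  wfrac <- 0.5 + 0.15 * smooth_field(n, cs)      # angular split between deposits

  r_lum <- pmax(r_lum, 0.3)
  t_wall <- pmax(t_wall, 0.2)
  a_tot <- pmin(pmax(a_tot, 0), 340)
  wfrac <- pmin(pmax(wfrac, 0.25), 0.75)
  gap <- 0.01  # radial seat of deposits off the lumen boundary, mm

  th <- seq(0, 2 * pi, length.out = cfg$contour_points + 1)[-(cfg$contour_points + 1)]
  sections <- vector("list", n)
  for (i in seq_len(n)) {
    if (t_calc[i] + gap >= t_wall[i])
      stop("slice ", i, ": calcification deposit (", signif(t_calc[i], 3),
           " mm) thicker than the wall (", signif(t_wall[i], 3), " mm)",
           call. = FALSE)
    rfun <- function(theta_rad)
      r_lum[i] * (1 + cfg$lumen_ellipticity *
                    cos(2 * (theta_rad - phi2[i] * pi / 180)))
    lum <- cbind(rfun(th) * cos(th), rfun(th) * sin(th))
    out <- cbind((rfun(th) + t_wall[i]) * cos(th), (rfun(th) + t_wall[i]) * sin(th))
    calc <- list()
    if (a_tot[i] > 1) {
      two <- cfg$n_deposits_max > 1 && a_tot[i] > 90
      spans <- if (two) a_tot[i] * c(wfrac[i], 1 - wfrac[i]) else a_tot[i]
      centers <- if (two) c(c1[i], c1[i] + 180 + dc2[i]) else c1[i]
      for (k in seq_along(spans)) {
        th0 <- (centers[k] - spans[k] / 2) * pi / 180
        th1 <- (centers[k] + spans[k] / 2) * pi / 180
        ths <- seq(th0, th1, length.out = max(12, ceiling(spans[k] / 3)))
        rin <- rfun(ths) + gap
        calc[[k]] <- rbind(cbind(rin * cos(ths), rin * sin(ths)),
                           cbind((rev(rin) + t_calc[i]) * cos(rev(ths)),
                                 (rev(rin) + t_calc[i]) * sin(rev(ths))))
      }
    }
    sections[[i]] <- cross_section(z = (i - 1) * cfg$spacing,
                                   lumen_contour = lum, outer_contour = out,
                                   calc_regions = calc, slice_index = i,
                                   validate = FALSE)
  }
  structure(sections, class = c("stent_vessel", "list"), config = cfg)
}

#' @export
print.stent_vessel <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<stent_vessel> %d sections, %.2f mm spacing (seed %d)\n",
              length(x), cfg$spacing, cfg$seed))
  invisible(x)
}

#' Write / read a vessel directory
#'
#' Plain-text serialization of a vessel: `contours.csv` with columns
#' `slice`, `ring`, `label`, `x`, `y` (ring 0 = lumen, 1 = outer wall,
#' 2.. = calcification deposits), `slices.csv` with the axial positions,
#' and `config.yaml` with the generator configuration when available.
#'
#' @param vessel list of [cross_section()] objects.
#' @param dir directory to create/fill.
#' @return `write_vessel` returns `dir` invisibly; `read_vessel` returns a
#'   list of `cross_section` objects.
#' @export
write_vessel <- function(vessel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_along(vessel)) {
    s <- vessel[[i]]
    rings <- c(list(s$lumen_contour, s$outer_contour), s$calc_regions)
    labels <- c("lumen", "outer", rep("calcification", length(s$calc_regions)))
    for (k in seq_along(rings)) {
      rows[[length(rows) + 1]] <- data.frame(
        slice = i, ring = k - 1L, label = labels[k],
        x = rings[[k]][, 1], y = rings[[k]][, 2])
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "contours.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(slice = seq_along(vessel),
                              z = vapply(vessel, function(s) s$z, numeric(1))),
                   file.path(dir, "slices.csv"), row.names = FALSE)
  cfg <- attr(vessel, "config")
  if (!is.null(cfg)) yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Write / read a labeled mask as an 8-bit TIFF
#'
#' Stores the integer label palette (0 background, 1 lumen, 2 fibrotic,
#' 3 calcification) directly as 8-bit gray values.
#'
#' @param mask a `vessel_mask` from [rasterize_section()].
#' @param path file path (`.tif`).
#' @return `write_mask` returns `path` invisibly; `read_mask` returns the
#'   integer label matrix.
#' @export
write_mask <- function(mask, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write masks", call. = FALSE)
  tiff::writeTIFF(unclass(mask) / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read masks", call. = FALSE)
  m <- round(tiff::readTIFF(path) * 255)
  storage.mode(m) <- "integer"
  m
}

#' @rdname write_vessel
#' @export
read_vessel <- function(dir) {
  con <- utils::read.csv(file.path(dir, "contours.csv"))
  zs <- utils::read.csv(file.path(dir, "slices.csv"))
  sections <- lapply(zs$slice, function(i) {
    sl <- con[con$slice == i, ]
    lum <- as.matrix(sl[sl$ring == 0, c("x", "y")])
    out <- as.matrix(sl[sl$ring == 1, c("x", "y")])
    calc <- lapply(sort(unique(sl$ring[sl$ring >= 2])), function(k)
      as.matrix(sl[sl$ring == k, c("x", "y")]))
    cross_section(z = zs$z[zs$slice == i], lumen_contour = lum,
                  outer_contour = out, calc_regions = calc,
                  slice_index = i, validate = FALSE)
  })
  cfg_path <- file.path(dir, "config.yaml")
  cfg <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else NULL
  structure(sections, class = c("stent_vessel", "list"), config = cfg)
}
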