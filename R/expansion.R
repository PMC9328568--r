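#' Stent parameters for the composite-ring expansion surrogate
#'
#' Kinematic description of the stent: nominal, crimped and expansion
#' (balloon) outer diameters, the calcification stretch cap, and the
#' scaffold recoil compliance. The 316L steel constants are carried as
#' documentation only -- the stent enters the mechanics purely as a
#' kinematic boundary condition.
#'
#' `recoil_compliance` is the scaffold give during unloading, in mm of
#' circumference per unit membrane tension (N/mm): 0 means a rigid
#' scaffold (no recoil). The default is calibrated once, via
#' [calibrate_recoil_compliance()], so that a calcification-free reference
#' section (1 mm lumen radius) recoils from the 3.3 mm balloon diameter to
#' a final lumen diameter of 3.0 mm (the nominal stent size, lumen area
#' 7.06 mm^2).
#'
#' @param nominal_diameter,crimped_diameter,expansion_diameter mm;
#'   must satisfy crimped < nominal < expansion.
#' @param recoil_compliance mm circumference per N/mm tension, or `NULL`
#'   to use the calibrated default.
#' @param calc_stretch_cap maximum circumferential engineering strain of
#'   the calcified arc (default 0.02, reflecting the orders-of-magnitude
#'   modulus contrast between calcification and soft plaque).
#' @param fibrotic_stretch_limit lock-up stretch of the fibrotic arc:
#'   plastic flow at the yield plateau stops once the collagenous tissue
#'   reaches this circumferential stretch (default 2.0). Slices whose
#'   calcified arc leaves too little fibrotic circumference to span the
#'   balloon therefore underexpand.
#' @param materials named list of [material_coefficients()] presets used
#'   for the default calibration.
#' @param steel_doc documented-only 316L constants.
#' @return Object of class `stent_params`.
#' @export
stent_params <- function(nominal_diameter = 3.0,
                         crimped_diameter = 1.0,
                         expansion_diameter = 3.3,
                         recoil_compliance = NULL,
                         calc_stretch_cap = 0.02,
                         fibrotic_stretch_limit = 2.0,
                         materials = tissue_presets(),
                         steel_doc = list(youngs_modulus_GPa = 190,
                                          poisson_ratio = 0.3,
                                          yield_strength_MPa = 207)) {
  stopifnot(crimped_diameter < nominal_diameter,
            nominal_diameter < expansion_diameter,
            calc_stretch_cap > 0, fibrotic_stretch_limit > 1.5)
  sp <- structure(list(nominal_diameter = nominal_diameter,
                       crimped_diameter = crimped_diameter,
                       expansion_diameter = expansion_diameter,
                       recoil_compliance = recoil_compliance,
                       calc_stretch_cap = calc_stretch_cap,
                       fibrotic_stretch_limit = fibrotic_stretch_limit,
                       steel_doc = steel_doc),
                  class = "stent_params")
  if (is.null(recoil_compliance))
    sp$recoil_compliance <- calibrate_recoil_compliance(sp, materials)
  stopifnot(sp$recoil_compliance >= 0)
  sp
}

#' @export
print.stent_params <- function(x, ...) {
  cat(sprintf("<stent_params> %g mm nominal, crimped to %g mm, expanded to %g mm\n",
              x$nominal_diameter, x$crimped_diameter, x$expansion_diameter))
  cat(sprintf("  recoil compliance %.3f mm/(N/mm); calcification stretch cap %g\n",
              x$recoil_compliance, 1 + x$calc_stretch_cap))
  invisible(x)
}

# Radius of a star-shaped contour about `origin` at angles `theta` (deg),
# by linear interpolation over vertex angles.
radius_at <- function(contour, origin, theta) {
  contour <- as_contour(contour)
  a <- angle_deg(contour[, 1], contour[, 2], origin)
  r <- sqrt((contour[, 1] - origin[1])^2 + (contour[, 2] - origin[2])^2)
  o <- order(a)
  a <- a[o]; r <- r[o]
  a <- c(a[length(a)] - 360, a, a[1] + 360)
  r <- c(r[length(r)], r, r[1])
  stats::approx(a, r, xout = theta %% 360, rule = 2)$y
}

# Per-arc mechanical summary of one section: arc lengths, effective
# thicknesses and anchor radius of the calcified arc.
section_arc_properties <- function(section) {
  origin <- polygon_centroid(section$lumen_contour)
  arcs <- inner_arc_lengths(section)
  u <- calc_angular_union(section)
  thetas_all <- seq(0, 359.5, by = 0.5)
  in_c <- angle_in_union(thetas_all, u)
  r_lum <- radius_at(section$lumen_contour, origin, thetas_all)
  r_out <- radius_at(section$outer_contour, origin, thetas_all)
  wall <- r_out - r_lum
  t_f <- if (any(!in_c)) mean(wall[!in_c]) else mean(wall)
  t_wc <- if (any(in_c)) mean(wall[in_c]) else mean(wall)
  t_c <- if (nrow(u) > 0) {
    ch <- ray_calc_chords(section, thetas_all[in_c])
    if (any(ch > 0)) mean(ch[ch > 0]) else 0
  } else 0
  list(L0 = sum(arcs), Lc0 = unname(arcs["arclength_c"]),
       Lf0 = unname(arcs["arclength_f"]),
       t_f = t_f, t_c = t_c, t_wall_c = t_wc,
       r_anchor = if (any(in_c)) mean(r_lum[in_c]) else mean(r_lum),
       pre_area = polygon_area(section$lumen_contour))
}

# Invert a monotone nominal-stress tension curve T(lam) = N(lam) * thick
# on [1, lam_hi]; returns lam_hi when the demanded tension exceeds the
# curve's end value.
invert_tension <- function(tension, mat, thick, lam_hi) {
  if (tension <= 0) return(1)
  f <- function(l) uniaxial_nominal_stress(l, mat) * thick - tension
  if (f(lam_hi) <= 0) return(lam_hi)
  stats::uniroot(f, c(1 + 1e-12, lam_hi), tol = 1e-12)$root
}

#' Expand one cross section with the composite-ring surrogate
#'
#' Two-phase, per-slice reduction of the stenting mechanics.
#' *Loading*: the lumen boundary is driven toward the balloon circumference
#' \eqn{\pi d_{exp}}; the circumferential stretch partitions between the
#' calcified arc (its hyperelastic law, capped at `1 + calc_stretch_cap`)
#' and the fibrotic arc (elastoplastic law) under equal membrane tension
#' (nominal stress times effective arc thickness); once the fibrotic arc
#' yields, it flows plastically at constant tension until the target
#' circumference is reached. *Recoil*: the scaffold, with finite recoil
#' compliance, unloads against the residual inward load: the elastically
#' unloading fibrotic arc (permanent set retained) plus the elastic hoop
#' recovery of the arterial wall carried outward by the rigid calcified
#' arc, weighted by arc fractions. The final circumference is mapped to a
#' circular post-stenting lumen area.
#'
#' @param section a [cross_section()].
#' @param stent a [stent_params()].
#' @param materials named list with `artery`, `fibrotic` (with yield
#'   parameters) and `calcification` presets.
#' @return Object of class `expansion_result`: list with
#'   `post_lumen_area`, `pre_lumen_area` (mm^2), `fibrotic_stretch`,
#'   `calc_stretch`, `recoil_fraction`, `loaded_circumference`,
#'   `final_circumference` (mm) and `tension_loading` (N/mm).
#' @export
expand_section <- function(section, stent = stent_params(),
                           materials = tissue_presets()) {
  stopifnot(inherits(section, "cross_section"), inherits(stent, "stent_params"))
  fib <- materials$fibrotic
  cal <- materials$calcification
  art <- materials$artery
  if (is.null(fib$yield_stress_nominal))
    stop("fibrotic material must carry yield parameters", call. = FALSE)

  ap <- section_arc_properties(section)
  L_target <- pi * stent$expansion_diameter
  cap <- 1 + stent$calc_stretch_cap
  lam_y <- yield_stretch(fib)
  t_yf <- fib$yield_stress_nominal * ap$t_f

  if (ap$L0 >= L_target) {
    # lumen already at or beyond the balloon size: no expansion
    lam_c <- 1; lam_f <- 1; c_load <- ap$L0; t_load <- 0
  } else if (ap$Lf0 < 1e-9) {
    # rigid-ring limit: fully calcified, stretch capped
    lam_c <- min(L_target / ap$Lc0, cap)
    lam_f <- 1
    c_load <- ap$Lc0 * lam_c
    t_load <- max(0, uniaxial_nominal_stress(lam_c, cal) * ap$t_c)
  } else {
    lam_c_at <- function(tt) if (ap$Lc0 < 1e-9) 1 else
      invert_tension(tt, cal, max(ap$t_c, 1e-6), cap)
    gap_fun <- function(tt)
      ap$Lc0 * lam_c_at(tt) + ap$Lf0 * invert_tension(tt, fib, ap$t_f, lam_y) -
        L_target
    if (gap_fun(t_yf) < 0) {
      # fibrotic arc yields and flows plastically at constant tension,
      # up to its lock-up stretch
      t_load <- t_yf
      lam_c <- lam_c_at(t_load)
      lam_f <- min((L_target - ap$Lc0 * lam_c) / ap$Lf0,
                   stent$fibrotic_stretch_limit)
    } else {
      sol <- stats::uniroot(gap_fun, c(0, t_yf), tol = 1e-12)
      t_load <- sol$root
      lam_c <- lam_c_at(t_load)
      lam_f <- invert_tension(t_load, fib, ap$t_f, lam_y)
      resid <- abs(gap_fun(t_load))
      if (resid > 1e-6)
        stop(sprintf("tension-balance solve did not converge (residual %.3e mm)",
                     resid), call. = FALSE)
    }
    c_load <- ap$Lc0 * lam_c + ap$Lf0 * lam_f
  }

  # --- recoil -------------------------------------------------------------
  w_c <- ap$Lc0 / ap$L0
  w_f <- ap$Lf0 / ap$L0
  yielded <- lam_f > lam_y
  lam_p <- if (yielded) lam_f / lam_y else 1   # fibrotic permanent set

  tension_in <- function(cc) {
    tf <- if (ap$Lf0 < 1e-9) 0 else {
      lam_now <- lam_f - (c_load - cc) / ap$Lf0
      lam_e <- lam_now / lam_p
      if (lam_e <= 1) 0 else
        min(t_yf, uniaxial_nominal_stress(lam_e, fib) * ap$t_f)
    }
    tw <- if (ap$Lc0 < 1e-9) 0 else {
      lam_w <- max(1, (cc / (2 * pi)) / ap$r_anchor)
      max(0, uniaxial_nominal_stress(lam_w, art) * ap$t_wall_c)
    }
    w_f * tf + w_c * tw
  }

  c_pre_equiv <- 2 * sqrt(pi * ap$pre_area)
  c_floor <- min(c_pre_equiv, c_load)
  s_r <- stent$recoil_compliance
  if (s_r <= 0 || tension_in(c_load) <= 0) {
    c_final <- c_load
  } else {
    h <- function(cc) (c_load - cc) - s_r * tension_in(cc)
    c_final <- if (h(c_floor) <= 0) c_floor else
      stats::uniroot(h, c(c_floor, c_load), tol = 1e-10)$root
  }
  c_final <- max(c_final, c_pre_equiv)

  structure(list(
    post_lumen_area = c_final^2 / (4 * pi),
    pre_lumen_area = ap$pre_area,
    fibrotic_stretch = lam_f,
    calc_stretch = lam_c,
    recoil_fraction = (c_load - c_final) / c_load,
    loaded_circumference = c_load,
    final_circumference = c_final,
    tension_loading = t_load,
    fibrotic_yielded = yielded
  ), class = "expansion_result")
}

#' @export
print.expansion_result <- function(x, ...) {
  cat(sprintf("<expansion_result> lumen %.3f -> %.3f mm^2 (recoil %.1f%%)\n",
              x$pre_lumen_area, x$post_lumen_area, 100 * x$recoil_fraction))
  cat(sprintf("  stretches: fibrotic %.3f, calcified %.4f\n",
              x$fibrotic_stretch, x$calc_stretch))
  invisible(x)
}

#' Expand every section of a vessel
#'
#' @param sections list of [cross_section()] objects.
#' @inheritParams expand_section
#' @return List of `expansion_result` objects (order preserved); empty
#'   input gives an empty list.
#' @export
expand_vessel <- function(sections, stent = stent_params(),
                          materials = tissue_presets()) {
  lapply(seq_along(sections), function(i)
    tryCatch(expand_section(sections[[i]], stent, materials),
             error = function(e) stop("expansion failed at slice ", i, ": ",
                                      conditionMessage(e), call. = FALSE)))
}

#' Tabulate expansion results
#'
#' @param results list of `expansion_result` objects.
#' @param z optional axial positions to include.
#' @return `data.frame` with one row per slice.
#' @export
expansion_results_df <- function(results, z = NULL) {
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(pre_area = r$pre_lumen_area, post_area = r$post_lumen_area,
               fibrotic_stretch = r$fibrotic_stretch,
               calc_stretch = r$calc_stretch,
               recoil_fraction = r$recoil_fraction)))
  if (!is.null(z)) df <- cbind(z = z, df)
  df
}

#' Calibrate the scaffold recoil compliance
#'
#' Solves for the recoil compliance at which a calcification-free circular
#' reference section (lumen radius `reference_radius`, wall thickness
#' `reference_wall`) recoils from the balloon diameter to
#' `target_final_diameter`. Used for the [stent_params()] default.
#'
#' @param stent a `stent_params`-like list with the diameters and cap
#'   (its `recoil_compliance` is ignored).
#' @param materials named preset list.
#' @param target_final_diameter mm (default: the nominal stent diameter).
#' @param reference_radius,reference_wall reference geometry, mm.
#' @return Compliance in mm circumference per N/mm tension.
#' @export
calibrate_recoil_compliance <- function(stent, materials = tissue_presets(),
                                        target_final_diameter = stent$nominal_diameter,
                                        reference_radius = 1.0,
                                        reference_wall = 0.85) {
  ref <- cross_section(z = 0,
                       lumen_contour = circle_contour(reference_radius, 96),
                       outer_contour = circle_contour(reference_radius + reference_wall, 96),
                       validate = FALSE)
  sp0 <- stent
  sp0$recoil_compliance <- 0
  class(sp0) <- "stent_params"
  loaded <- expand_section(ref, sp0, materials)
  c_load <- loaded$loaded_circumference
  c_star <- pi * target_final_diameter
  if (c_star >= c_load)
    stop("target final diameter must lie below the balloon diameter", call. = FALSE)
  fib <- materials$fibrotic
  ap <- section_arc_properties(ref)
  lam_max <- loaded$fibrotic_stretch
  lam_p <- lam_max / yield_stretch(fib)
  lam_e <- (lam_max - (c_load - c_star) / ap$Lf0) / lam_p
  if (lam_e <= 1)
    stop("reference section cannot recoil that far elastically", call. = FALSE)
  t_u <- uniaxial_nominal_stress(lam_e, fib) * ap$t_f
  (c_load - c_star) / t_u
}
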