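#' Material coefficients for a reduced-polynomial hyperelastic tissue
#'
#' Bundles the strain-energy coefficients (in MPa) of one tissue,
#' \deqn{U = C_{10}(I_1-3) + C_{01}(I_2-3) + C_{11}(I_1-3)(I_2-3) +
#'       C_{20}(I_1-3)^2 + C_{02}(I_2-3)^2 + C_{30}(I_1-3)^3 + C_{03}(I_2-3)^3,}
#' plus optional perfect-plasticity parameters (nominal yield stress in MPa
#' and the corresponding engineering yield strain).
#'
#' @param name tissue label, e.g. `"artery"`, `"fibrotic"`, `"calcification"`.
#' @param c10,c01,c11,c20,c02,c30,c03 strain-energy coefficients, MPa.
#'   Absent terms default to zero.
#' @param yield_stress_nominal nominal (first Piola-Kirchhoff) yield stress,
#'   MPa, or `NULL` for a purely hyperelastic material.
#' @param yield_strain_engineering engineering strain at yield (dimensionless),
#'   or `NULL`. Must be given together with `yield_stress_nominal`.
#' @return An object of class `material_coefficients`.
#' @seealso [tissue_preset()] for the built-in tissue laws.
#' @export
material_coefficients <- function(name,
                                  c10 = 0, c01 = 0, c11 = 0,
                                  c20 = 0, c02 = 0, c30 = 0, c03 = 0,
                                  yield_stress_nominal = NULL,
                                  yield_strain_engineering = NULL) {
  coefs <- c(c10 = c10, c01 = c01, c11 = c11, c20 = c20,
             c02 = c02, c30 = c30, c03 = c03)
  if (!all(is.finite(coefs)))
    stop("all strain-energy coefficients must be finite", call. = FALSE)
  if (is.null(yield_stress_nominal) != is.null(yield_strain_engineering))
    stop("yield stress and yield strain must be given together", call. = FALSE)
  if (!is.null(yield_stress_nominal)) {
    stopifnot(yield_stress_nominal > 0, yield_strain_engineering > 0)
  }
  structure(
    list(name = as.character(name), coefs = coefs,
         yield_stress_nominal = yield_stress_nominal,
         yield_strain_engineering = yield_strain_engineering),
    class = "material_coefficients"
  )
}

#' @export
print.material_coefficients <- function(x, ...) {
  cat("<material_coefficients> ", x$name, "\n", sep = "")
  nz <- x$coefs[x$coefs != 0]
  cat("  ", paste(sprintf("%s=%g", names(nz), nz), collapse = ", "),
      " (MPa)\n", sep = "")
  if (!is.null(x$yield_stress_nominal))
    cat(sprintf("  perfect plasticity: yield %g MPa at %g%% engineering strain\n",
                x$yield_stress_nominal, 100 * x$yield_strain_engineering))
  invisible(x)
}

#' Built-in tissue material presets
#'
#' The three coronary-lesion constituents used throughout the package:
#' the arterial wall, fibrotic plaque, and calcification. Coefficients are
#' literature values for the reduced third-order polynomial law (MPa).
#' Fibrotic plaque additionally carries a perfect-plasticity pair
#' (0.07 MPa nominal yield stress at 34% engineering strain), consistent
#' with its hyperelastic curve: the nominal stress of the fibrotic law at
#' stretch 1.34 evaluates to 0.0702 MPa.
#'
#' @param name one of `"artery"`, `"fibrotic"`, `"calcification"`.
#' @return `tissue_preset()` returns one `material_coefficients` object;
#'   `tissue_presets()` returns a named list of all three.
#' @examples
#' uniaxial_nominal_stress(1.34, tissue_preset("fibrotic")) # ~0.07 MPa
#' @export
tissue_preset <- function(name = c("artery", "fibrotic", "calcification")) {
  name <- match.arg(name)
  switch(name,
    artery = material_coefficients("artery",
      c10 = 0.10881, c01 = -0.101, c11 = -0.1790674,
      c20 = 0.0885618, c02 = 0.062686),
    fibrotic = material_coefficients("fibrotic",
      c10 = 0.04, c02 = 0.003, c03 = 0.02976,
      yield_stress_nominal = 0.07, yield_strain_engineering = 0.34),
    calcification = material_coefficients("calcification",
      c10 = -0.49596, c01 = 0.50661, c11 = 1.19353,
      c20 = 3.6378, c30 = 4.73725)
  )
}

#' @rdname tissue_preset
#' @export
tissue_presets <- function() {
  nm <- c("artery", "fibrotic", "calcification")
  stats::setNames(lapply(nm, tissue_preset), nm)
}

#' Principal stretch triplet
#'
#' Constructs a triplet of principal stretch ratios. With `lam3 = NULL` the
#' third stretch is filled in from incompressibility
#' (\eqn{\lambda_1\lambda_2\lambda_3 = 1}); when all three are supplied the
#' product is checked against 1 within `1e-12` if `incompressible = TRUE`.
#'
#' @param lam1,lam2,lam3 principal stretches (> 0).
#' @param incompressible enforce unit volume ratio.
#' @return Object of class `principal_stretches` (numeric length-3).
#' @export
principal_stretches <- function(lam1, lam2, lam3 = NULL, incompressible = TRUE) {
  if (is.null(lam3)) {
    if (lam1 <= 0 || lam2 <= 0)
      stop("principal stretches must be positive", call. = FALSE)
    lam3 <- 1 / (lam1 * lam2)
  }
  lam <- c(lam1, lam2, lam3)
  if (any(!is.finite(lam)) || any(lam <= 0))
    stop("principal stretches must be positive and finite", call. = FALSE)
  if (incompressible && abs(prod(lam) - 1) > 1e-12)
    stop("stretches violate incompressibility (product != 1)", call. = FALSE)
  structure(lam, class = "principal_stretches")
}

#' Uniaxial incompressible stretch state
#'
#' @param lam axial stretch (> 0); transverse stretches are
#'   \eqn{\lambda^{-1/2}}.
#' @return A `principal_stretches` object.
#' @export
uniaxial_stretches <- function(lam) {
  if (!is.finite(lam) || lam <= 0)
    stop("stretch must be positive and finite", call. = FALSE)
  principal_stretches(lam, 1 / sqrt(lam), 1 / sqrt(lam))
}

#' Invariants of the Cauchy-Green deformation tensor
#'
#' First and second invariants for an incompressible stretch state:
#' \eqn{I_1 = \sum_k \lambda_k^2} and \eqn{I_2 = \sum_k \lambda_k^{-2}}
#' (the incompressible form of the second invariant).
#'
#' @param stretches a [principal_stretches()] object, or a numeric length-3
#'   vector of positive stretches.
#' @return Object of class `invariant_pair`: list with `i1` and `i2`.
#' @examples
#' cg_invariants(uniaxial_stretches(1.34))
#' @export
cg_invariants <- function(stretches) {
  if (!inherits(stretches, "principal_stretches"))
    stretches <- principal_stretches(stretches[1], stretches[2], stretches[3])
  lam <- unclass(stretches)
  structure(list(i1 = sum(lam^2), i2 = sum(1 / lam^2)),
            class = "invariant_pair")
}

as_invariant_pair <- function(inv) {
  if (inherits(inv, "invariant_pair")) return(inv)
  if (inherits(inv, "principal_stretches")) return(cg_invariants(inv))
  stopifnot(is.numeric(inv), length(inv) == 2)
  structure(list(i1 = inv[1], i2 = inv[2]), class = "invariant_pair")
}

#' Reduced-polynomial strain-energy density
#'
#' Evaluates the seven-term reduced third-order polynomial strain-energy
#' density (MPa) at a pair of deformation invariants.
#'
#' @param inv an `invariant_pair` (see [cg_invariants()]), a
#'   `principal_stretches` object, or a numeric `c(i1, i2)`.
#' @param mat a [material_coefficients()] object.
#' @return Strain-energy density in MPa (zero at the identity).
#' @export
strain_energy <- function(inv, mat) {
  inv <- as_invariant_pair(inv)
  stopifnot(inherits(mat, "material_coefficients"))
  p <- inv$i1 - 3
  q <- inv$i2 - 3
  cf <- mat$coefs
  cf[["c10"]] * p + cf[["c01"]] * q + cf[["c11"]] * p * q +
    cf[["c20"]] * p^2 + cf[["c02"]] * q^2 + cf[["c30"]] * p^3 + cf[["c03"]] * q^3
}

# Partial derivatives of U wrt I1, I2 at (i1, i2); vectorized over inputs.
energy_partials <- function(i1, i2, mat) {
  p <- i1 - 3
  q <- i2 - 3
  cf <- mat$coefs
  list(
    dU1 = cf[["c10"]] + cf[["c11"]] * q + 2 * cf[["c20"]] * p + 3 * cf[["c30"]] * p^2,
    dU2 = cf[["c01"]] + cf[["c11"]] * p + 2 * cf[["c02"]] * q + 3 * cf[["c03"]] * q^2
  )
}

#' Uniaxial Cauchy stress of an incompressible reduced-polynomial law
#'
#' Along the incompressible uniaxial path
#' (\eqn{\lambda_2 = \lambda_3 = \lambda^{-1/2}}) the Cauchy stress is
#' \deqn{\sigma = 2(\lambda^2 - \lambda^{-1})
#'   \left(\partial U/\partial I_1 + \lambda^{-1}\,\partial U/\partial I_2\right).}
#'
#' @param lam axial stretch(es), > 0; vectorized.
#' @param mat a [material_coefficients()] object.
#' @return Cauchy stress in MPa.
#' @export
uniaxial_cauchy_stress <- function(lam, mat) {
  stopifnot(inherits(mat, "material_coefficients"))
  if (any(!is.finite(lam)) || any(lam <= 0))
    stop("stretch must be positive and finite", call. = FALSE)
  i1 <- lam^2 + 2 / lam
  i2 <- 1 / lam^2 + 2 * lam
  d <- energy_partials(i1, i2, mat)
  2 * (lam^2 - 1 / lam) * (d$dU1 + d$dU2 / lam)
}

#' Uniaxial nominal (first Piola-Kirchhoff) stress
#'
#' Nominal stress along the incompressible uniaxial path,
#' \eqn{N(\lambda) = \sigma(\lambda)/\lambda}. For the fibrotic preset this
#' evaluates to 0.0702 MPa at \eqn{\lambda = 1.34}, matching its stated
#' yield pair (0.07 MPa at 34% engineering strain).
#'
#' @inheritParams uniaxial_cauchy_stress
#' @return Nominal stress in MPa.
#' @export
uniaxial_nominal_stress <- function(lam, mat) {
  uniaxial_cauchy_stress(lam, mat) / lam
}

# Tangent dN/dlam of the nominal-stress curve (central difference).
nominal_tangent <- function(lam, mat, h = 1e-6) {
  (uniaxial_nominal_stress(lam + h, mat) -
     uniaxial_nominal_stress(lam - h, mat)) / (2 * h)
}

# Stretch at which the hyperelastic nominal stress first reaches the
# nominal yield stress.
yield_stretch <- function(mat, upper = 3) {
  stopifnot(!is.null(mat$yield_stress_nominal))
  stats::uniroot(function(l) uniaxial_nominal_stress(l, mat) - mat$yield_stress_nominal,
                 interval = c(1 + 1e-9, upper), tol = 1e-12)$root
}

#' Elastoplastic uniaxial response along a stretch path
#'
#' Perfect plasticity on the nominal-stress measure with a multiplicative
#' elastic-plastic split of the stretch (\eqn{\lambda = \lambda_e \lambda_p}):
#' the response follows the hyperelastic nominal-stress curve until it
#' first reaches the material's nominal yield stress, is capped there on
#' further loading (plastic flow accumulates in \eqn{\lambda_p}), and
#' unloads elastically along the hyperelastic curve evaluated at the
#' elastic stretch \eqn{\lambda/\lambda_p}. The permanent set is the
#' stretch at zero stress after unloading from the maximum attained
#' stretch, \eqn{\lambda_{max}/\lambda_{yield}}.
#'
#' @param lam_path ordered numeric vector of stretches, starting at 1.
#' @param mat a [material_coefficients()] object with yield parameters.
#' @return List of class `elastoplastic_response` with `lam` (the input
#'   path), `stress` (nominal stress, MPa, per path point), `permanent_set`
#'   (stretch at zero stress after unloading from the maximum attained
#'   stretch; 1 if the path never yielded) and `yielded` (logical).
#' @export
elastoplastic_uniaxial_response <- function(lam_path, mat) {
  stopifnot(inherits(mat, "material_coefficients"))
  if (is.null(mat$yield_stress_nominal))
    stop("material '", mat$name, "' has no yield parameters", call. = FALSE)
  if (length(lam_path) < 1 || abs(lam_path[1] - 1) > 1e-9)
    stop("stretch path must start at lambda = 1", call. = FALSE)
  if (any(lam_path <= 0)) stop("stretches must be positive", call. = FALSE)

  n_y <- mat$yield_stress_nominal
  lam_y <- yield_stretch(mat)
  stress <- numeric(length(lam_path))
  lam_max <- 1
  for (k in seq_along(lam_path)) {
    lam <- lam_path[k]
    lam_max <- max(lam_max, lam_path[seq_len(k)])
    if (lam_max <= lam_y) {
      # never yielded: purely hyperelastic (loading and unloading coincide)
      stress[k] <- uniaxial_nominal_stress(lam, mat)
    } else if (lam >= lam_max) {
      stress[k] <- n_y  # on the plastic plateau
    } else {
      lam_p <- lam_max / lam_y
      stress[k] <- uniaxial_nominal_stress(max(lam / lam_p, 1e-6), mat)
    }
  }
  yielded <- lam_max > lam_y
  permanent_set <- if (yielded) lam_max / lam_y else 1
  structure(list(lam = lam_path, stress = stress,
                 permanent_set = permanent_set, yielded = yielded,
                 lam_max = lam_max, yield_stretch = lam_y),
            class = "elastoplastic_response")
}

#' @export
print.elastoplastic_response <- function(x, ...) {
  cat("<elastoplastic_response> ", length(x$lam), " path points; max stretch ",
      format(x$lam_max, digits = 4), if (x$yielded) " (yielded)", "\n", sep = "")
  cat("  permanent set: ", format(x$permanent_set, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Dump the built-in material presets to a structured config
#'
#' @param path optional file path; when given, the presets are written as
#'   YAML and the path is returned invisibly. Otherwise the list is returned.
#' @return Named list (or invisible path) with coefficients in MPa.
#' @export
dump_material_presets <- function(path = NULL) {
  out <- lapply(tissue_presets(), function(m) {
    l <- c(as.list(m$coefs), list(name = m$name))
    if (!is.null(m$yield_stress_nominal)) {
      l$yield_stress_nominal <- m$yield_stress_nominal
      l$yield_strain_engineering <- m$yield_strain_engineering
    }
    l
  })
  if (is.null(path)) return(out)
  yaml::write_yaml(out, path)
  invisible(path)
}
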