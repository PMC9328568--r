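# Independent oracles used across the suite. Each is implemented from the
# mathematical definition, separately from the package code paths it checks.

# Central finite difference of the strain-energy density along the
# incompressible uniaxial path; for an incompressible material the Cauchy
# stress is lambda * dU/dlambda.
fd_uniaxial_cauchy <- function(lam, mat, rel_step = 1e-5) {
  h <- rel_step * lam
  u_at <- function(l) strain_energy(cg_invariants(uniaxial_stretches(l)), mat)
  lam * (u_at(lam + h) - u_at(lam - h)) / (2 * h)
}

# Ray-casting measure of the calcification angle: fraction of a dense
# angular grid whose centroid ray intersects any calcification polygon.
# Scalar segment-intersection code, independent of the package's
# interval arithmetic.
raycast_angle_oracle <- function(section, step_deg = 0.01,
                                 theta_min = 0, theta_max = 360) {
  origin <- polygon_centroid(section$lumen_contour)
  thetas <- seq(theta_min, theta_max - step_deg / 2, by = step_deg)
  hit <- rep(FALSE, length(thetas))
  for (poly in section$calc_regions) {
    p <- poly
    n <- nrow(p)
    q <- p[c(2:n, 1), , drop = FALSE]
    rx <- q[, 1] - p[, 1]; ry <- q[, 2] - p[, 2]
    wx <- p[, 1] - origin[1]; wy <- p[, 2] - origin[2]
    dx <- cos(thetas * pi / 180); dy <- sin(thetas * pi / 180)
    for (e in seq_len(n)) {
      den <- dx * ry[e] - dy * rx[e]
      ok <- abs(den) > 1e-14
      tt <- (wx[e] * ry[e] - wy[e] * rx[e]) / den
      ss <- (dx * wy[e] - dy * wx[e]) / (-den)
      hit <- hit | (ok & tt > 1e-9 & ss >= 0 & ss < 1)
    }
  }
  mean(hit) * (theta_max - theta_min)
}

# Dense-ray maximum chord oracle for the calcification thickness.
dense_ray_thickness_oracle <- function(section, n_rays = 10000) {
  origin <- polygon_centroid(section$lumen_contour)
  thetas <- seq(0, 360, length.out = n_rays + 1)[-1]
  best <- 0
  for (poly in section$calc_regions) {
    p <- poly
    n <- nrow(p)
    q <- p[c(2:n, 1), , drop = FALSE]
    rx <- q[, 1] - p[, 1]; ry <- q[, 2] - p[, 2]
    wx <- p[, 1] - origin[1]; wy <- p[, 2] - origin[2]
    for (th in thetas) {
      dx <- cos(th * pi / 180); dy <- sin(th * pi / 180)
      den <- dx * ry - dy * rx
      tt <- (wx * ry - wy * rx) / den
      ss <- (dx * wy - dy * wx) / (-den)
      ts <- sort(tt[abs(den) > 1e-14 & tt > 1e-9 & ss >= 0 & ss < 1])
      if (length(ts) >= 2) {
        if (length(ts) %% 2 == 1) ts <- ts[-length(ts)]
        best <- max(best, sum(ts[seq(2, length(ts), 2)] - ts[seq(1, length(ts), 2)]))
      }
    }
  }
  best
}

# Numeric arc-integration oracle: lumen-contour length split by whether the
# segment midpoint's centroid angle falls in any of the given angular
# intervals (degrees, possibly overlapping).
arc_partition_oracle <- function(lumen, intervals) {
  origin <- polygon_centroid(lumen)
  n <- nrow(lumen)
  nxt <- c(2:n, 1)
  seg <- sqrt(rowSums((lumen[nxt, ] - lumen)^2))
  mid <- (lumen + lumen[nxt, ]) / 2
  th <- (atan2(mid[, 2] - origin[2], mid[, 1] - origin[1]) * 180 / pi) %% 360
  inside <- rep(FALSE, n)
  for (k in seq_len(nrow(intervals))) {
    a <- intervals[k, 1] %% 360; b <- intervals[k, 2]
    if (b <= 360 && a <= b %% 360) {
      inside <- inside | (th >= a & th <= b)
    } else {  # wrapping interval
      b <- b %% 360
      inside <- inside | (th >= a | th <= b)
    }
  }
  c(sum(seg[inside]), sum(seg[!inside]))
}

# Raster pixel-averaging centroid oracle.
raster_centroid_oracle <- function(contour, pixel = 1e-3) {
  bb <- apply(contour, 2, range)
  xs <- seq(bb[1, 1], bb[2, 1], by = pixel)
  ys <- seq(bb[1, 2], bb[2, 2], by = pixel)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  inside <- pracma::inpolygon(gx, gy, contour[, 1], contour[, 2])
  c(mean(gx[inside]), mean(gy[inside]))
}

# Incremental-integration oracle for the perfectly plastic uniaxial
# response with a multiplicative elastic-plastic split: small-step return
# mapping driven entirely by finite-difference stresses of the energy
# density (no analytic stress formulas).
incremental_plastic_oracle <- function(lam_end, mat, n_steps = 2000) {
  n_y <- mat$yield_stress_nominal
  fd_nominal <- function(l) fd_uniaxial_cauchy(l, mat, rel_step = 1e-6) / l
  lam_path <- seq(1, lam_end, length.out = n_steps)
  lam_p <- 1
  for (lam in lam_path[-1]) {
    trial <- fd_nominal(lam / lam_p)
    if (trial > n_y) {
      # return mapping: grow lam_p until the elastic trial sits at yield
      lam_p <- lam / stats::uniroot(function(le) fd_nominal(le) - n_y,
                                    c(1 + 1e-9, lam / lam_p),
                                    tol = 1e-12)$root
    }
  }
  list(stress_at_end = min(fd_nominal(lam_end / lam_p), n_y),
       permanent_set = lam_p,
       unload_stress = function(l) fd_nominal(l / lam_p))
}

# Epsilon-SVR dual solved as an explicit QP with kernlab::ipop.
# Variables beta = (alpha, alpha*); objective
#   min 1/2 (a - a*)' K (a - a*) + eps * sum(a + a*) - y'(a - a*)
# s.t. sum(a - a*) = 0, 0 <= a, a* <= C.
svr_qp_oracle <- function(x, y, C, eps, kfun) {
  n <- length(y)
  K <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) kfun(x[i, ], x[j, ])))
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-9, 2 * n)
  cc <- c(eps - y, eps + y)
  A <- matrix(c(rep(1, n), rep(-1, n)), nrow = 1)
  sol <- kernlab::ipop(c = cc, H = H, A = A, b = 0, r = 0,
                       l = rep(0, 2 * n), u = rep(C, 2 * n),
                       sigf = 10, maxiter = 200)
  beta <- kernlab::primal(sol)
  coefs <- beta[1:n] - beta[(n + 1):(2 * n)]
  # intercept from a free support vector (0 < alpha < C)
  tol <- C * 1e-5
  f0 <- as.numeric(K %*% coefs)
  up <- which(beta[1:n] > tol & beta[1:n] < C - tol)
  lo <- which(beta[(n + 1):(2 * n)] > tol & beta[(n + 1):(2 * n)] < C - tol)
  b <- if (length(up)) mean(y[up] - f0[up] - eps)
       else if (length(lo)) mean(y[lo] - f0[lo] + eps)
       else mean(y - f0)
  list(predict = function(newx) {
    kv <- apply(newx, 1, function(z)
      sum(coefs * apply(x, 1, function(xi) kfun(xi, z))))
    kv + b
  }, coefs = coefs, b = b)
}

# One informative feature embedded in the canonical 8-column layout
# (remaining columns zero, which leaves dot products and distances - and
# hence every kernel - unchanged).
pad_single_feature <- function(v) {
  df <- as.data.frame(matrix(0, length(v), 8,
                             dimnames = list(NULL, FEATURE_NAMES)))
  df$area_a <- v
  df
}

# Deterministic toy sections used in several files.
annulus_section <- function(r_in = 1, r_out = 2, n = 360, calc = list()) {
  cross_section(0, circle_contour(r_in, n), circle_contour(r_out, n),
                calc_regions = calc, validate = FALSE)
}
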