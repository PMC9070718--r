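# Independent oracles used across the suite. These deliberately avoid the
# package's own EDT / convolution / meshing code paths.

# logical ball of radius r centred in an n^3 grid (voxel centres, inclusive)
digitize_ball <- function(r, n = 2 * ceiling(r) + 9, center = rep((n + 1) / 2, 3)) {
  x <- seq_len(n)
  array(outer(outer((x - center[1])^2, (x - center[2])^2, `+`),
              (x - center[3])^2, `+`) <= r^2, c(n, n, n))
}

# brute-force binary erosion with the inclusive digital ball, out-of-grid
# treated as background
brute_erode <- function(mask, radius) {
  d <- dim(mask)
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius,
                      dz = -radius:radius)
  offs <- offs[offs$dx^2 + offs$dy^2 + offs$dz^2 <= radius^2, ]
  out <- array(TRUE, d)
  for (i in seq_len(nrow(offs))) {
    sh <- array(FALSE, d)  # mask shifted by -off, FALSE where out of grid
    sx <- max(1, 1 + offs$dx[i]):min(d[1], d[1] + offs$dx[i])
    sy <- max(1, 1 + offs$dy[i]):min(d[2], d[2] + offs$dy[i])
    sz <- max(1, 1 + offs$dz[i]):min(d[3], d[3] + offs$dz[i])
    tx <- sx - offs$dx[i]; ty <- sy - offs$dy[i]; tz <- sz - offs$dz[i]
    sh[tx, ty, tz] <- mask[sx, sy, sz]
    out <- out & sh
  }
  out & mask
}

# brute-force signed distance: all-pairs minimum distance to the surface
# voxels (pore voxels with a 6-neighbour outside), sign from membership
brute_signed_distance <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  co <- arrayInd(idx, d)
  surf <- logical(length(idx))
  for (i in seq_along(idx)) {
    p <- co[i, ]
    nb <- rbind(p + c(1, 0, 0), p - c(1, 0, 0), p + c(0, 1, 0),
                p - c(0, 1, 0), p + c(0, 0, 1), p - c(0, 0, 1))
    outside <- nb[, 1] < 1 | nb[, 1] > d[1] | nb[, 2] < 1 | nb[, 2] > d[2] |
      nb[, 3] < 1 | nb[, 3] > d[3]
    inside <- !outside
    vals <- logical(nrow(nb))
    vals[outside] <- FALSE
    if (any(inside))
      vals[inside] <- mask[cbind(nb[inside, 1], nb[inside, 2], nb[inside, 3])]
    surf[i] <- any(!vals)
  }
  sco <- co[surf, , drop = FALSE]
  all_co <- arrayInd(seq_len(prod(d)), d)
  dist2 <- matrix(Inf, nrow(all_co), 1)
  dmin <- rep(Inf, nrow(all_co))
  for (j in seq_len(nrow(sco))) {
    dd <- (all_co[, 1] - sco[j, 1])^2 + (all_co[, 2] - sco[j, 2])^2 +
      (all_co[, 3] - sco[j, 3])^2
    dmin <- pmin(dmin, dd)
  }
  out <- array(sqrt(dmin), d)
  out[!mask] <- -out[!mask]
  out
}

# error function by numerical quadrature of the Gaussian density,
# independent of pnorm
erf_quad <- function(x) {
  vapply(x, function(xx) {
    s <- sign(xx)
    if (xx == 0) return(0)
    2 / sqrt(pi) * s *
      stats::integrate(function(t) exp(-t^2), 0, abs(xx),
                       rel.tol = 1e-12)$value
  }, numeric(1))
}

# continuum convolution of a ball (radius R, unit contrast) with an isotropic
# Gaussian (sd sigma), evaluated at radial distance rho from the ball centre;
# dense 1D quadrature over spherical shells
ball_gauss_value <- function(rho, R, sigma) {
  vapply(rho, function(r) {
    f <- function(s) {
      # integral of the Gaussian over the sphere of radius s, centre distance r
      if (r < 1e-9)
        return(4 * pi * s^2 * (2 * pi * sigma^2)^(-3 / 2) *
                 exp(-s^2 / (2 * sigma^2)))
      s^2 * (2 * pi * sigma^2)^(-3 / 2) * 2 * pi * (sigma^2 / (s * r)) *
        (exp(-(r - s)^2 / (2 * sigma^2)) - exp(-(r + s)^2 / (2 * sigma^2)))
    }
    ss <- seq(1e-6, R, length.out = 4000)
    sum(vapply(ss, f, numeric(1))) * (ss[2] - ss[1])
  }, numeric(1))
}

# direct (non-separable) truncated-Gaussian convolution of a volume at one
# voxel, same kernel definition as the generator but computed as a plain
# triple sum
direct_conv_value <- function(vol, sigma, at, truncate = 3) {
  r <- ceiling(truncate * sigma)
  k1 <- exp(-(-r:r)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  s <- 0
  for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
    s <- s + k1[dx + r + 1] * k1[dy + r + 1] * k1[dz + r + 1] *
      vol[at[1] + dx, at[2] + dy, at[3] + dz]
  }
  s
}

# surface area of a prolate spheroid with semi-axes (a, c, c), a > c
prolate_area <- function(a, c) {
  e <- sqrt(1 - (c / a)^2)
  2 * pi * c^2 * (1 + (a / (c * e)) * asin(e))
}

# small, fast phantom used by several module tests
small_phantom <- function(seed = 2, ...) {
  args <- list(grid_shape = c(120, 120, 120), n_closed_pores = 6, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  generate_phantom(do.call(phantom_spec, args))
}
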