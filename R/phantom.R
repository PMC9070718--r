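#' Phantom specification
#'
#' Describes a synthetic reconstructed volume emulating a scaffold with
#' closed, roughly spherical pores of higher gray value, a main connected
#' pore space touching one volume face, Gaussian edge blur of known width,
#' additive Gaussian noise, and a slow multiplicative background drift of up
#' to a stated fraction of the scaffold gray level.
#'
#' Defaults correspond to the conditions the quality metrics are validated
#' under: a 200 voxel cube at 50 nm voxels, scaffold/pore gray levels
#' 100/200, 35 closed pores of radius 9--11 voxels, blur sigma 2 voxels and
#' noise sigma 10 gray units (true SNR 10).
#'
#' @param grid_shape integer length-3, volume dimensions in voxels.
#' @param voxel_size voxel edge length in nm.
#' @param gray_scaffold scaffold gray level.
#' @param gray_pore pore gray level, must exceed \code{gray_scaffold}.
#' @param gray_bone optional mineralized-tissue gray level; when given, a
#'   tissue layer is deposited on the main-pore-space wall.
#' @param n_closed_pores number of isolated pores to place.
#' @param pore_radius_range numeric length-2, radii in voxels (min >= 2).
#' @param blur_sigma Gaussian blur standard deviation in voxels (>= 0).
#' @param noise_sigma additive noise standard deviation in gray units (>= 0).
#' @param drift_amplitude (max - min)/gray_scaffold of the multiplicative
#'   background field, in [0, 1).
#' @param include_main_pore_space place a pore-level channel touching the
#'   x = 1 face so a boundary-connected component exists.
#' @param seed integer seed; identical spec and seed give identical volumes.
#' @return an object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(200, 200, 200),
                         voxel_size = 50,
                         gray_scaffold = 100,
                         gray_pore = 200,
                         gray_bone = NULL,
                         n_closed_pores = 35,
                         pore_radius_range = c(9, 11),
                         blur_sigma = 2,
                         noise_sigma = 10,
                         drift_amplitude = 0,
                         include_main_pore_space = TRUE,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape <= 0))
    stop("grid_shape must be 3 positive integers")
  if (gray_pore <= gray_scaffold) stop("gray_pore must exceed gray_scaffold")
  if (n_closed_pores < 0) stop("n_closed_pores must be non-negative")
  if (length(pore_radius_range) != 2 || pore_radius_range[1] < 2 ||
      diff(pore_radius_range) < 0)
    stop("pore_radius_range must be (min, max) with min >= 2 voxels")
  if (blur_sigma < 0 || noise_sigma < 0) stop("blur and noise sigmas must be >= 0")
  if (drift_amplitude < 0 || drift_amplitude >= 1)
    stop("drift_amplitude must be in [0, 1)")
  structure(list(
    grid_shape = grid_shape, voxel_size = voxel_size,
    gray_scaffold = gray_scaffold, gray_pore = gray_pore, gray_bone = gray_bone,
    n_closed_pores = as.integer(n_closed_pores),
    pore_radius_range = as.numeric(pore_radius_range),
    blur_sigma = blur_sigma, noise_sigma = noise_sigma,
    drift_amplitude = drift_amplitude,
    include_main_pore_space = isTRUE(include_main_pore_space),
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<phantom_spec> %dx%dx%d @ %.4g nm | %d pores r[%.3g, %.3g] | ",
    "blur %.3g vox | noise %.3g | drift %.3g | seed %d\n"),
    x$grid_shape[1], x$grid_shape[2], x$grid_shape[3], x$voxel_size,
    x$n_closed_pores, x$pore_radius_range[1], x$pore_radius_range[2],
    x$blur_sigma, x$noise_sigma, x$drift_amplitude, x$seed))
  invisible(x)
}

# width of the main-pore-space channel slab along x, and of the optional
# mineralized layer on its wall
CHANNEL_WIDTH <- 6L
BONE_THICKNESS <- 3L

#' Generate a synthetic phantom volume with ground truth
#'
#' Builds the noiseless phase image (scaffold, closed pores, optional main
#' channel and tissue layer), modulates it with the multiplicative drift
#' field, convolves with an isotropic Gaussian (kernel truncated at 3 sigma),
#' and adds i.i.d. Gaussian noise. Pores are placed by seeded rejection
#' sampling with a guaranteed pairwise surface separation of at least twice
#' the blur support radius, and cannot touch the boundary or the main pore
#' space.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param max_tries rejection-sampling retries per pore before failing.
#' @return a list with elements \code{volume} (\code{\link{gray_volume}}) and
#'   \code{truth}, where \code{truth} contains \code{labels}
#'   (\code{\link{pore_label_volume}} of the placed pores), \code{pores}
#'   (tibble: label, x, y, z, radius, voxel_count), \code{pore_space_mask}
#'   (\code{\link{binary_mask}} of closed pores plus main channel),
#'   \code{bone_mask} (or NULL), \code{true_fwhm} (nm), \code{true_snr},
#'   \code{blur_support_radius} (voxels) and the generating \code{spec}.
#' @export
generate_phantom <- function(spec, max_tries = 2000L) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  support <- if (spec$blur_sigma > 0) ceiling(3 * spec$blur_sigma) else 0L

  res <- withr::with_seed(spec$seed, {
    # drift coefficients are always drawn so the RNG stream (and hence the
    # noise) is identical between runs that differ only in drift_amplitude
    drift_coef <- runif(9, -1, 1)

    # pore placement by rejection sampling
    rmin <- spec$pore_radius_range[1]; rmax <- spec$pore_radius_range[2]
    clear_b <- 12  # boundary clearance beyond the radius (room for shells)
    xlow_extra <- if (spec$include_main_pore_space)
      CHANNEL_WIDTH + (if (is.null(spec$gray_bone)) 0L else BONE_THICKNESS) +
        2 * support + 1 else 0
    centers <- matrix(numeric(0), ncol = 3)
    radii <- numeric(0)
    for (i in seq_len(spec$n_closed_pores)) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        r <- runif(1, rmin, rmax)
        lo <- ceiling(r + clear_b + 1)
        hi <- d - lo + 1
        lo_x <- max(lo, ceiling(xlow_extra + r + 1))
        if (lo_x > hi[1] || any(lo > hi)) next
        cx <- sample(lo_x:hi[1], 1)
        cy <- sample(lo:hi[2], 1)
        cz <- sample(lo:hi[3], 1)
        ok <- TRUE
        if (length(radii) > 0) {
          dd <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2 +
                       (centers[, 3] - cz)^2)
          ok <- all(dd >= radii + r + 2 * support)
        }
        if (ok) {
          centers <- rbind(centers, c(cx, cy, cz))
          radii <- c(radii, r)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf("pore placement failed at pore %d after %d tries; ",
                     i, max_tries),
             "reduce n_closed_pores or pore radii, or enlarge the grid")
    }

    # noiseless phase image and ground-truth geometry
    vol <- array(spec$gray_scaffold, d)
    labels <- array(0L, d)
    pore_space <- array(FALSE, d)
    bone <- NULL
    if (spec$include_main_pore_space) {
      vol[seq_len(CHANNEL_WIDTH), , ] <- spec$gray_pore
      pore_space[seq_len(CHANNEL_WIDTH), , ] <- TRUE
      if (!is.null(spec$gray_bone)) {
        bx <- CHANNEL_WIDTH + seq_len(BONE_THICKNESS)
        vol[bx, , ] <- spec$gray_bone
        bone <- array(FALSE, d)
        bone[bx, , ] <- TRUE
      }
    }
    counts <- integer(length(radii))
    for (k in seq_along(radii)) {
      c0 <- centers[k, ]; r <- radii[k]; ri <- ceiling(r)
      xs <- (c0[1] - ri):(c0[1] + ri)
      ys <- (c0[2] - ri):(c0[2] + ri)
      zs <- (c0[3] - ri):(c0[3] + ri)
      sub <- outer(outer((xs - c0[1])^2, (ys - c0[2])^2, `+`),
                   (zs - c0[3])^2, `+`) <= r^2
      counts[k] <- sum(sub)
      lab_sub <- labels[xs, ys, zs]
      lab_sub[sub] <- k
      labels[xs, ys, zs] <- lab_sub
      v_sub <- vol[xs, ys, zs]
      v_sub[sub] <- spec$gray_pore
      vol[xs, ys, zs] <- v_sub
      ps_sub <- pore_space[xs, ys, zs]
      ps_sub[sub] <- TRUE
      pore_space[xs, ys, zs] <- ps_sub
    }

    # multiplicative low-order polynomial drift field, span = drift_amplitude
    if (spec$drift_amplitude > 0) {
      u <- (seq_len(d[1]) - 1) / max(d[1] - 1, 1)
      v <- (seq_len(d[2]) - 1) / max(d[2] - 1, 1)
      w <- (seq_len(d[3]) - 1) / max(d[3] - 1, 1)
      U <- array(u, d)
      V <- array(rep(v, each = d[1]), d)
      W <- array(rep(w, each = d[1] * d[2]), d)
      p <- drift_coef[1] * U + drift_coef[2] * V + drift_coef[3] * W +
        drift_coef[4] * U * V + drift_coef[5] * U * W + drift_coef[6] * V * W +
        drift_coef[7] * U^2 + drift_coef[8] * V^2 + drift_coef[9] * W^2
      rng <- range(p)
      if (diff(rng) == 0) p[] <- 0.5 else p <- (p - rng[1]) / diff(rng)
      g <- 1 + spec$drift_amplitude * (p - 0.5)
      vol <- vol * g
    } else {
      g <- NULL
    }

    if (spec$blur_sigma > 0)
      vol <- conv_sep(vol, gaussian_kernel(spec$blur_sigma, truncate = 3))
    if (spec$noise_sigma > 0)
      vol <- vol + array(rnorm(length(vol), 0, spec$noise_sigma), d)

    list(vol = vol, labels = labels, pore_space = pore_space, bone = bone,
         centers = centers, radii = radii, counts = counts, drift = g)
  })

  contrast <- spec$gray_pore - spec$gray_scaffold
  truth <- list(
    labels = pore_label_volume(res$labels, spec$voxel_size),
    pores = tibble::tibble(
      label = seq_along(res$radii),
      x = if (length(res$radii)) res$centers[, 1] else numeric(0),
      y = if (length(res$radii)) res$centers[, 2] else numeric(0),
      z = if (length(res$radii)) res$centers[, 3] else numeric(0),
      radius = res$radii,
      voxel_count = res$counts
    ),
    pore_space_mask = binary_mask(res$pore_space, spec$voxel_size),
    bone_mask = if (is.null(res$bone)) NULL else
      binary_mask(res$bone, spec$voxel_size),
    drift_field = res$drift,
    true_fwhm = gaussian_fwhm(spec$blur_sigma) * spec$voxel_size,
    true_snr = if (spec$noise_sigma > 0) contrast / spec$noise_sigma else Inf,
    blur_support_radius = support,
    spec = spec
  )
  list(volume = gray_volume(res$vol, spec$voxel_size), truth = truth)
}

#' Ideal planar edge-spread profile
#'
#' The step response of an ideal unit step blurred by a Gaussian of standard
#' deviation \code{blur_sigma}:
#' \code{0.5 * (1 + erf(d / (sqrt(2) * blur_sigma)))}. For
#' \code{blur_sigma = 0} the unit step itself is returned (0.5 at d = 0).
#'
#' @param blur_sigma Gaussian sigma in voxels (>= 0).
#' @param distances signed distances in voxels, positive toward the bright
#'   side.
#' @return numeric vector of ideal profile values in [0, 1].
#' @export
analytic_edge_profile <- function(blur_sigma, distances) {
  stopifnot(blur_sigma >= 0)
  if (blur_sigma == 0)
    return(ifelse(distances < 0, 0, ifelse(distances > 0, 1, 0.5)))
  0.5 * (1 + erf(distances / (sqrt(2) * blur_sigma)))
}
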