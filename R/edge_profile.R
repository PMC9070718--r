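#' Signed Euclidean distance to a pore surface
#'
#' Surface voxels are pore voxels with at least one 6-neighbour outside the
#' mask (the grid border counts as outside). Every voxel gets the Euclidean
#' distance to its nearest surface voxel, positive inside the pore, negative
#' outside, and 0 on the surface voxels themselves.
#'
#' @param mask logical 3D array (single pore), or a \code{\link{binary_mask}}.
#' @return numeric 3D array of signed distances in voxels.
#' @export
signed_distance <- function(mask) {
  if (inherits(mask, "binary_mask")) mask <- mask$values
  if (!any(mask)) stop("empty mask has no surface")
  surf <- surface_voxels(mask)
  d <- sqrt(edt_sq(!surf))
  d[!mask] <- -d[!mask]
  d
}

# pore voxels with a face neighbour outside the mask (grid border = outside)
surface_voxels <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  bg <- !mask
  # face-neighbour is background, handling the border as background
  has_bg <- array(FALSE, d)
  has_bg[1, , ] <- TRUE; has_bg[d[1], , ] <- TRUE
  has_bg[, 1, ] <- TRUE; has_bg[, d[2], ] <- TRUE
  has_bg[, , 1] <- TRUE; has_bg[, , d[3]] <- TRUE
  has_bg[-1, , ] <- has_bg[-1, , ] | bg[-d[1], , ]
  has_bg[-d[1], , ] <- has_bg[-d[1], , ] | bg[-1, , ]
  has_bg[, -1, ] <- has_bg[, -1, ] | bg[, -d[2], ]
  has_bg[, -d[2], ] <- has_bg[, -d[2], ] | bg[, -1, ]
  has_bg[, , -1] <- has_bg[, , -1] | bg[, , -d[3]]
  has_bg[, , -d[3]] <- has_bg[, , -d[3]] | bg[, , -1]
  out[mask & has_bg] <- TRUE
  out
}

#' Distance-binned gray-value step-up curve
#'
#' Mean gray value of the original data as a function of signed distance
#' from the segmented pore surface, in steps of one voxel: shell k collects
#' voxels whose signed distance falls in [k - 0.5, k + 0.5). Outside shells
#' (k < 0) are intersected with \code{context_mask} so neighbouring pores,
#' tissue or other phases are excluded; inside shells are restricted to the
#' pore itself. Moving from scaffold into the pore the curve steps up.
#'
#' @param volume a \code{\link{gray_volume}}.
#' @param pore_mask logical array or \code{\link{binary_mask}} of one pore.
#' @param context_mask logical array or \code{\link{binary_mask}} of voxels
#'   eligible for outside shells (the scaffold phase); NULL admits all
#'   non-pore voxels.
#' @param max_range maximum shell index outside the pore (>= 3).
#' @param max_range_inside maximum shell index inside; default
#'   \code{min(max_range, floor(inscribed radius))}. Shells that would be
#'   empty truncate the range with a warning.
#' @return an \code{edge_profile} tibble: \code{distance} (voxels, unit
#'   spacing), \code{mean_gray}, \code{n_voxels}; voxel size kept as an
#'   attribute.
#' @export
step_curve <- function(volume, pore_mask, context_mask = NULL, max_range = 10,
                       max_range_inside = NULL) {
  stopifnot(inherits(volume, "gray_volume"), max_range >= 3)
  if (inherits(pore_mask, "binary_mask")) pore_mask <- pore_mask$values
  if (inherits(context_mask, "binary_mask")) context_mask <- context_mask$values
  if (!identical(dim(pore_mask), dim(volume$values)))
    stop("mask and volume shapes differ")
  sd_field <- signed_distance(pore_mask)
  if (is.null(context_mask)) context_mask <- !pore_mask
  step_curve_sd(volume, sd_field, pore_mask, context_mask, max_range,
                max_range_inside)
}

# shell binning given a precomputed signed-distance field
step_curve_sd <- function(volume, sd_field, pore_mask, context_mask,
                          max_range = 10, max_range_inside = NULL) {
  r_in <- max_range_inside %||% min(max_range, floor(max(sd_field)))
  ks <- seq.int(-max_range, r_in)
  shell <- floor(sd_field + 0.5)  # shell index of every voxel
  eligible <- (shell > 0L & pore_mask) | (shell == 0L & pore_mask) |
    (shell < 0L & !pore_mask & context_mask)

  mg <- nv <- numeric(length(ks))
  for (i in seq_along(ks)) {
    sel <- eligible & shell == ks[i]
    nv[i] <- sum(sel)
    mg[i] <- if (nv[i] > 0) mean(volume$values[sel]) else NA_real_
  }
  # truncate at the first empty shell on either side of the transition
  ok <- nv > 0
  if (!all(ok)) {
    zero_i <- which(ks == 0L)
    lo <- max(which(!ok & seq_along(ks) < zero_i), 0) + 1L
    hi_bad <- which(!ok & seq_along(ks) > zero_i)
    hi <- if (length(hi_bad)) min(hi_bad) - 1L else length(ks)
    warning(sprintf("empty shells: profile truncated to [%d, %d] voxels",
                    ks[lo], ks[hi]))
    keep <- lo:hi
    ks <- ks[keep]; mg <- mg[keep]; nv <- nv[keep]
  }
  out <- tibble::tibble(distance = as.numeric(ks), mean_gray = mg,
                        n_voxels = as.integer(nv))
  attr(out, "voxel_size") <- volume$voxel_size
  class(out) <- c("edge_profile", class(out))
  out
}

#' Fit the error-function step model to an edge profile
#'
#' Least-squares fit of
#' \deqn{f(d) = A_1 + \frac{A_2 - A_1}{2}\left[1 +
#'   \mathrm{erf}\!\left(\frac{d - x_0}{\sqrt{2}\,\sigma}\right)\right]}
#' to the shell means, shells weighted equally (optionally by voxel count).
#' Initialization takes the plateau means and the mid-level crossing.
#'
#' @param profile an \code{edge_profile} from \code{\link{step_curve}}.
#' @param contrast_floor minimum plateau difference \code{A2 - A1}; below it
#'   the fit aborts with a "no contrast" error.
#' @param weight \code{"equal"} (default) or \code{"voxels"}.
#' @return an object of class \code{erf_fit} with elements \code{A1},
#'   \code{A2}, \code{x0}, \code{sigma_fit}, \code{rmse}, \code{converged},
#'   the profile and the voxel size.
#' @export
fit_erf <- function(profile, contrast_floor = 1e-6, weight = c("equal", "voxels")) {
  weight <- match.arg(weight)
  d <- profile$distance
  y <- profile$mean_gray
  if (sum(d < 0) < 2 || sum(d > 0) < 2)
    stop("profile must span both plateaus (>= 2 shells each side)")
  n_pl <- max(2L, min(3L, sum(d < 0) - 1L))
  a1 <- mean(y[order(d)][seq_len(n_pl)])
  a2 <- mean(y[order(-d)][seq_len(n_pl)])
  if (!is.finite(a1) || !is.finite(a2) || (a2 - a1) < contrast_floor)
    stop2("porequal_no_contrast", "no contrast: plateau difference below floor")

  mid <- (a1 + a2) / 2
  x0_init <- tryCatch({
    above <- which(y >= mid)
    i <- min(above[above > 1])
    d[i - 1] + (mid - y[i - 1]) / (y[i] - y[i - 1])
  }, error = function(e) 0)
  if (!is.finite(x0_init)) x0_init <- 0
  w <- if (weight == "voxels") profile$n_voxels else rep(1, length(d))

  model <- function(p) p[1] + (p[2] - p[1]) / 2 *
    (1 + erf((d - p[3]) / (sqrt(2) * p[4])))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(a1, a2, x0_init, 1.5),
      lower = c(-Inf, -Inf, min(d), 1e-4),
      upper = c(Inf, Inf, max(d), diff(range(d))),
      fn = function(p) sqrt(w) * (y - model(p)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop2("porequal_fit_failure", paste("erf fit failed:", conditionMessage(e))))
  if (!(fit$info %in% 1:4))
    stop2("porequal_fit_failure",
          paste("erf fit did not converge:", fit$message))
  p <- stats::setNames(fit$par, c("A1", "A2", "x0", "sigma"))
  if (p[["A2"]] - p[["A1"]] < contrast_floor)
    stop2("porequal_no_contrast", "no contrast: fitted plateau difference below floor")
  res <- y - model(fit$par)
  structure(list(
    A1 = unname(p[["A1"]]), A2 = unname(p[["A2"]]), x0 = unname(p[["x0"]]),
    sigma_fit = unname(p[["sigma"]]),
    rmse = sqrt(mean(res^2)),
    converged = TRUE,
    profile = profile,
    voxel_size = attr(profile, "voxel_size")
  ), class = "erf_fit")
}

predict_erf <- function(p, d)
  p[["A1"]] + (p[["A2"]] - p[["A1"]]) / 2 *
    (1 + erf((d - p[["x0"]]) / (sqrt(2) * p[["sigma"]])))

stop2 <- function(class, msg)
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))

#' @export
print.erf_fit <- function(x, ...) {
  cat(sprintf(
    "<erf_fit> A1 = %.4g, A2 = %.4g, x0 = %.3f vox, sigma = %.3f vox, rmse = %.3g\n",
    x$A1, x$A2, x$x0, x$sigma_fit, x$rmse))
  invisible(x)
}

#' @method tidy erf_fit
#' @export
tidy.erf_fit <- function(x, ...) {
  tibble::tibble(
    term = c("A1", "A2", "x0", "sigma_fit"),
    estimate = c(x$A1, x$A2, x$x0, x$sigma_fit))
}

#' @method glance erf_fit
#' @export
glance.erf_fit <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, converged = x$converged,
                 contrast = x$A2 - x$A1,
                 fwhm_model_nm = gaussian_fwhm(x$sigma_fit) * x$voxel_size)
}

#' Interface resolution as the FWHM of the blurring Gaussian
#'
#' The levels \eqn{L_1 = A_1 + c (A_2 - A_1)} and
#' \eqn{L_2 = A_1 + (1 - c)(A_2 - A_1)}, with
#' \eqn{c = [1 - \mathrm{erf}(\sqrt{\ln 2})]/2 \approx 0.1196}, are where the
#' ideal erf step brackets the half-maximum points of the blurring Gaussian;
#' the distance between the measured step-up curve's crossings of the two
#' levels is therefore the Gaussian's FWHM. Crossings are located by linear
#' interpolation between shells, taking the crossing pair bracketing the
#' fitted edge centre \code{x0}. The model-implied value
#' \eqn{2\sqrt{2\ln 2}\,\sigma_{fit}} is reported alongside for
#' cross-checking.
#'
#' @param profile the \code{edge_profile} the fit was made on.
#' @param fit an \code{\link{erf_fit}}.
#' @param voxel_size voxel edge length in nm (default: from the profile).
#' @param c_level level constant; default \code{\link{level_constant}()}.
#' @return one-row tibble: \code{fwhm_nm} (level-crossing estimate),
#'   \code{fwhm_model_nm}, \code{L1}, \code{L2}, \code{x1}, \code{x2}
#'   (voxels) and \code{defined}. A curve that does not cross a level within
#'   range gives \code{defined = FALSE} and NA widths.
#' @export
resolution_fwhm <- function(profile, fit, voxel_size = NULL,
                            c_level = level_constant()) {
  stopifnot(inherits(fit, "erf_fit"))
  vs <- voxel_size %||% attr(profile, "voxel_size")
  L1 <- fit$A1 + c_level * (fit$A2 - fit$A1)
  L2 <- fit$A1 + (1 - c_level) * (fit$A2 - fit$A1)
  x1 <- level_crossing(profile, L1, fit$x0, side = "below")
  x2 <- level_crossing(profile, L2, fit$x0, side = "above")
  defined <- is.finite(x1) && is.finite(x2) && x2 > x1
  tibble::tibble(
    fwhm_nm = if (defined) (x2 - x1) * vs else NA_real_,
    fwhm_model_nm = gaussian_fwhm(fit$sigma_fit) * vs,
    L1 = L1, L2 = L2, x1 = x1, x2 = x2, defined = defined)
}

# crossing of the measured curve with `level`, nearest to x0 from the given
# side (the pair bracketing x0). Brackets are found linearly between shell
# centres, then refined on a monotone Hermite interpolant of the neighbouring
# shells: plain linear interpolation on the convex erf tail overshoots the
# crossing by ~3% of the FWHM at unit shell spacing.
level_crossing <- function(profile, level, x0, side = c("below", "above")) {
  side <- match.arg(side)
  d <- profile$distance
  y <- profile$mean_gray
  xs <- c()
  for (i in seq_len(length(d) - 1)) {
    y0 <- y[i]; y1 <- y[i + 1]
    if (is.na(y0) || is.na(y1) || y0 == y1) next
    if ((y0 - level) * (y1 - level) <= 0) {
      xc <- d[i] + (level - y0) / (y1 - y0)
      lo <- max(1, i - 1); hi <- min(length(d), i + 2)
      if (hi - lo >= 2 && !anyNA(y[lo:hi])) {
        sf <- tryCatch(stats::splinefun(d[lo:hi], y[lo:hi], method = "monoH.FC"),
                       error = function(e) NULL)
        if (!is.null(sf) &&
            (sf(d[i]) - level) * (sf(d[i + 1]) - level) <= 0) {
          xc <- tryCatch(
            stats::uniroot(function(x) sf(x) - level, c(d[i], d[i + 1]),
                           tol = 1e-10)$root,
            error = function(e) xc)
        }
      }
      if (xc >= d[i] && xc <= d[i + 1]) xs <- c(xs, xc)
    }
  }
  if (length(xs) == 0) return(NA_real_)
  if (side == "below") {
    cand <- xs[xs <= x0]
    if (length(cand) == 0) cand <- xs
    cand[which.min(abs(cand - x0))]
  } else {
    cand <- xs[xs >= x0]
    if (length(cand) == 0) cand <- xs
    cand[which.min(abs(cand - x0))]
  }
}

#' Plot an edge profile with its fitted step model
#'
#' @param object an \code{edge_profile} or \code{erf_fit}.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot edge_profile
#' @export
autoplot.edge_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance, y = .data$mean_gray)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "signed distance from pore surface (voxels)",
                  y = "mean gray value",
                  title = "Edge-spread step-up curve")
}

#' @rdname autoplot.edge_profile
#' @method autoplot erf_fit
#' @export
autoplot.erf_fit <- function(object, ...) {
  prof <- object$profile
  dd <- seq(min(prof$distance), max(prof$distance), length.out = 200)
  fitted <- tibble::tibble(
    distance = dd,
    mean_gray = predict_erf(
      list(A1 = object$A1, A2 = object$A2, x0 = object$x0,
           sigma = object$sigma_fit), dd))
  autoplot.edge_profile(prof) +
    ggplot2::geom_line(data = fitted, color = "red3") +
    ggplot2::labs(subtitle = sprintf("sigma = %.2f vox, x0 = %.2f vox",
                                     object$sigma_fit, object$x0))
}
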