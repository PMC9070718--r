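#' Threshold a gray volume
#'
#' The pore phase is the brighter phase, so the mask is TRUE where the gray
#' value strictly exceeds the threshold.
#'
#' @param volume a \code{\link{gray_volume}}.
#' @param threshold finite scalar, or \code{"otsu"} to estimate it with
#'   \code{\link{otsu_threshold}}.
#' @return a \code{\link{binary_mask}} of the bright phase.
#' @export
binarize <- function(volume, threshold) {
  stopifnot(inherits(volume, "gray_volume"))
  if (identical(threshold, "otsu")) threshold <- otsu_threshold(volume$values)
  if (!is.finite(threshold)) stop("threshold must be finite")
  binary_mask(volume$values > threshold, volume$voxel_size)
}

#' Otsu's threshold
#'
#' Maximizes between-class variance on a 256-bin histogram of the values;
#' returns a threshold on the original gray scale.
#'
#' @param values numeric array or vector.
#' @param n_bins histogram bins.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(values, br, all.inside = TRUE), n_bins)
  mids <- (br[-1] + br[-(n_bins + 1L)]) / 2
  w1 <- cumsum(h)
  w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  bcv <- w1 * w2 * (m1 - m2)^2
  bcv[w1 == 0 | w2 == 0] <- -Inf
  mids[which.max(bcv)]
}

#' Label isolated (closed) pores
#'
#' Connected components of the pore mask, excluding the main pore space --
#' every component that touches the volume boundary -- and, when a
#' mineralized-tissue mask is supplied, every component whose one-voxel
#' dilation intersects tissue (pores in contact with tissue are not closed).
#' Remaining components are relabeled 1..K in scan order.
#'
#' @param pore_mask \code{\link{binary_mask}} of the pore phase.
#' @param bone_mask optional \code{\link{binary_mask}} of mineralized tissue.
#' @param connectivity 6, 18 or 26 (default) for the pore components.
#' @return a \code{\link{pore_label_volume}}; empty input gives 0 labels.
#' @export
find_isolated_pores <- function(pore_mask, bone_mask = NULL, connectivity = 26L) {
  stopifnot(inherits(pore_mask, "binary_mask"))
  m <- pore_mask$values
  d <- dim(m)
  lab <- label_array(m, connectivity)
  k <- max(lab)
  if (k == 0L) return(pore_label_volume(array(0L, d), pore_mask$voxel_size))

  drop <- logical(k)
  on_boundary <- unique(lab[boundary_shell(d) & m])
  drop[on_boundary] <- TRUE

  if (!is.null(bone_mask)) {
    stopifnot(inherits(bone_mask, "binary_mask"))
    if (!identical(dim(bone_mask$values), d)) stop("mask shapes differ")
    # labels within a 1-voxel (26-neighbourhood) dilation of bone: equivalently
    # bone voxels' neighbourhoods sampled on the label volume
    near <- edt_sq(!bone_mask$values) <= 3  # chebyshev-1 within sqrt(3) euclid
    touch <- unique(lab[near & m & lab > 0L])
    drop[touch] <- TRUE
  }

  keep <- which(!drop)
  new_id <- integer(k)
  new_id[keep] <- seq_along(keep)
  out <- array(0L, d)
  sel <- lab > 0L
  out[sel] <- new_id[lab[sel]]
  pore_label_volume(out, pore_mask$voxel_size)
}

#' Triangulated-isosurface area of a binary object
#'
#' Marching-tetrahedra area of the 0.5 level set of the object's indicator
#' field after light Gaussian smoothing (default sigma 0.8 voxel). The
#' smoothing suppresses the staircase overestimate of meshing raw binary
#' data (about +9 percent for spheres) while leaving the surface at the
#' voxelized boundary; the same estimator serves the shape factor and the
#' morphometry module. Surface cut off by the volume boundary is not
#' counted.
#'
#' @param mask logical 3D array.
#' @param smooth_sigma Gaussian sigma (voxels) applied to the indicator
#'   before meshing; 0 meshes the raw binary field.
#' @return surface area in voxel^2 units.
#' @export
surface_area_mesh <- function(mask, smooth_sigma = 0.8) {
  f <- array(as.double(mask), dim(mask))
  if (smooth_sigma > 0) f <- gaussian_smooth(f, smooth_sigma)
  mt_area(f, 0.5)
}

#' Per-pore shape descriptors
#'
#' For each label: voxel count, volume \code{V} (voxel count times voxel
#' volume, um^3), triangulated-isosurface area \code{A} (um^2) and the
#' sphericity shape factor \code{S = A / (36 pi V^2)^(1/3)}, which is scale
#' free, equals 1 for a perfect sphere and grows as the object becomes more
#' irregular.
#'
#' @param labels a \code{\link{pore_label_volume}}.
#' @param label optional subset of labels (default: all).
#' @param smooth_sigma see \code{\link{surface_area_mesh}}.
#' @return a tibble with columns \code{label}, \code{voxel_count},
#'   \code{volume_um3}, \code{surface_area_um2}, \code{sphericity}.
#' @export
pore_shapes <- function(labels, label = NULL, smooth_sigma = 0.8) {
  stopifnot(inherits(labels, "pore_label_volume"))
  ids <- label %||% seq_len(labels$n_labels)
  if (length(ids) == 0)
    return(tibble::tibble(label = integer(), voxel_count = integer(),
                          volume_um3 = double(), surface_area_um2 = double(),
                          sphericity = double()))
  if (!all(ids %in% seq_len(labels$n_labels))) stop("label absent from volume")
  vs_um <- labels$voxel_size * 1e-3
  pad <- ceiling(4 * smooth_sigma) + 1L
  purrr::map_dfr(ids, function(k) {
    sel <- labels$values == k
    bb <- mask_bbox(sel, pad = pad)
    sub <- sel[bb$x, bb$y, bb$z]
    count <- sum(sub)
    a_vox <- surface_area_mesh(sub, smooth_sigma)
    v_um3 <- count * vs_um^3
    a_um2 <- a_vox * vs_um^2
    tibble::tibble(
      label = as.integer(k), voxel_count = as.integer(count),
      volume_um3 = v_um3, surface_area_um2 = a_um2,
      sphericity = a_um2 / (36 * pi * v_um3^2)^(1 / 3))
  })
}

#' Size and sphericity pore filter
#'
#' Keeps pores with strictly more than \code{min_voxels} voxels and
#' sphericity strictly below \code{max_sphericity}; both inequalities are
#' strict. The input tibble is returned with logical columns
#' \code{passed_size_filter}, \code{passed_shape_filter} and \code{kept}
#' added, so excluded pores stay accounted for.
#'
#' @param shapes tibble from \code{\link{pore_shapes}}.
#' @param min_voxels size cutoff (default 1000).
#' @param max_sphericity shape cutoff (default 1.3).
#' @return the annotated tibble.
#' @export
filter_pores <- function(shapes, min_voxels = 1000, max_sphericity = 1.3) {
  dplyr::mutate(
    tibble::as_tibble(shapes),
    passed_size_filter = .data$voxel_count > min_voxels,
    passed_shape_filter = .data$sphericity < max_sphericity,
    kept = .data$passed_size_filter & .data$passed_shape_filter)
}

#' @importFrom rlang .data
NULL
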