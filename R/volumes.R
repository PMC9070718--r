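#' Gray-value volume
#'
#' A light wrapper around a numeric 3D array: the reconstructed scalar field
#' the metrics are computed on (the raw floating-point reconstruction in the
#' nanoCT use case). Dimensions are \code{(nx, ny, nz)} with voxel centers at
#' integer coordinates; all physical distances derive from \code{voxel_size}
#' in nanometres.
#'
#' @param values numeric 3D array, all finite.
#' @param voxel_size voxel edge length in nm (> 0).
#' @param origin numeric length-3 offset of voxel (1,1,1), default c(0,0,0).
#' @return an object of class \code{gray_volume}.
#' @export
gray_volume <- function(values, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (!all(is.finite(values))) stop("gray_volume values must all be finite")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    stop("voxel_size must be a single positive number (nm)")
  structure(
    list(values = values, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin)),
    class = "gray_volume"
  )
}

#' @export
print.gray_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<gray_volume> %d x %d x %d voxels, voxel size %.4g nm\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  gray range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.gray_volume <- function(x) dim(x$values)

#' Binary mask
#'
#' Logical 3D array marking one phase (e.g. the segmented pore space, the
#' paper-style binary segmentation). Must share the shape of its parent
#' volume.
#'
#' @param values logical 3D array.
#' @param voxel_size voxel edge length in nm.
#' @return an object of class \code{binary_mask}.
#' @export
binary_mask <- function(values, voxel_size) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  storage.mode(values) <- "logical"
  if (anyNA(values)) stop("binary_mask values must not contain NA")
  structure(list(values = values, voxel_size = as.numeric(voxel_size)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, %d foreground (%.2f%%)\n",
              d[1], d[2], d[3], sum(x$values), 100 * mean(x$values)))
  invisible(x)
}

#' @export
dim.binary_mask <- function(x) dim(x$values)

#' Labeled pore volume
#'
#' Integer 3D array with 0 = background and consecutive positive labels
#' 1..K, one connected component each (the labeled isolated-pore dataset).
#'
#' @param values integer 3D array of non-negative labels.
#' @param voxel_size voxel edge length in nm.
#' @return an object of class \code{pore_label_volume}.
#' @export
pore_label_volume <- function(values, voxel_size) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  storage.mode(values) <- "integer"
  if (anyNA(values) || any(values < 0)) stop("labels must be non-negative integers")
  k <- max(values)
  present <- sort(unique(values[values > 0]))
  if (k > 0 && !identical(present, seq_len(k)))
    stop("labels must be consecutive integers 1..K")
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 n_labels = as.integer(k)),
            class = "pore_label_volume")
}

#' @export
print.pore_label_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pore_label_volume> %d x %d x %d voxels, %d labels\n",
              d[1], d[2], d[3], x$n_labels))
  invisible(x)
}

#' @export
dim.pore_label_volume <- function(x) dim(x$values)

#' Three-phase map
#'
#' Integer 3D array with phase codes 0 = pore/void, 1 = scaffold,
#' 2 = mineralized tissue.
#'
#' @param values integer 3D array with values in \{0, 1, 2\}.
#' @param voxel_size voxel edge length in nm.
#' @return an object of class \code{phase_map}.
#' @export
phase_map <- function(values, voxel_size) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  storage.mode(values) <- "integer"
  if (anyNA(values) || !all(values %in% 0:2))
    stop("phase codes must be 0 (pore), 1 (scaffold) or 2 (mineralized tissue)")
  structure(list(values = values, voxel_size = as.numeric(voxel_size)),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  d <- dim(x$values)
  n <- length(x$values)
  cat(sprintf("<phase_map> %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  pore %.1f%% | scaffold %.1f%% | mineralized %.1f%%\n",
              100 * sum(x$values == 0L) / n, 100 * sum(x$values == 1L) / n,
              100 * sum(x$values == 2L) / n))
  invisible(x)
}

#' @export
dim.phase_map <- function(x) dim(x$values)

# ---- internal array helpers -------------------------------------------------

# squared Euclidean distance (voxels^2) from TRUE voxels to the nearest FALSE
# voxel; 0 on FALSE voxels. Out-of-grid space is not background.
edt_sq <- function(mask) {
  d <- dim(mask)
  array(cpp_edt_sq(as.logical(mask), as.integer(d)), d)
}

# connected-component labels, deterministic scan order
label_array <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  array(cpp_label(as.logical(mask), as.integer(d), as.integer(connectivity)), d)
}

# separable convolution with reflecting boundary
conv_sep <- function(vol, kernel) {
  d <- dim(vol)
  array(cpp_conv_sep(as.double(vol), as.integer(d), as.double(kernel)), d)
}

# normalized 1D Gaussian kernel truncated at `truncate` sigmas
gaussian_kernel <- function(sigma, truncate = 3) {
  if (sigma <= 0) return(1)
  r <- ceiling(truncate * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# 3D Gaussian smoothing (no-op for sigma = 0)
gaussian_smooth <- function(vol, sigma, truncate = 3) {
  if (sigma <= 0) return(vol)
  conv_sep(vol, gaussian_kernel(sigma, truncate))
}

# triangulated isosurface area (voxel^2 units) of a scalar field at `level`
mt_area <- function(field, level = 0.5) {
  cpp_mt_area(as.double(field), as.integer(dim(field)), as.double(level))
}

# bounding box of TRUE voxels, padded and clipped to the grid;
# returns list(x=, y=, z=) of index ranges or NULL for empty masks
mask_bbox <- function(mask, pad = 0L) {
  w <- which(mask)
  if (length(w) == 0) return(NULL)
  d <- dim(mask)
  ix <- (w - 1L) %% d[1] + 1L
  iy <- ((w - 1L) %/% d[1]) %% d[2] + 1L
  iz <- (w - 1L) %/% (d[1] * d[2]) + 1L
  list(
    x = max(1L, min(ix) - pad):min(d[1], max(ix) + pad),
    y = max(1L, min(iy) - pad):min(d[2], max(iy) + pad),
    z = max(1L, min(iz) - pad):min(d[3], max(iz) + pad)
  )
}

# TRUE where the voxel lies on any face of the grid
boundary_shell <- function(d) {
  b <- array(FALSE, d)
  b[c(1L, d[1]), , ] <- TRUE
  b[, c(1L, d[2]), ] <- TRUE
  b[, , c(1L, d[3])] <- TRUE
  b
}
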