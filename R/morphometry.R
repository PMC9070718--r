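#' Three-phase segmentation by double threshold
#'
#' Splits a gray volume into pore/void, scaffold and mineralized tissue with
#' two thresholds. The default mapping assigns tissue below \code{t_low},
#' scaffold in [\code{t_low}, \code{t_high}) and pore above, matching
#' reconstructions where tissue is darkest; pass \code{mapping} to permute
#' the assignment when the brightness ordering differs.
#'
#' @param volume a \code{\link{gray_volume}}.
#' @param t_low,t_high finite thresholds, \code{t_low < t_high}.
#' @param mapping integer length-3 phase codes for (below, between, above);
#'   default \code{c(2, 1, 0)} = (tissue, scaffold, pore).
#' @return a \code{\link{phase_map}}; warns when a phase comes out empty.
#' @export
three_phase_segment <- function(volume, t_low, t_high, mapping = c(2L, 1L, 0L)) {
  stopifnot(inherits(volume, "gray_volume"))
  if (!is.finite(t_low) || !is.finite(t_high)) stop("thresholds must be finite")
  if (t_low >= t_high) stop("t_low must be below t_high")
  if (!setequal(mapping, 0:2)) stop("mapping must be a permutation of 0:2")
  v <- volume$values
  codes <- array(mapping[1], dim(v))
  codes[v >= t_low & v < t_high] <- mapping[2]
  codes[v >= t_high] <- mapping[3]
  for (ph in c(scaffold = 1L)) if (!any(codes == ph))
    warning("scaffold phase is empty for these thresholds")
  phase_map(codes, volume$voxel_size)
}

# closed cavities of a phase: connected components of the complement that do
# not reach the volume boundary
closed_cavities <- function(mask, connectivity = 6L) {
  lab <- label_array(!mask, connectivity)
  if (max(lab) == 0L) return(array(FALSE, dim(mask)))
  open_ids <- unique(lab[boundary_shell(dim(mask)) & !mask])
  lab > 0L & !(lab %in% open_ids)
}

#' Specific surface area of a phase
#'
#' Triangulated-isosurface area of the phase (the same estimator as
#' \code{\link{pore_shapes}}) normalized two ways: by the bulk volume of the
#' analyzed region (specific surface area, um^-1) and by the phase volume
#' (surface-to-volume ratio, um^-1). With \code{include_closed = FALSE},
#' cavities fully enclosed by the phase are filled before surfacing, so their
#' walls do not count. Surface on the volume boundary is excluded.
#'
#' @param phases a \code{\link{phase_map}} (or a \code{\link{binary_mask}}).
#' @param phase phase code to analyze (default 1, scaffold).
#' @param include_closed count the walls of fully enclosed cavities?
#' @param smooth_sigma see \code{\link{surface_area_mesh}}.
#' @return one-row tibble: \code{surface_area_um2},
#'   \code{specific_surface_um_inv} (per bulk volume),
#'   \code{surface_to_volume_um_inv} (per phase volume),
#'   \code{phase_volume_um3}, \code{bulk_volume_um3}.
#' @export
specific_surface <- function(phases, phase = 1L, include_closed = TRUE,
                             smooth_sigma = 0.8) {
  if (inherits(phases, "binary_mask")) {
    mask <- phases$values
    vs <- phases$voxel_size
  } else {
    stopifnot(inherits(phases, "phase_map"))
    mask <- phases$values == phase
    vs <- phases$voxel_size
  }
  if (!any(mask)) stop("phase absent from volume")
  if (!include_closed) mask <- mask | closed_cavities(mask)
  vs_um <- vs * 1e-3
  a_um2 <- surface_area_mesh(mask, smooth_sigma) * vs_um^2
  phase_vol <- sum(mask) * vs_um^3
  bulk_vol <- length(mask) * vs_um^3
  tibble::tibble(
    surface_area_um2 = a_um2,
    specific_surface_um_inv = a_um2 / bulk_vol,
    surface_to_volume_um_inv = a_um2 / phase_vol,
    phase_volume_um3 = phase_vol,
    bulk_volume_um3 = bulk_vol)
}

#' Mineralized-tissue coverage of the scaffold surface
#'
#' Fraction of the available scaffold boundary faces whose adjacent voxel is
#' mineralized tissue. Faces are counted with 6-neighbour adjacency;
#' "available" excludes faces toward closed porosities (tissue cannot reach
#' them) and faces on the volume boundary.
#'
#' @param phases a \code{\link{phase_map}}.
#' @return one-row tibble: \code{coverage_fraction}, \code{n_faces_tissue},
#'   \code{n_faces_available}. No available scaffold boundary gives
#'   \code{coverage_fraction = NA} with a warning.
#' @export
surface_coverage <- function(phases) {
  stopifnot(inherits(phases, "phase_map"))
  v <- phases$values
  scaffold <- v == 1L
  if (!any(scaffold)) stop("scaffold phase absent")
  tissue <- v == 2L
  closed <- closed_cavities(scaffold)
  eligible_nb <- !scaffold & !closed  # open pore or tissue, not a closed cavity

  n_av <- 0; n_mt <- 0
  for (axis in 1:3) for (dir in c(-1L, 1L)) {
    nb_el <- shift_array(eligible_nb, axis, dir, fill = FALSE)
    nb_mt <- shift_array(tissue, axis, dir, fill = FALSE)
    n_av <- n_av + sum(scaffold & nb_el)
    n_mt <- n_mt + sum(scaffold & nb_el & nb_mt)
  }
  if (n_av == 0) {
    warning("scaffold has no available boundary faces")
    return(tibble::tibble(coverage_fraction = NA_real_, n_faces_tissue = 0L,
                          n_faces_available = 0L))
  }
  tibble::tibble(coverage_fraction = n_mt / n_av,
                 n_faces_tissue = as.integer(n_mt),
                 n_faces_available = as.integer(n_av))
}

# value of the neighbour at +dir along axis; `fill` beyond the boundary
shift_array <- function(a, axis, dir, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  n <- d[axis]
  src <- if (dir > 0) 2:n else 1:(n - 1)
  dst <- if (dir > 0) 1:(n - 1) else 2:n
  idx_src <- idx_dst <- list(quote(expr =), quote(expr =), quote(expr =))
  if (axis == 1) { out[dst, , ] <- a[src, , ] }
  else if (axis == 2) { out[, dst, ] <- a[, src, ] }
  else { out[, , dst] <- a[, , src] }
  out
}

#' Full morphometry report
#'
#' Per-phase volumes, scaffold surface area including and excluding closed
#' porosity (with both normalizations), and mineralized-tissue coverage of
#' the available scaffold surface.
#'
#' @param phases a \code{\link{phase_map}}.
#' @param smooth_sigma see \code{\link{surface_area_mesh}}.
#' @return a list of class \code{morphometry_report} with tibbles
#'   \code{phase_volumes}, \code{scaffold_surface} (rows including/excluding
#'   closed porosity) and \code{coverage}.
#' @export
morphometry_report <- function(phases, smooth_sigma = 0.8) {
  stopifnot(inherits(phases, "phase_map"))
  vs_um <- phases$voxel_size * 1e-3
  counts <- tabulate(phases$values + 1L, 3L)
  vols <- tibble::tibble(
    phase = c("pore", "scaffold", "mineralized_tissue"),
    code = 0:2, voxel_count = counts, volume_um3 = counts * vs_um^3)
  surf <- dplyr::bind_rows(
    dplyr::mutate(specific_surface(phases, 1L, include_closed = TRUE,
                                   smooth_sigma = smooth_sigma),
                  closed_porosity = "included"),
    dplyr::mutate(specific_surface(phases, 1L, include_closed = FALSE,
                                   smooth_sigma = smooth_sigma),
                  closed_porosity = "excluded"))
  structure(list(phase_volumes = vols,
                 scaffold_surface = surf,
                 coverage = surface_coverage(phases),
                 voxel_size = phases$voxel_size),
            class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat("<morphometry_report>\n")
  cat("phase volumes:\n"); print(x$phase_volumes)
  cat("scaffold surface:\n")
  print(x$scaffold_surface[, c("closed_porosity", "specific_surface_um_inv",
                               "surface_to_volume_um_inv")])
  cat(sprintf("tissue coverage of available scaffold surface: %.3f\n",
              x$coverage$coverage_fraction))
  invisible(x)
}
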