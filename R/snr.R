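#' Binary erosion with a spherical structuring element
#'
#' Erodes with the digital ball \{v : ||v||2 <= radius\} (voxel centres,
#' inclusive). Implemented through the exact squared Euclidean distance
#' transform: a voxel survives iff no background voxel -- including the
#' space outside the grid -- lies within the radius. Radius 0 is the
#' identity.
#'
#' @param mask logical 3D array or \code{\link{binary_mask}}.
#' @param radius integer erosion radius in voxels (>= 0), default 5.
#' @return same type as the input.
#' @export
erode_ball <- function(mask, radius = 5L) {
  stopifnot(radius >= 0, radius == round(radius))
  wrap <- inherits(mask, "binary_mask")
  m <- if (wrap) mask$values else mask
  if (radius == 0) return(mask)
  d <- dim(m)
  keep <- m & edt_sq(m) > radius^2
  # out-of-grid space is background: nearest outside voxel centre sits
  # straight out along an axis
  ix <- slice.index(m, 1); iy <- slice.index(m, 2); iz <- slice.index(m, 3)
  border <- pmin(ix, d[1] - ix + 1L, iy, d[2] - iy + 1L, iz, d[3] - iz + 1L)
  keep <- keep & border > radius
  if (wrap) binary_mask(keep, mask$voxel_size) else keep
}

#' Per-pore signal-to-noise ratio on eroded regions
#'
#' \deqn{SNR = \frac{\mu_{pore} - \mu_{scaffold}}
#'   {\max(\sigma_{pore}, \sigma_{scaffold})}}
#' computed on the gray values of the voxels remaining after erosion of the
#' pore and of the surrounding scaffold. Pores with no more than
#' \code{min_voxels} voxels remaining are flagged invalid and excluded from
#' aggregation, as is the degenerate noiseless case (both standard
#' deviations zero), whose SNR is reported as +Inf.
#'
#' @param volume a \code{\link{gray_volume}}.
#' @param pore_eroded logical array / \code{\link{binary_mask}} of the eroded
#'   pore.
#' @param scaffold_eroded logical array / \code{\link{binary_mask}} of the
#'   eroded scaffold region used for this pore (local shell or global).
#' @param min_voxels strict lower bound on eroded pore voxels (default 100:
#'   pores need more than 100 voxels remaining).
#' @return one-row tibble: \code{mu_pore}, \code{mu_scaffold},
#'   \code{sigma_pore}, \code{sigma_scaffold}, \code{snr},
#'   \code{n_pore_voxels}, \code{n_scaffold_voxels}, \code{valid}.
#' @export
pore_snr <- function(volume, pore_eroded, scaffold_eroded, min_voxels = 100) {
  stopifnot(inherits(volume, "gray_volume"))
  pe <- if (inherits(pore_eroded, "binary_mask")) pore_eroded$values else pore_eroded
  se <- if (inherits(scaffold_eroded, "binary_mask")) scaffold_eroded$values
        else scaffold_eroded
  if (any(pe & se)) stop("pore and scaffold regions must be disjoint")
  gp <- volume$values[pe]
  gs <- volume$values[se]
  np <- length(gp); ns <- length(gs)
  if (np == 0 || ns == 0)
    return(tibble::tibble(mu_pore = NA_real_, mu_scaffold = NA_real_,
                          sigma_pore = NA_real_, sigma_scaffold = NA_real_,
                          snr = NA_real_, n_pore_voxels = np,
                          n_scaffold_voxels = ns, valid = FALSE))
  mu_p <- mean(gp); mu_s <- mean(gs)
  sd_p <- if (np > 1) sd(gp) else 0
  sd_s <- if (ns > 1) sd(gs) else 0
  den <- max(sd_p, sd_s)
  snr <- if (den > 0) (mu_p - mu_s) / den else Inf
  valid <- np > min_voxels && is.finite(snr)
  tibble::tibble(mu_pore = mu_p, mu_scaffold = mu_s, sigma_pore = sd_p,
                 sigma_scaffold = sd_s, snr = snr, n_pore_voxels = np,
                 n_scaffold_voxels = ns, valid = valid)
}

#' Aggregate per-pore quality records
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of SNR and
#' resolution over the valid pores, plus the pore count -- the summary-table
#' shape used to compare scan configurations (SNR mean +/- STD, resolution
#' mean +/- STD, number of porosities).
#'
#' @param records tibble with columns \code{snr}, \code{resolution_nm} and
#'   validity flags (\code{snr_valid}, \code{resolution_defined}) or plain
#'   finite/NA values.
#' @return one-row tibble: \code{n_pores}, \code{snr_mean}, \code{snr_sd},
#'   \code{resolution_mean_nm}, \code{resolution_sd_nm}, \code{n_snr},
#'   \code{n_resolution}. With zero valid records, counts are 0 and moments
#'   NA; with one record the SD is reported as 0.
#' @export
aggregate_quality <- function(records) {
  records <- tibble::as_tibble(records)
  snr_ok <- if ("snr_valid" %in% names(records)) records$snr_valid
            else is.finite(records$snr)
  res_ok <- if ("resolution_defined" %in% names(records))
    records$resolution_defined else is.finite(records$resolution_nm)
  snr_ok[is.na(snr_ok)] <- FALSE
  res_ok[is.na(res_ok)] <- FALSE
  s <- records$snr[snr_ok]
  r <- records$resolution_nm[res_ok]
  msd <- function(x) {
    if (length(x) == 0) return(c(NA_real_, NA_real_))
    c(mean(x), if (length(x) > 1) sd(x) else 0)
  }
  sm <- msd(s); rm <- msd(r)
  tibble::tibble(
    n_pores = nrow(records),
    n_snr = length(s), snr_mean = sm[1], snr_sd = sm[2],
    n_resolution = length(r), resolution_mean_nm = rm[1],
    resolution_sd_nm = rm[2])
}
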