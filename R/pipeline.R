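#' Evaluation run configuration
#'
#' Bundles every tunable of the per-pore evaluation. Inputs are either a
#' \code{\link{phantom_spec}} (the volume and its segmentation are generated)
#' or paths / in-memory objects for the three datasets: labeled isolated
#' pores, binary pore-space mask and the raw gray volume. All parameters are
#' echoed verbatim into the output summary.
#'
#' @param phantom a \code{\link{phantom_spec}}, or NULL when volumes are given.
#' @param volume,pore_mask,labels gray volume, binary pore-space mask and
#'   label volume: objects, or file paths readable by
#'   \code{\link{read_volume}}.
#' @param bone_mask optional mineralized-tissue mask (object or path).
#' @param threshold numeric or \code{"otsu"}: re-segment the volume instead
#'   of using supplied/ground-truth masks; NULL (default) uses them directly.
#' @param min_voxels,max_sphericity pore filter (strict inequalities).
#' @param erosion_radius spherical-erosion radius in voxels for SNR.
#' @param snr_min_voxels strict lower bound on eroded pore voxels.
#' @param local_shell scaffold-neighbourhood radius (voxels) for per-pore
#'   scaffold statistics; used when \code{snr_scope = "local"}.
#' @param snr_scope \code{"local"} (default: scaffold within
#'   \code{local_shell} of the pore surface) or \code{"global"}.
#' @param max_range outside shell range in voxels; inside range is
#'   \code{min(max_range, inscribed radius)} per pore.
#' @param c_level level constant for the FWHM crossings.
#' @param connectivity component connectivity for segmentation.
#' @param smooth_sigma indicator smoothing for surface areas.
#' @param seed seed for any phantom generation.
#' @param output_dir optional directory for the per-pore CSV, summary JSON
#'   and run log.
#' @return a list of class \code{run_config}.
#' @export
run_config <- function(phantom = NULL, volume = NULL, pore_mask = NULL,
                       labels = NULL, bone_mask = NULL, threshold = NULL,
                       min_voxels = 1000, max_sphericity = 1.3,
                       erosion_radius = 5L, snr_min_voxels = 100,
                       local_shell = 15, snr_scope = c("local", "global"),
                       max_range = 10, c_level = level_constant(),
                       connectivity = 26L, smooth_sigma = 0.8,
                       seed = 1L, output_dir = NULL) {
  snr_scope <- match.arg(snr_scope)
  if (is.null(phantom) && is.null(volume))
    stop("provide either a phantom spec or a volume")
  structure(list(
    phantom = phantom, volume = volume, pore_mask = pore_mask,
    labels = labels, bone_mask = bone_mask, threshold = threshold,
    min_voxels = min_voxels, max_sphericity = max_sphericity,
    erosion_radius = as.integer(erosion_radius),
    snr_min_voxels = snr_min_voxels, local_shell = local_shell,
    snr_scope = snr_scope, max_range = max_range, c_level = c_level,
    connectivity = as.integer(connectivity), smooth_sigma = smooth_sigma,
    seed = as.integer(seed), output_dir = output_dir
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of \code{\link{run_config}}; a \code{phantom}
#' block holds \code{\link{phantom_spec}} arguments.
#'
#' @param path YAML file.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$phantom)) y$phantom <- do.call(phantom_spec, y$phantom)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, y)
}

resolve_volume <- function(x, reader, voxel_size = NULL) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) reader(x, voxel_size) else x
}

#' Run the full per-pore quality evaluation
#'
#' Orchestrates segmentation (or ground-truth/given masks), the size and
#' sphericity pore filter, the edge-spread resolution fit and the
#' erosion-based SNR for every isolated pore, then aggregates SNR and
#' resolution as mean +/- STD with pore counts. Fully deterministic given the
#' config (phantom randomness flows from the config seed); the only inputs
#' are the config values.
#'
#' @param config a \code{\link{run_config}} or path to a YAML config.
#' @return an object of class \code{porequal_run}: \code{records} (per-pore
#'   tibble), \code{summary} (one row), \code{exclusions} (reason counts),
#'   \code{config}, and \code{truth} when a phantom was generated.
#' @export
run_evaluation <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  truth <- NULL
  if (!is.null(config$phantom)) {
    spec <- config$phantom
    spec$seed <- config$seed
    gen <- generate_phantom(spec)
    volume <- gen$volume
    truth <- gen$truth
    say("phantom generated: %d pores, seed %d", spec$n_closed_pores, spec$seed)
    if (is.null(config$threshold)) {
      labels <- truth$labels
      pore_space <- truth$pore_space_mask
      bone <- truth$bone_mask
      say("using phantom ground-truth segmentation")
    } else {
      pore_space <- binarize(volume, config$threshold)
      bone <- truth$bone_mask
      labels <- find_isolated_pores(pore_space, bone, config$connectivity)
      say("re-segmented at threshold; %d isolated pores", labels$n_labels)
    }
  } else {
    volume <- resolve_volume(config$volume, read_volume)
    bone <- resolve_volume(config$bone_mask, read_volume)
    if (!is.null(bone) && !inherits(bone, "binary_mask"))
      bone <- binary_mask(bone$values > 0.5, volume$voxel_size)
    if (!is.null(config$threshold)) {
      pore_space <- binarize(volume, config$threshold)
      labels <- find_isolated_pores(pore_space, bone, config$connectivity)
    } else {
      pore_space <- resolve_volume(config$pore_mask, read_volume)
      if (!inherits(pore_space, "binary_mask"))
        pore_space <- binary_mask(pore_space$values > 0.5, volume$voxel_size)
      if (!is.null(config$labels)) {
        labels <- resolve_volume(config$labels, read_volume)
        if (!inherits(labels, "pore_label_volume"))
          labels <- pore_label_volume(
            array(as.integer(round(labels$values)), dim(labels$values)),
            volume$voxel_size)
      } else {
        labels <- find_isolated_pores(pore_space, bone, config$connectivity)
      }
    }
  }
  if (!identical(dim(labels$values), dim(volume$values)))
    stop("label volume and gray volume shapes differ")

  d <- dim(volume$values)
  scaffold <- !pore_space$values
  if (!is.null(bone)) scaffold <- scaffold & !bone$values
  halo <- ceiling(config$max_range / 2)  # blur-halo guard around other pores

  # pores touching the analyzed-volume boundary have truncated shells
  on_bd <- unique(labels$values[boundary_shell(d) & labels$values > 0L])
  n_lab <- labels$n_labels
  say("%d labeled pores, %d touch the volume boundary", n_lab, length(on_bd))

  shapes <- pore_shapes(labels, smooth_sigma = config$smooth_sigma)
  shapes <- filter_pores(shapes, config$min_voxels, config$max_sphericity)

  scaffold_eroded <- erode_ball(scaffold, config$erosion_radius)
  pad <- as.integer(max(config$local_shell, config$max_range) +
                      config$erosion_radius + 2)

  measure_one <- function(k) {
    rec <- list(id = k, fit_converged = FALSE, resolution_defined = FALSE,
                snr = NA_real_, snr_valid = FALSE, resolution_nm = NA_real_,
                fwhm_model_nm = NA_real_, rmse = NA_real_, x1 = NA_real_,
                x2 = NA_real_, n_pore_eroded = NA_integer_,
                n_scaffold_local = NA_integer_, fit_note = "")
    sel <- labels$values == k
    bb <- mask_bbox(sel, pad = pad)
    pm <- sel[bb$x, bb$y, bb$z]
    vol_c <- gray_volume(volume$values[bb$x, bb$y, bb$z], volume$voxel_size)
    scaf_c <- scaffold[bb$x, bb$y, bb$z]
    other_pore <- pore_space$values[bb$x, bb$y, bb$z] & !pm

    # context: scaffold away from the blur halo of any other pore
    context <- scaf_c
    if (any(other_pore) && halo > 0)
      context <- context & edt_sq(!other_pore) > halo^2

    sdf <- signed_distance(pm)
    prof <- withCallingHandlers(
      step_curve_sd(vol_c, sdf, pm, context, config$max_range),
      warning = function(w) invokeRestart("muffleWarning"))

    fit <- tryCatch(fit_erf(prof), error = function(e) e)
    if (inherits(fit, "error")) {
      rec$fit_note <- conditionMessage(fit)
    } else {
      rec$fit_converged <- TRUE
      rec$rmse <- fit$rmse
      res <- resolution_fwhm(prof, fit, volume$voxel_size, config$c_level)
      rec$resolution_defined <- res$defined
      rec$resolution_nm <- res$fwhm_nm
      rec$fwhm_model_nm <- res$fwhm_model_nm
      rec$x1 <- res$x1; rec$x2 <- res$x2
      if (!res$defined) rec$fit_note <- "level crossing not found"
    }

    pore_eroded <- erode_ball(pm, config$erosion_radius)
    scaf_eroded_c <- scaffold_eroded[bb$x, bb$y, bb$z]
    scaf_region <- if (config$snr_scope == "local")
      scaf_eroded_c & sdf < 0 & sdf >= -config$local_shell else scaf_eroded_c
    snr <- pore_snr(vol_c, pore_eroded, scaf_region, config$snr_min_voxels)
    rec$snr <- snr$snr
    rec$snr_valid <- snr$valid
    rec$n_pore_eroded <- snr$n_pore_voxels
    rec$n_scaffold_local <- snr$n_scaffold_voxels
    rec$mu_pore <- snr$mu_pore; rec$mu_scaffold <- snr$mu_scaffold
    rec$sigma_pore <- snr$sigma_pore; rec$sigma_scaffold <- snr$sigma_scaffold
    tibble::as_tibble(rec)
  }

  to_measure <- shapes$label[shapes$kept & !(shapes$label %in% on_bd)]
  empty_measured <- tibble::tibble(
    id = integer(), fit_converged = logical(), resolution_defined = logical(),
    snr = double(), snr_valid = logical(), resolution_nm = double(),
    fwhm_model_nm = double(), rmse = double(), x1 = double(), x2 = double(),
    n_pore_eroded = integer(), n_scaffold_local = integer(),
    fit_note = character(), mu_pore = double(), mu_scaffold = double(),
    sigma_pore = double(), sigma_scaffold = double())
  measured <- if (length(to_measure))
    purrr::map_dfr(to_measure, measure_one) else empty_measured

  records <- dplyr::left_join(
    dplyr::rename(shapes, id = "label"), measured, by = "id")
  records$passed_boundary <- !(records$id %in% on_bd)
  records$passed_erosion_filter <- records$kept & records$passed_boundary &
    !is.na(records$n_pore_eroded) &
    records$n_pore_eroded > config$snr_min_voxels
  records$passed_erosion_filter[is.na(records$passed_erosion_filter)] <- FALSE

  records$exclusion_reason <- dplyr::case_when(
    !records$passed_boundary ~ "boundary",
    !records$passed_size_filter ~ "size",
    !records$passed_shape_filter ~ "sphericity",
    !records$passed_erosion_filter ~ "erosion",
    !records$snr_valid | !records$resolution_defined |
      is.na(records$snr_valid) ~ "fit",
    TRUE ~ "kept")

  # aggregation uses kept, measurable pores
  agg_in <- dplyr::filter(records, .data$kept & .data$passed_boundary)
  summary <- aggregate_quality(agg_in)
  exclusions <- dplyr::count(records, .data$exclusion_reason, name = "n")
  say("kept %d / %d pores; SNR %.3g +/- %.3g (n=%d); resolution %.4g +/- %.3g nm (n=%d)",
      sum(records$exclusion_reason == "kept"), n_lab,
      summary$snr_mean, summary$snr_sd, summary$n_snr,
      summary$resolution_mean_nm, summary$resolution_sd_nm,
      summary$n_resolution)

  run <- structure(list(records = records, summary = summary,
                        exclusions = exclusions, config = config,
                        truth = truth, log = log_lines),
                   class = "porequal_run")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_pore_table(records, file.path(config$output_dir, "pores.csv"))
    cfg <- config
    cfg$phantom <- if (!is.null(cfg$phantom)) unclass(cfg$phantom) else NULL
    for (fld in c("volume", "pore_mask", "labels", "bone_mask"))
      if (!is.null(cfg[[fld]]) && !is.character(cfg[[fld]]))
        cfg[[fld]] <- "<in-memory>"
    jsonlite::write_json(
      list(summary = summary, exclusions = exclusions, config = unclass(cfg)),
      file.path(config$output_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(log_lines, file.path(config$output_dir, "run.log"))
  }
  run
}

#' @export
print.porequal_run <- function(x, ...) {
  cat("<porequal_run>\n")
  print(x$summary)
  cat("exclusions:\n")
  print(x$exclusions)
  invisible(x)
}

#' @method tidy porequal_run
#' @export
tidy.porequal_run <- function(x, ...) x$records

#' @method glance porequal_run
#' @export
glance.porequal_run <- function(x, ...) x$summary

#' Plot the per-pore quality metrics of a run
#'
#' @param object a \code{porequal_run}.
#' @param ... unused.
#' @return a ggplot object: SNR against resolution, colored by exclusion
#'   status.
#' @method autoplot porequal_run
#' @export
autoplot.porequal_run <- function(object, ...) {
  df <- dplyr::filter(object$records, !is.na(.data$snr) |
                        !is.na(.data$resolution_nm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$resolution_nm, y = .data$snr,
                                   color = .data$exclusion_reason)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "resolution FWHM (nm)", y = "SNR",
                  color = "status", title = "Per-pore image quality")
}
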