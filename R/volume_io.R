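#' Read a 3D volume from disk
#'
#' Supported layouts:
#' \itemize{
#'   \item multi-page TIFF (\code{.tif}/\code{.tiff}) with a JSON sidecar
#'     \code{<path>.json} carrying \code{voxel_size_nm} and, for rescaled
#'     float data, \code{scale}/\code{offset};
#'   \item a directory of numbered single-page TIFF slices, assembled in
#'     numeric order of the digits in their file names;
#'   \item raw binary with a JSON sidecar \code{<path>.json} declaring
#'     \code{shape} (nx, ny, nz; x fastest / z slowest on disk),
#'     \code{dtype} (\code{uint8}, \code{int16}, \code{uint16},
#'     \code{int32}, \code{float32}, \code{float64}), \code{byte_order}
#'     (\code{little}/\code{big}) and \code{voxel_size_nm}.
#' }
#'
#' @param path file or directory path.
#' @param voxel_size fallback voxel size in nm when no sidecar carries one.
#' @return a \code{\link{gray_volume}}.
#' @export
read_volume <- function(path, voxel_size = NULL) {
  if (dir.exists(path)) return(read_slice_dir(path, voxel_size))
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    return(read_tiff_stack(path, voxel_size))
  read_raw_volume(path, voxel_size)
}

sidecar_path <- function(path) paste0(path, ".json")

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) return(NULL)
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

read_tiff_stack <- function(path, voxel_size = NULL) {
  meta <- read_sidecar(path)
  # integer TIFFs are read as stored; float TIFFs come back in [0, 1] and are
  # mapped through the sidecar scale/offset
  scaled <- !is.null(meta$scale)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !scaled)
  if (!is.list(pages)) pages <- list(pages)
  vs <- meta$voxel_size_nm %||% voxel_size
  if (is.null(vs)) stop("voxel size not found: provide a sidecar or voxel_size")
  nz <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  vals <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) vals[, , k] <- t(pages[[k]])  # page rows = y, cols = x
  if (!is.null(meta$scale)) vals <- vals * meta$scale + meta$offset
  gray_volume(vals, vs)
}

read_slice_dir <- function(path, voxel_size = NULL) {
  files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0) stop("no TIFF slices in ", path)
  num <- suppressWarnings(as.numeric(gsub("\\D", "", basename(files))))
  if (anyNA(num) || anyDuplicated(num))
    stop("slice file names must contain unique slice numbers")
  files <- files[order(num)]
  meta <- read_sidecar(file.path(path, "volume"))
  vs <- meta$voxel_size_nm %||% voxel_size
  if (is.null(vs)) stop("voxel size not found: provide a sidecar or voxel_size")
  scaled <- !is.null(meta$scale)
  pages <- lapply(files, function(f) {
    p <- tiff::readTIFF(f, as.is = !scaled)
    if (is.list(p)) p <- p[[1]]
    p
  })
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  vals <- array(0, c(nx, ny, length(pages)))
  for (k in seq_along(pages)) vals[, , k] <- t(pages[[k]])
  if (!is.null(meta$scale)) vals <- vals * meta$scale + meta$offset
  gray_volume(vals, vs)
}

raw_dtypes <- list(
  uint8   = list(what = "integer", size = 1L, signed = FALSE),
  int16   = list(what = "integer", size = 2L, signed = TRUE),
  uint16  = list(what = "integer", size = 2L, signed = FALSE),
  int32   = list(what = "integer", size = 4L, signed = TRUE),
  float32 = list(what = "numeric", size = 4L, signed = TRUE),
  float64 = list(what = "numeric", size = 8L, signed = TRUE)
)

read_raw_volume <- function(path, voxel_size = NULL) {
  meta <- read_sidecar(path)
  if (is.null(meta)) stop("raw volume requires a JSON sidecar: ", sidecar_path(path))
  for (f in c("shape", "dtype")) if (is.null(meta[[f]]))
    stop("raw sidecar missing field: ", f)
  shape <- as.integer(meta$shape)
  dt <- raw_dtypes[[meta$dtype]]
  if (is.null(dt)) stop("unsupported raw dtype: ", meta$dtype)
  endian <- switch(meta$byte_order %||% "little", little = "little",
                   big = "big", stop("byte_order must be little or big"))
  n <- prod(shape)
  expected <- n * dt$size
  if (file.size(path) != expected)
    stop(sprintf("raw file size %d does not match declared shape (%d bytes)",
                 file.size(path), expected))
  con <- file(path, "rb"); on.exit(close(con))
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = endian)
  vs <- meta$voxel_size_nm %||% voxel_size
  if (is.null(vs)) stop("voxel size not found: provide it in the sidecar")
  # disk order z-slowest, x-fastest == R column-major (x, y, z)
  gray_volume(array(as.double(vals), shape), vs)
}

#' Write a 3D volume to disk
#'
#' Formats are selected by extension / arguments; a JSON sidecar
#' \code{<path>.json} always records the voxel size and, where needed, the
#' value scaling. Integer TIFF round-trips are exact; float TIFFs are stored
#' min--max rescaled to 32-bit with scale/offset in the sidecar (round trip
#' within float32 representation precision). Raw \code{float64} output is
#' lossless.
#'
#' @param volume a \code{\link{gray_volume}} (or a mask/label volume, written
#'   as integers).
#' @param path output path: \code{.tif}/\code{.tiff} for a multi-page TIFF,
#'   anything else for raw binary + sidecar.
#' @param dtype for raw output: one of \code{uint8}, \code{int16},
#'   \code{uint16}, \code{int32}, \code{float32}, \code{float64}; for TIFF:
#'   \code{uint8}, \code{uint16} or \code{float32}.
#' @param byte_order raw byte order, \code{little} (default) or \code{big}.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(volume, path, dtype = NULL, byte_order = "little") {
  vals <- volume_values(volume)
  vs <- volume_voxel_size(volume)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    write_tiff_stack(vals, vs, path, dtype %||% "float32")
  } else {
    write_raw_volume(vals, vs, path, dtype %||% "float64", byte_order)
  }
  invisible(path)
}

volume_values <- function(v) {
  if (inherits(v, c("gray_volume", "binary_mask", "pore_label_volume",
                    "phase_map"))) {
    out <- v$values
    storage.mode(out) <- "double"
    out
  } else if (is.array(v) && length(dim(v)) == 3) {
    out <- v; storage.mode(out) <- "double"; out
  } else stop("not a 3D volume object")
}

volume_voxel_size <- function(v) {
  if (is.list(v) && !is.null(v$voxel_size)) v$voxel_size else NA_real_
}

write_tiff_stack <- function(vals, vs, path, dtype) {
  d <- dim(vals)
  meta <- list(voxel_size_nm = vs, shape = d)
  if (dtype == "float32") {
    rng <- range(vals)
    scale <- if (diff(rng) > 0) diff(rng) else 1
    norm <- (vals - rng[1]) / scale
    meta$scale <- scale
    meta$offset <- rng[1]
    bits <- 32L
  } else if (dtype %in% c("uint8", "uint16")) {
    top <- if (dtype == "uint8") 255 else 65535
    if (min(vals) < 0 || max(vals) > top)
      stop("values out of range for ", dtype)
    norm <- vals / top  # rescaled back to integers by the writer
    bits <- if (dtype == "uint8") 8L else 16L
  } else stop("unsupported TIFF dtype: ", dtype)
  pages <- lapply(seq_len(d[3]), function(k) t(norm[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

write_raw_volume <- function(vals, vs, path, dtype, byte_order) {
  dt <- raw_dtypes[[dtype]]
  if (is.null(dt)) stop("unsupported raw dtype: ", dtype)
  d <- dim(vals)
  con <- file(path, "wb")
  v <- as.vector(vals)
  if (dt$what == "integer") {
    if (any(v != round(v))) stop("non-integer values cannot be written as ", dtype)
    writeBin(as.integer(v), con, size = dt$size, endian = byte_order)
  } else {
    writeBin(as.double(v), con, size = dt$size, endian = byte_order)
  }
  close(con)
  jsonlite::write_json(
    list(shape = d, dtype = dtype, byte_order = byte_order, voxel_size_nm = vs),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

#' Convert a volume to 8-bit
#'
#' Optional explicit linear min--max rescale to [0, 255]; the metric pipeline
#' itself always operates on the native floating-point values.
#'
#' @param volume a \code{\link{gray_volume}}.
#' @return a \code{\link{gray_volume}} with values in [0, 255] (integers).
#' @export
convert_8bit <- function(volume) {
  stopifnot(inherits(volume, "gray_volume"))
  v <- volume$values
  rng <- range(v)
  out <- if (diff(rng) > 0) round(255 * (v - rng[1]) / diff(rng)) else v * 0
  gray_volume(out, volume$voxel_size, volume$origin)
}

#' Write / read the per-pore quality table
#'
#' One row per pore with the stable column set \code{id}, \code{voxel_count},
#' \code{volume_um3}, \code{surface_area_um2}, \code{sphericity}, \code{snr},
#' \code{resolution_nm}, \code{passed_size_filter}, \code{passed_shape_filter},
#' \code{passed_erosion_filter}. Undefined values (e.g. a resolution whose
#' fit failed) are written as empty cells, never as 0.
#'
#' @param records tibble of per-pore records (see
#'   \code{\link{run_evaluation}}).
#' @param path CSV output path.
#' @return \code{path} invisibly (\code{write_pore_table});
#'   a tibble (\code{read_pore_table}).
#' @export
write_pore_table <- function(records, path) {
  cols <- c("id", "voxel_count", "volume_um3", "surface_area_um2",
            "sphericity", "snr", "resolution_nm", "passed_size_filter",
            "passed_shape_filter", "passed_erosion_filter")
  tab <- tibble::as_tibble(records)
  for (cl in setdiff(cols, names(tab))) tab[[cl]] <- NA
  readr::write_csv(tab[cols], path, na = "")
  invisible(path)
}

#' @rdname write_pore_table
#' @export
read_pore_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, col_types = readr::cols(
    id = "i", voxel_count = "d", volume_um3 = "d", surface_area_um2 = "d",
    sphericity = "d", snr = "d", resolution_nm = "d",
    passed_size_filter = "l", passed_shape_filter = "l",
    passed_erosion_filter = "l"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
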