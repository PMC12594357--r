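#' Construct a voxel volume
#'
#' A `voxel_volume` is a 3D logical grid of pore voxels (`TRUE` = pore) with
#' an isotropic voxel edge length in micrometres. The pore set may be empty
#' or disconnected.
#'
#' @param grid logical 3D array (or numeric array, nonzero coerced to pore).
#' @param resolution voxel edge length in micrometres (> 0).
#' @return object of class `voxel_volume` with fields `grid`, `dims`,
#'   `resolution`.
#' @export
voxel_volume <- function(grid, resolution = 1) {
  if (length(dim(grid)) != 3L) stop_config("grid must be a 3D array")
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop_config("resolution must be a positive scalar")
  g <- array(as.logical(grid != 0), dim = dim(grid))
  structure(list(grid = g, dims = dim(g), resolution = as.numeric(resolution)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("voxel_volume %dx%dx%d, resolution %g um, %d pore voxels (%.1f%%)\n",
              x$dims[1], x$dims[2], x$dims[3], x$resolution,
              sum(x$grid), 100 * mean(x$grid)))
  invisible(x)
}

as_volume <- function(x) {
  if (inherits(x, "voxel_volume")) return(x)
  if (is.array(x) && length(dim(x)) == 3L) return(voxel_volume(x))
  stop_config("expected a voxel_volume or a 3D array")
}

#' Load a 3D volume from disk
#'
#' Reads either a multi-page TIFF (one page per constant-`k` plane) or a raw
#' byte file accompanied by a JSON sidecar (`<path>.json`) giving `dims` and
#' `resolution`; in the raw format `i` is the fastest axis. Nonzero voxels
#' become pore.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tiff"` or `"raw"`.
#' @param dims integer vector of length 3, required for raw files without a
#'   sidecar.
#' @param resolution voxel edge length (micrometres); overrides the sidecar.
#' @return a [voxel_volume()].
#' @export
load_volume <- function(path, format = c("auto", "tiff", "raw"),
                        dims = NULL, resolution = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_config("file does not exist: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "raw"
  }
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) if (length(dim(p)) > 2L) p[, , 1] else p)
    d <- c(dim(pages[[1]]), length(pages))
    g <- array(FALSE, dim = d)
    for (k in seq_along(pages)) g[, , k] <- pages[[k]] != 0
    return(voxel_volume(g, resolution = if (is.null(resolution)) 1 else resolution))
  }
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(dims)) dims <- as.integer(meta$dims)
    if (is.null(resolution) && !is.null(meta$resolution)) resolution <- meta$resolution
  }
  if (is.null(dims) || length(dims) != 3L)
    stop_config("raw format requires dims (argument or JSON sidecar)")
  sz <- file.info(path)$size
  if (sz != prod(dims))
    stop_config("raw file has ", sz, " bytes but dims imply ", prod(dims))
  bytes <- readBin(path, what = "integer", n = prod(dims), size = 1L, signed = FALSE)
  voxel_volume(array(bytes != 0, dim = dims),
               resolution = if (is.null(resolution)) 1 else resolution)
}

#' Write a volume to disk
#'
#' Binary volumes are written as multi-page TIFF (0/1, one page per plane) or
#' as raw bytes with a JSON sidecar carrying `dims` and `resolution`.
#'
#' @param volume a [voxel_volume()].
#' @param path output path.
#' @param format `"tiff"` or `"raw"`.
#' @export
write_volume <- function(volume, path, format = c("tiff", "raw")) {
  volume <- as_volume(volume)
  format <- match.arg(format)
  if (format == "tiff") {
    pages <- lapply(seq_len(volume$dims[3]),
                    function(k) matrix(as.numeric(volume$grid[, , k]),
                                       volume$dims[1], volume$dims[2]))
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else {
    writeBin(as.raw(as.integer(volume$grid)), path)
    jsonlite::write_json(list(dims = volume$dims, resolution = volume$resolution),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# label images: stored as 32-bit float TIFF with values label/2^16 (exact
# dyadic fractions for labels < 2^24), or exactly as raw+sidecar CSV
write_labels_tiff <- function(labels, path) {
  d <- dim(labels)
  pages <- lapply(seq_len(d[3]),
                  function(k) matrix(labels[, , k] / 65536, d[1], d[2]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

read_labels_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(dim(pages[[1]]), length(pages))
  out <- array(0L, dim = d)
  for (k in seq_along(pages)) out[, , k] <- as.integer(round(pages[[k]] * 65536))
  out
}

#' Binarize a gray-level volume (median filter + Otsu)
#'
#' Applies a box median filter of the given radius, then an Otsu threshold
#' (exhaustive maximization of the between-class variance over 256 candidate
#' levels). Voxels strictly below the threshold are pore (pore space appears
#' dark in CT imagery); set `invert = TRUE` for bright pores.
#'
#' @param gray numeric 3D array of intensities.
#' @param median_radius box median filter radius in voxels (0 disables it).
#' @param invert if `TRUE`, voxels at or above the threshold become pore.
#' @param resolution voxel edge length, micrometres.
#' @return a [voxel_volume()]; the chosen threshold is in attribute
#'   `threshold`.
#' @export
binarize <- function(gray, median_radius = 1, invert = FALSE, resolution = 1) {
  if (length(dim(gray)) != 3L) stop_config("gray must be a 3D array")
  x <- gray
  if (median_radius >= 1)
    x <- median3d_cpp(as.numeric(x), dim(gray), as.integer(median_radius))
  rng <- range(x)
  if (rng[1] == rng[2])
    stop_numeric("constant image after filtering: no threshold exists")
  thr <- otsu_threshold(as.numeric(x))
  pore <- if (invert) array(x >= thr, dim(gray)) else array(x < thr, dim(gray))
  out <- voxel_volume(pore, resolution = resolution)
  attr(out, "threshold") <- thr
  out
}

# Otsu: scan all 256 bin boundaries of the value range, maximize between-class
# variance; returns the threshold value (lower bin edge of the best cut).
otsu_threshold <- function(x) {
  rng <- range(x)
  nb <- 256L
  br <- seq(rng[1], rng[2], length.out = nb + 1L)
  h <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), nb), nbins = nb)
  w <- cumsum(h)
  m <- cumsum(h * seq_len(nb))
  n <- w[nb]; mt <- m[nb]
  w0 <- w[-nb]; m0 <- m[-nb]
  valid <- w0 > 0 & w0 < n
  bc <- rep(-Inf, nb - 1L)
  bc[valid] <- (mt * w0[valid] - n * m0[valid])^2 / (w0[valid] * (n - w0[valid]))
  cut <- which.max(bc)
  br[cut + 1L]
}

#' Boundary voxels of the pore set
#'
#' A pore voxel is on the boundary B when at least one of its 26 neighbours
#' lies outside the pore set S; voxels on the array border count as having
#' outside neighbours.
#'
#' @param volume a [voxel_volume()] or logical 3D array.
#' @return integer matrix of boundary voxel coordinates (columns `i`,`j`,`k`,
#'   1-based), in lexicographic order.
#' @export
boundary <- function(volume) {
  volume <- as_volume(volume)
  voxel_coords(boundary_mask(volume$grid))
}

boundary_mask <- function(grid) {
  d <- dim(grid)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- grid
  all26 <- array(TRUE, d)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    all26 <- all26 & pad[(2:(d[1] + 1)) + di, (2:(d[2] + 1)) + dj, (2:(d[3] + 1)) + dk, drop = FALSE]
  }
  grid & !all26
}
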