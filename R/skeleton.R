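#' Euclidean distance transform of the pore set
#'
#' For each pore voxel, the Euclidean distance (voxel units, between voxel
#' centres) to the nearest background voxel; the array border counts as
#' background. Diagnostic only — the thinning algorithm does not consume it.
#'
#' @param volume a [voxel_volume()] or logical 3D array with nonempty pore set.
#' @return object of class `distance_map`: list with `values` (numeric array,
#'   `NA` outside the pore set) and `dims`.
#' @export
distance_transform <- function(volume) {
  volume <- as_volume(volume)
  if (!any(volume$grid)) stop_numeric("empty pore set: distance transform undefined")
  d <- volume$dims
  pad <- array(TRUE, d + 2L)                      # background everywhere ...
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- !volume$grid  # ... except pores
  d2 <- edt_sq_cpp(pad, d + 2L)
  vals <- sqrt(d2[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)])
  vals[!volume$grid] <- NA_real_
  structure(list(values = vals, dims = d), class = "distance_map")
}

#' Euler characteristic of a voxel set
#'
#' Computed on the cubical complex spanned by the pore voxels (union of
#' closed unit cubes) as vertices - edges + faces - octants. For the
#' 26-connected object this equals components - tunnels + cavities.
#'
#' @param volume a [voxel_volume()] or logical 3D array.
#' @return integer.
#' @export
euler_characteristic <- function(volume) {
  volume <- as_volume(volume)
  as.integer(chi_cpp(volume$grid, volume$dims))
}

#' Test whether a pore voxel may be deleted during homotopic thinning
#'
#' A voxel is deletable when it (i) lies on the boundary of the pore set,
#' (ii) is not an ending point (a voxel with at most one 26-neighbour),
#' (iii) its removal preserves the Euler characteristic, and (iv) its removal
#' preserves the number of 26-connected components. Conditions (iii)/(iv) are
#' evaluated on the 3x3x3 neighbourhood (simple-point test); the Euler part of
#' the local test is exactly equivalent to the global one because every
#' complex cell incident to the voxel lies inside the block.
#'
#' @param volume a [voxel_volume()] or logical 3D array.
#' @param voxel integer vector `c(i, j, k)`, 1-based; must be a pore voxel.
#' @return logical scalar.
#' @export
is_deletable <- function(volume, voxel) {
  volume <- as_volume(volume)
  v <- as.integer(voxel)
  if (length(v) != 3L) stop_config("voxel must be c(i, j, k)")
  if (any(v < 1L) || any(v > volume$dims))
    stop_config("voxel out of bounds")
  if (!volume$grid[v[1], v[2], v[3]]) stop_config("voxel is not in the pore set")
  is_deletable_cpp(volume$grid, volume$dims, v[1] - 1L, v[2] - 1L, v[3] - 1L)
}

#' Curve skeleton by homotopic thinning
#'
#' Repeatedly deletes deletable boundary voxels until the fixed point is
#' reached. Each pass collects the current boundary voxels in lexicographic
#' (i,j,k) order and attempts deletions sequentially against the already
#' updated volume, so the result is reproducible bit-for-bit. The skeleton
#' has the same number of 26-connected components and the same Euler
#' characteristic as the input, is one voxel thick, and is a fixed point of
#' the procedure (idempotence). No pruning of small branches is performed.
#'
#' @param volume a [voxel_volume()] or logical 3D array (disconnected pore
#'   sets allowed).
#' @return object of class `skeleton`: list with `mask` (logical array),
#'   `voxels` (coordinate matrix), `parent_dims`, `resolution`.
#' @export
curve_skeletonize <- function(volume) {
  volume <- as_volume(volume)
  sk <- thin_cpp(volume$grid, volume$dims)
  structure(list(mask = sk, voxels = voxel_coords(sk),
                 parent_dims = volume$dims, resolution = volume$resolution),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("skeleton: %d voxels in %dx%dx%d volume\n", nrow(x$voxels),
              x$parent_dims[1], x$parent_dims[2], x$parent_dims[3]))
  invisible(x)
}

as_skeleton <- function(x) {
  if (inherits(x, "skeleton")) return(x)
  if (is.array(x) && length(dim(x)) == 3L && is.logical(x))
    return(structure(list(mask = x, voxels = voxel_coords(x),
                          parent_dims = dim(x), resolution = 1),
                     class = "skeleton"))
  stop_config("expected a skeleton or logical 3D array")
}

#' Export a skeleton as a CSV of voxel coordinates
#' @param skeleton a [curve_skeletonize()] result.
#' @param path output CSV path.
#' @export
write_skeleton_csv <- function(skeleton, path) {
  write.csv(as.data.frame(skeleton$voxels), path, row.names = FALSE)
  invisible(path)
}
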