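#' Classify skeleton voxels as ending, simple or interior
#'
#' Classification by the number of 26-neighbours within the skeleton: ending
#' voxels have one neighbour, simple voxels exactly two, interior voxels more
#' than two. Isolated voxels (no neighbour) are classed as ending.
#'
#' @param skeleton a [curve_skeletonize()] result (or logical 3D array).
#' @return object of class `skeleton_classification`: list with `class`
#'   (integer array: 0 background, 1 ending, 2 simple, 3 interior),
#'   `nbr_count` (integer array) and `table` (counts per class).
#' @export
classify_voxels <- function(skeleton) {
  skeleton <- as_skeleton(skeleton)
  nc <- neighbour_count_cpp(skeleton$mask, skeleton$parent_dims)
  cls <- array(0L, skeleton$parent_dims)
  cls[skeleton$mask & nc <= 1L] <- 1L
  cls[skeleton$mask & nc == 2L] <- 2L
  cls[skeleton$mask & nc > 2L] <- 3L
  tab <- c(ending = sum(cls == 1L), simple = sum(cls == 2L), interior = sum(cls == 3L))
  structure(list(class = cls, nbr_count = nc, table = tab, skeleton = skeleton),
            class = "skeleton_classification")
}

#' @export
print.skeleton_classification <- function(x, ...) {
  cat(sprintf("skeleton classification: %d ending, %d simple, %d interior\n",
              x$table["ending"], x$table["simple"], x$table["interior"]))
  invisible(x)
}

#' Segment a skeleton into maximal simple branches
#'
#' A branch is a maximal 26-connected set of simple voxels. Ending and
#' interior voxels are attached so that every skeleton voxel carries exactly
#' one branch id: an ending voxel joins the branch of its unique neighbour,
#' an interior (junction) voxel joins the adjacent branch with the smallest
#' id; attachment is iterated so chains resolve. Skeleton voxels with no
#' reachable branch (isolated voxels, or clusters with no simple voxel, e.g.
#' a tiny "+") form their own branches. Core branch ids are assigned in
#' lexicographic order of each branch's minimal voxel; leftover branches get
#' subsequent ids in the same order.
#'
#' @param skeleton a [curve_skeletonize()] result.
#' @param classification optional [classify_voxels()] result (recomputed
#'   when missing).
#' @return object of class `branch_set`: list with `labels` (integer array,
#'   0 off-skeleton), `n` branches, `sizes`, and the `skeleton`.
#' @export
segment_branches <- function(skeleton, classification = NULL) {
  skeleton <- as_skeleton(skeleton)
  if (is.null(classification)) classification <- classify_voxels(skeleton)
  cls <- classification$class
  d <- skeleton$parent_dims

  lab <- label_components_cpp(cls == 2L, d, 26L)
  lab <- relabel_lexicographic(lab)
  nb <- max(lab)

  # iterative attachment of ending/interior voxels to adjacent branches
  repeat {
    todo <- which(skeleton$mask & lab == 0L)
    if (length(todo) == 0L) break
    nbmin <- neighbour_min_label(lab, d, todo)
    assignable <- nbmin > 0L
    if (!any(assignable)) break
    lab[todo[assignable]] <- nbmin[assignable]
  }

  # leftover clusters (no simple voxel anywhere reachable) become new branches
  left <- skeleton$mask & lab == 0L
  if (any(left)) {
    extra <- label_components_cpp(left, d, 26L)
    extra <- relabel_lexicographic(extra)
    lab[left] <- nb + extra[left]
    nb <- nb + max(extra)
  }

  structure(list(labels = lab, n = nb,
                 sizes = tabulate(lab[lab > 0L], nbins = nb),
                 skeleton = skeleton),
            class = "branch_set")
}

# smallest positive branch label among the 26 neighbours of each given voxel
neighbour_min_label <- function(lab, d, idx) {
  i <- (idx - 1L) %% d[1] + 1L
  j <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
  k <- (idx - 1L) %/% (d[1] * d[2]) + 1L
  best <- rep.int(.Machine$integer.max, length(idx))
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    ii <- i + di; jj <- j + dj; kk <- k + dk
    ok <- ii >= 1L & jj >= 1L & kk >= 1L & ii <= d[1] & jj <= d[2] & kk <= d[3]
    if (!any(ok)) next
    v <- integer(length(idx))
    v[ok] <- lab[cbind(ii[ok], jj[ok], kk[ok])]
    sel <- ok & v > 0L & v < best
    best[sel] <- v[sel]
  }
  best[best == .Machine$integer.max] <- 0L
  best
}

#' @export
print.branch_set <- function(x, ...) {
  cat(sprintf("branch set: %d branches over %d skeleton voxels\n",
              x$n, sum(x$labels > 0L)))
  invisible(x)
}

#' Export branches as a per-branch CSV (id, size)
#' @param branches a [segment_branches()] result.
#' @param path output CSV path.
#' @export
write_branches_csv <- function(branches, path) {
  write.csv(data.frame(id = seq_len(branches$n), size = branches$sizes),
            path, row.names = FALSE)
  invisible(path)
}
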