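#' Construct a pore graph from node and arc tables
#'
#' @param nodes data.frame with at least `id`, `volume` (voxel^3) and
#'   centroid columns `cx`, `cy`, `cz` (voxel units).
#' @param arcs data.frame with columns `r`, `s` (region ids, `r < s`),
#'   `faces` (shared voxel faces) and `distance` (centre-to-centre, voxel
#'   units); may have zero rows.
#' @param resolution voxel edge length, micrometres.
#' @return object of class `pore_graph`.
#' @export
pore_graph <- function(nodes, arcs, resolution = 1) {
  stopifnot(is.data.frame(nodes), is.data.frame(arcs))
  if (!all(c("id", "volume") %in% names(nodes)))
    stop_config("nodes must have columns id and volume")
  if (nrow(arcs) > 0L) {
    if (!all(c("r", "s") %in% names(arcs))) stop_config("arcs must have columns r and s")
    if (any(arcs$r == arcs$s)) stop_config("self-arcs are not allowed")
    lo <- pmin(arcs$r, arcs$s); hi <- pmax(arcs$r, arcs$s)
    arcs$r <- lo; arcs$s <- hi
    if (anyDuplicated(lo * (max(hi) + 1) + hi)) stop_config("duplicate arcs")
    if (!all(c(arcs$r, arcs$s) %in% nodes$id)) stop_config("arc endpoint not a node")
  }
  structure(list(nodes = nodes, arcs = arcs, resolution = resolution),
            class = "pore_graph")
}

#' Build the attributed relational graph from a region partition
#'
#' One pass over the label image: for each pore voxel, the three
#' positive-direction neighbours `(i+1,j,k)`, `(i,j+1,k)`, `(i,j,k+1)` are
#' examined; each pair of differing positive labels creates (or increments)
#' an arc whose attribute counts shared voxel faces. Adjacency is therefore
#' face-only (6-connectivity); edge or corner contacts do not create arcs.
#' Arc distance is the Euclidean distance between the two region centroids
#' (voxel units), floored at 1 voxel for interlocking regions whose centroids
#' come closer than one voxel (logged via `message()`).
#'
#' @param partition a [assign_regions()] or [partition_from_labels()] result.
#' @param resolution voxel edge length (defaults to the partition's).
#' @return a [pore_graph()]: nodes carry `id`, `source_branch`, centroid
#'   (`cx`,`cy`,`cz`) and `volume`; arcs carry `faces`, `area_um2` and
#'   `distance`.
#' @export
build_graph <- function(partition, resolution = partition$resolution) {
  L <- partition$labels
  d <- dim(L)
  pairs_r <- integer(0); pairs_s <- integer(0)
  for (axis in 1:3) {
    n <- d[axis]
    if (n < 2L) next
    a <- switch(axis,
                L[-n, , , drop = FALSE],
                L[, -n, , drop = FALSE],
                L[, , -n, drop = FALSE])
    b <- switch(axis,
                L[-1, , , drop = FALSE],
                L[, -1, , drop = FALSE],
                L[, , -1, drop = FALSE])
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) {
      pairs_r <- c(pairs_r, pmin(a[sel], b[sel]))
      pairs_s <- c(pairs_s, pmax(a[sel], b[sel]))
    }
  }
  nodes <- data.frame(id = partition$regions$id,
                      source_branch = partition$regions$source_branch,
                      cx = partition$regions$cx,
                      cy = partition$regions$cy,
                      cz = partition$regions$cz,
                      volume = partition$regions$volume_voxels)
  if (length(pairs_r) == 0L) {
    arcs <- data.frame(r = integer(0), s = integer(0), faces = integer(0),
                       area_um2 = numeric(0), distance = numeric(0))
    return(pore_graph(nodes, arcs, resolution))
  }
  key <- as.double(pairs_r) * (nrow(nodes) + 1) + pairs_s
  o <- order(key)
  rl <- rle(key[o])
  first <- o[cumsum(c(1L, head(rl$lengths, -1L)))]
  r <- pairs_r[first]; s <- pairs_s[first]
  faces <- rl$lengths
  dx <- nodes$cx[r] - nodes$cx[s]
  dy <- nodes$cy[r] - nodes$cy[s]
  dz <- nodes$cz[r] - nodes$cz[s]
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  floored <- dist < 1
  if (any(floored))
    message("build_graph: ", sum(floored), " arc distance(s) floored at 1 voxel")
  dist[floored] <- 1
  arcs <- data.frame(r = r, s = s, faces = as.integer(faces),
                     area_um2 = faces * resolution^2, distance = dist)
  pore_graph(nodes, arcs, resolution)
}

#' @export
print.pore_graph <- function(x, ...) {
  cat(sprintf("pore graph: %d nodes, %d arcs (GCI %.2f)\n",
              nrow(x$nodes), nrow(x$arcs),
              if (nrow(x$nodes) > 0) nrow(x$arcs) / nrow(x$nodes) else NA))
  invisible(x)
}

#' Global Connectivity Indicator
#'
#' The number of arcs divided by the number of nodes of the pore graph, a
#' scalar summary of how interconnected the pore network is.
#'
#' @param graph a [pore_graph()].
#' @return ratio (numeric scalar); 0 for a graph without arcs.
#' @export
gci <- function(graph) {
  if (!inherits(graph, "pore_graph")) stop_config("graph must be a pore_graph")
  if (nrow(graph$nodes) < 1L) stop_numeric("gci undefined for an empty graph")
  nrow(graph$arcs) / nrow(graph$nodes)
}

#' Minimal pore graph with prescribed node and arc counts
#'
#' Builds a structurally valid graph carrying the given counts (unit volumes,
#' zero centroids, unit contact faces), for connectivity arithmetic such as
#' [gci()] on networks whose only published description is their size.
#'
#' @param n_nodes number of nodes.
#' @param n_arcs number of distinct arcs (at most `choose(n_nodes, 2)`).
#' @return a [pore_graph()].
#' @export
make_counts_graph <- function(n_nodes, n_arcs) {
  n_nodes <- as.integer(n_nodes); n_arcs <- as.integer(n_arcs)
  if (n_arcs > n_nodes * (n_nodes - 1) / 2)
    stop_config("too many arcs for ", n_nodes, " nodes")
  r <- integer(0); s <- integer(0); offset <- 1L
  while (length(r) < n_arcs) {
    take <- min(n_nodes - offset, n_arcs - length(r))
    r <- c(r, seq_len(take))
    s <- c(s, seq_len(take) + offset)
    offset <- offset + 1L
  }
  nodes <- data.frame(id = seq_len(n_nodes), volume = 1,
                      cx = 0, cy = 0, cz = 0)
  arcs <- data.frame(r = r, s = s, faces = 1L, area_um2 = 1, distance = 1)
  pore_graph(nodes, arcs, resolution = 1)
}

#' Convert a pore graph to an igraph object
#' @param graph a [pore_graph()].
#' @return an `igraph` graph with node/arc attributes.
#' @export
as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = nrow(graph$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(graph$nodes$id))
  for (nm in setdiff(names(graph$nodes), "id"))
    g <- igraph::set_vertex_attr(g, nm, value = graph$nodes[[nm]])
  if (nrow(graph$arcs) > 0L) {
    g <- igraph::add_edges(g, rbind(graph$arcs$r, graph$arcs$s))
    for (nm in setdiff(names(graph$arcs), c("r", "s")))
      g <- igraph::set_edge_attr(g, nm, value = graph$arcs[[nm]])
  }
  g
}

#' Is the pore graph connected?
#' @param graph a [pore_graph()].
#' @return logical.
#' @export
graph_connected <- function(graph) {
  igraph::is_connected(as_igraph(graph))
}

#' Export a pore graph as GraphML
#' @param graph a [pore_graph()].
#' @param path output path.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' Export the arc list as CSV
#' @param graph a [pore_graph()].
#' @param path output path.
#' @export
write_arcs_csv <- function(graph, path) {
  write.csv(graph$arcs, path, row.names = FALSE)
  invisible(path)
}
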