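# Connected-component labeling of sparse voxel sets. Components are
# computed on the graph whose vertices are the supplied voxels and whose
# edges join 26-neighbours (in 2D, i.e. with a singleton z axis, this
# degenerates to the standard 8-connectivity). Only voxels above
# threshold are ever passed in, so the graph stays small even for large
# stacks.

labelComponents <- function(coords, dims) {
  k <- nrow(coords)
  if (k == 0L) return(integer())
  if (k == 1L) return(1L)
  nz <- dims[1L]; ny <- dims[2L]; nx <- dims[3L]
  encode <- function(cc)
    (cc[, 3L] - 1) * (as.double(ny) * nz) + (cc[, 2L] - 1) * nz + cc[, 1L]
  codes <- encode(coords)
  ord <- order(codes)
  sortedCodes <- codes[ord]
  offsets <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offsets <- offsets[!(offsets$dz == 0 & offsets$dy == 0 & offsets$dx == 0), ]
  edges <- vector("list", nrow(offsets))
  for (o in seq_len(nrow(offsets))) {
    nb <- cbind(coords[, 1L] + offsets$dz[o],
                coords[, 2L] + offsets$dy[o],
                coords[, 3L] + offsets$dx[o])
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= nz &
          nb[, 2L] >= 1L & nb[, 2L] <= ny &
          nb[, 3L] >= 1L & nb[, 3L] <= nx
    if (!any(ok)) next
    hit <- findInterval(encode(nb[ok, , drop = FALSE]), sortedCodes)
    valid <- hit >= 1L &
      sortedCodes[pmax(hit, 1L)] == encode(nb[ok, , drop = FALSE])
    if (!any(valid)) next
    edges[[o]] <- cbind(which(ok)[valid], ord[hit[valid]])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  as.integer(igraph::components(g)$membership)
}
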