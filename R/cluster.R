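#' Label connected components of a 3-D binary map
#'
#' Connected-component labelling of supra-threshold voxels under 6-, 18-, or
#' 26-neighbour connectivity (default 26, i.e. face, edge, and corner
#' neighbours).
#'
#' @param mask logical 3-D array.
#' @param connectivity one of 6, 18, 26.
#' @return List with `labels` (integer 3-D array, 0 = background, clusters
#'   numbered by decreasing size) and `sizes` (integer vector of cluster
#'   sizes, one per label).
#' @export
label_clusters <- function(mask, connectivity = 26L) {
  if (length(dim(mask)) != 3L || !is.logical(mask))
    stop("`mask` must be a logical 3-D array")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18, or 26")
  d <- dim(mask)
  nv <- sum(mask)
  labels <- array(0L, d)
  if (nv == 0L) return(list(labels = labels, sizes = integer(0)))

  ids <- array(0L, d)
  ids[mask] <- seq_len(nv)

  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nonzero <- rowSums(offs != 0)
  offs <- offs[nonzero > 0 & nonzero <= switch(as.character(connectivity),
                                               "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  ## keep one of each +/- pair (lexicographically positive)
  keep <- offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
                                             (offs[, 2] == 0 & offs[, 1] > 0)))
  offs <- offs[keep, , drop = FALSE]

  edges <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    off <- offs[o, ]
    sx <- seq.int(max(1L, 1L - off[1]), min(d[1], d[1] - off[1]))
    sy <- seq.int(max(1L, 1L - off[2]), min(d[2], d[2] - off[2]))
    sz <- seq.int(max(1L, 1L - off[3]), min(d[3], d[3] - off[3]))
    a <- ids[sx, sy, sz, drop = FALSE]
    b <- ids[sx + off[1], sy + off[2], sz + off[3], drop = FALSE]
    sel <- a > 0L & b > 0L
    if (any(sel)) edges[[o]] <- cbind(a[sel], b[sel])
  }
  edges <- do.call(rbind, edges)

  if (is.null(edges)) {
    comp <- seq_len(nv)
  } else {
    gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0L, nv - igraph::vcount(gr)))
    comp <- igraph::components(gr)$membership
  }
  sizes <- tabulate(comp)
  ord <- order(sizes, decreasing = TRUE)
  relabel <- integer(length(sizes))
  relabel[ord] <- seq_along(ord)
  labels[mask] <- relabel[comp]
  list(labels = labels, sizes = sizes[ord])
}
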