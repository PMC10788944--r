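# Molecular-graph utilities built on igraph: connectivity, isomorphism with
# element/bond-order labels, maximum common substructure (modular-product
# clique), ring-bond detection.

# igraph graph of a structure; vertex attr `el`, edge attr `order`
mol_graph <- function(m, heavy_only = FALSE) {
  keep <- if (heavy_only) which(is_heavy(m)) else seq_len(n_atoms(m))
  ms <- if (heavy_only) subset_structure(m, keep) else m
  g <- igraph::make_empty_graph(n = n_atoms(ms), directed = FALSE)
  if (nrow(ms$bonds)) {
    g <- igraph::add_edges(g, rbind(ms$bonds$i, ms$bonds$j))
    igraph::E(g)$order <- ms$bonds$order
  }
  igraph::V(g)$el <- ms$atoms$element
  attr(g, "atom_idx") <- keep   # map back to original indices
  g
}

.element_colors <- function(...) {
  els <- unlist(list(...))
  as.integer(factor(els, levels = sort(unique(els))))
}

# all vertex mappings g1 -> g2 that respect elements and bond orders
# (graph isomorphisms; both graphs must have equal vertex counts)
mol_isomorphisms <- function(m1, m2, heavy_only = TRUE) {
  g1 <- mol_graph(m1, heavy_only); g2 <- mol_graph(m2, heavy_only)
  if (igraph::vcount(g1) != igraph::vcount(g2) ||
      igraph::ecount(g1) != igraph::ecount(g2)) return(list())
  cols <- .element_colors(igraph::V(g1)$el, igraph::V(g2)$el)
  c1 <- cols[seq_len(igraph::vcount(g1))]
  c2 <- cols[-seq_len(igraph::vcount(g1))]
  maps <- igraph::subgraph_isomorphisms(
    g1, g2, method = "vf2",
    vertex.color1 = c1, vertex.color2 = c2,
    edge.color1 = igraph::E(g1)$order, edge.color2 = igraph::E(g2)$order)
  idx1 <- attr(g1, "atom_idx"); idx2 <- attr(g2, "atom_idx")
  lapply(maps, function(mp) {
    v <- as.integer(mp)          # v[k] = vertex in g2 matched to vertex k of g1
    stats::setNames(idx2[v], idx1)
  })
}

# TRUE if the two structures have identical molecular graphs
graphs_isomorphic <- function(m1, m2, heavy_only = TRUE) {
  length(mol_isomorphisms(m1, m2, heavy_only)) > 0
}

# bond indices (rows of m$bonds) that lie in a ring
ring_bonds <- function(m) {
  g <- mol_graph(m)
  if (!nrow(m$bonds)) return(integer())
  which(vapply(seq_len(nrow(m$bonds)), function(k) {
    g2 <- igraph::delete_edges(g, k)
    igraph::distances(g2, v = m$bonds$i[k], to = m$bonds$j[k]) < Inf
  }, logical(1)))
}

# connected components as lists of atom indices
graph_components <- function(m) {
  g <- mol_graph(m)
  comp <- igraph::components(g)
  split(seq_len(n_atoms(m)), comp$membership)
}

#' Maximum common substructure mapping between two molecules
#'
#' Finds the largest common induced substructure (heavy atoms, element and
#' bond-order labels must match) via maximal cliques of the modular product
#' graph. Ties are broken by largest mapped-bond count, then by the
#' lexicographically smallest mobile-atom index tuple, so the result is
#' deterministic.
#'
#' @param mobile,reference `mol_structure` objects.
#' @return an `atom_mapping`: tibble with columns `mobile`, `reference`
#'   (original atom indices) and attributes `source = "MCS"` and `n_bonds`.
#' @export
mcs_mapping <- function(mobile, reference) {
  g1 <- mol_graph(mobile, heavy_only = TRUE)
  g2 <- mol_graph(reference, heavy_only = TRUE)
  n1 <- igraph::vcount(g1); n2 <- igraph::vcount(g2)
  a1 <- igraph::as_adjacency_matrix(g1, sparse = FALSE)
  a2 <- igraph::as_adjacency_matrix(g2, sparse = FALSE)
  o1 <- matrix(0L, n1, n1); o2 <- matrix(0L, n2, n2)
  if (igraph::ecount(g1)) {
    e <- igraph::as_edgelist(g1)
    o1[e] <- igraph::E(g1)$order; o1[e[, 2:1, drop = FALSE]] <- igraph::E(g1)$order
  }
  if (igraph::ecount(g2)) {
    e <- igraph::as_edgelist(g2)
    o2[e] <- igraph::E(g2)$order; o2[e[, 2:1, drop = FALSE]] <- igraph::E(g2)$order
  }
  # modular product vertices: element-compatible pairs
  pairs <- which(outer(igraph::V(g1)$el, igraph::V(g2)$el, "=="), arr.ind = TRUE)
  np <- nrow(pairs)
  if (np == 0) stop("no usable common scaffold: no element-compatible atom pairs")
  edges <- integer()
  for (p in seq_len(np - 1)) {
    i1 <- pairs[p, 1]; j1 <- pairs[p, 2]
    q <- (p + 1):np
    i2 <- pairs[q, 1]; j2 <- pairs[q, 2]
    ok <- i2 != i1 & j2 != j1 &
      (a1[i1, i2] == a2[j1, j2]) &
      (o1[i1, i2] == o2[j1, j2])
    if (any(ok)) edges <- c(edges, rbind(p, q[ok]))
  }
  gp <- igraph::make_empty_graph(np, directed = FALSE)
  if (length(edges)) gp <- igraph::add_edges(gp, edges)
  cl <- igraph::largest_cliques(gp)
  if (!length(cl)) stop("no usable common scaffold")
  score <- function(cq) {
    v <- sort(as.integer(cq))
    i <- pairs[v, 1]; j <- pairs[v, 2]
    nb <- sum(a1[i, i][upper.tri(a1[i, i])] > 0)
    list(n = length(v), nb = nb, key = paste(sort(i), collapse = ","))
  }
  sc <- lapply(cl, score)
  nb <- vapply(sc, `[[`, numeric(1), "nb")
  best <- which(nb == max(nb))
  if (length(best) > 1) {
    keys <- vapply(sc[best], `[[`, character(1), "key")
    best <- best[order(keys)][1]
  }
  v <- sort(as.integer(cl[[best]]))
  idx1 <- attr(g1, "atom_idx"); idx2 <- attr(g2, "atom_idx")
  out <- tibble::tibble(mobile = idx1[pairs[v, 1]], reference = idx2[pairs[v, 2]])
  out <- dplyr::arrange(out, .data$mobile)
  attr(out, "source") <- "MCS"
  attr(out, "n_bonds") <- sc[[best]]$nb
  class(out) <- c("atom_mapping", class(out))
  out
}
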