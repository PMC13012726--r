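# Centerline skeletonization, hair pruning and vascular graph construction.

#' Skeletonize a vessel mask to a centerline
#'
#' Homotopy-preserving 3D thinning: border voxels that are simple points (and
#' not curve endpoints) are removed in six directional subiterations per pass
#' until stable. The result is a one-voxel-thick curve skeleton that is
#' connected wherever the mask is connected.
#'
#' @param mask a cleaned, hole-free [binary_mask()].
#' @return An object of class `vessel_skeleton` with fields `voxels`
#'   (n x 3 matrix of 1-based voxel indices), `dims` and `voxel_size`.
#' @export
skeletonize <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$voxels)) stop("empty mask")
  d <- dim(mask$voxels)
  thin <- array(cpp_thin3d(mask$voxels, d), d)
  idx <- which(thin, arr.ind = TRUE)
  structure(list(voxels = unname(idx), dims = d, voxel_size = mask$voxel_size),
            class = "vessel_skeleton")
}

#' @export
print.vessel_skeleton <- function(x, ...) {
  cat(sprintf("<vessel_skeleton> %d centerline voxels in %d x %d x %d grid\n",
              nrow(x$voxels), x$dims[1], x$dims[2], x$dims[3]))
  invisible(x)
}

# 26-neighbourhood adjacency of skeleton voxels; returns neighbour id lists
# and degrees, in the voxel order of sk$voxels
skeleton_adjacency <- function(sk) {
  v <- sk$voxels
  d <- sk$dims
  n <- nrow(v)
  lin <- v[, 1] + d[1] * (v[, 2] - 1) + d[1] * d[2] * (v[, 3] - 1)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  neigh <- vector("list", n)
  for (r in seq_len(nrow(off))) {
    nb <- v[, 1] + off[r, 1] + d[1] * (v[, 2] + off[r, 2] - 1) +
      d[1] * d[2] * (v[, 3] + off[r, 3] - 1)
    inb <- v[, 1] + off[r, 1] >= 1 & v[, 1] + off[r, 1] <= d[1] &
      v[, 2] + off[r, 2] >= 1 & v[, 2] + off[r, 2] <= d[2] &
      v[, 3] + off[r, 3] >= 1 & v[, 3] + off[r, 3] <= d[3]
    hit <- match(nb, lin)
    hit[!inb] <- NA
    found <- which(!is.na(hit))
    for (i in found) neigh[[i]] <- c(neigh[[i]], hit[i])
  }
  list(neigh = neigh, degree = lengths(neigh), lin = lin)
}

# walk from voxel `from` into neighbour `nxt` along a degree-2 chain until a
# voxel with degree != 2 is reached; returns the voxel-id path including ends
walk_chain <- function(adj, from, nxt) {
  path <- c(from, nxt)
  prev <- from
  cur <- nxt
  while (adj$degree[cur] == 2) {
    nb <- adj$neigh[[cur]]
    nxt2 <- nb[nb != prev][1]
    path <- c(path, nxt2)
    prev <- cur
    cur <- nxt2
    if (cur == from && adj$degree[from] == 2) break  # closed loop
  }
  path
}

arc_length <- function(P) sum(sqrt(rowSums(diff(P)^2)))

#' Prune short terminal "hair" branches from a skeleton
#'
#' Terminal branches shorter than `min_hair_length` (polyline arc length in
#' micrometers, measured from the junction to the tip) are removed
#' iteratively, shortest first, with junction degrees re-evaluated after each
#' removal. At a junction left with two terminal branches, the shorter is
#' removed and the longer merges with the continuing vessel when the
#' junction's degree falls to 2, minimizing the centerline length removed.
#' Isolated chains terminal on both ends are never pruned. Idempotent.
#'
#' @param skeleton a `vessel_skeleton`.
#' @param min_hair_length hairs strictly shorter than this are removed (um,
#'   default 20).
#' @return The pruned `vessel_skeleton`.
#' @export
prune_hairs <- function(skeleton, min_hair_length = 20) {
  sk <- skeleton
  sp <- sk$voxel_size
  repeat {
    adj <- skeleton_adjacency(sk)
    # drop triangle shortcuts: a degree-2 voxel whose two neighbours are
    # junction voxels that touch each other directly adds a spurious
    # one-voxel parallel loop (a pruning remnant), never real centerline
    tri <- which(vapply(seq_len(nrow(sk$voxels)), function(i) {
      if (adj$degree[i] != 2) return(FALSE)
      nb <- adj$neigh[[i]]
      if (any(adj$degree[nb] < 3)) return(FALSE)
      all(abs(sk$voxels[nb[1], ] - sk$voxels[nb[2], ]) <= 1)
    }, TRUE))
    if (length(tri)) {
      sk$voxels <- sk$voxels[-tri[1], , drop = FALSE]
      next
    }
    tips <- which(adj$degree == 1)
    if (!length(tips)) break
    hairs <- list()
    for (tp in tips) {
      nb <- adj$neigh[[tp]]
      if (!length(nb)) next
      path <- walk_chain(adj, tp, nb[1])
      endv <- path[length(path)]
      if (adj$degree[endv] < 3) next  # isolated chain, not a hair
      P <- sweep(sk$voxels[path, , drop = FALSE] - 1, 2, sp, "*")
      len <- arc_length(P)
      if (len < min_hair_length)
        hairs[[length(hairs) + 1L]] <- list(tip = tp, path = path, len = len)
    }
    if (!length(hairs)) break
    lens <- vapply(hairs, function(h) h$len, 0)
    tiplin <- vapply(hairs, function(h) adj$lin[h$tip], 0)
    ord <- order(lens, tiplin)
    h <- hairs[[ord[1]]]
    drop <- h$path[-length(h$path)]  # keep the junction voxel
    sk$voxels <- sk$voxels[-drop, , drop = FALSE]
  }
  sk
}

new_vascular_graph <- function(nodes, edges, voxel_size, dims) {
  structure(list(nodes = nodes, edges = edges, voxel_size = voxel_size,
                 dims = dims),
            class = "vascular_graph")
}

#' @export
print.vascular_graph <- function(x, ...) {
  nj <- sum(x$nodes$degree >= 3)
  nt <- sum(x$nodes$degree == 1)
  cat(sprintf("<vascular_graph> %d nodes (%d junctions, %d endpoints), %d vessel segments\n",
              nrow(x$nodes), nj, nt, length(x$edges)))
  if (length(x$edges)) {
    lens <- vapply(x$edges, function(e) e$length, 0)
    cat(sprintf("  segment length: mean %.1f um, range [%.1f, %.1f] um\n",
                mean(lens), min(lens), max(lens)))
  }
  invisible(x)
}

#' @export
summary.vascular_graph <- function(object, ...) {
  lens <- vapply(object$edges, function(e) e$length, 0)
  list(n_nodes = nrow(object$nodes),
       n_junctions = sum(object$nodes$degree >= 3),
       n_endpoints = sum(object$nodes$degree == 1),
       n_segments = length(object$edges),
       total_length = sum(lens),
       mean_segment_length = if (length(lens)) mean(lens) else NA_real_)
}

#' Build a vascular graph from a pruned skeleton
#'
#' Skeleton voxels with degree != 2 become nodes (26-adjacent junction voxels
#' are merged into a single junction node at their centroid); maximal
#' degree-2 chains become vessel-segment edges carrying ordered vertex
#' positions in micrometers. Closed degree-2 loops receive an anchor node at
#' their lexicographically smallest voxel and become one self-edge.
#'
#' @param skeleton a `vessel_skeleton` (after [prune_hairs()]).
#' @param min_loop_length self-loops shorter than this (um) are dropped as
#'   mask-tunnel artifacts (default 20, matching the hair threshold).
#' @return A `vascular_graph` with `nodes` (data frame: id, x, y, z, degree)
#'   and `edges` (list: id, from, to, `path` n x 3 um matrix, length um).
#' @export
build_graph <- function(skeleton, min_loop_length = 20) {
  sk <- skeleton
  sp <- sk$voxel_size
  adj <- skeleton_adjacency(sk)
  n <- nrow(sk$voxels)
  pos <- sweep(sk$voxels - 1, 2, sp, "*")
  is_node <- adj$degree != 2

  # cluster junction voxels (degree >= 3) that touch each other
  cluster <- integer(n)  # 0 = not a node voxel
  ncl <- 0L
  for (i in which(is_node)) {
    if (cluster[i] != 0L) next
    ncl <- ncl + 1L
    if (adj$degree[i] >= 3) {
      stack <- i
      cluster[i] <- ncl
      while (length(stack)) {
        cu <- stack[[1]]; stack <- stack[-1]
        for (nb in adj$neigh[[cu]]) {
          if (adj$degree[nb] >= 3 && cluster[nb] == 0L) {
            cluster[nb] <- ncl
            stack <- c(stack, nb)
          }
        }
      }
    } else cluster[i] <- ncl
  }

  edges <- list()
  visited_step <- character(0)  # "a>b" directed half-edge keys
  for (i in which(is_node)) {
    for (nb in adj$neigh[[i]]) {
      if (is_node[nb] && cluster[nb] == cluster[i]) next  # intra-cluster
      key <- paste0(i, ">", nb)
      if (key %in% visited_step) next
      path <- if (is_node[nb]) c(i, nb) else walk_chain(adj, i, nb)
      endv <- path[length(path)]
      visited_step <- c(visited_step, key,
                        paste0(endv, ">", path[length(path) - 1L]))
      P <- pos[path, , drop = FALSE]
      edges[[length(edges) + 1L]] <-
        list(from_cluster = cluster[i], to_cluster = cluster[endv],
             path = P, length = arc_length(P))
    }
  }

  # closed degree-2 loops with no node voxel
  used <- rep(FALSE, n)
  used[is_node] <- TRUE
  for (i in which(is_node)) for (nb in adj$neigh[[i]]) {
    if (is_node[nb]) next
    path <- walk_chain(adj, i, nb)
    used[path] <- TRUE
  }
  loop_left <- which(!used & adj$degree == 2)
  while (length(loop_left)) {
    # anchor at lexicographically smallest voxel of the loop
    lin_left <- adj$lin[loop_left]
    start <- loop_left[which.min(lin_left)]
    nb <- adj$neigh[[start]][1]
    path <- c(start)
    prev <- start
    cur <- nb
    while (cur != start) {
      path <- c(path, cur)
      nbs <- adj$neigh[[cur]]
      nxt <- nbs[nbs != prev][1]
      prev <- cur
      cur <- nxt
    }
    path <- c(path, start)
    ncl <- ncl + 1L
    cluster[start] <- ncl
    P <- pos[path, , drop = FALSE]
    edges[[length(edges) + 1L]] <-
      list(from_cluster = ncl, to_cluster = ncl, path = P,
           length = arc_length(P))
    used[path] <- TRUE
    loop_left <- which(!used & adj$degree == 2)
  }

  # node table: one node per cluster, at the cluster centroid
  node_ids <- sort(unique(cluster[cluster != 0L]))
  nx <- vapply(node_ids, function(cl) mean(pos[cluster == cl, 1]), 0)
  ny <- vapply(node_ids, function(cl) mean(pos[cluster == cl, 2]), 0)
  nz <- vapply(node_ids, function(cl) mean(pos[cluster == cl, 3]), 0)
  remap <- match(seq_len(max(c(node_ids, 0L))), node_ids)
  deg <- rep(0L, length(node_ids))
  out_edges <- vector("list", length(edges))
  for (k in seq_along(edges)) {
    e <- edges[[k]]
    from <- remap[e$from_cluster]
    to <- remap[e$to_cluster]
    deg[from] <- deg[from] + 1L
    deg[to] <- deg[to] + 1L
    out_edges[[k]] <- list(id = k, from = from, to = to, path = e$path,
                           length = e$length)
  }
  nodes <- data.frame(id = seq_along(node_ids), x = nx, y = ny, z = nz,
                      degree = deg)
  g <- new_vascular_graph(nodes, out_edges, sp, sk$dims)
  g <- dissolve_degree2_nodes(g)
  g <- contract_short_junction_edges(g)
  g <- drop_short_self_loops(g, min_loop_length)
  dissolve_degree2_nodes(g)
}

# self-loops below the hair threshold are segmentation/thinning artifacts
# (tunnels in the mask), not anatomy; the graph invariant forbids them
drop_short_self_loops <- function(g, min_loop_length = 20) {
  repeat {
    hit <- NULL
    for (k in seq_along(g$edges)) {
      e <- g$edges[[k]]
      if (e$from == e$to && e$length < min_loop_length) { hit <- k; break }
    }
    if (is.null(hit)) break
    g$edges[[hit]] <- NULL
    for (k in seq_along(g$edges)) g$edges[[k]]$id <- k
  }
  g
}

# thinning can split one anatomical branch point into two junction voxels a
# couple of voxels apart; an inter-junction edge shorter than the voxel
# resolution limit is such an artifact and is contracted
contract_short_junction_edges <- function(g, max_length = 3) {
  repeat {
    deg <- rep(0L, nrow(g$nodes))
    for (e in g$edges) {
      deg[e$from] <- deg[e$from] + 1L
      deg[e$to] <- deg[e$to] + 1L
    }
    hit <- NULL
    for (k in seq_along(g$edges)) {
      e <- g$edges[[k]]
      if (e$from != e$to && deg[e$from] >= 3 && deg[e$to] >= 3 &&
          e$length <= max_length) { hit <- k; break }
    }
    # also drop degenerate self-loops below the resolution limit
    if (is.null(hit)) {
      for (k in seq_along(g$edges)) {
        e <- g$edges[[k]]
        if (e$from == e$to && e$length <= max_length) { hit <- -k; break }
      }
    }
    if (is.null(hit)) break
    if (hit < 0) {
      g$edges[[-hit]] <- NULL
    } else {
      e <- g$edges[[hit]]
      a <- e$from; b <- e$to
      g$nodes[a, c("x", "y", "z")] <- (g$nodes[a, c("x", "y", "z")] +
                                         g$nodes[b, c("x", "y", "z")]) / 2
      g$edges[[hit]] <- NULL
      for (k in seq_along(g$edges)) {
        if (g$edges[[k]]$from == b) g$edges[[k]]$from <- a
        if (g$edges[[k]]$to == b) g$edges[[k]]$to <- a
      }
    }
    # renumber edges; drop isolated node b lazily (dissolve pass cleans up)
    for (k in seq_along(g$edges)) g$edges[[k]]$id <- k
  }
  g
}

# merge the two edges meeting at any junction remnant of degree 2 into one
# through-edge (the node is dissolved); endpoint and true junction nodes are
# untouched
dissolve_degree2_nodes <- function(g) {
  repeat {
    deg <- rep(0L, nrow(g$nodes))
    for (e in g$edges) {
      deg[e$from] <- deg[e$from] + 1L
      deg[e$to] <- deg[e$to] + 1L
    }
    loops <- unique(unlist(lapply(g$edges, function(e)
      if (e$from == e$to) e$from else NULL)))
    cand <- which(deg == 2L)
    cand <- setdiff(cand, loops)
    merged <- FALSE
    for (nd in cand) {
      inc <- which(vapply(g$edges, function(e) e$from == nd || e$to == nd, TRUE))
      if (length(inc) != 2L) next
      e1 <- g$edges[[inc[1]]]
      e2 <- g$edges[[inc[2]]]
      p1 <- if (e1$to == nd) e1$path else e1$path[nrow(e1$path):1, , drop = FALSE]
      p2 <- if (e2$from == nd) e2$path else e2$path[nrow(e2$path):1, , drop = FALSE]
      a <- if (e1$to == nd) e1$from else e1$to
      b <- if (e2$from == nd) e2$to else e2$from
      path <- rbind(p1, p2[-1, , drop = FALSE])
      g$edges[[inc[1]]] <- list(id = e1$id, from = a, to = b, path = path,
                                length = arc_length(path))
      g$edges[[inc[2]]] <- NULL
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  # drop now-isolated nodes and renumber
  deg <- rep(0L, nrow(g$nodes))
  for (e in g$edges) {
    deg[e$from] <- deg[e$from] + 1L
    deg[e$to] <- deg[e$to] + 1L
  }
  keep <- which(deg > 0L | seq_along(deg) %in%
                  unlist(lapply(g$edges, function(e) c(e$from, e$to))))
  if (!length(keep)) keep <- seq_along(deg)
  remap <- match(seq_along(deg), keep)
  g$nodes <- g$nodes[keep, , drop = FALSE]
  g$nodes$id <- seq_len(nrow(g$nodes))
  g$nodes$degree <- deg[keep]
  rownames(g$nodes) <- NULL
  for (k in seq_along(g$edges)) {
    g$edges[[k]]$from <- remap[g$edges[[k]]$from]
    g$edges[[k]]$to <- remap[g$edges[[k]]$to]
    g$edges[[k]]$id <- k
  }
  g
}

#' Smooth edge centerlines and compute vertex tangents
#'
#' Vertex positions along each edge are smoothed coordinate-wise with a
#' Gaussian (sigma in vertex-index units, default 3) using linear
#' extrapolation padding, so straight centerlines are left exactly unchanged.
#' Tangents are central differences of the smoothed positions (one-sided at
#' the ends), normalized to unit length.
#'
#' @param graph a `vascular_graph`.
#' @param sigma_vertices Gaussian sigma in vertex index units (default 3).
#' @return The graph with `smoothed` (n x 3 um) and `tangents` (n x 3 unit
#'   vectors) added to every edge.
#' @export
smooth_and_tangents <- function(graph, sigma_vertices = 3) {
  stopifnot(inherits(graph, "vascular_graph"))
  for (k in seq_along(graph$edges)) {
    P <- graph$edges[[k]]$path
    if (nrow(P) < 2) stop("edge with a single vertex cannot be smoothed")
    S <- apply(P, 2, smooth_linear_extrap, sigma = sigma_vertices)
    n <- nrow(S)
    Tg <- matrix(0, n, 3)
    if (n == 2) {
      Tg[1, ] <- Tg[2, ] <- S[2, ] - S[1, ]
    } else {
      Tg[1, ] <- S[2, ] - S[1, ]
      Tg[n, ] <- S[n, ] - S[n - 1, ]
      Tg[2:(n - 1), ] <- S[3:n, ] - S[1:(n - 2), ]
    }
    nrm <- sqrt(rowSums(Tg^2))
    bad <- nrm < 1e-12
    if (any(bad)) {
      good <- which(!bad)
      if (!length(good)) stop("degenerate edge: no nonzero tangent")
      for (b in which(bad)) Tg[b, ] <- Tg[good[which.min(abs(good - b))], ]
      nrm <- sqrt(rowSums(Tg^2))
    }
    Tg <- Tg / nrm
    graph$edges[[k]]$smoothed <- S
    graph$edges[[k]]$tangents <- Tg
  }
  graph
}

#' Convert a vascular graph to an igraph object
#'
#' Nodes carry positions; edges carry segment length and id.
#'
#' @param graph a `vascular_graph`.
#' @return An [igraph::graph] (undirected; may contain multi-edges and
#'   self-loops).
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "vascular_graph"))
  el <- t(vapply(graph$edges, function(e) c(e$from, e$to), c(0, 0)))
  g <- igraph::graph_from_edgelist(matrix(el, ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(graph$nodes) - igraph::vcount(g)))
  igraph::V(g)$x <- graph$nodes$x
  igraph::V(g)$y <- graph$nodes$y
  igraph::V(g)$z <- graph$nodes$z
  igraph::E(g)$length <- vapply(graph$edges, function(e) e$length, 0)
  igraph::E(g)$edge_id <- vapply(graph$edges, function(e) e$id, 0)
  g
}
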