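# shared fixture builders (all fixtures are generated in code)

iso <- c(0.99, 0.99, 0.99)

# internal helpers exercised directly in tests
cpp_label3d <- microvasc:::cpp_label3d
cpp_edt3d <- microvasc:::cpp_edt3d
euler_to_rotation <- microvasc:::euler_to_rotation
convolve3 <- microvasc:::convolve3
sphere_mask <- microvasc:::sphere_mask

# straight tube along x through the middle of a cube
straight_tube_spec <- function(radius = 3, n = 40, intensity = 600,
                               timepoints = list(1), margin = 2) {
  mid <- (n - 1) * 0.99 / 2
  phantom_spec(c(n, n, n), iso,
               tubes = list(list(
                 centerline = rbind(c(margin, mid, mid),
                                    c((n - 1) * 0.99 - margin, mid, mid)),
                 radius = radius, intensity = intensity)),
               timepoints = timepoints)
}

# three tubes meeting at one junction (Y topology)
y_spec <- function(radius = 2.5, n = 60, intensity = 600,
                   timepoints = list(1)) {
  c0 <- (n - 1) * 0.99 / 2
  ctr <- c(c0, c0, c0)
  arm <- function(dir) rbind(ctr, ctr + dir / sqrt(sum(dir^2)) * (c0 - 4))
  phantom_spec(c(n, n, n), iso,
               tubes = list(
                 list(centerline = arm(c(1, 0, 0)), radius = radius,
                      intensity = intensity),
                 list(centerline = arm(c(-1, 1, 0)), radius = radius,
                      intensity = intensity),
                 list(centerline = arm(c(-1, -1, 0)), radius = radius,
                      intensity = intensity)),
               timepoints = timepoints)
}

# skeleton object straight from voxel index rows (for pruning semantics)
skeleton_from_indices <- function(idx, dims, voxel_size = iso) {
  structure(list(voxels = as.matrix(idx), dims = as.integer(dims),
                 voxel_size = voxel_size),
            class = "vessel_skeleton")
}

# minimal vascular graph over an edge list, with named radii and lengths
toy_vgraph <- function(el, n_nodes, lengths, radii) {
  edges <- lapply(seq_len(nrow(el)), function(k)
    list(id = k, from = el[k, 1], to = el[k, 2],
         path = rbind(c(0, 0, 0), c(lengths[k], 0, 0)), length = lengths[k]))
  nodes <- data.frame(id = seq_len(n_nodes), x = 0, y = 0, z = 0,
                      degree = tabulate(as.integer(el), n_nodes))
  list(graph = microvasc:::new_vascular_graph(nodes, edges, iso, c(9, 9, 9)),
       radii = setNames(radii, seq_len(nrow(el))),
       lengths = setNames(lengths, seq_len(nrow(el))))
}

# independent Pearson-over-linked-pairs oracle for assortativity
assortativity_oracle <- function(values, links) {
  xs <- c(values[links[, 1]], values[links[, 2]])
  ys <- c(values[links[, 2]], values[links[, 1]])
  n <- length(xs)
  mx <- sum(xs) / n
  my <- sum(ys) / n
  sxy <- sum((xs - mx) * (ys - my))
  sxx <- sum((xs - mx)^2)
  syy <- sum((ys - my)^2)
  sxy / sqrt(sxx * syy)
}

# exhaustive least-resistive-path efficiency oracle (all simple paths)
efficiency_oracle <- function(el, w, n_nodes) {
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < n_nodes)
    g <- igraph::add_vertices(g, n_nodes - igraph::vcount(g))
  igraph::E(g)$w <- w
  tot <- 0
  for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
    if (i == j) next
    ps <- igraph::all_simple_paths(g, i, j)
    if (!length(ps)) next
    best <- min(vapply(ps, function(p) {
      ep <- igraph::E(g, path = p)
      sum(ep$w)
    }, 0))
    tot <- tot + 1 / best
  }
  tot / (n_nodes * (n_nodes - 1))
}
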