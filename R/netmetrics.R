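# Vessel- and network-level analysis: per-vessel summaries and responder
# classification, the vessel adjacency (line) graph, assortativity of radius
# changes, Poiseuille hydraulic resistance and capillary network efficiency,
# and whole-network morphometrics.

#' Summarize vessels across time points
#'
#' Aggregates the vertex table into one row per vessel segment: per-time-point
#' mean radius, baseline mean and baseline SD (the SD of the edge's mean
#' radius across baseline time points), radius change (post mean minus
#' baseline mean), mean depth, size class (capillary: mean baseline radius
#' < 5 um) and responder status.
#'
#' @param records vertex table from [estimate_vertex_radii()] (optionally
#'   with `neuron_distance` from [neuron_distance()]).
#' @param graph the `vascular_graph` the records came from.
#' @param baseline_timepoints,post_timepoints time point indices for the
#'   baseline and post-stimulus periods.
#' @param capillary_max_radius capillary/large split, um (default 5).
#' @param min_length vessels at or under this length are never responders,
#'   um (default 20).
#' @return Data frame of class `vessel_summary` with one row per edge.
#' @export
vessel_summaries <- function(records, graph, baseline_timepoints,
                             post_timepoints, capillary_max_radius = 5,
                             min_length = 20) {
  stopifnot(inherits(graph, "vascular_graph"))
  ids <- vapply(graph$edges, `[[`, 0, "id")
  lens <- vapply(graph$edges, `[[`, 0, "length")
  rows <- lapply(seq_along(ids), function(i) {
    rec <- records[records$edge == ids[i], ]
    tps <- sort(unique(records$timepoint))
    tp_mean <- vapply(tps, function(t)
      mean(rec$radius[rec$timepoint == t], na.rm = TRUE), 0)
    tp_sd <- vapply(tps, function(t)
      sd(rec$radius[rec$timepoint == t], na.rm = TRUE), 0)
    bl <- tp_mean[tps %in% baseline_timepoints]
    po <- tp_mean[tps %in% post_timepoints]
    base_mean <- mean(bl, na.rm = TRUE)
    base_sd <- if (sum(!is.na(bl)) >= 2) sd(bl, na.rm = TRUE) else NA_real_
    out <- data.frame(edge = ids[i], length = lens[i],
                      baseline_radius_mean = base_mean,
                      baseline_radius_sd = base_sd,
                      delta_radius = mean(po, na.rm = TRUE) - base_mean,
                      intra_vessel_sd = mean(tp_sd[tps %in% baseline_timepoints],
                                             na.rm = TRUE),
                      mean_depth = mean(rec$z, na.rm = TRUE),
                      min_neuron_distance = if ("neuron_distance" %in% names(rec))
                        suppressWarnings(min(rec$neuron_distance, na.rm = TRUE))
                      else NA_real_)
    for (t in tps) out[[paste0("radius_t", t)]] <- tp_mean[tps == t]
    out
  })
  out <- do.call(rbind, rows)
  out$size_class <- ifelse(out$baseline_radius_mean < capillary_max_radius,
                           "capillary", "large")
  out <- classify_responders(out, min_length = min_length)
  class(out) <- c("vessel_summary", "data.frame")
  out
}

#' Classify responder vessels
#'
#' A vessel responds when its radius change exceeds twice the standard
#' deviation of its baseline radius: dilator if `delta_radius` >
#' 2 x baseline SD, constrictor if below -2 x baseline SD, otherwise none.
#' Vessels of length <= `min_length` are never responders, and vessels with
#' fewer than two baseline time points are excluded (NA) with a warning.
#'
#' @param summaries data frame with `delta_radius`, `baseline_radius_sd` and
#'   `length` columns (see [vessel_summaries()]).
#' @param sd_gate response threshold in baseline SDs (default 2).
#' @param min_length minimum responder length, um (default 20).
#' @return `summaries` with a `responder` factor column
#'   (`dilator`/`constrictor`/`none`).
#' @export
classify_responders <- function(summaries, sd_gate = 2, min_length = 20) {
  sdv <- summaries$baseline_radius_sd
  if (any(is.na(sdv)))
    warning("vessels with a single baseline time point excluded from responder classification")
  resp <- ifelse(summaries$delta_radius > sd_gate * sdv, "dilator",
                 ifelse(summaries$delta_radius < -sd_gate * sdv, "constrictor",
                        "none"))
  resp[summaries$length <= min_length] <- "none"
  resp[is.na(sdv)] <- NA
  summaries$responder <- factor(resp, levels = c("dilator", "constrictor", "none"))
  summaries
}

#' Vessel adjacency (line) graph
#'
#' One node per included vessel segment; a link joins every unordered pair of
#' included vessels that share at least one junction node. Node values (e.g.
#' radius changes) ride along for assortativity.
#'
#' @param graph a `vascular_graph`.
#' @param values named numeric vector of per-edge values; names are edge ids
#'   and define which vessels are included.
#' @return An object of class `line_graph`: `nodes` (edge ids), `values`,
#'   `links` (2-column matrix of node indices).
#' @export
vessel_line_graph <- function(graph, values) {
  stopifnot(inherits(graph, "vascular_graph"))
  ids <- as.integer(names(values))
  pos <- match(ids, vapply(graph$edges, `[[`, 0, "id"))
  if (anyNA(pos)) stop("values name edges absent from the graph")
  incident <- vector("list", nrow(graph$nodes))
  for (k in seq_along(pos)) {
    e <- graph$edges[[pos[k]]]
    incident[[e$from]] <- unique(c(incident[[e$from]], k))
    incident[[e$to]] <- unique(c(incident[[e$to]], k))
  }
  links <- matrix(integer(0), 0, 2)
  for (node in seq_along(incident)) {
    inc <- incident[[node]]
    if (length(inc) >= 2) {
      pr <- t(utils::combn(sort(inc), 2))
      links <- rbind(links, pr)
    }
  }
  links <- unique(links)
  links <- links[links[, 1] != links[, 2], , drop = FALSE]
  structure(list(nodes = ids, values = unname(values), links = links),
            class = "line_graph")
}

#' @export
print.line_graph <- function(x, ...) {
  cat(sprintf("<line_graph> %d vessels, %d adjacency links\n",
              length(x$nodes), nrow(x$links)))
  invisible(x)
}

#' Assortativity of vessel attribute changes
#'
#' The Pearson correlation of the node attribute over linked vessel pairs,
#' with each undirected link contributing both orientations (x, y) and
#' (y, x), making the statistic symmetric. q lies in [-1, 1].
#'
#' @param line_graph a `line_graph` from [vessel_line_graph()].
#' @return The assortativity coefficient q.
#' @export
assortativity <- function(line_graph) {
  stopifnot(inherits(line_graph, "line_graph"))
  L <- line_graph$links
  if (nrow(L) < 2) stop("need >= 2 links for assortativity")
  v <- line_graph$values
  xs <- c(v[L[, 1]], v[L[, 2]])
  ys <- c(v[L[, 2]], v[L[, 1]])
  if (sd(xs) == 0 || sd(ys) == 0)
    stop("zero variance of endpoint values: assortativity undefined")
  cor(xs, ys)
}

#' Poiseuille hydraulic resistance of a vessel segment
#'
#' rho = 8 mu L / (pi R^4), with the viscosity in centipoise converted to
#' Pa s and lengths/radii from micrometers to meters.
#'
#' @param length_um segment length, um.
#' @param radius_um segment radius, um.
#' @param viscosity_cp dynamic viscosity, centipoise (default 4 cP).
#' @return Resistance in Pa s m^-3.
#' @export
edge_resistance <- function(length_um, radius_um, viscosity_cp = 4) {
  if (any(radius_um <= 0)) stop("radius must be > 0")
  if (any(length_um <= 0)) stop("length must be > 0")
  mu <- viscosity_cp * 1e-3
  8 * mu * (length_um * 1e-6) / (pi * (radius_um * 1e-6)^4)
}

#' Hydraulic efficiency of the capillary network
#'
#' Vessels wider than `max_diameter` are excluded; the remaining junction
#' graph gets per-edge Poiseuille resistances, and the efficiency is the
#' average over ordered junction pairs of the inverse least-resistive path
#' resistance. Disconnected pairs contribute zero (no flow path).
#'
#' @param graph a `vascular_graph`.
#' @param edge_radii named numeric vector (names = edge ids): per-edge mean
#'   radius at the time point of interest, um.
#' @param edge_lengths optional named lengths, um (default: graph lengths).
#' @param max_diameter exclusion threshold, um (default 10: vessels with
#'   2 x radius > 10 um are excluded).
#' @param viscosity_cp viscosity, cP (default 4).
#' @return Efficiency E (Pa^-1 s^-1 m^3), with attribute `nodes` (junction
#'   ids retained) and `n_nodes`.
#' @export
capillary_efficiency <- function(graph, edge_radii, edge_lengths = NULL,
                                 max_diameter = 10, viscosity_cp = 4) {
  stopifnot(inherits(graph, "vascular_graph"))
  ids <- vapply(graph$edges, `[[`, 0, "id")
  if (is.null(edge_lengths)) {
    edge_lengths <- setNames(vapply(graph$edges, `[[`, 0, "length"), ids)
  }
  r <- edge_radii[as.character(ids)]
  keep <- !is.na(r) & r > 0 & 2 * r <= max_diameter
  if (!any(keep)) stop("no capillary edges after the diameter exclusion")
  el <- t(vapply(graph$edges[keep], function(e) c(e$from, e$to), c(0, 0)))
  w <- edge_resistance(edge_lengths[as.character(ids)][keep], r[keep],
                       viscosity_cp)
  nodes <- sort(unique(as.integer(el)))
  if (length(nodes) < 2) stop("need >= 2 junctions for efficiency")
  g <- igraph::graph_from_edgelist(matrix(match(el, nodes), ncol = 2),
                                   directed = FALSE)
  D <- igraph::distances(g, weights = w)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  N <- length(nodes)
  E <- sum(inv) / (N * (N - 1))
  attr(E, "nodes") <- nodes
  attr(E, "n_nodes") <- N
  E
}

#' Stimulation-induced efficiency change
#'
#' @param E_baseline,E_post efficiencies from [capillary_efficiency()]
#'   computed on the same node set.
#' @return A list: `delta` (E_post - E_baseline) and `pct` (percent of
#'   baseline).
#' @export
efficiency_change <- function(E_baseline, E_post) {
  nb <- attr(E_baseline, "nodes")
  np <- attr(E_post, "nodes")
  if (!is.null(nb) && !is.null(np) && !identical(nb, np))
    stop("efficiencies computed on differing node sets are not comparable")
  delta <- as.numeric(E_post) - as.numeric(E_baseline)
  list(delta = delta, pct = 100 * delta / as.numeric(E_baseline))
}

#' Whole-network morphometrics
#'
#' Counts and densities over the field of view: vessel and junction counts
#' and densities, terminal vessel count, mean segment length, cumulative
#' length density (m/mm^3), mean baseline radius and intra-vessel radius SD,
#' vascular volume density (sum over vertices of pi r^2 x vertex spacing)
#' and neuron soma count/density (26-connected components of the soma mask).
#'
#' @param graph a `vascular_graph`.
#' @param records vertex table from [estimate_vertex_radii()].
#' @param fov_volume_mm3 field-of-view physical volume, mm^3 (> 0).
#' @param neuron_mask optional [binary_mask()] of neuron somas.
#' @param baseline_timepoint time point used for radii (default 1).
#' @return A list of morphometrics.
#' @export
compute_morphometrics <- function(graph, records, fov_volume_mm3,
                                  neuron_mask = NULL, baseline_timepoint = 1) {
  stopifnot(inherits(graph, "vascular_graph"))
  if (fov_volume_mm3 <= 0) stop("FOV volume must be > 0")
  lens <- vapply(graph$edges, `[[`, 0, "length")
  n_vessel <- length(graph$edges)
  n_junction <- sum(graph$nodes$degree >= 3)
  terminal <- vapply(graph$edges, function(e)
    any(graph$nodes$degree[c(e$from, e$to)] == 1), TRUE)
  rec <- records[records$timepoint == baseline_timepoint, ]
  per_edge_mean <- tapply(rec$radius, rec$edge, mean, na.rm = TRUE)
  per_edge_sd <- tapply(rec$radius, rec$edge, sd, na.rm = TRUE)
  # vascular volume: per-vertex disks x local vertex spacing
  vol_um3 <- 0
  for (e in graph$edges) {
    er <- rec[rec$edge == e$id, ]
    if (!nrow(er)) next
    r <- er$radius[order(er$vertex)]
    r[is.na(r)] <- mean(r, na.rm = TRUE)
    if (all(is.na(r))) next
    seg <- sqrt(rowSums(diff(e$path)^2))
    spac <- c(seg[1] / 2, (seg[-1] + seg[-length(seg)]) / 2, seg[length(seg)] / 2)
    n <- min(length(r), length(spac))
    vol_um3 <- vol_um3 + sum(pi * r[seq_len(n)]^2 * spac[seq_len(n)], na.rm = TRUE)
  }
  n_neuron <- NA_integer_
  if (!is.null(neuron_mask)) {
    if (any(neuron_mask$voxels)) {
      lab <- cpp_label3d(neuron_mask$voxels, dim(neuron_mask$voxels), 26L)
      n_neuron <- attr(lab, "n_components")
    } else n_neuron <- 0L
  }
  list(vessel_count = n_vessel,
       vessel_density_mm3 = n_vessel / fov_volume_mm3,
       junction_count = n_junction,
       junction_density_mm3 = n_junction / fov_volume_mm3,
       terminal_vessel_count = sum(terminal),
       mean_segment_length_um = mean(lens),
       cumulative_length_density_m_mm3 = sum(lens) * 1e-6 / fov_volume_mm3,
       mean_baseline_radius_um = mean(per_edge_mean, na.rm = TRUE),
       mean_intra_vessel_radius_sd_um = mean(per_edge_sd, na.rm = TRUE),
       vascular_volume_density = vol_um3 * 1e-9 / fov_volume_mm3,
       neuron_count = n_neuron,
       neuron_density_mm3 = if (is.na(n_neuron)) NA_real_ else
         n_neuron / fov_volume_mm3)
}
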