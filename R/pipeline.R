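# End-to-end orchestration: configuration and the full phantom-to-report run.

#' Pipeline configuration
#'
#' Collects all stage parameters with their defaults. Baseline and
#' post-stimulus frames are explicit (never inferred from file names) and
#' must be disjoint and nonempty.
#'
#' @param volumes list, one element per time point, each a list with
#'   `vascular` and (optionally) `neuron` [image_volume()]s or file paths
#'   readable by [read_volume()].
#' @param reference index of the reference time point for registration.
#' @param baseline,post integer vectors of time point indices.
#' @param target_spacing isotropic working spacing, um.
#' @param min_component minimum retained mask component, voxels.
#' @param dilation_rounds mask dilation passes before the union.
#' @param hair_length hair pruning threshold, um.
#' @param rl_iterations Richardson-Lucy iterations.
#' @param sigma_vertices centerline smoothing sigma, vertices.
#' @param capillary_max_radius capillary/large split, um.
#' @param efficiency_max_diameter efficiency exclusion diameter, um.
#' @param viscosity_cp blood plasma viscosity, cP.
#' @param segment_method `"otsu"` or `"fixed"`.
#' @param segment_threshold threshold for `segment_method = "fixed"`.
#' @param psf a [psf_model()] or NULL for the default Gaussian model.
#' @param register TRUE to rigidly register time points to the reference.
#' @param seed integer seed.
#' @param output_dir optional directory for stage artifacts.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(volumes, reference = 1L, baseline = 1L,
                            post = 2L, target_spacing = 0.99,
                            min_component = 50, dilation_rounds = 3,
                            hair_length = 20, rl_iterations = 10,
                            sigma_vertices = 3, capillary_max_radius = 5,
                            efficiency_max_diameter = 10, viscosity_cp = 4,
                            segment_method = "otsu", segment_threshold = NULL,
                            psf = NULL, register = TRUE, seed = 1L,
                            output_dir = NULL) {
  if (!length(baseline) || !length(post)) stop("baseline and post must be nonempty")
  if (length(intersect(baseline, post))) stop("baseline and post frames must be disjoint")
  structure(list(volumes = volumes, reference = as.integer(reference),
                 baseline = as.integer(baseline), post = as.integer(post),
                 target_spacing = target_spacing,
                 min_component = min_component,
                 dilation_rounds = dilation_rounds, hair_length = hair_length,
                 rl_iterations = rl_iterations,
                 sigma_vertices = sigma_vertices,
                 capillary_max_radius = capillary_max_radius,
                 efficiency_max_diameter = efficiency_max_diameter,
                 viscosity_cp = viscosity_cp,
                 segment_method = segment_method,
                 segment_threshold = segment_threshold, psf = psf,
                 register = register, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full reconstruction and analysis pipeline
#'
#' Executes upsample, registration to the reference frame, segmentation and
#' cleanup, dilation + union across time points, skeletonization, hair
#' pruning, graph construction, centerline smoothing/tangents,
#' Richardson-Lucy deconvolution, vertex-wise radius estimation, neuron
#' distances, vessel summaries with responder classification, morphometrics,
#' assortativity and capillary efficiency. Every stage logs counts to the
#' returned `manifest`.
#'
#' @param config a [pipeline_config()].
#' @return A list: `graph`, `records` (vertex table), `summaries`,
#'   `report` (morphometrics + network metrics), `transforms`, `union_mask`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(parameters = config[setdiff(names(config), "volumes")])
  ntp <- length(config$volumes)
  load_vol <- function(x, channel) {
    if (inherits(x, "image_volume")) x else read_volume(x, channel = channel)
  }

  # 1. load + upsample
  vasc <- vector("list", ntp)
  neur <- vector("list", ntp)
  for (t in seq_len(ntp)) {
    vasc[[t]] <- upsample_isotropic(load_vol(config$volumes[[t]]$vascular,
                                             "vascular"),
                                    config$target_spacing)
    if (!is.null(config$volumes[[t]]$neuron))
      neur[[t]] <- upsample_isotropic(load_vol(config$volumes[[t]]$neuron,
                                               "neuron"),
                                      config$target_spacing)
  }
  manifest$n_timepoints <- ntp

  # 2. rigid registration to the reference frame
  transforms <- vector("list", ntp)
  ref <- config$reference
  for (t in seq_len(ntp)) {
    if (!config$register || t == ref) {
      transforms[[t]] <- rigid_transform()
    } else {
      transforms[[t]] <- rigid_register(vasc[[t]], vasc[[ref]])
      vasc[[t]] <- apply_transform(vasc[[t]], transforms[[t]], "linear")
      if (!is.null(neur[[t]]))
        neur[[t]] <- apply_transform(neur[[t]], transforms[[t]], "linear")
    }
  }

  # 3. segmentation + cleanup per time point
  masks <- vector("list", ntp)
  for (t in seq_len(ntp)) {
    masks[[t]] <- threshold_segment(vasc[[t]], config$segment_method,
                                    config$segment_threshold)
    masks[[t]] <- clean_mask(masks[[t]], config$min_component)
  }
  manifest$mask_voxels <- vapply(masks, function(m) sum(m$voxels), 0)

  # 4. union, skeleton, pruning, graph
  union <- union_masks(masks, config$dilation_rounds)
  skel <- skeletonize(union)
  n_before <- nrow(skel$voxels)
  skel <- prune_hairs(skel, config$hair_length)
  manifest$skeleton_voxels <- nrow(skel$voxels)
  manifest$pruned_voxels <- n_before - nrow(skel$voxels)
  graph <- build_graph(skel)
  graph <- smooth_and_tangents(graph, config$sigma_vertices)
  manifest$n_segments <- length(graph$edges)
  manifest$n_junctions <- sum(graph$nodes$degree >= 3)

  # 5. priors, deconvolution, vertex radii
  priors <- prior_radius_dt(union, graph)
  psf <- if (is.null(config$psf))
    gaussian_psf(voxel_size = rep(config$target_spacing, 3)) else config$psf
  dec <- lapply(vasc, deconvolve, psf = psf,
                iterations = config$rl_iterations)
  records <- estimate_vertex_radii(dec, graph, priors)
  manifest$n_vertex_estimates <- sum(!is.na(records$radius))
  manifest$n_vertex_failures <- sum(is.na(records$radius))

  # 6. neuron distances
  neuron_mask <- NULL
  if (!is.null(neur[[ref]])) {
    neuron_mask <- threshold_segment(neur[[ref]], config$segment_method,
                                     config$segment_threshold,
                                     label = "neuron")
    records <- neuron_distance(neuron_mask, records,
                               radius_timepoint = min(config$baseline))
  }

  # 7. summaries, responders, network metrics
  summaries <- vessel_summaries(records, graph, config$baseline, config$post,
                                config$capillary_max_radius)
  d <- dim(union$voxels)
  fov_mm3 <- prod(d * union$voxel_size) * 1e-9
  report <- list(
    morphometrics = compute_morphometrics(graph, records, fov_mm3,
                                          neuron_mask,
                                          min(config$baseline)))
  caps <- summaries$size_class == "capillary" & !is.na(summaries$delta_radius)
  if (sum(caps) >= 2) {
    lg <- vessel_line_graph(graph, setNames(summaries$delta_radius[caps],
                                            summaries$edge[caps]))
    report$assortativity <- tryCatch(assortativity(lg),
                                     error = function(e) NA_real_)
  }
  mean_tp_radius <- function(tps) {
    cols <- paste0("radius_t", tps)
    r <- rowMeans(as.matrix(summaries[, cols, drop = FALSE]), na.rm = TRUE)
    setNames(r, summaries$edge)
  }
  eff <- tryCatch({
    Eb <- capillary_efficiency(graph, mean_tp_radius(config$baseline),
                               max_diameter = config$efficiency_max_diameter,
                               viscosity_cp = config$viscosity_cp)
    Ep <- capillary_efficiency(graph, mean_tp_radius(config$post),
                               max_diameter = config$efficiency_max_diameter,
                               viscosity_cp = config$viscosity_cp)
    list(baseline = as.numeric(Eb), post = as.numeric(Ep),
         change = efficiency_change(Eb, Ep))
  }, error = function(e) NULL)
  report$efficiency <- eff

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    export_vertex_table(records, file.path(config$output_dir, "vertices.csv"))
    write.csv(summaries, file.path(config$output_dir, "vessels.csv"),
              row.names = FALSE)
    export_graph_graphml(graph, file.path(config$output_dir, "graph.graphml"))
    jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  list(graph = graph, records = records, summaries = summaries,
       report = report, transforms = transforms, union_mask = union,
       manifest = manifest)
}
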