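# File formats: TIFF/NIfTI volumes, GraphML + CSV graph exchange, YAML
# phantom specs and JSON reports.

#' Write a volume to multi-page TIFF or NIfTI
#'
#' TIFF stores one 32-bit float page per z slice with the voxel size recorded
#' in the image description; NIfTI stores the voxel size in pixdim.
#'
#' @param volume an [image_volume()] or [binary_mask()].
#' @param path output path; format chosen by extension (`.tif`/`.tiff` or
#'   `.nii`/`.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  v <- if (inherits(volume, "binary_mask")) volume$voxels * 1 else volume$voxels
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    mx <- max(v)
    scale <- if (mx > 0) mx else 1
    pages <- lapply(seq_len(dim(v)[3]), function(k) t(v[, , k]) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    # voxel size and intensity scale in a JSON sidecar (microscopy TIFFs
    # frequently lack reliable resolution tags)
    jsonlite::write_json(list(voxel_size = volume$voxel_size, scale = scale),
                         paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(v)
    RNifti::pixdim(img) <- volume$voxel_size
    RNifti::writeNifti(img, path)
  } else stop("unsupported volume format: ", path)
  invisible(path)
}

#' Read a volume from TIFF or NIfTI
#'
#' @param path input path (`.tif`/`.tiff` or `.nii`/`.nii.gz`).
#' @param channel channel role for the result.
#' @param voxel_size override for the voxel size (required if the file
#'   carries none).
#' @return An [image_volume()].
#' @export
read_volume <- function(path, channel = "vascular", voxel_size = NULL) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    scale <- 1
    meta_file <- paste0(path, ".meta.json")
    if (file.exists(meta_file)) {
      meta <- jsonlite::fromJSON(meta_file)
      if (is.null(voxel_size)) voxel_size <- meta$voxel_size
      if (!is.null(meta$scale)) scale <- meta$scale
    }
    if (is.null(voxel_size))
      stop("TIFF carries no voxel size; pass voxel_size=")
    v <- simplify2array(lapply(pages, t)) * scale
    image_volume(v, voxel_size, channel)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    if (is.null(voxel_size)) voxel_size <- RNifti::pixdim(img)[1:3]
    image_volume(array(as.numeric(img), dim(img)), voxel_size, channel)
  } else stop("unsupported volume format: ", path)
}

#' Export a vascular graph as GraphML
#'
#' Topology plus node positions; vertex paths live in the companion CSV from
#' [export_vertex_table()].
#'
#' @param graph a `vascular_graph`.
#' @param path output `.graphml` path.
#' @return `path`, invisibly.
#' @export
export_graph_graphml <- function(graph, path) {
  g <- as_igraph(graph)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export the per-vertex table as CSV
#'
#' @param x a `vascular_graph` (vertex paths, smoothed positions, tangents)
#'   or a records data frame from [estimate_vertex_radii()].
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
export_vertex_table <- function(x, path) {
  if (inherits(x, "vascular_graph")) {
    rows <- lapply(x$edges, function(e) {
      n <- nrow(e$path)
      df <- data.frame(edge = e$id, vertex = seq_len(n),
                       x = e$path[, 1], y = e$path[, 2], z = e$path[, 3])
      if (!is.null(e$smoothed)) {
        df$sx <- e$smoothed[, 1]; df$sy <- e$smoothed[, 2]; df$sz <- e$smoothed[, 3]
        df$tx <- e$tangents[, 1]; df$ty <- e$tangents[, 2]; df$tz <- e$tangents[, 3]
      }
      df
    })
    write.csv(do.call(rbind, rows), path, row.names = FALSE)
  } else {
    write.csv(x, path, row.names = FALSE)
  }
  invisible(path)
}

#' Serialize or load a phantom spec as YAML
#'
#' Tube radius functions are not serializable; specs written to YAML must use
#' scalar radii.
#'
#' @param spec a [phantom_spec()].
#' @param path `.yaml` path.
#' @return For `write_phantom_spec`, `path` invisibly; for
#'   `read_phantom_spec`, the [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  x <- unclass(spec)
  x$tubes <- lapply(x$tubes, function(tb) {
    if (is.function(tb$radius)) stop("function radii cannot be serialized")
    list(centerline = apply(as.matrix(tb$centerline), 1, as.numeric,
                            simplify = FALSE),
         radius = tb$radius, intensity = tb$intensity)
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  x$tubes <- lapply(x$tubes, function(tb) {
    list(centerline = unname(do.call(rbind, lapply(tb$centerline, unlist))),
         radius = tb$radius, intensity = tb$intensity)
  })
  phantom_spec(volume_shape = unlist(x$volume_shape),
               voxel_size = unlist(x$voxel_size), tubes = x$tubes,
               beads = x$beads, neurons = x$neurons,
               background_level = x$background_level,
               timepoints = x$timepoints, seed = x$seed)
}

#' Serialize a rigid transform as a 4x4 homogeneous matrix sidecar
#'
#' @param transform a [rigid_transform()].
#' @param path text file path.
#' @return For the writer, `path` invisibly; for the reader, the
#'   [rigid_transform()].
#' @export
write_transform <- function(transform, path) {
  H <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  utils::write.table(H, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  H <- unname(as.matrix(utils::read.table(path)))
  rigid_transform(H[1:3, 1:3], H[1:3, 4])
}
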