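#' Save voxel fields to a plain-text container
#'
#' Writes a phantom and any number of grid-shaped fields to a directory
#' container: a JSON header (`header.json`: dimensions, voxel size, origin,
#' per-region properties) plus one flat CSV per array (column-major voxel
#' order, one value per row). The format is self-describing and
#' tool-agnostic; [load_fields()] restores it.
#'
#' @param path directory to create/overwrite.
#' @param grid a `voxel_grid`.
#' @param fields named list of grid-shaped numeric arrays (may be empty).
#' @return `path`, invisibly.
#' @export
save_fields <- function(path, grid, fields = list()) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(fields))
    if (!identical(dim(fields[[nm]]), as.integer(grid$dims)))
      stop("field '", nm, "' does not match the grid dimensions")
  header <- list(
    format = "pattwin-fields-1",
    dims = grid$dims, dl = grid$dl, origin = grid$origin,
    regions = lapply(grid$props, function(p) unclass(p)),
    fields = as.list(names(fields)))
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(data.frame(label = as.vector(grid$labels)),
                   file.path(path, "region_labels.csv"), row.names = FALSE)
  for (nm in names(fields))
    utils::write.csv(data.frame(value = as.vector(fields[[nm]])),
                     file.path(path, paste0(nm, ".csv")), row.names = FALSE)
  invisible(path)
}

#' Load voxel fields from a plain-text container
#'
#' @param path directory written by [save_fields()].
#' @return List with `grid` (a `voxel_grid`) and `fields` (named list of
#'   arrays).
#' @export
load_fields <- function(path) {
  header <- jsonlite::read_json(file.path(path, "header.json"),
                                simplifyVector = TRUE)
  if (!identical(header$format, "pattwin-fields-1"))
    stop("not a pattwin field container: ", path)
  dims <- as.integer(header$dims)
  labels <- array(as.integer(
    utils::read.csv(file.path(path, "region_labels.csv"))$label), dim = dims)
  props <- lapply(header$regions, function(p)
    do.call(tissue_properties, p[setdiff(names(p), character(0))]))
  grid <- new_voxel_grid(dims, header$dl, labels, props,
                         origin = as.numeric(header$origin))
  fields <- list()
  for (nm in unlist(header$fields))
    fields[[nm]] <- array(
      utils::read.csv(file.path(path, paste0(nm, ".csv")))$value, dim = dims)
  list(grid = grid, fields = fields)
}

#' Write sampling-point trajectories as CSV
#'
#' Long format: `time_s, point, truth, model_only, fused, pa_only`
#' (whichever columns the run produced).
#'
#' @param traj trajectory data frame (e.g. from [run_ptt_twin()]).
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_trajectories <- function(traj, file) {
  utils::write.csv(traj, file, row.names = FALSE)
  invisible(file)
}

#' Write a calibration model as a structured text document
#'
#' @param cal a [calibration_model()].
#' @param file output YAML path.
#' @return `file`, invisibly.
#' @export
write_calibration <- function(cal, file) {
  yaml::write_yaml(c(unclass(cal), list(written = format(Sys.time()))), file)
  invisible(file)
}

#' Load an experiment configuration from YAML
#'
#' Reads a structured text config and merges it over the experiment's
#' defaults (recursively: config keys override defaults, unspecified keys
#' keep their default).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param defaults default config list (e.g. [ptt_twin_config()]).
#' @return Merged configuration list.
#' @export
load_config <- function(path, defaults) {
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  merge_rec <- function(a, b) {
    for (nm in names(b))
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_rec(a[[nm]], b[[nm]]) else b[[nm]]
    a
  }
  merge_rec(defaults, user)
}
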