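# End-to-end orchestration: simulate -> rasterise -> reconstruct ->
# measure -> aggregate, with per-stage seed substreams and a run manifest.

# stage-keyed substream of a global seed, kept below 2^31
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Run configuration for an end-to-end phantom study
#'
#' Fully serialisable description of a run: one or more phantom specs
#' (fields), reconstruction parameters, and the global seed from which
#' every stage derives its own substream. A run is reproducible from the
#' config alone.
#' @param specs list of [phantom_spec()] (one per field); a single spec is
#'   accepted.
#' @param step,spur,min_object_volume,segmentation reconstruction
#'   parameters (see [reconstruct_capillaries()]).
#' @param z_calibration axial calibration factor applied to the image
#'   volume before vectorisation; use `1 / z_shrinkage` to undo the
#'   phantom's axial compression.
#' @param seed global integer seed.
#' @param out_dir output directory, or NULL to skip file outputs.
#' @return object of class `run_config`.
#' @export
run_config <- function(specs, step = 5, spur = 5, min_object_volume = 100,
                       segmentation = "otsu", z_calibration = NULL,
                       seed = 1L, out_dir = NULL) {
  if (inherits(specs, "phantom_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, TRUE, "phantom_spec")),
            step > 0, spur >= 0)
  structure(list(specs = specs, step = step, spur = spur,
                 min_object_volume = min_object_volume,
                 segmentation = segmentation,
                 z_calibration = z_calibration,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Measure one phantom field through the full image pipeline
#'
#' Generates the network, rasterises it (with the spec's axial shrinkage
#' and noise), applies axial calibration, reconstructs the vector graph
#' and computes all network parameters; the same parameters are computed
#' on the exact generated graph as ground truth.
#' @param spec a [phantom_spec()].
#' @param step,spur,smooth,min_object_volume,segmentation reconstruction
#'   parameters (see [reconstruct_capillaries()]).
#' @param z_calibration axial calibration; default `1 / z_shrinkage`.
#' @param fibres optional `fibre_model` for fibre-normalised densities.
#' @return list with `truth` (exact metrics), `measured`
#'   (`morphometry_result`), `graph` (reconstructed), `truth_graph`.
#' @export
run_capillary_field <- function(spec, step = 5, spur = 5, smooth = 8,
                                min_object_volume = 100,
                                segmentation = "otsu",
                                z_calibration = NULL, fibres = NULL) {
  if (is.null(z_calibration)) z_calibration <- 1 / spec$z_shrinkage
  net <- generate_capillary_network(spec)
  vol <- rasterise_network(net$graph, spec)
  vol <- apply_axial_calibration(vol, z_calibration)
  g <- reconstruct_capillaries(vol, step = step, spur = spur,
                               smooth = smooth, method = segmentation,
                               min_object_volume = min_object_volume)
  V <- prod(spec$field_size)
  measured <- compute_morphometry(g, V, fibres = fibres)
  list(truth = net$truth, measured = measured, graph = g,
       truth_graph = net$graph)
}

#' Compare measured field metrics against phantom ground truth
#'
#' Relative errors of each recovered parameter against the exact
#' vector-graph value, with pass/fail against a tolerance table.
#' @param measured a `morphometry_result`.
#' @param truth the `truth` list from [generate_capillary_network()].
#' @param tolerances named relative tolerances per metric.
#' @return data.frame with metric, measured, truth, rel_error, tol, pass.
#' @export
validate_against_truth <- function(measured, truth,
                                   tolerances = c(LVm = 0.10,
                                                  Br_dens = 0.15,
                                                  tortuosity = 0.15,
                                                  MeanCap = 0.15)) {
  if (is.null(truth)) stop("missing ground truth")
  key <- c(LVm = "LVm", Br_dens = "NV", tortuosity = "tortuosity",
           MeanCap = "MeanCap")
  rows <- lapply(names(tolerances), function(mname) {
    tv <- truth[[key[[mname]]]]
    mv <- measured[[mname]]
    degenerate <- is.null(tv) || is.na(tv) || tv == 0
    rel <- if (degenerate) NA_real_ else abs(mv - tv) / abs(tv)
    data.frame(metric = mname, measured = mv,
               truth = if (degenerate) NA_real_ else tv,
               rel_error = rel, tol = tolerances[[mname]],
               pass = !is.na(rel) && rel <= tolerances[[mname]],
               degenerate = degenerate)
  })
  do.call(rbind, rows)
}

#' Execute a full run from a configuration
#'
#' For every field in the config: generate, rasterise, reconstruct and
#' measure; optionally write the stack, graphs, a per-field metrics CSV
#' (reporting units) and a manifest (software version, config hash, seed,
#' per-file checksums). Rerunning an identical config reproduces the same
#' outputs byte for byte.
#' @param config a [run_config()].
#' @return list with `fields` (per-field results), `metrics`
#'   (reporting-scale data.frame), `manifest`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  fields <- list()
  for (i in seq_along(config$specs)) {
    spec <- config$specs[[i]]
    spec$seed <- stage_seed(config$seed, paste0("field", i, "_", spec$seed))
    res <- tryCatch(
      run_capillary_field(spec, step = config$step, spur = config$spur,
                          min_object_volume = config$min_object_volume,
                          segmentation = config$segmentation,
                          z_calibration = config$z_calibration),
      error = function(e) list(error = conditionMessage(e)))
    fields[[i]] <- res
    if (!is.null(out_dir) && is.null(res$error)) {
      write_graph_json(res$graph,
                       file.path(out_dir, sprintf("field%02d_graph.json", i)))
      write_graph_swc(res$graph,
                      file.path(out_dir, sprintf("field%02d_graph.swc", i)),
                      radius = spec$capillary_radius)
    }
  }
  ok <- vapply(fields, function(f) is.null(f$error), TRUE)
  metrics <- if (any(ok))
    cbind(field = which(ok),
          format_morphometry(lapply(fields[ok], `[[`, "measured")))
  else NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("myocap3d")),
    seed = config$seed,
    config_hash = config_hash(config),
    n_fields = length(config$specs),
    failed_fields = which(!ok))
  if (!is.null(out_dir)) {
    if (!is.null(metrics))
      utils::write.csv(metrics, file.path(out_dir, "field_metrics.csv"),
                       row.names = FALSE)
    files <- list.files(out_dir, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    manifest$files <- data.frame(
      file = basename(files),
      md5 = unname(tools::md5sum(files)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(fields = fields, metrics = metrics, manifest = manifest)
}

# stable hash of the serialisable config content
config_hash <- function(config) {
  s <- jsonlite::toJSON(list(
    specs = lapply(config$specs, unclass),
    step = config$step, spur = config$spur,
    min_object_volume = config$min_object_volume,
    segmentation = config$segmentation,
    z_calibration = config$z_calibration, seed = config$seed),
    auto_unbox = TRUE, digits = 10)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(s), tf)
  unname(tools::md5sum(tf))
}
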