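# End-to-end pipeline: read -> repair -> diameter policy -> soma scale ->
# tessellate -> color -> scale to print units -> stats -> thickness report
# -> export, with logging and a reproducibility manifest.

#' Build a run configuration
#'
#' Every field has a default; the effective configuration (defaults
#' included) is logged and hashed into the run manifest.
#'
#' @param input path to an SWC/ASC file, or a [Morphology], or a list of
#'   them (multi-cell merge).
#' @param format `"auto"`, `"swc"` or `"asc"`.
#' @param reattach repair detached roots ([repairDetached]).
#' @param dropAxon remove the axon before meshing ([removeAxon]).
#' @param policy a [DiameterPolicy], `"auto"` (fixed diameter solved from
#'   the print spec via [suggestDiameter]), or `NULL` (leave diameters).
#' @param somaScale scale factor for [scaleSoma] (1 = untouched).
#' @param spec a [PrintSpec].
#' @param resolution spatial step in microns, or `NULL` for the default.
#' @param scheme a [ColorScheme] or `NULL` for uncolored output.
#' @param outStl,outWrl,outJson output paths (`NULL` to skip).
#' @param force proceed despite thickness violations.
#' @param name model name recorded in the metadata.
#' @return a named list (class `neuroprintConfig`).
#' @export
runConfig <- function(input, format = "auto", reattach = TRUE,
                      dropAxon = FALSE, policy = "auto", somaScale = 1,
                      spec = printSpec(), resolution = NULL, scheme = NULL,
                      outStl = NULL, outWrl = NULL, outJson = NULL,
                      force = FALSE, name = "model") {
  cfg <- list(input = input, format = format, reattach = reattach,
              dropAxon = dropAxon, policy = policy, somaScale = somaScale,
              spec = spec, resolution = resolution, scheme = scheme,
              outStl = outStl, outWrl = outWrl, outJson = outJson,
              force = force, name = name)
  class(cfg) <- "neuroprintConfig"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Recognised keys mirror [runConfig]; `policy` may be given as
#' `{mode: fixed, value: 9}` or a `per_kind` map, `spec` as
#' `{coordinate_scale: 0.2, min_thickness: 1.0, recommended_thickness: 1.2}`.
#'
#' @param file YAML path.
#' @return a configuration list for [runPipeline].
#' @export
loadRunConfig <- function(file) {
  y <- yaml::read_yaml(file)
  spec <- printSpec(
    coordinateScale = y$spec$coordinate_scale %||% 0.2,
    minThickness = y$spec$min_thickness %||% 1.0,
    recommendedThickness = y$spec$recommended_thickness %||% 1.2)
  pol <- if (is.null(y$policy)) "auto"
  else if (identical(y$policy, "none")) NULL
  else if (!is.null(y$policy$per_kind))
    diameterPolicy("per_kind", perKind = y$policy$per_kind)
  else diameterPolicy(y$policy$mode, y$policy$value)
  runConfig(input = y$input,
            format = y$format %||% "auto",
            reattach = y$reattach %||% TRUE,
            dropAxon = y$drop_axon %||% FALSE,
            policy = pol,
            somaScale = y$soma_scale %||% 1,
            spec = spec,
            resolution = y$resolution,
            outStl = y$out_stl, outWrl = y$out_wrl, outJson = y$out_json,
            force = y$force %||% FALSE,
            name = y$name %||% "model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

readMorphologyFile <- function(path, format = "auto") {
  if (is(path, "Morphology")) return(path)
  fmt <- if (format == "auto") {
    if (grepl("\\.asc$", path, ignore.case = TRUE)) "asc" else "swc"
  } else format
  if (fmt == "asc") readASC(path) else readSWC(path)
}

pipelineLog <- function(stage, fmt, ...) {
  message(sprintf("[neuroprint] %-12s %s", stage, sprintf(fmt, ...)))
}

#' Run the printable-model pipeline
#'
#' Executes read, repair, diameter policy, soma scaling, thickness
#' validation, tessellation, optional coloring, scaling to print units,
#' mesh measurement and export, logging every stage.  Identical
#' configuration and inputs give byte-identical outputs.  Thickness
#' violations abort the run unless `force = TRUE`.
#'
#' @param config from [runConfig] or [loadRunConfig].
#' @return (invisibly) list with `mesh` (printed-size [TriangleMesh]),
#'   `morphology` (configured, unscaled), `stats` ([MeshStats]),
#'   `version` ([PrintableVersion]), `report` ([ThicknessReport]),
#'   `magnification`, and `manifest`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "neuroprintConfig"))
  t0 <- Sys.time()
  stage <- function(nm) pipelineLog(nm, "starting")
  fail <- function(nm, e) stop("pipeline stage '", nm, "' failed: ",
                               conditionMessage(e), call. = FALSE)
  run <- function(nm, expr) {
    tryCatch(expr, error = function(e) fail(nm, e))
  }

  inputs <- config$input
  if (!is.list(inputs) || is(inputs, "Morphology")) inputs <- list(inputs)
  cells <- run("read", lapply(inputs, readMorphologyFile, config$format))
  pipelineLog("read", "%d cell(s)", length(cells))

  if (config$reattach)
    cells <- run("repair", lapply(cells, repairDetached))
  if (config$dropAxon)
    cells <- run("repair", lapply(cells, removeAxon))

  policy <- config$policy
  if (identical(policy, "auto")) {
    d <- suggestDiameter(config$spec)
    pipelineLog("policy", "auto fixed diameter %.3g um", d)
    policy <- diameterPolicy("fixed", d)
  }
  if (!is.null(policy))
    cells <- run("policy", lapply(cells, applyDiameterPolicy, policy))
  if (config$somaScale != 1) {
    pipelineLog("soma", "scaling soma by %.3g", config$somaScale)
    cells <- run("soma", lapply(cells, scaleSoma, config$somaScale))
  }

  report <- run("thickness", {
    reps <- lapply(cells, checkThickness, config$spec)
    reps[[which.min(vapply(reps, function(r) r@passFlag, logical(1)))]]
  })
  if (!report@passFlag) {
    bad <- unique(report@violations$sectionId)
    if (!config$force)
      stop("pipeline stage 'thickness' failed: printed thickness below ",
           config$spec@minThickness, " mm in section(s) ",
           paste(bad, collapse = ", "), " (use force = TRUE to override)",
           call. = FALSE)
    pipelineLog("thickness", "WARNING: %d violating section(s), forced on",
                length(bad))
  } else pipelineLog("thickness", "pass")

  res <- if (is.null(config$resolution)) NULL
         else meshResolution(config$resolution)
  mesh <- run("tessellate", mergeCells(cells, res))
  pipelineLog("tessellate", "%d faces, %d component(s)",
              nrow(faces(mesh)), mesh@metadata$nComponents)

  if (!is.null(config$scheme)) {
    mesh <- run("color", {
      frusta <- frustaFromCells(cells)
      asg <- mapTrianglesToSegments(mesh, frusta)
      assignColors(mesh, asg, config$scheme, cells[[1]])
    })
    pipelineLog("color", "per-face colors assigned (%s)",
                config$scheme@mode)
  }

  sc <- run("scale", scaleModel(mesh, config$spec))
  pipelineLog("scale", "magnification %gx", sc$magnification)
  stats <- run("stats", meshStats(sc$model, unit = config$spec@outputUnit))
  pv <- printabilityReport(cells[[1]], config$spec, stats,
                           name = config$name)

  outputs <- character()
  if (!is.null(config$outStl)) {
    run("export", suppressWarnings(writeSTL(sc$model, config$outStl)))
    outputs <- c(outputs, config$outStl)
  }
  if (!is.null(config$outWrl)) {
    run("export", writeWRL(sc$model, config$outWrl))
    outputs <- c(outputs, config$outWrl)
  }
  if (!is.null(config$outJson)) {
    run("export", printableVersionToJSON(pv$version, config$outJson))
    outputs <- c(outputs, config$outJson)
  }
  if (length(outputs)) pipelineLog("export", "%s",
                                   paste(outputs, collapse = ", "))

  manifest <- list(
    configHash = hashConfig(config),
    packageVersion = as.character(utils::packageVersion("neuroprint")),
    nCells = length(cells),
    spatialStep = mesh@metadata$spatialStep,
    magnification = sc$magnification,
    elapsedSec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  invisible(list(mesh = sc$model, morphology = cells[[1]], stats = stats,
                 version = pv$version, report = report,
                 magnification = sc$magnification, manifest = manifest))
}

# stable digest of the configuration (file-content based for path inputs)
hashConfig <- function(config) {
  cfg <- config
  cfg$scheme <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg, tmp, version = 2)
  unname(tools::md5sum(tmp))
}
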