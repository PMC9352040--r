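# End-to-end orchestration: segmentation -> smoothing -> local thickness ->
# skeletonization -> pruning -> thickness labelling -> graph -> report.

#' Pipeline configuration
#'
#' Collects the tunable parameters of the full analysis with defaults
#' matching the reference micro-CT protocol: Otsu segmentation of the
#' full-volume histogram, isotropic Gaussian smoothing with a 5-voxel
#' window, two 4-voxel pruning cycles, and the radius convention for local
#' thickness.
#'
#' @param input Path to the input volume (read with [readVolume()]), or a
#'   [VoxelVolume-class] held in memory.
#' @param labels Optional path to a label volume, or a
#'   [LabelVolume-class].
#' @param spacingUm Optional spacing override (um).
#' @param kernelSizeVx Gaussian smoothing window (voxels); default 5.
#' @param thresholdLadder Re-threshold ladder for connectivity-preserving
#'   smoothing.
#' @param pruneVx Pruning twig length (voxels); default 4.
#' @param pruneCycles Pruning cycles; default 2.
#' @param ltConvention `"radius"` or `"diameter"`.
#' @param lengthMethod Branch-length estimator, see [buildGraph()].
#' @param outputDir Optional directory for intermediates, report and
#'   provenance (created if missing).
#' @param seed Integer seed recorded in provenance (the analysis itself is
#'   deterministic; randomness only enters phantom generation).
#' @return A list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(input, labels = NULL, spacingUm = NULL,
                           kernelSizeVx = 5L,
                           thresholdLadder = seq(0.5, 0.05, by = -0.05),
                           pruneVx = 4L, pruneCycles = 2L,
                           ltConvention = "radius",
                           lengthMethod = "smoothed",
                           outputDir = NULL, seed = 1L) {
  structure(list(input = input, labels = labels, spacingUm = spacingUm,
                 kernelSizeVx = as.integer(kernelSizeVx),
                 thresholdLadder = thresholdLadder,
                 pruneVx = as.integer(pruneVx),
                 pruneCycles = as.integer(pruneCycles),
                 ltConvention = ltConvention,
                 lengthMethod = lengthMethod,
                 outputDir = outputDir, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipelineConfig()].
#' @return A `"PipelineConfig"` list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y)
}

#' Run the full morphometry pipeline
#'
#' Executes segmentation, connectivity-preserving smoothing, the
#' local-thickness transform, thinning skeletonization, pruning,
#' thickness labelling, graph construction and branch statistics, then
#' assembles a [MorphometryReport-class].  When `config$outputDir` is set,
#' every intermediate is written to disk along with `report.json`,
#' `branch_statistics.csv`, `skeleton.swc` and a `provenance.json`
#' recording package version, parameters, stage wall times and output
#' checksums.  Identical inputs and configuration give identical outputs
#' (timestamps excluded).
#'
#' @param config A `"PipelineConfig"` from [pipelineConfig()].
#' @param verbose Print stage progress?
#' @return The [MorphometryReport-class]; intermediates are attached as
#'   `attr(, "stages")` (mask, smoothed, thickness, skeleton, graph,
#'   statistics).
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    if (verbose)
      message(sprintf("[%s] %.2fs", name,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    attr(out, ".elapsed") <- as.numeric(difftime(Sys.time(), t0,
                                                 units = "secs"))
    out
  }
  times <- list()
  note <- character(0)

  vol <- stage("read", {
    v <- if (is.character(config$input)) readVolume(config$input)
         else config$input
    if (!is(v, "VoxelVolume"))
      stop("input must be a VoxelVolume (or a path to one)")
    if (!is.null(config$spacingUm))
      v <- VoxelVolume(voxelData(v), .assertSpacing(config$spacingUm),
                       origin(v))
    v
  })
  times$read <- attr(vol, ".elapsed")
  labels <- NULL
  if (!is.null(config$labels)) {
    labels <- if (is.character(config$labels)) readVolume(config$labels)
              else config$labels
    if (!is(labels, "LabelVolume"))
      stop("labels must be a LabelVolume (or a path to one)")
  }

  mask <- stage("segment", segmentVolume(vol))
  times$segment <- attr(mask, ".elapsed")
  # local thickness is measured on the raw binarized volume; the smoothed
  # volume only feeds skeletonization (smoothing suppresses spurious
  # branches but thins fine tubes, which would bias the calibre labels)
  lt <- stage("thickness",
              localThickness(mask, convention = config$ltConvention))
  times$thickness <- attr(lt, ".elapsed")
  smoothed <- stage("smooth",
                    smoothPreservingConnectivity(mask, config$kernelSizeVx,
                                                 config$thresholdLadder))
  times$smooth <- attr(smoothed, ".elapsed")
  skel <- stage("skeletonize", skeletonize(smoothed))
  times$skeletonize <- attr(skel, ".elapsed")
  skel <- stage("prune",
                pruneSkeleton(skel, config$pruneVx, config$pruneCycles))
  times$prune <- attr(skel, ".elapsed")
  # smoothing can add the odd voxel outside the raw mask; refresh the
  # thickness field on the union so every skeleton voxel carries a label
  if (any(voxelData(skel) & voxelData(lt) == 0)) {
    lt <- localThickness(BinaryMask(voxelData(mask) | voxelData(smoothed),
                                    spacing(mask), origin(mask)),
                         convention = config$ltConvention)
  }
  skel <- stage("label", labelWithThickness(skel, lt))
  times$label <- attr(skel, ".elapsed")
  graph <- stage("graph", buildGraph(skel, lengthMethod = config$lengthMethod))
  times$graph <- attr(graph, ".elapsed")
  stats <- stage("statistics", branchStatistics(graph, labels))
  times$statistics <- attr(stats, ".elapsed")

  volumes <- NULL
  openings <- NULL
  if (!is.null(labels)) {
    volumes <- volumeByLabel(labels)
    openings <- withCallingHandlers(
      endpointCountsByLabel(graph, labels),
      warning = function(w) {
        note <<- c(note, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  } else {
    openings <- c(total = sum(graph@nodes$type == "endpoint"))
  }
  report <- makeReport(volumes = volumes, openings = openings,
                       notes = note)

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$outputDir, f)
    writeVolume(mask, p("mask.tif"))
    writeVolume(smoothed, p("mask_smoothed.tif"))
    writeVolume(lt, p("local_thickness.raw"))
    writeVolume(BinaryMask(voxelData(skel), spacing(skel), origin(skel)),
                p("skeleton.tif"))
    writeSWC(graph, p("skeleton.swc"))
    write.csv(stats, p("branch_statistics.csv"), row.names = FALSE)
    write.csv(graph@branches, p("branches.csv"), row.names = FALSE)
    writeReport(report, p("report.json"))
    cfgOut <- config
    cfgOut$input <- if (is.character(config$input)) config$input else "<in-memory>"
    cfgOut$labels <- if (is.character(config$labels %||% "")) config$labels
                     else "<in-memory>"
    files <- c("mask.tif", "mask_smoothed.tif", "local_thickness.raw",
               "skeleton.tif", "skeleton.swc", "branch_statistics.csv",
               "branches.csv", "report.json")
    prov <- list(package = "canalmorph",
                 version = as.character(utils::packageVersion("canalmorph")),
                 timestamp = format(Sys.time(), tz = "UTC"),
                 config = cfgOut[!vapply(cfgOut, is.null, logical(1))],
                 stage_seconds = times,
                 checksums = as.list(tools::md5sum(
                   vapply(files, p, character(1)))))
    jsonlite::write_json(prov, p("provenance.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = 8, force = TRUE)
  }
  attr(report, "stages") <- list(mask = mask, smoothed = smoothed,
                                 thickness = lt, skeleton = skel,
                                 graph = graph, statistics = stats)
  report
}
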