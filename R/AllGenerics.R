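#' Accessors for voxel-grid classes
#'
#' `voxelData()` returns the underlying 3D array, `spacing()` the per-axis
#' voxel spacing (dz, dy, dx) in micrometres, `origin()` the physical
#' position of voxel (1,1,1), and `labelNames()` the label-id to
#' structure-name map of a [LabelVolume-class].
#'
#' @param x A grid object.
#' @return `voxelData()`: a 3D array; `spacing()`/`origin()`: numeric
#'   length-3; `labelNames()`: a named character vector.
#' @examples
#' v <- VoxelVolume(array(0L, c(2, 3, 4)), spacing = c(62, 62, 62))
#' spacing(v)
#' dim(voxelData(v))
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname grid-accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname grid-accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname grid-accessors
#' @export
setGeneric("labelNames", function(x) standardGeneric("labelNames"))

#' @rdname writeVolume
#' @export
setGeneric("writeVolume", function(x, path, ...) standardGeneric("writeVolume"))

#' @rdname segmentVolume
#' @export
setGeneric("segmentVolume", function(x, ...) standardGeneric("segmentVolume"))

#' @rdname localThickness
#' @export
setGeneric("localThickness", function(x, ...) standardGeneric("localThickness"))

#' @rdname skeletonize
#' @export
setGeneric("skeletonize", function(x, ...) standardGeneric("skeletonize"))

for (cl in c("VoxelVolume", "BinaryMask", "LabelVolume")) {
  setMethod("voxelData", cl, function(x) x@data)
  setMethod("spacing", cl, function(x) x@spacing)
  setMethod("origin", cl, function(x) x@origin)
}
setMethod("voxelData", "ThicknessField", function(x) x@values)
setMethod("spacing", "ThicknessField", function(x) x@spacing)
setMethod("origin", "ThicknessField", function(x) x@origin)
setMethod("voxelData", "Skeleton", function(x) x@data)
setMethod("spacing", "Skeleton", function(x) x@spacing)
setMethod("origin", "Skeleton", function(x) x@origin)
setMethod("spacing", "SkeletonGraph", function(x) x@spacing)
setMethod("labelNames", "LabelVolume", function(x) x@labelNames)

#' Construct grid objects
#'
#' Constructors for the voxel-grid classes; see [canalmorph-classes].
#'
#' @param data A 3D array (numeric for `VoxelVolume`, logical for
#'   `BinaryMask`, non-negative integer for `LabelVolume`).
#' @param spacing Voxel spacing (dz, dy, dx) in micrometres; a single value
#'   is recycled to all three axes.
#' @param origin Physical position (um) of voxel (1,1,1).
#' @param labelNames Named character vector mapping label id (as character)
#'   to structure name; auto-generated as `"label_<id>"` when missing.
#' @return An object of the corresponding class.
#' @examples
#' m <- BinaryMask(array(TRUE, c(3, 3, 3)), spacing = 62)
#' spacing(m)
#' @name grid-constructors
NULL

#' @rdname grid-constructors
#' @export
VoxelVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  .assertGrid3d(data)
  new("VoxelVolume", data = data, spacing = .assertSpacing(spacing),
      origin = as.numeric(origin))
}

#' @rdname grid-constructors
#' @export
BinaryMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  .assertGrid3d(data)
  storage.mode(data) <- "logical"
  new("BinaryMask", data = data, spacing = .assertSpacing(spacing),
      origin = as.numeric(origin))
}

#' @rdname grid-constructors
#' @export
LabelVolume <- function(data, labelNames = NULL, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  .assertGrid3d(data)
  storage.mode(data) <- "integer"
  ids <- sort(unique(data[data > 0L]))
  if (is.null(labelNames))
    labelNames <- stats::setNames(paste0("label_", ids), as.character(ids))
  new("LabelVolume", data = data, labelNames = labelNames,
      spacing = .assertSpacing(spacing), origin = as.numeric(origin))
}

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelVolume %d x %d x %d (z,y,x), spacing %s um, range [%g, %g]\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = " x "),
              min(object@data), max(object@data)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("BinaryMask %d x %d x %d (z,y,x), spacing %s um, %d fg voxels\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = " x "),
              sum(object@data)))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("LabelVolume %d x %d x %d (z,y,x), %d labels: %s\n",
              d[1], d[2], d[3], length(object@labelNames),
              paste(object@labelNames, collapse = ", ")))
})

setMethod("show", "ThicknessField", function(object) {
  d <- dim(object@values)
  fg <- object@values > 0
  cat(sprintf("ThicknessField %d x %d x %d (z,y,x), %s convention, LT in [%g, %g] um\n",
              d[1], d[2], d[3], object@convention,
              if (any(fg)) min(object@values[fg]) else 0,
              max(object@values)))
})

setMethod("show", "Skeleton", function(object) {
  cat(sprintf("Skeleton with %d voxels%s, spacing %s um\n",
              sum(object@data),
              if (length(object@ltLabel)) " (LT-labelled)" else "",
              paste(signif(object@spacing, 4), collapse = " x ")))
})

setMethod("show", "SkeletonGraph", function(object) {
  tab <- table(factor(object@nodes$type,
                      levels = c("junction", "endpoint", "isolated")))
  cat(sprintf("SkeletonGraph: %d branches, %d junctions, %d endpoints, %d isolated\n",
              nrow(object@branches), tab[["junction"]], tab[["endpoint"]],
              tab[["isolated"]]))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d segments, %d labels, seed %d\n",
              nrow(object@segments), length(unique(object@segments$label)),
              object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: B=%d J=%d E=%d, analytic volume %.4g cm^3\n",
              object@counts$B, object@counts$J, object@counts$E,
              object@volumeCm3))
})

setMethod("show", "MorphometryReport", function(object) {
  cat("MorphometryReport\n")
  if (length(object@volumesCm3)) {
    cat("  volumes [cm^3]:\n")
    for (n in names(object@volumesCm3))
      cat(sprintf("    %-18s %.3f\n", n, object@volumesCm3[[n]]))
  }
  if (length(object@openings)) {
    cat("  openings:\n")
    for (n in names(object@openings))
      cat(sprintf("    %-18s %d\n", n, as.integer(object@openings[[n]])))
  }
  if (length(object@extrapolation))
    cat(sprintf("  extrapolation: inner %d, outer %d (%d arms)\n",
                object@extrapolation$innerTotal, object@extrapolation$outerTotal,
                object@extrapolation$nArms))
  for (n in object@notes) cat("  note:", n, "\n")
})
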