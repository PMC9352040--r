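#' Voxel-grid and skeleton classes
#'
#' `VoxelVolume` holds a 3D scalar grid (a grayscale scan or a rendered
#' phantom) with per-axis physical spacing; `BinaryMask` a segmented
#' foreground; `LabelVolume` an integer substructure labelling (0 =
#' background); `ThicknessField` the per-voxel local-thickness values in
#' micrometres; `Skeleton` a one-voxel-wide medial axis (optionally labelled
#' with local thickness); `SkeletonGraph` its branch/junction/endpoint
#' decomposition.
#'
#' The fixed axis convention is `dim = (z, y, x)` with z the slice index;
#' `spacing` and `origin` follow the same (dz, dy, dx) order in micrometres.
#' Voxel indices are 1-based in R; the physical centre of voxel `(i, j, k)`
#' is `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @slot data For `VoxelVolume` a numeric/integer 3D array; for `BinaryMask`
#'   and `Skeleton` a logical 3D array; for `LabelVolume` an integer 3D
#'   array with 0 meaning background.
#' @slot spacing Numeric length-3, voxel spacing (dz, dy, dx) in um.
#' @slot origin Numeric length-3, physical position (um) of voxel (1,1,1).
#' @slot labelNames Named character vector mapping label id (as character)
#'   to structure name, e.g. `c("1" = "central_canal")`.
#' @slot values Numeric 3D array of local-thickness values (um), zero on
#'   background.
#' @slot convention Either `"radius"` (default; the radius of the maximal
#'   inscribed sphere) or `"diameter"`.
#' @slot ltLabel Numeric 3D array of per-skeleton-voxel local thickness
#'   (um); length-0 array when unset.
#'
#' @name canalmorph-classes
#' @aliases VoxelVolume-class BinaryMask-class LabelVolume-class
#'   ThicknessField-class Skeleton-class
NULL

#' @rdname canalmorph-classes
#' @export
setClass("VoxelVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3L || any(dim(object@data) < 1L))
      msg <- c(msg, "data must have exactly 3 axes, each of length >= 1")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "all spacing components must be > 0")
    if (length(object@origin) != 3L)
      msg <- c(msg, "origin must have 3 components")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname canalmorph-classes
#' @export
setClass("BinaryMask",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!is.logical(object@data))
      msg <- c(msg, "mask data must be logical")
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must have exactly 3 axes")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "all spacing components must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname canalmorph-classes
#' @export
setClass("LabelVolume",
  representation(data = "array", labelNames = "character",
                 spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must have exactly 3 axes")
    if (any(object@data < 0))
      msg <- c(msg, "labels must be non-negative integers")
    ids <- sort(unique(object@data[object@data > 0]))
    if (length(ids) && !all(as.character(ids) %in% names(object@labelNames)))
      msg <- c(msg, "every nonzero label id must appear in labelNames")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "all spacing components must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname canalmorph-classes
#' @export
setClass("ThicknessField",
  representation(values = "array", spacing = "numeric", origin = "numeric",
                 convention = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "values must have exactly 3 axes")
    if (!object@convention %in% c("radius", "diameter"))
      msg <- c(msg, "convention must be 'radius' or 'diameter'")
    if (any(object@values < 0))
      msg <- c(msg, "thickness values must be >= 0 (zero on background)")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "all spacing components must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname canalmorph-classes
#' @export
setClass("Skeleton",
  representation(data = "array", ltLabel = "array",
                 spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!is.logical(object@data) || length(dim(object@data)) != 3L)
      msg <- c(msg, "skeleton data must be a logical 3D array")
    if (length(object@ltLabel) &&
        !identical(dim(object@ltLabel), dim(object@data)))
      msg <- c(msg, "ltLabel must match the skeleton grid when set")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "all spacing components must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname canalmorph-classes
#' @slot nodes data.frame of node clusters: id, type
#'   ("junction"/"endpoint"/"isolated"), physical centroid (z, y, x in um)
#'   and voxel count.
#' @slot branches data.frame of branches: id, node ids at either end,
#'   number of slab voxels, path length (um), Euclidean end-to-end distance
#'   (um), ED/length ratio, mean and median local-thickness label (um) and
#'   a loop flag.
#' @slot paths list of integer matrices (one per branch) with the 1-based
#'   (z, y, x) indices of the branch path, terminal node voxels included.
#' @slot dim Integer grid dimensions of the source skeleton.
#' @aliases SkeletonGraph-class
#' @export
setClass("SkeletonGraph",
  representation(nodes = "data.frame", branches = "data.frame",
                 paths = "list", spacing = "numeric", origin = "numeric",
                 dim = "integer"))

#' Phantom specification and ground truth
#'
#' A `PhantomSpec` describes a branching-tube network in physical units:
#' one row per tube segment (straight, or a circular arc through a stored
#' via-point), with start/end coordinates and radii in micrometres, a label
#' id and the analytic arc length.  `voxelize()` renders it onto a voxel
#' grid and returns a `GroundTruth` carrying the exact expected topology
#' (branch/junction/endpoint counts, per-branch length, chord, tortuosity
#' and radius), the analytic tube volume and the noise-free occupancy grid.
#'
#' @slot segments data.frame with columns id, parent (0 = root), sz, sy,
#'   sx, ez, ey, ex (start/end, um), vz, vy, vx (arc via-point, NA when
#'   straight), r0Um, r1Um (radius ramp), lengthUm, label, labelName.
#' @slot grayscale Numeric length-3: foreground mean, background mean,
#'   additive Gaussian noise sigma (8-bit gray levels).
#' @slot seed Integer seed that fully determines the spec and rendering.
#'
#' @name phantom-classes
#' @aliases PhantomSpec-class GroundTruth-class
NULL

#' @rdname phantom-classes
#' @export
setClass("PhantomSpec",
  representation(segments = "data.frame", grayscale = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    s <- object@segments
    need <- c("id", "parent", "sz", "sy", "sx", "ez", "ey", "ex",
              "vz", "vy", "vx", "r0Um", "r1Um", "lengthUm", "label",
              "labelName")
    if (!all(need %in% names(s)))
      msg <- c(msg, paste("segments must have columns:",
                          paste(need, collapse = ", ")))
    else if (nrow(s) && any(s$r0Um <= 0 | s$r1Um <= 0))
      msg <- c(msg, "all radii must be > 0")
    if (length(object@grayscale) != 3L)
      msg <- c(msg, "grayscale must be (fgMean, bgMean, noiseSigma)")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname phantom-classes
#' @slot counts list with overall B, J, E and a per-label data.frame.
#' @slot branches data.frame: id, label, labelName, lengthUm, chordUm,
#'   tortuosity, radiusUm, axisLengthUm (expected medial-axis length after
#'   tip inset), terminal flag.
#' @slot volumeCm3 Analytic tube volume (sum of frustum volumes), cm^3.
#' @slot occupancy The noise-free `BinaryMask` ground-truth occupancy.
#' @export
setClass("GroundTruth",
  representation(counts = "list", branches = "data.frame",
                 volumeCm3 = "numeric", occupancy = "BinaryMask"))

#' Morphometry report
#'
#' Aggregates the pipeline's quantitative summaries: per-structure volumes
#' (cm^3), opening (skeleton endpoint) counts per substructure,
#' whole-organism extrapolation and scalar body morphometrics.
#'
#' @slot volumesCm3 Named numeric vector, structure -> volume in cm^3.
#' @slot openings Named numeric vector, structure/wing -> endpoint count.
#' @slot extrapolation list with innerTotal, outerTotal, nArms (or empty).
#' @slot scalars list of scalar morphometrics, e.g. apparentDiameterCm,
#'   adherenceRatio (or empty).
#' @slot notes Character vector of caveats attached by the pipeline.
#'
#' @aliases MorphometryReport-class
#' @export
setClass("MorphometryReport",
  representation(volumesCm3 = "numeric", openings = "numeric",
                 extrapolation = "list", scalars = "list",
                 notes = "character"))
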