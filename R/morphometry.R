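# Quantitative summaries: per-structure volumes, opening counts,
# whole-organism extrapolation and scalar body morphometrics.

#' Per-structure volumes from a label volume
#'
#' Volume of each labelled substructure as voxel count times physical
#' voxel volume, converted from cubic micrometres to cubic centimetres
#' (divide by 1e12).
#'
#' @param labels A [LabelVolume-class].
#' @return Named numeric vector of volumes in cm^3, one entry per label
#'   name plus `"total"` (all nonzero labels).
#' @examples
#' a <- array(0L, c(10, 10, 10)); a[1:10, , ] <- 1L
#' volumeByLabel(LabelVolume(a, c("1" = "umbrella"), spacing = 62))
#' @export
volumeByLabel <- function(labels) {
  stopifnot(is(labels, "LabelVolume"))
  vox <- prod(labels@spacing) / 1e12    # um^3 -> cm^3
  ids <- as.integer(names(labels@labelNames))
  counts <- vapply(ids, function(i) sum(labels@data == i), numeric(1))
  out <- stats::setNames(counts * vox, unname(labels@labelNames))
  c(total = sum(labels@data > 0L) * vox, out)
}

#' Opening (endpoint) counts per substructure
#'
#' Assigns every skeleton endpoint to the substructure label at its voxel.
#' Endpoints on background (label 0) are counted under `"unassigned"` with
#' a warning.  An endpoint of the pruned skeleton is the operational
#' equivalent of a canal aperture.
#'
#' @param graph A [SkeletonGraph-class].
#' @param labels A [LabelVolume-class] on the skeleton grid.
#' @return Named integer vector, label name -> endpoint count (zero
#'   entries included).
#' @export
endpointCountsByLabel <- function(graph, labels) {
  stopifnot(is(graph, "SkeletonGraph"), is(labels, "LabelVolume"))
  if (!identical(dim(labels@data), as.integer(graph@dim)))
    stop("labels grid does not match the skeleton graph")
  ep <- graph@nodes[graph@nodes$type == "endpoint", , drop = FALSE]
  vox <- cbind(round((ep$z - graph@origin[1]) / graph@spacing[1]) + 1,
               round((ep$y - graph@origin[2]) / graph@spacing[2]) + 1,
               round((ep$x - graph@origin[3]) / graph@spacing[3]) + 1)
  lab <- if (nrow(ep)) labels@data[vox] else integer(0)
  ids <- as.integer(names(labels@labelNames))
  out <- stats::setNames(
    vapply(ids, function(i) sum(lab == i), integer(1)),
    unname(labels@labelNames))
  if (any(lab == 0L)) {
    warning(sum(lab == 0L), " endpoint(s) fall on unlabelled voxels; ",
            "counted under 'unassigned'")
    out <- c(out, unassigned = sum(lab == 0L))
  }
  out
}

#' Extrapolate opening counts to the whole organism
#'
#' From per-arm wing counts measured on a single oral arm, extrapolates to
#' an organism with `nArms` arms:
#' `innerTotal = nArms * perArmInner + centralCanal` and
#' `outerTotal = nArms * sum(perArmOuter)`.
#'
#' @param perArmInner Endpoint count of the inner wing of one arm.
#' @param perArmOuter Integer vector of outer-wing endpoint counts of one
#'   arm.
#' @param centralCanal Endpoint count of the central canal (not
#'   replicated per arm).
#' @param nArms Number of arms; default 8.
#' @return list with `innerTotal`, `outerTotal`, `nArms`.
#' @examples
#' extrapolateOpenings(234, c(129, 128), 81)   # inner 1953, outer 2056
#' @export
extrapolateOpenings <- function(perArmInner, perArmOuter, centralCanal,
                                nArms = 8L) {
  vals <- c(perArmInner, perArmOuter, centralCanal)
  if (any(vals < 0) || any(vals != round(vals)))
    stop("counts must be non-negative integers")
  if (nArms < 1L) stop("nArms must be >= 1")
  list(innerTotal = as.integer(nArms * perArmInner + centralCanal),
       outerTotal = as.integer(nArms * sum(perArmOuter)),
       nArms = as.integer(nArms))
}

#' Apparent umbrella diameter of a hemispherical medusa
#'
#' For a medusa whose umbrella is practically a hemisphere, the functional
#' (flat-projected) diameter follows from the inter-rhopaliar arc length
#' RD as `AD = 2 * RD / pi`.
#'
#' @param realDiameter The real diameter RD (arc length over the
#'   exumbrellar surface), any length unit; must be > 0.
#' @return The apparent diameter AD in the same unit.
#' @examples
#' apparentDiameter(pi / 2)   # 1
#' @export
apparentDiameter <- function(realDiameter) {
  if (any(realDiameter <= 0)) stop("realDiameter must be > 0")
  2 * realDiameter / pi
}

#' Adherence ratio of a double hemi-canal
#'
#' Ratio of the medial adhering-stripe width to the total canal width in a
#' paired hemi-canal cross-section.
#'
#' @param stripeWidth Width of the adhering stripe (same unit as
#'   `canalTotalWidth`), in `[0, canalTotalWidth]`.
#' @param canalTotalWidth Total canal width, > 0.
#' @return The dimensionless ratio in `[0, 1]`.
#' @examples
#' adherenceRatio(3.5, 10)    # 0.35
#' @export
adherenceRatio <- function(stripeWidth, canalTotalWidth) {
  if (any(canalTotalWidth <= 0)) stop("canalTotalWidth must be > 0")
  if (any(stripeWidth < 0) || any(stripeWidth > canalTotalWidth))
    stop("stripeWidth must lie in [0, canalTotalWidth]")
  stripeWidth / canalTotalWidth
}

#' Assemble a morphometry report
#'
#' @param volumes Named numeric vector of volumes (cm^3) or NULL.
#' @param openings Named numeric vector of opening counts or NULL.
#' @param extrapolation list from [extrapolateOpenings()] or NULL.
#' @param scalars list of scalar morphometrics or NULL.
#' @param notes Character vector of caveats.
#' @return A [MorphometryReport-class].
#' @export
makeReport <- function(volumes = NULL, openings = NULL, extrapolation = NULL,
                       scalars = NULL, notes = character(0)) {
  new("MorphometryReport",
      volumesCm3 = volumes %||% stats::setNames(numeric(0), character(0)),
      openings = openings %||% stats::setNames(numeric(0), character(0)),
      extrapolation = extrapolation %||% list(),
      scalars = scalars %||% list(),
      notes = notes)
}

#' Write / read a morphometry report as JSON
#'
#' The JSON schema is versioned; sections that were not computed are
#' emitted as `null`, not omitted.
#'
#' @param report A [MorphometryReport-class].
#' @param path Output (input) JSON path.
#' @return `writeReport`: `path` invisibly; `readReport`: the report.
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "MorphometryReport"))
  asNull <- function(x) if (length(x)) as.list(x) else NULL
  obj <- list(
    schema_version = "1.0",
    volumes_cm3 = asNull(report@volumesCm3),
    openings = asNull(report@openings),
    extrapolation = if (length(report@extrapolation)) report@extrapolation else NULL,
    scalars = if (length(report@scalars)) report@scalars else NULL,
    notes = if (length(report@notes)) as.list(report@notes) else NULL)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) if (is.null(x)) NULL else
    stats::setNames(vapply(x, as.numeric, numeric(1)), names(x))
  makeReport(volumes = num(obj$volumes_cm3),
             openings = num(obj$openings),
             extrapolation = if (is.null(obj$extrapolation)) NULL else
               lapply(obj$extrapolation, function(v)
                 if (is.numeric(v)) as.integer(v) else v),
             scalars = obj$scalars,
             notes = if (is.null(obj$notes)) character(0) else
               unlist(obj$notes))
}
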