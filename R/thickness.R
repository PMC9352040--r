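# Local-thickness transform: per-voxel radius of the largest inscribed
# sphere containing the voxel.

#' Euclidean distance transform of a mask
#'
#' Physical-unit distance from each foreground voxel centre to the nearest
#' background voxel centre (anisotropic spacing respected; positions
#' outside the grid count as background).
#'
#' @param mask A [BinaryMask-class].
#' @return Numeric 3D array of distances in micrometres, zero on
#'   background.
#' @examples
#' m <- BinaryMask(array(TRUE, c(5, 5, 5)), spacing = 1)
#' distanceTransform(m)[3, 3, 3]    # centre is 3 voxels from outside
#' @export
distanceTransform <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  a <- mask@data
  sq <- cpp_edt_sq(as.vector(a), dim(a), mask@spacing, TRUE)
  array(sqrt(sq), dim(a))
}

#' Local-thickness transform
#'
#' For every foreground voxel v, computes
#' `LT(v) = max { r(c) : ||v - c|| <= r(c) + h }` over foreground voxels c,
#' where `r(c) = EDT(c) - h` is the inscribed-sphere radius at c (EDT being
#' the distance to the nearest background voxel centre and
#' `h = min(spacing)/2`; radii are measured to the voxel boundary, and a
#' sphere contains a voxel when it reaches within half a voxel of its
#' centre).  This
#' is the radius of the largest sphere fully inside the foreground that
#' contains v -- computed exactly by sphere propagation over descending
#' radius levels, not approximated by the EDT alone.  Anisotropic spacing
#' is handled by working in physical units (spheres become ellipsoids in
#' index space).
#'
#' @param x A [BinaryMask-class].
#' @param convention `"radius"` (default) or `"diameter"` (doubles the
#'   values).
#' @param maxLevels Cap on the number of distinct radius levels processed;
#'   when exceeded the level ladder is thinned, bounding the error by the
#'   largest gap between retained levels (well under one voxel in
#'   practice).
#' @param ... Unused.
#' @return A [ThicknessField-class] in micrometres, zero on background.
#' @examples
#' b <- ballMask(radiusVx = 5, spacingUm = 1)
#' lt <- localThickness(b)
#' range(voxelData(lt)[voxelData(b)])   # about the ball radius everywhere
#' @name localThickness
NULL

#' @rdname localThickness
#' @export
setMethod("localThickness", "BinaryMask",
          function(x, convention = c("radius", "diameter"),
                   maxLevels = 96L, ...) {
  convention <- match.arg(convention)
  a <- x@data
  lt <- cpp_local_thickness(as.vector(a), dim(a), x@spacing,
                            as.integer(maxLevels))
  v <- array(lt, dim(a))
  if (convention == "diameter") v <- v * 2
  new("ThicknessField", values = v, spacing = x@spacing, origin = x@origin,
      convention = convention)
})

#' Per-label local-thickness histogram
#'
#' Bins the foreground local-thickness values into equal-width bins
#' covering `[0, max(LT)]`, overall or per substructure label.
#'
#' @param field A [ThicknessField-class].
#' @param labels Optional [LabelVolume-class] on the same grid; when
#'   omitted all foreground voxels are pooled under label `"all"`.
#' @param binWidthUm Positive bin width in micrometres.
#' @return data.frame with columns `label`, `bin_lo_um`, `bin_hi_um`,
#'   `count`; every label gets a row for every bin (zero counts included).
#' @export
thicknessHistogram <- function(field, labels = NULL, binWidthUm) {
  stopifnot(is(field, "ThicknessField"))
  if (binWidthUm <= 0) stop("binWidthUm must be > 0")
  fg <- field@values > 0
  maxLt <- if (any(fg)) max(field@values) else binWidthUm
  nb <- max(1L, ceiling(maxLt / binWidthUm))
  lo <- (seq_len(nb) - 1) * binWidthUm
  labNames <- "all"
  labOf <- function(nm) fg
  if (!is.null(labels)) {
    stopifnot(is(labels, "LabelVolume"))
    if (!identical(dim(labels@data), dim(field@values)))
      stop("labels grid does not match the thickness field")
    labNames <- unname(labels@labelNames)
    ids <- as.integer(names(labels@labelNames))
    labOf <- function(nm) fg & (labels@data == ids[match(nm, labNames)])
  }
  out <- do.call(rbind, lapply(labNames, function(nm) {
    v <- field@values[labOf(nm)]
    bin <- pmin(pmax(floor(v / binWidthUm) + 1L, 1L), nb)
    data.frame(label = nm, bin_lo_um = lo, bin_hi_um = lo + binWidthUm,
               count = tabulate(bin, nbins = nb))
  }))
  rownames(out) <- NULL
  out
}

#' Maximum-likelihood lognormal fit
#'
#' Fits `Lognormal(mu, sigma)` by maximum likelihood (closed form on log
#' samples) and reports the Kolmogorov-Smirnov distance between the sample
#' and the fitted CDF as a descriptive goodness-of-fit measure (no
#' p-value).  Used for the canal-thickness distributions, which follow an
#' almost perfect lognormal trend in real endocasts.
#'
#' @param samples Numeric vector of at least 10 strictly positive values.
#' @return Named list: `mu`, `sigma` (log-scale parameters) and `ks`.
#'   Constant samples yield `sigma = 0` with the KS distance taken against
#'   the point mass.
#' @examples
#' x <- stats::rlnorm(1000, 0.5, 0.3)
#' fitLognormal(x)$mu
#' @export
fitLognormal <- function(samples) {
  if (length(samples) < 10L)
    stop("need at least 10 samples")
  if (any(!is.finite(samples)) || any(samples <= 0))
    stop("all samples must be strictly positive")
  lx <- log(samples)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  if (sigma == 0) {
    # all samples equal: the fitted point mass matches the empirical CDF
    return(list(mu = mu, sigma = 0, ks = 0))
  }
  xs <- sort(samples)
  n <- length(xs)
  cdf <- stats::plnorm(xs, mu, sigma)
  ks <- max(abs(seq_len(n) / n - cdf), abs(cdf - (seq_len(n) - 1) / n))
  list(mu = mu, sigma = sigma, ks = ks)
}
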