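# Otsu segmentation and connectivity-preserving smoothing.

#' Gray-level histogram with 256 bins
#'
#' Builds the full-volume grayscale frequency histogram used by Otsu
#' thresholding.  8-bit data get one bin per gray level (centres 0..255);
#' wider-range data are rebinned into 256 equal bins over the observed
#' range.
#'
#' @param x A [VoxelVolume-class] or numeric array.
#' @return A list of class `"Histogram256"` with `counts` (integer, length
#'   256) and `breaks` (numeric, length 257).
#' @examples
#' v <- VoxelVolume(array(c(30L, 200L), c(2, 2, 2)))
#' h <- grayHistogram(v)
#' sum(h$counts) == 8
#' @export
grayHistogram <- function(x) {
  a <- if (is(x, "VoxelVolume")) x@data else x
  v <- as.vector(a)
  rng <- range(v)
  if (rng[1] >= 0 && rng[2] <= 255 && all(v == round(v))) {
    breaks <- seq(-0.5, 255.5, by = 1)
    counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
  } else {
    breaks <- seq(rng[1], rng[2], length.out = 257)
    if (rng[1] == rng[2]) breaks <- rng[1] + seq(-0.5, 0.5, length.out = 257)
    bin <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), 256L)
    counts <- tabulate(bin, nbins = 256L)
  }
  structure(list(counts = as.integer(counts), breaks = breaks),
            class = "Histogram256")
}

#' Otsu threshold of a 256-bin histogram
#'
#' Returns the 0-based bin index `t` that maximizes the between-class
#' variance of the two classes `{bins <= t}` and `{bins > t}`.  Ties are
#' broken toward the lowest maximizing index, which makes the result
#' deterministic.
#'
#' @param hist A `"Histogram256"` from [grayHistogram()], or a plain
#'   numeric vector of 256 counts.
#' @return Integer bin index in `0..254` (for 8-bit data this is the gray
#'   level; foreground is strictly above it).
#' @examples
#' h <- integer(256); h[11] <- 100; h[201] <- 100   # peaks at levels 10, 200
#' otsuThreshold(h)
#' @export
otsuThreshold <- function(hist) {
  counts <- if (inherits(hist, "Histogram256")) hist$counts else as.numeric(hist)
  if (length(counts) != 256L)
    stop("expected 256 histogram bins")
  if (any(counts < 0))
    stop("histogram counts must be non-negative")
  if (sum(counts > 0) < 2L)
    stop("degenerate histogram: all mass in a single bin, no threshold exists")
  n <- sum(counts)
  lev <- 0:255
  w0 <- cumsum(counts)                 # class {<= t}, t = 0..255
  m0 <- cumsum(counts * lev)
  mT <- m0[256]
  t <- 0:254
  wb <- w0[t + 1]
  wf <- n - wb
  valid <- wb > 0 & wf > 0
  mu0 <- m0[t + 1] / wb
  mu1 <- (mT - m0[t + 1]) / wf
  bcv <- (wb / n) * (wf / n) * (mu0 - mu1)^2
  bcv[!valid] <- -Inf
  as.integer(t[which.max(bcv)])        # which.max takes the first (lowest) tie
}

#' Segment a grayscale volume by Otsu thresholding
#'
#' Thresholds the full-volume 256-bin histogram with [otsuThreshold()];
#' foreground is every voxel strictly above the threshold level.
#'
#' @param x A [VoxelVolume-class].
#' @param ... Unused.
#' @return A [BinaryMask-class] with the volume's spacing and origin.
#' @examples
#' a <- array(30L, c(4, 4, 8)); a[, , 5:8] <- 200L
#' m <- segmentVolume(VoxelVolume(a, spacing = 62))
#' sum(voxelData(m)) == 4 * 4 * 4
#' @name segmentVolume
NULL

#' @rdname segmentVolume
#' @export
setMethod("segmentVolume", "VoxelVolume", function(x, ...) {
  h <- grayHistogram(x)
  t <- otsuThreshold(h)
  cut <- h$breaks[t + 2]               # upper edge of bin t (0-based)
  BinaryMask(array(x@data > cut, dim(x@data)), x@spacing, x@origin)
})

#' Gaussian smoothing that preserves mask connectivity
#'
#' Blurs a binary mask with an isotropic Gaussian kernel (window
#' `kernelSizeVx` voxels per axis, sigma = `kernelSizeVx / 4`), then
#' re-thresholds at the highest level of a descending ladder for which the
#' number of 26-connected foreground components equals that of the input.
#' This suppresses surface roughness (and hence spurious skeleton
#' branches) without merging or splitting structures.  If no ladder level
#' preserves the component count, the 0.5 level is used and a warning is
#' issued.
#'
#' @param mask A [BinaryMask-class].
#' @param kernelSizeVx Odd kernel window in voxels (>= 3); default 5.
#' @param ladder Descending re-threshold levels to try.
#' @return A smoothed [BinaryMask-class] with unchanged 26-component count
#'   (unless a warning was issued).
#' @examples
#' m <- cylinderMask(radiusVx = 6, lengthVx = 20)
#' s <- smoothPreservingConnectivity(m)
#' connectedComponents(s)$sizes
#' @export
smoothPreservingConnectivity <- function(mask, kernelSizeVx = 5L,
                                         ladder = seq(0.5, 0.05, by = -0.05)) {
  stopifnot(is(mask, "BinaryMask"))
  kernelSizeVx <- as.integer(kernelSizeVx)
  if (kernelSizeVx < 3L || kernelSizeVx %% 2L == 0L)
    stop("kernelSizeVx must be odd and >= 3")
  a <- mask@data
  if (!any(a))
    return(mask)
  nc0 <- .countComponents(a, 26L)
  blur <- array(cpp_gauss3d(as.vector(a * 1.0), dim(a),
                            sigma = kernelSizeVx / 4, ksize = kernelSizeVx),
                dim(a))
  for (lev in ladder) {
    m2 <- blur >= lev
    if (any(m2) && .countComponents(m2, 26L) == nc0)
      return(BinaryMask(m2, mask@spacing, mask@origin))
  }
  warning("no re-threshold level preserved connectivity; using 0.5 ",
          "(component count changed)")
  BinaryMask(blur >= 0.5, mask@spacing, mask@origin)
}

.countComponents <- function(a, connectivity) {
  lab <- cpp_label_cc(as.vector(a), dim(a), as.integer(connectivity))
  max(lab)
}

#' Connected components of a binary mask
#'
#' Labels foreground components under 6-, 18- or 26-connectivity; labels
#' are numbered 1..K in decreasing component size (ties broken by scan
#' order).
#'
#' @param mask A [BinaryMask-class].
#' @param connectivity 6, 18 or 26 (default 26, the foreground convention
#'   paired with 6-connected background used throughout).
#' @return A list with `labels` (a [LabelVolume-class]) and `sizes`
#'   (integer voxel counts, one per component, decreasing).
#' @examples
#' a <- array(FALSE, c(3, 3, 3)); a[1, 1, 1] <- a[3, 3, 3] <- TRUE
#' connectedComponents(BinaryMask(a), connectivity = 6)$sizes
#' @export
connectedComponents <- function(mask, connectivity = 26L) {
  stopifnot(is(mask, "BinaryMask"))
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  lab <- cpp_label_cc(as.vector(mask@data), dim(mask@data),
                      as.integer(connectivity))
  k <- max(lab)
  if (k == 0L) {
    return(list(labels = LabelVolume(array(0L, dim(mask@data)),
                                     spacing = mask@spacing,
                                     origin = mask@origin),
                sizes = integer(0)))
  }
  sizes <- tabulate(lab, nbins = k)
  ord <- order(sizes, decreasing = TRUE)
  remap <- integer(k)
  remap[ord] <- seq_len(k)
  out <- array(0L, dim(mask@data))
  nz <- lab > 0L
  out[nz] <- remap[lab[nz]]
  nms <- stats::setNames(paste0("component_", seq_len(k)),
                         as.character(seq_len(k)))
  list(labels = LabelVolume(out, labelNames = nms, spacing = mask@spacing,
                            origin = mask@origin),
       sizes = sort(sizes, decreasing = TRUE))
}
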