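# Medial-axis extraction by homotopy-preserving thinning, pruning of short
# terminal branches, and thickness labelling.

#' Skeletonize a binary mask by 3D thinning
#'
#' Iteratively deletes (26,6) simple points -- border voxels whose removal
#' changes neither the foreground 26-topology nor the background
#' 6-topology -- in six directional sub-iterations (z-, z+, y-, y+, x-,
#' x+), re-checking simplicity at deletion time, until stable.  Curve
#' endpoints (voxels with at most one foreground 26-neighbour) are never
#' deleted, so tubes reduce to one-voxel-wide centrelines.  The fixed scan
#' order makes the result deterministic; homotopy preservation means
#' component and tunnel counts are unchanged.
#'
#' @param x A [BinaryMask-class].
#' @param ... Unused.
#' @return A [Skeleton-class] (every skeleton voxel lies inside the mask).
#' @examples
#' sk <- skeletonize(cylinderMask(radiusVx = 3, lengthVx = 30))
#' sum(voxelData(sk)) < sum(voxelData(cylinderMask(3, 30)))
#' @name skeletonize
NULL

#' @rdname skeletonize
#' @export
setMethod("skeletonize", "BinaryMask", function(x, ...) {
  thin <- cpp_thin(as.vector(x@data), dim(x@data))
  new("Skeleton", data = array(thin, dim(x@data)),
      ltLabel = array(numeric(0), c(0L, 0L, 0L)),
      spacing = x@spacing, origin = x@origin)
})

#' Euler characteristic of a voxel complex
#'
#' Computes V - E + F - C over the cubical complex spanned by the
#' foreground voxels (vertices, edges, faces, cubes).  For a connected
#' solid without cavities the number of tunnels is `1 - chi`; a solid ball
#' gives 1, a solid torus 0.  Used to verify that thinning preserves
#' topology.
#'
#' @param x A [BinaryMask-class], [Skeleton-class] or logical array.
#' @return Integer Euler characteristic.
#' @examples
#' eulerCharacteristic(ballMask(4))        # 1
#' eulerCharacteristic(torusMask(8, 3))    # 0
#' @export
eulerCharacteristic <- function(x) {
  a <- if (is.array(x)) x else voxelData(x)
  storage.mode(a) <- "logical"
  d <- dim(a)
  orShift <- function(offs) {
    acc <- array(FALSE, d + 1L)
    for (o in offs) {
      acc[(1:d[1]) + o[1], (1:d[2]) + o[2], (1:d[3]) + o[3]] <-
        acc[(1:d[1]) + o[1], (1:d[2]) + o[2], (1:d[3]) + o[3]] | a
    }
    sum(acc)
  }
  offs2 <- function(axes) {
    grid <- expand.grid(rep(list(0:1), length(axes)))
    lapply(seq_len(nrow(grid)), function(i) {
      o <- c(0L, 0L, 0L)
      o[axes] <- as.integer(grid[i, ])
      o
    })
  }
  C <- sum(a)
  V <- orShift(offs2(1:3))
  E <- orShift(offs2(2:3)) + orShift(offs2(c(1, 3))) + orShift(offs2(1:2))
  F <- orShift(offs2(1)) + orShift(offs2(2)) + orShift(offs2(3))
  as.integer(V - E + F - C)
}

#' Prune short terminal skeleton branches
#'
#' Per cycle, deletes every terminal branch (one end a curve endpoint, the
#' other a junction) whose length in voxels -- slab voxels plus the
#' endpoint voxel, the junction voxel excluded -- is at most
#' `minBranchVx`.  Junction voxels left with two or fewer neighbours are
#' reclassified on the next graph rebuild, which also merges the flanking
#' branches (their lengths summing), so the tree identity `B = E + J - 1`
#' is maintained.  Branches connecting two junctions are never deleted,
#' nor are isolated endpoint-to-endpoint paths or closed loops, so no
#' component is ever disconnected.  The default (4 voxels, 2 cycles)
#' removes discretization twigs while keeping the short branches at real
#' canal apertures.
#'
#' @param skel A [Skeleton-class].
#' @param minBranchVx Maximum twig length (voxels) to delete; default 4.
#' @param cycles Number of pruning passes; default 2.
#' @return The pruned [Skeleton-class].
#' @export
pruneSkeleton <- function(skel, minBranchVx = 4L, cycles = 2L) {
  stopifnot(is(skel, "Skeleton"))
  if (minBranchVx < 1L) stop("minBranchVx must be >= 1")
  m <- skel@data
  for (cy in seq_len(cycles)) {
    if (!any(m)) break
    g <- buildGraph(new("Skeleton", data = m,
                        ltLabel = array(numeric(0), c(0L, 0L, 0L)),
                        spacing = skel@spacing, origin = skel@origin),
                    lengthMethod = "steps")
    br <- g@branches
    if (!nrow(br)) break
    typeOf <- stats::setNames(g@nodes$type, g@nodes$id)
    removed <- FALSE
    for (i in seq_len(nrow(br))) {
      if (br$isLoop[i]) next
      t1 <- typeOf[as.character(br$node1[i])]
      t2 <- typeOf[as.character(br$node2[i])]
      oneEnd <- xor(t1 == "endpoint", t2 == "endpoint")
      if (!isTRUE(oneEnd)) next                 # keep junction-junction and
      if (!("junction" %in% c(t1, t2))) next    # endpoint-endpoint paths
      twigLen <- br$nSlab[i] + 1L               # slabs + endpoint voxel
      if (twigLen > minBranchVx) next
      path <- g@paths[[i]]
      drop <- if (t1 == "endpoint") seq_len(nrow(path) - 1L)
              else 2:nrow(path)                 # keep the junction voxel
      m[path[drop, , drop = FALSE]] <- FALSE
      removed <- TRUE
    }
    if (!removed) break
  }
  new("Skeleton", data = m, ltLabel = array(numeric(0), c(0L, 0L, 0L)),
      spacing = skel@spacing, origin = skel@origin)
}

#' Label a skeleton with local-thickness values
#'
#' Attaches to every skeleton voxel the local-thickness value at that
#' voxel, producing the thickness-labelled medial axis used for canal
#' calibre profiles.
#'
#' @param skel A [Skeleton-class].
#' @param lt A [ThicknessField-class] computed from the same mask the
#'   skeleton came from.
#' @return The skeleton with its `ltLabel` slot filled (values in um,
#'   positive at every skeleton voxel).
#' @export
labelWithThickness <- function(skel, lt) {
  stopifnot(is(skel, "Skeleton"), is(lt, "ThicknessField"))
  if (!identical(dim(skel@data), dim(lt@values)))
    stop("thickness field grid does not match the skeleton")
  if (any(skel@data & lt@values <= 0))
    stop("skeleton voxel outside the thickness-field foreground: ",
         "skeleton and thickness were not derived from the same mask")
  lab <- array(0, dim(skel@data))
  lab[skel@data] <- lt@values[skel@data]
  new("Skeleton", data = skel@data, ltLabel = lab,
      spacing = skel@spacing, origin = skel@origin)
}
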