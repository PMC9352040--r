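# Synthetic tubular-network phantoms with exact ground truth.
#
# Phantoms are specified in physical units (um) and voxelized afterwards,
# so spacing-convergence experiments are possible.  Curved segments are
# circular arcs: their tortuosity (chord / arc length) is analytic.

# ---- simple geometric masks (deterministic fixtures) -----------------------

.coordArrays <- function(d) {
  list(Z = array(rep(seq_len(d[1]), times = d[2] * d[3]), d),
       Y = array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d),
       X = array(rep(seq_len(d[3]), each = d[1] * d[2]), d))
}

#' Geometric test masks
#'
#' Digital solid ball, cylinder, torus and paired hemi-canal masks with
#' known topology, used as fixtures throughout the test suite and in
#' examples.  Foreground is every voxel whose centre lies within the
#' analytic solid (boundary inclusive).
#'
#' @param radiusVx,tubeRadiusVx Solid/tube radius in voxels.
#' @param lengthVx Cylinder length in voxel planes along the axis.
#' @param majorRadiusVx Torus centreline radius in voxels.
#' @param axis Cylinder axis: `"z"`, `"y"` or `"x"`.
#' @param gapVx Background gap (voxels) between the paired hemi-canals.
#' @param bridged Logical; bridge the two hemi-canals with a thin plate
#'   (one 26-connected component) or leave them separate (two).
#' @param spacingUm Isotropic voxel spacing in micrometres.
#' @param padVx Background padding around the solid.
#' @return A [BinaryMask-class].
#' @examples
#' sum(voxelData(ballMask(3)))
#' @name phantom-masks
NULL

#' @rdname phantom-masks
#' @export
ballMask <- function(radiusVx, spacingUm = 62, padVx = 2L) {
  n <- 2L * (radiusVx + padVx) + 1L
  d <- c(n, n, n)
  co <- .coordArrays(d)
  c0 <- radiusVx + padVx + 1L
  fg <- (co$Z - c0)^2 + (co$Y - c0)^2 + (co$X - c0)^2 <= radiusVx^2 + 1e-9
  BinaryMask(fg, spacing = spacingUm)
}

#' @rdname phantom-masks
#' @export
cylinderMask <- function(radiusVx, lengthVx, axis = "x", spacingUm = 62,
                         padVx = 2L) {
  nr <- 2L * (radiusVx + padVx) + 1L
  na <- lengthVx + 2L * padVx
  d <- switch(axis, z = c(na, nr, nr), y = c(nr, na, nr), x = c(nr, nr, na))
  co <- .coordArrays(d)
  c0 <- radiusVx + padVx + 1L
  ax <- switch(axis, z = co$Z, y = co$Y, x = co$X)
  p1 <- switch(axis, z = co$Y, y = co$Z, x = co$Z)
  p2 <- switch(axis, z = co$X, y = co$X, x = co$Y)
  fg <- (p1 - c0)^2 + (p2 - c0)^2 <= radiusVx^2 + 1e-9 &
        ax > padVx & ax <= padVx + lengthVx
  BinaryMask(fg, spacing = spacingUm)
}

#' @rdname phantom-masks
#' @export
torusMask <- function(majorRadiusVx, tubeRadiusVx, spacingUm = 62,
                      padVx = 2L) {
  ext <- majorRadiusVx + tubeRadiusVx + padVx
  nz <- 2L * (tubeRadiusVx + padVx) + 1L
  nyx <- 2L * ext + 1L
  d <- c(nz, nyx, nyx)
  co <- .coordArrays(d)
  cz <- tubeRadiusVx + padVx + 1L
  cyx <- ext + 1L
  rr <- sqrt((co$Y - cyx)^2 + (co$X - cyx)^2)
  fg <- (rr - majorRadiusVx)^2 + (co$Z - cz)^2 <= tubeRadiusVx^2 + 1e-9
  BinaryMask(fg, spacing = spacingUm)
}

#' @rdname phantom-masks
#' @export
hemiCanalMask <- function(radiusVx = 4L, lengthVx = 30L, gapVx = 1L,
                          bridged = FALSE, spacingUm = 62, padVx = 2L) {
  sep <- 2L * radiusVx + 1L + gapVx     # centre-to-centre separation (y)
  nz <- 2L * (radiusVx + padVx) + 1L
  ny <- sep + 2L * (radiusVx + padVx) + 1L
  nx <- lengthVx + 2L * padVx
  d <- c(nz, ny, nx)
  co <- .coordArrays(d)
  cz <- radiusVx + padVx + 1L
  cy1 <- radiusVx + padVx + 1L
  cy2 <- cy1 + sep
  inx <- co$X > padVx & co$X <= padVx + lengthVx
  fg <- inx & (((co$Y - cy1)^2 + (co$Z - cz)^2 <= radiusVx^2 + 1e-9) |
               ((co$Y - cy2)^2 + (co$Z - cz)^2 <= radiusVx^2 + 1e-9))
  if (bridged) {
    fg <- fg | (inx & co$Z == cz & co$Y > cy1 & co$Y < cy2)
  }
  BinaryMask(fg, spacing = spacingUm)
}

# ---- segment-row constructors ---------------------------------------------

.segRow <- function(id, parent, s, e, v, r0, r1, len, label, labelName) {
  data.frame(id = id, parent = parent,
             sz = s[1], sy = s[2], sx = s[3],
             ez = e[1], ey = e[2], ex = e[3],
             vz = v[1], vy = v[2], vx = v[3],
             r0Um = r0, r1Um = r1, lengthUm = len,
             label = label, labelName = labelName,
             stringsAsFactors = FALSE)
}

#' Build phantom segments by hand
#'
#' Row constructors for [PhantomSpec-class] segment tables, for fixtures
#' whose geometry must be exact (straight tubes, tapering cones, quarter
#' circles).  Coordinates are (z, y, x) in micrometres.
#'
#' @param start,end Numeric length-3 start/end points (um).
#' @param via For `arcSegment`, a third point on the circular arc (um).
#' @param radiusUm Tube radius (um); `radiusEndUm` enables a linear ramp.
#' @param id,parent Segment id and parent id (0 = root).
#' @param label,labelName Substructure label id and name.
#' @return A one-row segments data.frame.
#' @examples
#' seg <- straightSegment(c(0, 0, 0), c(0, 0, 3100), radiusUm = 250)
#' ph <- PhantomSpec(seg)
#' @name phantom-segments
NULL

#' @rdname phantom-segments
#' @export
straightSegment <- function(start, end, radiusUm, radiusEndUm = radiusUm,
                            id = 1L, parent = 0L, label = 1L,
                            labelName = "tube") {
  .segRow(id, parent, start, end, c(NA_real_, NA_real_, NA_real_),
          radiusUm, radiusEndUm, sqrt(sum((end - start)^2)), label, labelName)
}

#' @rdname phantom-segments
#' @export
arcSegment <- function(start, end, via, radiusUm, radiusEndUm = radiusUm,
                       id = 1L, parent = 0L, label = 1L, labelName = "tube") {
  pts <- .arcPoints(start, end, via, step = sqrt(sum((end - start)^2)) / 256)
  len <- .pathLength(pts)
  .segRow(id, parent, start, end, via, radiusUm, radiusEndUm, len,
          label, labelName)
}

#' @rdname phantom-classes
#' @param segments Segments data.frame (see [straightSegment()]).
#' @param grayscale Numeric (fgMean, bgMean, noiseSigma) gray levels.
#' @param seed Integer seed.
#' @export
PhantomSpec <- function(segments, grayscale = c(200, 30, 10), seed = 1L) {
  new("PhantomSpec", segments = segments, grayscale = as.numeric(grayscale),
      seed = as.integer(seed))
}

# ---- arc geometry ----------------------------------------------------------

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) v / sqrt(sum(v^2))

# points along a circular arc through (s, v, e), spaced <= step
.arcPoints <- function(s, e, v, step) {
  if (any(is.na(v))) {
    L <- sqrt(sum((e - s)^2))
    n <- max(2L, as.integer(ceiling(L / step)) + 1L)
    t <- seq(0, 1, length.out = n)
    return(cbind(s[1] + t * (e[1] - s[1]),
                 s[2] + t * (e[2] - s[2]),
                 s[3] + t * (e[3] - s[3])))
  }
  u1 <- v - s
  u2 <- e - s
  e1 <- .unit(u1)
  w <- u2 - sum(u2 * e1) * e1
  e2 <- .unit(w)
  b1 <- sqrt(sum(u1^2))                  # via  = (b1, 0) in plane coords
  c1 <- sum(u2 * e1)                     # end  = (c1, c2)
  c2 <- sum(u2 * e2)
  ox <- b1 / 2
  oy <- (c1^2 + c2^2 - c1 * b1) / (2 * c2)
  R <- sqrt(ox^2 + oy^2)
  ang <- function(p1, p2) atan2(p2 - oy, p1 - ox)
  aS <- ang(0, 0); aV <- ang(b1, 0); aE <- ang(c1, c2)
  dV <- (aV - aS) %% (2 * pi)
  dE <- (aE - aS) %% (2 * pi)
  if (dV > dE) {                         # go clockwise instead
    dE <- 2 * pi - dE
    dirn <- -1
  } else dirn <- 1
  arc <- R * dE
  n <- max(3L, as.integer(ceiling(arc / step)) + 1L)
  phi <- aS + dirn * seq(0, dE, length.out = n)
  px <- ox + R * cos(phi)
  py <- oy + R * sin(phi)
  cbind(s[1] + px * e1[1] + py * e2[1],
        s[2] + px * e1[2] + py * e2[2],
        s[3] + px * e1[3] + py * e2[3])
}

# half-angle of a circular arc with chord/arc ratio tau: sin(t)/t = tau
.arcHalfAngle <- function(tau) {
  if (tau >= 1) return(0)
  uniroot(function(t) sin(t) / t - tau, c(1e-8, pi - 1e-8), tol = 1e-12)$root
}

# build one arc (or straight) segment from start, unit direction, arc
# length and tortuosity; perp is a unit vector orthogonal to dir giving
# the bulge plane.  Returns list(end, via, tangentEnd).
.layoutSegment <- function(start, dir, lenUm, tau, perp) {
  if (tau >= 0.999) {
    return(list(end = start + lenUm * dir, via = c(NA_real_, NA_real_, NA_real_),
                tangentEnd = dir))
  }
  theta <- .arcHalfAngle(tau)
  chord <- tau * lenUm
  R <- chord / (2 * sin(theta))
  sag <- R * (1 - cos(theta))
  end <- start + chord * dir
  via <- start + (chord / 2) * dir + sag * perp
  # end tangent: chord direction rotated by +theta toward the bulge side
  tangentEnd <- .unit(cos(theta) * dir - sin(theta) * perp)
  list(end = end, via = via, tangentEnd = tangentEnd)
}

# minimum distance between two point sets, restricted to pairs allowed by
# arc-distance exclusions near a shared junction
.minPairDist <- function(P, cumP, Q, cumQ, exclP, exclQ) {
  selP <- cumP > exclP
  selQ <- cumQ > exclQ
  if (!any(selP) || !any(selQ)) return(Inf)
  A <- P[selP, , drop = FALSE]
  B <- Q[selQ, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Sample a random branching-tube tree specification
#'
#' Draws a bifurcating tree of `nLevels` levels (a full binary tree:
#' `2^nLevels - 1` segments).  Branch arc lengths and radii are lognormal;
#' each branch is a circular arc whose chord/arc ratio equals
#' `tortuosity` (1 = straight), with a random bulge plane.  Children leave
#' their parent's end tangent at `branchAngleDeg` (plus jitter) on
#' opposite azimuths.  Segment placements are rejection-sampled so that no
#' two non-adjacent tubes come closer than the sum of their radii plus
#' `clearanceUm`, which keeps the voxelized topology equal to the declared
#' tree.  Identical seeds give identical specs.
#'
#' @param nLevels Tree depth (>= 1).
#' @param lengthMedianMm Median branch arc length (lognormal), mm.
#' @param lengthSdLog Log-scale sd of branch length.
#' @param radiusMedianUm Median tube radius (lognormal), um.
#' @param radiusSdLog Log-scale sd of tube radius.
#' @param radiusMinUm Floor on sampled radii (um), so every tube stays
#'   resolvable (about 2 voxels at the default 62 um scan scale).
#' @param tortuosity Target chord/arc ratio in (0.6, 1].
#' @param branchAngleDeg Mean angle between a child and its parent's end
#'   tangent, degrees.
#' @param grayscale (fgMean, bgMean, noiseSigma) rendering levels.
#' @param seed Integer seed.
#' @param clearanceUm Extra clearance between non-adjacent tube surfaces
#'   (um); generous enough that smoothing cannot bridge neighbouring tubes.
#' @param maxTries Rejection-sampling attempts per segment.
#' @return A [PhantomSpec-class].
#' @examples
#' sp <- sampleTreeSpec(nLevels = 2, seed = 1)
#' nrow(sp@segments)    # 3 segments
#' @export
sampleTreeSpec <- function(nLevels = 3L, lengthMedianMm = 2.36,
                           lengthSdLog = 0.25, radiusMedianUm = 200,
                           radiusSdLog = 0.2, radiusMinUm = 130,
                           tortuosity = 0.8,
                           branchAngleDeg = 45,
                           grayscale = c(200, 30, 10), seed = 1L,
                           clearanceUm = 250, maxTries = 200L) {
  if (!(tortuosity > 0.6 && tortuosity <= 1))
    stop("tortuosity must lie in (0.6, 1]")
  if (nLevels < 1L) stop("nLevels must be >= 1")
  # rejection sampling over whole trees: if a segment cannot be placed,
  # the tree is redrawn from a seed-derived stream, so the result is still
  # a deterministic function of `seed`
  for (attempt in 0:4) {
    out <- tryCatch(
      .sampleTreeOnce(nLevels, lengthMedianMm, lengthSdLog, radiusMedianUm,
                      radiusSdLog, radiusMinUm, tortuosity, branchAngleDeg,
                      grayscale, seed,
                      (seed %% 1000003L) + attempt * 1000003L,
                      clearanceUm, maxTries),
      error = function(e)
        if (attempt < 4 && grepl("could not place", conditionMessage(e)))
          NULL else stop(e))
    if (!is.null(out)) return(out)
  }
}

.sampleTreeOnce <- function(nLevels, lengthMedianMm, lengthSdLog,
                            radiusMedianUm, radiusSdLog, radiusMinUm,
                            tortuosity, branchAngleDeg, grayscale, seed,
                            streamSeed, clearanceUm, maxTries) {
  withSeed(streamSeed, {
    segs <- list()
    geom <- list()                       # per segment: pts, cum, r, parent
    perpOf <- function(d) {              # random unit vector orthogonal to d
      repeat {
        v <- rnorm(3)
        w <- v - sum(v * d) * d
        if (sqrt(sum(w^2)) > 1e-6) return(.unit(w))
      }
    }
    # radii are drawn iid lognormal for the whole tree, then assigned in
    # level order (thickest proximal): the pooled radius distribution stays
    # exactly lognormal while junctions taper realistically, which keeps
    # the medial-axis topology equal to the declared tree.  A floor keeps
    # every tube resolvable (>~ 2 voxels at the default scan scale).
    nSeg <- 2L^nLevels - 1L
    radPool <- pmax(sort(rlnorm(nSeg, log(radiusMedianUm), radiusSdLog),
                         decreasing = TRUE), radiusMinUm)
    lenPool <- rlnorm(nSeg, log(lengthMedianMm * 1000), lengthSdLog)
    place <- function(id, start, dir0, parent) {
      lenUm <- lenPool[id]
      r <- radPool[id]
      for (tries in seq_len(maxTries)) {
        dir <- dir0
        if (tries > 1L && parent > 0L) { # re-jitter direction on retries,
          ax <- perpOf(dir0)             # opening the cone as tries mount
          ja <- runif(1, 0, min(80, 10 + tries)) * pi / 180
          dir <- .unit(cos(ja) * dir0 + sin(ja) * ax)
        }
        lay <- .layoutSegment(start, dir, lenUm, tortuosity, perpOf(dir))
        pts <- .arcPoints(start, lay$end, lay$via, step = 40)
        cum <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
        ok <- TRUE
        for (j in seq_along(geom)) {
          g <- geom[[j]]
          # allowed overlap near a shared node, capped so short segments
          # still get checked over most of their extent
          excl <- min(2.5 * (r + g$r), 0.35 * lenUm, 0.35 * max(g$cum))
          dmin <- if (j == parent)
            .minPairDist(pts, cum, g$pts, max(g$cum) - g$cum, excl, excl)
          else if (sqrt(sum((g$s0 - start)^2)) < 1e-6)   # sibling
            .minPairDist(pts, cum, g$pts, g$cum, excl, excl)
          else
            .minPairDist(pts, cum, g$pts, g$cum, -Inf, -Inf)
          if (dmin < r + g$r + clearanceUm) { ok <- FALSE; break }
        }
        if (ok)
          return(list(end = lay$end, via = lay$via, tan = lay$tangentEnd,
                      r = r, len = lenUm, pts = pts, cum = cum))
      }
      stop("could not place a tube segment without collisions; ",
           "reduce nLevels, branch angle or tortuosity")
    }
    queue <- list(list(start = c(0, 0, 0), dir = c(0, 0, 1), parent = 0L,
                       level = 1L))
    while (length(queue)) {
      item <- queue[[1]]
      queue <- queue[-1]
      id <- length(segs) + 1L
      pl <- place(id, item$start, item$dir, item$parent)
      segs[[id]] <- .segRow(id, item$parent, item$start, pl$end, pl$via,
                            pl$r, pl$r, pl$len, 1L, "tree")
      geom[[id]] <- list(pts = pl$pts, cum = pl$cum, r = pl$r,
                         s0 = item$start)
      if (item$level < nLevels) {
        alpha <- (branchAngleDeg + runif(2, -5, 5)) * pi / 180
        p1 <- perpOf(pl$tan)
        p2 <- .unit(.cross3(pl$tan, p1))
        phi0 <- runif(1, 0, 2 * pi)
        for (k in 1:2) {
          phi <- phi0 + (k - 1) * pi
          cd <- .unit(cos(alpha[k]) * pl$tan +
                      sin(alpha[k]) * (cos(phi) * p1 + sin(phi) * p2))
          queue <- c(queue, list(list(start = pl$end, dir = cd, parent = id,
                                      level = item$level + 1L)))
        }
      }
    }
    PhantomSpec(do.call(rbind, segs), grayscale = grayscale, seed = seed)
  })
}

# ---- voxelization ----------------------------------------------------------

.rasterizeSegment <- function(occ, lab, seg, spacing, origin, dims,
                              sphereStart = FALSE, sphereEnd = FALSE) {
  s <- c(seg$sz, seg$sy, seg$sx)
  e <- c(seg$ez, seg$ey, seg$ex)
  v <- c(seg$vz, seg$vy, seg$vx)
  rmax <- max(seg$r0Um, seg$r1Um)
  pts <- .arcPoints(s, e, v, step = max(min(spacing) * 0.75, rmax / 4))
  cum <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  total <- max(cum[length(cum)], 1e-9)
  pad <- rmax + 2 * max(spacing)
  loIdx <- pmax(floor((apply(pts, 2, min) - pad - origin) / spacing) + 1, 1)
  hiIdx <- pmin(ceiling((apply(pts, 2, max) + pad - origin) / spacing) + 1,
                dims)
  rng <- lapply(1:3, function(a) seq.int(loIdx[a], hiIdx[a]))
  d <- vapply(rng, length, integer(1))
  co <- .coordArrays(d)
  Z <- origin[1] + (rng[[1]][co$Z] - 1) * spacing[1]
  Y <- origin[2] + (rng[[2]][co$Y] - 1) * spacing[2]
  X <- origin[3] + (rng[[3]][co$X] - 1) * spacing[3]
  inside <- array(FALSE, d)
  for (j in seq_len(nrow(pts) - 1L)) {
    a <- pts[j, ]; b <- pts[j + 1L, ]
    vv <- b - a
    L2 <- sum(vv^2)
    if (L2 == 0) next
    t <- ((Z - a[1]) * vv[1] + (Y - a[2]) * vv[2] + (X - a[3]) * vv[3]) / L2
    d2 <- (Z - a[1] - t * vv[1])^2 + (Y - a[2] - t * vv[2])^2 +
          (X - a[3] - t * vv[3])^2
    rt <- seg$r0Um + ((cum[j] + t * sqrt(L2)) / total) * (seg$r1Um - seg$r0Um)
    inside <- inside | (t >= 0 & t <= 1 & d2 <= rt^2 * (1 + 1e-12) + 1e-6)
  }
  # inscribed spheres at interior polyline joints (and at shared junction
  # points) fill the wedge gaps between flat-capped slabs without adding
  # volume outside the true tube
  jsel <- seq_len(nrow(pts))
  if (!sphereStart) jsel <- jsel[jsel != 1L]
  if (!sphereEnd) jsel <- jsel[jsel != nrow(pts)]
  for (j in jsel) {
    p <- pts[j, ]
    rj <- seg$r0Um + (cum[j] / total) * (seg$r1Um - seg$r0Um)
    inside <- inside | ((Z - p[1])^2 + (Y - p[2])^2 + (X - p[3])^2 <=
                          rj^2 * (1 + 1e-12) + 1e-6)
  }
  # free ends are flat-capped: clip everything beyond the terminal planes
  n <- nrow(pts)
  if (!sphereStart) {
    u <- pts[2, ] - pts[1, ]
    proj <- (Z - pts[1, 1]) * u[1] + (Y - pts[1, 2]) * u[2] +
            (X - pts[1, 3]) * u[3]
    inside <- inside & proj >= 0
  }
  if (!sphereEnd) {
    u <- pts[n, ] - pts[n - 1, ]
    proj <- (Z - pts[n, 1]) * u[1] + (Y - pts[n, 2]) * u[2] +
            (X - pts[n, 3]) * u[3]
    inside <- inside & proj <= 0
  }
  sub <- occ[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  occ[rng[[1]], rng[[2]], rng[[3]]] <- sub | inside
  labSub <- lab[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  labSub[inside & labSub == 0L] <- seg$label
  lab[rng[[1]], rng[[2]], rng[[3]]] <- labSub
  list(occ = occ, lab = lab)
}

#' Voxelize a phantom specification
#'
#' Renders a [PhantomSpec-class] onto a voxel grid: foreground is the
#' union of tube neighbourhoods (distance to the centreline at most the
#' local radius, flat end caps), gray levels are the declared
#' foreground/background means plus Gaussian noise, and the returned
#' [GroundTruth-class] carries the analytic branch lengths, chords,
#' tortuosities, radii, topology counts and the noise-free occupancy.
#'
#' @param spec A [PhantomSpec-class].
#' @param spacingUm Voxel spacing in um (scalar or (dz, dy, dx)).
#' @param marginVx Background margin around the bounding box, voxels.
#' @param maxVoxels Voxel budget; exceeding it is an error (see
#'   [makeArmPhantom()] for auto-coarsening).
#' @param noise Render Gaussian gray noise (seeded from the spec seed)?
#' @return list with `volume` ([VoxelVolume-class], 8-bit levels),
#'   `labels` ([LabelVolume-class]) and `truth` ([GroundTruth-class]).
#' @examples
#' ph <- voxelize(PhantomSpec(straightSegment(c(0, 0, 0), c(0, 0, 3100),
#'                                            radiusUm = 250)))
#' ph$truth@volumeCm3
#' @export
voxelize <- function(spec, spacingUm = 62, marginVx = 4L,
                     maxVoxels = 512^3, noise = TRUE) {
  stopifnot(is(spec, "PhantomSpec"))
  spacing <- .assertSpacing(spacingUm)
  segs <- spec@segments
  allPts <- do.call(rbind, lapply(seq_len(nrow(segs)), function(i) {
    s <- segs[i, ]
    .arcPoints(c(s$sz, s$sy, s$sx), c(s$ez, s$ey, s$ex),
               c(s$vz, s$vy, s$vx), step = max(min(spacing), s$r0Um / 2))
  }))
  rmax <- max(segs$r0Um, segs$r1Um)
  ptsMin <- apply(allPts, 2, min)
  # snap the origin to the lattice through the phantom's bounding-box
  # corner, so axis-aligned tubes are sampled symmetrically
  lo <- ptsMin - spacing * ceiling((rmax + marginVx * spacing) / spacing)
  hi <- apply(allPts, 2, max) + rmax + marginVx * spacing
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  if (prod(as.numeric(dims)) > maxVoxels)
    stop("voxel budget exceeded: grid ", paste(dims, collapse = "x"),
         " needs ", prod(as.numeric(dims)), " > ", maxVoxels, " voxels")
  origin <- lo
  occ <- array(FALSE, dims)
  lab <- array(0L, dims)
  hasChild <- segs$id %in% segs$parent
  for (i in seq_len(nrow(segs))) {
    res <- .rasterizeSegment(occ, lab, segs[i, ], spacing, origin, dims,
                             sphereStart = segs$parent[i] > 0L,
                             sphereEnd = hasChild[i])
    occ <- res$occ
    lab <- res$lab
  }
  gs <- spec@grayscale
  vol <- gs[2] + (gs[1] - gs[2]) * occ
  if (noise && gs[3] > 0) {
    vol <- vol + withSeed(spec@seed + 7777L,
                          array(rnorm(length(vol), 0, gs[3]), dims))
  }
  vol <- array(as.integer(pmin(pmax(round(vol), 0), 255)), dims)

  isParent <- segs$id %in% segs$parent
  isLeaf <- !isParent
  isRoot <- segs$parent == 0L
  chord <- sqrt((segs$ez - segs$sz)^2 + (segs$ey - segs$sy)^2 +
                (segs$ex - segs$sx)^2)
  rbar <- (segs$r0Um + segs$r1Um) / 2
  truthBranches <- data.frame(
    id = segs$id, label = segs$label, labelName = segs$labelName,
    lengthUm = segs$lengthUm, chordUm = chord,
    tortuosity = chord / segs$lengthUm, radiusUm = rbar,
    axisLengthUm = segs$lengthUm - segs$r0Um * isRoot - segs$r1Um * isLeaf,
    terminal = isLeaf | isRoot)
  J <- length(unique(segs$parent[segs$parent > 0L]))
  E <- sum(isLeaf) + 1L
  labTab <- unique(segs[, c("label", "labelName")])
  perLabel <- do.call(rbind, lapply(seq_len(nrow(labTab)), function(k) {
    sel <- segs$label == labTab$label[k]
    data.frame(label = labTab$label[k], labelName = labTab$labelName[k],
               B = sum(sel),
               E = sum(isLeaf & sel) + as.integer(any(isRoot & sel)))
  }))
  nms <- stats::setNames(labTab$labelName, as.character(labTab$label))
  list(volume = VoxelVolume(vol, spacing, origin),
       labels = LabelVolume(lab, labelNames = nms, spacing = spacing,
                            origin = origin),
       truth = new("GroundTruth",
                   counts = list(B = nrow(segs), J = J, E = E,
                                 perLabel = perLabel),
                   branches = truthBranches,
                   volumeCm3 = sum(pi / 3 * segs$lengthUm *
                                   (segs$r0Um^2 + segs$r0Um * segs$r1Um +
                                    segs$r1Um^2)) / 1e12,
                   occupancy = BinaryMask(occ, spacing, origin)))
}

# ---- labelled oral-arm phantom --------------------------------------------

#' Labelled oral-arm phantom
#'
#' Builds a stylized single-arm phantom: a central canal bearing lateral
#' branchlets plus three labelled "wings" (combs of terminal tubes), with
#' ground-truth opening counts equal to the requested values.  The canal's
#' proximal opening counts toward `centralCanalEndpoints` (the canal opens
#' to the stomach).  If the requested counts exceed the voxel budget at
#' the given spacing, the spacing is doubled until the grid fits, with a
#' warning.
#'
#' @param wingCounts Integer (inner, outer1, outer2) terminal-opening
#'   counts, each >= 1.
#' @param centralCanalEndpoints Central-canal opening count (>= 2: the
#'   proximal opening plus at least the distal tip).
#' @param seed Integer seed (rendering noise).
#' @param spacingUm Isotropic voxel spacing, um.
#' @param maxVoxels Voxel budget before auto-coarsening.
#' @param noise Render gray noise?
#' @return As [voxelize()]: list(volume, labels, truth).
#' @examples
#' ph <- makeArmPhantom(c(4, 3, 3), 2, seed = 1)
#' ph$truth@counts$perLabel
#' @export
makeArmPhantom <- function(wingCounts = c(12L, 7L, 7L),
                           centralCanalEndpoints = 4L, seed = 1L,
                           spacingUm = 62, maxVoxels = 2^24, noise = TRUE) {
  if (length(wingCounts) != 3L || any(wingCounts < 1L))
    stop("wingCounts must be three counts >= 1")
  if (centralCanalEndpoints < 2L)
    stop("centralCanalEndpoints must be >= 2")
  u <- spacingUm
  rc <- 3 * u; rw <- 2.5 * u; rt <- 2 * u
  pitchC <- 15 * u; pitchW <- 8 * u
  toothLen <- 12 * u; latLen <- 10 * u
  nLat <- centralCanalEndpoints - 2L
  wingNames <- c("wing_inner", "wing_outer_1", "wing_outer_2")
  wingDirs <- list(c(0, 1, 0), c(0, -1, 0), c(1, 0, 0))     # +y, -y, +z
  toothDirs <- list(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0))     # z, z, y

  segs <- list()
  nid <- 0L
  add <- function(parent, s, e, r, label, labelName) {
    nid <<- nid + 1L
    segs[[nid]] <<- .segRow(nid, parent, s, e,
                            c(NA_real_, NA_real_, NA_real_), r, r,
                            sqrt(sum((e - s)^2)), label, labelName)
    nid
  }
  # attachment slots along the canal: wings first, then laterals
  nAttach <- 3L + nLat
  slotX <- pitchC * seq_len(nAttach)
  canalLen <- slotX[nAttach] + 20 * u
  # canal pieces chained through the attachment points
  xs <- c(0, slotX, canalLen)
  prev <- 0L
  attachParent <- integer(nAttach)
  for (k in seq_len(length(xs) - 1L)) {
    prev <- add(prev, c(0, 0, xs[k]), c(0, 0, xs[k + 1]), rc, 1L,
                "central_canal")
    if (k <= nAttach) attachParent[k] <- prev
  }
  # canal lateral branchlets (alternating +/- z) on the later slots
  if (nLat > 0L) {
    for (j in seq_len(nLat)) {
      dirz <- if (j %% 2L == 1L) 1 else -1
      s <- c(0, 0, slotX[3L + j])
      add(attachParent[3L + j], s, s + c(dirz * latLen, 0, 0), rt, 1L,
          "central_canal")
    }
  }
  # wings: comb of terminal tubes on a trunk
  for (w in 1:3) {
    N <- wingCounts[w]
    wd <- wingDirs[[w]]
    td <- toothDirs[[w]]
    base <- c(0, 0, slotX[w])
    nTeeth <- N - 1L
    slots <- 10 * u + pitchW * (seq_len(nTeeth + 1L) - 1L)
    trunkLen <- slots[nTeeth + 1L]
    prevW <- attachParent[w]
    pos <- 0
    for (j in seq_len(nTeeth)) {
      prevW <- add(prevW, base + pos * wd, base + slots[j] * wd, rw,
                   w + 1L, wingNames[w])
      pos <- slots[j]
      dirt <- if (j %% 2L == 1L) 1 else -1
      s <- base + pos * wd
      add(prevW, s, s + dirt * toothLen * td, rt, w + 1L, wingNames[w])
    }
    add(prevW, base + pos * wd, base + trunkLen * wd, rw, w + 1L,
        wingNames[w])
  }
  spec <- PhantomSpec(do.call(rbind, segs), seed = seed)
  sp <- spacingUm
  repeat {
    out <- tryCatch(voxelize(spec, spacingUm = sp, maxVoxels = maxVoxels,
                             noise = noise),
                    error = function(e)
                      if (grepl("voxel budget", conditionMessage(e))) NULL
                      else stop(e))
    if (!is.null(out)) break
    sp <- sp * 2
    warning("voxel budget exceeded; auto-coarsening spacing to ", sp, " um")
  }
  out
}
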