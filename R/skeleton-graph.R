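# Decomposition of a one-voxel-wide skeleton into junctions, endpoints and
# branches, with per-branch length, Euclidean distance and tortuosity.

# Gaussian-smooth an n x 3 physical path, endpoints clamped.  Raw 26-step
# sums overestimate oblique digital paths by up to ~8%; smoothing the voxel
# polyline before summing steps removes the staircase bias while keeping
# path length >= endpoint chord (so ED/L <= 1 always holds).
.smoothPath <- function(P, sigmaVx) {
  n <- nrow(P)
  if (n < 5L || sigmaVx <= 0) return(P)
  h <- max(1L, as.integer(ceiling(2.5 * sigmaVx)))
  w <- dnorm(seq(-h, h), sd = sigmaVx)
  w <- w / sum(w)
  Q <- P
  for (j in 1:3) {
    v <- c(rep(P[1, j], h), P[, j], rep(P[n, j], h))
    sm <- stats::filter(v, w, sides = 2)
    Q[, j] <- as.numeric(sm)[(h + 1):(h + n)]
  }
  Q[1, ] <- P[1, ]
  Q[n, ] <- P[n, ]
  Q
}

.pathLength <- function(P) {
  if (nrow(P) < 2L) return(0)
  d <- diff(P)
  sum(sqrt(rowSums(d^2)))
}

# raw branch tracing over a fixed node decomposition.
# adj: adjacency list; nodeOf: node id per voxel (NA = slab);
# nodeType/nodeMembers: per node.  Returns list of raw branches
# (node1, node2, pathIds, isLoop).
.traceBranches <- function(adj, nodeOf, nodeType, nodeMembers, deg) {
  n <- length(adj)
  branches <- list()
  visited <- logical(n)
  push <- function(n1, n2, pathIds, isLoop) {
    branches[[length(branches) + 1L]] <<-
      list(node1 = n1, node2 = n2, pathIds = pathIds, isLoop = isLoop)
  }
  for (nd in seq_along(nodeMembers)) {
    if (nodeType[nd] == "isolated") next
    for (v in nodeMembers[[nd]]) {
      for (u in adj[[v]]) {
        if (!is.na(nodeOf[u]) || visited[u]) next
        pathIds <- c(v, u)
        visited[u] <- TRUE
        prev <- v
        cur <- u
        repeat {
          nbs <- adj[[cur]]
          nxt <- nbs[nbs != prev]
          if (length(nxt) == 0L) {           # dead-end slab (shouldn't occur)
            push(nd, nd, pathIds, TRUE)
            break
          }
          nxt <- nxt[1]
          if (!is.na(nodeOf[nxt])) {         # reached a node unit
            pathIds <- c(pathIds, nxt)
            push(nd, nodeOf[nxt], pathIds, FALSE)
            break
          }
          if (visited[nxt]) {                # closed back onto this trace
            pathIds <- c(pathIds, nxt)
            push(nd, nd, pathIds, TRUE)
            break
          }
          pathIds <- c(pathIds, nxt)
          visited[nxt] <- TRUE
          prev <- cur
          cur <- nxt
        }
      }
    }
  }
  # direct node-node adjacencies (no slab in between); junction-junction
  # pairs cannot occur (adjacent junction voxels share one cluster)
  for (v in seq_len(n)) {
    if (is.na(nodeOf[v])) next
    for (u in adj[[v]]) {
      if (u <= v || is.na(nodeOf[u]) || nodeOf[u] == nodeOf[v]) next
      if (nodeType[nodeOf[v]] == "endpoint" ||
          nodeType[nodeOf[u]] == "endpoint")
        push(nodeOf[v], nodeOf[u], c(v, u), FALSE)
    }
  }
  # leftover slab voxels form free cycles
  left <- which(is.na(nodeOf) & !visited & deg == 2L)
  for (s in left) {
    if (visited[s]) next
    pathIds <- s
    visited[s] <- TRUE
    prev <- s
    cur <- adj[[s]][1]
    while (!visited[cur]) {
      visited[cur] <- TRUE
      pathIds <- c(pathIds, cur)
      nbs <- adj[[cur]]
      nxt <- nbs[nbs != prev][1]
      prev <- cur
      cur <- nxt
    }
    pathIds <- c(pathIds, pathIds[1])
    push(NA_integer_, NA_integer_, pathIds, TRUE)
  }
  branches
}

#' Build the branch/junction/endpoint graph of a skeleton
#'
#' Classifies skeleton voxels by their number of foreground 26-neighbours
#' (endpoint: 1, slab: 2, junction: >= 3, isolated: 0), merges 26-adjacent
#' junction voxels into single junction nodes, and traces the slab paths
#' between nodes as branches.  Per branch it reports the path length (um),
#' the Euclidean distance between its terminal points (um), their ratio
#' (tortuosity, in (0, 1]; closed loops on one node get ED = 0 and are
#' flagged), and the mean/median local-thickness label when the skeleton
#' is LT-labelled.
#'
#' Two consolidation rules keep the node accounting anatomical rather than
#' an artifact of discretization.  First, on an LT-labelled skeleton,
#' junction nodes joined by a branch shorter than `mergeFactor` times the
#' sum of their local inscribed-sphere radii are merged into one node (two
#' branch points inside one sphere belong to one physical junction;
#' thinning occasionally splits such junctions into nearby clusters).
#' Second, tiny closed loops whose path lies entirely within one junction
#' neighbourhood are absorbed into the junction cluster.  Disable with
#' `mergeJunctions = FALSE`.
#'
#' Branch length is measured on the voxel polyline after Gaussian
#' smoothing of the coordinates (`lengthMethod = "smoothed"`, sigma
#' `smoothSigmaVx`, terminal points clamped), which removes the digital
#' staircase bias of raw step sums; `lengthMethod = "steps"` gives the
#' plain sum of face/edge/vertex step lengths (1, sqrt 2, sqrt 3 times the
#' spacing, anisotropy respected).  Branches ending at a junction are
#' extended to the junction-node centroid, so junction-to-junction
#' distances are measured between branch points, not cluster surfaces.
#'
#' @param skel A [Skeleton-class] (one voxel wide, as produced by
#'   [skeletonize()]).
#' @param lengthMethod `"smoothed"` (default) or `"steps"`.
#' @param smoothSigmaVx Smoothing sigma in voxels for the smoothed
#'   estimator; default 2.
#' @param mergeJunctions Apply the junction-consolidation rules (needs an
#'   LT-labelled skeleton; silently skipped otherwise)?
#' @param mergeFactor Scale of the LT-based merge radius; default 1.
#' @return A [SkeletonGraph-class].
#' @examples
#' g <- buildGraph(skeletonize(cylinderMask(3, 40)))
#' nrow(g@branches)                       # 1 straight branch
#' @export
buildGraph <- function(skel, lengthMethod = c("smoothed", "steps"),
                       smoothSigmaVx = 2, mergeJunctions = TRUE,
                       mergeFactor = 1) {
  stopifnot(is(skel, "Skeleton"))
  lengthMethod <- match.arg(lengthMethod)
  m <- skel@data
  dims <- dim(m)
  sp <- skel@spacing
  org <- skel@origin
  lin <- which(as.vector(m))
  n <- length(lin)
  emptyNodes <- data.frame(id = integer(0), type = character(0),
                           z = numeric(0), y = numeric(0), x = numeric(0),
                           nVoxels = integer(0))
  emptyBranches <- data.frame(id = integer(0), node1 = integer(0),
                              node2 = integer(0), nSlab = integer(0),
                              pathLengthUm = numeric(0),
                              euclideanDistanceUm = numeric(0),
                              edOverLength = numeric(0),
                              meanLtUm = numeric(0), medianLtUm = numeric(0),
                              radiusUm = numeric(0),
                              isLoop = logical(0))
  if (n == 0L)
    return(new("SkeletonGraph", nodes = emptyNodes, branches = emptyBranches,
               paths = list(), spacing = sp, origin = org,
               dim = as.integer(dims)))

  pos <- integer(prod(dims))
  pos[lin] <- seq_len(n)
  deg <- cpp_neighbor_count26(as.vector(m), dims)[lin]
  edges <- cpp_adjacency26(as.vector(m), dims)
  adj <- rep(list(integer(0)), n)
  if (nrow(edges)) {
    e1 <- pos[edges[, 1]]
    e2 <- pos[edges[, 2]]
    spl <- split(c(e2, e1), c(e1, e2))
    adj[as.integer(names(spl))] <- spl
  }
  hasLt <- length(skel@ltLabel) > 0
  ltv <- if (hasLt) skel@ltLabel[lin] else NULL
  coords <- .unlinearize(lin, dims)

  type <- ifelse(deg == 0L, "isolated",
          ifelse(deg == 1L, "endpoint",
          ifelse(deg == 2L, "slab", "junction")))

  # initial node units: junction clusters + individual endpoints/isolated
  nodeOf <- rep(NA_integer_, n)
  nodeType <- character(0)
  nodeMembers <- list()
  nextNode <- 0L
  jn <- which(type == "junction")
  if (length(jn)) {
    inJn <- logical(n)
    inJn[jn] <- TRUE
    seen <- logical(n)
    for (s in jn) {
      if (seen[s]) next
      nextNode <- nextNode + 1L
      comp <- integer(0)
      stack <- s
      seen[s] <- TRUE
      while (length(stack)) {
        c0 <- stack[length(stack)]
        stack <- stack[-length(stack)]
        comp <- c(comp, c0)
        for (nb in adj[[c0]]) {
          if (inJn[nb] && !seen[nb]) {
            seen[nb] <- TRUE
            stack <- c(stack, nb)
          }
        }
      }
      nodeOf[comp] <- nextNode
      nodeType[nextNode] <- "junction"
      nodeMembers[[nextNode]] <- comp
    }
  }
  for (s in which(type %in% c("endpoint", "isolated"))) {
    nextNode <- nextNode + 1L
    nodeOf[s] <- nextNode
    nodeType[nextNode] <- type[s]
    nodeMembers[[nextNode]] <- s
  }

  raw <- .traceBranches(adj, nodeOf, nodeType, nodeMembers, deg)

  stepLen <- function(pathIds)
    .pathLength(.voxelCenters(coords[pathIds, , drop = FALSE], sp, org))

  if (mergeJunctions && hasLt && length(raw)) {
    nodeLt <- vapply(nodeMembers, function(mm) mean(ltv[mm]), numeric(1))
    parent <- seq_len(nextNode)
    findRoot <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    absorbed <- rep(FALSE, length(raw))
    extraMembers <- rep(list(integer(0)), nextNode)
    for (b in seq_along(raw)) {
      rb <- raw[[b]]
      if (is.na(rb$node1) || is.na(rb$node2)) next
      if (nodeType[rb$node1] != "junction" ||
          nodeType[rb$node2] != "junction") next
      len <- stepLen(rb$pathIds)
      limit <- mergeFactor * (nodeLt[rb$node1] + nodeLt[rb$node2])
      mergeable <- if (rb$node1 == rb$node2) len <= 2 * limit else len <= limit
      if (!mergeable) next
      r1 <- findRoot(rb$node1)
      r2 <- findRoot(rb$node2)
      parent[max(r1, r2)] <- min(r1, r2)
      slab <- rb$pathIds[is.na(nodeOf[rb$pathIds])]
      extraMembers[[min(r1, r2)]] <- c(extraMembers[[min(r1, r2)]], slab)
      absorbed[b] <- TRUE
    }
    if (any(absorbed)) {
      root <- vapply(seq_len(nextNode), findRoot, integer(1))
      keep <- sort(unique(root))
      remap <- integer(nextNode)
      remap[keep] <- seq_along(keep)
      newMembers <- lapply(keep, function(k) {
        mm <- unlist(c(nodeMembers[which(root == k)],
                       extraMembers[which(root == k)]))
        unique(mm)
      })
      nodeMembers <- newMembers
      nodeType <- nodeType[keep]
      nextNode <- length(keep)
      nodeOf <- rep(NA_integer_, n)
      for (k in seq_len(nextNode)) nodeOf[nodeMembers[[k]]] <- k
      raw <- .traceBranches(adj, nodeOf, nodeType, nodeMembers, deg)
    }
  }

  # dissolve pass-through "junction" clusters: a compact clump of voxels
  # with pairwise 26-degree >= 3 but only two incident branches is
  # thinning residue on a single branch, not a branch point; splice its
  # two branches together
  repeat {
    inc <- rep(0L, nextNode)
    incBr <- rep(list(integer(0)), nextNode)
    for (b in seq_along(raw)) {
      rb <- raw[[b]]
      for (nd in c(rb$node1, rb$node2)) {
        if (!is.na(nd)) {
          inc[nd] <- inc[nd] + 1L
          incBr[[nd]] <- c(incBr[[nd]], b)
        }
      }
    }
    # a junction cluster left with a single incident branch (e.g. after a
    # tip loop was absorbed) is a branch terminus, not a branch point
    solo <- which(nodeType == "junction" & inc == 1L)
    if (length(solo)) {
      nodeType[solo] <- "endpoint"
      next
    }
    cand <- which(nodeType == "junction" & inc == 2L)
    cand <- cand[vapply(cand, function(nd) {
      bs <- incBr[[nd]]
      length(unique(bs)) == 2L && !any(vapply(raw[bs], `[[`, logical(1),
                                              "isLoop"))
    }, logical(1))]
    if (!length(cand)) break
    nd <- cand[1]
    bs <- incBr[[nd]]
    r1 <- raw[[bs[1]]]
    r2 <- raw[[bs[2]]]
    p1 <- if (r1$node2 == nd) r1$pathIds else rev(r1$pathIds)
    n1 <- if (r1$node2 == nd) r1$node1 else r1$node2
    p2 <- if (r2$node1 == nd) r2$pathIds else rev(r2$pathIds)
    n2 <- if (r2$node1 == nd) r2$node2 else r2$node1
    if (p2[1] == p1[length(p1)]) p2 <- p2[-1]
    merged <- list(node1 = n1, node2 = n2, pathIds = c(p1, p2),
                   isLoop = n1 == n2 && nodeType[n1] == "junction")
    raw[[bs[1]]] <- merged
    raw[[bs[2]]] <- NULL
    # the dissolved cluster's voxels become slab voxels of the branch
    nodeOf[nodeMembers[[nd]]] <- NA_integer_
    nodeType[nd] <- "dissolved"
  }
  keepNodes <- which(nodeType != "dissolved")
  if (length(keepNodes) < nextNode) {
    remap <- rep(NA_integer_, nextNode)
    remap[keepNodes] <- seq_along(keepNodes)
    for (b in seq_along(raw)) {
      if (!is.na(raw[[b]]$node1)) raw[[b]]$node1 <- remap[raw[[b]]$node1]
      if (!is.na(raw[[b]]$node2)) raw[[b]]$node2 <- remap[raw[[b]]$node2]
    }
    nodeMembers <- nodeMembers[keepNodes]
    nodeType <- nodeType[keepNodes]
    nextNode <- length(keepNodes)
    nodeOf <- rep(NA_integer_, n)
    for (k in seq_len(nextNode)) nodeOf[nodeMembers[[k]]] <- k
  }

  cent <- if (nextNode) t(vapply(seq_len(nextNode), function(nd) {
    colMeans(.voxelCenters(coords[nodeMembers[[nd]], , drop = FALSE],
                           sp, org))
  }, numeric(3))) else matrix(numeric(0), 0, 3)

  branches <- list()
  paths <- list()
  for (b in seq_along(raw)) {
    rb <- raw[[b]]
    pathIds <- rb$pathIds
    isLoop <- rb$isLoop ||
      (!is.na(rb$node1) && !is.na(rb$node2) && rb$node1 == rb$node2)
    P <- .voxelCenters(coords[pathIds, , drop = FALSE], sp, org)
    # extend to junction-node centroids so lengths run branch point to
    # branch point
    if (!isLoop) {
      if (!is.na(rb$node1) && nodeType[rb$node1] == "junction") {
        c1 <- cent[rb$node1, ]
        if (sqrt(sum((P[1, ] - c1)^2)) > 1e-9) P <- rbind(c1, P)
      }
      if (!is.na(rb$node2) && nodeType[rb$node2] == "junction") {
        c2 <- cent[rb$node2, ]
        if (sqrt(sum((P[nrow(P), ] - c2)^2)) > 1e-9) P <- rbind(P, c2)
      }
    }
    Puse <- if (lengthMethod == "smoothed") .smoothPath(P, smoothSigmaVx)
            else P
    len <- .pathLength(Puse)
    ed <- if (isLoop) 0 else sqrt(sum((P[nrow(P), ] - P[1, ])^2))
    k <- length(branches) + 1L
    branches[[k]] <- data.frame(
      id = k, node1 = rb$node1, node2 = rb$node2,
      nSlab = sum(is.na(nodeOf[pathIds])),
      pathLengthUm = len, euclideanDistanceUm = ed,
      edOverLength = if (isLoop || len == 0) 0 else ed / len,
      meanLtUm = if (hasLt) mean(ltv[pathIds]) else NA_real_,
      medianLtUm = if (hasLt) median(ltv[pathIds]) else NA_real_,
      # tube-radius estimate: LT radii run to the voxel boundary, so the
      # half-voxel is added back when estimating the physical radius
      radiusUm = if (hasLt) median(ltv[pathIds]) + min(sp) / 2 else NA_real_,
      isLoop = isLoop)
    paths[[k]] <- coords[pathIds, , drop = FALSE]
  }
  branchDf <- if (length(branches)) do.call(rbind, branches) else emptyBranches

  nodesDf <- if (nextNode)
    data.frame(id = seq_len(nextNode), type = nodeType,
               z = cent[, 1], y = cent[, 2], x = cent[, 3],
               nVoxels = vapply(nodeMembers, length, integer(1)))
  else emptyNodes
  new("SkeletonGraph", nodes = nodesDf, branches = branchDf, paths = paths,
      spacing = sp, origin = org, dim = as.integer(dims))
}

#' Per-label skeleton branch statistics
#'
#' Summarizes a [SkeletonGraph-class]: branch, junction and endpoint
#' counts, average branch length and Euclidean distance (mm) and mean
#' tortuosity (ED/length, loops excluded), overall and optionally per
#' substructure label.  A branch is assigned to the label at its path
#' midpoint voxel, a node to the label at its centroid voxel.
#'
#' @param graph A [SkeletonGraph-class].
#' @param labels Optional [LabelVolume-class] on the skeleton grid.
#' @return data.frame with one row per label plus a `"total"` row:
#'   `label`, `nBranches`, `nJunctions`, `nEndpoints`, `nLoops`,
#'   `avgBranchLengthMm`, `avgEuclideanMm`, `meanEdOverLength`.
#' @export
branchStatistics <- function(graph, labels = NULL) {
  stopifnot(is(graph, "SkeletonGraph"))
  br <- graph@branches
  nodes <- graph@nodes
  summarize <- function(brSel, nodeSel, label) {
    b <- br[brSel, , drop = FALSE]
    nd <- nodes[nodeSel, , drop = FALSE]
    ok <- !b$isLoop
    data.frame(label = label,
               nBranches = nrow(b),
               nJunctions = sum(nd$type == "junction"),
               nEndpoints = sum(nd$type == "endpoint"),
               nLoops = sum(b$isLoop),
               avgBranchLengthMm = if (nrow(b)) mean(b$pathLengthUm) / 1000 else 0,
               avgEuclideanMm = if (any(ok)) mean(b$euclideanDistanceUm[ok]) / 1000 else 0,
               meanEdOverLength = if (any(ok)) mean(b$edOverLength[ok]) else 0)
  }
  out <- summarize(rep(TRUE, nrow(br)), rep(TRUE, nrow(nodes)), "total")
  if (!is.null(labels)) {
    stopifnot(is(labels, "LabelVolume"))
    if (!identical(dim(labels@data), as.integer(graph@dim)))
      stop("labels grid does not match the skeleton graph")
    labAt <- function(vox) labels@data[matrix(vox, ncol = 3)]
    brLab <- vapply(graph@paths, function(p) {
      mid <- p[ceiling(nrow(p) / 2), , drop = FALSE]
      as.integer(labAt(mid))
    }, integer(1))
    nodeVox <- cbind(
      pmin(pmax(round((nodes$z - graph@origin[1]) / graph@spacing[1]) + 1, 1),
           graph@dim[1]),
      pmin(pmax(round((nodes$y - graph@origin[2]) / graph@spacing[2]) + 1, 1),
           graph@dim[2]),
      pmin(pmax(round((nodes$x - graph@origin[3]) / graph@spacing[3]) + 1, 1),
           graph@dim[3]))
    nodeLab <- if (nrow(nodes)) as.integer(labAt(nodeVox)) else integer(0)
    ids <- as.integer(names(labels@labelNames))
    for (k in seq_along(ids)) {
      out <- rbind(out, summarize(brLab == ids[k], nodeLab == ids[k],
                                  unname(labels@labelNames[k])))
    }
    if (any(brLab == 0L) || any(nodeLab == 0L))
      out <- rbind(out, summarize(brLab == 0L, nodeLab == 0L, "unassigned"))
  }
  rownames(out) <- NULL
  out
}

#' Branch-length frequency table
#'
#' @param graph A [SkeletonGraph-class].
#' @param binWidthMm Positive bin width in millimetres.
#' @return data.frame with `bin_lo_mm`, `bin_hi_mm`, `count`.
#' @export
branchLengthHistogram <- function(graph, binWidthMm) {
  stopifnot(is(graph, "SkeletonGraph"), binWidthMm > 0)
  lmm <- graph@branches$pathLengthUm / 1000
  nb <- max(1L, ceiling(max(lmm, binWidthMm) / binWidthMm))
  lo <- (seq_len(nb) - 1) * binWidthMm
  bin <- pmin(pmax(floor(lmm / binWidthMm) + 1L, 1L), nb)
  data.frame(bin_lo_mm = lo, bin_hi_mm = lo + binWidthMm,
             count = tabulate(bin, nbins = nb))
}

#' Export a skeleton graph to SWC
#'
#' Writes the skeleton voxels as an SWC file (id, type, x, y, z in um,
#' radius = local-thickness label when available, parent id).  Parents
#' follow a spanning traversal of each branch path; cycles are broken at
#' the closing edge (SWC is tree-structured).
#'
#' @param graph A [SkeletonGraph-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeSWC <- function(graph, path) {
  stopifnot(is(graph, "SkeletonGraph"))
  idOf <- new.env(hash = TRUE)
  lines <- character(0)
  nextId <- 0L
  key <- function(v) paste(v, collapse = ",")
  for (bi in seq_along(graph@paths)) {
    p <- graph@paths[[bi]]
    prevId <- -1L
    for (r in seq_len(nrow(p))) {
      k <- key(p[r, ])
      if (!is.null(idOf[[k]])) {
        prevId <- idOf[[k]]
        next
      }
      nextId <- nextId + 1L
      idOf[[k]] <- nextId
      pos <- graph@origin + (p[r, ] - 1) * graph@spacing
      rad <- graph@branches$meanLtUm[bi]
      if (is.na(rad)) rad <- graph@spacing[1] / 2
      lines <- c(lines, sprintf("%d 0 %.3f %.3f %.3f %.3f %d",
                                nextId, pos[3], pos[2], pos[1], rad, prevId))
      prevId <- nextId
    }
  }
  writeLines(c("# SWC export: id type x y z radius parent (um)", lines), path)
  invisible(path)
}
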