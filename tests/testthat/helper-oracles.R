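# Independent oracles and small fixture builders shared across tests.

# Naive Otsu: recompute class weights/means from scratch for every cut.
naiveOtsu <- function(counts) {
  n <- sum(counts)
  best <- -Inf
  bestT <- NA_integer_
  for (t in 0:254) {
    w0 <- sum(counts[1:(t + 1)])
    w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum((0:t) * counts[1:(t + 1)]) / w0
    mu1 <- sum(((t + 1):255) * counts[(t + 2):256]) / w1
    bcv <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
    if (bcv > best + 1e-12) {
      best <- bcv
      bestT <- t
    }
  }
  bestT
}

# Brute-force local thickness by enumeration: physical-unit distances
# between all voxel pairs, outside-the-grid counting as background, sphere
# radii measured to the voxel boundary (EDT - h) and coverage allowed up
# to half a voxel beyond the sphere surface -- the same convention the
# package documents, computed by a completely different route.
bruteLocalThickness <- function(mask) {
  a <- voxelData(mask)
  sp <- spacing(mask)
  h <- min(sp) / 2
  d <- dim(a)
  fg <- which(a, arr.ind = TRUE)
  if (!nrow(fg)) return(array(0, d))
  bg <- which(!a, arr.ind = TRUE)
  P <- sweep(fg - 1, 2, sp, "*")
  edt <- rep(Inf, nrow(fg))
  if (nrow(bg)) {
    Q <- sweep(bg - 1, 2, sp, "*")
    for (i in seq_len(nrow(fg)))
      edt[i] <- sqrt(min(colSums((t(Q) - P[i, ])^2)))
  }
  border <- apply(fg, 1, function(v)
    min(pmin(v, d - v + 1) * sp))
  edt <- pmin(edt, border)
  rad <- edt - h
  lt <- numeric(nrow(fg))
  D <- as.matrix(dist(P))
  for (i in seq_len(nrow(fg)))
    lt[i] <- max(rad[D[i, ] <= rad + h + 1e-9])
  out <- array(0, d)
  out[fg] <- lt
  out
}

# random blobby mask: union of a few digital balls inside an nz x ny x nx
# grid (deterministic given the caller's RNG state)
randomBlobMask <- function(dims, nBlobs = 3, spacingUm = 1) {
  a <- array(FALSE, dims)
  co <- expand.grid(z = seq_len(dims[1]), y = seq_len(dims[2]),
                    x = seq_len(dims[3]))
  for (b in seq_len(nBlobs)) {
    c0 <- c(sample(dims[1], 1), sample(dims[2], 1), sample(dims[3], 1))
    r <- runif(1, 1.5, max(2, min(dims) / 3))
    sel <- (co$z - c0[1])^2 + (co$y - c0[2])^2 + (co$x - c0[3])^2 <= r^2
    a[cbind(co$z[sel], co$y[sel], co$x[sel])] <- TRUE
  }
  BinaryMask(a, spacing = spacingUm)
}

# hand-built Y skeleton: stem along x plus two diagonal limbs, optionally
# with a short terminal twig rising from the junction
ySkeleton <- function(twigVx = 0, spacingUm = 62) {
  a <- array(FALSE, c(30, 40, 40))
  a[15, 20, 5:20] <- TRUE
  for (i in 1:15) {
    a[15, 20 + i, 20 + i] <- TRUE
    a[15, 20 - i, 20 + i] <- TRUE
  }
  if (twigVx > 0)
    a[15 + seq_len(twigVx), 20, 20] <- TRUE
  new("Skeleton", data = a, ltLabel = array(numeric(0), c(0L, 0L, 0L)),
      spacing = rep(spacingUm, 3), origin = c(0, 0, 0))
}

# straight one-voxel path along x
pathSkeleton <- function(nVoxels, spacingUm = 62) {
  a <- array(FALSE, c(5, 5, nVoxels + 4))
  a[3, 3, 2 + seq_len(nVoxels)] <- TRUE
  new("Skeleton", data = a, ltLabel = array(numeric(0), c(0L, 0L, 0L)),
      spacing = rep(spacingUm, 3), origin = c(0, 0, 0))
}

graphCounts <- function(g) {
  c(B = nrow(g@branches),
    J = sum(g@nodes$type == "junction"),
    E = sum(g@nodes$type == "endpoint"))
}
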