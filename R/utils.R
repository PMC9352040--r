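# Internal helpers shared across modules.

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

.assertSpacing <- function(spacing) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive values (dz, dy, dx) in micrometres")
  as.numeric(spacing)
}

.assertGrid3d <- function(a) {
  if (!is.array(a) || length(dim(a)) != 3L || any(dim(a) < 1L))
    stop("data must be a 3D array with every axis of length >= 1")
  invisible(a)
}

# physical coordinates (um) of voxel centres, given 1-based indices (n x 3)
.voxelCenters <- function(idx, spacing, origin) {
  sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
}

# linear index -> (z, y, x) 1-based matrix
.unlinearize <- function(lin, dims) {
  lin0 <- lin - 1L
  z <- lin0 %% dims[1]
  y <- (lin0 %/% dims[1]) %% dims[2]
  x <- lin0 %/% (dims[1] * dims[2])
  cbind(z = z + 1L, y = y + 1L, x = x + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
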