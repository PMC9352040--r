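# Reading and writing 3D volumes with physical-spacing metadata.
#
# Supported on-disk forms:
#   * multi-page grayscale TIFF (8/16-bit), optionally with a plain-text
#     sidecar "<path>.meta" carrying spacing and label names;
#   * a directory of per-slice TIFFs in lexicographic order;
#   * raw binary with a mandatory "<path>.meta" sidecar declaring shape,
#     dtype, byte order and spacing.
#
# Axis convention: dim = (z, y, x), z = slice index; spacing = (dz, dy, dx)
# in micrometres.  TIFF slices are stored as (y, x) matrices.

.sidecarPath <- function(path) paste0(path, ".meta")

.writeSidecar <- function(path, fields) {
  lines <- vapply(names(fields), function(k)
    paste0(k, "=", fields[[k]]), character(1))
  writeLines(lines, .sidecarPath(path))
}

.readSidecar <- function(path) {
  sp <- .sidecarPath(path)
  if (!file.exists(sp)) return(NULL)
  lines <- readLines(sp, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  as.list(stats::setNames(
    vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)),
    vapply(kv, function(x) trimws(x[1]), character(1))
  ))
}

.parseNum3 <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])

.encodeNames <- function(nm)
  paste(paste0(names(nm), ":", nm), collapse = ";")

.decodeNames <- function(s) {
  if (is.null(s) || !nzchar(s)) return(character(0))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  stats::setNames(vapply(parts, `[`, character(1), 2),
                  vapply(parts, `[`, character(1), 1))
}

.dtypeSize <- function(dtype)
  switch(dtype, uint8 = 1L, uint16 = 2L, int32 = 4L,
         float32 = 4L, float64 = 8L,
         stop("unsupported dtype: ", dtype))

#' Read a 3D volume from disk
#'
#' Reads a multi-page TIFF, a directory of per-slice TIFFs (lexicographic
#' slice order) or a raw binary file with a `<path>.meta` sidecar.  The
#' sidecar (written by [writeVolume()]) records spacing, origin, the grid
#' kind and label names; a TIFF without one is read with spacing
#' `(1, 1, 1)` um and a warning.
#'
#' @param path File or directory to read.
#' @param formatHint One of `"auto"`, `"tiff"`, `"tiffdir"`, `"raw"`.
#' @return A [VoxelVolume-class], [BinaryMask-class], [LabelVolume-class]
#'   or [ThicknessField-class], as recorded in the sidecar (`VoxelVolume`
#'   when there is none).
#' @examples
#' f <- tempfile(fileext = ".tif")
#' writeVolume(VoxelVolume(array(1:24, c(2, 3, 4)), spacing = 62), f)
#' readVolume(f)
#' @export
readVolume <- function(path, formatHint = c("auto", "tiff", "tiffdir", "raw")) {
  formatHint <- match.arg(formatHint)
  if (!file.exists(path))
    stop("file not found: ", path)
  if (formatHint == "auto") {
    formatHint <- if (dir.exists(path)) "tiffdir"
      else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff"
      else "raw"
  }
  meta <- .readSidecar(path)
  if (formatHint == "raw") {
    if (is.null(meta))
      stop("raw volume requires a sidecar file: ", .sidecarPath(path))
    shape <- as.integer(.parseNum3(meta[["shape"]]))
    dtype <- meta[["dtype"]]
    endian <- if (identical(meta[["byteorder"]], "big")) "big" else "little"
    n <- prod(shape)
    expect <- n * .dtypeSize(dtype)
    if (file.info(path)$size != expect)
      stop(sprintf("size mismatch: sidecar declares %d bytes (%s voxels of %s) but file has %d",
                   expect, paste(shape, collapse = "x"), dtype,
                   file.info(path)$size))
    con <- file(path, "rb")
    on.exit(close(con))
    raw <- switch(dtype,
      uint8 = as.integer(readBin(con, "integer", n, size = 1, signed = FALSE,
                                 endian = endian)),
      uint16 = as.integer(readBin(con, "integer", n, size = 2, signed = FALSE,
                                  endian = endian)),
      int32 = readBin(con, "integer", n, size = 4, endian = endian),
      float32 = readBin(con, "double", n, size = 4, endian = endian),
      float64 = readBin(con, "double", n, size = 8, endian = endian))
    a <- array(raw, dim = shape)
  } else {
    slices <- if (formatHint == "tiffdir") {
      fl <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                            ignore.case = TRUE))
      if (!length(fl)) stop("no TIFF slices found in directory: ", path)
      unlist(lapply(fl, function(f) tiff::readTIFF(f, all = TRUE, as.is = TRUE)),
             recursive = FALSE)
    } else {
      tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    }
    if (!is.list(slices)) slices <- list(slices)
    slices <- lapply(slices, function(s) {
      if (length(dim(s)) == 3L) s <- s[, , 1]   # collapse any channel axis
      s
    })
    shp <- dim(slices[[1]])
    if (!all(vapply(slices, function(s) identical(dim(s), shp), logical(1))))
      stop("inconsistent slice shapes in TIFF stack")
    a <- array(0, dim = c(length(slices), shp))
    for (i in seq_along(slices)) a[i, , ] <- slices[[i]]
    if (all(a == round(a))) storage.mode(a) <- "integer"
  }
  spacingKey <- intersect(c("spacing_um", "spacing"), names(meta))
  spacingKnown <- length(spacingKey) > 0
  spacing <- if (spacingKnown) .parseNum3(meta[[spacingKey[1]]]) else c(1, 1, 1)
  if (!spacingKnown) {
    warning("no spacing metadata found for ", path,
            "; defaulting to (1, 1, 1) um")
  }
  orig <- if (!is.null(meta) && "origin_um" %in% names(meta))
    .parseNum3(meta[["origin_um"]]) else c(0, 0, 0)
  kind <- if (!is.null(meta)) meta[["kind"]] %||% "volume" else "volume"
  switch(kind,
    mask = BinaryMask(array(a != 0, dim(a)), spacing, orig),
    labels = LabelVolume(a, labelNames = .decodeNames(meta[["names"]]),
                         spacing = spacing, origin = orig),
    thickness = new("ThicknessField", values = a * 1.0, spacing = spacing,
                    origin = orig,
                    convention = meta[["convention"]] %||% "radius"),
    VoxelVolume(a, spacing, orig))
}

.writeTiffStack <- function(a, path, bits) {
  maxv <- 2^bits - 1
  slices <- lapply(seq_len(dim(a)[1]), function(i) {
    m <- a[i, , , drop = TRUE]
    if (!is.matrix(m)) m <- matrix(m, dim(a)[2], dim(a)[3])
    m / maxv
  })
  tiff::writeTIFF(slices, path, bits.per.sample = bits)
}

#' Write a grid object to disk
#'
#' Integer-valued grids (`VoxelVolume`, `BinaryMask`, `LabelVolume`) are
#' written as multi-page TIFF when `path` ends in `.tif`/`.tiff`, or as raw
#' binary otherwise; real-valued grids (`ThicknessField`, non-integer
#' `VoxelVolume`) always use the raw form.  A plain-text `<path>.meta`
#' sidecar records shape, dtype, spacing, origin, the grid kind and (for
#' `LabelVolume`) the label-name map, so that
#' `readVolume(writeVolume(x, path))` reproduces grid, class and spacing.
#'
#' @param x The grid object to write.
#' @param path Output file path; the parent directory must exist.
#' @param ... Unused.
#' @return `path`, invisibly.
#' @seealso [readVolume()]
#' @name writeVolume
NULL

.writeGrid <- function(a, path, kind, spacing, origin, extra = list()) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  isTiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  intLike <- is.integer(a) || (is.numeric(a) && all(a == round(a)) &&
                               max(a) <= 65535 && min(a) >= 0)
  fields <- list(kind = kind,
                 shape = paste(dim(a), collapse = ","),
                 spacing_um = paste(spacing, collapse = ","),
                 origin_um = paste(origin, collapse = ","))
  if (isTiff && intLike) {
    bits <- if (max(a) <= 255) 8L else 16L
    .writeTiffStack(a, path, bits)
    fields$dtype <- if (bits == 8L) "uint8" else "uint16"
  } else {
    if (isTiff)
      stop("real-valued grids must be written as raw binary, not TIFF")
    if (intLike) {
      storage.mode(a) <- "integer"
      con <- file(path, "wb")
      writeBin(as.vector(a), con, size = 4, endian = "little")
      close(con)
      fields$dtype <- "int32"
    } else {
      con <- file(path, "wb")
      writeBin(as.vector(a * 1.0), con, size = 8, endian = "little")
      close(con)
      fields$dtype <- "float64"
    }
    fields$byteorder <- "little"
  }
  .writeSidecar(path, c(fields, extra))
  invisible(path)
}

#' @rdname writeVolume
#' @export
setMethod("writeVolume", "VoxelVolume", function(x, path, ...) {
  .writeGrid(x@data, path, "volume", x@spacing, x@origin)
})

#' @rdname writeVolume
#' @export
setMethod("writeVolume", "BinaryMask", function(x, path, ...) {
  .writeGrid(array(as.integer(x@data), dim(x@data)), path, "mask",
             x@spacing, x@origin)
})

#' @rdname writeVolume
#' @export
setMethod("writeVolume", "LabelVolume", function(x, path, ...) {
  .writeGrid(x@data, path, "labels", x@spacing, x@origin,
             extra = list(names = .encodeNames(x@labelNames)))
})

#' @rdname writeVolume
#' @export
setMethod("writeVolume", "ThicknessField", function(x, path, ...) {
  .writeGrid(x@values, path, "thickness", x@spacing, x@origin,
             extra = list(convention = x@convention))
})
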