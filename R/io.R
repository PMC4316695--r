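#' Read a displacement field from disk
#'
#' Supported dialects are NIfTI-1 (`.nii`, `.nii.gz`) storing the field as a
#' 4-D array whose fourth dimension holds the three vector components (a 5-D
#' layout `nx x ny x nz x 1 x 3` is also accepted), and MetaImage
#' (`.mhd`/`.mha`) with `ElementNumberOfChannels = 3`. Components are ordered
#' `(x, y, z)` = `(column, row, slice)`. Values are converted to millimetres
#' when the NIfTI header declares metres or micrometres; MetaImage carries no
#' unit field and is taken to be mm. Headers with non-identity direction
#' matrices (oblique grids) are rejected: all voxel-wise arithmetic in this
#' package presumes an axis-aligned lattice.
#'
#' @param path Path to the volume.
#' @param format `"auto"` (from extension), `"nifti"` or `"metaimage"`.
#' @return A [displacement_field()].
#' @seealso [write_displacement_field()], [read_mask()]
#' @export
read_displacement_field <- function(path, format = c("auto", "nifti", "metaimage")) {
  format <- detect_format(path, match.arg(format))
  vol <- switch(format,
    nifti = read_nifti_volume(path),
    metaimage = read_metaimage_volume(path)
  )
  arr <- vol$data
  nd <- length(dim(arr))
  if (nd == 5L && dim(arr)[4] == 1L) {
    arr <- array(arr, dim = dim(arr)[c(1, 2, 3, 5)])
    nd <- 4L
  }
  if (nd != 4L) {
    stop("not a vector field: expected a 3-component vector volume", call. = FALSE)
  }
  if (dim(arr)[4] != 3L) {
    stop(sprintf("not a 3-component vector field (found %d components)", dim(arr)[4]),
         call. = FALSE)
  }
  geom <- grid_geometry(dim(arr)[1:3], vol$spacing, vol$origin)
  displacement_field(geom, arr * vol$to_mm)
}

#' Write a displacement field to disk
#'
#' Vectors are stored as 64-bit floats in both dialects, so a write/read
#' round trip reproduces the field bit-exactly.
#'
#' @param field A [displacement_field()].
#' @param path Destination path.
#' @param format `"auto"` (from extension), `"nifti"` or `"metaimage"`.
#' @return Invisibly, `path`.
#' @export
write_displacement_field <- function(field, path,
                                     format = c("auto", "nifti", "metaimage")) {
  stopifnot(inherits(field, "displacement_field"))
  format <- detect_format(path, match.arg(format))
  switch(format,
    nifti = write_nifti_volume(field$vectors, field$geometry, path),
    metaimage = write_metaimage_volume(field$vectors, field$geometry, path,
                                       channels = 3L)
  )
  invisible(path)
}

#' Read or write a binary structure mask
#'
#' Masks are single-component volumes in either dialect; any stored dtype is
#' accepted and binarized with the `value > 0.5` rule, so float masks carrying
#' interpolation residue load as clean bitmaps. `write_mask` stores unsigned
#' 8-bit values {0, 1}.
#'
#' @param path Path to the volume.
#' @param format `"auto"`, `"nifti"` or `"metaimage"`.
#' @param label Structure name attached to the mask.
#' @return `read_mask`: a [structure_mask()]. `write_mask`: invisibly, `path`.
#' @export
read_mask <- function(path, format = c("auto", "nifti", "metaimage"),
                      label = "structure") {
  format <- detect_format(path, match.arg(format))
  vol <- switch(format,
    nifti = read_nifti_volume(path),
    metaimage = read_metaimage_volume(path)
  )
  arr <- drop_trailing_singletons(vol$data)
  if (length(dim(arr)) != 3L) {
    stop("not a scalar mask volume", call. = FALSE)
  }
  geom <- grid_geometry(dim(arr), vol$spacing, vol$origin)
  structure_mask(geom, arr, label = label)
}

#' @rdname read_mask
#' @param mask A [structure_mask()].
#' @export
write_mask <- function(mask, path, format = c("auto", "nifti", "metaimage")) {
  stopifnot(inherits(mask, "structure_mask"))
  format <- detect_format(path, match.arg(format))
  arr <- array(as.double(mask$occupancy), dim = mask$geometry$dims)
  switch(format,
    nifti = write_nifti_volume(arr, mask$geometry, path),
    metaimage = write_metaimage_volume(arr, mask$geometry, path,
                                       channels = 1L, element_type = "MET_UCHAR")
  )
  invisible(path)
}

#' Read or write a scalar volume (Jacobian or discrepancy map)
#'
#' @param path Path to the volume.
#' @param format `"auto"`, `"nifti"` or `"metaimage"`.
#' @param units Unit label attached on read (not stored in the file).
#' @return `read_scalar_volume`: a [scalar_volume()].
#' @export
read_scalar_volume <- function(path, format = c("auto", "nifti", "metaimage"),
                               units = "") {
  format <- detect_format(path, match.arg(format))
  vol <- switch(format,
    nifti = read_nifti_volume(path),
    metaimage = read_metaimage_volume(path)
  )
  arr <- drop_trailing_singletons(vol$data)
  if (length(dim(arr)) != 3L) {
    stop("not a scalar volume", call. = FALSE)
  }
  geom <- grid_geometry(dim(arr), vol$spacing, vol$origin)
  scalar_volume(geom, arr, units = units)
}

#' @rdname read_scalar_volume
#' @param scalar A [scalar_volume()].
#' @export
write_scalar_volume <- function(scalar, path, format = c("auto", "nifti", "metaimage")) {
  stopifnot(inherits(scalar, "scalar_volume"))
  format <- detect_format(path, match.arg(format))
  switch(format,
    nifti = write_nifti_volume(scalar$values, scalar$geometry, path),
    metaimage = write_metaimage_volume(scalar$values, scalar$geometry, path,
                                       channels = 1L)
  )
  invisible(path)
}

# --- format detection ---------------------------------------------------

detect_format <- function(path, format) {
  if (format != "auto") return(format)
  lp <- tolower(path)
  if (endsWith(lp, ".nii") || endsWith(lp, ".nii.gz")) return("nifti")
  if (endsWith(lp, ".mhd") || endsWith(lp, ".mha")) return("metaimage")
  stop(sprintf("cannot infer format from extension of '%s'", path), call. = FALSE)
}

drop_trailing_singletons <- function(arr) {
  d <- dim(arr)
  while (length(d) > 3L && d[length(d)] == 1L) d <- d[-length(d)]
  dim(arr) <- d
  arr
}

# --- NIfTI dialect (RNifti backend) -------------------------------------

read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  d <- dim(img)
  if (hdr$sform_code > 0 || hdr$qform_code > 0) {
    m <- RNifti::xform(img)
    rot <- m[1:3, 1:3]
    if (any(abs(rot - diag(diag(rot))) > 1e-6 * max(abs(diag(rot))))) {
      stop("oblique grids (non-identity direction matrix) are not supported",
           call. = FALSE)
    }
    if (any(diag(rot) <= 0)) {
      stop("grids with negated axes are not supported", call. = FALSE)
    }
    spacing <- diag(rot)
    origin <- m[1:3, 4]
  } else {
    spacing <- abs(hdr$pixdim[2:4])
    origin <- c(0, 0, 0)
  }
  if (any(spacing <= 0)) stop("undefined voxel spacing in header", call. = FALSE)
  units <- attr(img, "pixunits")[1]
  to_mm <- switch(units, m = 1000, um = 1e-3, 1)
  arr <- as.array(img)
  attributes(arr) <- list(dim = d)
  list(data = arr, spacing = spacing * to_mm, origin = origin * to_mm, to_mm = to_mm)
}

write_nifti_volume <- function(arr, geom, path) {
  if (!dir.exists(dirname(path))) {
    stop(sprintf("cannot open '%s' for writing", path), call. = FALSE)
  }
  sp <- geom$spacing
  or <- geom$origin
  nd <- length(dim(arr))
  hdr <- list(
    pixdim = c(1, sp, rep(1, nd - 3), rep(0, 4 - (nd - 3)))[1:8],
    sform_code = 1L, qform_code = 0L,
    srow_x = c(sp[1], 0, 0, or[1]),
    srow_y = c(0, sp[2], 0, or[2]),
    srow_z = c(0, 0, sp[3], or[3]),
    xyzt_units = 2L  # millimetres
  )
  img <- RNifti::asNifti(arr, reference = hdr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# --- MetaImage dialect (self-contained) ----------------------------------
# MetaImage is a plain-text header (Key = Value lines) followed by (or
# pointing at) a raw little/big-endian block. Channels interleave fastest,
# then x, y, z. No R package on hand reads it, so the dialect is implemented
# here directly.

metaimage_types <- list(
  MET_DOUBLE = list(size = 8L, what = "double"),
  MET_FLOAT  = list(size = 4L, what = "double"),
  MET_UCHAR  = list(size = 1L, what = "integer", signed = FALSE),
  MET_CHAR   = list(size = 1L, what = "integer", signed = TRUE),
  MET_USHORT = list(size = 2L, what = "integer", signed = FALSE),
  MET_SHORT  = list(size = 2L, what = "integer", signed = TRUE),
  MET_UINT   = list(size = 4L, what = "integer", signed = TRUE),
  MET_INT    = list(size = 4L, what = "integer", signed = TRUE)
)

write_metaimage_volume <- function(arr, geom, path, channels = 1L,
                                   element_type = "MET_DOUBLE") {
  local_data <- endsWith(tolower(path), ".mha")
  data_file <- if (local_data) "LOCAL" else paste0(
    sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %.17g %.17g %.17g", geom$origin[1], geom$origin[2], geom$origin[3]),
    sprintf("ElementSpacing = %.17g %.17g %.17g",
            geom$spacing[1], geom$spacing[2], geom$spacing[3]),
    sprintf("DimSize = %d %d %d", geom$dims[1], geom$dims[2], geom$dims[3]),
    if (channels > 1L) sprintf("ElementNumberOfChannels = %d", channels),
    sprintf("ElementType = %s", element_type),
    sprintf("ElementDataFile = %s", data_file)
  )
  payload <- if (channels > 1L) as.vector(aperm(arr, c(4, 1, 2, 3))) else as.vector(arr)
  tinfo <- metaimage_types[[element_type]]
  if (is.null(tinfo)) stop("unsupported MetaImage element type", call. = FALSE)
  if (tinfo$what == "integer") payload <- as.integer(round(payload))
  con <- tryCatch(suppressWarnings(file(path, "wb")), error = function(e) {
    stop(sprintf("cannot open '%s' for writing", path), call. = FALSE)
  })
  on.exit(close(con), add = TRUE)
  writeLines(header, con)
  if (local_data) {
    writeBin(payload, con, size = tinfo$size, endian = "little")
  } else {
    rawcon <- file(file.path(dirname(path), data_file), "wb")
    on.exit(close(rawcon), add = TRUE)
    writeBin(payload, rawcon, size = tinfo$size, endian = "little")
  }
  invisible(path)
}

read_metaimage_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  bytes <- readBin(path, "raw", n = file.size(path))
  # Header ends at the newline after the ElementDataFile line; binary payload
  # may follow, so probe only up to the first NUL byte.
  probe_len <- min(length(bytes), 65536L)
  first_nul <- which(bytes[seq_len(probe_len)] == as.raw(0))[1]
  if (!is.na(first_nul)) probe_len <- first_nul - 1L
  probe <- rawToChar(bytes[seq_len(probe_len)])
  lines_all <- strsplit(probe, "\n", fixed = TRUE, useBytes = TRUE)[[1]]
  idx_edf <- grep("^\\s*ElementDataFile", lines_all, useBytes = TRUE)
  if (length(idx_edf) == 0) stop("malformed MetaImage header: no ElementDataFile",
                                 call. = FALSE)
  header_lines <- lines_all[seq_len(idx_edf[1])]
  header_nbytes <- sum(nchar(header_lines, type = "bytes")) + idx_edf[1]
  fields <- list()
  for (ln in header_lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    fields[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
  }
  num3 <- function(key, default = NULL) {
    if (is.null(fields[[key]])) return(default)
    as.numeric(strsplit(fields[[key]], "\\s+")[[1]])
  }
  dims <- as.integer(num3("DimSize"))
  if (is.null(dims) || length(dims) != 3L) {
    stop("MetaImage volume must be 3-D", call. = FALSE)
  }
  spacing <- num3("ElementSpacing", default = num3("ElementSize"))
  if (is.null(spacing)) stop("undefined voxel spacing in header", call. = FALSE)
  origin <- num3("Offset", default = c(0, 0, 0))
  tm <- num3("TransformMatrix", default = c(1, 0, 0, 0, 1, 0, 0, 0, 1))
  if (any(abs(tm - c(1, 0, 0, 0, 1, 0, 0, 0, 1)) > 1e-6)) {
    stop("oblique grids (non-identity TransformMatrix) are not supported",
         call. = FALSE)
  }
  channels <- as.integer(fields[["ElementNumberOfChannels"]] %||% "1")
  etype <- fields[["ElementType"]] %||% "MET_FLOAT"
  tinfo <- metaimage_types[[etype]]
  if (is.null(tinfo)) stop(sprintf("unsupported ElementType '%s'", etype), call. = FALSE)
  msb <- identical(toupper(fields[["BinaryDataByteOrderMSB"]] %||% "FALSE"), "TRUE")
  if (identical(toupper(fields[["CompressedData"]] %||% "FALSE"), "TRUE")) {
    stop("compressed MetaImage payloads are not supported", call. = FALSE)
  }
  n <- prod(dims) * channels
  edf <- fields[["ElementDataFile"]]
  if (identical(edf, "LOCAL")) {
    payload_raw <- bytes[(header_nbytes + 1):length(bytes)]
  } else {
    raw_path <- file.path(dirname(path), edf)
    if (!file.exists(raw_path)) {
      stop(sprintf("raw data file not found: '%s'", raw_path), call. = FALSE)
    }
    payload_raw <- readBin(raw_path, "raw", n = file.size(raw_path))
  }
  if (length(payload_raw) < n * tinfo$size) {
    stop("MetaImage payload shorter than header declares", call. = FALSE)
  }
  values <- readBin(payload_raw, what = tinfo$what, n = n, size = tinfo$size,
                    signed = tinfo$signed %||% TRUE,
                    endian = if (msb) "big" else "little")
  values <- as.double(values)
  if (channels > 1L) {
    arr <- array(values, dim = c(channels, dims))
    arr <- aperm(arr, c(2, 3, 4, 1))
  } else {
    arr <- array(values, dim = dims)
  }
  list(data = arr, spacing = spacing, origin = origin, to_mm = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
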