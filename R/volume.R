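#' CT volume container
#'
#' A `voxel_volume` couples a 3-D grid of scalar intensities (Hounsfield
#' units) with a 4x4 affine mapping 0-based voxel indices to world
#' coordinates in millimetres.  The world frame is LPS (+x left,
#' +y posterior, +z superior), the convention native to DICOM-derived CT;
#' NIfTI RAS affines are converted on load.  Index `(0, 0, 0)` maps to the
#' centre of the corner voxel.
#'
#' @param data numeric 3-D array of intensities (HU).
#' @param affine numeric 4x4 matrix; upper-left 3x3 block must be
#'   invertible and the last row `(0, 0, 0, 1)`.
#' @return An object of class `voxel_volume` with elements `data` and
#'   `affine`.
#' @examples
#' vol <- voxel_volume(array(0, c(4, 4, 4)), diag(4))
#' vol_spacing(vol)
#' @export
voxel_volume <- function(data, affine = diag(4)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    mm_validation_error("'data' must be a 3-D array")
  if (any(dim(data) < 1L))
    mm_validation_error("all volume dimensions must be positive")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    mm_validation_error("'affine' must be a 4x4 matrix")
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-9)
    mm_validation_error("last affine row must be (0, 0, 0, 1)")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 100)
    mm_validation_error("affine upper-left 3x3 block is singular")
  storage.mode(data) <- "double"
  dimnames(data) <- NULL
  dimnames(affine) <- NULL
  structure(list(data = data, affine = affine), class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  sp <- vol_spacing(x)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], sp[1], sp[2], sp[3]))
  cat(sprintf("  intensity range [%.4g, %.4g] HU\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname voxel_volume
#' @param volume a `voxel_volume`.
#' @export
vol_spacing <- function(volume) {
  sqrt(colSums(volume$affine[1:3, 1:3]^2))
}

#' @rdname voxel_volume
#' @export
vol_dims <- function(volume) dim(volume$data)

# coerce a length-3 vector or n x 3 matrix to n x 3 double matrix
as_point_matrix <- function(x, arg = "points") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != 3L)
      mm_validation_error(sprintf("'%s' must have 3 components", arg))
    x <- matrix(x, nrow = 1L)
  }
  if (ncol(x) != 3L)
    mm_validation_error(sprintf("'%s' must be an n x 3 matrix", arg))
  storage.mode(x) <- "double"
  if (any(!is.finite(x)))
    mm_validation_error(sprintf("'%s' contains non-finite coordinates", arg))
  x
}

#' Map voxel indices to world coordinates (and back)
#'
#' Applies the volume affine to homogeneous 0-based voxel indices.
#' Fractional and out-of-bounds indices are allowed; sub-voxel centroids
#' rely on this.  `world_to_voxel()` applies the inverse affine.
#'
#' @param volume a [voxel_volume()].
#' @param index,points a length-3 vector or n x 3 matrix of 0-based voxel
#'   indices (`voxel_to_world`) or world mm coordinates (`world_to_voxel`).
#' @return An n x 3 matrix (or length-3 vector when the input was a
#'   vector) of world mm / voxel indices.
#' @examples
#' vol <- voxel_volume(array(0, c(8, 8, 8)),
#'                     rbind(cbind(diag(c(0.5, 0.5, 0.6)), 0), c(0, 0, 0, 1)))
#' voxel_to_world(vol, c(2, 2, 5))   # (1, 1, 3) mm
#' @export
voxel_to_world <- function(volume, index) {
  vec_in <- is.null(dim(index))
  idx <- as_point_matrix(index, "index")
  out <- t(volume$affine[1:3, 1:3] %*% t(idx) + volume$affine[1:3, 4])
  if (vec_in) drop(out) else out
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(volume, points) {
  vec_in <- is.null(dim(points))
  pts <- as_point_matrix(points)
  out <- t(solve(volume$affine[1:3, 1:3], t(pts) - volume$affine[1:3, 4]))
  if (vec_in) drop(out) else out
}

# world-coordinate bounding box of the voxel grid (corner-to-corner,
# including the half-voxel margin around voxel centres)
vol_world_bounds <- function(volume) {
  d <- vol_dims(volume)
  corners <- as.matrix(expand.grid(c(-0.5, d[1] - 0.5),
                                   c(-0.5, d[2] - 0.5),
                                   c(-0.5, d[3] - 0.5)))
  w <- voxel_to_world(volume, corners)
  rbind(lo = apply(w, 2, min), hi = apply(w, 2, max))
}

#' Read and write CT volumes
#'
#' Supported formats are NIfTI-1 (`.nii`, `.nii.gz`; via \pkg{RNifti}) and
#' NRRD (`.nrrd`; a built-in NRRD0004 codec supporting `raw` and `gzip`
#' encodings).  NIfTI stores RAS affines; these are converted to the
#' package's internal LPS world convention on read and converted back on
#' write, so world coordinates agree across formats.
#'
#' @param path file path; the format is chosen by extension, falling back
#'   to content sniffing.
#' @param volume a [voxel_volume()].
#' @param format one of `"auto"`, `"nifti"`, `"nrrd"`.
#' @return `read_volume()` returns a [voxel_volume()]; `write_volume()`
#'   returns `path` invisibly.
#' @export
read_volume <- function(path, format = c("auto", "nifti", "nrrd")) {
  format <- match.arg(format)
  if (!file.exists(path))
    mm_format_error(sprintf("volume file does not exist: '%s'", path))
  if (format == "auto") format <- sniff_volume_format(path)
  switch(format,
         nifti = read_nifti_volume(path),
         nrrd  = read_nrrd_volume(path))
}

sniff_volume_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.nrrd$", lower)) return("nrrd")
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  magic <- readBin(path, "raw", n = 4L)
  if (identical(rawToChar(magic), "NRRD")) return("nrrd")
  # gzip magic or nifti sizeof_hdr: let RNifti try
  "nifti"
}

# RAS <-> LPS: negate the first two world axes
ras_lps_flip <- diag(c(-1, -1, 1, 1))

read_nifti_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path, internal = FALSE),
                  error = function(e)
                    mm_format_error(sprintf("cannot read '%s' as NIfTI: %s",
                                            path, conditionMessage(e))))
  if (length(dim(img)) != 3L)
    mm_format_error(sprintf("'%s' is not a 3-D volume", path))
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  aff <- matrix(as.numeric(aff), 4, 4)
  if (abs(det(aff[1:3, 1:3])) < .Machine$double.eps * 100)
    mm_metadata_error(sprintf("'%s' has no usable spatial metadata", path))
  dat <- array(as.numeric(img), dim = dim(img))
  voxel_volume(dat, ras_lps_flip %*% aff)
}

write_nifti_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- vol_spacing(volume)
  aff <- ras_lps_flip %*% volume$affine   # back to RAS for NIfTI
  attr(aff, "code") <- 2L
  img <- RNifti::`sform<-`(img, aff)
  # qform only encodes rotations; skip it for sheared affines
  img <- tryCatch(RNifti::`qform<-`(img, aff), error = function(e) img)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path, format = c("auto", "nifti", "nrrd")) {
  format <- match.arg(format)
  if (!inherits(volume, "voxel_volume"))
    mm_validation_error("'volume' must be a voxel_volume")
  if (!dir.exists(dirname(path)))
    mm_error(sprintf("directory does not exist: '%s'", dirname(path)),
             "markermorph_io_error")
  if (format == "auto")
    format <- if (grepl("\\.nrrd$", tolower(path))) "nrrd" else "nifti"
  switch(format,
         nifti = write_nifti_volume(volume, path),
         nrrd  = write_nrrd_volume(volume, path))
  invisible(path)
}

## ---- minimal NRRD0004 codec (3-D, raw/gzip, LPS space) ----------------

nrrd_types <- list(
  "double" = list(what = "double",  size = 8L, signed = TRUE),
  "float"  = list(what = "double",  size = 4L, signed = TRUE),
  "short"  = list(what = "integer", size = 2L, signed = TRUE),
  "int"    = list(what = "integer", size = 4L, signed = TRUE),
  "uchar"  = list(what = "integer", size = 1L, signed = FALSE),
  "ushort" = list(what = "integer", size = 2L, signed = FALSE)
)
nrrd_type_aliases <- c(
  "signed short" = "short", "short int" = "short", "int16" = "short",
  "int16_t" = "short", "uint16" = "ushort", "uint16_t" = "ushort",
  "int32" = "int", "int32_t" = "int", "unsigned char" = "uchar",
  "uint8" = "uchar", "uint8_t" = "uchar", "float64" = "double",
  "float32" = "float"
)

parse_nrrd_vector <- function(s) {
  s <- gsub("[()]", "", trimws(s))
  as.numeric(strsplit(s, ",")[[1]])
}

read_nrrd_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD000[1-5]$", magic))
    mm_format_error(sprintf("'%s' is not an NRRD file", path))
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      mm_format_error(sprintf("'%s': NRRD header not terminated", path))
    if (line == "") break
    if (grepl("^#", line)) next
    m <- regmatches(line, regexec("^([^:]+): ?(.*)$", line))[[1]]
    if (length(m) == 3L) fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  need <- function(key) {
    if (is.null(fields[[key]]))
      mm_metadata_error(sprintf("'%s': NRRD header lacks '%s'", path, key))
    fields[[key]]
  }
  if (as.integer(need("dimension")) != 3L)
    mm_format_error(sprintf("'%s': only 3-D NRRD volumes are supported", path))
  sizes <- as.integer(strsplit(need("sizes"), "[ \t]+")[[1]])
  tname <- need("type")
  if (tname %in% names(nrrd_type_aliases))
    tname <- unname(nrrd_type_aliases[tname])
  tinfo <- nrrd_types[[tname]]
  if (is.null(tinfo))
    mm_format_error(sprintf("'%s': unsupported NRRD type '%s'", path, tname))
  encoding <- tolower(fields[["encoding"]] %||% "raw")
  endian <- tolower(fields[["endian"]] %||% "little")

  # spatial metadata: prefer full space directions, else spacings
  if (!is.null(fields[["space directions"]])) {
    dirs <- regmatches(fields[["space directions"]],
                       gregexpr("\\([^)]*\\)", fields[["space directions"]]))[[1]]
    if (length(dirs) != 3L)
      mm_metadata_error(sprintf("'%s': need 3 space directions", path))
    lin <- vapply(dirs, parse_nrrd_vector, numeric(3))  # columns
    origin <- if (is.null(fields[["space origin"]])) c(0, 0, 0) else
      parse_nrrd_vector(fields[["space origin"]])
    space <- tolower(fields[["space"]] %||% "left-posterior-superior")
    flip <- switch(space,
                   "left-posterior-superior" = , "lps" = c(1, 1, 1),
                   "right-anterior-superior" = , "ras" = c(-1, -1, 1),
                   "left-anterior-superior"  = , "las" = c(1, -1, 1),
                   mm_metadata_error(sprintf("'%s': unsupported NRRD space '%s'",
                                             path, space)))
    lin <- lin * flip
    origin <- origin * flip
    affine <- rbind(cbind(lin, origin), c(0, 0, 0, 1))
  } else if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(fields[["spacings"]], "[ \t]+")[[1]])
    affine <- rbind(cbind(diag(sp), c(0, 0, 0)), c(0, 0, 0, 1))
  } else {
    mm_metadata_error(sprintf(
      "'%s': NRRD header has neither space directions nor spacings", path))
  }

  n <- prod(sizes)
  payload <- readBin(con, "raw", n = file.size(path))
  if (encoding == "gzip" || encoding == "gz") {
    payload <- memDecompress(payload, type = "gzip")
  } else if (encoding != "raw") {
    mm_format_error(sprintf("'%s': unsupported NRRD encoding '%s'",
                            path, encoding))
  }
  vals <- readBin(payload, tinfo$what, n = n, size = tinfo$size,
                  signed = tinfo$signed,
                  endian = if (endian == "big") "big" else "little")
  if (length(vals) < n)
    mm_format_error(sprintf("'%s': truncated NRRD payload", path))
  voxel_volume(array(as.numeric(vals), dim = sizes), affine)
}

write_nrrd_volume <- function(volume, path) {
  lin <- volume$affine[1:3, 1:3]
  origin <- volume$affine[1:3, 4]
  fmt_vec <- function(v) sprintf("(%.17g,%.17g,%.17g)", v[1], v[2], v[3])
  header <- c(
    "NRRD0004",
    "# written by markermorph",
    "type: double",
    "dimension: 3",
    sprintf("sizes: %d %d %d", dim(volume$data)[1], dim(volume$data)[2],
            dim(volume$data)[3]),
    "space: left-posterior-superior",
    sprintf("space directions: %s %s %s", fmt_vec(lin[, 1]),
            fmt_vec(lin[, 2]), fmt_vec(lin[, 3])),
    sprintf("space origin: %s", fmt_vec(origin)),
    "endian: little",
    "encoding: raw",
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  writeBin(as.vector(volume$data), con, size = 8L, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
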