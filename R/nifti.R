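#' Minimal NIfTI-1 input/output
#'
#' The package carries its own compact NIfTI reader/writer because the
#' analysis environment provides no NIfTI package.  Scope is deliberately
#' narrow: single-file `.nii` / `.nii.gz`, the datatypes PET pipelines emit
#' (uint8, int16, uint16, int32, float32, float64), `scl_slope`/`scl_inter`
#' scaling, sform or qform affines, both endiannesses.  NIfTI-2 headers are
#' read; writing always produces NIfTI-1 with a float32 or float64 payload
#' and an sform affine (`sform_code = 2`).
#'
#' @name nifti-io
#' @keywords internal
NULL

.nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

.open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

# int64 little/big-endian raw -> double (exact for |x| < 2^53, ample for dims)
.raw_to_int64 <- function(r, endian) {
  if (endian == "big") r <- rev(r)
  sum(as.numeric(r) * 2^(8 * (0:7)))
}

.quaternion_affine <- function(h) {
  b <- h$quatern[1L]; c_ <- h$quatern[2L]; d <- h$quatern[3L]
  a2 <- 1 - b^2 - c_^2 - d^2
  a <- sqrt(max(a2, 0))
  qfac <- if (is.na(h$pixdim[1L]) || h$pixdim[1L] >= 0) 1 else -1
  R <- matrix(c(
    a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d),   2 * (b * d + a * c_),
    2 * (b * c_ + a * d),   a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b),
    2 * (b * d - a * c_),   2 * (c_ * d + a * b),   a^2 + d^2 - b^2 - c_^2
  ), 3L, 3L, byrow = TRUE)
  sp <- c(h$pixdim[2L], h$pixdim[3L], h$pixdim[4L] * qfac)
  aff <- diag(4)
  aff[1:3, 1:3] <- R %*% diag(sp)
  aff[1:3, 4L] <- h$qoffset
  aff
}

.read_nifti_header <- function(con) {
  hdr_size_raw <- readBin(con, "raw", 4L)
  size_le <- readBin(hdr_size_raw, "integer", 1L, endian = "little")
  endian <- if (size_le %in% c(348L, 540L)) "little" else "big"
  size <- readBin(hdr_size_raw, "integer", 1L, endian = endian)
  if (!size %in% c(348L, 540L))
    stop("not a NIfTI file (sizeof_hdr = ", size_le, ")")
  rb <- function(what, n, bytes) readBin(con, what, n, size = bytes,
                                         endian = endian)
  if (size == 348L) {                       # NIfTI-1
    readBin(con, "raw", 36L)                # dim_info etc.
    dim <- rb("integer", 8L, 2L)
    readBin(con, "raw", 14L)                # intent params etc.
    datatype <- rb("integer", 1L, 2L)
    rb("integer", 1L, 2L)                   # bitpix
    rb("integer", 1L, 2L)                   # slice_start
    pixdim <- rb("double", 8L, 4L)
    vox_offset <- rb("double", 1L, 4L)
    scl_slope <- rb("double", 1L, 4L)
    scl_inter <- rb("double", 1L, 4L)
    readBin(con, "raw", 123L)               # slice/cal/descrip/aux
    qform_code <- rb("integer", 1L, 2L)
    sform_code <- rb("integer", 1L, 2L)
    quatern <- rb("double", 3L, 4L)
    qoffset <- rb("double", 3L, 4L)
    srow <- matrix(rb("double", 12L, 4L), 3L, 4L, byrow = TRUE)
    readBin(con, "raw", 16L)                # intent_name
    magic <- rawToChar(readBin(con, "raw", 4L)[1:3])
    if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI-1 magic: ", magic)
  } else {                                  # NIfTI-2
    magic <- rawToChar(readBin(con, "raw", 8L)[1:3])
    if (!magic %in% c("n+2", "ni2")) stop("bad NIfTI-2 magic: ", magic)
    datatype <- rb("integer", 1L, 2L)
    rb("integer", 1L, 2L)                   # bitpix
    dim <- vapply(1:8, function(i)
      .raw_to_int64(readBin(con, "raw", 8L), endian), numeric(1))
    rb("double", 3L, 8L)                    # intent params
    pixdim <- rb("double", 8L, 8L)
    vox_offset <- .raw_to_int64(readBin(con, "raw", 8L), endian)
    scl_slope <- rb("double", 1L, 8L)
    scl_inter <- rb("double", 1L, 8L)
    rb("double", 2L, 8L)                    # cal_max/min
    rb("double", 2L, 8L)                    # slice_duration/toffset
    rb("integer", 2L, 8L)                   # slice_start/end (int64)
    readBin(con, "raw", 104L)               # descrip + aux_file
    qform_code <- rb("integer", 1L, 4L)
    sform_code <- rb("integer", 1L, 4L)
    quatern <- rb("double", 3L, 8L)
    qoffset <- rb("double", 3L, 8L)
    srow <- matrix(rb("double", 12L, 8L), 3L, 4L, byrow = TRUE)
    rb("integer", 1L, 4L)                   # slice_code
    rb("integer", 1L, 4L)                   # xyzt_units
    rb("integer", 1L, 4L)                   # intent_code
    readBin(con, "raw", 16L + 4L + 1L + 15L)
  }
  list(endian = endian, dim = dim, datatype = datatype, pixdim = pixdim,
       vox_offset = vox_offset, scl_slope = scl_slope, scl_inter = scl_inter,
       qform_code = qform_code, sform_code = sform_code,
       quatern = quatern, qoffset = qoffset, srow = srow)
}

#' Read a NIfTI image
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (numeric array, dimensionality per the header),
#'   `affine` (4x4 voxel-to-world matrix, mm) and `pixdim` (voxel sizes, mm).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- .open_maybe_gz(path, "rb")
  on.exit(close(con))
  h <- .read_nifti_header(con)
  nd <- h$dim[1L]
  if (nd < 1L || nd > 7L) stop("invalid NIfTI ndim: ", nd)
  dims <- as.integer(h$dim[2:(1L + nd)])
  dt <- .nifti_dtypes[[as.character(h$datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", h$datatype)
  # header already consumed (348 bytes for NIfTI-1, 540 for NIfTI-2); skip
  # the extension flag and any extensions up to vox_offset
  base <- if (h$vox_offset >= 544) 540L else 348L
  skip <- as.integer(h$vox_offset) - base
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = h$endian)
  if (length(vals) < n) stop("truncated NIfTI payload in ", path)
  vals <- as.numeric(vals)
  if (is.finite(h$scl_slope) && h$scl_slope != 0 &&
      !(h$scl_slope == 1 && h$scl_inter == 0))
    vals <- vals * h$scl_slope + h$scl_inter
  affine <- if (h$sform_code > 0L) {
    rbind(h$srow, c(0, 0, 0, 1))
  } else if (h$qform_code > 0L) {
    .quaternion_affine(h)
  } else {
    diag(c(h$pixdim[2:4], 1))
  }
  list(data = array(vals, dims), affine = affine,
       pixdim = abs(h$pixdim[2:4]))
}

#' Write a NIfTI-1 image
#'
#' @param data numeric array (3D or 4D).
#' @param path output `.nii` or `.nii.gz` path.
#' @param affine 4x4 voxel-to-world matrix (mm); default identity spacing.
#' @param datatype `"float64"` (default, lossless for R doubles) or
#'   `"float32"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = diag(4),
                        datatype = c("float64", "float32")) {
  datatype <- match.arg(datatype)
  dims <- dim(data)
  if (is.null(dims) || length(dims) < 2L || length(dims) > 7L)
    stop("data must be an array of 2..7 dimensions")
  if (anyNA(data)) data[is.na(data)] <- NaN
  code <- if (datatype == "float64") 64L else 16L
  bitpix <- if (datatype == "float64") 64L else 32L
  vsz <- sqrt(colSums(affine[1:3, 1:3]^2))
  con <- .open_maybe_gz(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  w(348L, 4L)
  writeBin(raw(36L), con)
  dim8 <- integer(8L); dim8[1L] <- length(dims)
  dim8[2:(1L + length(dims))] <- as.integer(dims)
  dim8[dim8 == 0L] <- 1L; dim8[1L] <- length(dims)
  w(as.integer(dim8), 2L)
  writeBin(raw(14L), con)                   # intent
  w(code, 2L)
  w(bitpix, 2L)
  w(0L, 2L)                                 # slice_start
  pixdim8 <- c(1, vsz, rep(1, 4))
  w(as.numeric(pixdim8), 4L)
  w(352, 4L)                                # vox_offset
  w(1, 4L)                                  # scl_slope
  w(0, 4L)                                  # scl_inter
  writeBin(raw(123L), con)
  w(0L, 2L)                                 # qform_code
  w(2L, 2L)                                 # sform_code
  w(rep(0, 3), 4L)                          # quatern
  w(rep(0, 3), 4L)                          # qoffset
  w(as.numeric(t(affine[1:3, ])), 4L)       # srow_x/y/z
  writeBin(raw(16L), con)
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)
  writeBin(raw(4L), con)                    # extension flag
  w(as.numeric(data), if (datatype == "float64") 8L else 4L)
  invisible(path)
}
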