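#' Read a 3D CT volume
#'
#' Reads a volume from NIfTI (`.nii`/`.nii.gz`), MetaImage (`.mhd` + raw), or
#' a directory of uncompressed single-frame DICOM slices, and returns it in
#' the internal `[slice, row, column]` convention. DICOM rescale slope and
#' intercept are applied so voxel values are in HU. The format is inferred
#' from the path when `format = NULL`.
#'
#' @param path file (NIfTI/MetaImage) or directory (DICOM series).
#' @param format one of `"nifti"`, `"mhd"`, `"dicom_dir"`, or `NULL` to infer.
#' @param side side label to attach, see [ct_volume()].
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, format = NULL, side = "full") {
  if (!file.exists(path))
    stop(sprintf("path does not exist: '%s'", path), call. = FALSE)
  if (is.null(format)) {
    format <- if (dir.exists(path)) "dicom_dir"
      else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
      else if (grepl("\\.mhd$", path, ignore.case = TRUE)) "mhd"
      else stop(sprintf("cannot infer volume format from '%s'", path),
                call. = FALSE)
  }
  format <- match.arg(format, c("nifti", "mhd", "dicom_dir"))
  switch(format,
    nifti     = read_nifti_volume(path, side),
    mhd       = read_mhd_volume(path, side),
    dicom_dir = read_dicom_series(path, side)
  )
}

#' Write a 3D CT volume
#'
#' Writes to NIfTI or MetaImage so that [read_volume()] returns a
#' voxel-identical volume with the same spacing. Integer-valued volumes
#' within the int16 range are stored as 16-bit integers (the native CT
#' representation), others as doubles.
#'
#' @param volume a [ct_volume()].
#' @param path output path (`.nii`, `.nii.gz`, or `.mhd`).
#' @param format `"nifti"`, `"mhd"`, or `NULL` to infer from `path`.
#' @export
write_volume <- function(volume, path, format = NULL) {
  stopifnot_volume(volume)
  if (!dir.exists(dirname(path)))
    stop(sprintf("parent directory does not exist: '%s'", dirname(path)),
         call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
      else if (grepl("\\.mhd$", path, ignore.case = TRUE)) "mhd"
      else stop(sprintf("cannot infer volume format from '%s'", path),
                call. = FALSE)
  }
  format <- match.arg(format, c("nifti", "mhd"))
  switch(format,
    nifti = write_nifti_volume(volume, path),
    mhd   = write_mhd_volume(volume, path)
  )
  invisible(NULL)
}

is_int16_valued <- function(v) {
  all(v == round(v)) && min(v) >= -32768 && max(v) <= 32767
}

## ---- NIfTI (via RNifti); file axes are (x, a, s), fastest first ----------

read_nifti_volume <- function(path, side) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop(sprintf("'%s' is not a 3D NIfTI volume", path), call. = FALSE)
  pd <- RNifti::pixdim(img)[1:3]
  vox <- aperm(array(as.double(arr), dim = dim(arr)), c(3, 2, 1))
  ct_volume(vox, spacing = rev(pd), side = side)
}

write_nifti_volume <- function(volume, path) {
  arr <- aperm(volume$voxels, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(volume$spacing)
  dtype <- if (is_int16_valued(volume$voxels)) "int16" else "double"
  RNifti::writeNifti(img, path, datatype = dtype)
}

## ---- MetaImage (.mhd text header + raw little-endian data) ---------------
## No MetaImage reader exists on CRAN/Bioconductor; the format is a flat
## key = value header plus a raw block, read and written here directly.

read_mhd_volume <- function(path, side) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- m[3]
  }
  need <- c("NDims", "DimSize", "ElementType", "ElementDataFile")
  miss <- setdiff(need, names(kv))
  if (length(miss))
    stop(sprintf("MetaImage header '%s' missing field(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  if (as.integer(kv$NDims) != 3L)
    stop(sprintf("'%s': only 3D MetaImage volumes are supported", path),
         call. = FALSE)
  if (!is.null(kv$CompressedData) && toupper(kv$CompressedData) == "TRUE")
    stop(sprintf("'%s': compressed MetaImage data is not supported", path),
         call. = FALSE)
  dims <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])        # (x, a, s)
  spacing <- if (!is.null(kv$ElementSpacing))
    as.double(strsplit(kv$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  raw_path <- file.path(dirname(path), kv$ElementDataFile)
  if (!file.exists(raw_path))
    stop(sprintf("MetaImage data file missing: '%s'", raw_path), call. = FALSE)
  n <- prod(dims)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- switch(kv$ElementType,
    MET_SHORT  = readBin(con, "integer", n, size = 2, signed = TRUE,
                         endian = "little"),
    MET_USHORT = readBin(con, "integer", n, size = 2, signed = FALSE,
                         endian = "little"),
    MET_FLOAT  = readBin(con, "double", n, size = 4, endian = "little"),
    MET_DOUBLE = readBin(con, "double", n, size = 8, endian = "little"),
    stop(sprintf("'%s': unsupported ElementType '%s'", path, kv$ElementType),
         call. = FALSE))
  if (length(vals) != n)
    stop(sprintf("'%s': raw file holds %d values, header promises %d",
                 raw_path, length(vals), n), call. = FALSE)
  vox <- aperm(array(as.double(vals), dim = dims), c(3, 2, 1))
  ct_volume(vox, spacing = rev(spacing), side = side)
}

write_mhd_volume <- function(volume, path) {
  raw_name <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  arr <- aperm(volume$voxels, c(3, 2, 1))
  int16 <- is_int16_valued(volume$voxels)
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("DimSize = %d %d %d", dim(arr)[1], dim(arr)[2], dim(arr)[3]),
    sprintf("ElementSpacing = %.17g %.17g %.17g",
            volume$spacing[3], volume$spacing[2], volume$spacing[1]),
    sprintf("ElementType = %s", if (int16) "MET_SHORT" else "MET_DOUBLE"),
    sprintf("ElementDataFile = %s", raw_name)
  )
  writeLines(header, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  if (int16) {
    writeBin(as.integer(arr), con, size = 2, endian = "little")
  } else {
    writeBin(as.double(arr), con, size = 8, endian = "little")
  }
}

## ---- DICOM series (minimal uncompressed little-endian reader) ------------
## Reads the subset of DICOM that CT series use: explicit or implicit VR
## little endian, one frame per file, 16-bit pixel data. Enough structure is
## parsed to recover geometry, rescale slope/intercept, and slice order; it
## is not a general DICOM implementation.

dcm_group   <- function(tag) bitwShiftR(tag, 16)
dcm_element <- function(tag) bitwAnd(tag, 0xFFFF)

read_dicom_file <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  buf <- readBin(con, "raw", sz)
  if (length(buf) < 140 || !identical(buf[129:132], charToRaw("DICM")))
    stop(sprintf("'%s' is not a DICOM file (missing DICM magic)", path),
         call. = FALSE)
  pos <- 133L   # first byte after the magic
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  explicit <- TRUE
  n <- length(buf)
  read_u16 <- function(at) as.integer(buf[at]) + 256L * as.integer(buf[at + 1L])
  read_u32 <- function(at) {
    as.integer(buf[at]) + 256 * as.integer(buf[at + 1L]) +
      65536 * as.integer(buf[at + 2L]) + 16777216 * as.integer(buf[at + 3L])
  }
  while (pos + 7L <= n) {
    group <- read_u16(pos); elem <- read_u16(pos + 2L)
    tag <- sprintf("%04X,%04X", group, elem)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (group == 0x0002 || explicit) {
      if (grepl("^[A-Z]{2}$", vr)) {
        if (vr %in% long_vrs) {
          len <- read_u32(pos + 8L); hdr <- 12L
        } else {
          len <- read_u16(pos + 6L); hdr <- 8L
        }
      } else if (group != 0x0002) {
        explicit <- FALSE
        vr <- "UN"; len <- read_u32(pos + 4L); hdr <- 8L
      } else {
        stop(sprintf("'%s': malformed DICOM header near byte %d", path, pos),
             call. = FALSE)
      }
    } else {
      vr <- "UN"; len <- read_u32(pos + 4L); hdr <- 8L
    }
    if (len == 4294967295) # undefined length (sequences) — not supported
      stop(sprintf("'%s': undefined-length DICOM elements are not supported",
                   path), call. = FALSE)
    start <- pos + hdr
    if (len > 0 && start + len - 1L > n)
      stop(sprintf("'%s': truncated DICOM element %s", path, tag),
           call. = FALSE)
    tags[[tag]] <- list(vr = vr,
                        bytes = if (len > 0) buf[start:(start + len - 1L)]
                                else raw(0))
    pos <- start + len
    if (group == 0x7FE0 && elem == 0x0010) break
  }
  tags
}

dcm_string <- function(tags, tag, default = NULL) {
  el <- tags[[tag]]
  if (is.null(el)) return(default)
  trimws(rawToChar(el$bytes[el$bytes != as.raw(0)]))
}

dcm_numbers <- function(tags, tag, default = NULL) {
  s <- dcm_string(tags, tag)
  if (is.null(s) || !nzchar(s)) return(default)
  as.double(strsplit(s, "\\\\")[[1]])
}

dcm_u16 <- function(tags, tag, default = NULL) {
  el <- tags[[tag]]
  if (is.null(el)) return(default)
  as.integer(el$bytes[1]) + 256L * as.integer(el$bytes[2])
}

read_dicom_series <- function(dir, side) {
  files <- sort(list.files(dir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (!length(files))
    stop(sprintf("DICOM directory '%s' contains no files", dir), call. = FALSE)
  slices <- vector("list", length(files))
  meta <- NULL
  order_key <- numeric(length(files))
  for (i in seq_along(files)) {
    tags <- read_dicom_file(files[i])
    rows <- dcm_u16(tags, "0028,0010"); cols <- dcm_u16(tags, "0028,0011")
    bits <- dcm_u16(tags, "0028,0100", 16L)
    signed <- identical(dcm_u16(tags, "0028,0103", 0L), 1L)
    if (is.null(rows) || is.null(cols))
      stop(sprintf("'%s': missing Rows/Columns", files[i]), call. = FALSE)
    if (bits != 16L)
      stop(sprintf("'%s': only 16-bit DICOM pixel data is supported (got %d)",
                   files[i], bits), call. = FALSE)
    px <- tags[["7FE0,0010"]]
    if (is.null(px))
      stop(sprintf("'%s': no PixelData element", files[i]), call. = FALSE)
    vals <- readBin(px$bytes, "integer", rows * cols, size = 2,
                    signed = signed, endian = "little")
    if (length(vals) != rows * cols)
      stop(sprintf("'%s': PixelData holds %d values, expected %d",
                   files[i], length(vals), rows * cols), call. = FALSE)
    slope <- dcm_numbers(tags, "0028,1053", 1)[1]
    inter <- dcm_numbers(tags, "0028,1052", 0)[1]
    spacing_rc <- dcm_numbers(tags, "0028,0030", c(1, 1))     # (row, col) mm
    thick <- dcm_numbers(tags, "0018,0050", 1)[1]
    geom <- c(rows, cols, spacing_rc, thick)
    if (is.null(meta)) meta <- geom
    else if (!isTRUE(all.equal(meta, geom)))
      stop(sprintf(
        "inconsistent slice geometry in '%s': '%s' disagrees with the first slice",
        dir, basename(files[i])), call. = FALSE)
    ipp <- dcm_numbers(tags, "0020,0032")
    inst <- dcm_numbers(tags, "0020,0013", i)[1]
    order_key[i] <- if (!is.null(ipp) && length(ipp) >= 3) ipp[3] else inst
    ## DICOM pixel order is row-major: fill a (cols x rows) matrix and flip
    slices[[i]] <- t(matrix(vals * slope + inter, nrow = cols, ncol = rows))
  }
  ord <- order(order_key)
  vox <- array(0, dim = c(length(files), meta[1], meta[2]))
  for (k in seq_along(ord)) vox[k, , ] <- slices[[ord[k]]]
  ct_volume(vox, spacing = c(meta[5], meta[3], meta[4]), side = side)
}
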