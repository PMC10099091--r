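strip_attrs <- function(arr) {
  d <- dim(arr)
  attributes(arr) <- list(dim = d)
  arr
}

#' Read a 3D volume from disk
#'
#' Supports NIfTI (`.nii`, `.nii.gz`), MetaImage (`.mha`, `.mhd` + raw) and
#' directories of single-frame DICOM slices (explicit VR little endian).
#' Stored intensities are taken as HU verbatim (after DICOM rescale
#' slope/intercept); no recalibration is applied.
#'
#' @param path File (NIfTI/MetaImage) or directory (DICOM series).
#' @param format One of `"nifti"`, `"metaimage"`, `"dicom_series"`, or
#'   `"auto"` to guess from the path.
#' @return A [volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "metaimage",
                                         "dicom_series")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    nifti = read_volume_nifti(path),
    metaimage = read_volume_meta(path),
    dicom_series = read_volume_dicom(path))
}

guess_format <- function(path) {
  if (dir.exists(path)) return("dicom_series")
  if (grepl("\\.nii(\\.gz)?$", path)) return("nifti")
  if (grepl("\\.(mha|mhd)$", path)) return("metaimage")
  stop("cannot guess volume format from path: ", path)
}

#' Write a 3D volume to disk
#'
#' @param v A [volume()].
#' @param path Destination file; format follows the extension (`.nii`,
#'   `.nii.gz`, `.mha`, `.mhd`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "dirgan_volume"))
  fmt <- guess_format(path)
  if (fmt == "nifti") write_nifti_array(v$data, v$spacing, v$origin, path)
  else if (fmt == "metaimage") write_volume_meta(v, path)
  else stop("unsupported output format for: ", path)
  invisible(path)
}

read_volume_nifti <- function(path) {
  if (!file.exists(path)) stop("cannot read volume, no such file: ", path)
  img <- RNifti::readNifti(path)
  arr <- strip_attrs(as.array(img))
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3) stop("expected a 3D NIfTI image: ", path)
  # spacing and origin come from the world matrix (the pixdim attribute is
  # not reliably populated by all writers); NIfTI world axes are RAS while
  # we keep plain voxel-grid axes, so magnitudes are taken.
  xf <- RNifti::xform(img)
  sp <- sqrt(colSums(xf[1:3, 1:3]^2))
  orig <- abs(xf[1:3, 4])
  volume(arr, spacing = sp, origin = orig)
}

write_nifti_array <- function(arr, spacing, origin, path) {
  img <- RNifti::asNifti(arr)
  mat <- diag(4)
  mat[1, 1] <- -spacing[1]
  mat[2, 2] <- -spacing[2]
  mat[3, 3] <- spacing[3]
  mat[1:3, 4] <- c(-origin[1], -origin[2], origin[3])
  # qform assignment renormalizes the rotation and loses anisotropic
  # scales; the sform carries the full affine faithfully
  RNifti::sform(img) <- structure(mat, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read/write a displacement field as 4D NIfTI
#'
#' The three displacement components (voxel units of the stored grid) are
#' stacked along the 4th dimension; the grid spacing is kept in the header.
#'
#' @param path NIfTI file path.
#' @return [read_dvf()]: a [dvf()]. [write_dvf()]: invisibly, `path`.
#' @export
read_dvf <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- strip_attrs(as.array(img))
  d <- dim(arr)
  if (length(d) == 5 && d[4] == 1) {
    arr <- array(arr, c(d[1:3], d[5]))
    d <- dim(arr)
  }
  if (length(d) != 4 || d[4] != 3)
    stop("expected a 4D NIfTI with 3 components: ", path)
  xf <- RNifti::xform(img)
  dvf(arr, spacing = sqrt(colSums(xf[1:3, 1:3]^2)))
}

#' @rdname read_dvf
#' @param d A [dvf()].
#' @export
write_dvf <- function(d, path) {
  stopifnot(inherits(d, "dirgan_dvf"))
  write_nifti_array(d$u, d$spacing, c(0, 0, 0), path)
}

# ------------------------------------------------------------- MetaImage ---

read_volume_meta <- function(path) {
  if (!file.exists(path)) stop("cannot read volume, no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (!length(line)) stop("MetaImage header truncated: ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["NDims"]], "3")) stop("only 3D MetaImage supported")
  if (identical(toupper(hdr[["CompressedData"]]), "TRUE"))
    stop("compressed MetaImage not supported: ", path)
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  sp <- if (!is.null(hdr[["ElementSpacing"]]))
    as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]]) else c(1, 1, 1)
  orig <- NULL
  for (k in c("Offset", "Position", "Origin"))
    if (!is.null(hdr[[k]])) orig <- as.numeric(strsplit(hdr[[k]], "\\s+")[[1]])
  if (is.null(orig)) orig <- c(0, 0, 0)
  type <- hdr[["ElementType"]]
  n <- prod(dims)
  msb <- identical(toupper(hdr[["ElementByteOrderMSB"]]), "TRUE") ||
    identical(toupper(hdr[["BinaryDataByteOrderMSB"]]), "TRUE")
  endian <- if (msb) "big" else "little"
  datafile <- hdr[["ElementDataFile"]]
  if (identical(datafile, "LOCAL")) {
    raw_con <- con
  } else {
    raw_path <- file.path(dirname(path), datafile)
    if (!file.exists(raw_path)) stop("MetaImage data file missing: ", raw_path)
    raw_con <- file(raw_path, "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  vals <- switch(type,
    MET_SHORT = readBin(raw_con, "integer", n, size = 2, signed = TRUE, endian = endian),
    MET_USHORT = readBin(raw_con, "integer", n, size = 2, signed = FALSE, endian = endian),
    MET_UCHAR = readBin(raw_con, "integer", n, size = 1, signed = FALSE, endian = endian),
    MET_FLOAT = readBin(raw_con, "numeric", n, size = 4, endian = endian),
    MET_DOUBLE = readBin(raw_con, "numeric", n, size = 8, endian = endian),
    stop("unsupported MetaImage ElementType: ", type))
  if (length(vals) != n) stop("MetaImage data shorter than DimSize: ", path)
  volume(array(as.numeric(vals), dims), spacing = sp, origin = orig)
}

write_volume_meta <- function(v, path) {
  dims <- dim(v$data)
  local_data <- grepl("\\.mha$", path)
  datafile <- if (local_data) "LOCAL" else sub("\\.mhd$", ".raw", basename(path))
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(dims, collapse = " ")),
    paste("ElementSpacing =", paste(v$spacing, collapse = " ")),
    paste("Offset =", paste(v$origin, collapse = " ")),
    "ElementType = MET_DOUBLE",
    paste("ElementDataFile =", datafile))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (local_data) {
    writeBin(as.numeric(v$data), con, size = 8, endian = "little")
  } else {
    rcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(as.numeric(v$data), rcon, size = 8, endian = "little")
  }
  invisible(path)
}

# ----------------------------------------------------------------- DICOM ---

# Minimal explicit-VR little-endian single-frame CT slice reader; enough for
# uncompressed exports and the synthetic test series written by
# write_dicom_series().
read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  u16 <- function(at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
  u32 <- function(at) sum(as.numeric(raw[at + 0:3]) * 256^(0:3))
  while (pos + 7L <= length(raw)) {
    grp <- u16(pos); ele <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); dstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); dstart <- pos + 8L
    }
    if (len == 4294967295) stop("undefined-length DICOM element unsupported: ", path)
    key <- sprintf("%04x%04x", grp, ele)
    tags[[key]] <- list(vr = vr, start = dstart, len = len)
    pos <- dstart + as.integer(len)
  }
  gets <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    trimws(rawToChar(raw[t$start + seq_len(t$len) - 1L]))
  }
  getn <- function(key) as.numeric(strsplit(gets(key), "\\\\")[[1]])
  rows <- u16(tags[["00280010"]]$start)
  cols <- u16(tags[["00280011"]]$start)
  ps <- getn("00280030")
  ipp <- getn("00200032")
  if (is.null(ipp)) stop("DICOM slice without ImagePositionPatient: ", path)
  slope <- if (!is.null(gets("00281053"))) getn("00281053") else 1
  inter <- if (!is.null(gets("00281052"))) getn("00281052") else 0
  bits <- u16(tags[["00280100"]]$start)
  if (bits != 16) stop("only 16-bit DICOM pixel data supported: ", path)
  pd <- tags[["7fe00010"]]
  if (is.null(pd)) stop("DICOM slice without pixel data: ", path)
  npix <- rows * cols
  con <- rawConnection(raw[pd$start + seq_len(2 * npix) - 1L])
  px <- readBin(con, "integer", npix, size = 2, signed = TRUE, endian = "little")
  close(con)
  # DICOM pixel data is row-major: x (column index) varies fastest
  slice <- matrix(px, nrow = cols, ncol = rows)
  list(pixels = slice * slope + inter,
       rows = rows, cols = cols, spacing_xy = rev(ps), pos = ipp)
}

read_volume_dicom <- function(path) {
  if (!dir.exists(path)) stop("cannot read DICOM series, no such directory: ", path)
  files <- sort(list.files(path, pattern = "\\.dcm$", full.names = TRUE))
  if (!length(files)) files <- sort(list.files(path, full.names = TRUE))
  if (!length(files)) stop("empty DICOM series directory: ", path)
  slices <- lapply(files, read_dicom_slice)
  z <- vapply(slices, function(s) s$pos[3], 0)
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  if (length(z) > 1) {
    dz <- diff(z)
    if (any(abs(dz - dz[1]) > 1e-4 * max(abs(dz[1]), 1)))
      stop("inconsistent DICOM slice spacing (missing or duplicate slice?) in: ",
           path)
    if (dz[1] <= 0) stop("non-increasing DICOM slice positions in: ", path)
  }
  nx <- slices[[1]]$cols; ny <- slices[[1]]$rows
  arr <- array(0, c(nx, ny, length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]$pixels
  sp_xy <- slices[[1]]$spacing_xy
  sp_z <- if (length(z) > 1) diff(z)[1] else 1
  volume(arr, spacing = c(sp_xy[1], sp_xy[2], sp_z),
         origin = c(slices[[1]]$pos[1], slices[[1]]$pos[2], z[1]))
}

# DICOM series writer (test plumbing): one explicit-VR little-endian CT
# slice file per z index.
write_dicom_series <- function(v, dir_path) {
  if (!dir.exists(dir_path)) dir.create(dir_path, recursive = TRUE)
  d <- dim(v$data)
  for (k in seq_len(d[3])) {
    slice <- round(v$data[, , k])
    path <- file.path(dir_path, sprintf("slice_%03d.dcm", k))
    con <- file(path, "wb")
    writeBin(raw(128), con)
    writeBin(charToRaw("DICM"), con)
    wtag <- function(grp, ele, vr, payload) {
      writeBin(as.integer(c(grp %% 256, grp %/% 256,
                            ele %% 256, ele %/% 256)), con, size = 1)
      writeBin(charToRaw(vr), con)
      if (vr %in% c("OB", "OW")) {
        writeBin(as.integer(c(0, 0)), con, size = 1)
        writeBin(as.integer(length(payload)), con, size = 4, endian = "little")
      } else {
        writeBin(as.integer(length(payload)), con, size = 2, endian = "little")
      }
      writeBin(payload, con)
    }
    str_pad <- function(s) {
      r <- charToRaw(s)
      if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))
      r
    }
    int2raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
    wtag(0x0020, 0x0032, "DS",
         str_pad(paste(c(v$origin[1:2], v$origin[3] + (k - 1) * v$spacing[3]),
                       collapse = "\\")))
    wtag(0x0028, 0x0010, "US", int2raw(d[2]))  # Rows
    wtag(0x0028, 0x0011, "US", int2raw(d[1]))  # Columns
    wtag(0x0028, 0x0030, "DS", str_pad(paste(v$spacing[c(2, 1)], collapse = "\\")))
    wtag(0x0028, 0x0100, "US", int2raw(16))    # BitsAllocated
    wtag(0x0028, 0x0103, "US", int2raw(1))     # PixelRepresentation (signed)
    wtag(0x0028, 0x1052, "DS", str_pad("0"))
    wtag(0x0028, 0x1053, "DS", str_pad("1"))
    # pixel data: row-major, x fastest — column-major order of slice[x, y]
    px <- as.integer(slice)
    wtag(0x7fe0, 0x0010, "OW",
         writeBin(px, raw(), size = 2, endian = "little"))
    close(con)
  }
  invisible(dir_path)
}

# -------------------------------------------------------------- landmarks ---

#' Read/write landmark tables
#'
#' Landmarks are stored as CSV with header `label,x_mm,y_mm,z_mm` in
#' physical millimetre coordinates.
#'
#' @param path CSV file path.
#' @return [read_landmarks()]: a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("cannot read landmarks, no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have header label,x_mm,y_mm,z_mm: ", path)
  landmark_set(df$label, as.matrix(df[, c("x_mm", "y_mm", "z_mm")]))
}

#' @rdname read_landmarks
#' @param ls A [landmark_set()].
#' @export
write_landmarks <- function(ls, path) {
  stopifnot(inherits(ls, "dirgan_landmarks"))
  df <- data.frame(label = ls$labels,
                   x_mm = ls$coords[, 1],
                   y_mm = ls$coords[, 2],
                   z_mm = ls$coords[, 3])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
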