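#' Read a 3D volume from NIfTI or MetaImage
#'
#' NIfTI (`.nii`, `.nii.gz`) is read through RNifti; MetaImage (`.mhd` with a
#' companion `.raw`, or self-contained `.mha`) is parsed directly. Values,
#' spacing and origin are taken from the header; the unit tag is supplied by
#' the caller (images on disk do not carry one).
#'
#' @param path Path to the image file.
#' @param unit Unit tag for the returned volume.
#' @return A `volume_grid`.
#' @export
read_volume <- function(path, unit = "unitless") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(sub("^.*?(\\.nii\\.gz|\\.[a-z]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 3L)
      stop(sprintf("expected a 3D image, got %dD", length(dim(img))), call. = FALSE)
    vals <- array(as.double(img), dim(img))
    spacing <- RNifti::pixdim(img)[seq_len(3)]
    # axis-aligned, non-flipped orientation assumed (oblique matrices are out
    # of scope); the translation column of the xform is the first voxel center
    xf <- try(RNifti::xform(img), silent = TRUE)
    origin <- c(0, 0, 0)
    if (!inherits(xf, "try-error") && is.matrix(xf))
      origin <- xf[seq_len(3), 4]
    return(volume_grid(vals, spacing, origin, unit))
  }
  if (ext %in% c(".mhd", ".mha")) return(read_metaimage(path, unit))
  stop(sprintf("unsupported image format: %s", ext), call. = FALSE)
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' Data are stored as float32; a read/write round trip reproduces values at
#' float32 precision. The format is chosen from the file extension.
#'
#' @param vol A `volume_grid`.
#' @param path Output path (`.nii`, `.nii.gz`, `.mhd`, `.mha`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory does not exist: %s", dirname(path)), call. = FALSE)
  ext <- tolower(sub("^.*?(\\.nii\\.gz|\\.[a-z]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    vals <- vol$values
    attr(vals, "pixdim") <- vol$spacing
    img <- RNifti::asNifti(vals, datatype = "float")
    m <- diag(4)
    diag(m)[seq_len(3)] <- vol$spacing
    m[seq_len(3), 4] <- vol$origin
    RNifti::sform(img) <- structure(m, code = 2L)
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  if (ext %in% c(".mhd", ".mha")) return(write_metaimage(vol, path))
  stop(sprintf("unsupported image format: %s", ext), call. = FALSE)
}

meta_type_map <- c(MET_FLOAT = "float", MET_DOUBLE = "double",
                   MET_SHORT = "short", MET_USHORT = "ushort",
                   MET_UCHAR = "uchar", MET_CHAR = "char", MET_INT = "int")

read_metaimage <- function(path, unit = "unitless") {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated MetaImage header", call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) next
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  ndims <- as.integer(hdr$NDims %||% "3")
  if (ndims != 3L)
    stop(sprintf("expected a 3D image, got %dD", ndims), call. = FALSE)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr$Offset %||% hdr$Position %||% hdr$Origin %||%
                                  "0 0 0", "\\s+")[[1]])
  if (isTRUE(toupper(hdr$CompressedData %||% "FALSE") == "TRUE"))
    stop("compressed MetaImage data not supported", call. = FALSE)
  type <- hdr$ElementType %||% "MET_FLOAT"
  if (!type %in% names(meta_type_map))
    stop(sprintf("unsupported ElementType: %s", type), call. = FALSE)
  msb <- isTRUE(toupper(hdr$BinaryDataByteOrderMSB %||% "FALSE") == "TRUE")
  n <- prod(dims)
  sizes <- c(float = 4L, double = 8L, short = 2L, ushort = 2L, uchar = 1L,
             char = 1L, int = 4L)
  what <- meta_type_map[[type]]
  endian <- if (msb) "big" else "little"
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw <- read_meta_bin(con, what, n, sizes[[what]], endian)
  } else {
    datapath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(datapath))
      stop(sprintf("MetaImage data file not found: %s", datapath), call. = FALSE)
    con2 <- file(datapath, "rb")
    on.exit(close(con2), add = TRUE)
    raw <- read_meta_bin(con2, what, n, sizes[[what]], endian)
  }
  vals <- array(as.double(raw), dim = dims)
  volume_grid(vals, spacing, origin, unit)
}

read_meta_bin <- function(con, what, n, size, endian) {
  type <- switch(what,
                 float = , double = "double",
                 "integer")
  signed <- !what %in% c("uchar", "ushort")
  readBin(con, what = type, n = n, size = size, signed = signed, endian = endian)
}

write_metaimage <- function(vol, path) {
  ext <- tolower(sub("^.*\\.", ".", path))
  local <- ext == ".mha"
  dataname <- if (local) "LOCAL" else sub("\\.mhd$", ".raw", basename(path))
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           paste("DimSize =", paste(dim(vol$values), collapse = " ")),
           paste("ElementSpacing =", paste(format(vol$spacing, digits = 17), collapse = " ")),
           paste("Offset =", paste(format(vol$origin, digits = 17), collapse = " ")),
           "ElementType = MET_FLOAT",
           paste("ElementDataFile =", dataname))
  con <- file(path, "wb")
  writeLines(hdr, con)
  if (local) {
    writeBin(as.double(vol$values), con, size = 4L, endian = "little")
    close(con)
  } else {
    close(con)
    con2 <- file(file.path(dirname(path), dataname), "wb")
    writeBin(as.double(vol$values), con2, size = 4L, endian = "little")
    close(con2)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a JSON run manifest
#'
#' Records the parameters and seeds of a pipeline stage next to its outputs
#' so a run can be reproduced exactly.
#'
#' @param params Named list of parameters (must be JSON-serializable).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(params, path) {
  params$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

log_msg <- function(fmt, ...) {
  message(sprintf(paste0("[sctqa] ", fmt), ...))
}
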