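#' Read a 3D volume from NRRD, MetaImage or NIfTI
#'
#' Spacing and origin are taken from the file header; the voxel-center, 0-based
#' world convention of [image_volume()] applies. Supported formats: NRRD
#' (\code{.nrrd}; raw, ascii/text or gzip encodings, attached data), MetaImage
#' (\code{.mha} with local data, \code{.mhd} with a detached raw file) and
#' NIfTI (\code{.nii}, \code{.nii.gz}, via RNifti). Direction matrices other
#' than axis-aligned scaling are rejected.
#'
#' @param path Path to the volume file.
#' @return An \code{image_volume}.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z0-9]+)$", "\\1", basename(path)))
  switch(ext,
    ".nrrd" = read_nrrd(path),
    ".mha" = read_metaimage(path),
    ".mhd" = read_metaimage(path),
    ".nii" = read_nifti_volume(path),
    ".nii.gz" = read_nifti_volume(path),
    stop("unsupported volume format: ", ext)
  )
}

#' Write a 3D volume
#'
#' Format is chosen from the file extension (see [read_volume()]). NRRD and
#' MetaImage are written with little-endian binary data by default.
#'
#' @param vol An \code{image_volume}.
#' @param path Output path.
#' @param encoding For NRRD only: "raw", "ascii" or "gzip".
#' @return Invisibly, \code{path}.
#' @export
write_volume <- function(vol, path, encoding = "raw") {
  if (!is_image_volume(vol)) stop("`vol` must be an image_volume")
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z0-9]+)$", "\\1", basename(path)))
  switch(ext,
    ".nrrd" = write_nrrd(vol, path, encoding),
    ".mha" = write_metaimage(vol, path, local = TRUE),
    ".mhd" = write_metaimage(vol, path, local = FALSE),
    ".nii" = write_nifti_volume(vol, path),
    ".nii.gz" = write_nifti_volume(vol, path),
    stop("unsupported volume format: ", ext)
  )
  invisible(path)
}

## ---- NIfTI (RNifti) ----

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  if (max(abs(rot - diag(spacing))) > 1e-6 * max(spacing))
    stop("oblique/rotated NIfTI volumes are not supported")
  data <- as.array(img)
  if (length(dim(data)) != 3L) stop("only 3D NIfTI volumes are supported")
  image_volume(data, spacing = spacing, origin = xf[1:3, 4])
}

write_nifti_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
}

## ---- NRRD ----

nrrd_r_type <- function(type) {
  type <- tolower(type)
  if (type %in% c("double", "float64")) list(what = "double", size = 8L, double = TRUE)
  else if (type %in% c("float", "float32")) list(what = "double", size = 4L, double = TRUE)
  else if (type %in% c("signed char", "int8", "int8_t")) list(what = "integer", size = 1L, signed = TRUE)
  else if (type %in% c("uchar", "unsigned char", "uint8", "uint8_t")) list(what = "integer", size = 1L, signed = FALSE)
  else if (type %in% c("short", "short int", "signed short", "int16", "int16_t")) list(what = "integer", size = 2L, signed = TRUE)
  else if (type %in% c("ushort", "unsigned short", "uint16", "uint16_t")) list(what = "integer", size = 2L, signed = FALSE)
  else if (type %in% c("int", "signed int", "int32", "int32_t")) list(what = "integer", size = 4L, signed = TRUE)
  else if (type %in% c("uint", "unsigned int", "uint32", "uint32_t")) list(what = "integer", size = 4L, signed = FALSE)
  else stop("unsupported NRRD type: ", type)
}

parse_nrrd_vector <- function(s) {
  s <- gsub("[()]", "", trimws(s))
  as.numeric(strsplit(s, ",")[[1]])
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD000", magic)) stop("not a NRRD file (bad magic): ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("corrupt NRRD header: no blank line before data")
    if (line == "") break
    if (grepl("^#", line)) next
    m <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(m) != 3L) stop("corrupt NRRD header line: ", line)
    fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  if (is.null(fields$dimension) || as.integer(fields$dimension) != 3L)
    stop("only 3D NRRD volumes are supported")
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  ti <- nrrd_r_type(fields$type)
  encoding <- tolower(if (is.null(fields$encoding)) "raw" else fields$encoding)
  endian <- if (!is.null(fields$endian) && grepl("big", fields$endian)) "big" else "little"
  if (!is.null(fields[["data file"]]) || !is.null(fields$datafile))
    stop("detached NRRD data files are not supported")

  spacing <- c(1, 1, 1)
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space directions"]])) {
    toks <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    if (length(toks) != 3L) stop("corrupt NRRD space directions")
    dirs <- vapply(toks, parse_nrrd_vector, numeric(3))
    if (max(abs(dirs - diag(sqrt(colSums(dirs^2))))) > 1e-9 * max(abs(dirs)))
      stop("oblique NRRD volumes are not supported")
    spacing <- sqrt(colSums(dirs^2))
  } else if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  }
  if (!is.null(fields[["space origin"]]))
    origin <- parse_nrrd_vector(fields[["space origin"]])

  n <- prod(sizes)
  data <- switch(encoding,
    raw = readBin(con, ti$what, n = n, size = ti$size, endian = endian,
                  signed = if (ti$what == "integer") isTRUE(ti$signed) || ti$size > 2L else TRUE),
    ascii = , text = , txt = scan(con, what = double(), n = n, quiet = TRUE),
    gzip = , gz = {
      gz <- gzcon(con)
      readBin(gz, ti$what, n = n, size = ti$size, endian = endian,
              signed = if (ti$what == "integer") isTRUE(ti$signed) || ti$size > 2L else TRUE)
    },
    stop("unsupported NRRD encoding: ", encoding)
  )
  if (length(data) != n) stop("truncated NRRD data in ", path)
  image_volume(array(as.double(data), dim = sizes), spacing = spacing, origin = origin)
}

write_nrrd <- function(vol, path, encoding = "raw") {
  encoding <- match.arg(encoding, c("raw", "ascii", "gzip"))
  d <- dim(vol$data)
  hdr <- c(
    "NRRD0004",
    "# generated by bonecho",
    "type: double",
    "dimension: 3",
    "space dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            vol$spacing[1], vol$spacing[2], vol$spacing[3]),
    "kinds: domain domain domain",
    if (encoding != "ascii") "endian: little",
    sprintf("encoding: %s", encoding),
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            vol$origin[1], vol$origin[2], vol$origin[3]),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (encoding == "raw") {
    writeBin(as.vector(vol$data), con, size = 8L, endian = "little")
  } else if (encoding == "ascii") {
    writeLines(paste(format(as.vector(vol$data), digits = 17, trim = TRUE,
                            scientific = TRUE), collapse = " "), con)
  } else {
    gz <- gzcon(con)
    writeBin(as.vector(vol$data), gz, size = 8L, endian = "little")
    flush(gz)
  }
  invisible(path)
}

## ---- MetaImage ----

met_r_type <- function(type) {
  switch(toupper(type),
    MET_DOUBLE = list(what = "double", size = 8L),
    MET_FLOAT = list(what = "double", size = 4L),
    MET_UCHAR = list(what = "integer", size = 1L, signed = FALSE),
    MET_CHAR = list(what = "integer", size = 1L, signed = TRUE),
    MET_SHORT = list(what = "integer", size = 2L, signed = TRUE),
    MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
    MET_INT = list(what = "integer", size = 4L, signed = TRUE),
    MET_UINT = list(what = "integer", size = 4L, signed = TRUE),
    stop("unsupported MetaImage element type: ", type)
  )
}

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list()
  data_file <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("corrupt MetaImage header: no ElementDataFile")
    m <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(m) != 3L) stop("corrupt MetaImage header line: ", line)
    key <- m[2]; val <- trimws(m[3])
    if (key == "ElementDataFile") { data_file <- val; break }
    fields[[key]] <- val
  }
  if (is.null(fields$NDims) || as.integer(fields$NDims) != 3L)
    stop("only 3D MetaImage volumes are supported")
  sizes <- as.integer(strsplit(fields$DimSize, "\\s+")[[1]])
  ti <- met_r_type(fields$ElementType)
  spacing <- if (!is.null(fields$ElementSpacing))
    as.numeric(strsplit(fields$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- c(0, 0, 0)
  for (k in c("Offset", "Origin", "Position"))
    if (!is.null(fields[[k]]))
      origin <- as.numeric(strsplit(fields[[k]], "\\s+")[[1]])
  msb <- isTRUE(toupper(fields$BinaryDataByteOrderMSB %||% "FALSE") == "TRUE") ||
    isTRUE(toupper(fields$ElementByteOrderMSB %||% "FALSE") == "TRUE")
  endian <- if (msb) "big" else "little"
  compressed <- isTRUE(toupper(fields$CompressedData %||% "FALSE") == "TRUE")

  n <- prod(sizes)
  read_payload <- function(raw_bytes) {
    if (compressed) raw_bytes <- memDecompress(raw_bytes, type = "gzip")
    readBin(raw_bytes, ti$what, n = n, size = ti$size, endian = endian,
            signed = if (ti$what == "integer") isTRUE(ti$signed) || ti$size > 2L else TRUE)
  }
  if (identical(data_file, "LOCAL")) {
    bytes <- readBin(con, "raw", n = file.info(path)$size)
    data <- read_payload(bytes)
  } else {
    raw_path <- file.path(dirname(path), data_file)
    if (!file.exists(raw_path)) stop("detached data file not found: ", raw_path)
    data <- read_payload(readBin(raw_path, "raw", n = file.info(raw_path)$size))
  }
  if (length(data) != n) stop("truncated MetaImage data in ", path)
  image_volume(array(as.double(data), dim = sizes), spacing = spacing, origin = origin)
}

write_metaimage <- function(vol, path, local = TRUE) {
  d <- dim(vol$data)
  raw_name <- paste0(sub("\\.[Mm][Hh][DdAa]$", "", basename(path)), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.17g %.17g %.17g",
            vol$spacing[1], vol$spacing[2], vol$spacing[3]),
    sprintf("Offset = %.17g %.17g %.17g",
            vol$origin[1], vol$origin[2], vol$origin[3]),
    "ElementType = MET_DOUBLE",
    sprintf("ElementDataFile = %s", if (local) "LOCAL" else raw_name)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (local) {
    writeBin(as.vector(vol$data), con, size = 8L, endian = "little")
  } else {
    rcon <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(as.vector(vol$data), rcon, size = 8L, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
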