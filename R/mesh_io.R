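#' Read a triangle mesh from PLY or STL
#'
#' PLY: ascii and binary_little_endian, float/double vertex properties,
#' triangular faces. STL: binary and ascii; STL triangle soups are welded on
#' exactly coincident vertices to recover connectivity.
#'
#' @param path Path to the mesh file.
#' @param label Role tag stored on the mesh.
#' @return A \code{surface_mesh} with vertices in mm.
#' @export
read_mesh <- function(path, label = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = read_ply(path, label),
    stl = read_stl(path, label),
    stop("unsupported mesh format: .", ext)
  )
}

#' Write a triangle mesh to PLY or STL
#'
#' PLY is written ascii; STL is written binary. Writing an empty mesh is an
#' error.
#'
#' @param mesh A \code{surface_mesh}.
#' @param path Output path (.ply or .stl).
#' @return Invisibly, \code{path}.
#' @export
write_mesh <- function(mesh, path) {
  if (!inherits(mesh, "surface_mesh")) stop("`mesh` must be a surface_mesh")
  if (nrow(mesh$vertices) == 0L || nrow(mesh$faces) == 0L)
    stop("refusing to write an empty mesh")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = write_ply(mesh, path),
    stl = write_stl(mesh, path),
    stop("unsupported mesh format: .", ext)
  )
  invisible(path)
}

## ---- PLY ----

read_ply <- function(path, label = "") {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readLines(con, n = 1L, warn = FALSE), "ply"))
    stop("not a PLY file: ", path)
  fmt <- NULL
  elements <- list() # list of list(name, count, props = data.frame(type, name))
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("corrupt PLY header")
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    if (toks[1] == "comment") next
    if (toks[1] == "format") { fmt <- toks[2]; next }
    if (toks[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = toks[2], count = as.integer(toks[3]), props = list())
      next
    }
    if (toks[1] == "property") {
      cur$props[[length(cur$props) + 1L]] <- toks[-1]
      next
    }
    if (toks[1] == "end_header") { if (!is.null(cur)) elements[[cur$name]] <- cur; break }
  }
  if (is.null(elements$vertex)) stop("PLY without vertex element")
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)

  ply_size <- function(t) switch(t, char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
    short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
    int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
    float = 4L, float32 = 4L, double = 8L, float64 = 8L,
    stop("unsupported PLY type: ", t))
  ply_what <- function(t) if (t %in% c("float", "float32", "double", "float64")) "double" else "integer"

  verts <- NULL; faces <- NULL
  if (fmt == "ascii") {
    lines <- readLines(con, warn = FALSE)
    pos <- 0L
    for (el in elements) {
      if (el$count == 0L) next
      block <- lines[(pos + 1L):(pos + el$count)]
      pos <- pos + el$count
      if (el$name == "vertex") {
        pn <- vapply(el$props, function(p) p[length(p)], "")
        vals <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), as.numeric))
        verts <- vals[, match(c("x", "y", "z"), pn), drop = FALSE]
      } else if (el$name == "face") {
        fl <- lapply(strsplit(trimws(block), "\\s+"), as.integer)
        if (any(vapply(fl, `[`, 1L, 1L) != 3L))
          stop("only triangular PLY faces are supported")
        faces <- do.call(rbind, lapply(fl, function(x) x[2:4])) + 1L
      }
    }
  } else {
    for (el in elements) {
      if (el$name == "vertex") {
        types <- vapply(el$props, `[`, "", 1L)
        pn <- vapply(el$props, function(p) p[length(p)], "")
        if (any(types == "list")) stop("list properties on vertices unsupported")
        sizes <- vapply(types, ply_size, 1L)
        verts <- matrix(0, el$count, 3)
        same <- length(unique(types)) == 1L
        if (same) {
          all_vals <- readBin(con, ply_what(types[1]), n = el$count * length(types),
                              size = sizes[1], endian = "little",
                              signed = !(sizes[1] <= 2 && grepl("^u", types[1])))
          m <- matrix(all_vals, ncol = length(types), byrow = TRUE)
          verts <- m[, match(c("x", "y", "z"), pn), drop = FALSE]
        } else {
          for (i in seq_len(el$count)) {
            row <- numeric(length(types))
            for (j in seq_along(types))
              row[j] <- readBin(con, ply_what(types[j]), n = 1L, size = sizes[j],
                                endian = "little",
                                signed = !(sizes[j] <= 2 && grepl("^u", types[j])))
            verts[i, ] <- row[match(c("x", "y", "z"), pn)]
          }
        }
      } else if (el$name == "face") {
        p <- el$props[[1]]
        if (p[1] != "list") stop("unsupported face property")
        cs <- ply_size(p[2]); is <- ply_size(p[3])
        faces <- matrix(0L, el$count, 3)
        for (i in seq_len(el$count)) {
          cnt <- readBin(con, "integer", n = 1L, size = cs, endian = "little",
                         signed = !(cs <= 2 && grepl("^u", p[2])))
          idx <- readBin(con, "integer", n = cnt, size = is, endian = "little")
          if (cnt != 3L) stop("only triangular PLY faces are supported")
          faces[i, ] <- idx + 1L
        }
      } else {
        # skip unknown element payload conservatively (ascii-only safe); bail out
        if (el$count > 0) stop("unsupported PLY element: ", el$name)
      }
    }
  }
  storage.mode(verts) <- "double"
  surface_mesh(verts, if (is.null(faces)) matrix(integer(), 0, 3) else faces, label)
}

write_ply <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  writeLines(c(
    "ply", "format ascii 1.0", "comment generated by bonecho",
    sprintf("element vertex %d", nv),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nf),
    "property list uchar int vertex_indices",
    "end_header"), con, sep = "\n")
  vtxt <- apply(mesh$vertices, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE), collapse = " "))
  ftxt <- apply(mesh$faces - 1L, 1, function(r) paste(c(3L, r), collapse = " "))
  writeLines(c(vtxt, ftxt), con, sep = "\n")
  invisible(path)
}

## ---- STL ----

read_stl <- function(path, label = "") {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = 80L)
  is_ascii <- identical(rawToChar(head[1:5]), "solid")
  if (is_ascii) {
    # verify: binary STL may also start with 'solid'; check triangle count math
    ntri_guess <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (length(ntri_guess) == 1L && sz == 84 + 50 * as.numeric(ntri_guess))
      is_ascii <- FALSE
  }
  if (is_ascii) {
    close(con); on.exit(NULL)
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    tri <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(x) as.numeric(x[2:4])))
  } else {
    seek(con, 80L)
    ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    payload <- readBin(con, "raw", n = 50L * ntri)
    m <- matrix(payload, nrow = 50L)
    tri <- matrix(0, ntri * 3L, 3L)
    for (v in 0:2) {
      off <- 12L + 12L * v
      for (c in 0:2) {
        bytes <- m[(off + 4L * c + 1L):(off + 4L * c + 4L), , drop = FALSE]
        tri[seq_len(ntri) * 3L - 2L + v, c + 1L] <-
          readBin(as.vector(bytes), "double", n = ntri, size = 4L, endian = "little")
      }
    }
  }
  if (is.null(tri) || nrow(tri) %% 3L != 0L) stop("corrupt STL file: ", path)
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "_")
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  verts <- tri[uk, , drop = FALSE]
  faces <- matrix(vid, ncol = 3L, byrow = TRUE)
  surface_mesh(verts, faces, label)
}

write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw(sprintf("%-79s", "bonecho binary STL")), as.raw(0L)), con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  v <- mesh$vertices
  for (i in seq_len(nf)) {
    a <- v[mesh$faces[i, 1], ]; b <- v[mesh$faces[i, 2], ]; cc <- v[mesh$faces[i, 3], ]
    nrm <- c((b - a)[2] * (cc - a)[3] - (b - a)[3] * (cc - a)[2],
             (b - a)[3] * (cc - a)[1] - (b - a)[1] * (cc - a)[3],
             (b - a)[1] * (cc - a)[2] - (b - a)[2] * (cc - a)[1])
    nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
    writeBin(as.numeric(c(nrm, a, b, cc)), con, size = 4L, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
  invisible(path)
}
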