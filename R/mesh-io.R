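#' Read a triangular mesh from file
#'
#' Supports PLY (ascii and binary little-endian), Wavefront OBJ (`v`/`f`
#' records) and legacy VTK POLYDATA.  Polygonal faces with more than three
#' vertices are triangulated fan-wise; vertex order is preserved.  Extra
#' per-vertex scalar properties (PLY properties beyond x/y/z, VTK
#' `POINT_DATA` scalars) are returned in the mesh's `vertex_data`.
#'
#' @param path path to the mesh file.
#' @param format one of `"ply"`, `"obj"`, `"vtk"` or `"auto"` (guess from
#'   the file extension).
#' @return a [trimesh()].
#' @export
read_mesh <- function(path, format = c("auto", "ply", "obj", "vtk")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", basename(path)))
    format <- switch(ext, ply = "ply", obj = "obj", vtk = "vtk",
                     stop("cannot guess mesh format from extension '.",
                          ext, "'"))
  }
  switch(format,
         ply = read_ply(path),
         obj = read_obj(path),
         vtk = read_vtk(path))
}

#' Write a triangular mesh to file
#'
#' Counterpart of [read_mesh()]: `read_mesh(write_mesh(m, p), p)` reproduces
#' vertices within floating-point round-trip and faces exactly.  Per-vertex
#' scalar attachments are written as extra PLY vertex properties or VTK
#' `POINT_DATA` scalars (OBJ has no standard slot for them and they are
#' silently dropped there).
#'
#' @param mesh a [trimesh()].
#' @param path output path.
#' @param format `"ply"`, `"obj"`, `"vtk"` or `"auto"` (from extension).
#' @param binary for PLY only: write binary little-endian instead of ascii.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply", "obj", "vtk"),
                       binary = FALSE) {
  stopifnot(inherits(mesh, "trimesh"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", basename(path)))
    format <- switch(ext, ply = "ply", obj = "obj", vtk = "vtk",
                     stop("cannot guess mesh format from extension '.",
                          ext, "'"))
  }
  switch(format,
         ply = write_ply(mesh, path, binary = binary),
         obj = write_obj(mesh, path),
         vtk = write_vtk(mesh, path))
  invisible(path)
}

## ---- PLY ------------------------------------------------------------------

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_is_float <- function(type) type %in% c("float", "float32",
                                           "double", "float64")

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL
  elements <- list()   # list of list(name, count, props = data.frame)
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of PLY header")
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(tok) == 0L || tok[1L] == "comment") next
    if (tok[1L] == "format") {
      fmt <- tok[2L]
    } else if (tok[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2L], count = as.integer(tok[3L]),
                  props = list())
    } else if (tok[1L] == "property") {
      if (tok[2L] == "list") {
        cur$props[[tok[5L]]] <- list(list = TRUE, count_type = tok[3L],
                                     value_type = tok[4L])
      } else {
        cur$props[[tok[3L]]] <- list(list = FALSE, type = tok[2L])
      }
    } else if (tok[1L] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)
  if (fmt == "ascii") {
    dat <- read_ply_ascii(con, elements)
  } else {
    dat <- read_ply_binary(con, elements)
  }
  vtab <- dat$vertex
  if (is.null(vtab)) stop("PLY file has no vertex element")
  verts <- as.matrix(vtab[, c("x", "y", "z")])
  extra <- setdiff(names(vtab), c("x", "y", "z"))
  vdata <- if (length(extra)) vtab[, extra, drop = FALSE] else NULL
  faces <- triangulate_polys(dat$face_polys)
  trimesh(verts, faces, vertex_data = vdata)
}

read_ply_ascii <- function(con, elements) {
  txt <- readLines(con)
  txt <- txt[nzchar(trimws(txt))]
  pos <- 0L
  out <- list(face_polys = list())
  for (el in elements) {
    rows <- txt[pos + seq_len(el$count)]
    pos <- pos + el$count
    toks <- strsplit(trimws(rows), "\\s+")
    if (any(vapply(el$props, `[[`, TRUE, "list"))) {
      polys <- lapply(toks, function(tk) {
        n <- as.integer(tk[1L])
        as.integer(tk[1L + seq_len(n)]) + 1L
      })
      if (el$name == "face") out$face_polys <- polys
    } else {
      nm <- names(el$props)
      mat <- do.call(rbind, lapply(toks, function(tk)
        as.numeric(tk[seq_along(nm)])))
      tab <- as.data.frame(mat)
      names(tab) <- nm
      out[[el$name]] <- tab
    }
  }
  out
}

read_ply_binary <- function(con, elements) {
  out <- list(face_polys = list())
  for (el in elements) {
    nm <- names(el$props)
    has_list <- any(vapply(el$props, `[[`, TRUE, "list"))
    if (!has_list) {
      # fixed-size rows: read the whole block and slice per property
      sizes <- vapply(el$props, function(p) ply_type_size[[p$type]], 1L)
      row_bytes <- sum(sizes)
      raw <- readBin(con, "raw", n = el$count * row_bytes)
      tab <- vector("list", length(nm))
      off <- 0L
      for (k in seq_along(nm)) {
        p <- el$props[[k]]
        idx <- as.vector(outer(off + seq_len(sizes[k]),
                               (seq_len(el$count) - 1L) * row_bytes, `+`))
        bytes <- raw[idx]
        what <- if (ply_is_float(p$type)) "double" else "integer"
        tab[[k]] <- readBin(bytes, what, n = el$count,
                            size = sizes[k], endian = "little",
                            signed = !p$type %in% c("uchar", "uint8",
                                                    "ushort", "uint16"))
        off <- off + sizes[k]
      }
      tab <- as.data.frame(tab)
      names(tab) <- nm
      out[[el$name]] <- tab
    } else {
      polys <- vector("list", el$count)
      p <- el$props[[1L]]
      csz <- ply_type_size[[p$count_type]]
      vsz <- ply_type_size[[p$value_type]]
      for (i in seq_len(el$count)) {
        n <- readBin(con, "integer", n = 1L, size = csz,
                     endian = "little", signed = csz > 1L)
        polys[[i]] <- readBin(con, "integer", n = n, size = vsz,
                              endian = "little") + 1L
      }
      if (el$name == "face") out$face_polys <- polys
    }
  }
  out
}

write_ply <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  vd <- mesh$vertex_data
  extra <- if (!is.null(vd)) names(vd) else character()
  hdr <- c("ply",
           paste("format",
                 if (binary) "binary_little_endian" else "ascii", "1.0"),
           paste("element vertex", nrow(v)),
           "property double x", "property double y", "property double z",
           if (length(extra)) paste("property double", extra) else character(),
           paste("element face", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  vmat <- cbind(v, if (length(extra)) as.matrix(vd[extra]) else NULL)
  if (binary) {
    writeBin(as.vector(t(vmat)), con, size = 8L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4L, endian = "little")
    }
  } else {
    writeLines(apply(vmat, 1L, function(r)
      paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
            collapse = " ")), con)
    writeLines(paste(3L, f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L), con)
  }
}

## ---- OBJ ------------------------------------------------------------------

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(txt), "\\s+")
  tag <- vapply(toks, function(tk) if (length(tk)) tk[1L] else "", "")
  vt <- toks[tag == "v"]
  verts <- do.call(rbind, lapply(vt, function(tk) as.numeric(tk[2:4])))
  ft <- toks[tag == "f"]
  polys <- lapply(ft, function(tk) {
    # "f 1 2 3", "f 1/1 2/2 3/3" or "f 1//1 ..." -> leading index only
    as.integer(sub("/.*", "", tk[-1L]))
  })
  if (is.null(verts)) stop("OBJ file has no vertices: ", path)
  trimesh(verts, triangulate_polys(polys))
}

write_obj <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  lines <- c(paste("v",
                   format(v[, 1L], digits = 17, trim = TRUE),
                   format(v[, 2L], digits = 17, trim = TRUE),
                   format(v[, 3L], digits = 17, trim = TRUE)),
             paste("f", f[, 1L], f[, 2L], f[, 3L]))
  writeLines(lines, path)
}

## ---- VTK legacy POLYDATA --------------------------------------------------

read_vtk <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (!grepl("^# vtk DataFile", txt[1L]))
    stop("not a legacy VTK file: ", path)
  if (!any(grepl("^ASCII", toupper(trimws(txt)))))
    stop("only ASCII legacy VTK files are supported")
  if (!any(grepl("^DATASET\\s+POLYDATA", toupper(trimws(txt)))))
    stop("only DATASET POLYDATA is supported")
  words <- strsplit(paste(txt, collapse = " "), "\\s+")[[1L]]
  words <- words[nzchar(words)]
  ip <- match("POINTS", toupper(words))
  n_pts <- as.integer(words[ip + 1L])
  coords <- as.numeric(words[ip + 2L + seq_len(3L * n_pts)])
  verts <- matrix(coords, ncol = 3L, byrow = TRUE)
  ic <- match("POLYGONS", toupper(words))
  if (is.na(ic)) stop("VTK file has no POLYGONS section")
  n_poly <- as.integer(words[ic + 1L])
  total <- as.integer(words[ic + 2L])
  cells <- as.integer(words[ic + 2L + seq_len(total)])
  polys <- vector("list", n_poly)
  pos <- 1L
  for (i in seq_len(n_poly)) {
    n <- cells[pos]
    polys[[i]] <- cells[pos + seq_len(n)] + 1L
    pos <- pos + n + 1L
  }
  vdata <- NULL
  ipd <- match("POINT_DATA", toupper(words))
  if (!is.na(ipd)) {
    vdata <- data.frame(row.names = seq_len(n_pts))
    j <- ipd
    while (!is.na(j <- match_from("SCALARS", words, j + 1L))) {
      nm <- words[j + 1L]
      k <- match_from("LOOKUP_TABLE", words, j)
      vals <- as.numeric(words[k + 1L + seq_len(n_pts)])
      vdata[[nm]] <- vals
      j <- k
    }
    if (ncol(vdata) == 0L) vdata <- NULL
  }
  trimesh(verts, triangulate_polys(polys), vertex_data = vdata)
}

match_from <- function(what, words, from) {
  if (from > length(words)) return(NA_integer_)
  hit <- match(what, toupper(words[from:length(words)]))
  if (is.na(hit)) NA_integer_ else from + hit - 1L
}

write_vtk <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "trimesh surface", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(apply(v, 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
  writeLines(paste(3L, f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L), con)
  vd <- mesh$vertex_data
  if (!is.null(vd) && ncol(vd) > 0L) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (nm in names(vd)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(vd[[nm]], digits = 17, trim = TRUE,
                        scientific = FALSE), con)
    }
  }
}

# fan triangulation of polygon index lists -> integer matrix of triangles
triangulate_polys <- function(polys) {
  if (!length(polys)) return(matrix(integer(), ncol = 3L))
  tri <- lapply(polys, function(p) {
    n <- length(p)
    if (n < 3L) stop("polygon with fewer than 3 vertices")
    if (n == 3L) return(matrix(p, ncol = 3L))
    cbind(p[1L], p[2:(n - 1L)], p[3:n])
  })
  do.call(rbind, tri)
}
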