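#' Read and write surface meshes (STL / PLY)
#'
#' `read_mesh()` dispatches on the file extension and accepts both ASCII
#' and binary dialects of STL and (little-endian) PLY. `write_mesh()`
#' writes ASCII by default; STL is triangle-only, so quads are split on
#' write, while PLY preserves quads.
#'
#' @param path File path ending in `.stl` or `.ply`.
#' @param mesh A [surface_mesh].
#' @param binary Write binary STL (ignored for PLY, which is always ASCII
#'   on write).
#' @return `read_mesh()` returns a [surface_mesh]; `write_mesh()` returns
#'   `path` invisibly.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path),
         stop("unsupported mesh format: ", ext))
}

#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl(mesh, path, binary = binary),
         ply = write_ply(mesh, path),
         stop("unsupported mesh format: ", ext))
  invisible(path)
}

triangulate_faces <- function(faces) {
  if (ncol(faces) == 3L) return(faces)
  rbind(faces[, c(1L, 2L, 3L), drop = FALSE],
        faces[, c(1L, 3L, 4L), drop = FALSE])
}

write_stl <- function(mesh, path, binary = FALSE) {
  tri <- triangulate_faces(mesh$faces)
  v <- mesh$vertices
  n1 <- v[tri[, 2], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  n2 <- v[tri[, 3], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  nrm <- cbind(n1[, 2] * n2[, 3] - n1[, 3] * n2[, 2],
               n1[, 3] * n2[, 1] - n1[, 1] * n2[, 3],
               n1[, 1] * n2[, 2] - n1[, 2] * n2[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / ifelse(len > 0, len, 1)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(tri)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(tri))) {
      writeBin(as.numeric(c(nrm[i, ], t(v[tri[i, ], ]))), con, size = 4,
               endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(tri))) {
      writeLines(sprintf("facet normal %.9g %.9g %.9g",
                         nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
      writeLines("  outer loop", con)
      for (k in 1:3) {
        p <- v[tri[i, k], ]
        writeLines(sprintf("    vertex %.9g %.9g %.9g", p[1], p[2], p[3]),
                   con)
      }
      writeLines("  endloop", con)
      writeLines("endfacet", con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}

read_stl <- function(path) {
  # binary STL has an 84-byte header then 50 bytes/triangle; ASCII starts
  # with "solid" but so can a binary header, so check the size arithmetic
  sz <- file.size(path)
  con <- file(path, "rb")
  head <- readBin(con, "raw", 84)
  close(con)
  is_binary <- FALSE
  if (sz >= 84) {
    ntri <- readBin(head[81:84], "integer", size = 4, endian = "little")
    if (!is.na(ntri) && sz == 84 + 50 * as.numeric(ntri)) is_binary <- TRUE
  }
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    ntri <- readBin(con, "integer", size = 4, endian = "little")
    vv <- matrix(0, ntri * 3L, 3L)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      readBin(con, "raw", 2)
      vv[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    vv <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[2:4])))
  }
  dedup_triangles(vv)
}

# collapse repeated vertices of a triangle soup into an indexed mesh
dedup_triangles <- function(vv) {
  key <- apply(vv, 1, function(p) paste(signif(p, 12), collapse = ","))
  ids <- match(key, unique(key))
  verts <- vv[!duplicated(key), , drop = FALSE]
  faces <- matrix(ids, ncol = 3L, byrow = TRUE)
  surface_mesh(verts, faces)
}

write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  nv <- ncol(f)
  writeLines(paste(nv, apply(f - 1L, 1, paste, collapse = " ")), con)
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # read header lines byte-wise so a binary body is untouched
  read_hline <- function() {
    out <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1)
      if (length(b) == 0 || b == as.raw(10)) break
      out <- c(out, b)
    }
    sub("\r$", "", rawToChar(out))
  }
  stopifnot(read_hline() == "ply")
  fmt <- NULL; nvert <- 0L; nface <- 0L
  vprops <- character(0)
  elem <- ""
  repeat {
    ln <- read_hline()
    if (ln == "end_header") break
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    if (tok[1] == "element") {
      elem <- tok[2]
      if (elem == "vertex") nvert <- as.integer(tok[3])
      if (elem == "face") nface <- as.integer(tok[3])
    }
    if (tok[1] == "property" && elem == "vertex" && tok[2] != "list")
      vprops <- c(vprops, tok[3])
  }
  ix <- match(c("x", "y", "z"), vprops)
  if (anyNA(ix)) stop("PLY vertex element lacks x/y/z")
  if (fmt == "ascii") {
    lines <- character(nvert + nface)
    for (i in seq_along(lines)) lines[i] <- read_hline()
    vdat <- do.call(rbind, lapply(strsplit(trimws(lines[seq_len(nvert)]),
                                           "\\s+"), as.numeric))
    verts <- vdat[, ix, drop = FALSE]
    flist <- lapply(strsplit(trimws(lines[nvert + seq_len(nface)]), "\\s+"),
                    function(x) as.integer(x[-1]) + 1L)
  } else if (fmt %in% c("binary_little_endian", "binary_big_endian")) {
    endian <- if (fmt == "binary_little_endian") "little" else "big"
    np <- length(vprops)
    vdat <- matrix(readBin(con, "numeric", n = nvert * np, size = 4,
                           endian = endian), nvert, np, byrow = TRUE)
    verts <- vdat[, ix, drop = FALSE]
    flist <- vector("list", nface)
    for (i in seq_len(nface)) {
      cnt <- as.integer(readBin(con, "integer", 1, size = 1, signed = FALSE,
                                endian = endian))
      flist[[i]] <- readBin(con, "integer", cnt, size = 4,
                            endian = endian) + 1L
    }
  } else stop("unsupported PLY format: ", fmt)
  ns <- lengths(flist)
  if (all(ns == 4L)) faces <- do.call(rbind, flist)
  else faces <- do.call(rbind, lapply(flist, function(x)
    if (length(x) == 3L) x else stop("mixed polygon sizes in PLY")))
  surface_mesh(verts, faces)
}

#' Write a legacy-VTK unstructured grid
#'
#' ASCII legacy VTK writer used to export the layered solid mesh with its
#' integer `material_id` cell-data field, and deployment results with
#' point-data arrays.
#'
#' @param vertices `n x 3` point matrix (mm).
#' @param cells Integer cell connectivity matrix (`m x 8` hexahedra or
#'   `m x 4` quads), 1-based.
#' @param path Output file.
#' @param cell_data Named list of per-cell vectors (integer fields are
#'   written as `int`).
#' @param point_data Named list of per-point numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(vertices, cells, path, cell_data = list(),
                      point_data = list()) {
  n_pt <- nrow(vertices)
  n_cell <- nrow(cells)
  npc <- ncol(cells)
  vtk_type <- switch(as.character(npc), "8" = 12L, "4" = 9L, "3" = 5L,
                     stop("unsupported cell size"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "tpvuq unstructured grid",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n_pt)), con)
  writeLines(sprintf("%.9g %.9g %.9g", vertices[, 1], vertices[, 2],
                     vertices[, 3]), con)
  writeLines(sprintf("CELLS %d %d", n_cell, n_cell * (npc + 1L)), con)
  writeLines(paste(npc, apply(cells - 1L, 1, paste, collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", n_cell), con)
  writeLines(as.character(rep(vtk_type, n_cell)), con)
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", n_cell), con)
    for (nm in names(cell_data)) {
      x <- cell_data[[nm]]
      tp <- if (is.integer(x)) "int" else "double"
      writeLines(c(sprintf("SCALARS %s %s 1", nm, tp), "LOOKUP_TABLE default"),
                 con)
      writeLines(as.character(x), con)
    }
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n_pt), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", point_data[[nm]]), con)
    }
  }
  invisible(path)
}
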