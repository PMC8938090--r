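# Mesh file I/O. Supported formats: ASCII STL, ASCII PLY and legacy ASCII
# VTK polydata. STL stores no connectivity, so coincident facet corners are
# merged on read. The ostium rim travels in a separate ordered CSV
# (columns x,y,z or index), since neither STL nor PLY carries it natively.

#' Read a triangulated surface mesh
#'
#' @param path file path (ASCII STL, PLY or legacy VTK polydata)
#' @param format_hint one of "auto", "stl", "ply", "vtk"; "auto" uses the
#'   file extension
#' @param rim_path optional CSV of ordered rim points (columns x,y,z) or rim
#'   vertex indices (single column `index`, 1-based); matched to mesh
#'   vertices within `rim_tol` mm
#' @param rim_tol matching tolerance for rim points, mm
#' @return an [laa_mesh()]
#' @export
read_surface_mesh <- function(path, format_hint = "auto", rim_path = NULL,
                              rim_tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fmt <- match.arg(format_hint, c("auto", "stl", "ply", "vtk"))
  if (fmt == "auto") {
    fmt <- switch(tolower(tools::file_ext(path)),
                  stl = "stl", ply = "ply", vtk = "vtk", vtp = "vtk",
                  stop("cannot infer mesh format from extension: ", path,
                       call. = FALSE))
  }
  mesh <- switch(fmt,
                 stl = read_stl_ascii(path),
                 ply = read_ply_ascii(path),
                 vtk = read_vtk_polydata(path))
  if (!is.null(rim_path)) {
    mesh$ostium_rim <- read_ostium_rim(rim_path, mesh, tol = rim_tol)
    validate_mesh(mesh)
  }
  mesh
}

#' @keywords internal
read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) stop("not an ASCII STL file: ", path, call. = FALSE)
  nums <- matrix(as.numeric(unlist(strsplit(trimws(sub("^\\s*vertex\\s+", "",
                                                       vl)), "\\s+"))),
                 ncol = 3, byrow = TRUE)
  if (nrow(nums) %% 3 != 0) {
    stop("malformed STL: vertex count not a multiple of 3", call. = FALSE)
  }
  # merge coincident corners
  key <- apply(round(nums, 9), 1, paste, collapse = ",")
  uidx <- !duplicated(key)
  verts <- nums[uidx, , drop = FALSE]
  map <- match(key, key[uidx])
  faces <- matrix(map, ncol = 3, byrow = TRUE)
  laa_mesh(verts, faces)
}

#' @keywords internal
read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stop("not an ASCII PLY file: ", path, call. = FALSE)
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", hdr, value = TRUE)[1]))
  if (any(grepl("format binary", hdr))) {
    stop("binary PLY not supported; write ASCII", call. = FALSE)
  }
  body <- lines[(hdr_end + 1):length(lines)]
  vl <- body[seq_len(nv)]
  verts <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))),
                  nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  fl <- body[nv + seq_len(nf)]
  ff <- strsplit(trimws(fl), "\\s+")
  faces <- t(vapply(ff, function(r) {
    r <- as.integer(r)
    if (r[1] != 3L) stop("non-triangular PLY face", call. = FALSE)
    r[2:4] + 1L
  }, integer(3)))
  laa_mesh(verts, faces)
}

#' @keywords internal
read_vtk_polydata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS", lines)[1]
  if (is.na(ip)) stop("not a legacy VTK polydata file: ", path, call. = FALSE)
  np <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  ipoly <- grep("^POLYGONS", lines)[1]
  if (is.na(ipoly)) stop("VTK file has no POLYGONS block", call. = FALSE)
  nums <- as.numeric(unlist(strsplit(trimws(
    paste(lines[(ip + 1):(ipoly - 1)], collapse = " ")), "\\s+")))
  verts <- matrix(nums[seq_len(3 * np)], ncol = 3, byrow = TRUE)
  hdr <- strsplit(lines[ipoly], "\\s+")[[1]]
  nf <- as.integer(hdr[2])
  ipd <- grep("^POINT_DATA", lines)[1]
  poly_end <- if (is.na(ipd)) length(lines) else ipd - 1L
  body <- as.integer(unlist(strsplit(trimws(
    paste(lines[(ipoly + 1):poly_end], collapse = " ")), "\\s+")))
  faces <- matrix(NA_integer_, nf, 3)
  pos <- 1L
  for (i in seq_len(nf)) {
    k <- body[pos]
    if (k != 3L) stop("non-triangular VTK polygon", call. = FALSE)
    faces[i, ] <- body[(pos + 1):(pos + 3)] + 1L
    pos <- pos + k + 1L
  }
  laa_mesh(verts, faces)
}

#' @keywords internal
read_ostium_rim <- function(rim_path, mesh, tol = 1e-6) {
  df <- read.csv(rim_path)
  if ("index" %in% names(df) && !all(c("x", "y", "z") %in% names(df))) {
    return(as.integer(df$index))
  }
  pts <- as.matrix(df[, c("x", "y", "z")])
  idx <- integer(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    d2 <- rowSums(sweep(mesh$vertices, 2, pts[i, ])^2)
    j <- which.min(d2)
    if (d2[j] > tol^2) {
      stop("rim point ", i, " does not match any mesh vertex within ",
           tol, " mm", call. = FALSE)
    }
    idx[i] <- j
  }
  idx
}

#' Write a surface mesh
#'
#' @param mesh an [laa_mesh()]
#' @param path output path; extension selects the format (.stl, .ply, .vtk)
#' @param point_data optional named list of per-vertex numeric vectors,
#'   written as POINT_DATA scalars (VTK only)
#' @return `path`, invisibly
#' @export
write_surface_mesh <- function(mesh, path, point_data = NULL) {
  fmt <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  if (fmt == "stl") {
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      tri <- v[f[i, ], , drop = FALSE]
      writeLines(c(" facet normal 0 0 0", "  outer loop",
                   sprintf("   vertex %.9g %.9g %.9g",
                           tri[, 1], tri[, 2], tri[, 3]),
                   "  endloop", " endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  } else if (fmt == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(v)),
                 "property float x", "property float y", "property float z",
                 paste("element face", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"),
               con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
               con)
  } else if (fmt %in% c("vtk", "vtp")) {
    writeLines(c("# vtk DataFile Version 3.0", "laametrics surface", "ASCII",
                 "DATASET POLYDATA",
                 paste("POINTS", nrow(v), "double")), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(paste("POLYGONS", nrow(f), 4L * nrow(f)), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
               con)
    if (!is.null(point_data)) {
      writeLines(paste("POINT_DATA", nrow(v)), con)
      for (nm in names(point_data)) {
        writeLines(c(paste("SCALARS", nm, "double 1"),
                     "LOOKUP_TABLE default",
                     sprintf("%.9g", point_data[[nm]])), con)
      }
    }
  } else {
    stop("unsupported mesh output format: ", fmt, call. = FALSE)
  }
  invisible(path)
}

#' Write the ostium rim as an ordered point CSV
#' @param mesh an [laa_mesh()] with a rim
#' @param path output CSV path
#' @export
write_ostium_rim <- function(mesh, path) {
  rim <- mesh$ostium_rim
  if (!length(rim)) stop("mesh has no ostium rim", call. = FALSE)
  df <- data.frame(mesh$vertices[rim, , drop = FALSE], index = rim)
  names(df)[1:3] <- c("x", "y", "z")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
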