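# The laa_mesh container: triangulated LA/LAA wall geometry in mm with an
# identified ostium rim (ordered closed loop of vertex indices).

#' Construct a surface mesh object
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm)
#' @param faces integer m x 3 matrix of 1-based triangle vertex indices
#' @param ostium_rim optional integer vector of vertex indices forming the
#'   ordered, closed (not repeated at the end) ostium rim loop
#' @param cap_faces optional logical vector of length m flagging faces that
#'   belong to an ostium-closing cap (excluded from the LAA wall area)
#' @param validate check mesh invariants (face indices in range, no
#'   zero-area triangles, rim a valid loop)
#' @return an object of class `laa_mesh`
#' @export
laa_mesh <- function(vertices, faces, ostium_rim = NULL, cap_faces = NULL,
                     validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3) stop("vertices must be n x 3", call. = FALSE)
  if (ncol(faces) != 3) stop("faces must be m x 3", call. = FALSE)
  if (is.null(cap_faces)) cap_faces <- rep(FALSE, nrow(faces))
  m <- structure(list(vertices = vertices, faces = faces,
                      ostium_rim = as.integer(ostium_rim),
                      cap_faces = cap_faces,
                      is_capped = any(cap_faces)),
                 class = "laa_mesh")
  if (validate) validate_mesh(m)
  m
}

#' @keywords internal
validate_mesh <- function(mesh) {
  nv <- nrow(mesh$vertices)
  f <- mesh$faces
  if (any(f < 1L) || any(f > nv)) {
    stop("invalid mesh: face references a missing vertex", call. = FALSE)
  }
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3])) {
    stop("invalid mesh: degenerate face with repeated vertex", call. = FALSE)
  }
  if (any(triangle_areas(mesh) < 1e-12)) {
    stop("invalid mesh: zero-area triangle", call. = FALSE)
  }
  rim <- mesh$ostium_rim
  if (length(rim)) {
    if (length(rim) < 16L) {
      stop("invalid mesh: ostium rim has fewer than 16 vertices",
           call. = FALSE)
    }
    if (anyDuplicated(rim)) {
      stop("invalid mesh: ostium rim revisits a vertex (not a simple loop)",
           call. = FALSE)
    }
  }
  invisible(mesh)
}

#' Triangle areas of a mesh (mm^2)
#' @keywords internal
triangle_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Is every edge shared by exactly two faces?
#' @param mesh an `laa_mesh`
#' @return logical
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Close the ostium with a fan cap from the rim centroid
#'
#' Adds one vertex at the rim centroid and a triangle fan over the rim so
#' that volume can be computed on a watertight mesh. Cap faces are flagged
#' and excluded from the wall area.
#'
#' @param mesh an `laa_mesh` with a defined ostium rim
#' @return a capped `laa_mesh`
#' @export
cap_ostium <- function(mesh) {
  rim <- mesh$ostium_rim
  if (!length(rim)) stop("mesh has no ostium rim to cap", call. = FALSE)
  if (mesh$is_capped) return(mesh)
  ctr <- colMeans(mesh$vertices[rim, , drop = FALSE])
  v <- rbind(mesh$vertices, ctr)
  ci <- nrow(v)
  nr <- length(rim)
  fan <- cbind(rim, rim[c(2:nr, 1)], rep(ci, nr))
  laa_mesh(v, rbind(mesh$faces, fan), ostium_rim = rim,
           cap_faces = c(mesh$cap_faces, rep(TRUE, nr)), validate = FALSE)
}

#' Vertex normals (area-weighted, outward if faces consistently oriented)
#' @keywords internal
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  vn <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    for (c_ in 1:3) {
      vn[, c_] <- vn[, c_] + tapply_add(fn[, c_], f[, k], nrow(v))
    }
  }
  len <- pmax(row_norms(vn), 1e-300)
  vn / len
}

#' @keywords internal
tapply_add <- function(vals, idx, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' @export
print.laa_mesh <- function(x, ...) {
  cat("laa_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  if (length(x$ostium_rim)) {
    cat("  ostium rim:", length(x$ostium_rim), "vertices\n")
  }
  cat("  capped:", x$is_capped, "\n")
  invisible(x)
}
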