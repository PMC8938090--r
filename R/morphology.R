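# Morphological characterisation of the LAA: common reference frame
# (ostium plane = zx-plane), ostium metrics, centreline, appendage extents,
# volume/area and the three-region partition.

#' Align a mesh to the ostium reference frame
#'
#' Places the least-squares plane of the ostium rim onto the zx-plane with
#' the appendage body on the +y side, the rim centroid at the origin, and
#' the maximum-diameter direction of the rim along the x-axis.
#'
#' @param mesh an [laa_mesh()] with a defined ostium rim
#' @return list with `mesh` (aligned copy) and `transform`
#'   (`list(R, centre)` such that aligned = R (v - centre))
#' @export
align_to_ostium_frame <- function(mesh) {
  rim_idx <- mesh$ostium_rim
  if (!length(rim_idx)) stop("mesh has no ostium rim", call. = FALSE)
  rim <- mesh$vertices[rim_idx, , drop = FALSE]
  pl <- fit_plane(rim)
  n <- pl$normal
  body_dir <- colMeans(mesh$vertices) - pl$centroid
  if (sum(body_dir * n) < 0) n <- -n
  # project rim into plane, find D_max direction
  R1 <- rotation_between(n, c(0, 1, 0))
  v1 <- apply_rigid(mesh$vertices, R1, centre = pl$centroid)
  rim1 <- v1[rim_idx, c(1, 3), drop = FALSE]  # zx-plane coords (x, z)
  dm <- farthest_pair(rim1)
  dir2 <- rim1[dm[2], ] - rim1[dm[1], ]
  # dominant-component-positive sign convention keeps alignment stable
  if (dir2[which.max(abs(dir2))] < 0) dir2 <- -dir2
  ang <- atan2(dir2[2], dir2[1])  # angle of D_max dir in (x, z) plane
  # rotate about y by +ang so D_max direction maps to +x
  ca <- cos(ang); sa <- sin(ang)
  R2 <- matrix(c(ca, 0, sa,
                 0,  1, 0,
                 -sa, 0, ca), 3, 3, byrow = TRUE)
  R <- R2 %*% R1
  v <- apply_rigid(mesh$vertices, R, centre = pl$centroid)
  out <- mesh
  out$vertices <- v
  list(mesh = out, transform = list(R = R, centre = pl$centroid))
}

#' @keywords internal
farthest_pair <- function(pts) {
  h <- if (nrow(pts) > 3 && ncol(pts) == 2) {
    grDevices::chull(pts)
  } else {
    seq_len(nrow(pts))
  }
  hp <- pts[h, , drop = FALSE]
  d <- as.matrix(stats::dist(hp))
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  c(h[ij[1]], h[ij[2]])
}

#' Ostium metrics from the rim polygon
#'
#' The rim is projected onto its least-squares plane. `D_max` is the
#' maximum pairwise rim distance, `D_min` the minimal rotating-caliper
#' width, `D_mean = (D_max + D_min)/2`, `r_min` the minimal distance from
#' the rim centroid to the rim polygon, area the planar polygon area,
#' perimeter the closed polyline length and eccentricity `1 - D_min/D_max`.
#'
#' @param rim_points ordered n x 3 matrix of rim points (closed loop, not
#'   repeated), n >= 16
#' @return list of class `ostium_metrics` with fields `d_max`, `d_min`,
#'   `d_mean`, `r_min`, `area`, `perimeter`, `eccentricity`, `centroid`
#' @export
ostium_metrics <- function(rim_points) {
  rim_points <- as.matrix(rim_points)
  if (nrow(rim_points) < 16) {
    stop("ostium rim needs at least 16 points", call. = FALSE)
  }
  pl <- fit_plane(rim_points)
  # in-plane orthonormal basis
  b1 <- c(1, 0, 0) - pl$normal[1] * pl$normal
  if (sqrt(sum(b1^2)) < 1e-6) b1 <- c(0, 1, 0) - pl$normal[2] * pl$normal
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(pl$normal[2] * b1[3] - pl$normal[3] * b1[2],
          pl$normal[3] * b1[1] - pl$normal[1] * b1[3],
          pl$normal[1] * b1[2] - pl$normal[2] * b1[1])
  ctr3 <- pl$centroid
  rel <- sweep(rim_points, 2, ctr3)
  xy <- cbind(rel %*% b1, rel %*% b2)
  if (polygon_self_intersects(xy)) {
    stop("ostium rim polygon is self-intersecting", call. = FALSE)
  }
  d_max <- max_pairwise_distance(xy)
  d_min <- min_caliper_width(xy)
  ctr2 <- colMeans(xy)
  poly <- cbind(xy - matrix(ctr2, nrow(xy), 2, byrow = TRUE), 0)
  r_min <- min_dist_point_to_polygon(c(0, 0, 0), poly)
  structure(list(d_max = d_max, d_min = d_min, d_mean = (d_max + d_min) / 2,
                 r_min = r_min, area = polygon_area(xy),
                 perimeter = polygon_perimeter(xy),
                 eccentricity = 1 - d_min / d_max,
                 centroid = ctr3),
            class = "ostium_metrics")
}

#' @export
print.ostium_metrics <- function(x, ...) {
  cat(sprintf(paste0("ostium: D_max %.2f mm, D_min %.2f mm, area %.1f mm^2,",
                     " perimeter %.1f mm, eccentricity %.2f\n"),
              x$d_max, x$d_min, x$area, x$perimeter, x$eccentricity))
  invisible(x)
}

#' Extract the LAA centreline
#'
#' Ordered interior polyline from the ostium centre to the appendage tip,
#' obtained by marching perpendicular cross-sections: starting at the rim
#' centroid (the LAA origin) and heading along the inward rim-plane
#' normal, the mesh is sliced with the plane orthogonal to the current
#' direction one step ahead; the area centroid of the nearest closed
#' intersection contour becomes the next centreline point (after a
#' corrector re-slice perpendicular to the updated direction) and updates
#' the direction through a taper-adaptive damping that keeps the march
#' stable inside strongly tapered bends. Marching stops at the tip dome
#' (little wall left ahead within a corridor of the axis) or when the
#' section radius falls below 1 mm; the thin tail is then finished by
#' binning the remaining wall vertices along the tail's own principal
#' axis. The path is lightly smoothed and resampled at `spacing` mm.
#'
#' @param mesh an aligned, rim-bearing [laa_mesh()] (uncapped or capped;
#'   cap faces are ignored)
#' @param spacing resample spacing, mm (default 0.5)
#' @param step marching step, mm (default 2)
#' @return object of class `laa_centreline` with `points`, `arc_length`,
#'   `tortuosity`, `bending_angle`
#' @export
extract_centreline <- function(mesh, spacing = 0.5, step = 2) {
  rim <- mesh$ostium_rim
  if (!length(rim)) stop("mesh has no ostium rim", call. = FALSE)
  fw <- mesh$faces[!mesh$cap_faces, , drop = FALSE]
  # slice against the capped surface: an open ostium would let tilted cuts
  # escape through the rim as low-area open contours
  capped <- if (mesh$is_capped) mesh else cap_ostium(mesh)
  v <- capped$vertices
  f <- capped$faces
  rimpts <- v[rim, , drop = FALSE]
  o_laa <- colMeans(rimpts)
  pl <- fit_plane(rimpts)
  d <- pl$normal
  wall <- sort(unique(as.vector(fw)))
  vw <- v[wall, , drop = FALSE]
  if (sum((colMeans(vw) - o_laa) * d) < 0) d <- -d
  r0 <- mean(row_norms(sweep(rimpts, 2, o_laa)))
  r_prev <- r0
  bbox <- apply(vw, 2, range)
  maxlen <- 4 * sqrt(sum(diff(bbox)^2))
  pts <- matrix(o_laa, 1, 3)
  c_cur <- o_laa
  total <- 0
  tanb <- 0  # running taper-rate estimate |dr/ds|
  repeat {
    st <- min(step, max(0.7, 0.25 * r_prev))
    sec <- slice_section(v, f, c_cur + st * d, d, r_ref = r_prev)
    if (is.null(sec)) break
    step_vec <- sec$centroid - c_cur
    nl <- sqrt(sum(step_vec^2))
    if (nl < 1e-9) break
    d_new <- step_vec / nl
    # corrector: re-slice at the tentative centroid with the updated
    # normal, so the stored point is a perpendicular-section centroid
    sec2 <- slice_section(v, f, sec$centroid, d_new, r_ref = r_prev)
    if (!is.null(sec2)) {
      sec <- sec2
      dd <- sec$centroid - c_cur
      nl <- sqrt(sum(dd^2))
      if (nl > 1e-9) d_new <- dd / nl
    }
    # a tilted cut of a tapered tube biases the centroid sideways with
    # gain ~ r |dr/ds| / st; damp the direction update so the induced
    # oscillation cannot grow
    lam <- 0.6 * st / (r_prev * tanb + 0.6 * st)
    d_new <- (1 - lam) * d + lam * d_new
    d_new <- d_new / sqrt(sum(d_new^2))
    if (sum(d_new * d) < 0) break
    total <- total + nl
    pts <- rbind(pts, sec$centroid)
    c_cur <- sec$centroid
    d <- d_new
    tanb <- 0.5 * tanb + 0.5 * abs(sec$radius - r_prev) / nl
    r_prev <- sec$radius
    if (r_prev < 1.0 || total > maxlen) break
    # tip dome: little wall left ahead within the corridor of the axis
    # (the corridor excludes a distal limb curling back past the bend)
    rel <- sweep(vw, 2, c_cur)
    ahead <- as.vector(rel %*% d)
    lat2 <- rowSums(rel^2) - ahead^2
    ahead_max <- max(c(0, ahead[lat2 < (1.2 * r_prev)^2]))
    if (ahead_max < max(0.7 * r_prev, 1.2 * st)) break
  }
  if (nrow(pts) < 2) {
    stop("no interior path found: mesh does not extend beyond the rim",
         call. = FALSE)
  }
  # finish the thin tail (below the marching radius floor) by binning the
  # remaining vertices along the tail's own principal axis (the marching
  # direction may lag at the stop)
  rel <- sweep(vw, 2, c_cur)
  ahead <- as.vector(rel %*% d)
  lat <- sqrt(pmax(rowSums(rel^2) - ahead^2, 0))
  cand <- which(ahead > 0.2 & lat < pmax(3 * r_prev, 4))
  if (length(cand) >= 3) {
    d_tail <- colMeans(rel[cand, , drop = FALSE])
    d_tail <- d_tail / max(sqrt(sum(d_tail^2)), 1e-12)
    ahead2 <- as.vector(rel %*% d_tail)
    lat2 <- sqrt(pmax(rowSums(rel^2) - ahead2^2, 0))
    ti <- which(ahead2 > 0.2 & lat2 < pmax(2 * r_prev, 3))
    if (length(ti) >= 3) {
      # the epsilon keeps a ring of vertices lying exactly on a bin
      # boundary in one bin (an even split would park both centroids
      # off-axis)
      tb <- pmax(1L, ceiling((ahead2[ti] - 1e-7) / 1.5))
      ctrs <- rowsum(vw[ti, , drop = FALSE], tb)
      cnt <- rowsum(rep(1, length(ti)), tb)
      ord <- order(as.numeric(rownames(ctrs)))
      pts <- rbind(pts, (ctrs / as.vector(cnt))[ord, , drop = FALSE])
    }
  }
  sm <- smooth_polyline(pts, 3L)
  new_centreline(resample_polyline(sm, spacing))
}

#' Intersection of the wall with a plane: nearest closed contour
#'
#' Cuts the triangulation with the plane through `p0` orthogonal to `n`,
#' chains the per-face intersection segments into contours via shared
#' edges, and returns the planar area centroid and equivalent radius of
#' the contour nearest `p0` (NULL when no contour lies within the
#' acceptance distance — a deliberately tight gate, since a looser one
#' risks capturing the returning limb of a strongly bent appendage).
#'
#' @keywords internal
slice_section <- function(v, f, p0, n, r_ref) {
  s <- as.vector(sweep(v, 2, p0) %*% n)
  s[abs(s) < 1e-12] <- 1e-9  # nudge vertices exactly on the plane
  s1 <- s[f[, 1]]; s2 <- s[f[, 2]]; s3 <- s[f[, 3]]
  cut <- which(pmin(s1, s2, s3) < 0 & pmax(s1, s2, s3) > 0)
  if (length(cut) < 3) return(NULL)
  fc <- f[cut, , drop = FALSE]
  # vectorised edge crossings: edge slots (1,2), (2,3), (3,1) per face
  ea <- cbind(fc[, 1], fc[, 2], fc[, 3])
  eb <- cbind(fc[, 2], fc[, 3], fc[, 1])
  sa <- cbind(s1[cut], s2[cut], s3[cut])
  sb <- cbind(s2[cut], s3[cut], s1[cut])
  hit <- sa * sb < 0  # exactly two TRUE per row after the nudge
  two <- rowSums(hit) == 2L
  if (sum(two) < 3) return(NULL)
  ea <- ea[two, , drop = FALSE]; eb <- eb[two, , drop = FALSE]
  sa <- sa[two, , drop = FALSE]; sb <- sb[two, , drop = FALSE]
  hit <- hit[two, , drop = FALSE]
  slot1 <- max.col(hit, ties.method = "first")
  slot2 <- max.col(hit, ties.method = "last")
  m <- nrow(hit)
  pick <- function(slot) {
    i <- cbind(seq_len(m), slot)
    a <- ea[i]; b <- eb[i]
    t <- sa[i] / (sa[i] - sb[i])
    list(key = paste(pmin(a, b), pmax(a, b)),
         pt = v[a, , drop = FALSE] +
           t * (v[b, , drop = FALSE] - v[a, , drop = FALSE]))
  }
  h1 <- pick(slot1); h2 <- pick(slot2)
  keymat <- cbind(h1$key, h2$key)
  all_keys <- unique(as.vector(keymat))
  ptsbykey <- matrix(NA_real_, length(all_keys), 3)
  ptsbykey[match(h1$key, all_keys), ] <- h1$pt
  ptsbykey[match(h2$key, all_keys), ] <- h2$pt
  visited <- rep(FALSE, m)
  best <- NULL; bestd <- Inf
  key_to_faces <- split(rep(seq_len(m), 2), as.vector(keymat))
  # in-plane orthonormal basis for the area centroid
  b1 <- c(1, 0, 0) - n[1] * n
  if (sqrt(sum(b1^2)) < 1e-6) b1 <- c(0, 1, 0) - n[2] * n
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(n[2] * b1[3] - n[3] * b1[2],
          n[3] * b1[1] - n[1] * b1[3],
          n[1] * b1[2] - n[2] * b1[1])
  for (start in seq_len(m)) {
    if (visited[start]) next
    loop_keys <- character(0)
    cur <- start
    key_in <- keymat[cur, 1]
    repeat {
      visited[cur] <- TRUE
      loop_keys <- c(loop_keys, key_in)
      key_out <- setdiff(keymat[cur, ], key_in)
      if (!length(key_out)) break
      key_out <- key_out[1]
      nxt <- setdiff(key_to_faces[[key_out]], cur)
      if (!length(nxt) || visited[nxt[1]]) {
        loop_keys <- c(loop_keys, key_out)
        break
      }
      cur <- nxt[1]
      key_in <- key_out
    }
    cpts <- ptsbykey[match(unique(loop_keys), all_keys), , drop = FALSE]
    if (nrow(cpts) < 3) next
    cand <- polygon_area_centroid(cpts, p0, b1, b2)
    if (!is.null(cand) && cand$dist < bestd) {
      bestd <- cand$dist
      best <- cand
    }
    # in a strongly bent appendage the slice plane can wrap around the
    # bend, merging both limbs into one contour whose centroid is far
    # from the target; rescue the local sub-loop near the target
    if (is.null(cand) || cand$dist > max(1.5, 0.6 * r_ref + 1)) {
      sub <- local_subloop(cpts, p0, 2.2 * r_ref)
      if (!is.null(sub)) {
        cand2 <- polygon_area_centroid(sub, p0, b1, b2)
        if (!is.null(cand2) && cand2$dist < bestd) {
          bestd <- cand2$dist
          best <- cand2
        }
      }
    }
  }
  # the true next section sits close to the predicted point; a looser gate
  # risks capturing the returning limb of a strongly bent appendage
  if (is.null(best) || bestd > max(1.5, 0.6 * r_ref + 1)) return(NULL)
  best
}

#' Planar area centroid of a chain-ordered contour polygon
#'
#' Crossing points are not uniformly spaced around the contour (a plain
#' point mean is biased) and contours at tight bends are crescents (angle
#' sorting would fold the polygon), so the polygon is taken in chain
#' order.
#' @keywords internal
polygon_area_centroid <- function(cpts, p0, b1, b2) {
  rel <- sweep(cpts, 2, p0)
  xy <- cbind(rel %*% b1, rel %*% b2)
  x <- xy[, 1]; y <- xy[, 2]
  i2 <- c(2:nrow(xy), 1)
  cr <- x * y[i2] - x[i2] * y
  area2 <- sum(cr)
  if (abs(area2) < 1e-9) return(NULL)
  cx <- sum((x + x[i2]) * cr) / (3 * area2)
  cy <- sum((y + y[i2]) * cr) / (3 * area2)
  ctr <- p0 + cx * b1 + cy * b2
  list(centroid = ctr, radius = sqrt(abs(area2) / (2 * pi)),
       dist = sqrt(cx^2 + cy^2))
}

#' Longest chain-ordered run of contour points within `rad` of `p0`
#' (cyclic), closed into a polygon by its end chord
#' @keywords internal
local_subloop <- function(cpts, p0, rad) {
  nearp <- row_norms(sweep(cpts, 2, p0)) < rad
  if (all(nearp)) return(NULL)
  if (sum(nearp) < 3) return(NULL)
  # longest cyclic run of TRUE
  n <- length(nearp)
  x2 <- c(nearp, nearp)
  best_len <- 0; best_start <- NA
  i <- 1
  while (i <= n) {
    if (x2[i]) {
      j <- i
      while (j < i + n && x2[j + 1]) j <- j + 1
      if (j - i + 1 > best_len) { best_len <- j - i + 1; best_start <- i }
      i <- j + 1
    } else i <- i + 1
  }
  if (best_len < 3) return(NULL)
  idx <- ((best_start - 1) + seq_len(best_len) - 1) %% n + 1
  cpts[idx, , drop = FALSE]
}

#' @keywords internal
new_centreline <- function(pts) {
  m <- centreline_metrics(pts)
  structure(list(points = pts, arc_length = m["length"],
                 tortuosity = m["tortuosity"],
                 bending_angle = m["bending_angle"]),
            class = "laa_centreline")
}

#' @export
print.laa_centreline <- function(x, ...) {
  cat(sprintf("laa_centreline: %d points, length %.1f mm, tortuosity %.2f, bending %.0f deg\n",
              nrow(x$points), x$arc_length, x$tortuosity, x$bending_angle))
  invisible(x)
}

#' Length, tortuosity and bending of a centreline
#'
#' Length is the polyline arc length; tortuosity the chord-to-arc ratio
#' (1 = straight, lower = more winding); the bending angle is the angle in
#' degrees between the mean tangent direction of the proximal third and of
#' the distal third of the polyline (180 = no bend).
#'
#' @param centreline an `laa_centreline` or an n x 3 point matrix (n >= 3)
#' @return named vector `c(length, tortuosity, bending_angle)`
#' @export
centreline_metrics <- function(centreline) {
  pts <- if (inherits(centreline, "laa_centreline")) {
    centreline$points
  } else {
    as.matrix(centreline)
  }
  if (nrow(pts) < 3) stop("centreline needs at least 3 points", call. = FALSE)
  seg <- diff(pts)
  len <- row_norms(seg)
  arc <- sum(len)
  chord <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
  s_mid <- c(0, cumsum(len))[-1] - len / 2  # segment midpoints in arc length
  tang <- seg / len
  prox <- s_mid <= arc / 3
  dist_ <- s_mid >= 2 * arc / 3
  mean_dir <- function(sel) {
    d <- colSums(tang[sel, , drop = FALSE] * len[sel])
    d / sqrt(sum(d^2))
  }
  dp <- mean_dir(prox); dd <- mean_dir(dist_)
  turn <- acos(pmin(pmax(sum(dp * dd), -1), 1)) * 180 / pi
  c(length = arc, tortuosity = chord / arc, bending_angle = 180 - turn)
}

#' Appendage extents in the ostium frame
#'
#' Requires an aligned mesh (ostium plane = zx-plane, body on +y).
#' `d_A`/`d_P` are the distances along x from the volume centre of mass to
#' the extreme anterior/posterior wall vertices, `d_AP` their sum; `h_LAA`
#' the perpendicular extent above the ostium plane; `h_theta` the maximum
#' Euclidean distance from the LAA origin (rim centroid) to any vertex.
#'
#' @param mesh an aligned [laa_mesh()]; capped internally if needed
#' @param tol tolerance for the alignment check (mm)
#' @return named list `d_A`, `d_P`, `d_AP`, `h_LAA`, `h_theta`, `p_mass`
#' @export
appendage_extents <- function(mesh, tol = 1e-6) {
  rim <- mesh$ostium_rim
  if (!length(rim)) stop("mesh has no ostium rim", call. = FALSE)
  rimpts <- mesh$vertices[rim, , drop = FALSE]
  scale <- max(abs(rimpts))
  pl <- fit_plane(rimpts)
  if (max(abs(pl$centroid)) > 1e-3 * scale + tol ||
      abs(abs(pl$normal[2]) - 1) > 1e-6 + tol) {
    stop("mesh is not in the ostium-aligned frame; run align_to_ostium_frame",
         call. = FALSE)
  }
  capped <- if (mesh$is_capped) mesh else cap_ostium(mesh)
  pm <- unname(volume_centroid(capped))
  vx <- mesh$vertices[, 1]
  d_a <- unname(max(vx) - pm[1])
  d_p <- unname(pm[1] - min(vx))
  list(d_A = d_a, d_P = d_p, d_AP = d_a + d_p,
       h_LAA = max(mesh$vertices[, 2]),
       h_theta = max(row_norms(mesh$vertices)),
       p_mass = pm)
}

#' @keywords internal
volume_centroid <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  detv <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
    p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
    p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  vol6 <- sum(detv)
  ctr <- colSums((p1 + p2 + p3) / 4 * detv) / vol6
  ctr
}

#' LAA volume and wall area of a capped mesh
#'
#' Volume by signed tetrahedra (mm^3 converted to ml); area sums wall
#' triangles only, excluding any ostium cap.
#'
#' @param mesh a capped, watertight [laa_mesh()] (or one with a rim, which
#'   is capped internally)
#' @return list `volume_ml`, `area_mm2`
#' @export
mesh_measures <- function(mesh) {
  if (!mesh$is_capped && length(mesh$ostium_rim)) {
    mesh <- cap_ostium(mesh)
  }
  if (!is_watertight(mesh)) {
    stop("mesh is not watertight after capping; volume undefined",
         call. = FALSE)
  }
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  detv <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
    p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
    p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  vol <- abs(sum(detv)) / 6
  areas <- triangle_areas(mesh)
  list(volume_ml = vol / 1000,
       area_mm2 = sum(areas[!mesh$cap_faces]))
}

#' Partition wall vertices into inferior/middle/superior regions
#'
#' The centreline is split at one and two thirds of its arc length; each
#' wall vertex is labelled by the third containing its nearest centreline
#' point (Euclidean distance). Inferior is closest to the ostium.
#'
#' @param mesh an [laa_mesh()] (aligned; cap ignored)
#' @param centreline an `laa_centreline`
#' @return factor of length `nrow(mesh$vertices)` with levels
#'   `inferior`, `middle`, `superior` (cap-only vertices are `NA`)
#' @export
region_partition <- function(mesh, centreline) {
  pts <- centreline$points
  seglen <- row_norms(diff(pts))
  s <- c(0, cumsum(seglen))
  arc <- s[length(s)]
  thirds <- cut(s, breaks = c(-Inf, arc / 3, 2 * arc / 3, Inf),
                labels = c("inferior", "middle", "superior"))
  wall <- sort(unique(as.vector(mesh$faces[!mesh$cap_faces, , drop = FALSE])))
  lab <- factor(rep(NA_character_, nrow(mesh$vertices)),
                levels = levels(thirds))
  vv <- mesh$vertices[wall, , drop = FALSE]
  # nearest centreline point per wall vertex, blockwise
  nearest <- integer(length(wall))
  block <- 2000L
  for (i0 in seq(1L, length(wall), by = block)) {
    i1 <- min(i0 + block - 1L, length(wall))
    d2 <- outer(rowSums(vv[i0:i1, , drop = FALSE]^2), rowSums(pts^2), `+`) -
      2 * vv[i0:i1, , drop = FALSE] %*% t(pts)
    nearest[i0:i1] <- max.col(-d2, ties.method = "first")
  }
  lab[wall] <- thirds[nearest]
  if (any(table(lab) == 0)) {
    stop("empty region: centreline does not match the mesh", call. = FALSE)
  }
  lab
}

#' Full morphological feature set for one subject
#'
#' Runs alignment, ostium metrics, volume/area, extents, centreline and
#' derived metrics, returning the per-subject morphology row.
#'
#' @param mesh an [laa_mesh()] with a rim, in any pose
#' @param shape_label optional carried metadata ("chicken-wing" or
#'   "non-chicken-wing"); not computed from the geometry
#' @param la_volume_ml optional left-atrium volume (ml) used for the
#'   LAA/LA volume ratio
#' @param centreline_args list of extra arguments to [extract_centreline()]
#' @return named list of morphological features (class `morpho_features`)
#' @export
morpho_features <- function(mesh, shape_label = NA_character_,
                            la_volume_ml = NA_real_,
                            centreline_args = list()) {
  al <- align_to_ostium_frame(mesh)
  m <- al$mesh
  om <- ostium_metrics(m$vertices[m$ostium_rim, , drop = FALSE])
  meas <- mesh_measures(m)
  ext <- appendage_extents(m)
  cl <- do.call(extract_centreline, c(list(m), centreline_args))
  structure(list(
    d_max = om$d_max, d_min = om$d_min, d_mean = om$d_mean,
    r_min = om$r_min, ostium_area = om$area,
    ostium_perimeter = om$perimeter, eccentricity = om$eccentricity,
    laa_volume_ml = meas$volume_ml, laa_area_mm2 = meas$area_mm2,
    la_volume_ml = la_volume_ml,
    ratio_laav_lav = if (is.na(la_volume_ml)) NA_real_ else
      meas$volume_ml / la_volume_ml,
    h_laa = ext$h_LAA, h_theta = ext$h_theta,
    d_a = ext$d_A, d_p = ext$d_P, d_ap = ext$d_AP,
    centreline_length = unname(cl$arc_length),
    tortuosity = unname(cl$tortuosity),
    bending_angle = unname(cl$bending_angle),
    shape_label = shape_label),
    class = "morpho_features", centreline = cl, aligned_mesh = m)
}
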