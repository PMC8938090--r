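# Shared fixtures: small analytic meshes and synthetic wall/flow series
# built in code at test time.

# capped cylinder of radius r and height h along +y, rim at y = 0
make_cylinder <- function(r = 10, h = 40, n_ring = 48, n_axial = 32,
                          close_top = TRUE) {
  phi <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
  ys <- seq(0, h, length.out = n_axial)
  verts <- do.call(rbind, lapply(ys, function(y) {
    cbind(r * cos(phi), y, r * sin(phi))
  }))
  faces <- NULL
  for (i in seq_len(n_axial - 1)) {
    r0 <- (i - 1) * n_ring; r1 <- i * n_ring
    j <- seq_len(n_ring); j2 <- c(2:n_ring, 1)
    faces <- rbind(faces,
                   cbind(r0 + j, r0 + j2, r1 + j2),
                   cbind(r0 + j, r1 + j2, r1 + j))
  }
  if (close_top) {
    top_c <- nrow(verts) + 1
    verts <- rbind(verts, c(0, h, 0))
    r0 <- (n_axial - 1) * n_ring
    j <- seq_len(n_ring); j2 <- c(2:n_ring, 1)
    faces <- rbind(faces, cbind(r0 + j, r0 + j2, top_c))
  }
  laa_mesh(verts, faces, ostium_rim = seq_len(n_ring))
}

# UV sphere of radius r; watertight, no rim
make_sphere <- function(r = 10, n_theta = 40, n_phi = 60) {
  th <- seq(0, pi, length.out = n_theta)[-c(1, n_theta)]
  ph <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  verts <- rbind(c(0, 0, r))
  for (t in th) {
    verts <- rbind(verts, cbind(r * sin(t) * cos(ph), r * sin(t) * sin(ph),
                                r * cos(t)))
  }
  south <- nrow(verts) + 1
  verts <- rbind(verts, c(0, 0, -r))
  faces <- NULL
  j <- seq_len(n_phi); j2 <- c(2:n_phi, 1)
  faces <- rbind(faces, cbind(1, 1 + j, 1 + j2))
  nb <- length(th)
  for (b in seq_len(nb - 1)) {
    r0 <- 1 + (b - 1) * n_phi; r1 <- 1 + b * n_phi
    faces <- rbind(faces,
                   cbind(r0 + j, r1 + j, r1 + j2),
                   cbind(r0 + j, r1 + j2, r0 + j2))
  }
  r0 <- 1 + (nb - 1) * n_phi
  faces <- rbind(faces, cbind(r0 + j, south, r0 + j2))
  laa_mesh(verts, faces)
}

# quarter-torus tube: ring radius R in the yz-plane, tube radius r,
# capped at both ends; rim at the y = 0 end
make_quarter_torus <- function(R = 20, r = 4, n_ring = 32, n_axial = 40) {
  ang <- seq(0, pi / 2, length.out = n_axial)
  phi <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
  verts <- NULL
  for (a in ang) {
    ctr <- c(0, R * sin(a), R * (1 - cos(a)))
    nrm <- c(0, -sin(a), cos(a))  # in-plane section axis
    ring <- cbind(r * cos(phi), 0, 0) +
      matrix(ctr, n_ring, 3, byrow = TRUE) + outer(r * sin(phi), nrm)
    verts <- rbind(verts, ring)
  }
  faces <- NULL
  for (i in seq_len(n_axial - 1)) {
    r0 <- (i - 1) * n_ring; r1 <- i * n_ring
    j <- seq_len(n_ring); j2 <- c(2:n_ring, 1)
    faces <- rbind(faces,
                   cbind(r0 + j, r0 + j2, r1 + j2),
                   cbind(r0 + j, r1 + j2, r1 + j))
  }
  end_c <- nrow(verts) + 1
  a <- pi / 2
  verts <- rbind(verts, c(0, R * sin(a), R * (1 - cos(a))))
  r0 <- (n_axial - 1) * n_ring
  j <- seq_len(n_ring); j2 <- c(2:n_ring, 1)
  faces <- rbind(faces, cbind(r0 + j, r0 + j2, end_c))
  laa_mesh(verts, faces, ostium_rim = seq_len(n_ring))
}

# wall series with a single constant WSS vector at every node
make_constant_series <- function(vec = c(0.5, 0, 0), n_nodes = 5,
                                 beat_period = 1, n_beats = 3,
                                 steps_per_beat = 40) {
  times <- seq(0, n_beats * beat_period,
               by = beat_period / steps_per_beat)
  wss <- array(0, c(n_nodes, length(times), 3))
  for (k in 1:3) wss[, , k] <- vec[k]
  wall_series(times, wss, beat_period, n_beats)
}

# ellipse rim point matrix in the zx-plane (major axis along x)
make_ellipse_rim <- function(a, b, n = 200) {
  phi <- 2 * pi * (seq_len(n) - 1) / n
  cbind(a * cos(phi), 0, b * sin(phi))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
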