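# Synthetic cohort generator.
#
# Emits parametric LAA meshes (elliptical cross-section swept along a
# constant-curvature centreline, tapered to a rounded tip), synthetic wall
# shear stress series and ostium flow traces, with per-subject ground truth,
# calibrated to the printed per-group distributions of the study cohort
# (control n = 38, TIA/CVA n = 33).

#' Default synthetic cohort specification
#'
#' Per-group marginal distributions for the generator. Normally distributed
#' features carry mean/sd; volume-like features are log-normal matched to
#' the printed median and (min-max) range; tortuosity is logit-normal.
#' Haemodynamic per-subject targets (whole-LAA TAWSS, OSI, velocity/volume,
#' stagnation) are drawn per subject and realised exactly in the
#' synthesised fields.
#'
#' @param n_control,n_case group sizes
#' @param beat_period cardiac period (s)
#' @param n_beats simulated beats (beat 1 is a ramped stabilisation beat)
#' @param steps_per_beat timesteps per beat in synthesised series
#' @param n_ring vertices per cross-section ring of generated meshes
#' @param axial_spacing target ring spacing along the centreline (mm)
#' @param rho_ostium copula correlation between the two ostium diameters
#' @param rho_ostium_volume copula correlation between ostium diameters and
#'   LAA volume
#' @return list of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_control = 38L, n_case = 33L, beat_period = 1.0,
                           n_beats = 3L, steps_per_beat = 40L,
                           n_ring = 48L, axial_spacing = 1.25,
                           rho_ostium = 0.7, rho_ostium_volume = 0.4) {
  grp <- function(d_max, d_min, length, tort_med, tort_rng, bend,
                  laa_vol_med, laa_vol_rng, la_vol_med, la_vol_rng,
                  p_chicken, tawss, osi, ecap, vel, stag_mean) {
    list(d_max = d_max, d_min = d_min, length = length,
         tort_med = tort_med, tort_rng = tort_rng, bend = bend,
         laa_vol_med = laa_vol_med, laa_vol_rng = laa_vol_rng,
         la_vol_med = la_vol_med, la_vol_rng = la_vol_rng,
         p_chicken = p_chicken, tawss = tawss, osi = osi, ecap = ecap,
         vel = vel, stag_mean = stag_mean)
  }
  structure(list(
    control = grp(d_max = c(25.77, 4.40), d_min = c(17.46, 3.66),
                  length = c(34.48, 7.06), tort_med = 0.79,
                  tort_rng = c(0.50, 0.96), bend = c(114, 17.55),
                  laa_vol_med = 6.63, laa_vol_rng = c(2.59, 15.50),
                  la_vol_med = 163, la_vol_rng = c(82, 256),
                  p_chicken = 0.1579, tawss = c(0.31, 0.12),
                  osi = c(0.15, 0.05), ecap = c(0.87, 0.61),
                  vel = c(0.99, 0.80), stag_mean = 12.39),
    case = grp(d_max = c(30.20, 4.90), d_min = c(19.63, 2.95),
               length = c(38.82, 8.74), tort_med = 0.77,
               tort_rng = c(0.45, 0.88), bend = c(103, 23.84),
               laa_vol_med = 8.09, laa_vol_rng = c(4.12, 15.88),
               la_vol_med = 164, la_vol_rng = c(100, 269),
               p_chicken = 0.1333, tawss = c(0.35, 0.14),
               osi = c(0.17, 0.04), ecap = c(1.08, 0.69),
               vel = c(0.84, 0.35), stag_mean = 19.77),
    n_control = as.integer(n_control), n_case = as.integer(n_case),
    beat_period = beat_period, n_beats = as.integer(n_beats),
    steps_per_beat = as.integer(steps_per_beat),
    n_ring = as.integer(n_ring), axial_spacing = axial_spacing,
    stag_sd = 6.0,
    rho_ostium = rho_ostium, rho_ostium_volume = rho_ostium_volume),
    class = "synthetic_spec")
}

# expected standardised extreme of a normal sample of n ~ 38; used to turn
# printed (min-max) ranges into log-scale sds
.range_k <- 2.2

#' @keywords internal
lognormal_from_median_range <- function(med, rng) {
  list(meanlog = log(med), sdlog = (log(rng[2]) - log(rng[1])) / (2 * .range_k))
}

#' Draw per-subject generator parameters
#'
#' Gaussian-copula sampling: the two ostium diameters and the LAA volume
#' are correlated (`rho_ostium`, `rho_ostium_volume`); all other features
#' are independent. Normal margins are truncated at +/-3 sd (the whole
#' subject is redrawn when any margin falls outside, or when the drawn
#' minimum diameter crowds the maximum); redraw counts are recorded in the
#' `resampled` attribute.
#'
#' @param spec a [synthetic_spec()]
#' @param seed integer seed
#' @return data.frame with one row per subject: identifiers, group and all
#'   generating draws
#' @export
sample_cohort_params <- function(spec, seed) {
  set.seed(seed)
  rho <- spec$rho_ostium; rhov <- spec$rho_ostium_volume
  sigma <- matrix(c(1, rho, rhov,
                    rho, 1, rhov,
                    rhov, rhov, 1), 3, 3)
  ch <- chol(sigma)
  n_resampled <- 0L
  draw_group <- function(g, n, label, id0) {
    tort_par <- list(mu = qlogis(g$tort_med),
                     sd = (qlogis(g$tort_rng[2]) - qlogis(g$tort_rng[1])) /
                       (2 * .range_k))
    laa_ln <- lognormal_from_median_range(g$laa_vol_med, g$laa_vol_rng)
    la_ln <- lognormal_from_median_range(g$la_vol_med, g$la_vol_rng)
    vel_ln <- moment_lognormal(g$vel[1], g$vel[2])
    ecap_ln <- moment_lognormal(g$ecap[1], g$ecap[2])
    stag_ln <- moment_lognormal(g$stag_mean, spec$stag_sd)
    one <- function(i) {
      repeat {
        z3 <- as.vector(t(ch) %*% rnorm(3))
        zi <- rnorm(9)
        if (any(abs(c(z3, zi[1:4])) > 3)) {
          n_resampled <<- n_resampled + 1L
          next
        }
        d_max <- g$d_max[1] + g$d_max[2] * z3[1]
        d_min <- g$d_min[1] + g$d_min[2] * z3[2]
        laa_vol <- exp(laa_ln$meanlog + laa_ln$sdlog * z3[3])
        len <- g$length[1] + g$length[2] * zi[1]
        tort <- plogis(tort_par$mu + tort_par$sd * zi[2])
        bend <- g$bend[1] + g$bend[2] * zi[3]
        la_vol <- exp(la_ln$meanlog + la_ln$sdlog * zi[4])
        tawss <- g$tawss[1] + g$tawss[2] * zi[5]
        osi <- g$osi[1] + g$osi[2] * zi[6]
        vel <- exp(vel_ln$meanlog + vel_ln$sdlog * zi[7])
        stag <- exp(stag_ln$meanlog + stag_ln$sdlog * zi[8])
        ecap <- exp(ecap_ln$meanlog + ecap_ln$sdlog * zi[9])
        tort <- min(max(tort, 0.45), 0.985)
        ok <- d_min > 5 && d_max > d_min + 1 && len > 15 &&
          tawss > 0.05 && osi > 0.02 && osi < 0.45 && stag < 90 &&
          ecap > 0.05 &&
          turn_from_tortuosity(tort) * (d_min / 2) / len < 0.9
        if (!ok) {
          n_resampled <<- n_resampled + 1L
          next
        }
        return(data.frame(
          subject_id = sprintf("S%03d", id0 + i), group = label,
          d_max = d_max, d_min = d_min, centreline_length = len,
          tortuosity = tort,
          bending_angle = bend, laa_volume_ml = laa_vol,
          la_volume_ml = la_vol,
          shape_label = if (runif(1) < g$p_chicken) "chicken-wing" else
            "non-chicken-wing",
          tawss = tawss, osi = osi, ecap = ecap, vel_laav = vel,
          stagnation_pct = stag, stringsAsFactors = FALSE))
      }
    }
    do.call(rbind, lapply(seq_len(n), one))
  }
  out <- rbind(draw_group(spec$control, spec$n_control, "control", 0L),
               draw_group(spec$case, spec$n_case, "case",
                          spec$n_control))
  attr(out, "resampled") <- n_resampled
  out
}

#' Total turning angle of a constant-curvature arc with given chord/arc
#' ratio (inverse of sinc(theta/2))
#' @keywords internal
turn_from_tortuosity <- function(eta) {
  if (eta >= 1 - 1e-9) return(0)
  2 * uniroot(function(x) sin(x) / x - eta, c(1e-9, 2.6), tol = 1e-12)$root
}

#' @keywords internal
moment_lognormal <- function(m, s) {
  list(meanlog = log(m^2 / sqrt(m^2 + s^2)),
       sdlog = sqrt(log(1 + s^2 / m^2)))
}

#' Build a parametric LAA mesh from a parameter draw
#'
#' The centreline is a constant-curvature arc in the yz-plane whose total
#' turn is solved so that the chord-to-arc ratio equals the drawn
#' tortuosity; arc length equals the drawn centreline length. The
#' cross-section is an ellipse (drawn ostium diameters) with its major axis
#' perpendicular to the bending plane, tapering as `(1 - u^2)^(gamma/2)`
#' towards a rounded tip, with `gamma` solved so the swept volume matches
#' the drawn LAA volume (clamped to the feasible taper family where
#' necessary). The ostium rim is the first ring, lying in the zx-plane.
#'
#' @param params one-row data.frame or named list with `d_max`, `d_min`,
#'   `centreline_length`, `tortuosity`, `laa_volume_ml`
#' @param n_ring vertices per ring
#' @param axial_spacing target ring spacing (mm)
#' @return list with `mesh` (an uncapped [laa_mesh()] with rim) and
#'   `truth` (analytic centreline polyline, arc length, chord, realised
#'   tortuosity/bending/volume, per-vertex arc position)
#' @export
build_laa_mesh <- function(params, n_ring = 48L, axial_spacing = 1.25) {
  a0 <- params$d_max / 2
  b0 <- params$d_min / 2
  L <- params$centreline_length
  eta <- params$tortuosity
  stopifnot(a0 > 0, b0 > 0, b0 <= a0, L > 0, eta > 0, eta <= 1)
  # total turn from tortuosity: chord/arc of a circular arc = sinc(theta/2)
  theta <- turn_from_tortuosity(eta)
  kappa <- theta / L
  if (kappa * b0 >= 0.98) {
    stop("self-intersecting sweep: bend radius ", signif(1 / kappa, 3),
         " mm below tube radius ", signif(b0, 3), " mm", call. = FALSE)
  }
  # taper exponent from target volume: V = pi a0 b0 L I(gamma),
  # I(gamma) = int_0^1 (1 - u^2)^gamma du
  I_gamma <- function(g) sqrt(pi) * gamma(g + 1) / (2 * gamma(g + 1.5))
  v_target <- params$laa_volume_ml * 1000
  ratio <- v_target / (pi * a0 * b0 * L)
  g_lo <- 0.35; g_hi <- 6
  gam <- if (ratio >= I_gamma(g_lo)) g_lo else if (ratio <= I_gamma(g_hi)) {
    g_hi
  } else {
    uniroot(function(g) I_gamma(g) - ratio, c(g_lo, g_hi), tol = 1e-10)$root
  }
  v_real <- pi * a0 * b0 * L * I_gamma(gam)
  centre_fun <- function(s) {
    if (kappa == 0) return(cbind(0, s, 0))
    R <- 1 / kappa
    cbind(0, R * sin(kappa * s), R * (1 - cos(kappa * s)))
  }
  tangent_fun <- function(s) {
    if (kappa == 0) return(cbind(0, rep(1, length(s)), 0))
    cbind(0, cos(kappa * s), sin(kappa * s))
  }
  normal_fun <- function(s) {  # in-plane section axis (bending plane)
    if (kappa == 0) return(cbind(0, rep(0, length(s)), 1))
    cbind(0, -sin(kappa * s), cos(kappa * s))
  }
  n_s <- max(24L, as.integer(ceiling(L / axial_spacing)))
  u <- sin(seq(0, pi / 2, length.out = n_s + 1L))
  gfac <- (1 - u^2)^(gam / 2)
  keep <- gfac > 0.02
  keep[length(keep)] <- FALSE  # apex handled separately
  u <- u[keep]; gfac <- gfac[keep]
  s <- u * L
  phi <- 2 * pi * (seq_len(n_ring) - 1L) / n_ring
  nrk <- length(s)
  verts <- matrix(0, nrk * n_ring + 1L, 3)
  vs <- numeric(nrk * n_ring + 1L)
  ctr <- centre_fun(s)
  nrm <- normal_fun(s)
  for (i in seq_len(nrk)) {
    ring <- cbind(a0 * gfac[i] * cos(phi), 0, 0) +
      matrix(ctr[i, ], n_ring, 3, byrow = TRUE) +
      outer(b0 * gfac[i] * sin(phi), nrm[i, ])
    rows <- (i - 1L) * n_ring + seq_len(n_ring)
    verts[rows, ] <- ring
    vs[rows] <- s[i]
  }
  apex <- nrow(verts)
  verts[apex, ] <- centre_fun(L)
  vs[apex] <- L
  faces <- matrix(0L, 0L, 3L)
  fl <- vector("list", nrk)
  for (i in seq_len(nrk - 1L)) {
    r0 <- (i - 1L) * n_ring
    r1 <- i * n_ring
    j <- seq_len(n_ring)
    j2 <- c(2:n_ring, 1L)
    fl[[i]] <- rbind(cbind(r0 + j, r0 + j2, r1 + j2),
                     cbind(r0 + j, r1 + j2, r1 + j))
  }
  r0 <- (nrk - 1L) * n_ring
  j <- seq_len(n_ring); j2 <- c(2:n_ring, 1L)
  fl[[nrk]] <- cbind(r0 + j, r0 + j2, apex)
  faces <- do.call(rbind, fl)
  mesh <- laa_mesh(verts, faces, ostium_rim = seq_len(n_ring))
  cl_s <- seq(0, L, by = 0.25)
  truth <- list(
    centreline = centre_fun(cl_s),
    arc_length = L,
    chord = sqrt(sum(centre_fun(L)^2)),
    tortuosity = if (theta == 0) 1 else sin(theta / 2) / (theta / 2),
    bending_angle = 180 - (2 / 3) * theta * 180 / pi,
    volume_ml = v_real / 1000,
    gamma = gam, theta = theta,
    d_max = params$d_max, d_min = params$d_min,
    vertex_s = vs)
  list(mesh = mesh, truth = truth)
}

#' Synthesise wall shear stress and flow series for a generated mesh
#'
#' Per wall node at arc position `s`, the WSS vector is
#' `tau0 w(t) [cos(psi) e1 + sin(psi) sin(2 pi t / P) e2]` with `e1` the
#' local centreline tangent and `e2` circumferential; `psi` is solved per
#' node so that the discrete-time OSI equals its target, and `tau0` scales
#' the discrete TAWSS onto its target. Targets decay from ostium to tip
#' (`exp(-s/lambda)`, `lambda = L/2` for TAWSS; a mild linear decline for
#' OSI) and are normalised so their node means equal the subject's
#' whole-LAA draws. The pulsatile envelope `w(t) = 1 + 0.35 cos(4 pi t/P)`
#' is orthogonal to the reversing harmonic, so it perturbs neither index.
#' Beat 1 is multiplied by a quadratic amplitude ramp, making it visibly
#' non-periodic (the averaging window must skip it). The ostium flow trace
#' is a signed sinusoid whose per-beat outflow volume inverts the
#' perfect-mixing washout formula at the subject's stagnation target, and
#' intra-LAA velocity samples decay along the centreline, scaled so the
#' volume-normalised velocity index equals its target.
#'
#' @param params one-row parameter draw (see [sample_cohort_params()])
#' @param mesh the generated [laa_mesh()] (canonical pose)
#' @param truth the ground-truth list from [build_laa_mesh()]
#' @param beat_period,n_beats,steps_per_beat series discretisation
#' @param n_vel_samples number of intra-LAA velocity sample points
#' @return list `series` (a [wall_series()]), `flow` (a [flow_series()]),
#'   and `targets` (per-node TAWSS/OSI targets, stored as ground truth)
#' @export
synthesize_flow <- function(params, mesh, truth, beat_period = 1.0,
                            n_beats = 3L, steps_per_beat = 40L,
                            n_vel_samples = 50L) {
  P <- beat_period
  L <- truth$arc_length
  times <- seq(0, n_beats * P, by = P / steps_per_beat)
  nt <- length(times)
  s <- truth$vertex_s
  su <- s / L
  nn <- length(su)
  # per-node targets: OSI declines mildly from ostium to tip and its node
  # mean equals the subject's whole-LAA draw; the wall-shear magnitude
  # decays as exp(-s/lambda), lambda = L/2, and its scale is solved so the
  # trimmed-mean ECAP equals the subject's ECAP draw (TAWSS and RRT group
  # levels then emerge rather than being calibrated; the printed group
  # table cannot be matched in all five indices at once because the
  # per-node identities do not survive averaging)
  osi_t <- pmin(pmax(1.15 - 0.45 * su, 0.2), 2)
  osi_t <- osi_t / mean(osi_t) * params$osi
  osi_t <- pmin(pmax(osi_t, 0), 0.48)
  if (any(osi_t > 0.5)) stop("unreachable OSI target > 0.5", call. = FALSE)
  # mild side-to-side variation: walls are not axisymmetric, and distinct
  # per-node values keep percentile-trim boundaries off the ring-wise ties
  # a swept mesh would otherwise produce (the curve lies in the x = 0
  # plane, so x is a pure circumferential coordinate)
  prof <- exp(-2 * su) * (1 + 0.05 * tanh(mesh$vertices[, 1] / 5))
  ecap_target <- if (!is.null(params$ecap)) params$ecap else {
    params$osi / params$tawss
  }
  # window grid quantities (beats 2..n_beats)
  widx <- which(times >= P - 1e-9)
  tw <- times[widx]
  T_ <- diff(range(tw))
  wenv <- 1 + 0.35 * cos(4 * pi * tw / P)
  sphi <- sin(2 * pi * tw / P)
  int_w <- trapz_int(tw, wenv)
  # discrete OSI(psi) lookup on this grid
  psi_grid <- seq(0, pi / 2 - 1e-4, length.out = 400)
  osi_of_psi <- vapply(psi_grid, function(ps) {
    den <- trapz_int(tw, wenv * sqrt(cos(ps)^2 + sin(ps)^2 * sphi^2))
    0.5 * (1 - cos(ps) * int_w / den)
  }, numeric(1))
  psi <- approx(osi_of_psi, psi_grid, xout = osi_t, rule = 2)$y
  # tau0 from TAWSS target on the same grid: TAWSS = tau0 int w*u dt / T
  uu <- sqrt(outer(cos(psi)^2, rep(1, length(tw))) +
               outer(sin(psi)^2, sphi^2))
  wu <- sweep(uu, 2, wenv, `*`)
  int_wu <- as.vector((wu[, -1, drop = FALSE] +
                         wu[, -ncol(wu), drop = FALSE]) %*% diff(tw)) / 2
  # the OSI the discrete grid will actually produce at each node; using it
  # (rather than the requested profile) makes the trimmed-mean ECAP
  # calibration exact
  osi_disc <- 0.5 * (1 - cos(psi) * int_w / int_wu)
  cscale <- trimmed_aggregate(osi_disc / prof) / ecap_target
  tawss_t <- cscale * prof
  tau0 <- tawss_t * T_ / int_wu
  # local frames
  theta <- truth$theta
  kappa <- theta / L
  tang <- if (kappa == 0) {
    matrix(rep(c(0, 1, 0), each = nn), nn, 3)
  } else {
    cbind(0, cos(kappa * s), sin(kappa * s))
  }
  ctr_s <- if (kappa == 0) cbind(0, s, 0) else {
    cbind(0, sin(kappa * s) / kappa, (1 - cos(kappa * s)) / kappa)
  }
  rad <- mesh$vertices - ctr_s
  e2 <- cbind(tang[, 2] * rad[, 3] - tang[, 3] * rad[, 2],
              tang[, 3] * rad[, 1] - tang[, 1] * rad[, 3],
              tang[, 1] * rad[, 2] - tang[, 2] * rad[, 1])
  e2n <- row_norms(e2)
  degen <- e2n < 1e-9
  e2[degen, ] <- matrix(rep(c(1, 0, 0), each = sum(degen)), ncol = 3)
  e2 <- e2 / pmax(row_norms(e2), 1e-300)
  # full-time envelopes with beat-1 ramp
  ramp <- pmin(times / P, 1)^2
  wfull <- (1 + 0.35 * cos(4 * pi * times / P)) * ramp
  sfull <- sin(2 * pi * times / P)
  coefA <- outer(tau0 * cos(psi), wfull)
  coefB <- outer(tau0 * sin(psi), wfull) *
    matrix(sfull, nn, nt, byrow = TRUE)
  wss <- array(0, c(nn, nt, 3))
  for (k in 1:3) wss[, , k] <- coefA * tang[, k] + coefB * e2[, k]
  series <- wall_series(times, wss, beat_period = P, n_beats = n_beats)
  # flow: ostium trace inverting the mixing washout at the stagnation target
  v_laa <- truth$volume_ml
  v_out <- -v_laa * log(params$stagnation_pct / 100)
  q <- (pi * v_out / P) * sin(2 * pi * times / P) * ramp
  sk <- (seq_len(n_vel_samples) - 0.5) / n_vel_samples
  wk <- (1 - sk^2)^truth$gamma
  wk <- wk / sum(wk) * v_laa
  wv <- (0.35 + 0.325 * (1 - cos(2 * pi * times / P))) * ramp
  vel <- outer(exp(-2 * sk), wv)
  flow0 <- flow_series(times, q, vel, wk, beat_period = P, n_beats = n_beats)
  sc <- params$vel_laav / velocity_index(flow0, v_laa)
  flow0$vel_samples <- flow0$vel_samples * sc
  list(series = series, flow = flow0,
       targets = list(tawss = tawss_t, osi = osi_t))
}

#' Generate a full synthetic cohort
#'
#' Draws per-subject parameters, builds each mesh, applies a random rigid
#' pose (stored in the ground truth), and optionally synthesises wall and
#' flow series. With `outdir` set, writes per-subject PLY mesh, rim CSV,
#' wall-series CSV + manifest, flow CSV and truth JSON plus a cohort
#' manifest with md5 hashes; otherwise returns everything in memory.
#'
#' @param spec a [synthetic_spec()]
#' @param seed integer seed (single source of randomness)
#' @param outdir optional output directory
#' @param with_flow synthesise wall/flow series (default TRUE); FALSE
#'   generates geometry only
#' @return list of class `laa_cohort`: `params` (data.frame) and
#'   `subjects` (list of `mesh`, `truth`, and when requested `series`,
#'   `flow`)
#' @export
generate_cohort <- function(spec = synthetic_spec(), seed = 42L,
                            outdir = NULL, with_flow = TRUE) {
  params <- sample_cohort_params(spec, seed)
  subjects <- vector("list", nrow(params))
  names(subjects) <- params$subject_id
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    bl <- build_laa_mesh(p, n_ring = spec$n_ring,
                         axial_spacing = spec$axial_spacing)
    sub <- list(truth = bl$truth, params = p)
    if (with_flow) {
      fl <- synthesize_flow(p, bl$mesh, bl$truth,
                            beat_period = spec$beat_period,
                            n_beats = spec$n_beats,
                            steps_per_beat = spec$steps_per_beat)
      sub$series <- fl$series
      sub$flow <- fl$flow
      sub$truth$target_tawss <- fl$targets$tawss
      sub$truth$target_osi <- fl$targets$osi
    }
    # random rigid pose
    R <- random_rotation()
    shift <- runif(3, -30, 30)
    mesh <- bl$mesh
    mesh$vertices <- apply_rigid(mesh$vertices, R, shift = shift)
    sub$truth$centreline <- apply_rigid(sub$truth$centreline, R,
                                        shift = shift)
    if (with_flow) {
      for (k in seq_along(sub$series$times)) {
        sub$series$wss[, k, ] <- sub$series$wss[, k, ] %*% t(R)
      }
    }
    sub$truth$pose <- list(R = R, shift = shift)
    sub$mesh <- mesh
    subjects[[i]] <- sub
  }
  cohort <- structure(list(params = params, subjects = subjects,
                           spec = spec, seed = seed),
                      class = "laa_cohort")
  if (!is.null(outdir)) write_cohort(cohort, outdir)
  cohort
}

#' @export
print.laa_cohort <- function(x, ...) {
  cat("laa_cohort:", nrow(x$params), "subjects (",
      sum(x$params$group == "control"), "control /",
      sum(x$params$group == "case"), "case ), seed", x$seed, "\n")
  invisible(x)
}

#' @keywords internal
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (id in names(cohort$subjects)) {
    sub <- cohort$subjects[[id]]
    mp <- file.path(outdir, paste0(id, ".ply"))
    write_surface_mesh(sub$mesh, mp)
    rp <- file.path(outdir, paste0(id, "_rim.csv"))
    write_ostium_rim(sub$mesh, rp)
    tp <- file.path(outdir, paste0(id, "_truth.json"))
    tr <- sub$truth
    tr$centreline <- NULL; tr$vertex_s <- NULL
    tr$target_tawss <- NULL; tr$target_osi <- NULL; tr$pose <- NULL
    jsonlite::write_json(tr, tp, auto_unbox = TRUE, digits = NA)
    files <- c(files, mp, rp, tp)
    if (!is.null(sub$series)) {
      sp <- file.path(outdir, paste0(id, "_wss.json"))
      write_wall_series(sub$series, sp)
      files <- c(files, sp, sub("\\.json$", ".csv", sp))
    }
  }
  pp <- file.path(outdir, "params.csv")
  write_feature_table(cohort$params, pp)
  files <- c(files, pp)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  invisible(outdir)
}

#' Measure one generated subject through the analysis pipeline
#'
#' @param sub one element of `generate_cohort()$subjects`
#' @param with_flow include haemodynamic features (needs series/flow)
#' @return named list of measured features
#' @export
measure_subject <- function(sub, with_flow = !is.null(sub$series)) {
  mf <- morpho_features(sub$mesh, shape_label = sub$params$shape_label,
                        la_volume_ml = sub$params$la_volume_ml)
  out <- unclass(mf)
  if (with_flow) {
    hf <- haemo_features(sub$series, sub$flow,
                         attr(mf, "aligned_mesh"),
                         attr(mf, "centreline"),
                         laa_volume_ml = out$laa_volume_ml)
    out <- c(out, unclass(hf))
  }
  out
}

#' Measure a whole cohort into a cohort feature table
#'
#' @param cohort an `laa_cohort`
#' @param with_flow include haemodynamic features
#' @return data.frame (cohort table) with `subject_id`, `group` and all
#'   measured features
#' @export
measure_cohort <- function(cohort, with_flow = TRUE) {
  rows <- lapply(seq_along(cohort$subjects), function(i) {
    f <- measure_subject(cohort$subjects[[i]], with_flow = with_flow)
    f <- f[!vapply(f, is.null, logical(1))]
    data.frame(subject_id = cohort$params$subject_id[i],
               group = cohort$params$group[i],
               as.data.frame(f[vapply(f, length, integer(1)) == 1]),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  validate_cohort_table(df)
}
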