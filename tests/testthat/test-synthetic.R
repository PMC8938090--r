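# The cohort generator: seeded reproducibility, calibration of the draws,
# mesh realization fidelity and field-synthesis recovery.

test_that("parameter draws are reproducible and calibrated", {
  spec <- synthetic_spec()
  p1 <- sample_cohort_params(spec, 7)
  p2 <- sample_cohort_params(spec, 7)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 71)
  expect_equal(sum(p1$group == "control"), 38)

  # large-sample calibration of the maximum ostium diameter (control row)
  big <- synthetic_spec(n_control = 1000L, n_case = 2L)
  pb <- sample_cohort_params(big, 5)
  ctl <- pb[pb$group == "control", ]
  se <- 4.40 / sqrt(1000)
  expect_lt(abs(mean(ctl$d_max) - 25.77), 3 * se + 0.15)
  expect_lt(abs(sd(ctl$d_max) - 4.40), 0.5)
  # drawn ostium diameters co-vary as configured
  expect_gt(cor(ctl$d_max, ctl$d_min), 0.5)
})

test_that("an identity copula leaves features uncorrelated", {
  spec <- synthetic_spec(n_control = 1000L, n_case = 2L,
                         rho_ostium = 0, rho_ostium_volume = 0)
  pb <- sample_cohort_params(spec, 6)
  ctl <- pb[pb$group == "control", ]
  # d_max/d_min are excluded: the feasibility redraw (minimum diameter must
  # stay below the maximum) correlates them even under an identity copula
  cors <- cor(ctl[, c("d_max", "laa_volume_ml", "centreline_length")])
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.1)
})

test_that("generated meshes are watertight with the right topology", {
  spec <- synthetic_spec()
  p <- sample_cohort_params(spec, 3)
  for (i in c(1, 2, 40)) {
    b <- build_laa_mesh(p[i, ])
    capped <- cap_ostium(b$mesh)
    expect_true(is_watertight(capped))
    nv <- nrow(capped$vertices)
    nf <- nrow(capped$faces)
    ne <- nv + nf - 2  # Euler characteristic 2 for a closed surface
    e <- rbind(capped$faces[, 1:2], capped$faces[, 2:3],
               capped$faces[, c(3, 1)])
    e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
    expect_equal(nrow(e), ne)
  }
})

test_that("a straight unit-tortuosity draw yields a straight tube", {
  b <- build_laa_mesh(list(d_max = 22, d_min = 18, centreline_length = 38,
                           tortuosity = 1, laa_volume_ml = 7))
  expect_equal(b$truth$tortuosity, 1)
  expect_equal(b$truth$bending_angle, 180)
  cl <- extract_centreline(align_to_ostium_frame(b$mesh)$mesh)
  expect_lt(abs(cl$arc_length / 38 - 1), 0.02)
})

test_that("swept analytic volume matches the measured mesh volume", {
  spec <- synthetic_spec()
  p <- sample_cohort_params(spec, 13)
  for (i in c(2, 17, 55)) {
    b <- build_laa_mesh(p[i, ])
    mm <- mesh_measures(b$mesh)
    expect_lt(abs(mm$volume_ml / b$truth$volume_ml - 1), 0.02)
  }
})

test_that("an infeasible bend/radius combination is a build error", {
  expect_error(
    build_laa_mesh(list(d_max = 40, d_min = 36, centreline_length = 20,
                        tortuosity = 0.45, laa_volume_ml = 10)),
    "self-intersecting sweep")
})

test_that("synthesised fields recover their per-node index targets", {
  spec <- synthetic_spec()
  p <- sample_cohort_params(spec, 42)
  for (i in c(1, 40)) {
    b <- build_laa_mesh(p[i, ])
    fl <- synthesize_flow(p[i, ], b$mesh, b$truth)
    idx <- compute_wss_indices(fl$series)
    expect_lt(max(abs(idx$osi - fl$targets$osi)), 0.01)
    expect_lt(max(abs(idx$tawss / fl$targets$tawss - 1)), 0.02)
    # trimmed-mean ECAP equals the subject's draw by construction
    expect_equal(trimmed_aggregate(idx$ecap), p$ecap[i], tolerance = 1e-6)
    v <- b$truth$volume_ml
    expect_lt(abs(stagnation_fraction(fl$flow, v) - p$stagnation_pct[i]), 1)
    expect_equal(velocity_index(fl$flow, v), p$vel_laav[i],
                 tolerance = 1e-9)
    # sample weights integrate to the LAA volume
    expect_lt(abs(sum(fl$flow$sample_weights) / v - 1), 0.02)
  }
})

test_that("zero oscillatory target yields zero OSI everywhere", {
  spec <- synthetic_spec()
  p <- sample_cohort_params(spec, 2)
  pr <- p[1, ]
  pr$osi <- 0
  b <- build_laa_mesh(pr)
  fl <- synthesize_flow(pr, b$mesh, b$truth)
  idx <- compute_wss_indices(fl$series)
  expect_lt(max(idx$osi), 1e-6)
})

test_that("including the ramped first beat biases the indices", {
  spec <- synthetic_spec()
  p <- sample_cohort_params(spec, 8)
  b <- build_laa_mesh(p[1, ])
  fl <- synthesize_flow(p[1, ], b$mesh, b$truth)
  i12 <- compute_wss_indices(fl$series, window = c(1, 2))
  i23 <- compute_wss_indices(fl$series, window = c(2, 3))
  expect_gt(mean(abs(i12$tawss / i23$tawss - 1)), 0.05)
})

test_that("cohort generation is deterministic and written bundles verify", {
  spec <- synthetic_spec(n_control = 2L, n_case = 1L)
  c1 <- generate_cohort(spec, seed = 4, with_flow = FALSE)
  c2 <- generate_cohort(spec, seed = 4, with_flow = FALSE)
  expect_identical(c1$params, c2$params)
  expect_identical(c1$subjects[[1]]$mesh$vertices,
                   c2$subjects[[1]]$mesh$vertices)
  outdir <- file.path(tempdir(), "cohort-bundle")
  unlink(outdir, recursive = TRUE)
  generate_cohort(spec, seed = 4, outdir = outdir, with_flow = FALSE)
  man <- read.csv(file.path(outdir, "manifest.csv"))
  expect_true(all(file.exists(file.path(outdir, man$file))))
  md5 <- unname(tools::md5sum(file.path(outdir, man$file)))
  expect_identical(md5, man$md5)
  # mesh + rim round-trip through the bundle
  id <- c1$params$subject_id[1]
  back <- read_surface_mesh(file.path(outdir, paste0(id, ".ply")),
                            rim_path = file.path(outdir,
                                                 paste0(id, "_rim.csv")),
                            rim_tol = 1e-4)
  expect_equal(nrow(back$vertices), nrow(c1$subjects[[1]]$mesh$vertices))
  expect_equal(back$ostium_rim, c1$subjects[[1]]$mesh$ostium_rim)
})

test_that("a small cohort runs the full pipeline without missing features", {
  spec <- synthetic_spec(n_control = 2L, n_case = 2L)
  coh <- generate_cohort(spec, seed = 12)
  tab <- measure_cohort(coh)
  expect_equal(nrow(tab), 4)
  num <- vapply(tab, is.numeric, logical(1))
  expect_false(anyNA(tab[, num]))
})
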