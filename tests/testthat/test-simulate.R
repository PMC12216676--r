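test_that("excited reflections satisfy the Ewald condition and round-trip", {
  set.seed(71)
  det <- test_detector()
  cr <- random_test_crystal()
  eps <- 0.002
  nd <- diffracting_nodes(cr, 20, det, eps, 2.5)
  expect_gt(nrow(nd), 50)
  inv_lambda <- 1 / det$wavelength_A
  radii <- sqrt((nd$qx + inv_lambda)^2 + nd$qy^2 + nd$qz^2)
  expect_true(all(abs(radii - inv_lambda) <= eps))

  # re-projection through the Ewald back-projection reproduces each node
  rec <- spots_to_nodes(nd, det)
  err <- sqrt(rowSums((rec - as.matrix(nd[, c("qx", "qy", "qz")]))^2))
  expect_true(all(err <= eps + 1e-9))

  # a vanishing excitation tolerance excites (almost surely) nothing
  expect_equal(nrow(diffracting_nodes(cr, 20, det, 1e-12, 2.5)), 0)
})

test_that("Miller-index enumeration covers exactly the resolution sphere", {
  # cubic 100 A cell at 2 A cutoff: indices run to a/d = 50 per axis
  cr <- synthetic_crystal(c(100, 100, 100, 90, 90, 90), diag(3),
                          c(0, 0, 0), rep(0.01, 3))
  lat <- crossmesh:::crystal_lattice_points(cr, 2)
  expect_equal(max(abs(lat$h)), 50)
  expect_true(all(sqrt(rowSums(lat$q^2)) <= 0.5 + 1e-12))
  # the axial reflection at the cutoff is present
  expect_true(any(lat$h[, 1] == 50 & lat$h[, 2] == 0 & lat$h[, 3] == 0))
})

test_that("rendering is deterministic and footprints match the box geometry", {
  cf <- simulation_config(n_crystals = 2, seed = 123, n_u = 14, n_v = 10)
  a <- render_double_mesh(cf)
  b <- render_double_mesh(cf)
  expect_identical(a, b)

  # a crystal spanning 3 x 2 cells produces exactly those non-noise cells
  sim <- a
  ct <- sim$truth$contributors1
  for (id in unique(ct$crystal)) {
    b1 <- sim$truth$footprints1[[id]]
    g <- sim$scan1$geometry
    iu <- 0:(g$n_u - 1); iv <- 0:(g$n_v - 1)
    cu <- g$grid_origin_mm[1] + iu * g$step_mm
    cv <- g$grid_origin_mm[2] + iv * g$step_mm
    want_u <- iu[cu >= b1$u - b1$hu & cu <= b1$u + b1$hu]
    want_v <- iv[cv >= b1$v - b1$hv & cv <= b1$v + b1$hv]
    got <- ct[ct$crystal == id, c("iu", "iv")]
    expect_setequal(got$iu, want_u)
    expect_setequal(got$iv, want_v)
    expect_equal(nrow(got), length(want_u) * length(want_v))
  }
})

test_that("noiseless footprint centroids triangulate back to the seeded position", {
  sim <- render_double_mesh(simulation_config(n_crystals = 3, seed = 83,
                                              noise_per_cell = 0))
  step <- sim$scan1$geometry$step_mm
  score_centroid <- function(scan, cells) {
    sc <- vapply(seq_len(nrow(cells)), function(i) {
      scan$cells[[cells$iv[i] * scan$geometry$n_u + cells$iu[i] + 1]]$score
    }, numeric(1))
    cen <- crossmesh:::cell_centre_mm(scan$geometry, cells$iu, cells$iv)
    w <- sc / sum(sc)
    c(u = sum(w * cen[, "u"]), v = sum(w * cen[, "v"]))
  }
  for (id in sim$truth$visible_both) {
    c1 <- score_centroid(sim$scan1,
                         sim$truth$contributors1[sim$truth$contributors1$crystal == id, ])
    c2 <- score_centroid(sim$scan2,
                         sim$truth$contributors2[sim$truth$contributors2$crystal == id, ])
    p <- triangulate_centre(c(c1[["v"]], c1[["u"]]), c(c2[["v"]], c2[["u"]]),
                            sim$truth$alpha_deg)
    tr <- sim$truth$crystals[id, ]
    expect_lte(abs(p$x - tr$x), step / 2)
    expect_lte(abs(p$y - tr$y), step / 2)
    expect_lte(abs(p$z - tr$z), step / 2)
  }
})

test_that("crystals at one grid position but different depths separate in scan 2", {
  det <- test_detector()
  mk <- function(x) synthetic_crystal(c(60, 60, 60, 90, 90, 90), diag(3),
                                      c(x, 0.05, 0.1), rep(0.008, 3))
  b1a <- crossmesh:::footprint_box(mk(0.00), 0)
  b1b <- crossmesh:::footprint_box(mk(0.08), 0)
  expect_equal(b1a$v, b1b$v)
  expect_equal(b1a$u, b1b$u)
  b2a <- crossmesh:::footprint_box(mk(0.00), 30)
  b2b <- crossmesh:::footprint_box(mk(0.08), 30)
  expect_gt(abs(b2a$v - b2b$v), 0.01)
})

test_that("node sets of one crystal at the two angles are slices of one lattice", {
  set.seed(89)
  det <- test_detector()
  cfg <- crossmesh_config()
  hits <- vapply(1:5, function(i) {
    cr <- random_test_crystal()
    dmin <- crossmesh:::auto_d_min(cr$cell, 0.002, 500)
    n1 <- spots_to_nodes(diffracting_nodes(cr, 0, det, 0.002, dmin), det)
    n2 <- spots_to_nodes(diffracting_nodes(cr, 60, det, 0.002, dmin), det)
    pv <- find_planes(n1, cfg)
    if (nrow(pv) == 0) return(NA)
    scores <- vapply(seq_len(nrow(pv)), function(k) {
      check_plane(rotate_about_axis(c(pv$vx[k], pv$vy[k], pv$vz[k]), 60), n2, cfg)
    }, numeric(1))
    max(scores) > 5
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.95)
})
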