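test_that("the direction set is a unit-norm, well-spread hemisphere layout", {
  expect_equal(dim(build_direction_set(1)), c(1, 3))
  expect_equal(sum(build_direction_set(1)^2), 1)

  D <- build_direction_set(2500)
  norms <- sqrt(rowSums(D^2))
  expect_true(all(abs(norms - 1) < 1e-12))
  expect_true(all(D[, 3] > 0))   # one hemisphere: no antipodal duplicates

  # quasi-uniformity: minimum pairwise angle within a constant of the
  # ideal spacing sqrt(2*pi/n)
  G <- unclass(D) %*% t(unclass(D))
  diag(G) <- -1
  min_angle <- acos(min(max(G), 1))
  expect_gte(min_angle, 0.6 * sqrt(2 * pi / 2500))
})

test_that("projections are linear axis coordinates", {
  nodes <- rbind(c(0.1, 0.2, 0.3), c(-0.05, 0, 0.02))
  expect_equal(project_nodes(nodes, c(1, 0, 0)), c(0.1, -0.05))
  u <- c(0.3, -0.5, 0.8)
  expect_equal(project_nodes(nodes, -u), -project_nodes(nodes, u))
})

test_that("projections of lattice nodes onto a family normal are near-integer multiples", {
  set.seed(19)
  det <- test_detector()
  cr <- random_test_crystal()
  nd <- diffracting_nodes(cr, 0, det, 0.002, 2.5)
  fam <- lattice_families(cr)
  j <- which.min(fam$lengths)
  u <- fam$vectors[j, ] / fam$lengths[j]
  coords <- project_nodes(as.matrix(nd[, c("qx", "qy", "qz")]), u) * fam$lengths[j]
  # true node positions project to exact integers (lattice geometry)
  expect_true(all(abs(coords - round(coords)) < 1e-9))
  # reconstructed nodes stay within the excitation tolerance of those planes
  rec <- project_nodes(spots_to_nodes(nd, det), u) * fam$lengths[j]
  expect_true(all(abs(rec - round(rec)) < 0.002 * fam$lengths[j] + 1e-6))
})

test_that("histogram normalisation removes offset and scales to unit variance", {
  # constant counts: moving average equals the counts, h is identically 0
  h <- normalize_histogram(rep(7, 256))
  expect_true(all(abs(h$h) < 1e-12))

  # a single occupied bin on a flat background peaks at that bin
  H <- rep(20, 128)
  H[60] <- 120
  nh <- normalize_histogram(H)
  expect_equal(which.max(nh$h), 60)

  # histogram construction: counts and span
  set.seed(5)
  x <- runif(1000, -0.4, 0.4)
  hist <- make_histogram(x, 0.002)
  expect_equal(sum(hist$counts), 1000)
  expect_gte(length(hist$counts), diff(range(x)) / 0.002)
})

test_that("spectrum scaling makes a pure cosine score sqrt(n/2) and the null Rayleigh", {
  h <- cos(2 * pi * 10 * (0:127) / 128)
  sp <- score_spectrum(h, bin_width = 0.002)
  expect_equal(sp$score[sp$k == 10], sqrt(128 / 2), tolerance = 1e-12)

  expect_true(all(score_spectrum(rep(0, 128), 0.002)$score == 0))

  # Rayleigh tail probabilities behind the two decision thresholds
  expect_equal(rayleigh_survival(7), exp(-49 / 2))
  expect_equal(rayleigh_survival(5), exp(-25 / 2))

  # i.i.d. Poisson counts: unmasked scores are unit Rayleigh
  set.seed(8)
  H <- rpois(4096, 100)
  sp <- score_spectrum(normalize_histogram(H)$h, bin_width = 0.002)
  sc <- sp$score[!sp$masked]
  ks <- ks.test(sc, function(q) 1 - exp(-q^2 / 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("compiled direction scan equals the R pipeline composition", {
  set.seed(23)
  nodes <- striped_nodes(120, d_A = 28)
  D <- build_direction_set(40)
  pl <- crossmesh_config()$planes
  fast <- crossmesh:::cpp_scan_directions(nodes, unclass(D), pl$bin_width_invA,
                                          pl$smooth_sigma_bins, pl$p_floor,
                                          pl$g_max, pl$min_period_A)
  for (j in seq_len(nrow(D))) {
    coords <- project_nodes(nodes, D[j, ])
    hist <- make_histogram(coords, pl$bin_width_invA)
    nh <- normalize_histogram(hist, pl$smooth_sigma_bins, pl$p_floor)
    sp <- score_spectrum(nh$h, pl$bin_width_invA, pl$smooth_sigma_bins,
                         pl$g_max, pl$min_period_A)
    pk <- spectrum_peak(sp)
    expect_equal(unname(pk$score), unname(fast[j, 1]), tolerance = 1e-8)
    expect_equal(unname(pk$freq_A), unname(fast[j, 2]), tolerance = 1e-8)
  }
})

test_that("find_planes recovers true lattice-plane families", {
  set.seed(29)
  det <- test_detector()
  ok <- vapply(1:5, function(i) {
    cr <- random_test_crystal()
    nd <- diffracting_nodes(cr, 0, det, 0.002,
                            crossmesh:::auto_d_min(cr$cell, 0.002, 500))
    pv <- find_planes(spots_to_nodes(nd, det), crossmesh_config())
    matches_family(pv, lattice_families(cr))
  }, logical(1))
  expect_gte(sum(ok), 4)
})

test_that("find_planes is empty for sparse input and lattice-free nodes", {
  cfg <- crossmesh_config()
  expect_equal(nrow(find_planes(matrix(rnorm(30), 10, 3), cfg)), 0)
  set.seed(37)
  expect_equal(nrow(find_planes(noise_nodes(300), cfg)), 0)
})

test_that("no two reported plane vectors are near-parallel duplicates", {
  set.seed(43)
  det <- test_detector()
  cr <- random_test_crystal()
  nd <- diffracting_nodes(cr, 0, det, 0.002, 2.5)
  pv <- find_planes(spots_to_nodes(nd, det), fast_config(1500))
  if (nrow(pv) > 1) {
    for (i in seq_len(nrow(pv) - 1)) {
      for (j in (i + 1):nrow(pv)) {
        vi <- c(pv$vx[i], pv$vy[i], pv$vz[i])
        vj <- c(pv$vx[j], pv$vy[j], pv$vz[j])
        ang <- acos(min(1, abs(sum(vi * vj)) /
                          sqrt(sum(vi^2) * sum(vj^2)))) * 180 / pi
        same <- ang < 2 && abs(pv$freq_A[i] / pv$freq_A[j] - 1) < 0.02
        expect_false(same)
      }
    }
  }
  expect_true(all(pv$score > 7))
  expect_equal(sqrt(pv$vx^2 + pv$vy^2 + pv$vz^2), pv$freq_A)
})
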