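test_that("cell score is the background-weighted intensity sum", {
  expect_equal(cell_score(data.frame(intensity = numeric(0),
                                     background = numeric(0))), 0)
  expect_equal(cell_score(data.frame(intensity = 10, background = 0)), 10)
  sp <- data.frame(intensity = c(2, 5, 1), background = c(1, 4, 0))
  expect_equal(cell_score(transform(sp, intensity = 2 * intensity)),
               2 * cell_score(sp))
})

test_that("cell similarity counts one-to-one matches within the pixel radius", {
  a <- data.frame(x_px = c(10, 50, 90), y_px = c(10, 50, 90),
                  intensity = 1, background = 0)
  expect_equal(cell_similarity(a, a), 1)
  b <- data.frame(x_px = a$x_px + 500, y_px = a$y_px, intensity = 1,
                  background = 0)
  expect_equal(cell_similarity(a, b), 0)
  # one spot matched, displaced within the radius; two beyond it
  c_ <- data.frame(x_px = c(12, 70, 200), y_px = c(11, 80, 300),
                   intensity = 1, background = 0)
  expect_equal(cell_similarity(a, c_), 1 / 3)
  # a single target spot can absorb only one query spot
  d1 <- data.frame(x_px = c(10, 11), y_px = c(10, 10), intensity = 1,
                   background = 0)
  d2 <- data.frame(x_px = 10, y_px = 10, intensity = 1, background = 0)
  expect_equal(cell_similarity(d1, d2), 1)  # smaller list has one spot
  expect_equal(cell_similarity(d2, d1), 1)
})

test_that("adjacent cells of one simulated crystal are similar above threshold", {
  sim <- render_double_mesh(simulation_config(n_crystals = 1, seed = 21))
  ct <- sim$truth$contributors1
  cells <- lapply(seq_len(nrow(ct)), function(i) {
    sim$scan1$cells[[ct$iv[i] * sim$scan1$geometry$n_u + ct$iu[i] + 1]]
  })
  expect_gt(length(cells), 1)
  sims <- c()
  for (i in seq_along(cells)) for (j in seq_along(cells)) {
    if (i < j && abs(cells[[i]]$iu - cells[[j]]$iu) +
        abs(cells[[i]]$iv - cells[[j]]$iv) == 1) {
      sims <- c(sims, cell_similarity(cells[[i]]$spots, cells[[j]]$spots))
    }
  }
  expect_true(all(sims > 0.4))
})

test_that("multi-pattern flag separates single from superimposed patterns", {
  set.seed(31)
  sim <- render_double_mesh(simulation_config(n_crystals = 6, seed = 7))
  det <- sim$scan1$detector
  ct <- sim$truth$contributors1
  by_crystal <- split(seq_len(nrow(ct)), ct$crystal)
  one_cell <- function(k) {
    i <- by_crystal[[k]][1]
    sim$scan1$cells[[ct$iv[i] * sim$scan1$geometry$n_u + ct$iu[i] + 1]]$spots
  }
  # single-crystal cells are not flagged
  singles <- vapply(seq_along(by_crystal), function(k) {
    multipattern_flag(one_cell(k), det = det)
  }, logical(1))
  expect_true(all(!singles))
  # merged spot lists of two different crystals are flagged
  overlaps <- c()
  for (i in seq_along(by_crystal)) for (j in seq_along(by_crystal)) {
    if (i < j) {
      overlaps <- c(overlaps,
                    multipattern_flag(rbind(one_cell(i), one_cell(j)), det = det))
    }
  }
  expect_gte(mean(overlaps), 0.8)
  # below the evidence floor nothing is flagged
  few <- one_cell(1)[1:10, ]
  expect_false(multipattern_flag(few, det = det))
})

test_that("segmentation recovers simulated crystals as labelled partitions", {
  cfg <- fast_config()
  sim <- render_double_mesh(simulation_config(n_crystals = 2, seed = 17))
  seg <- segment_scan(sim$scan1, cfg)
  expect_length(seg$regions, 2)

  # partition: every labelled cell belongs to exactly one region
  lab <- seg$labels
  for (r in seg$regions) {
    got <- lab[cbind(r$cells$iv + 1, r$cells$iu + 1)]
    expect_true(all(got == r$label))
  }
  counted <- sum(vapply(seg$regions, function(r) nrow(r$cells), integer(1)))
  expect_equal(sum(lab %in% seq_along(seg$regions)), counted)

  # labels 1..K ordered by decreasing integral score
  sc <- vapply(seg$regions, `[[`, numeric(1), "integral_score")
  expect_equal(vapply(seg$regions, `[[`, integer(1), "label"), seq_along(sc))
  expect_true(all(diff(sc) <= 0))

  # each region's cells coincide with one crystal's footprint cells
  ids <- region_truth_ids(seg, sim$truth$contributors1)
  expect_setequal(ids, c(1L, 2L))

  # beam size: smallest aperture covering the smaller extent
  for (r in seg$regions) {
    ap <- c(10, 20, 30, 50)
    need <- min(r$extents_mm) * 1000
    want <- if (any(ap >= need)) min(ap[ap >= need]) else max(ap)
    expect_equal(r$beam_size_um, want)
  }
})

test_that("an empty scan yields no regions", {
  sim <- render_double_mesh(simulation_config(n_crystals = 0, seed = 2,
                                              n_u = 8, n_v = 6,
                                              noise_per_cell = 0))
  seg <- segment_scan(sim$scan1)
  expect_length(seg$regions, 0)
  expect_true(all(seg$labels == 0))
})

test_that("region count equals seeded crystal count across seeds", {
  cfg <- fast_config()
  hits <- vapply(1:12, function(s) {
    sim <- render_double_mesh(simulation_config(n_crystals = 4, seed = 100 + s,
                                                min_gap_cells = 2))
    seg <- segment_scan(sim$scan1, cfg)
    visible <- length(unique(sim$truth$contributors1$crystal))
    length(seg$regions) == visible
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("pair candidates equal the brute-force rotation-axis filter", {
  cfg <- crossmesh_config()
  set.seed(41)
  mkregion <- function(label, u, v) {
    structure(list(label = label, cells = data.frame(iu = 0, iv = 0, score = 1),
                   centroid_mm = c(u = u, v = v), extents_mm = c(du = 0.01, dv = 0.01),
                   integral_score = 1, nodes = NULL, beam_size_um = 10),
              class = "CrystalRegion")
  }
  mkseg <- function(n) {
    structure(list(regions = lapply(seq_len(n), function(i) {
      mkregion(i, runif(1, 0, 0.4), runif(1, 0, 0.2))
    }), labels = NULL), class = "MeshSegmentation")
  }
  seg1 <- mkseg(43)
  seg2 <- mkseg(37)
  step <- 0.01
  cands <- pair_candidates(seg1, seg2, 60, step, cfg)
  tol <- cfg$segment$pairing_tolerance_cells * step
  brute <- 0
  for (a in seg1$regions) for (b in seg2$regions) {
    if (abs(a$centroid_mm[["u"]] - b$centroid_mm[["u"]]) <= tol) brute <- brute + 1
  }
  expect_equal(nrow(cands), brute)
  expect_true(all(cands$z_gap_mm <= tol))

  # identical u always pairs; a 5-cell offset never does
  s1 <- structure(list(regions = list(mkregion(1, 0.10, 0.05))),
                  class = "MeshSegmentation")
  s2a <- structure(list(regions = list(mkregion(1, 0.10, 0.02))),
                   class = "MeshSegmentation")
  s2b <- structure(list(regions = list(mkregion(1, 0.15, 0.02))),
                   class = "MeshSegmentation")
  expect_equal(nrow(pair_candidates(s1, s2a, 60, step, cfg)), 1)
  expect_equal(nrow(pair_candidates(s1, s2b, 60, step, cfg)), 0)
})
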