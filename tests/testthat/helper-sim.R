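# Shared fixtures and oracles, all built in code.

test_detector <- function() {
  detector_geometry(0.861, 180, c(2074, 2181), 0.075, c(4148, 4362))
}

# random crystal with a given cell-length range, at the origin
random_test_crystal <- function(len_range = c(40, 90), ang_range = c(80, 100),
                                position = c(0, 0.05, 0.1), half = rep(0.01, 3)) {
  cell <- c(runif(3, len_range[1], len_range[2]),
            runif(3, ang_range[1], ang_range[2]))
  synthetic_crystal(cell, crossmesh:::random_rotation(), position, half)
}

# lattice-free nodes: uniform random detector positions back-projected onto
# the Ewald sphere
noise_nodes <- function(n, det = test_detector()) {
  spots_to_nodes(data.frame(x_px = runif(n, 50, det$detector_shape_px[1] - 50),
                            y_px = runif(n, 50, det$detector_shape_px[2] - 50)),
                 det)
}

# direct-lattice plane families (vectors t = u a + v b + w c, |t| <= max_len)
# of a crystal at scan angle omega; the oracle for plane-vector recovery
lattice_families <- function(crystal, omega_deg = 0, max_order = 3,
                             max_len = 250) {
  A <- rotate_about_axis(t(crystal$orientation %*%
                             crossmesh:::direct_basis(crystal$cell)), omega_deg)
  comb <- as.matrix(expand.grid(-max_order:max_order, -max_order:max_order,
                                -max_order:max_order))
  comb <- comb[rowSums(comb != 0) > 0, ]
  Tv <- comb %*% A
  Tl <- sqrt(rowSums(Tv^2))
  keep <- Tl <= max_len
  list(vectors = Tv[keep, , drop = FALSE], lengths = Tl[keep])
}

# TRUE when at least one recovered plane vector matches a true family
# within ang_tol degrees in direction and rel_tol in period
matches_family <- function(planes, fam, ang_tol = 1, rel_tol = 0.02) {
  if (nrow(planes) == 0) return(FALSE)
  any(vapply(seq_len(nrow(planes)), function(i) {
    v <- c(planes$vx[i], planes$vy[i], planes$vz[i])
    vl <- sqrt(sum(v^2))
    cosang <- abs(fam$vectors %*% v) / (fam$lengths * vl)
    ang <- acos(pmin(1, cosang)) * 180 / pi
    any(ang < ang_tol & abs(vl / fam$lengths - 1) < rel_tol)
  }, logical(1)))
}

# map each segmented region to the simulator crystal contributing most cells
region_truth_ids <- function(seg, contributors) {
  vapply(seg$regions, function(r) {
    ids <- integer(0)
    for (k in seq_len(nrow(r$cells))) {
      ids <- c(ids, contributors[contributors$iu == r$cells$iu[k] &
                                   contributors$iv == r$cells$iv[k], "crystal"])
    }
    if (!length(ids)) NA_integer_
    else as.integer(names(sort(table(ids), decreasing = TRUE))[1])
  }, integer(1))
}

# elongated striped node cloud: nodes quantised with period d_A along a
# random axis, long extent along that axis and small perpendicular spread;
# gives a single strong, angularly broad periodicity
striped_nodes <- function(n = 100, d_A = 30, span = 0.15, perp = 0.04) {
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  a <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- crossmesh:::pracma_cross(u, a); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- crossmesh:::pracma_cross(u, e1)
  t <- round(runif(n, -span, span) * d_A) / d_A
  outer(t, u) + outer(runif(n, -perp, perp), e1) + outer(runif(n, -perp, perp), e2)
}

# reduced-size analysis config for unit tests (fewer scan directions)
fast_config <- function(n_directions = 800, ...) {
  crossmesh_config(list(planes = list(n_directions = n_directions, ...)))
}
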