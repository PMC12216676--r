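#' Synthetic crystal
#'
#' A virtual crystal for the double-mesh simulator: triclinic unit cell,
#' orientation, 3D position in the frame of the first scan, box half-extents
#' and an intensity scale.
#'
#' @param cell length-6 numeric `(a, b, c, alpha, beta, gamma)`
#'   (angstrom / degrees).
#' @param orientation 3 x 3 rotation matrix.
#' @param position_mm length-3 `(x, y, z)` position (mm, scan-1 frame:
#'   x along the beam, z along the rotation axis).
#' @param half_extents_mm length-3 box half-extents (mm).
#' @param intensity_scale arbitrary intensity unit for generated spots.
#' @return Object of class `SyntheticCrystal`.
#' @export
synthetic_crystal <- function(cell, orientation, position_mm, half_extents_mm,
                              intensity_scale = 50) {
  stopifnot(length(cell) == 6, all(cell[1:3] > 0),
            all(dim(orientation) == c(3, 3)),
            length(position_mm) == 3, length(half_extents_mm) == 3,
            all(half_extents_mm > 0))
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-8) {
    stop("orientation is not orthonormal", call. = FALSE)
  }
  structure(
    list(cell = as.numeric(cell), orientation = orientation,
         position_mm = as.numeric(position_mm),
         half_extents_mm = as.numeric(half_extents_mm),
         intensity_scale = intensity_scale),
    class = "SyntheticCrystal"
  )
}

# direct-basis matrix (columns a, b, c) from cell parameters
direct_basis <- function(cell) {
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  cx <- cos(be)
  cy <- (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz2 <- 1 - cx^2 - cy^2
  if (cz2 <= 0) stop("degenerate unit cell", call. = FALSE)
  cbind(
    c(a, 0, 0),
    c(b * cos(ga), b * sin(ga), 0),
    cc * c(cx, cy, sqrt(cz2))
  )
}

# reciprocal-basis matrix (columns a*, b*, c*); q = Bstar %*% h
reciprocal_basis <- function(cell) t(solve(direct_basis(cell)))

# random rotation matrix via a uniform quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Enumerate reciprocal-lattice points of one crystal (scan-1 frame, omega
# relative to scan 1 equal to zero) within |q| <= 1/d_min.  The Miller-index
# bound |h_i| <= ceil(len_i / d_min) is exact: h_i is the dot product of q
# with the i-th direct basis vector.
crystal_lattice_points <- function(crystal, d_min) {
  Bs <- crystal$orientation %*% reciprocal_basis(crystal$cell)
  qmax <- 1 / d_min
  hmax <- ceiling(crystal$cell[1:3] / d_min)
  h2 <- seq(-hmax[2], hmax[2])
  h3 <- seq(-hmax[3], hmax[3])
  grid23 <- as.matrix(expand.grid(h = 0, k = h2, l = h3))
  out_h <- vector("list", 2 * hmax[1] + 1)
  out_q <- vector("list", 2 * hmax[1] + 1)
  i <- 0
  for (h1 in seq(-hmax[1], hmax[1])) {
    grid23[, 1] <- h1
    q <- grid23 %*% t(Bs)
    keep <- rowSums(q^2) <= qmax^2 & !(grid23[, 1] == 0 & grid23[, 2] == 0 & grid23[, 3] == 0)
    i <- i + 1
    out_h[[i]] <- grid23[keep, , drop = FALSE]
    out_q[[i]] <- q[keep, , drop = FALSE]
  }
  list(h = do.call(rbind, out_h), q = do.call(rbind, out_q))
}

#' Reciprocal-lattice nodes satisfying the diffraction condition
#'
#' Enumerates the crystal's reciprocal lattice to the resolution cutoff,
#' rotates it to the requested goniometer angle and keeps the nodes lying
#' within the excitation tolerance of the Ewald sphere,
#' \eqn{||q + k_{in}| - 1/\lambda| \le \epsilon}; each surviving node is
#' projected to its detector spot position.  The excitation tolerance is the
#' simulator's stand-in for mosaicity and bandwidth.
#'
#' @param crystal a [synthetic_crystal()].
#' @param omega_deg goniometer angle relative to the first scan (degrees).
#' @param det a [detector_geometry()].
#' @param epsilon excitation tolerance (1/angstrom).
#' @param d_min resolution cutoff (angstrom).
#' @return Data frame with Miller indices `h`, `k`, `l`, node position
#'   `qx`, `qy`, `qz` (1/angstrom, laboratory frame at `omega_deg`) and
#'   detector position `x_px`, `y_px`.  Nodes whose diffracted ray misses
#'   the detector are dropped.
#' @export
diffracting_nodes <- function(crystal, omega_deg, det, epsilon = 0.002,
                              d_min = 2.5) {
  stopifnot(epsilon > 0, d_min > 0)
  lat <- crystal_lattice_points(crystal, d_min)
  if (nrow(lat$q) == 0) return(empty_node_df())
  q <- rotate_about_axis(lat$q, omega_deg)
  inv_lambda <- 1 / det$wavelength_A
  kx <- q[, 1] + inv_lambda
  kn <- sqrt(kx^2 + q[, 2]^2 + q[, 3]^2)
  keep <- abs(kn - inv_lambda) <= epsilon
  if (!any(keep)) return(empty_node_df())
  q <- q[keep, , drop = FALSE]
  hkl <- lat$h[keep, , drop = FALSE]
  kx <- kx[keep]; kn <- kn[keep]
  ux <- kx / kn; uy <- q[, 2] / kn; uz <- q[, 3] / kn
  fwd <- ux > 0.05
  t_ <- det$distance_mm / ux
  x_px <- det$beam_centre_px[1] + (t_ * uz) / det$pixel_size_mm
  y_px <- det$beam_centre_px[2] + (t_ * uy) / det$pixel_size_mm
  ok <- fwd & x_px >= 0 & x_px <= det$detector_shape_px[1] &
    y_px >= 0 & y_px <= det$detector_shape_px[2]
  data.frame(h = hkl[ok, 1], k = hkl[ok, 2], l = hkl[ok, 3],
             qx = q[ok, 1], qy = q[ok, 2], qz = q[ok, 3],
             x_px = x_px[ok], y_px = y_px[ok])
}

empty_node_df <- function() {
  data.frame(h = integer(0), k = integer(0), l = integer(0),
             qx = numeric(0), qy = numeric(0), qz = numeric(0),
             x_px = numeric(0), y_px = numeric(0))
}

#' Simulation configuration
#'
#' Defaults emulate a multi-crystal micromesh sample scanned on a modern
#' MX beamline: 10-30 micron crystals on a 10 micron-pitch grid, a
#' 4M-class pixel area at 180 mm, 14.4 keV (0.861 angstrom), two scans 60
#' degrees apart, five uniform noise spots per image and an excitation
#' tolerance of 0.002 per angstrom.
#'
#' @param n_crystals number of crystals.
#' @param seed RNG seed; the output is bit-reproducible given the seed.
#' @param omega1_deg,omega2_deg goniometer angles of the two scans.
#' @param n_u,n_v,step_mm,grid_origin_mm scan grid.
#' @param detector a [detector_geometry()].
#' @param cell_len_range,cell_ang_range unit-cell sampling ranges
#'   (angstrom / degrees).
#' @param size_um_range crystal edge-length sampling range (micron).
#' @param epsilon excitation tolerance (1/angstrom).
#' @param d_min resolution cutoff (angstrom), or `NULL` to pick per crystal
#'   so that roughly `target_spots` reflections are excited.
#' @param target_spots per-crystal spot-count target used when
#'   `d_min = NULL`.
#' @param spot_cap maximum spots retained per cell (strongest first).
#' @param noise_per_cell expected uniform noise spots per grid cell.
#' @param noise_intensity_max noise spot intensity upper bound.
#' @param background mean local background reported with every spot.
#' @param intensity_scale crystal spot intensity scale.
#' @param min_gap_cells minimum footprint separation (grid cells) enforced
#'   between crystals in both scans.
#' @return List of class `SimulationConfig`.
#' @export
simulation_config <- function(n_crystals = 8, seed = 1,
                              omega1_deg = 0, omega2_deg = 60,
                              n_u = 30, n_v = 20, step_mm = 0.01,
                              grid_origin_mm = c(0, 0),
                              detector = detector_geometry(
                                0.861, 180, c(2074, 2181), 0.075, c(4148, 4362)),
                              cell_len_range = c(40, 90),
                              cell_ang_range = c(80, 100),
                              size_um_range = c(10, 30),
                              epsilon = 0.002, d_min = NULL,
                              target_spots = 600, spot_cap = 600,
                              noise_per_cell = 5, noise_intensity_max = 2,
                              background = 10, intensity_scale = 50,
                              min_gap_cells = 1) {
  stopifnot(n_crystals >= 0, epsilon > 0,
            abs(sin((omega2_deg - omega1_deg) * pi / 180)) > 1e-9)
  structure(as.list(environment()), class = "SimulationConfig")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# resolution cutoff giving ~target excited reflections for a cell volume:
# the Ewald shell of thickness 2*epsilon inside |q| < qmax holds about
# pi * qmax^2 * 2 * epsilon * V_cell nodes
auto_d_min <- function(cell, epsilon, target) {
  V <- abs(det(direct_basis(cell)))
  qmax <- sqrt(target / (pi * 2 * epsilon * V))
  1 / min(max(qmax, 0.25), 0.72)
}

# footprint of a crystal box on the scan grid at relative angle omega:
# centre (u, v), half-extents (hu, hv) in mm
footprint_box <- function(crystal, omega_deg) {
  p <- crystal$position_mm
  he <- crystal$half_extents_mm
  a <- omega_deg * pi / 180
  list(
    u = p[3],
    v = p[2] * cos(a) - p[1] * sin(a),
    hu = he[3],
    hv = abs(he[1] * sin(a)) + abs(he[2] * cos(a))
  )
}

boxes_separated <- function(b1, b2, gap_mm) {
  (abs(b1$u - b2$u) > b1$hu + b2$hu + gap_mm) ||
    (abs(b1$v - b2$v) > b1$hv + b2$hv + gap_mm)
}

#' Render a synthetic double mesh scan
#'
#' Generates two mesh scans of a virtual multi-crystal sample with exact
#' ground truth.  Crystals receive random unit cells, orientations, sizes
#' and positions (rejection-sampled so that footprints stay inside both
#' scan grids and do not overlap); each crystal's excited reflections are
#' computed per scan from the Ewald condition and written into every grid
#' cell covered by the crystal's projected footprint, with intensities
#' scaled by the cell-overlap fraction.  Uniform noise spots are added to
#' every cell.
#'
#' @param config a [simulation_config()].
#' @return List of class `DoubleMeshSim` with components `scan1`, `scan2`
#'   (class `MeshScan`) and `truth` (crystal table, per-scan footprints,
#'   per-cell contributors and the identities visible in both scans).
#' @export
render_double_mesh <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_seed(config$seed, render_double_mesh_impl(config))
}

render_double_mesh_impl <- function(cf) {
  alpha <- cf$omega2_deg - cf$omega1_deg
  geom1 <- scan_geometry(cf$omega1_deg, cf$grid_origin_mm, cf$step_mm, cf$n_u, cf$n_v)
  geom2 <- scan_geometry(cf$omega2_deg, cf$grid_origin_mm, cf$step_mm, cf$n_u, cf$n_v)
  u_rng <- cf$grid_origin_mm[1] + c(0, (cf$n_u - 1)) * cf$step_mm
  v_rng <- cf$grid_origin_mm[2] + c(0, (cf$n_v - 1)) * cf$step_mm

  crystals <- list()
  boxes1 <- list()
  boxes2 <- list()
  gap_mm <- cf$min_gap_cells * cf$step_mm
  attempts <- 0
  while (length(crystals) < cf$n_crystals) {
    attempts <- attempts + 1
    if (attempts > 500 * max(1, cf$n_crystals)) {
      stop("could not place crystals with the requested separation", call. = FALSE)
    }
    cell <- c(runif(3, cf$cell_len_range[1], cf$cell_len_range[2]),
              runif(3, cf$cell_ang_range[1], cf$cell_ang_range[2]))
    he <- runif(3, cf$size_um_range[1], cf$size_um_range[2]) / 2000  # um -> mm half
    # sample grid coordinates directly so both footprints land on-grid
    m_u <- he[3] + cf$step_mm
    v1 <- runif(1, v_rng[1], v_rng[2])
    v2 <- runif(1, v_rng[1], v_rng[2])
    z <- runif(1, u_rng[1] + m_u, u_rng[2] - m_u)
    pos3 <- triangulate_centre(c(v1, z), c(v2, z), alpha)
    cr <- synthetic_crystal(cell, random_rotation(),
                            c(pos3$x, pos3$y, pos3$z), he, cf$intensity_scale)
    b1 <- footprint_box(cr, 0)
    b2 <- footprint_box(cr, alpha)
    in1 <- b1$v - b1$hv >= v_rng[1] && b1$v + b1$hv <= v_rng[2]
    in2 <- b2$v - b2$hv >= v_rng[1] && b2$v + b2$hv <= v_rng[2]
    if (!in1 || !in2) next
    clash <- FALSE
    for (i in seq_along(crystals)) {
      if (!boxes_separated(b1, boxes1[[i]], gap_mm) ||
          !boxes_separated(b2, boxes2[[i]], gap_mm)) {
        clash <- TRUE
        break
      }
    }
    if (clash) next
    crystals[[length(crystals) + 1]] <- cr
    boxes1[[length(boxes1) + 1]] <- b1
    boxes2[[length(boxes2) + 1]] <- b2
  }

  n_cr <- length(crystals)
  d_min <- numeric(n_cr)
  nodes_by_scan <- list(vector("list", n_cr), vector("list", n_cr))
  for (i in seq_len(n_cr)) {
    d_min[i] <- if (is.null(cf$d_min)) {
      auto_d_min(crystals[[i]]$cell, cf$epsilon, cf$target_spots)
    } else {
      cf$d_min
    }
    for (s in 1:2) {
      om <- if (s == 1) 0 else alpha
      nd <- diffracting_nodes(crystals[[i]], om, cf$detector, cf$epsilon, d_min[i])
      if (nrow(nd) > 0) {
        nd$intensity <- crystals[[i]]$intensity_scale * runif(nrow(nd), 0.3, 1)
      } else {
        nd$intensity <- numeric(0)
      }
      nodes_by_scan[[s]][[i]] <- nd
    }
  }

  build_scan <- function(s, geom, boxes) {
    cells <- vector("list", cf$n_u * cf$n_v)
    contributors <- list()
    footprints <- list()
    for (iv in seq_len(cf$n_v) - 1) {
      for (iu in seq_len(cf$n_u) - 1) {
        idx <- iv * cf$n_u + iu + 1
        cc <- cell_centre_mm(geom, iu, iv)
        spot_parts <- list()
        for (i in seq_len(n_cr)) {
          b <- boxes[[i]]
          ov_u <- min(cc[1] + cf$step_mm / 2, b$u + b$hu) -
            max(cc[1] - cf$step_mm / 2, b$u - b$hu)
          ov_v <- min(cc[2] + cf$step_mm / 2, b$v + b$hv) -
            max(cc[2] - cf$step_mm / 2, b$v - b$hv)
          covered <- (cc[1] >= b$u - b$hu && cc[1] <= b$u + b$hu &&
                        cc[2] >= b$v - b$hv && cc[2] <= b$v + b$hv)
          if (!covered) next
          w <- (max(ov_u, 0) / min(2 * b$hu, cf$step_mm)) *
            (max(ov_v, 0) / min(2 * b$hv, cf$step_mm))
          w <- min(w, 1)
          nd <- nodes_by_scan[[s]][[i]]
          if (nrow(nd) == 0 || w <= 0) next
          sp <- data.frame(x_px = nd$x_px, y_px = nd$y_px,
                           intensity = nd$intensity * w,
                           background = cf$background)
          if (nrow(sp) > cf$spot_cap) {
            sp <- sp[order(sp$intensity, decreasing = TRUE)[seq_len(cf$spot_cap)], ]
          }
          spot_parts[[length(spot_parts) + 1]] <- sp
          contributors[[length(contributors) + 1]] <- list(iu = iu, iv = iv, crystal = i)
        }
        n_noise <- rpois(1, cf$noise_per_cell)
        if (n_noise > 0) {
          spot_parts[[length(spot_parts) + 1]] <- data.frame(
            x_px = runif(n_noise, 0, cf$detector$detector_shape_px[1]),
            y_px = runif(n_noise, 0, cf$detector$detector_shape_px[2]),
            intensity = runif(n_noise, 0, cf$noise_intensity_max),
            background = cf$background
          )
        }
        spots <- if (length(spot_parts)) do.call(rbind, spot_parts) else {
          data.frame(x_px = numeric(0), y_px = numeric(0),
                     intensity = numeric(0), background = numeric(0))
        }
        rownames(spots) <- NULL
        cells[[idx]] <- list(iu = iu, iv = iv, score = cell_score(spots),
                             spots = spots)
      }
    }
    for (i in seq_len(n_cr)) {
      footprints[[i]] <- boxes[[i]]
    }
    list(
      scan = structure(list(geometry = geom, detector = cf$detector,
                            cells = cells), class = "MeshScan"),
      contributors = do.call(rbind, lapply(contributors, as.data.frame)),
      footprints = footprints
    )
  }

  s1 <- build_scan(1, geom1, boxes1)
  s2 <- build_scan(2, geom2, boxes2)
  seen1 <- unique(s1$contributors$crystal)
  seen2 <- unique(s2$contributors$crystal)
  truth <- list(
    crystals = if (n_cr) data.frame(
      id = seq_len(n_cr),
      x = vapply(crystals, function(cr) cr$position_mm[1], numeric(1)),
      y = vapply(crystals, function(cr) cr$position_mm[2], numeric(1)),
      z = vapply(crystals, function(cr) cr$position_mm[3], numeric(1)),
      hx = vapply(crystals, function(cr) cr$half_extents_mm[1], numeric(1)),
      hy = vapply(crystals, function(cr) cr$half_extents_mm[2], numeric(1)),
      hz = vapply(crystals, function(cr) cr$half_extents_mm[3], numeric(1)),
      d_min = d_min
    ) else data.frame(),
    crystal_objects = crystals,
    contributors1 = s1$contributors,
    contributors2 = s2$contributors,
    footprints1 = s1$footprints,
    footprints2 = s2$footprints,
    visible_both = intersect(seen1, seen2),
    alpha_deg = alpha
  )
  structure(list(scan1 = s1$scan, scan2 = s2$scan, truth = truth),
            class = "DoubleMeshSim")
}

#' @export
print.MeshScan <- function(x, ...) {
  g <- x$geometry
  ns <- sum(vapply(x$cells, function(cl) nrow(cl$spots), numeric(1)))
  cat(sprintf("MeshScan: %d x %d grid, step %.3f mm, omega %.1f deg, %d spots\n",
              g$n_u, g$n_v, g$step_mm, g$omega_deg, ns))
  invisible(x)
}
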