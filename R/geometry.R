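#' Detector geometry
#'
#' A flat detector orthogonal to the incident beam, described by the X-ray
#' wavelength, sample-to-detector distance, direct-beam position and pixel
#' size.  This is the minimal model needed for the Ewald back-projection of
#' spot positions; distortion, parallax and oblique incidence are out of
#' scope.
#'
#' @param wavelength_A X-ray wavelength (angstrom).
#' @param distance_mm sample-to-detector distance (mm).
#' @param beam_centre_px direct-beam position, length-2 (px).
#' @param pixel_size_mm pixel edge (mm).
#' @param detector_shape_px number of pixels, length-2 (fast, slow).
#' @return An object of class `DetectorGeometry`.
#' @examples
#' det <- detector_geometry(0.861, 180, c(2074, 2181), 0.075, c(4148, 4362))
#' det$wavelength_A
#' @export
detector_geometry <- function(wavelength_A, distance_mm, beam_centre_px,
                              pixel_size_mm, detector_shape_px) {
  stopifnot(
    is.numeric(wavelength_A), length(wavelength_A) == 1, wavelength_A > 0,
    is.numeric(distance_mm), length(distance_mm) == 1, distance_mm > 0,
    is.numeric(pixel_size_mm), length(pixel_size_mm) == 1, pixel_size_mm > 0,
    length(beam_centre_px) == 2, length(detector_shape_px) == 2,
    all(detector_shape_px >= 1)
  )
  if (any(beam_centre_px < 0) || any(beam_centre_px > detector_shape_px)) {
    stop("beam centre lies outside the detector", call. = FALSE)
  }
  structure(
    list(
      wavelength_A = as.numeric(wavelength_A),
      distance_mm = as.numeric(distance_mm),
      beam_centre_px = as.numeric(beam_centre_px),
      pixel_size_mm = as.numeric(pixel_size_mm),
      detector_shape_px = as.numeric(detector_shape_px)
    ),
    class = "DetectorGeometry"
  )
}

#' Mesh-scan geometry
#'
#' One mesh scan: the goniometer angle at which it was recorded and the
#' raster grid over the sample holder.  Grid axis `u` runs along the
#' goniometer rotation axis; `v` is the scan vertical.  Positive rotation
#' carries the laboratory beam axis (+x, beam direction of the first scan)
#' towards +y; the `v` axis points opposite laboratory +y (screen-down), so
#' a sample point at scan-frame position (x, y, z) appears at grid
#' coordinates u = z, v = y cos(omega) - x sin(omega).
#'
#' @param omega_deg goniometer angle of the scan (degrees).
#' @param grid_origin_mm physical position of cell (0, 0)'s centre, (u0, v0).
#' @param step_mm grid pitch (mm); equal to the beam size in typical scans.
#' @param n_u,n_v grid dimensions along `u` and `v`.
#' @return An object of class `ScanGeometry`.
#' @examples
#' scan_geometry(60, c(0, 0), 0.01, 30, 20)
#' @export
scan_geometry <- function(omega_deg, grid_origin_mm, step_mm, n_u, n_v) {
  stopifnot(
    is.numeric(omega_deg), length(omega_deg) == 1,
    length(grid_origin_mm) == 2,
    is.numeric(step_mm), length(step_mm) == 1, step_mm > 0,
    n_u >= 1, n_v >= 1
  )
  structure(
    list(
      omega_deg = as.numeric(omega_deg),
      grid_origin_mm = as.numeric(grid_origin_mm),
      step_mm = as.numeric(step_mm),
      n_u = as.integer(n_u),
      n_v = as.integer(n_v)
    ),
    class = "ScanGeometry"
  )
}

#' Back-project detector spots onto the Ewald sphere
#'
#' Reconstructs reciprocal-space node positions from diffraction-spot
#' detector coordinates: q = (u_hat - b_hat) / lambda, where b_hat is the
#' unit incident-beam direction and u_hat the unit vector from the sample to
#' the spot.  Every node lies exactly on the Ewald sphere of radius
#' 1/lambda centred at -b_hat/lambda, and |q| = 2 sin(theta) / lambda for
#' scattering angle 2 theta.
#'
#' @param spots data frame with columns `x_px`, `y_px` (detector position).
#'   Extra columns are ignored.
#' @param det a [detector_geometry()].
#' @return Numeric matrix with one row per spot and columns `qx`, `qy`, `qz`
#'   (1/angstrom) in the laboratory frame of the scan: x along the incident
#'   beam, z along the rotation axis, y vertical.
#' @examples
#' det <- detector_geometry(1, 100, c(100, 100), 1, c(200, 200))
#' spots_to_nodes(data.frame(x_px = 100, y_px = 100), det)  # q = 0
#' @export
spots_to_nodes <- function(spots, det) {
  stopifnot(inherits(det, "DetectorGeometry"))
  if (nrow(spots) == 0) {
    return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("qx", "qy", "qz"))))
  }
  if (any(spots$x_px < 0) || any(spots$x_px > det$detector_shape_px[1]) ||
      any(spots$y_px < 0) || any(spots$y_px > det$detector_shape_px[2])) {
    stop("spot position outside the detector", call. = FALSE)
  }
  # lab-frame ray from sample to spot: x along beam, y from the vertical
  # pixel coordinate, z (rotation axis) from the horizontal pixel coordinate
  rz <- (spots$x_px - det$beam_centre_px[1]) * det$pixel_size_mm
  ry <- (spots$y_px - det$beam_centre_px[2]) * det$pixel_size_mm
  rx <- rep(det$distance_mm, length(rz))
  nrm <- sqrt(rx^2 + ry^2 + rz^2)
  q <- cbind(qx = (rx / nrm - 1), qy = ry / nrm, qz = rz / nrm) / det$wavelength_A
  q
}

#' @rdname spots_to_nodes
#' @param x_px,y_px scalar spot position (px) for the single-spot form.
#' @export
spot_to_node <- function(x_px, y_px, det) {
  drop(spots_to_nodes(data.frame(x_px = x_px, y_px = y_px), det))
}

#' Rotate vectors about the goniometer axis
#'
#' Right-handed rotation about the laboratory z axis (the rotation axis):
#' a positive angle carries +x towards +y.  Accepts a single 3-vector or a
#' matrix with one vector per row.
#'
#' @param v numeric length-3 vector, or an n x 3 matrix.
#' @param angle_deg rotation angle (degrees).
#' @return Rotated vector(s), same shape as `v`.
#' @examples
#' rotate_about_axis(c(1, 0, 0), 90)  # (0, 1, 0)
#' @export
rotate_about_axis <- function(v, angle_deg) {
  a <- angle_deg * pi / 180
  R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  if (is.matrix(v)) {
    out <- v %*% t(R)
    colnames(out) <- colnames(v)
    out
  } else {
    drop(R %*% v)
  }
}

#' Triangulate a 3D centring position from two mesh-scan centroids
#'
#' The rotation-axis coordinate of a sample point is invariant under the
#' inter-scan rotation, while its vertical grid coordinate transforms as
#' v(omega) = y cos(omega) - x sin(omega) in the frame tied to the first
#' scan (x along the first scan's beam, z along the rotation axis).  Given
#' the region centroids (y_i, z_i) of the same crystal in the two scans,
#' the 3D position follows in closed form:
#' \deqn{x = (y_1 \cos\Omega - y_2)/\sin\Omega,\quad y = y_1,\quad
#'       z = (z_1 + z_2)/2.}
#' This inverts the simulator's forward projection exactly.
#'
#' @param centroid1,centroid2 length-2 numeric `(y, z)` centroids (mm) of the
#'   paired regions in scan 1 and scan 2.
#' @param omega_deg inter-scan rotation angle (degrees); must not be a
#'   multiple of 180.
#' @param z_tol_mm maximum allowed rotation-axis mismatch |z1 - z2|.
#' @return An object of class `CrystalPosition3D`: list with `x`, `y`, `z`
#'   (mm, frame of scan 1).
#' @examples
#' triangulate_centre(c(0.02, 0), c(-0.05, 0), 90)  # x = 0.05, y = 0.02
#' @export
triangulate_centre <- function(centroid1, centroid2, omega_deg, z_tol_mm = Inf) {
  stopifnot(length(centroid1) == 2, length(centroid2) == 2)
  s <- sin(omega_deg * pi / 180)
  if (abs(s) < 1e-9) {
    stop("degenerate geometry: inter-scan angle is a multiple of 180 degrees",
         call. = FALSE)
  }
  y1 <- centroid1[1]; z1 <- centroid1[2]
  y2 <- centroid2[1]; z2 <- centroid2[2]
  if (abs(z1 - z2) > z_tol_mm) {
    stop(sprintf("pairing error: rotation-axis coordinates differ by %.4g mm",
                 abs(z1 - z2)), call. = FALSE)
  }
  c_ <- cos(omega_deg * pi / 180)
  structure(
    list(
      x = unname((y1 * c_ - y2) / s),
      y = unname(y1),
      z = unname((z1 + z2) / 2)
    ),
    class = "CrystalPosition3D"
  )
}

#' @export
print.CrystalPosition3D <- function(x, ...) {
  cat(sprintf("3D centring position (mm): x = %.4f, y = %.4f, z = %.4f\n",
              x$x, x$y, x$z))
  invisible(x)
}

#' Forward-project a 3D position into one scan's grid coordinates
#'
#' The inverse companion of [triangulate_centre()]: where on a mesh scan at
#' relative angle `omega_deg` a sample point at scan-1-frame position
#' `(x, y, z)` appears.
#'
#' @param position length-3 numeric `(x, y, z)` (mm) or `CrystalPosition3D`.
#' @param omega_deg scan angle relative to scan 1 (degrees).
#' @return Length-2 numeric `(v, u)` grid coordinates (mm).
#' @export
project_position <- function(position, omega_deg) {
  p <- if (inherits(position, "CrystalPosition3D")) {
    c(position$x, position$y, position$z)
  } else {
    position
  }
  stopifnot(length(p) == 3)
  a <- omega_deg * pi / 180
  c(v = unname(p[2] * cos(a) - p[1] * sin(a)), u = unname(p[3]))
}

# physical centre (u, v) in mm of a 0-based grid cell
cell_centre_mm <- function(geom, iu, iv) {
  cbind(
    u = geom$grid_origin_mm[1] + iu * geom$step_mm,
    v = geom$grid_origin_mm[2] + iv * geom$step_mm
  )
}
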