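#' Read and write mesh scans
#'
#' The on-disk dialect is JSON lines: a header object (format name, version,
#' cell count, scan and detector geometry) followed by one object per grid
#' cell with its indices, diffraction score and spot list
#' `[x_px, y_px, intensity, background]`.  The round trip is lossless
#' (numbers are written at full precision).
#'
#' @param scan a `MeshScan`.
#' @param path file path.
#' @return `read_meshscan()` returns a `MeshScan`; `write_meshscan()`
#'   returns `path` invisibly.
#' @export
write_meshscan <- function(scan, path) {
  stopifnot(inherits(scan, "MeshScan"))
  g <- scan$geometry; d <- scan$detector
  header <- list(
    format = "crossmesh-meshscan", version = 1L,
    n_cells = length(scan$cells),
    geometry = list(omega_deg = g$omega_deg, grid_origin_mm = g$grid_origin_mm,
                    step_mm = g$step_mm, n_u = g$n_u, n_v = g$n_v),
    detector = list(wavelength_A = d$wavelength_A, distance_mm = d$distance_mm,
                    beam_centre_px = d$beam_centre_px,
                    pixel_size_mm = d$pixel_size_mm,
                    detector_shape_px = d$detector_shape_px)
  )
  lines <- character(length(scan$cells) + 1)
  lines[1] <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)
  for (i in seq_along(scan$cells)) {
    cl <- scan$cells[[i]]
    sp <- cl$spots
    lines[i + 1] <- jsonlite::toJSON(
      list(iu = cl$iu, iv = cl$iv, score = cl$score,
           spots = unname(as.matrix(sp[, c("x_px", "y_px", "intensity", "background")]))),
      auto_unbox = TRUE, digits = NA
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_meshscan
#' @export
read_meshscan <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty mesh-scan file", call. = FALSE)
  header <- tryCatch(jsonlite::fromJSON(lines[1]),
                     error = function(e) stop("parse error at line 1: malformed header",
                                              call. = FALSE))
  if (!identical(header$format, "crossmesh-meshscan")) {
    stop("parse error at line 1: not a crossmesh mesh-scan file", call. = FALSE)
  }
  if (length(lines) - 1 != header$n_cells) {
    stop(sprintf("truncated file: header declares %d cells, found %d lines",
                 header$n_cells, length(lines) - 1), call. = FALSE)
  }
  geom <- scan_geometry(header$geometry$omega_deg, header$geometry$grid_origin_mm,
                        header$geometry$step_mm, header$geometry$n_u,
                        header$geometry$n_v)
  det <- detector_geometry(header$detector$wavelength_A, header$detector$distance_mm,
                           header$detector$beam_centre_px,
                           header$detector$pixel_size_mm,
                           header$detector$detector_shape_px)
  cells <- vector("list", header$n_cells)
  for (i in seq_len(header$n_cells)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i + 1], simplifyMatrix = TRUE),
                    error = function(e) stop(sprintf("parse error at line %d", i + 1),
                                             call. = FALSE))
    if (is.null(rec$iu) || is.null(rec$iv) || is.null(rec$score)) {
      stop(sprintf("parse error at line %d: missing cell fields", i + 1),
           call. = FALSE)
    }
    sp <- rec$spots
    spots <- if (is.null(sp) || length(sp) == 0) {
      data.frame(x_px = numeric(0), y_px = numeric(0),
                 intensity = numeric(0), background = numeric(0))
    } else {
      sp <- matrix(as.numeric(sp), ncol = 4)
      data.frame(x_px = sp[, 1], y_px = sp[, 2],
                 intensity = sp[, 3], background = sp[, 4])
    }
    cells[[rec$iv * geom$n_u + rec$iu + 1]] <-
      list(iu = as.integer(rec$iu), iv = as.integer(rec$iv),
           score = as.numeric(rec$score), spots = spots)
  }
  if (any(vapply(cells, is.null, logical(1)))) {
    stop("invalid file: duplicate or missing grid cells", call. = FALSE)
  }
  structure(list(geometry = geom, detector = det, cells = cells),
            class = "MeshScan")
}

#' Write the diffraction heat map of a scan
#'
#' Tab-separated `n_v` x `n_u` matrix of per-cell diffraction scores (rows
#' are grid rows `iv`, columns are rotation-axis positions `iu`).
#'
#' @param scan a `MeshScan`.
#' @param path file path.
#' @return The score matrix, invisibly.
#' @export
write_heatmap <- function(scan, path) {
  stopifnot(inherits(scan, "MeshScan"))
  g <- scan$geometry
  m <- matrix(0, nrow = g$n_v, ncol = g$n_u)
  for (cl in scan$cells) {
    if (!is.null(cl)) m[cl$iv + 1, cl$iu + 1] <- cl$score
  }
  utils::write.table(m, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(m)
}

#' Write a crystal map and its region sidecar
#'
#' The crystal map is a tab-separated integer matrix labelling each grid
#' cell: 0 = no diffraction, 999 = superimposed/multi-pattern diffraction,
#' 1..K = ranked crystal regions.  A JSON sidecar (`<path>.json`) carries
#' per-region centroids, extents, scores and recommended beam sizes.
#'
#' @param seg a [segment_scan()] result.
#' @param path file path for the map; the sidecar gets `.json` appended.
#' @return The label matrix, invisibly.
#' @export
write_crystal_map <- function(seg, path) {
  stopifnot(inherits(seg, "MeshSegmentation"))
  utils::write.table(seg$labels, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  sidecar <- lapply(seg$regions, function(r) {
    list(label = r$label, n_cells = nrow(r$cells),
         centroid_mm = as.list(r$centroid_mm),
         extents_mm = as.list(r$extents_mm),
         integral_score = r$integral_score,
         beam_size_um = r$beam_size_um)
  })
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(seg$labels)
}

#' Write a cross-scan match report
#'
#' JSON report listing every candidate pair with its maximum check score,
#' the binary match decision, the triangulated 3D centring position and
#' the recommended beam size, ranked by integral diffraction score.
#'
#' @param result a [run_doublemesh()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_match_report <- function(result, path) {
  stopifnot(inherits(result, "DoubleMeshResult"))
  cands <- result$candidates
  pairs <- lapply(seq_len(nrow(cands)), function(i) {
    list(region_a = cands$region_a[i], region_b = cands$region_b[i],
         max_score = cands$max_score[i], matched = cands$matched[i],
         position_mm = list(x = cands$x[i], y = cands$y[i], z = cands$z[i]),
         beam_size_um = cands$beam_size_um[i],
         integral_score = cands$integral_score[i],
         rank = cands$rank[i])
  })
  jsonlite::write_json(
    list(alpha_deg = result$alpha_deg,
         n_regions = c(length(result$seg1$regions), length(result$seg2$regions)),
         n_candidates = nrow(cands), n_matched = nrow(result$matches),
         pairs = pairs),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
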