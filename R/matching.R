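#' Test a plane vector against a node set (check)
#'
#' Examines whether a (possibly rotated) plane vector fits the diffraction
#' of a crystal: the crystal's reciprocal-space nodes are projected onto
#' the vector's direction, the projection histogram is normalised and
#' Fourier-transformed exactly as in [find_planes()], and the maximum
#' Rayleigh-scaled magnitude inside a narrow window of `window_bins`
#' Fourier bins around the expected frequency (the plane vector's length,
#' in angstrom) is returned.  If the lattice periodicity encoded by the
#' vector is present in the nodes, the score is large; for an unrelated
#' crystal it follows the Rayleigh null.
#'
#' @param plane_vector length-3 numeric: direction times period (angstrom).
#' @param nodes n x 3 node matrix (1/angstrom).
#' @param config a [crossmesh_config()].
#' @return Scalar score (0 when `nodes` is below the evidence floor).
#' @export
check_plane <- function(plane_vector, nodes, config = crossmesh_config()) {
  pl <- config$planes
  stopifnot(length(plane_vector) == 3)
  freq <- sqrt(sum(plane_vector^2))
  nyquist <- 1 / (2 * pl$bin_width_invA)
  if (!is.finite(freq) || freq <= 0 || freq > nyquist) {
    stop(sprintf("plane-vector period %.1f A outside the representable range (Nyquist %.1f A)",
                 freq, nyquist), call. = FALSE)
  }
  if (is.null(nodes) || nrow(nodes) < pl$min_nodes) return(0)
  nodes <- thin_nodes(unname(as.matrix(nodes)), pl$node_cap)
  pk <- direction_peak(nodes, plane_vector / freq, pl,
                       expected_freq_A = freq,
                       window_bins = config$match$window_bins)
  pk$score
}

#' Score a cross-scan candidate pair
#'
#' Rotates the first region's plane vectors forwards by the inter-scan
#' angle and tests them against the second region's nodes, and the second
#' region's plane vectors backwards against the first region's nodes.
#' Combinations whose [check_plane()] score exceeds `match_threshold` are
#' then confirmed in direction: the plane direction is refined locally on
#' the target's own nodes, and if the optimum sits further than
#' `direction_tol_deg` from the rotated vector, the detected periodicity
#' belongs to a coincidentally aligned different family and the
#' combination is rejected.  The pair's match score is the maximum score
#' over the surviving combinations; the pair is declared the same crystal
#' when it exceeds `match_threshold`.
#'
#' @param planes1,planes2 [find_planes()] results for the two regions.
#' @param nodes1,nodes2 node matrices of the two regions.
#' @param alpha_deg inter-scan rotation angle (degrees).
#' @param config a [crossmesh_config()].
#' @return List with `max_score` (0 when both plane sets are empty) and
#'   `matched`.
#' @export
match_pair <- function(planes1, planes2, nodes1, nodes2, alpha_deg,
                       config = crossmesh_config()) {
  combos <- list()
  add <- function(planes, angle, nodes) {
    if (is.null(planes) || nrow(planes) == 0) return()
    V <- rotate_about_axis(as.matrix(planes[, c("vx", "vy", "vz")]), angle)
    for (j in seq_len(nrow(V))) {
      combos[[length(combos) + 1]] <<-
        list(v = V[j, ], nodes = nodes,
             score = check_plane(V[j, ], nodes, config))
    }
  }
  add(planes1, alpha_deg, nodes2)
  add(planes2, -alpha_deg, nodes1)
  if (length(combos) == 0) return(list(max_score = 0, matched = FALSE))

  thr <- config$match$match_threshold
  scores <- vapply(combos, `[[`, numeric(1), "score")
  ord <- order(scores, decreasing = TRUE)
  best <- 0
  for (j in ord) {
    s <- scores[j]
    if (s <= thr) break          # sub-threshold scores need no confirmation
    if (direction_consistent(combos[[j]]$v, combos[[j]]$nodes, config)) {
      best <- s
      break
    }
  }
  if (best == 0) {
    sub <- scores[scores <= thr]
    best <- if (length(sub)) max(sub) else 0
  }
  list(max_score = best, matched = best > thr)
}

# Confirm that a periodicity found at the rotated vector's frequency is
# centred on its direction: refine locally on the target nodes and compare
# the refined optimum's direction with the vector's.
direction_consistent <- function(v, nodes, config) {
  pl <- config$planes
  freq <- sqrt(sum(v^2))
  nodes <- thin_nodes(unname(as.matrix(nodes)), pl$node_cap)
  ref <- refine_direction(nodes, v / freq, pl)
  if (!is.finite(ref$score)) return(FALSE)
  shift <- acos(min(1, abs(sum(ref$dir * v / freq)))) * 180 / pi
  shift <= config$match$direction_tol_deg
}

#' Run the full double-mesh analysis
#'
#' The complete chain: segment both scans into crystal regions, extract
#' plane vectors from each region's reciprocal-lattice subset, form
#' geometric pair candidates by rotation-axis invariance, validate each
#' candidate by rotated-plane-vector checks, and triangulate 3D centring
#' positions for the confirmed pairs.  Matched pairs are ranked by their
#' combined integral diffraction score.
#'
#' @param scan1,scan2 `MeshScan` objects at two goniometer angles sharing
#'   the same grid.
#' @param config a [crossmesh_config()].
#' @param verbose emit per-stage counts to stderr.
#' @return Object of class `DoubleMeshResult`: list with `seg1`, `seg2`,
#'   `planes1`, `planes2` (per-region plane-vector tables), `candidates`
#'   and `matches` (data frame: one row per candidate with `max_score`,
#'   `matched`, triangulated `x`, `y`, `z`, `beam_size_um` and `rank`
#'   among matched pairs).
#' @export
run_doublemesh <- function(scan1, scan2, config = crossmesh_config(),
                           verbose = FALSE) {
  stopifnot(inherits(scan1, "MeshScan"), inherits(scan2, "MeshScan"))
  g1 <- scan1$geometry; g2 <- scan2$geometry
  if (g1$n_u != g2$n_u || g1$n_v != g2$n_v || g1$step_mm != g2$step_mm) {
    stop("the two scans must share grid dimensions and step", call. = FALSE)
  }
  alpha <- g2$omega_deg - g1$omega_deg
  if (abs(sin(alpha * pi / 180)) < 1e-9) {
    stop("degenerate geometry: inter-scan angle is a multiple of 180 degrees",
         call. = FALSE)
  }
  say <- function(...) if (verbose) message(sprintf(...))

  seg1 <- segment_scan(scan1, config)
  seg2 <- segment_scan(scan2, config)
  say("segmentation: %d region(s) in scan 1, %d in scan 2",
      length(seg1$regions), length(seg2$regions))

  planes1 <- lapply(seg1$regions, function(r) find_planes(r$nodes, config))
  planes2 <- lapply(seg2$regions, function(r) find_planes(r$nodes, config))
  say("plane vectors: %d region(s) with >=1 vector in scan 1, %d in scan 2",
      sum(vapply(planes1, nrow, integer(1)) > 0),
      sum(vapply(planes2, nrow, integer(1)) > 0))

  cands <- pair_candidates(seg1, seg2, alpha, g1$step_mm, config)
  say("pair candidates: %d", nrow(cands))

  if (nrow(cands) > 0) {
    res <- lapply(seq_len(nrow(cands)), function(i) {
      a <- cands$region_a[i]; b <- cands$region_b[i]
      match_pair(planes1[[a]], planes2[[b]],
                 seg1$regions[[a]]$nodes, seg2$regions[[b]]$nodes,
                 alpha, config)
    })
    cands$max_score <- vapply(res, `[[`, numeric(1), "max_score")
    cands$matched <- vapply(res, `[[`, logical(1), "matched")
    cands$integral_score <- vapply(seq_len(nrow(cands)), function(i) {
      seg1$regions[[cands$region_a[i]]]$integral_score +
        seg2$regions[[cands$region_b[i]]]$integral_score
    }, numeric(1))
    cands$beam_size_um <- vapply(seq_len(nrow(cands)), function(i) {
      max(seg1$regions[[cands$region_a[i]]]$beam_size_um,
          seg2$regions[[cands$region_b[i]]]$beam_size_um)
    }, numeric(1))
    cands <- cands[order(-cands$matched, -cands$integral_score), ]
    cands$rank <- NA_integer_
    cands$rank[cands$matched] <- seq_len(sum(cands$matched))
    rownames(cands) <- NULL
  } else {
    cands$max_score <- numeric(0)
    cands$matched <- logical(0)
    cands$integral_score <- numeric(0)
    cands$beam_size_um <- numeric(0)
    cands$rank <- integer(0)
  }
  say("matches: %d of %d candidates", sum(cands$matched), nrow(cands))

  structure(
    list(seg1 = seg1, seg2 = seg2, planes1 = planes1, planes2 = planes2,
         alpha_deg = alpha, candidates = cands,
         matches = cands[cands$matched, , drop = FALSE]),
    class = "DoubleMeshResult"
  )
}

#' @export
print.DoubleMeshResult <- function(x, ...) {
  cat(sprintf(
    "DoubleMeshResult: %d + %d regions, %d candidate pair(s), %d matched\n",
    length(x$seg1$regions), length(x$seg2$regions),
    nrow(x$candidates), nrow(x$matches)))
  if (nrow(x$matches)) {
    m <- x$matches
    for (i in seq_len(nrow(m))) {
      cat(sprintf(
        "  #%d: regions %d/%d, score %.1f, position (%.4f, %.4f, %.4f) mm, beam %d um\n",
        m$rank[i], m$region_a[i], m$region_b[i], m$max_score[i],
        m$x[i], m$y[i], m$z[i], m$beam_size_um[i]))
    }
  }
  invisible(x)
}
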