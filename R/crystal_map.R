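#' Per-cell diffraction score
#'
#' Background-relative diffraction score of one grid cell's spot list:
#' the sum over spots of intensity / (background + 1).  The score is zero
#' exactly when the cell has no spots, and scales linearly with intensity.
#'
#' @param spots data frame with columns `intensity` and `background`.
#' @return Non-negative scalar score.
#' @examples
#' cell_score(data.frame(intensity = 10, background = 0))  # 10
#' @export
cell_score <- function(spots) {
  if (is.null(spots) || nrow(spots) == 0) return(0)
  sum(spots$intensity / (spots$background + 1))
}

#' Flag cells containing superimposed diffraction patterns
#'
#' Tests whether the difference vectors of a cell's spots are explained by
#' a single lattice.  Spots are back-projected onto the Ewald sphere and
#' only their transverse reciprocal components (the two coordinates
#' perpendicular to the beam) are used: for the low-angle region these are
#' an exact affine projection of the crystal lattice, so one crystal's
#' short difference vectors cluster tightly around integer combinations of
#' at most three generator vectors.  The sign-folded, length-limited
#' difference vectors are clustered by single linkage; generators are
#' grown greedily from the strongest clusters (best of several starts),
#' and the total mass of clusters inconsistent with the generators'
#' integer combinations is compared with the explained mass.  A second
#' superimposed pattern contributes families no single-lattice generator
#' set can absorb, so the cell is flagged when the inconsistent mass
#' reaches an absolute evidence floor and exceeds `multipattern_fraction`
#' of the explained mass.  Cells with fewer than `min_spots_multipattern`
#' spots are never flagged (insufficient evidence).
#'
#' @param spots data frame with columns `x_px`, `y_px` (and optionally
#'   `intensity`; when the list is large a thinned subset spread across the
#'   intensity range is used so that a weaker superimposed pattern is not
#'   masked by a stronger one).
#' @param config a [crossmesh_config()].
#' @param det the [detector_geometry()] used to record the spots.
#' @return Logical flag.
#' @export
multipattern_flag <- function(spots, config = crossmesh_config(), det) {
  sg <- config$segment
  if (is.null(spots) || nrow(spots) < sg$min_spots_multipattern) return(FALSE)
  # internal constants of the criterion (see the methods vignette)
  radius <- 0.001   # cluster radius (1/A) in transverse reciprocal space
  dv_max <- 0.04    # longest difference vector considered (1/A)
  qperp_max <- 0.15 # low-angle cut on transverse momentum (1/A)
  cap <- 150; max_dv <- 1500; min_bad_mass <- 10

  q <- spots_to_nodes(spots, det)
  keep <- sqrt(q[, 2]^2 + q[, 3]^2) <= qperp_max
  q <- q[keep, , drop = FALSE]
  spots <- spots[keep, , drop = FALSE]
  n <- nrow(q)
  if (n < sg$min_spots_multipattern) return(FALSE)
  if (n > cap) {
    ord <- if (!is.null(spots$intensity)) order(spots$intensity, decreasing = TRUE)
           else seq_len(n)
    sel <- ord[unique(round(seq(1, n, length.out = cap)))]
    q <- q[sel, , drop = FALSE]
    n <- nrow(q)
  }
  xy <- q[, c(2, 3), drop = FALSE]
  ii <- rep(seq_len(n - 1), times = (n - 1):1)
  jj <- sequence((n - 1):1) + ii
  dv <- xy[jj, , drop = FALSE] - xy[ii, , drop = FALSE]
  flip <- dv[, 2] < 0 | (dv[, 2] == 0 & dv[, 1] < 0)
  dv[flip, ] <- -dv[flip, , drop = FALSE]
  len <- sqrt(rowSums(dv^2))
  dv <- dv[len >= 2.5 * radius & len <= dv_max, , drop = FALSE]
  if (nrow(dv) < 10) return(FALSE)
  if (nrow(dv) > max_dv) {
    dv <- dv[unique(round(seq(1, nrow(dv), length.out = max_dv))), , drop = FALSE]
  }
  cl <- cutree(hclust(dist(dv), method = "single"), h = radius)
  sizes <- tabulate(cl)
  centres <- t(vapply(seq_along(sizes), function(g) {
    colMeans(dv[cl == g, , drop = FALSE])
  }, numeric(2)))
  ord <- order(sizes, decreasing = TRUE)
  sizes <- sizes[ord]
  centres <- centres[ord, , drop = FALSE]
  if (sizes[1] < 6) return(FALSE)   # no dominant periodic family at all
  clen <- sqrt(rowSums(centres^2))
  tol <- 1.5 * radius
  fold <- function(m) {
    fl <- m[, 2] < 0 | (m[, 2] == 0 & m[, 1] < 0)
    m[fl, ] <- -m[fl, , drop = FALSE]
    m
  }
  inconsistent <- function(lat) {
    vapply(seq_len(nrow(centres)), function(i) {
      sqrt(min((lat[, 1] - centres[i, 1])^2 + (lat[, 2] - centres[i, 2])^2)) > tol
    }, logical(1))
  }
  lat_of <- function(gens) {
    rng <- lapply(seq_along(gens), function(gi) {
      g <- gens[[gi]]
      mm <- min(10, ceiling((dv_max + tol) / sqrt(sum(g^2))) + 1)
      # a still image slices the lattice: the third generator (out of the
      # dominant slab plane) enters only at low order
      if (gi == 3) mm <- min(mm, 1)
      -mm:mm
    })
    comb <- as.matrix(do.call(expand.grid, rng))
    fold(comb %*% do.call(rbind, gens))
  }
  grow <- function(first, next_rule) {
    gens <- list(centres[first, ])
    for (rep in 1:2) {
      bad <- inconsistent(lat_of(gens))
      cand <- which(bad & sizes >= 5)
      if (length(cand) == 0) break
      pick <- if (next_rule == "short") cand[which.min(clen[cand])] else cand[1]
      gens[[length(gens) + 1]] <- centres[pick, ]
    }
    bad <- inconsistent(lat_of(gens))
    big <- sizes >= 3
    c(sum(sizes[big & !bad]), sum(sizes[big & bad]))
  }
  # the greedy generator choice can go wrong on one lattice; try a few
  # starts and keep the assignment that explains the most
  starts <- 1L
  strong <- which(sizes >= 5)
  if (length(strong)) starts <- unique(c(starts, strong[which.min(clen[strong])]))
  combos <- expand.grid(s = starts, r = c("large", "short"),
                        stringsAsFactors = FALSE)
  res <- t(mapply(function(s, r) grow(s, r), combos$s, combos$r))
  best <- which.min(res[, 2])
  good <- res[best, 1]; bad_mass <- res[best, 2]
  bad_mass >= min_bad_mass && bad_mass >= sg$multipattern_fraction * good
}

#' Spot-position similarity of two cells
#'
#' Fraction of the smaller cell's spots that can be matched one-to-one to a
#' spot of the larger cell within `match_radius_px` pixels.  Adjacent cells
#' illuminating the same crystal show near-identical spot positions and
#' score close to 1; unrelated cells score near 0.  For very rich cells
#' only the `similarity_max_spots` strongest spots are compared.
#'
#' @param spots_a,spots_b spot data frames (`x_px`, `y_px`, optionally
#'   `intensity`).
#' @param config a [crossmesh_config()].
#' @return Fraction in `[0, 1]`.
#' @export
cell_similarity <- function(spots_a, spots_b, config = crossmesh_config()) {
  sg <- config$segment
  cap <- function(sp) {
    if (nrow(sp) > sg$similarity_max_spots && !is.null(sp$intensity)) {
      sp[order(sp$intensity, decreasing = TRUE)[seq_len(sg$similarity_max_spots)], ]
    } else {
      sp
    }
  }
  a <- cap(spots_a); b <- cap(spots_b)
  if (nrow(a) > nrow(b)) { tmp <- a; a <- b; b <- tmp }
  na <- nrow(a)
  if (na == 0) return(0)
  r <- sg$match_radius_px
  d2 <- outer(a$x_px, b$x_px, "-")^2 + outer(a$y_px, b$y_px, "-")^2
  cand <- which(d2 <= r^2, arr.ind = TRUE)
  if (nrow(cand) == 0) return(0)
  cand <- cand[order(d2[cand]), , drop = FALSE]
  used_a <- logical(na); used_b <- logical(nrow(b))
  matched <- 0L
  for (i in seq_len(nrow(cand))) {
    ra <- cand[i, 1]; rb <- cand[i, 2]
    if (!used_a[ra] && !used_b[rb]) {
      used_a[ra] <- TRUE; used_b[rb] <- TRUE
      matched <- matched + 1L
    }
  }
  matched / na
}

#' Segment a mesh scan into crystal regions
#'
#' Cells scoring at least `min_cell_score` and not flagged as multi-pattern
#' form the vertices of a graph whose edges connect 4-adjacent cells with
#' spot-position similarity at or above `similarity_threshold`; connected
#' components (single-linkage agglomeration over the adjacency graph)
#' become crystal regions.  Regions are labelled 1..K in order of
#' decreasing integral diffraction score (ties broken by centroid
#' position); multi-pattern cells receive the conventional label 999 and
#' belong to no region.  Each region carries its score-weighted centroid,
#' extents, pooled reciprocal-space nodes and a recommended beam aperture
#' (the smallest available aperture at least as large as the smaller
#' extent).
#'
#' @param scan a `MeshScan`.
#' @param config a [crossmesh_config()].
#' @return Object of class `MeshSegmentation`: list with `regions` (list of
#'   `CrystalRegion`) and `labels` (n_v x n_u integer matrix with entries
#'   0, 999 or region labels).
#' @export
segment_scan <- function(scan, config = crossmesh_config()) {
  stopifnot(inherits(scan, "MeshScan"))
  sg <- config$segment
  g <- scan$geometry
  n_u <- g$n_u; n_v <- g$n_v
  labels <- matrix(0L, nrow = n_v, ncol = n_u)
  scores <- vapply(scan$cells, function(cl) if (is.null(cl)) 0 else cl$score,
                   numeric(1))
  idx_of <- function(iu, iv) iv * n_u + iu + 1

  active <- which(scores >= sg$min_cell_score)
  if (length(active) == 0) {
    return(structure(list(regions = list(), labels = labels),
                     class = "MeshSegmentation"))
  }
  mp <- vapply(active, function(i) {
    multipattern_flag(scan$cells[[i]]$spots, config, scan$detector)
  }, logical(1))
  for (i in active[mp]) {
    cl <- scan$cells[[i]]
    labels[cl$iv + 1, cl$iu + 1] <- 999L
  }
  active <- active[!mp]

  # union-find over 4-adjacent similar cells
  parent <- seq_along(active)
  pos <- match(seq_along(scores), active)   # cell idx -> active rank
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_along(active)) {
    cl <- scan$cells[[active[r]]]
    for (nb in list(c(1L, 0L), c(0L, 1L))) {
      ju <- cl$iu + nb[1]; jv <- cl$iv + nb[2]
      if (ju >= n_u || jv >= n_v) next
      r2 <- pos[idx_of(ju, jv)]
      if (is.na(r2)) next
      sim <- cell_similarity(cl$spots, scan$cells[[active[r2]]]$spots, config)
      if (sim >= sg$similarity_threshold) {
        ra <- find(r); rb <- find(r2)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  comp <- vapply(seq_along(active), find, integer(1))
  groups <- unname(split(active, comp))

  regions <- lapply(groups, function(cells_idx) {
    cls <- scan$cells[cells_idx]
    iu <- vapply(cls, `[[`, numeric(1), "iu")
    iv <- vapply(cls, `[[`, numeric(1), "iv")
    sc <- scores[cells_idx]
    cen <- cell_centre_mm(g, iu, iv)
    w <- sc / sum(sc)
    extents <- c((diff(range(iu)) + 1) * g$step_mm,
                 (diff(range(iv)) + 1) * g$step_mm)
    spots <- do.call(rbind, lapply(cls, `[[`, "spots"))
    # the same reflection recorded in several member cells is one node;
    # duplicates would inflate the variance of the projection histograms
    # and break the Rayleigh calibration of the scores
    dup <- duplicated(round(cbind(spots$x_px, spots$y_px), 2))
    nodes <- spots_to_nodes(spots[!dup, , drop = FALSE], scan$detector)
    ap <- sg$apertures_um[sg$apertures_um >= min(extents) * 1000]
    structure(list(
      label = NA_integer_,
      cells = data.frame(iu = iu, iv = iv, score = sc),
      centroid_mm = c(u = sum(w * cen[, "u"]), v = sum(w * cen[, "v"])),
      extents_mm = c(du = extents[1], dv = extents[2]),
      integral_score = sum(sc),
      nodes = nodes,
      beam_size_um = if (length(ap)) min(ap) else max(sg$apertures_um)
    ), class = "CrystalRegion")
  })

  sc_int <- vapply(regions, `[[`, numeric(1), "integral_score")
  cu <- vapply(regions, function(r) r$centroid_mm[["u"]], numeric(1))
  cv <- vapply(regions, function(r) r$centroid_mm[["v"]], numeric(1))
  ord <- order(-sc_int, cu, cv)
  regions <- regions[ord]
  for (k in seq_along(regions)) {
    regions[[k]]$label <- k
    cells <- regions[[k]]$cells
    labels[cbind(cells$iv + 1, cells$iu + 1)] <- k
  }
  structure(list(regions = regions, labels = labels),
            class = "MeshSegmentation")
}

#' @export
print.MeshSegmentation <- function(x, ...) {
  cat(sprintf("MeshSegmentation: %d region(s), %d multi-pattern cell(s)\n",
              length(x$regions), sum(x$labels == 999L)))
  for (r in x$regions) {
    cat(sprintf(
      "  %2d: %2d cells, score %8.1f, centroid (u=%.3f, v=%.3f) mm, beam %d um\n",
      r$label, nrow(r$cells), r$integral_score,
      r$centroid_mm[["u"]], r$centroid_mm[["v"]], r$beam_size_um))
  }
  invisible(x)
}

#' Geometric cross-scan pair candidates
#'
#' All pairs of regions from the two scans whose centroids agree along the
#' rotation axis within `pairing_tolerance_cells` grid cells: the
#' rotation-axis coordinate of a crystal is invariant under the inter-scan
#' rotation, so only such pairs can be the same crystal.  Each candidate
#' carries the provisional triangulated 3D position.
#'
#' @param seg1,seg2 [segment_scan()] results for the two scans.
#' @param alpha_deg inter-scan rotation angle (degrees).
#' @param step_mm grid step (mm).
#' @param config a [crossmesh_config()].
#' @return Data frame with columns `region_a`, `region_b`, `z_gap_mm`,
#'   `x`, `y`, `z` (provisional position, mm).
#' @export
pair_candidates <- function(seg1, seg2, alpha_deg, step_mm,
                            config = crossmesh_config()) {
  tol_mm <- config$segment$pairing_tolerance_cells * step_mm
  out <- list()
  for (ra in seg1$regions) {
    for (rb in seg2$regions) {
      z_gap <- abs(ra$centroid_mm[["u"]] - rb$centroid_mm[["u"]])
      if (z_gap > tol_mm) next
      p <- triangulate_centre(
        c(ra$centroid_mm[["v"]], ra$centroid_mm[["u"]]),
        c(rb$centroid_mm[["v"]], rb$centroid_mm[["u"]]),
        alpha_deg
      )
      out[[length(out) + 1]] <- data.frame(
        region_a = ra$label, region_b = rb$label, z_gap_mm = z_gap,
        x = p$x, y = p$y, z = p$z
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(region_a = integer(0), region_b = integer(0),
                      z_gap_mm = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0)))
  }
  do.call(rbind, out)
}
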