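#' Quasi-uniform hemisphere direction set
#'
#' Builds `n` unit direction vectors covering the upper hemisphere
#' quasi-uniformly using a spherical Fibonacci layout.  Restricting to one
#' hemisphere avoids antipodal duplicates: a projection direction and its
#' negation define the same family of planes.
#'
#' @param n number of directions.
#' @return An `n` x 3 matrix of unit vectors (class `DirectionSet`).
#' @examples
#' D <- build_direction_set(100)
#' range(sqrt(rowSums(D^2)))
#' @export
build_direction_set <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- i / n                      # (0, 1): upper hemisphere, pole-free
  phi <- i * pi * (3 - sqrt(5))   # golden angle
  r <- sqrt(pmax(0, 1 - z^2))
  D <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  class(D) <- c("DirectionSet", class(D))
  D
}

#' Project nodes onto a direction
#'
#' Scalar projection coordinates of reciprocal-space nodes onto a unit
#' direction vector.
#'
#' @param nodes n x 3 matrix of node positions (1/angstrom).
#' @param u length-3 direction vector (normalised internally).
#' @return Numeric vector of projection coordinates (1/angstrom).
#' @export
project_nodes <- function(nodes, u) {
  stopifnot(is.matrix(nodes), ncol(nodes) == 3, length(u) == 3)
  u <- u / sqrt(sum(u^2))
  drop(nodes %*% u)
}

#' Histogram of projection coordinates
#'
#' Bins scalar projection coordinates at a fixed bin width over the data
#' range padded by 5 percent.  Degenerate (zero-range) input yields a
#' 16-bin histogram centred on the data.
#'
#' @param coords numeric vector of projection coordinates (1/angstrom).
#' @param bin_width bin width (1/angstrom).
#' @return An object of class `ProjectionHistogram`: list with `counts`,
#'   `bin_width`, `lo` (left edge of the first bin).
#' @export
make_histogram <- function(coords, bin_width) {
  stopifnot(bin_width > 0, length(coords) >= 1)
  mn <- min(coords); mx <- max(coords)
  range <- mx - mn
  if (range <= 0) {
    n <- 16L
    lo <- mn - 8 * bin_width
  } else {
    n <- max(16L, as.integer(ceiling(range * 1.05 / bin_width)))
    lo <- mn - 0.025 * range
  }
  idx <- pmin(pmax(floor((coords - lo) / bin_width), 0), n - 1) + 1
  counts <- tabulate(idx, nbins = n)
  structure(list(counts = counts, bin_width = bin_width, lo = lo),
            class = "ProjectionHistogram")
}

#' Normalise a counting histogram against its moving average
#'
#' Subtracts a slowly moving average (Gaussian filter of the counts) from
#' the histogram and divides by the square root of that average:
#' \eqn{h_i = (H_i - p_i)/\sqrt{p_i}}.  For a structureless counting
#' histogram the result has zero mean and unit variance per bin, so its
#' Fourier magnitudes (suitably scaled, see [score_spectrum()]) follow a
#' unit Rayleigh distribution.  Bins whose moving average does not exceed
#' `p_floor` carry no usable information and are set to zero.
#'
#' @param H a `ProjectionHistogram` or a bare numeric count vector.
#' @param sigma_bins Gaussian sigma of the moving average (bins).
#' @param p_floor minimum moving average for a bin to be retained.
#' @return The input object with components `p` (moving average) and `h`
#'   (normalised histogram) added; for numeric input, a list with `counts`,
#'   `p`, `h`.
#' @export
normalize_histogram <- function(H, sigma_bins = 10, p_floor = 0.5) {
  obj <- if (inherits(H, "ProjectionHistogram")) H else list(counts = as.numeric(H))
  counts <- as.numeric(obj$counts)
  p <- as.numeric(cpp_smooth_counts(counts, sigma_bins))
  h <- ifelse(p > p_floor, (counts - p) / sqrt(p), 0)
  obj$p <- p
  obj$h <- h
  obj$sigma_bins <- sigma_bins
  if (inherits(H, "ProjectionHistogram")) obj else structure(obj, class = "ProjectionHistogram")
}

#' Rayleigh-scaled Fourier spectrum of a normalised histogram
#'
#' Computes scores s_k = |DFT(h)_k| * sqrt(2 / n_bins) for frequencies
#' 0 < k < n/2, so that in the absence of periodicity the scores follow a
#' unit-scale Rayleigh (chi, 2 d.f.) distribution.  Each score is labelled
#' with the direct-space period it corresponds to, f_k = k / (n * bin_width)
#' (angstrom).  Components that the moving-average subtraction does not
#' fully suppress (low k) and periods below `min_period_A` are flagged as
#' masked; masked components are excluded from peak picking.
#'
#' @param h normalised histogram: output of [normalize_histogram()] or a
#'   bare numeric vector.
#' @param bin_width histogram bin width (1/angstrom).
#' @param sigma_bins sigma used in the normalisation (needed for the mask).
#' @param g_max mask threshold on the moving-average transfer function.
#' @param min_period_A shortest direct-space period retained (angstrom).
#' @return Data frame with columns `k`, `freq_A`, `score`, `masked`.
#' @export
score_spectrum <- function(h, bin_width, sigma_bins = 10, g_max = 0.02,
                           min_period_A = 10) {
  if (inherits(h, "ProjectionHistogram") || is.list(h)) {
    if (is.null(h$h)) stop("histogram has not been normalised", call. = FALSE)
    if (!is.null(h$sigma_bins)) sigma_bins <- h$sigma_bins
    if (!is.null(h$bin_width)) bin_width <- h$bin_width
    h <- h$h
  }
  n <- length(h)
  stopifnot(n >= 4, bin_width > 0)
  Fm <- Mod(stats::fft(h))
  kmax <- (n - 1) %/% 2            # strictly below Nyquist
  k <- seq_len(kmax)
  L <- n * bin_width
  score <- Fm[k + 1] * sqrt(2 / n)
  freq <- k / L
  kmin_transfer <- n * sqrt(-log(g_max) / (2 * pi^2 * sigma_bins^2))
  masked <- (k < kmin_transfer) | (freq < min_period_A)
  data.frame(k = k, freq_A = freq, score = score, masked = masked)
}

#' Peak of a scored spectrum with sub-bin refinement
#'
#' Picks the maximum unmasked score of a [score_spectrum()] table and
#' refines its position and height by parabolic interpolation through the
#' neighbouring Fourier bins (the standard three-point estimator for a
#' peak sampled on a grid).  This is the peak definition used throughout
#' the direction scan.
#'
#' @param sp data frame from [score_spectrum()].
#' @return List with `score` (interpolated peak height, never below the
#'   best bin) and `freq_A` (interpolated period), or zero score when all
#'   components are masked.
#' @export
spectrum_peak <- function(sp) {
  open <- which(!sp$masked)
  if (length(open) == 0) return(list(score = 0, freq_A = NA_real_))
  i <- open[which.max(sp$score[open])]
  k <- sp$k[i]
  m0 <- sp$score[i]
  mm <- if (any(sp$k == k - 1)) sp$score[sp$k == k - 1] else m0
  mp <- if (any(sp$k == k + 1)) sp$score[sp$k == k + 1] else m0
  denom <- mm - 2 * m0 + mp
  delta <- 0
  if (denom < 0) delta <- max(-0.5, min(0.5, 0.5 * (mm - mp) / denom))
  bin <- sp$freq_A[i] / k     # period per Fourier bin index
  list(score = max(m0, m0 - 0.25 * (mm - mp) * delta),
       freq_A = (k + delta) * bin)
}

#' Survival function of the unit Rayleigh distribution
#'
#' P(S > s) = exp(-s^2 / 2) for the unit-scale Rayleigh (chi distribution
#' with two degrees of freedom).  This is the null distribution of the
#' scores in [score_spectrum()], and calibrates the plane-acceptance
#' threshold 7 (tail 2e-11) and the match threshold 5 (tail 4e-6).
#'
#' @param s score value(s).
#' @return Tail probability.
#' @examples
#' rayleigh_survival(c(5, 7))
#' @export
rayleigh_survival <- function(s) exp(-s^2 / 2)

# Single-direction peak via the compiled pipeline.  expected_freq_A < 0
# scans the full unmasked range.
direction_peak <- function(nodes, u, pl, expected_freq_A = -1, window_bins = 0) {
  u <- u / sqrt(sum(u^2))
  proj <- drop(nodes %*% u)
  res <- cpp_peak_score(proj, pl$bin_width_invA, pl$smooth_sigma_bins,
                        pl$p_floor, pl$g_max, pl$min_period_A,
                        expected_freq_A, as.integer(window_bins))
  list(score = res$score, freq_A = res$freq_A)
}

# Minimal Nelder-Mead maximiser of the peak score over directions,
# parametrised in the tangent plane of the start direction.  Returns the
# best direction/score/frequency seen during the search (not merely the
# final simplex), capped at max_eval evaluations.  The initial simplex
# step never drops below a third of the coarse grid spacing, so the
# search can reach a peak sitting between coarse directions.
refine_direction <- function(nodes, d0, pl) {
  d0 <- d0 / sqrt(sum(d0^2))
  # tangent basis
  a <- if (abs(d0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- pracma_cross(d0, a); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- pracma_cross(d0, e1)
  best <- list(score = -Inf, freq_A = NA_real_, dir = d0)
  nev <- 0L
  fn <- function(par) {
    if (nev >= pl$refine_max_eval) return(Inf)
    nev <<- nev + 1L
    d <- d0 + par[1] * e1 + par[2] * e2
    d <- d / sqrt(sum(d^2))
    pk <- direction_peak(nodes, d, pl)
    if (pk$score > best$score) best <<- list(score = pk$score, freq_A = pk$freq_A, dir = d)
    -pk$score
  }
  spacing <- sqrt(2 * pi / pl$n_directions)
  step <- max(pl$refine_step_deg * pi / 180, spacing / 3)
  nelder_mead2(fn, c(0, 0), step, pl$refine_max_eval)
  best
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# 2-parameter Nelder-Mead with explicit initial step and evaluation cap.
nelder_mead2 <- function(fn, x0, step, max_eval,
                         alpha = 1, gamma = 2, rho = 0.5, sigma = 0.5) {
  pts <- list(x0, x0 + c(step, 0), x0 + c(0, step))
  vals <- vapply(pts, fn, numeric(1))
  nev <- 3L
  while (nev < max_eval) {
    ord <- order(vals)
    pts <- pts[ord]; vals <- vals[ord]
    centroid <- (pts[[1]] + pts[[2]]) / 2
    xr <- centroid + alpha * (centroid - pts[[3]])
    fr <- fn(xr); nev <- nev + 1L
    if (fr < vals[1]) {
      xe <- centroid + gamma * (xr - centroid)
      fe <- fn(xe); nev <- nev + 1L
      if (fe < fr) { pts[[3]] <- xe; vals[3] <- fe } else { pts[[3]] <- xr; vals[3] <- fr }
    } else if (fr < vals[2]) {
      pts[[3]] <- xr; vals[3] <- fr
    } else {
      xc <- centroid + rho * (pts[[3]] - centroid)
      fc <- fn(xc); nev <- nev + 1L
      if (fc < vals[3]) {
        pts[[3]] <- xc; vals[3] <- fc
      } else {
        pts[[2]] <- pts[[1]] + sigma * (pts[[2]] - pts[[1]])
        pts[[3]] <- pts[[1]] + sigma * (pts[[3]] - pts[[1]])
        vals[2] <- fn(pts[[2]]); vals[3] <- fn(pts[[3]]); nev <- nev + 2L
      }
    }
  }
  ord <- order(vals)
  list(par = pts[[ord[1]]], value = vals[ord[1]], nev = nev)
}

# deterministic thinning of an oversized node set
thin_nodes <- function(nodes, cap) {
  n <- nrow(nodes)
  if (n <= cap) return(nodes)
  nodes[unique(round(seq(1, n, length.out = cap))), , drop = FALSE]
}

#' Find plane vectors in a reciprocal-lattice subset
#'
#' Scans a quasi-uniform set of direction vectors; for each, the node
#' projections are histogrammed, normalised against their moving average and
#' Fourier-transformed, and the maximum Rayleigh-scaled magnitude over
#' unmasked frequencies is recorded.  The best `top_k` directions are
#' refined by a derivative-free simplex search, and each refined direction
#' whose peak score exceeds `plane_threshold` is converted to a plane
#' vector: the unit direction times the direct-space period of the Fourier
#' peak (angstrom).  Near-parallel results with matching periods are
#' deduplicated, keeping the higher score.
#'
#' @param nodes n x 3 matrix of reciprocal-space node positions
#'   (1/angstrom), e.g. from [spots_to_nodes()].
#' @param config a [crossmesh_config()].
#' @return Data frame with one plane vector per row: columns `vx`, `vy`,
#'   `vz` (angstrom; the vector is direction times period), `freq_A`
#'   (period, = vector norm), `score`.  Zero rows when fewer than
#'   `min_nodes` nodes are supplied or no direction passes the threshold.
#' @export
find_planes <- function(nodes, config = crossmesh_config()) {
  pl <- config$planes
  empty <- data.frame(vx = numeric(0), vy = numeric(0), vz = numeric(0),
                      freq_A = numeric(0), score = numeric(0))
  if (is.null(nodes) || nrow(nodes) < pl$min_nodes) return(empty)
  nodes <- thin_nodes(unname(as.matrix(nodes)), pl$node_cap)

  D <- build_direction_set(pl$n_directions)
  coarse <- cpp_scan_directions(nodes, unclass(D), pl$bin_width_invA,
                                pl$smooth_sigma_bins, pl$p_floor, pl$g_max,
                                pl$min_period_A)
  ord <- order(coarse[, 1], decreasing = TRUE)
  top <- ord[seq_len(min(pl$top_k, nrow(D)))]

  cands <- lapply(top, function(j) refine_direction(nodes, D[j, ], pl))
  # periods interpolated up against the Nyquist bound are unreliable and
  # could not be re-tested by check(); keep a safety margin
  nyquist <- 1 / (2 * pl$bin_width_invA)
  keep <- Filter(function(cc) is.finite(cc$score) && cc$score > pl$plane_threshold &&
                   is.finite(cc$freq_A) && cc$freq_A <= 0.995 * nyquist, cands)
  if (length(keep) == 0) return(empty)

  keep <- keep[order(vapply(keep, `[[`, numeric(1), "score"), decreasing = TRUE)]
  out <- list()
  for (cc in keep) {
    dup <- FALSE
    for (kk in out) {
      cosang <- abs(sum(cc$dir * kk$dir))
      ang <- acos(pmin(1, cosang)) * 180 / pi   # angle between lines
      if (ang < pl$dedup_angle_deg &&
          abs(cc$freq_A / kk$freq_A - 1) < pl$dedup_freq_rel) {
        dup <- TRUE
        break
      }
    }
    if (!dup) out[[length(out) + 1]] <- cc
  }
  data.frame(
    vx = vapply(out, function(cc) cc$dir[1] * cc$freq_A, numeric(1)),
    vy = vapply(out, function(cc) cc$dir[2] * cc$freq_A, numeric(1)),
    vz = vapply(out, function(cc) cc$dir[3] * cc$freq_A, numeric(1)),
    freq_A = vapply(out, `[[`, numeric(1), "freq_A"),
    score = vapply(out, `[[`, numeric(1), "score")
  )
}
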