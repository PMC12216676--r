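---
title: "Locating crystals in 3D from double X-ray mesh scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating crystals in 3D from double X-ray mesh scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A macromolecular crystallography mesh (raster) scan translates the sample
holder across a 2D grid under the beam and records one still diffraction
image per grid cell; per-cell diffraction scores form a heat map on which a
crystal can be centred in two dimensions. The third coordinate — depth along
the beam — is classically obtained from a second, orthogonal line scan. With
several crystals in the holder this fails in a characteristic way: nothing
guarantees that the line scan picks the *same* crystal that the mesh scan
did, because no step checks crystal identity between the two orientations.

crossmesh implements an analysis chain that resolves the ambiguity from two
*full* mesh scans taken at goniometer angles differing by $\alpha$:

1. **Segmentation** (`segment_scan()`): each scan's per-cell spot lists are
   grouped into connected regions belonging to individual crystals, and
   cells containing superimposed patterns from several crystals are excluded
   (conventional label 999).
2. **Reciprocal-lattice reconstruction** (`spots_to_nodes()`): each region's
   diffraction spots are back-projected through the Ewald construction,
   $q = (\hat u - \hat b)/\lambda$, giving a subset of the crystal's
   reciprocal lattice lying on the Ewald sphere.
3. **Periodicity detection** (`find_planes()`): families of parallel
   periodic planes through the node set are found by scanning an isotropic
   set of directions, histogramming the node projections, and scoring
   Fourier magnitudes calibrated against a Rayleigh null. Accepted
   directions become *plane vectors* — unit direction times the direct-space
   period (in Å) — which are intrinsic to the crystal lattice and transform
   by rotation only.
4. **Cross-scan validation** (`check_plane()`, `match_pair()`): a crystal
   region in scan 1 and one in scan 2 can be the same crystal only if their
   rotation-axis coordinates agree; for these geometric candidates, plane
   vectors from one scan are rotated by $\pm\alpha$ and tested against the
   other region's nodes. A pair is confirmed when the best score exceeds
   the match threshold.
5. **Triangulation** (`triangulate_centre()`): confirmed pairs combine their
   two 2D centroids into a full 3D centring position.

`run_doublemesh()` chains all stages and ranks confirmed crystals by
integral diffraction score, with a recommended beam aperture per crystal.

## Coordinate conventions

The frame is tied to the first scan: $\hat x$ along its incident beam,
$\hat z$ along the goniometer rotation axis (horizontal), $\hat y$ vertical;
positive rotation carries $+\hat x$ towards $+\hat y$. Scan grids use
$u \parallel \hat z$ and a vertical axis $v$ that points opposite laboratory
$+\hat y$ (the screen-down convention of scan displays). Under these
conventions a sample point $(x, y, z)$ appears at grid coordinates

$$u(\omega) = z, \qquad v(\omega) = y\cos\omega - x\sin\omega,$$

and the triangulation solves this pair of observations in closed form:
$x = (v_1\cos\alpha - v_2)/\sin\alpha$, $y = v_1$, $z = (z_1+z_2)/2$.
Reciprocal-space vectors rotate *forwards* by $+\alpha$ from scan 1 to
scan 2. The simulator and the triangulation share this one convention, and
the round trip (`project_position()` then `triangulate_centre()`) is tested
to float precision; the inter-scan angle must not be a multiple of 180°, and
accuracy degrades as $1/\sin\alpha$ for shallow angles (90° is optimal).

## The Rayleigh-calibrated periodicity score

For a direction $\hat u$ the node projections $q_i \cdot \hat u$ are
histogrammed at a fixed bin width (default 0.002 Å$^{-1}$, data range padded
5%). The raw counting histogram $H$ has a strong slowly-varying envelope
(the density of Ewald-sphere nodes along any axis is far from uniform), so
it is normalised against a moving average $p$ — a Gaussian filter of the
counts, $\sigma = 10$ bins — used as offset and scale:

$$h_i = \frac{H_i - p_i}{\sqrt{p_i}}, \qquad p_i > p_{\text{floor}} = 0.5.$$

For structureless counts each $h_i$ has zero mean and unit variance, so the
Fourier magnitudes scaled by $\sqrt{2/n_{\text{bins}}}$ asymptotically
follow a unit-scale Rayleigh ($\chi$, 2 d.f.) distribution. This gives the
two decision thresholds a precise meaning:

* **7** for accepting a refined direction as a plane vector — survival
  probability $e^{-49/2} \approx 2\times10^{-11}$, small enough to survive
  multiple testing over 2500 directions × ~1000 frequencies per region;
* **5** for the cross-scan check, where the frequency is *known* in advance
  (the rotated vector's length) and only a narrow window around it is
  examined — survival $e^{-25/2} \approx 4\times10^{-6}$.

Two classes of Fourier components are masked because they are not
Rayleigh-calibrated: $k = 0$ and components where the moving-average
subtraction passes more than `g_max` = 2% of the signal (low $k$; the
Gaussian filter's transfer function is known in closed form), plus periods
below `min_period_A` = 10 Å, shorter than any protein-cell axis. The peak
position and height are refined by three-point parabolic interpolation,
which brings the period accuracy to a fraction of a Fourier bin — needed to
meet a 2% period tolerance for short-period families.

The per-direction pipeline (histogram, smoothing, normalisation, FFT, masked
peak) is implemented twice: once as inspectable R functions
(`make_histogram()`, `normalize_histogram()`, `score_spectrum()`,
`spectrum_peak()`) and once in compiled code that the direction scan uses;
a test asserts the two paths agree to $10^{-8}$.

## Direction scan and refinement

The direction set is a spherical Fibonacci layout restricted to one
hemisphere (default $n = 2500$): the field's prescription of an isotropic
set in spherical coordinates leaves the lattice open, and the Fibonacci
layout avoids polar clustering while excluding antipodal duplicates (a
projection axis and its negation are the same family). The best `top_k`
= 10 coarse directions are refined by a small Nelder–Mead simplex on the
local tangent plane, capped at 40 evaluations. The initial simplex step is
0.5° but never less than a third of the coarse grid spacing
($\sqrt{2\pi/n}$): direction peaks of large-cell lattices are narrower than
the coarse spacing, and a fixed 0.5° step cannot travel far enough from a
neighbouring grid point to reach them. Refined directions scoring above 7
become plane vectors; near-parallel results (< 2° as lines, periods within
2%) are deduplicated keeping the higher score, and periods interpolated
against the Nyquist bound ($1/(2\,\text{bin width})$ = 250 Å) are dropped
as unreliable. Fewer than `min_nodes` = 50 nodes yields no vectors — too
little evidence for an $2\times10^{-11}$-tail decision. Node sets larger
than `node_cap` = 4000 are thinned deterministically; histogram shape, not
node count, carries the signal.

Harmonic peaks (a family at period $d$ and its doubling at $2d$) are both
genuine plane-vector families and both may be reported; deduplication only
removes same-direction, same-period repeats.

## Segmentation choices

Per-cell diffraction scores are the background-relative sum
$\sum I/(b+1)$ over spots — a transparent proxy for an external spot
finder's quality score, linear in intensity and zero for an empty cell.
Cells below `min_cell_score` = 5 are treated as non-diffracting: with the
simulator's noise floor (five weak uniform noise spots per image on
background 10) noise-only cells score well below 1, while any illuminated
cell scores in the hundreds, so the cut is not delicate.

Adjacent (4-connected) cells are joined when the spot-position similarity —
the fraction of the smaller list matched one-to-one within 4 px — reaches
0.4. Still images of the same crystal in neighbouring cells share spot
positions almost exactly; unrelated cells match only by accident. Connected
components of this graph are the crystal regions (single-linkage
agglomeration over the adjacency graph). Regions are labelled in order of
decreasing integral score, carry score-weighted centroids (which is what
makes the triangulated positions land well inside half a grid step: the
per-cell intensity weighting recovers the sub-cell centre of the crystal's
footprint), and recommend the smallest aperture from \{10, 20, 30, 50\} µm
covering the smaller region extent.

### Multi-pattern (999) cells

Cells where several crystals diffract simultaneously would poison both the
similarity graph and the pooled node sets, so they are excluded before
segmentation. The criterion asks whether the cell's spot set is consistent
with a *single* lattice, using difference vectors in transverse reciprocal
space: spots are back-projected onto the Ewald sphere and only the
components perpendicular to the beam are kept, restricted to the low-angle
region ($q_\perp \le 0.15$ Å$^{-1}$). In that representation a single
crystal's short difference vectors cluster, to ~$5\times10^{-4}$ Å$^{-1}$,
around integer combinations of at most three generator vectors (the
transverse projection of the lattice basis) — in detector pixels this fails,
because Ewald curvature smears the clusters by several pixels over a
~100 px span. Clusters (single linkage, radius $10^{-3}$ Å$^{-1}$) are
greedily explained by up to three generators, and the cell is flagged when
the unexplained cluster mass reaches an absolute floor of 10 and 20% of the
explained mass. On simulated scans this flags no single-crystal cell in
313 tried while detecting about half of deliberately merged two-crystal
cells — a deliberately conservative trade: a false 999 truncates a genuine
region (costing centring accuracy and possibly a match), while a missed
overlap cell merely adds background-like nodes to one region's pool. Cells
with fewer than 20 spots are never flagged; there is not enough evidence
either way.

## Cross-scan matching

Candidate pairs are all cross-combinations of regions whose rotation-axis
centroids agree within 1.5 grid cells (the rotation-axis coordinate is
invariant). Both rotation directions are tested — scan-1 vectors forwards,
scan-2 vectors backwards — because either region alone may have yielded
plane vectors. The check recomputes the projection histogram from the
*target* node set, so the expected frequency is located by its (fractional)
bin index in that histogram's own frequency grid; the peak is searched
within ±1 bin of it. The window width deserves a note: rotation preserves
a vector's length exactly, and the source peak's period is known to
sub-bin precision from the parabolic interpolation, so the window only
needs to absorb that interpolation error. A wider window (±3 bins was
tried first) measurably inflates the false-match rate, because unrelated
random crystals are surprisingly likely to share a *high-order* plane
family to within a degree and a percent — the density of lattice families
on the sphere grows steeply with period, and a loose period window admits
them. A winning combination (score above 5) is additionally confirmed in
*direction*: the check projects the target's nodes onto the rotated
vector's axis and is therefore blind to whether the periodicity it finds
is actually centred on that axis. Refining the plane direction on the
target's own nodes resolves this — for a genuine pair the local optimum
sits within a degree of the rotated vector, while a coincidentally
aligned foreign family pulls it visibly away; combinations whose optimum
shifts beyond `direction_tol_deg` (default 1.25°) are rejected. With the
±1-bin window and the direction confirmation, simulated false candidates
are rejected reliably while true pairs lose nothing. A pair matches when
the maximum surviving score exceeds 5. One-to-many outcomes are reported
as-is with their scores rather than resolved by assignment; downstream
users see every pair that passed.

Pooled region spots are deduplicated by position before back-projection:
the same reflection recorded in several member cells is one node, and
keeping copies would multiply the histogram counts' variance and silently
break the Rayleigh calibration (this was observed as occasional
cross-crystal scores slightly above 5 before the fix).

## The simulator

`render_double_mesh()` emulates the study conditions end to end: a
micromesh-style holder with `n_crystals` box-shaped crystals (default
edge lengths 10–30 µm), random triclinic cells (default axes 40–90 Å,
angles 80–100°), random orientations, on a 30 × 20 grid of 10 µm pitch;
a flat detector of 4148 × 4362 pixels (75 µm) at 180 mm and 0.861 Å
(14.4 keV); two scans at $\omega$ = 0° and 60° by default. Reflections are
excited when their reciprocal node lies within the excitation tolerance
$\epsilon$ = 0.002 Å$^{-1}$ of the Ewald sphere — a binary in/out stand-in
for mosaicity and bandwidth; partiality, Lorentz/polarisation factors and
structure-factor physics are deliberately absent. The resolution cutoff is
chosen per crystal so that roughly 600 reflections are excited (spot counts
of a few hundred to a thousand per image are typical of real mesh scans);
per-cell spot lists are capped at 600, strongest first, like a spot
finder's list. Each covered grid cell receives the crystal's full spot
list with intensities scaled by the cell-overlap fraction of the footprint
box, plus Poisson(5) uniform noise spots. Crystal positions are
rejection-sampled so that footprints stay on-grid in both scans and do not
overlap (default gap ≥ 1 cell) — deliberate overlaps for testing the
multi-pattern flag are constructed by merging cells explicitly.

Because the simulator shares the package's geometry functions in the
forward direction only (rotation, Ewald condition, detector projection),
round trips through the analysis — node reconstruction, plane recovery,
footprint triangulation — are genuine inversions, not tautologies.

What passing on this simulator does *not* show: robustness to detector
distortion, to mosaic smearing of spot positions, to intensity-dependent
spot-finding errors, to salt rings, or to crystals much larger than the
beam whose diffracting volume wanders with orientation. Those effects are
outside the model; results on real scans depend on them.

## Validation at study scale

The test suite validates, at the conditions above: the closed-form Rayleigh
tails behind the thresholds (2 × 10⁻¹¹ at 7, 4 × 10⁻⁶ at 5); unit-Rayleigh
behaviour of the scores on 50 i.i.d. Poisson histograms of 4096 bins and
absence of plane vectors on 200 lattice-free node sets; recovery of a true
lattice family (direction within 1°, period within 2%) on 50 single
crystals with cells 40–150 Å; sensitivity, false-match rate and centring
accuracy over 20 double-mesh simulations of 5–15 crystals at
$\alpha \in \{30°, 60°, 90°\}$; agreement of the coarse-plus-refined search
with a brute-force scan over a 10× finer direction grid on 20 striped node
clouds (elongated along the stripe normal so the direction peak is broad
enough for a 50-direction coarse grid — with narrow peaks the comparison
would measure luck, not search quality); and the near-linear growth of
`find_planes()` runtime in the node count (the per-direction histogram
length, not the node count, dominates). The same computations are re-run
by `scripts/acceptance.R`, which writes the measured rates to JSON.

Problem sizes were chosen to exercise the method at its intended scale —
hundreds of spots per image, thousands of nodes per region, the full
2500-direction scan — while each suite component completes in minutes.

## Known limitations

* The multi-pattern flag trades sensitivity for specificity, as discussed.
* Very shallow inter-scan angles amplify both centring noise ($1/\sin\alpha$)
  and the correlation between the two scans' footprints.
* Crystals whose pooled regions yield fewer than 50 usable nodes produce no
  plane vectors and can never be matched; weakly diffracting crystals need
  the evidence, not a lower threshold.
* Periods above ~250 Å (the Nyquist bound of the default bin width) are not
  representable; very large cells need a smaller `bin_width_invA`.
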