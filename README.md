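# crossmesh

Crystal identification and 3D centring from double X-ray mesh scans, for
multi-crystal macromolecular crystallography.

## The problem

An X-ray mesh (raster) scan rasters the sample holder through the beam and
scores the still diffraction image at every grid cell, locating crystals in
two dimensions. The depth coordinate classically comes from a second scan at
another goniometer angle — but when the holder contains *several* crystals,
nothing ties a region seen at one angle to a region seen at the other, and
the combined "3D centring" can silently mix two different crystals.

crossmesh analyses a pair of full mesh scans taken at goniometer angles
differing by α and establishes crystal identity across them from the
diffraction itself:

1. each scan is segmented into connected per-crystal regions (cells with
   superimposed patterns from several crystals are excluded, conventional
   label 999);
2. each region's spots are back-projected onto the Ewald sphere,
   **q** = (û − b̂)/λ, giving a reciprocal-lattice subset;
3. families of parallel periodic planes through that subset are detected by
   scanning 2500 quasi-uniform directions: node projections are
   histogrammed, normalised against a moving average (offset p, scale √p),
   and Fourier magnitudes scaled by √(2/n) are judged against their
   unit-Rayleigh null — a refined direction with peak score above 7
   (tail 2 × 10⁻¹¹) becomes a *plane vector* v = d · û, the family normal
   scaled by the direct-space period d (Å);
4. plane vectors are intrinsic to the lattice: rotated by ±α they must fit
   the other scan's nodes if — and, to the Rayleigh tail 4 × 10⁻⁶, only
   if — the two regions are the same crystal (peak above 5 at the known
   frequency);
5. confirmed pairs triangulate their two 2D centroids into a 3D centring
   position: x = (v₁ cos α − v₂)/sin α, y = v₁, z = (z₁ + z₂)/2, with a
   recommended beam aperture per crystal.

A bundled simulator (`render_double_mesh()`) generates complete
multi-crystal double mesh scans — random triclinic cells, orientations,
positions, Ewald-condition spot generation at both angles, noise spots —
with exact ground truth, and backs every test in the package.

## Worked example

```r
library(crossmesh)

sim <- render_double_mesh(simulation_config(n_crystals = 3, seed = 42))
res <- run_doublemesh(sim$scan1, sim$scan2, verbose = TRUE)
#> segmentation: 3 region(s) in scan 1, 3 in scan 2
#> plane vectors: 3 region(s) with >=1 vector in scan 1, 3 in scan 2
#> pair candidates: 3
#> matches: 3 of 3 candidates
res
#> DoubleMeshResult: 3 + 3 regions, 3 candidate pair(s), 3 matched
#>   #1: regions 1/1, score 26.0, position (-0.0069, 0.1153, 0.1092) mm, beam 30 um
#>   #2: regions 2/2, score 21.0, position (-0.0246, 0.1342, 0.1992) mm, beam 30 um
#>   #3: regions 3/3, score 27.5, position (-0.1105, 0.0600, 0.0200) mm, beam 10 um
```

Each matched line is one crystal confirmed in both scans: its region labels,
the maximum cross-scan check score (unit-Rayleigh scale; 26 is
overwhelming evidence against threshold 5), the triangulated 3D position in
the frame of the first scan (x along the beam, z along the rotation axis,
mm) and the recommended aperture. The seeded ground truth for this example
puts the three crystals at (−0.0053, 0.1176, 0.1081), (−0.0231, 0.1340,
0.1991) and (−0.1129, 0.0580, 0.0159) mm — all recovered to within a few
µm, half a 10 µm grid step. `write_match_report()`, `write_crystal_map()`
and `write_heatmap()` export the results as JSON and TSV.

The same pipeline is scriptable from a shell via the thin launcher in
`exec/`:

```sh
crossmesh run --config run.yaml --outdir out/       # simulate + analyse
crossmesh segment --scan out/scan1.jsonl --out map.tsv
crossmesh match --scan1 a.jsonl --scan2 b.jsonl --out report.json
```

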