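# paintcrypt

Encode text as docking-site patterns on 2D and 3D DNA origami, simulate
the DNA-PAINT localization data such patterns produce, and decode them
back with an unsupervised readout pipeline.

DNA origami cryptography hides a message in *which* staple strands of an
origami carry single-stranded docking extensions: each candidate site is
one bit. DNA-PAINT super-resolution imaging turns every visible site into
a small cloud of localizations, and recovering the message is then a
statistics problem — how many clusters, where is the template, which bits
are set. The package is aimed at people designing such encodings or
readout pipelines: it lets you measure, under controlled synthetic
conditions with ground truth, how detection efficiency, localization
precision, structural distortion and bit redundancy translate into
readout accuracy.

The decode stack per particle:

1. **k-means scan with elbow selection** — k-means (kmeans++ restarts)
   for every candidate cluster count k in `[N, M]`; the selected k is the
   smallest one whose normalized inertia drop has saturated (score
   `1 − Δ_k/max Δ ≥ 0.95`).
2. **Cluster filtering** — 2D clusters below `T_S ×` the mean size are
   discarded; 3D clouds pass a DBSCAN-style noise prefilter (ε = 7,
   4 neighbors) first.
3. **Template registration** — in 2D, minimize
   `C = √(D+1)/n · Σᵢ (|Aᵢ − Bᵢ| Pᵢ Sᵢ)²` over rotation → anisotropic
   scaling (shear) → translation of the template, where `Bᵢ` is the
   nearest transformed site to centroid `Aᵢ`, `Sᵢ` the cluster size,
   `Pᵢ = W_O > 1` on filled orientation markers and `D` counts stranded
   markers; in 3D, minimize `C = Σᵢ |Aᵢ − Bᵢ|²` over a z-scale ×
   z-rotation × translation grid after center-of-mass alignment, with a
   marker check discarding mis-oriented particles.
4. **Bit extraction** — a site reads 1 iff some centroid is assigned to
   it; logical bits are the OR over their redundancy group; the bit
   string splits into a character code and a 1-based position.

## Worked example

```r
library(paintcrypt)

rule <- rule_rro12()          # 12-site rectangle, 20 nm pitch, 3+3 bits
cmap <- default_map_3bit()    # 8-symbol demo alphabet

ds <- simulate_dataset("NSF", rule, cmap, n_per_char = 50,
                       generator_config(detection_map = 0.89), seed = 42)
ro <- decode_particles(ds$locs, rule, cmap, seed = 7)
print(ro)
#> <origami_readout> rro12: 150 particles, 150 decoded, 0 rejected
#> top readout cells:
#>  character position count
#>          S        2    37
#>          N        1    32
#>          F        3    27
#>          F        1    12
#>          A        1     7
summary(ro, ds$truth)
#> 150/150 particles decoded (0 rejected)
#> accuracy: 63.3%
```

The three encoded letters dominate the histogram — that is the decoded
message — while the minor peaks are the characteristic bit-drop errors
(`N` is `011`; dropping one of its bits reads `F` = `010` or `A` = `001`).
Accuracy here is the fraction of particles whose
character *and* position both match the ground truth; at a per-site
detection probability of 0.89 a pattern with b information bits cannot
beat ≈ 0.89^b, which is what the per-letter numbers track.

The same stack handles the 48-site rectangle with one-redundancy encoding
(where `recollapse_readout(ro, cmap, use_redundancy = FALSE)` gives the
paired no-redundancy readout of identical alignments — global accuracy
drops from roughly 0.85 to 0.45), and the 3D cuboctahedron with a planted
1/3.3 axial compression, where the fitted z-scale recovers 3.3 and the
marker check discards mis-oriented particles.

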