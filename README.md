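# bact3c

Analysis of binned chromosome-conformation-capture (3C/Hi-C) contact maps
from bacteria with multipartite genomes. The package covers the standard
desk-side workflow for a bacterial 3C study — from raw binned count matrices
to normalized maps, chromosomal interaction domains (CIDs), distance-decay
statistics, 3D-model compactness metrics, and structure–transcription
integration — and ships a synthetic contact-map generator with planted
ground truth, so every stage can be benchmarked without any sequencing data.

The default genome geometry mirrors *Deinococcus radiodurans* R1 — four
circular replicons (Chr1 2649 kb, Chr2 412 kb, pMP1 177 kb, pCP1 46 kb)
binned at 5 kb — but every function takes an arbitrary replicon layout.

Intended users: microbial genomicists analysing bacterial 3C/Hi-C matrices,
and method developers who need a planted-truth benchmark for domain callers
and contact-significance tests.

## What it computes

- **SCN normalization.** Sequential component normalization: each column
  vector of the valid submatrix is divided by its norm, then each row
  vector, iterating until the maximum relative entry change falls below a
  tolerance; the result is re-symmetrized as (M + Mᵀ)/2. Removes separable
  per-bin biases b_i·b_j exactly and is invariant to global scaling.
- **Directionality index and CID boundaries.** For each bin,
  A = upstream and B = downstream contact sums within a window (default
  100 kb) and DI = sign(B − A)·((A − E)²/E + (B − E)²/E), E = (A + B)/2.
  Boundaries are runs of negative DI flipping to runs of positive DI;
  CIDs are the segments between boundaries (wrapping on circular
  replicons).
- **Distance decay and significant contacts.** P(s) curves on shorter-arc
  (circular) distances, an expected-count model per distance stratum
  (weighted isotonic regression, non-increasing in s), upper-tail Poisson
  p-values P(X ≥ obs | μ = E(s)) per cis pair, Benjamini–Hochberg
  q-values, and the selection rule p < 0.05, q < 0.05, count > 2.
- **Map views.** Scalograms (flank half-width at which a bin accumulates
  15/30/45/60/75/100 % of its local contacts) and log2 condition-ratio
  maps by position and distance.
- **3D structure metrics.** A classical-MDS embedding of normalized maps
  (target distances c_ij^(−1/α), shortest-path completion), radius of
  gyration R_g, global compactness GC = ⟨R_g/d_ij⟩ over all bin pairs,
  local compactness LC(s) restricted to genomic separations ≤ s, and a
  Mann–Whitney spatial-proximity test for protein–protein interaction
  pairs.
- **Structure–transcription integration.** Boundary vs interior gene
  tests (expression, length, G+C), correlation of the contact-map
  diagonal with per-bin transcription, sliding-window permutation
  enrichment of differentially expressed genes (100 kb windows, 5 kb
  step), and per-bin G+C profiles.
- **Synthetic maps with planted truth.** Expected contacts
  E[i,j] = max(d_ij, 1)^(−α) · CID(i,j) · arm(i,j) · b_i·b_j scaled to a
  sequencing depth and Poisson-sampled, with planted domain walls, a faint
  secondary (inter-arm) diagonal, lognormal bin biases, and condition
  modifiers (short-range depletion, boundary loss) plus matched
  expression/DEG/PPI tracks.

## Worked example

Simulate a Chr1-sized map with 8 planted domain walls at 5×10⁶ read pairs,
normalize it, and call CIDs at the 100 kb scale:

```r
library(bact3c)
layout <- replicon_layout("Chr1", 2649000, circular = TRUE)
spec   <- truth_spec(layout = layout, depth = 5e6, seed = 42)
sim    <- simulate_map(spec)
sim$map
#> contact_matrix [raw_counts]: 530 bins (530 valid), total signal 9.103e+06

norm <- scn_normalize(sim$map, mask = filter_bins(sim$map), max_iter = 400)
di   <- directionality_index(norm$matrix, "Chr1", scale_bp = 1e5)
cids <- call_boundaries(di)
cids
#> boundary_set on Chr1: 8 boundaries, 8 CIDs (threshold |DI| >= 0.00301)
#>   CID sizes: 70 - 705 kb (mean 331.2 kb)

boundary_recovery(cids, spec, tol_bins = 2)[c("precision", "recall", "f1")]
#> precision 1.00, recall 1.00, F1 1.00
```

All eight planted walls are recovered exactly. Decay and significant
contacts come from the raw map:

```r
fit_ps_slope(ps_curve(sim$map, "Chr1"))$slope
#> -1.207        # effective decay: planted exponent 1 steepened by CID blocks
sig <- call_significant(sim$map, "Chr1")
classify_distances(sig)
#>      band    n proportion
#> 1 <450 kb 7243  0.7403659
#> 2 >450 kb 2540  0.2596341
```

About 74 % of significant cis contacts are short-range (< 450 kb) on this
wild-type-like map; simulating the UV-like condition (flattened decay,
boundary loss) shifts that balance toward the long-range band.

A full run (read/simulate → filter → normalize → domains → significance →
views → integration) is one call: `run_pipeline("config.yaml")`, or from a
shell via the thin wrapper `inst/cli/bact3c.R`.

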