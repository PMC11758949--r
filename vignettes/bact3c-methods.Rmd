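---
title: "Methods and design notes for bact3c"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for bact3c}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical models behind each stage of the
package, the parameters that matter and their defaults, what the synthetic
generator does and does not emulate, and the design decisions taken where
the methodology left genuine latitude.

## Coordinate model

All coordinates are 0-based, half-open (BED convention): bin *i* of a
replicon covers `[i*s, (i+1)*s)` at bin size *s* (default 5000 bp, the
resolution bacterial 3C studies typically use). A genome-wide matrix
concatenates replicons in layout order; cis/trans status is derived from
the bin table, never stored. All cis statistics (DI, P(s), significance,
scalograms) are computed per replicon on the cis submatrix: bacterial
replicons are circular and their arm geometry is replicon-specific, so
pooling cis signal across replicons would mix unrelated distance scales.
Distances on circular replicons are shorter-arc distances,
`min(|i-j|, L-|i-j|)`, bounded by `L/2`; windows (DI, scalogram, sliding
windows) wrap around the origin.

A gene is assigned to every bin it overlaps; where a single bin is needed
(PPI mapping, window counting) the bin containing the gene midpoint is
used. Midpoint assignment is deterministic, strand-free, and avoids double
counting across overlapping windows.

## SCN normalization

Raw binned 3C counts carry strong multiplicative per-bin biases
(restriction-site density, mappability, copy number). Sequential component
normalization alternates column-vector and row-vector normalization of the
valid submatrix until the maximum relative entry change between iterations
drops below `tol` (default 1e-6; `max_iter` default 200). The alternating
sweeps break exact symmetry, so the final matrix is re-symmetrized as
`(M + t(M))/2`.

Choices worth recording:

* **Norm.** The classical SCN step normalizes to unit Euclidean column
  norm, and that is the default. `norm = "sum"` is offered because
  row-stochastic maps are easier to interpret (each row is a contact
  probability profile) and because a *conservation* constraint is what
  makes condition-ratio maps signed: with unit row sums, depleting
  short-range contacts must show as negative short-range and positive
  long-range log-ratios. The ratio-map tests therefore use `norm = "sum"`.
* **Scope.** Normalization is genome-wide by default (bias factors are a
  property of a bin, not of a replicon pair); pass a per-replicon mask to
  normalize replicons separately.
* **Convergence.** On a 530-bin replicon the euclidean iteration converges
  geometrically but slowly (residuals of order 1e-5 after 200 sweeps);
  benchmarks that need tight fixed points pass `max_iter = 400-1000`.
  Non-convergence returns the result with `converged = FALSE` and a
  warning rather than an error, since a residual of 1e-5 is far below the
  Poisson noise floor of any real map.
* **Filtering.** Bins with zero coverage, or coverage below a quantile of
  the nonzero coverages (default quantile 0: zero-coverage only), are
  masked before normalization and left as zero rows.

## Directionality index and CID calling

`DI(i) = sign(B - A) * ((A - E)^2/E + (B - E)^2/E)` with `A`/`B` the
summed contacts of bin *i* with the `scale/s` bins upstream/downstream
(main diagonal excluded), `E = (A + B)/2`, and `DI = 0` when `A + B = 0`.
This is the established directionality-index functional form; the scale
default is 100 kb, the scale at which bacterial CIDs (30–400 kb) separate
cleanly.

A boundary is called at each transition from a run of at least
`min_run_bins` bins with `DI <= -t` to a run of at least `min_run_bins`
bins with `DI >= +t`, allowing at most one intervening near-zero bin. Two
thresholds were genuinely open:

* `min_run_bins = 3` suppresses single-bin sign flips from noise while
  keeping the caller sensitive to closely spaced walls.
* `t =` the 60th percentile of `|DI|` over valid bins. A *percentile*
  threshold makes calls exactly invariant to global matrix scaling (DI is
  linear in counts) and self-adapts to sequencing depth.

The boundary is reported as a bin interval (boundaries are areas, not
points) with a midpoint bin for distance computations. On a circular
replicon the number of CIDs equals the number of boundaries; on a linear
one it is boundaries + 1. DI is computed on the SCN-normalized map in the
benchmark pipeline: per-bin biases enter `A` and `B` through every partner
bin and are the dominant noise source for boundary recall on raw maps.

Cross-condition comparison (`compare_boundaries`) uses greedy nearest
matching of midpoints within `tol_bins` (default 2), each boundary matched
at most once; recovery against planted truth reports the standard
precision/recall/F1 derived from the same matching.

## Distance decay and significant contacts

The expected-count model is the empirical mean raw count per distance
stratum smoothed by *weighted* isotonic regression constrained to be
non-increasing in distance (pair counts as weights; pool-adjacent-violators
written here because the base isotonic fit takes no weights), floored at
the smallest positive stratum mean so expectations are strictly positive.

Significance per cis pair is the upper-tail Poisson probability
`P(X >= obs | mu = E(d))`, BH-corrected across all tested pairs, keeping
pairs with `p < 0.05`, `q < 0.05`, `count > 2`. A Poisson tail replaces
the binomial-plus-spline machinery of Fit-Hi-C-style callers: at bacterial
depths (counts per cell far below the total) the two are numerically
indistinguishable, and the Poisson form needs no coupling to the total
count. This is a re-implementation, not a wrapper. Significance is
computed on raw counts with the expectation from the same raw map
(normalization-free), mirroring common practice; the discrete Poisson tail
makes the caller slightly conservative at small expectations, which the
calibration benchmark (null means 20–200) quantifies.

Distance bands for significant contacts default to a single cut at 450 kb
(short- vs long-range); proportions are reported among significant pairs.

## Scalograms and ratio maps

Scalograms report, per bin, the flank half-width at which the cumulated
cis contacts within ±w first reach 15/30/45/60/75/100 % of the bin's
total within ±`max_halfwidth` (default 500 kb, clipped to half the
replicon on circular replicons). Compact chromatin reaches high fractions
at small widths. Half-widths are non-decreasing across levels by
construction.

Ratio maps report `log2((a + eps)/(b + eps))` per (bin, distance up to
`max_dist`), averaged over the upstream and downstream partner. The
pseudocount defaults to the 5th percentile of the pooled positive entries
of both maps — small enough not to flatten the informative short-range
signal, large enough to stabilise the log at sparse distal entries — and
is shared between numerator and denominator so that
`ratio_map(a, b) = -ratio_map(b, a)` holds exactly.

## 3D embedding and compactness metrics

The embedding is deliberately simple and documented as such: target
distances `d_ij = c_ij^(-1/alpha)` for positive normalized contacts
(`alpha = 1` default), missing pairs completed by shortest paths over the
contact graph, classical multidimensional scaling into three dimensions,
centred at the centroid. It is adequate for *metric-level* claims (radius
of gyration, compactness, relative distances) — the level at which the
package's structural comparisons operate — and is not a shape
reconstruction method. Models are average structures: the organism is
polyploid, and no reconstruction can distinguish intra- from inter-copy
contacts.

Compactness metrics (the formulas are this package's definitions):
`GC = mean over all pairs of Rg/d_ij` (inverse spatial distance in units
of the radius of gyration, hence invariant to uniform scaling), and
`LC(s)` the same mean restricted to pairs with genomic separation at most
*s* (shorter-arc). `LC` saturates to `GC` as *s* reaches the replicon
length. Higher values mean a more compact structure. Coincident points are
rejected by name rather than regularised.

The PPI proximity test maps each gene to its midpoint bin, drops pairs
landing in the same bin (their spatial distance is 0 by construction),
and compares PPI-pair distances against all distinct valid bin-pair
distances with a one-sided Mann–Whitney test.

## Integration analyses

* **Boundary genes**: genes overlapping a boundary interval extended by
  `flank_bins` (default 1) bins. Feature tests are one-sided Mann–Whitney:
  boundary genes *larger* for expression and length, *smaller* for G+C
  (boundaries are AT-rich).
* **Diagonal–expression correlation**: Pearson correlation between the
  per-bin length-weighted mean expression and the matrix diagonal.
* **Sliding-window DEG enrichment**: 100 kb windows advanced by 5 kb
  (circular wrap), DEG midpoints counted per window, and an empirical
  p-value per window from `n_perm` (default 999) permutations that
  reassign the DEG labels uniformly over the annotated genes. Permuting
  labels over *genes* rather than base pairs preserves gene density, the
  main spatial confound. BH is applied across windows even though windows
  overlap; this is conservative-leaning and kept for simplicity. With 999
  permutations the minimal attainable p (1e-3) is small enough to survive
  BH across the ~500 windows of a chromosome-scale replicon; fewer
  permutations can make detection impossible regardless of effect size.
* **G+C profiles**: fraction of G/C among unambiguous bases per bin;
  ambiguity codes leave the denominator. The boundary summary compares
  each boundary interval's mean G+C with the replicon-wide mean.

## The synthetic generator

Expected cis contacts are
`E[i,j] = max(d_ij,1)^(-alpha) * CID(i,j) * arm(i,j) * b_i * b_j`,
scaled so the expected total equals the sequencing depth, and sampled as
independent Poisson counts per cell (cell independence is what makes the
null p-value calibration checks exact). Defaults are the study-scale
conditions used throughout the tests: the four-replicon layout at 5 kb
bins, decay exponent `alpha = 1`, domain contrast 2 (one wall per ~330 kb,
walls at least 40 kb apart), faint secondary diagonal (strength 0.3,
Gaussian width 10 bins, reflecting inter-arm contacts about the
origin–terminus axis), lognormal bin biases (sdlog 0.3), depth 5e6 pairs,
2 % trans contacts. Condition modifiers: "uv" flattens the decay by 0.3
and deletes every second planted wall (domain fusion); "mutant" halves
contacts within 100 kb and deletes the middle third of the walls.

What the generator does **not** emulate: replication-gradient (ori-to-ter)
coverage, restriction-fragment granularity, polymer loop extrusion,
copy-number structure of the polyploid genome, and trans contacts with
distance structure. Passing benchmarks therefore demonstrate correctness
of the estimators under a clean multiplicative-bias, power-law-decay,
blocked-domain model — not robustness to every artefact of real libraries.

Benchmark problem sizes (chosen to exercise study-scale geometry while
keeping the default test run in minutes): boundary recovery on the 530-bin
chromosome at depth 5e6 over 5 seeds; significance calibration on a
46-bin circulant null (1035 pairs, means 20–200) over 100 replicates;
embeddings on 100–300-bin replicons with 10 jittered replicates per
condition; integration nulls and power at 500 genes / 500 bins over 100
seeds.

## Known limitations

* The DI threshold is a percentile, so on a map with *no* true boundaries
  the caller can still cross the threshold; the run-length requirement is
  the main guard. Callers needing strict control should pass an absolute
  `min_abs_di`.
* The expected-count model pools all cis pairs per distance; domain
  structure inflates expectations near the diagonal, making the
  significance caller conservative inside CIDs.
* Classical MDS with shortest-path completion distorts large-scale
  geometry when the contact graph is sparse; embeddings are for metric
  comparisons between conditions processed identically.
* BH across overlapping windows is not an exact FDR; an effective-number
  correction would be a drop-in replacement.
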