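# shared fixtures: small genomes and matrices built in code

small_bins <- function(n = 20, bin = 5000, circular = TRUE, name = "r") {
  bin_genome(replicon_layout(name, n * bin, circular), bin)
}

# symmetric integer power-law circulant matrix on a circular replicon
circulant_counts <- function(n, alpha = 1, scale = 1000) {
  idx <- 0:(n - 1)
  D <- outer(idx, idx, function(i, j) pmin(abs(i - j), n - abs(i - j)))
  M <- round(scale * pmax(D, 1)^(-alpha))
  (M + t(M)) / 2
}

chr1_layout <- function() replicon_layout("Chr1", 2649000, TRUE)

# standard benchmark run: simulate -> filter -> SCN -> DI -> boundaries
call_on_simulated <- function(spec, seed = spec$seed, scale_bp = 1e5) {
  sim <- simulate_map(spec, seed = seed)
  nr <- suppressWarnings(
    scn_normalize(sim$map, mask = filter_bins(sim$map), max_iter = 400))
  di <- directionality_index(nr$matrix, spec$layout$replicon_id[1],
                             scale_bp = scale_bp)
  list(sim = sim, norm = nr, di = di, calls = call_boundaries(di))
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
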