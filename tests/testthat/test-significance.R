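test_that("circular shorter-arc distance arithmetic", {
  expect_equal(circular_distance(0, 1500000, 2649000), 1149000)
  expect_equal(circular_distance(123, 123, 1000), 0)
  expect_equal(circular_distance(0, 500, 1000), 500)
  # symmetric and bounded by L/2
  set.seed(1)
  x <- runif(50, 0, 999); y <- runif(50, 0, 999)
  expect_equal(circular_distance(x, y, 1000), circular_distance(y, x, 1000))
  expect_true(all(circular_distance(x, y, 1000) <= 500))
  expect_error(circular_distance(-1, 0, 10), "\\[0, length_bp\\)")
})

test_that("P(s) is flat for translation-invariant maps and spans to L/2", {
  n <- 100
  bins <- small_bins(n)
  m <- contact_matrix(matrix(3, n, n), bins)
  ps <- ps_curve(m, "r")
  expect_true(all(abs(ps$mean_value - 3) < 1e-12))
  expect_equal(max(ps$distance_bp), (n / 2) * 5000)
  # Chr1-sized circular replicon: largest stratum at about L/2
  spec <- truth_spec(layout = chr1_layout(), depth = 1e6, seed = 5)
  ps1 <- ps_curve(simulate_map(spec)$map, "Chr1")
  expect_equal(max(ps1$distance_bp), 1325000)  # 265 bins * 5 kb
})

test_that("fitted log-log slope recovers the planted decay exponent", {
  for (a in c(0.8, 1.0, 1.5)) {
    spec <- truth_spec(layout = chr1_layout(), alpha = a, contrast = 1,
                       sec_strength = 0, bias_sdlog = 0, depth = 5e6,
                       seed = 7)
    fit <- fit_ps_slope(ps_curve(simulate_map(spec)$map, "Chr1"))
    expect_lt(abs(fit$slope - (-a)), 0.1)
  }
})

test_that("expected model is non-increasing, positive, and exact on constants", {
  n <- 40
  bins <- small_bins(n)
  m_const <- contact_matrix(matrix(5, n, n), bins)
  em <- expected_model(m_const, "r")
  expect_true(all(em$expected == 5))
  # noisy monotone decay: isotonic output non-increasing everywhere
  set.seed(9)
  spec <- truth_spec(layout = replicon_layout("Chr1", n * 5000, TRUE),
                     depth = 2e5, contrast = 1, sec_strength = 0, seed = 9)
  em2 <- expected_model(simulate_map(spec)$map, "Chr1")
  expect_true(all(diff(em2$expected) <= 1e-12))
  expect_true(all(em2$expected > 0))
  z <- contact_matrix(matrix(0, n, n), bins)
  expect_error(expected_model(z, "r"), "all-zero")
})

test_that("significant-contact caller enforces the count filter", {
  n <- 60
  bins <- small_bins(n)
  set.seed(3)
  idx <- 0:(n - 1)
  D <- outer(idx, idx, function(i, j) pmin(abs(i - j), n - abs(i - j)))
  mu <- 0.5 * pmax(D, 1)^-0.5   # low depth: many small counts
  M <- matrix(0, n, n)
  ut <- upper.tri(M)
  M[ut] <- rpois(sum(ut), mu[ut])
  M <- M + t(M)
  m <- contact_matrix(M, bins)
  sig <- call_significant(m, "r", alpha = 0.5, min_count = 2)
  if (nrow(sig)) expect_true(all(sig$observed > 2))
  # q >= p always
  expect_true(all(sig$q >= sig$p))
})

test_that("a planted 10x-expected pair is recovered with q < 0.05", {
  spec <- truth_spec(layout = chr1_layout(), contrast = 1, sec_strength = 0,
                     bias_sdlog = 0, depth = 5e6, seed = 3)
  sim <- simulate_map(spec)
  em <- expected_model(sim$map, "Chr1")
  target <- em[which.min(abs(em$expected - 5)), ]
  k <- target$distance_bp / 5000
  M <- sim$map$matrix
  i <- 10; j <- 10 + k
  M[i, j] <- M[j, i] <- round(10 * target$expected)
  m2 <- contact_matrix(M, sim$map$bins)
  sig <- call_significant(m2, "Chr1")
  hit <- sig[sig$bin_i == i - 1 & sig$bin_j == j - 1, ]
  expect_equal(nrow(hit), 1)
  expect_lt(hit$q, 0.05)
})

test_that("distance-band proportions are exhaustive and ordered as planted", {
  sig <- data.frame(bin_i = 0:3, bin_j = 1:4, observed = 5, expected = 1,
                    p = 0.01, q = 0.02,
                    distance_bp = c(10000, 10000, 10000, 500000))
  class(sig) <- c("sig_interactions", "data.frame")
  bands <- classify_distances(sig)
  expect_equal(sum(bands$proportion), 1)
  expect_equal(bands$proportion, c(0.75, 0.25))
  sig_short <- sig[1:3, ]
  class(sig_short) <- class(sig)
  expect_equal(classify_distances(sig_short)$proportion, c(1, 0))
  expect_error(classify_distances(sig[0, ]), "no significant")
  # flattened decay shifts significant contacts into the long band
  ctrl <- truth_spec(layout = chr1_layout(), depth = 5e6, seed = 5)
  uv <- truth_spec(layout = chr1_layout(), depth = 5e6, seed = 5,
                   condition = "uv")
  b_ctrl <- classify_distances(call_significant(simulate_map(ctrl)$map, "Chr1"))
  b_uv <- classify_distances(call_significant(simulate_map(uv, seed = 6)$map,
                                              "Chr1"))
  expect_gt(b_uv$proportion[2], b_ctrl$proportion[2])
})

test_that("expression classes split at the 10% quantiles and label bins", {
  lay <- replicon_layout("Chr1", 100 * 5000, TRUE)
  genes <- gene_table(sprintf("g%03d", 1:100), "Chr1",
                      seq(0, 99) * 5000 + 100, seq(0, 99) * 5000 + 1100,
                      expression_value = 1:100)
  cls <- bact3c:::expression_class(genes, 0.10)
  expect_equal(sum(cls == "high"), 10)
  expect_equal(sum(cls == "low"), 10)
  # equal expression: everything moderate, a single curve results
  genes_eq <- genes
  genes_eq$expression_value <- rep(2, 100)
  m <- contact_matrix(circulant_counts(100), bin_genome(lay, 5000))
  curves <- suppressWarnings(stratified_ps(m, genes_eq, "Chr1"))
  expect_equal(names(curves), "moderate")
})

test_that("extra short-range mass at high-expression bins shows in stratified P(s)", {
  n <- 120
  lay <- replicon_layout("Chr1", n * 5000, TRUE)
  bins <- bin_genome(lay, 5000)
  idx <- 0:(n - 1)
  D <- outer(idx, idx, function(i, j) pmin(abs(i - j), n - abs(i - j)))
  k_mod <- pmax(D, 1)^-1
  k_high <- pmax(D, 1)^-1.6
  k_high <- k_high * sum(k_mod) / sum(k_high)  # equal total mass
  high_bins <- 1:12
  w <- rep(1, n); w[high_bins] <- 0  # 0 marks the steep kernel
  E <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    E[i, j] <- sqrt((if (w[i]) k_mod[i, j] else k_high[i, j]) *
                    (if (w[j]) k_mod[i, j] else k_high[i, j]))
  set.seed(4)
  M <- matrix(0, n, n); ut <- upper.tri(M)
  M[ut] <- rpois(sum(ut), 2000 * E[ut])
  M <- M + t(M)
  m <- contact_matrix(M, bins)
  genes <- gene_table(sprintf("g%03d", 1:n), "Chr1", idx * 5000 + 100,
                      idx * 5000 + 1100,
                      expression_value = ifelse(idx %in% (high_bins - 1),
                                                1000, 10 + idx))
  curves <- stratified_ps(m, genes, "Chr1")
  expect_gt(curves$high$mean_value[1], curves$moderate$mean_value[1])
  far <- which.max(curves$high$distance_bp)
  expect_lt(curves$high$mean_value[far], curves$moderate$mean_value[far])
})
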