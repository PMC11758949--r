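test_that("map simulation is deterministic and depth-calibrated", {
  lay <- replicon_layout("Chr1", 150 * 5000, TRUE)
  spec <- truth_spec(layout = lay, depth = 1e6, seed = 12)
  a <- simulate_map(spec)
  b <- simulate_map(spec)
  expect_identical(a$map$matrix, b$map$matrix)
  # realised total within 4 sd of the expected depth
  tot <- sum(a$map$matrix[upper.tri(a$map$matrix, diag = TRUE)])
  expect_lt(abs(tot - 1e6), 4 * sqrt(1e6))
  # doubling depth doubles the total within Poisson error
  spec2 <- truth_spec(layout = lay, depth = 2e6, seed = 12)
  tot2 <- sum(simulate_map(spec2)$map$matrix[upper.tri(a$map$matrix,
                                                       diag = TRUE)])
  expect_lt(abs(tot2 - 2e6), 4 * sqrt(2e6))
})

test_that("raw coverage tracks the planted bias vector", {
  lay <- replicon_layout("Chr1", 300 * 5000, TRUE)
  spec <- truth_spec(layout = lay, depth = 5e6, bias_sdlog = 0.4, seed = 19)
  sim <- simulate_map(spec)
  expect_gte(cor(rowSums(sim$map$matrix), sim$bias), 0.9)
})

test_that("a contrast-1 unbiased map carries no directional signal", {
  lay <- replicon_layout("Chr1", 150 * 5000, TRUE)
  spec <- truth_spec(layout = lay, contrast = 1, bias_sdlog = 0,
                     sec_strength = 0, depth = 5e6, seed = 14)
  di_null <- directionality_index(simulate_map(spec)$map, "Chr1", 1e5)
  spec_cid <- truth_spec(layout = lay, contrast = 2, bias_sdlog = 0,
                         sec_strength = 0, depth = 5e6, seed = 14)
  di_cid <- directionality_index(simulate_map(spec_cid)$map, "Chr1", 1e5)
  # null DI magnitudes sit far below the planted-boundary peaks
  expect_lt(max(abs(di_null$di)), max(abs(di_cid$di)) / 5)
})

test_that("planted boundary walls shape the CID block structure", {
  walls <- c(20L, 60L)
  cid <- bact3c:::cid_of_bins(walls, 100)
  expect_equal(length(unique(cid)), 2)
  expect_true(all(cid[21:60] == cid[21]))
  # wrap: bins before the first wall join the last segment
  expect_equal(cid[1], cid[100])
  expect_false(cid[1] == cid[30])
})

test_that("simulated shapes have the advertised geometry", {
  s <- simulate_structure("circle", 50)
  nn <- sqrt(rowSums((s$coords - s$coords[c(2:50, 1), ])^2))
  expect_lt(diff(range(nn)), 1e-9)   # equal nearest-neighbour spacing
  expect_error(simulate_structure("circle", 5), ">= 10")
  s_rw <- simulate_structure("random_walk", 40, seed = 3)
  s_rw2 <- simulate_structure("random_walk", 40, seed = 3)
  expect_identical(s_rw$coords, s_rw2$coords)
})

test_that("a steeper planted exponent steepens the fitted P(s) slope", {
  slopes <- vapply(c(0.8, 1.0, 1.5), function(a) {
    s <- simulate_structure("circle", 200)
    m <- structure_to_contacts(s, alpha = a, depth = 2e6, seed = 5)
    fit_ps_slope(ps_curve(m, "circle"), min_bp = 2 * 5000,
                 max_bp = 50 * 5000)$slope
  }, 0)
  expect_true(all(diff(slopes) < 0))
})

test_that("expression/DEG generator honours multipliers and windows", {
  lay <- replicon_layout("Chr1", 500 * 5000, TRUE)
  spec <- truth_spec(layout = lay, n_genes = 400, n_deg = 80,
                     boundary_expr_mult = 3, boundary_len_mult = 2,
                     deg_windows = list(c(1e6, 1.2e6)), deg_weight = 50,
                     seed = 27)
  gd <- simulate_expression_degs(spec)
  bg <- attr(gd$genes, "boundary_gene")
  expect_gt(sum(bg), 0)
  lens <- gd$genes$end_bp - gd$genes$start_bp
  expect_gt(median(lens[bg]), median(lens[!bg]))
  expect_gt(median(gd$genes$expression_value[bg]),
            median(gd$genes$expression_value[!bg]))
  # DEGs pile into the designated window
  deg_mid <- (gd$genes$start_bp + gd$genes$end_bp)[match(gd$degs$gene_id,
                                                         gd$genes$gene_id)] / 2
  frac_in <- mean(deg_mid >= 1e6 & deg_mid < 1.2e6)
  expect_gt(frac_in, 0.3)  # window covers 4% of the genome
  expect_error(simulate_expression_degs(
    truth_spec(layout = lay, n_genes = 10, n_deg = 11)), "more DEGs")
})

test_that("PPI sampling is deterministic and respects the distance bias", {
  s <- simulate_structure("random_walk", 100, seed = 2)
  p1 <- simulate_ppi(s, 50, beta = 5, seed = 7)
  p2 <- simulate_ppi(s, 50, beta = 5, seed = 7)
  expect_identical(p1, p2)
  D <- as.matrix(dist(s$coords))
  d_biased <- D[cbind(p1$bin_i + 1, p1$bin_j + 1)]
  p0 <- simulate_ppi(s, 50, beta = 0, seed = 7)
  d_unif <- D[cbind(p0$bin_i + 1, p0$bin_j + 1)]
  expect_lt(median(d_biased), median(d_unif))
  expect_error(simulate_ppi(s, 1e6, beta = 0), "exceeds")
})

test_that("truth specs validate their parameters", {
  expect_error(truth_spec(contrast = 0.5), "contrast")
  expect_error(truth_spec(depth = 0), "depth")
  expect_error(truth_spec(trans_frac = 1), "trans_frac")
})
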