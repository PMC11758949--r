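test_that("DI evaluates the stated chi-square-style formula", {
  # construct a 3-bin-window case with known A and B for the centre bin
  n <- 20
  bins <- small_bins(n, circular = FALSE)
  M <- matrix(0, n, n)
  # bin 10 (1-based 11): 10 upstream contacts at offset -1, 20 downstream at +1
  M[11, 10] <- M[10, 11] <- 10
  M[11, 12] <- M[12, 11] <- 20
  m <- contact_matrix(M, bins)
  di <- directionality_index(m, "r", scale_bp = 5000)
  expect_equal(di$A[11], 10)
  expect_equal(di$B[11], 20)
  expect_equal(di$E[11], 15)
  expect_equal(di$di[11], 25 / 15 + 25 / 15)  # +3.33...
  # A = B gives DI exactly 0; A + B = 0 gives 0 too
  expect_equal(di$di[1], 0)
})

test_that("translation-invariant circulant maps have identically zero DI", {
  n <- 80
  bins <- small_bins(n)
  m <- contact_matrix(circulant_counts(n), bins)
  di <- directionality_index(m, "r", scale_bp = 10 * 5000)
  expect_true(all(abs(di$di) < 1e-9))
})

test_that("reversing the genome negates and reverses the DI track", {
  lay <- replicon_layout("Chr1", 120 * 5000, TRUE)
  spec <- truth_spec(layout = lay, depth = 1e6, seed = 13)
  m <- simulate_map(spec)$map
  di <- directionality_index(m, "Chr1", 1e5)
  rev_idx <- rev(seq_len(nrow(m$matrix)))
  m_rev <- contact_matrix(m$matrix[rev_idx, rev_idx], m$bins,
                          mask = m$mask[rev_idx])
  di_rev <- directionality_index(m_rev, "Chr1", 1e5)
  expect_equal(di_rev$di, -rev(di$di), tolerance = 1e-9)
})

test_that("DI rejects scales beyond half a circular replicon", {
  bins <- small_bins(30)
  m <- contact_matrix(circulant_counts(30), bins)
  expect_error(directionality_index(m, "r", 16 * 5000), "half")
  expect_error(directionality_index(m, "r", 7500), "multiple")
})

test_that("boundary calling places a wall at the sign transition", {
  # hand-built DI profile on a linear replicon: (-,-,-,+,+,+)
  n <- 6
  di <- data.frame(bin = 0:5, A = 0, B = 0, E = 1,
                   di = c(-5, -5, -5, 5, 5, 5))
  attr(di, "scale_bp") <- 5000; attr(di, "replicon") <- "r"
  attr(di, "circular") <- FALSE; attr(di, "n_bins") <- n
  attr(di, "bin_size_bp") <- 5000; attr(di, "mask") <- rep(TRUE, n)
  class(di) <- c("di_profile", "data.frame")
  bs <- call_boundaries(di, min_run_bins = 3, min_abs_di = 1)
  expect_equal(nrow(bs$boundaries), 1)
  expect_true(bs$boundaries$midpoint_bin %in% 2:3)
  # linear: boundaries + 1 CIDs
  expect_equal(nrow(bs$cids), 2)
  # one intervening near-zero bin is tolerated
  di$di <- c(-5, -5, -5, 0, 5, 5)
  di2 <- di; di2$di <- c(-5, -5, -5, 0, 5, 5)
  attr(di2, "n_bins") <- n
  bs2 <- call_boundaries(di2, min_run_bins = 2, min_abs_di = 1)
  expect_equal(nrow(bs2$boundaries), 1)
})

test_that("all-positive DI on a circular replicon yields one replicon-wide CID", {
  n <- 12
  di <- data.frame(bin = 0:(n - 1), A = 0, B = 0, E = 1, di = rep(4, n))
  attr(di, "scale_bp") <- 5000; attr(di, "replicon") <- "r"
  attr(di, "circular") <- TRUE; attr(di, "n_bins") <- n
  attr(di, "bin_size_bp") <- 5000; attr(di, "mask") <- rep(TRUE, n)
  class(di) <- c("di_profile", "data.frame")
  bs <- call_boundaries(di, min_run_bins = 3, min_abs_di = 1)
  expect_equal(nrow(bs$boundaries), 0)
  expect_equal(nrow(bs$cids), 1)
  expect_equal(bs$cids$size_bp, n * 5000)
})

test_that("boundary comparison matches greedily within tolerance", {
  a <- c(10L, 50L, 90L)
  same <- compare_boundaries(a, a, tol_bins = 2, n_bins = 120)
  expect_equal(same$n_conserved, 3)
  expect_equal(same$n_lost + same$n_gained, 0)
  far <- compare_boundaries(a, c(30L, 70L), tol_bins = 2, n_bins = 120)
  expect_equal(far$n_conserved, 0)
  # shift by exactly tol matches; tol+1 does not
  sh <- compare_boundaries(a, a + 2L, tol_bins = 2, n_bins = 120)
  expect_equal(sh$n_conserved, 3)
  sh3 <- compare_boundaries(a, a + 3L, tol_bins = 2, n_bins = 120)
  expect_equal(sh3$n_conserved, 0)
  # circular wrap: 119 matches 1 at tol 2
  wrap <- compare_boundaries(c(119L), c(1L), tol_bins = 2, n_bins = 120)
  expect_equal(wrap$n_conserved, 1)
})

test_that("boundary recovery scores identity and empty calls correctly", {
  truth <- c(5L, 40L, 80L)
  perfect <- boundary_recovery(truth, truth, n_bins = 100)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  none <- boundary_recovery(integer(), truth, n_bins = 100)
  expect_equal(none$recall, 0)
  # truth without boundaries: recall not applicable
  na_rec <- boundary_recovery(truth, integer(), n_bins = 100)
  expect_true(is.na(na_rec$recall))
})

test_that("planted boundaries are recovered through the normalize-DI route", {
  spec <- truth_spec(layout = chr1_layout(), depth = 5e6, seed = 1)
  run <- call_on_simulated(spec)
  rec <- boundary_recovery(run$calls, spec, tol_bins = 2)
  expect_equal(rec$n_truth, 8)
  expect_gte(rec$recall, 7 / 8)
  expect_gte(rec$f1, 0.8)
  # number of CIDs equals number of boundaries on a circular replicon
  expect_equal(nrow(run$calls$cids), nrow(run$calls$boundaries))
  # CID sizes cover the replicon exactly
  expect_equal(sum(run$calls$cids$size_bp), 530 * 5000)
})

test_that("boundary calls are invariant to global matrix scaling", {
  lay <- replicon_layout("Chr1", 200 * 5000, TRUE)
  spec <- truth_spec(layout = lay, depth = 2e6, bias_sdlog = 0, seed = 6)
  m <- simulate_map(spec)$map
  di1 <- directionality_index(m, "Chr1", 1e5)
  m9 <- contact_matrix(9 * m$matrix, m$bins)
  di9 <- directionality_index(m9, "Chr1", 1e5)
  b1 <- call_boundaries(di1)
  b9 <- call_boundaries(di9)
  expect_equal(b1$boundaries$midpoint_bin, b9$boundaries$midpoint_bin)
  expect_equal(di9$di, 9 * di1$di, tolerance = 1e-9)
})
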