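make_boundary_set <- function(mids, n = 100, s = 5000, circular = TRUE,
                              replicon = "Chr1") {
  di <- data.frame(bin = 0:(n - 1), A = 0, B = 0, E = 1, di = 0)
  boundaries <- data.frame(replicon = replicon, start_bin = mids,
                           end_bin = mids, midpoint_bin = mids,
                           stringsAsFactors = FALSE)
  structure(list(boundaries = boundaries,
                 cids = bact3c:::cids_from_boundaries(mids, n, circular, s,
                                                      replicon),
                 replicon = replicon, n_bins = n, circular = circular,
                 bin_size_bp = s, min_run_bins = 3, min_abs_di = 1),
            class = "boundary_set")
}

test_that("gene labelling respects half-open extended boundary intervals", {
  bs <- make_boundary_set(c(10L))
  # boundary interval bins 10, flank 1 -> bp [45000, 60000)
  genes <- gene_table(c("inside", "abutting", "far"), "Chr1",
                      c(50100, 60000, 300000), c(50900, 61000, 301000))
  labels <- classify_genes_by_boundary(genes, bs, flank_bins = 1)
  expect_equal(labels, c("boundary", "interior", "interior"))
  # genes placed on planted walls are labelled boundary at flank 1
  lay <- replicon_layout("Chr1", 500 * 5000, TRUE)
  spec <- truth_spec(layout = lay, n_genes = 400, seed = 31)
  gd <- simulate_expression_degs(spec)
  bs_truth <- make_boundary_set(spec$boundaries$Chr1, n = 500)
  lab <- classify_genes_by_boundary(gd$genes, bs_truth, flank_bins = 1)
  planted <- attr(gd$genes, "boundary_gene")
  expect_true(all(lab[planted] == "boundary"))
})

test_that("boundary feature test needs variation and adequate groups", {
  genes <- gene_table(sprintf("g%02d", 1:20), "Chr1", (0:19) * 1000,
                      (0:19) * 1000 + 500, expression_value = rep(3, 20))
  labels <- rep(c("boundary", "interior"), each = 10)
  expect_error(boundary_feature_test(labels, genes, "expression"),
               "no variation")
  labels2 <- c(rep("boundary", 2), rep("interior", 18))
  genes$expression_value <- 1:20
  expect_error(boundary_feature_test(labels2, genes, "expression"),
               "at least 5")
})

test_that("a planted expression shift at boundary genes is detected", {
  set.seed(17)
  n <- 500; nb <- 50
  labels <- c(rep("boundary", nb), rep("interior", n - nb))
  expr <- rlnorm(n, meanlog = 3, sdlog = 1)
  expr[1:nb] <- expr[1:nb] * 2
  genes <- gene_table(sprintf("g%03d", 1:n), "Chr1", (0:(n - 1)) * 1000,
                      (0:(n - 1)) * 1000 + 500, expression_value = expr)
  res <- boundary_feature_test(labels, genes, "expression")
  expect_lt(res$p, 0.01)
  expect_gt(res$median_boundary, res$median_interior)
  # gc alternative is one-sided "less"
  gc_vals <- runif(n, 0.6, 0.7); gc_vals[1:nb] <- gc_vals[1:nb] - 0.1
  res_gc <- boundary_feature_test(labels, genes, "gc", values = gc_vals)
  expect_lt(res_gc$p, 0.01)
  expect_equal(res_gc$alternative, "less")
})

test_that("diagonal-expression correlation recovers exact proportionality", {
  n <- 100
  lay <- replicon_layout("Chr1", n * 5000, TRUE)
  bins <- bin_genome(lay, 5000)
  set.seed(23)
  diag_vals <- runif(n, 0.5, 2)
  M <- diag(diag_vals)
  m <- contact_matrix(M, bins, state = "normalized", tol = 1e-6)
  genes <- gene_table(sprintf("g%03d", 1:n), "Chr1", (0:(n - 1)) * 5000,
                      (0:(n - 1)) * 5000 + 5000,
                      expression_value = 10 * diag_vals)
  res <- diagonal_expression_correlation(m, genes, "Chr1")
  expect_equal(res$r, 1, tolerance = 1e-9)
  # permuted expression decorrelates
  genes2 <- genes
  genes2$expression_value <- sample(genes$expression_value)
  res2 <- diagonal_expression_correlation(m, genes2, "Chr1")
  expect_lt(abs(res2$r), 0.3)
  genes3 <- genes
  genes3$expression_value <- rep(4, n)
  expect_error(diagonal_expression_correlation(m, genes3, "Chr1"),
               "undefined correlation")
})

test_that("window enrichment counts, geometry and extreme concentration", {
  lay <- replicon_layout("Chr1", 500 * 5000, TRUE)
  spec <- truth_spec(layout = lay, n_genes = 300, n_deg = 60,
                     deg_windows = list(c(1e6, 1.1e6)), deg_weight = 1000,
                     seed = 41)
  gd <- simulate_expression_degs(spec)
  we <- sliding_window_enrichment(gd$degs, gd$genes, "Chr1", lay,
                                  n_perm = 199, seed = 41)
  # circular replicon: length/step windows
  expect_equal(nrow(we), 500)
  # the top-count window sits in the loaded region at the minimal attainable p
  hotzone <- we$window_start >= 0.9e6 & we$window_start <= 1.1e6
  expect_true(hotzone[which.max(we$count)])
  expect_equal(min(we$p), 1 / 200)
  expect_equal(min(we$p[hotzone]), 1 / 200)
  # total midpoint mass over one non-overlapping phase equals the DEG count
  phase <- we[seq(1, 500, by = 20), ]
  expect_equal(sum(phase$count), attr(we, "n_deg"))
  expect_error(sliding_window_enrichment(gd$degs[0, ], gd$genes, "Chr1", lay),
               "no DEGs")
})

test_that("window counts are invariant to gene ordering", {
  lay <- replicon_layout("Chr1", 200 * 5000, TRUE)
  spec <- truth_spec(layout = lay, n_genes = 150, n_deg = 40, seed = 8)
  gd <- simulate_expression_degs(spec)
  we1 <- sliding_window_enrichment(gd$degs, gd$genes, "Chr1", lay,
                                   n_perm = 49, seed = 9)
  shuf <- gd$genes[sample(nrow(gd$genes)), ]
  class(shuf) <- class(gd$genes)
  we2 <- sliding_window_enrichment(gd$degs, shuf, "Chr1", lay,
                                   n_perm = 49, seed = 9)
  expect_equal(we1$count, we2$count)
})

test_that("gc profile computes per-bin fractions and matches genome mean", {
  lay <- replicon_layout("c", 20000, TRUE)
  bins <- bin_genome(lay, 5000)
  gp <- gc_profile(strrep("ATGC", 5000), bins, "c")
  expect_equal(gp, rep(0.5, 4))
  lay2 <- replicon_layout("c", 10000, TRUE)
  bins2 <- bin_genome(lay2, 5000)
  gp2 <- gc_profile(paste0(strrep("AT", 2500), strrep("GC", 2500)), bins2, "c")
  expect_equal(gp2, c(0, 1))
  expect_error(gc_profile("ATGC", bins2, "c"), "does not match")
  # ambiguity codes drop out of the denominator
  gp3 <- gc_profile(paste0(strrep("ATGN", 1250), strrep("GCNN", 1250)),
                    bins2, "c")
  expect_equal(gp3, c(1 / 3, 1))
  # weighted mean over bins equals the whole-replicon GC
  set.seed(2)
  seqc <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                collapse = "")
  gp4 <- gc_profile(seqc, bins, "c")
  whole <- sum(strsplit(seqc, "")[[1]] %in% c("G", "C")) / 20000
  expect_equal(mean(gp4), whole, tolerance = 1e-12)
})

test_that("planted low-GC boundaries are summarised below the genome mean", {
  set.seed(3)
  n <- 100
  gc_track <- runif(n, 0.62, 0.68)
  walls <- c(10L, 40L, 70L)
  gc_track[walls + 1] <- gc_track[walls + 1] - 0.1
  bs <- make_boundary_set(walls, n = n)
  gsum <- boundary_gc_summary(gc_track, bs)
  expect_equal(gsum$fraction_below, 1)
  expect_true(all(gsum$boundary_gc < gsum$genome_gc))
})

test_that("DEG direction percentages follow the table", {
  d <- deg_table(sprintf("g%d", 1:10), c(rep(2, 7), rep(-2, 3)),
                 rep(0.01, 10))
  counts <- deg_direction_counts(d)
  expect_equal(counts$n, c(7, 3))
  expect_equal(counts$percent, c(70, 30))
  expect_error(deg_table("g1", 2, 1.5), "\\[0,1\\]")
})
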