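#' Specification of a synthetic contact-map truth
#'
#' Bundles every parameter of the synthetic generator together with the
#' planted ground truth, so recovery tests can score calls against what was
#' actually simulated. The generative model for the expected cis contact
#' between bins `i`, `j` of a replicon is
#' `E[i,j] = max(d_ij, 1)^(-alpha) * CIDblock(i,j) * arm(i,j) * b_i * b_j`,
#' where `d_ij` is the (circular) bin distance, `CIDblock` multiplies
#' same-domain pairs by `contrast`, `arm` adds a faint secondary
#' (inter-arm) diagonal, and `b` is a lognormal per-bin bias vector.
#' Expectations are scaled to the sequencing `depth` and counts drawn
#' independently as Poisson per cell.
#'
#' Condition modifiers: `"uv"` flattens the decay by `uv_delta` (depleting
#' short-range relative to long-range contacts) and deletes the boundaries
#' listed in `lost_boundaries`, merging the flanking domains; `"mutant"`
#' multiplies contacts closer than `mutant_short_range_bp` by
#' `mutant_short_factor` and likewise deletes its lost boundaries.
#'
#' @param layout a [replicon_layout()]; defaults to [dr_genome_layout()].
#' @param bin_size_bp bin width (default 5000).
#' @param alpha distance-decay exponent (default 1).
#' @param boundaries named list (per replicon) of planted boundary bins
#'   (local 0-based domain walls); default plants roughly one boundary per
#'   330 kb with at least 40 kb between walls.
#' @param contrast within-CID contact multiplier (>= 1, default 2).
#' @param sec_strength,sec_width_bins strength and Gaussian width of the
#'   secondary (inter-arm) diagonal (defaults 0.3 and 10 bins).
#' @param bias_sdlog sdlog of the lognormal bin bias (default 0.3).
#' @param zero_bias_bins global 1-based bin rows whose bias is forced to 0
#'   (dead bins).
#' @param depth expected total pair count (default 5e6).
#' @param trans_frac fraction of the expected depth in trans contacts
#'   (default 0.02).
#' @param condition `"wt"`, `"uv"` or `"mutant"`.
#' @param uv_delta decay flattening under `"uv"` (default 0.3).
#' @param mutant_short_factor,mutant_short_range_bp short-range depletion
#'   under `"mutant"` (defaults 0.5 within 100 kb).
#' @param lost_boundaries named list (per replicon) of indices into
#'   `boundaries` deleted under a non-wt condition; default drops every
#'   second boundary for `"uv"` and the middle third for `"mutant"`.
#' @param n_genes,n_deg gene/DEG counts for [simulate_expression_degs()].
#' @param boundary_expr_mult,boundary_len_mult expression/length multipliers
#'   for boundary-adjacent genes (1 = null).
#' @param deg_windows list of `c(start, end)` bp windows (first replicon)
#'   with elevated DEG placement; `deg_weight` the relative weight inside.
#' @param seed RNG seed; all generators are deterministic given it.
#' @return A `truth_spec` object.
#' @export
truth_spec <- function(layout = dr_genome_layout(), bin_size_bp = 5000,
                       alpha = 1, boundaries = NULL, contrast = 2,
                       sec_strength = 0.3, sec_width_bins = 10,
                       bias_sdlog = 0.3, zero_bias_bins = integer(0),
                       depth = 5e6, trans_frac = 0.02,
                       condition = c("wt", "uv", "mutant"), uv_delta = 0.3,
                       mutant_short_factor = 0.5,
                       mutant_short_range_bp = 1e5, lost_boundaries = NULL,
                       n_genes = 500, n_deg = 100, boundary_expr_mult = 1,
                       boundary_len_mult = 1, deg_windows = NULL,
                       deg_weight = 1, seed = 1) {
  condition <- match.arg(condition)
  if (contrast < 1) stop("contrast must be >= 1")
  if (depth < 1) stop("depth must be >= 1")
  if (trans_frac < 0 || trans_frac >= 1) stop("trans_frac must be in [0,1)")
  bins <- bin_genome(layout, bin_size_bp)
  if (is.null(boundaries)) {
    boundaries <- list()
    set.seed(seed)
    for (r in layout$replicon_id) {
      n <- length(replicon_rows(bins, r))
      nb <- floor(n / 66)
      boundaries[[r]] <- if (nb >= 2)
        place_boundaries(n, nb, min_gap = 8) else integer(0)
    }
  }
  if (is.null(lost_boundaries) && condition != "wt") {
    lost_boundaries <- lapply(boundaries, function(b) {
      if (length(b) < 2) return(integer(0))
      if (condition == "uv") seq(2, length(b), by = 2)
      else {
        third <- floor(length(b) / 3)
        seq(third + 1, min(length(b), 2 * third + 1))
      }
    })
  }
  structure(list(layout = layout, bins = bins, bin_size_bp = bin_size_bp,
                 alpha = alpha, boundaries = boundaries, contrast = contrast,
                 sec_strength = sec_strength, sec_width_bins = sec_width_bins,
                 bias_sdlog = bias_sdlog, zero_bias_bins = zero_bias_bins,
                 depth = depth, trans_frac = trans_frac,
                 condition = condition, uv_delta = uv_delta,
                 mutant_short_factor = mutant_short_factor,
                 mutant_short_range_bp = mutant_short_range_bp,
                 lost_boundaries = lost_boundaries, n_genes = n_genes,
                 n_deg = n_deg, boundary_expr_mult = boundary_expr_mult,
                 boundary_len_mult = boundary_len_mult,
                 deg_windows = deg_windows, deg_weight = deg_weight,
                 seed = seed),
            class = "truth_spec")
}

# place nb boundary walls on a circular n-bin replicon, min_gap bins apart
place_boundaries <- function(n, nb, min_gap = 8) {
  repeat {
    b <- sort(sample.int(n, nb) - 1L)
    gaps <- diff(c(b, b[1] + n))
    if (all(gaps >= min_gap)) return(b)
  }
}

#' @export
print.truth_spec <- function(x, ...) {
  nb <- sum(lengths(x$boundaries))
  cat(sprintf(
    "truth_spec [%s]: %d replicons, bin %g bp, alpha %g, contrast %gx, %d planted boundaries, depth %.3g, seed %d\n",
    x$condition, nrow(x$layout), x$bin_size_bp, x$alpha, x$contrast, nb,
    x$depth, x$seed))
  invisible(x)
}

# boundaries active under the spec's condition (after deletions)
active_boundaries <- function(spec) {
  b <- spec$boundaries
  if (spec$condition == "wt" || is.null(spec$lost_boundaries)) return(b)
  for (r in names(b)) {
    lost <- spec$lost_boundaries[[r]]
    if (length(lost)) b[[r]] <- b[[r]][-lost]
  }
  b
}

# CID id per bin given wall positions (0-based) on an n-bin circle
cid_of_bins <- function(walls, n) {
  if (!length(walls)) return(rep(1L, n))
  walls <- sort(walls)
  id <- findInterval(0:(n - 1), walls)  # 0 before first wall
  id[id == 0L] <- length(walls)         # wrap: join last segment
  id
}

# expected cis matrix for one replicon (before bias and depth scaling)
expected_cis <- function(spec, replicon) {
  n <- length(replicon_rows(spec$bins, replicon))
  circular <- spec$layout$circular[match(replicon, spec$layout$replicon_id)]
  idx <- 0:(n - 1)
  D <- outer(idx, idx, function(i, j) circ_bin_dist(i, j, n, circular))
  alpha_eff <- spec$alpha - if (spec$condition == "uv") spec$uv_delta else 0
  # exact power law in bin distance; the diagonal shares the d = 1 level
  E <- pmax(D, 1)^(-alpha_eff)
  if (spec$condition == "mutant") {
    short <- D * spec$bin_size_bp < spec$mutant_short_range_bp & D > 0
    E[short] <- E[short] * spec$mutant_short_factor
  }
  walls <- active_boundaries(spec)[[replicon]]
  if (length(walls)) {
    cid <- cid_of_bins(walls, n)
    same <- outer(cid, cid, "==")
    E[same] <- E[same] * spec$contrast
  }
  if (spec$sec_strength > 0 && circular) {
    # reflection partner of bin i about the origin-terminus axis is (n - i)
    msum <- outer(idx, idx, function(i, j) {
      v <- (i + j) %% n
      pmin(v, n - v)
    })
    E <- E * (1 + spec$sec_strength * exp(-(msum / spec$sec_width_bins)^2))
  }
  E
}

#' Simulate a raw contact map with planted structure
#'
#' Draws a full-genome raw count matrix from the generative model described
#' in [truth_spec()]. Deterministic given the seed.
#'
#' @param spec a [truth_spec()].
#' @param seed RNG seed (defaults to the spec's).
#' @return list with `map` (raw [contact_matrix()]), `bias` (planted bin
#'   bias vector), and `spec` (the truth echo).
#' @export
simulate_map <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "truth_spec"))
  set.seed(seed)
  bins <- spec$bins
  n_tot <- nrow(bins)
  bias <- stats::rlnorm(n_tot, meanlog = 0, sdlog = spec$bias_sdlog)
  if (length(spec$zero_bias_bins)) bias[spec$zero_bias_bins] <- 0
  E <- matrix(0, n_tot, n_tot)
  for (r in spec$layout$replicon_id) {
    rows <- replicon_rows(bins, r)
    E[rows, rows] <- expected_cis(spec, r)
  }
  cis_total <- sum(E)
  if (spec$trans_frac > 0 && nrow(spec$layout) > 1) {
    is_trans <- outer(bins$replicon_id, bins$replicon_id, "!=")
    trans_level <- spec$trans_frac / (1 - spec$trans_frac) * cis_total /
      sum(is_trans)
    E[is_trans] <- trans_level
  }
  E <- E * outer(bias, bias)
  ut <- upper.tri(E, diag = TRUE)
  E[ut] <- E[ut] * spec$depth / sum(E[ut])
  counts <- matrix(0, n_tot, n_tot)
  counts[ut] <- stats::rpois(sum(ut), E[ut])
  counts <- counts + t(counts) - diag(diag(counts))
  map <- contact_matrix(counts, bins, state = "raw_counts",
                        mask = bias > 0,
                        note = sprintf("simulated (%s, seed %d)",
                                       spec$condition, seed))
  list(map = map, bias = bias, spec = spec)
}

#' Simulate a parametric 3D structure
#'
#' Shapes: `"circle"` (uniformly spaced ring, unit bond length), `"boat"` (a
#' flattened ring with bent arms running side by side, the shape the large
#' chromosome adopts) and `"random_walk"`. Coordinates are centred.
#'
#' @param shape `"circle"`, `"boat"` or `"random_walk"`.
#' @param n_bins number of bins (>= 10).
#' @param seed RNG seed (used by `"random_walk"`).
#' @param bin_size_bp genomic width per bin (default 5000).
#' @return A [structure_model()] with provenance `"simulated"`.
#' @export
simulate_structure <- function(shape = c("circle", "boat", "random_walk"),
                               n_bins, seed = 1, bin_size_bp = 5000) {
  shape <- match.arg(shape)
  if (n_bins < 10) stop("n_bins must be >= 10")
  n <- as.integer(n_bins)
  t <- 2 * pi * (seq_len(n) - 1) / n
  scale <- n / (2 * pi)
  coords <- switch(shape,
    circle = cbind(scale * cos(t), scale * sin(t), 0),
    boat = cbind(scale * cos(t), 0.35 * scale * sin(t),
                 0.15 * scale * sin(2 * t)),
    random_walk = {
      set.seed(seed)
      apply(matrix(stats::rnorm(3 * n), n, 3), 2, cumsum)
    })
  coords <- sweep(coords, 2, colMeans(coords))
  structure_model(coords, replicon = shape, bin = seq_len(n) - 1L,
                  pos_bp = (seq_len(n) - 0.5) * bin_size_bp,
                  length_bp = n * bin_size_bp,
                  circular = shape != "random_walk",
                  provenance = "simulated", model_id = shape)
}

#' Contact map implied by a 3D structure
#'
#' Expected contacts proportional to `d_ij^(-alpha)`, scaled to `depth` and
#' Poisson-sampled. The inverse operation of [embed_structure()]; the pair
#' is used for round-trip benchmarks.
#'
#' @param s a [structure_model()].
#' @param alpha distance-to-contact exponent (default 1).
#' @param depth expected total pair count.
#' @param seed RNG seed; `NULL` returns noiseless expectations (state
#'   `"normalized"`).
#' @return A [contact_matrix()] on a single-replicon bin table.
#' @export
structure_to_contacts <- function(s, alpha = 1, depth = 1e6, seed = 1) {
  stopifnot(inherits(s, "structure_model"))
  n <- nrow(s$coords)
  D <- as.matrix(stats::dist(s$coords))
  C <- matrix(0, n, n)
  off <- D > 0
  C[off] <- D[off]^(-alpha)
  lay <- replicon_layout(s$replicon, s$length_bp, s$circular)
  bins <- bin_genome(lay, s$length_bp / n)
  if (is.null(seed)) {
    C <- C / sum(C[upper.tri(C)])
    return(contact_matrix(C, bins, state = "normalized",
                          note = "noiseless structure contacts"))
  }
  ut <- upper.tri(C)
  C[ut] <- C[ut] * depth / sum(C[ut])
  set.seed(seed)
  counts <- matrix(0, n, n)
  counts[ut] <- stats::rpois(sum(ut), C[ut])
  counts <- counts + t(counts)
  contact_matrix(counts, bins, state = "raw_counts",
                 note = sprintf("structure contacts (alpha %g, seed %d)",
                                alpha, seed))
}

#' Simulate gene expression and DEG tables with truth labels
#'
#' Places `n_genes` genes on the first replicon of the spec's layout, gives
#' boundary-adjacent genes (midpoint within one bin of a planted domain
#' wall) the spec's length and expression multipliers, and samples `n_deg`
#' DEGs with elevated probability (`deg_weight`) inside the spec's
#' `deg_windows`. Truth labels are attached as attributes
#' `boundary_gene` and `in_deg_window`.
#'
#' @param spec a [truth_spec()].
#' @param seed RNG seed (defaults to the spec's).
#' @return list with `genes` ([gene_table()] with expression) and `degs`
#'   ([deg_table()]).
#' @export
simulate_expression_degs <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "truth_spec"))
  if (spec$n_deg > spec$n_genes) stop("more DEGs requested than genes")
  set.seed(seed)
  r <- spec$layout$replicon_id[1]
  L <- spec$layout$length_bp[1]
  s <- spec$bin_size_bp
  n_genes <- spec$n_genes
  len <- round(stats::rlnorm(n_genes, meanlog = log(900), sdlog = 0.4))
  start <- sort(round(stats::runif(n_genes, 0, L - max(len) - 1)))
  mid <- start + len / 2
  walls_bp <- spec$boundaries[[r]] * s
  boundary_gene <- rep(FALSE, n_genes)
  if (length(walls_bp)) {
    dmin <- vapply(mid, function(x)
      min(circular_distance_raw(x, walls_bp, L)), 0)
    boundary_gene <- dmin <= s
  }
  if (spec$boundary_len_mult != 1) {
    len[boundary_gene] <- round(len[boundary_gene] * spec$boundary_len_mult)
    mid <- start + len / 2
  }
  expr <- stats::rlnorm(n_genes, meanlog = 3, sdlog = 1)
  expr[boundary_gene] <- expr[boundary_gene] * spec$boundary_expr_mult
  genes <- gene_table(sprintf("g%04d", seq_len(n_genes)), r, start,
                      pmin(start + len, L), strand = "+",
                      expression_value = expr)
  in_window <- rep(FALSE, n_genes)
  for (w in spec$deg_windows)
    in_window <- in_window | (mid >= w[1] & mid < w[2])
  wgt <- ifelse(in_window, spec$deg_weight, 1)
  deg_idx <- sample.int(n_genes, spec$n_deg, prob = wgt)
  degs <- deg_table(genes$gene_id[deg_idx],
                    log2_fold_change = stats::runif(spec$n_deg, 1, 3),
                    adjusted_p = stats::runif(spec$n_deg, 0, 0.049))
  attr(genes, "boundary_gene") <- boundary_gene
  attr(genes, "in_deg_window") <- in_window
  attr(degs, "deg_idx") <- deg_idx
  list(genes = genes, degs = degs)
}

#' Simulate distance-biased pairs on a structure (PPI-like)
#'
#' Samples `n_pairs` distinct bin pairs with weight
#' `exp(-beta * d_ij / Rg)`; `beta = 0` gives uniform pairs (the null of
#' [ppi_distance_test()]), larger `beta` concentrates pairs at spatially
#' close bins.
#'
#' @param s a [structure_model()].
#' @param n_pairs number of pairs.
#' @param beta distance bias (>= 0).
#' @param seed RNG seed.
#' @return data frame `bin_i`, `bin_j` (local 0-based bins of `s`).
#' @export
simulate_ppi <- function(s, n_pairs, beta = 0, seed = 1) {
  stopifnot(inherits(s, "structure_model"))
  if (beta < 0) stop("beta must be >= 0")
  D <- as.matrix(stats::dist(s$coords))
  ut <- which(upper.tri(D), arr.ind = TRUE)
  if (n_pairs > nrow(ut)) stop("n_pairs exceeds available distinct pairs")
  rg <- radius_of_gyration(s)
  w <- exp(-beta * D[ut] / rg)
  set.seed(seed)
  pick <- sample.int(nrow(ut), n_pairs, prob = w)
  data.frame(bin_i = s$bin[ut[pick, 1]], bin_j = s$bin[ut[pick, 2]])
}
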