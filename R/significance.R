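#' Shorter-arc distance on a circular replicon
#'
#' On a circular replicon of length `L`, the interaction distance between two
#' loci is the shorter arc: `min(|i - j|, L - |i - j|)`, always `<= L/2`.
#'
#' @param pos_i,pos_j positions in `[0, L)` (vectorised).
#' @param length_bp replicon length `L`.
#' @return distance(s) in bp.
#' @examples
#' circular_distance(0, 1500000, 2649000)  # 1149000
#' @export
circular_distance <- function(pos_i, pos_j, length_bp) {
  if (any(pos_i < 0 | pos_i >= length_bp | pos_j < 0 | pos_j >= length_bp))
    stop("positions must lie in [0, length_bp)")
  d <- abs(pos_i - pos_j)
  pmin(d, length_bp - d)
}

# local-offset pair index helpers for one replicon's cis submatrix
cis_pair_table <- function(m, replicon, include_diag = FALSE) {
  rows <- replicon_rows(m$bins, replicon)
  n <- length(rows)
  s <- bin_size_of(m$bins)
  circular <- replicon_is_circular(m$bins, replicon)
  sub <- m$matrix[rows, rows, drop = FALSE]
  mask <- m$mask[rows]
  ut <- which(upper.tri(sub, diag = include_diag), arr.ind = TRUE)
  keep <- mask[ut[, 1]] & mask[ut[, 2]]
  ut <- ut[keep, , drop = FALSE]
  d_bins <- circ_bin_dist(ut[, 1], ut[, 2], n, circular)
  list(i = ut[, 1], j = ut[, 2], value = sub[ut],
       distance_bp = d_bins * s, n = n, circular = circular, s = s)
}

#' Contact frequency as a function of genomic distance, P(s)
#'
#' Mean cis contact value per distance stratum for one replicon, using
#' shorter-arc distances when the replicon is circular (so the largest
#' stratum is at `L/2`). Strata with no pairs are absent, not zero.
#'
#' @param m a [contact_matrix()].
#' @param replicon replicon name.
#' @param log_binning if `TRUE`, strata are bin-size resolution up to 100 kb
#'   then logarithmically spaced (factor `log_factor`).
#' @param log_factor stratum growth factor for log binning.
#' @param include_diag include the zero-distance diagonal stratum.
#' @return A `ps_curve` data frame: `distance_bp` (stratum representative:
#'   mean pair distance), `mean_value`, `n_pairs`.
#' @export
ps_curve <- function(m, replicon, log_binning = FALSE, log_factor = 1.25,
                     include_diag = FALSE) {
  pt <- cis_pair_table(m, replicon, include_diag = include_diag)
  if (!length(pt$value)) stop("no valid cis pairs for replicon ", replicon)
  d <- pt$distance_bp
  if (log_binning) {
    edges <- ps_log_edges(max(d), pt$s, log_factor)
    stratum <- cut(d, breaks = edges, include.lowest = TRUE, right = FALSE)
  } else {
    stratum <- factor(d)
  }
  mean_value <- tapply(pt$value, stratum, mean)
  mean_d <- tapply(d, stratum, mean)
  n_pairs <- tapply(rep(1, length(d)), stratum, sum)
  keep <- !is.na(mean_value)
  out <- data.frame(distance_bp = as.numeric(mean_d[keep]),
                    mean_value = as.numeric(mean_value[keep]),
                    n_pairs = as.integer(n_pairs[keep]))
  out <- out[order(out$distance_bp), ]
  rownames(out) <- NULL
  attr(out, "replicon") <- replicon
  attr(out, "bin_size_bp") <- pt$s
  class(out) <- c("ps_curve", "data.frame")
  out
}

ps_log_edges <- function(dmax, s, log_factor) {
  lin <- seq(0, min(1e5, dmax), by = s)
  edges <- lin
  cur <- max(lin)
  while (cur < dmax) {
    cur <- cur * log_factor
    edges <- c(edges, cur)
  }
  unique(c(edges, dmax + s))
}

#' Fit the distance-decay exponent of a P(s) curve
#'
#' Ordinary least squares of `log10(mean_value)` on `log10(distance)` over a
#' distance window, weighted by pair counts. For a power law
#' `P(s) ~ s^(-alpha)` the slope estimates `-alpha`.
#'
#' @param curve a [ps_curve()].
#' @param min_bp,max_bp fitted distance window (defaults: one bin size to a
#'   quarter of the largest distance, avoiding the circular flattening near
#'   `L/2`).
#' @return list with `slope`, `intercept`, `n_strata`.
#' @export
fit_ps_slope <- function(curve, min_bp = NULL, max_bp = NULL) {
  stopifnot(inherits(curve, "ps_curve"))
  if (is.null(min_bp)) min_bp <- attr(curve, "bin_size_bp")
  if (is.null(max_bp)) max_bp <- max(curve$distance_bp) / 2
  sub <- curve[curve$distance_bp >= min_bp & curve$distance_bp <= max_bp &
                 curve$mean_value > 0, ]
  if (nrow(sub) < 3) stop("too few strata in the fit window")
  fit <- stats::lm(log10(mean_value) ~ log10(distance_bp), data = sub,
                   weights = sub$n_pairs)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n_strata = nrow(sub))
}

#' @export
plot.ps_curve <- function(x, ...) {
  graphics::plot(x$distance_bp, x$mean_value, log = "xy", type = "l",
                 xlab = "genomic distance (bp)", ylab = "mean contact",
                 main = paste("P(s):", attr(x, "replicon")), ...)
  invisible(x)
}

# weighted pool-adjacent-violators for a non-increasing fit
pava_decreasing <- function(y, w) {
  vals <- y; wts <- w; sizes <- rep(1L, length(y))
  i <- 1
  while (i < length(vals)) {
    if (vals[i] < vals[i + 1] - 1e-15) {
      # merge adjacent blocks violating monotone non-increase
      vals[i] <- (vals[i] * wts[i] + vals[i + 1] * wts[i + 1]) /
        (wts[i] + wts[i + 1])
      wts[i] <- wts[i] + wts[i + 1]
      sizes[i] <- sizes[i] + sizes[i + 1]
      vals <- vals[-(i + 1)]; wts <- wts[-(i + 1)]; sizes <- sizes[-(i + 1)]
      if (i > 1) i <- i - 1
    } else i <- i + 1
  }
  rep(vals, times = sizes)
}

#' Expected contact count per distance stratum
#'
#' Empirical stratum means of raw cis counts, smoothed by weighted isotonic
#' regression constrained to be non-increasing in distance (pair counts as
#' weights), then floored at the smallest positive stratum mean so the
#' expectation is strictly positive wherever defined. This is the null decay
#' model for [call_significant()].
#'
#' @param m raw [contact_matrix()].
#' @param replicon replicon name.
#' @return An `expected_model` object: data frame `distance_bp`, `observed`
#'   (raw stratum mean), `expected` (smoothed), `n_pairs`.
#' @export
expected_model <- function(m, replicon) {
  if (!is_raw(m)) stop("expected_model works on raw counts")
  pt <- cis_pair_table(m, replicon)
  if (!length(pt$value) || sum(pt$value) == 0)
    stop("all-zero cis matrix for replicon ", replicon)
  stratum <- factor(pt$distance_bp)
  obs <- as.numeric(tapply(pt$value, stratum, mean))
  npairs <- as.numeric(tapply(rep(1, length(pt$value)), stratum, sum))
  d <- as.numeric(levels(stratum))
  o <- order(d)
  d <- d[o]; obs <- obs[o]; npairs <- npairs[o]
  exp_fit <- pava_decreasing(obs, npairs)
  floor_val <- min(exp_fit[exp_fit > 0])
  exp_fit <- pmax(exp_fit, floor_val)
  out <- data.frame(distance_bp = d, observed = obs, expected = exp_fit,
                    n_pairs = as.integer(npairs))
  attr(out, "replicon") <- replicon
  class(out) <- c("expected_model", "data.frame")
  out
}

#' Call significant cis contacts against the distance-decay expectation
#'
#' Per cis bin pair, the upper-tail Poisson p-value
#' `P(X >= observed | mu = expected(distance))` is computed, Benjamini-
#' Hochberg q-values are taken over all tested pairs, and pairs with
#' `p < alpha`, `q < alpha` and `count > min_count` are retained — the
#' selection rule of Fit-Hi-C-style callers at bacterial depths, with a
#' Poisson tail in place of the binomial/spline machinery.
#'
#' @param m raw [contact_matrix()] (significance is computed on raw counts).
#' @param expected an [expected_model()] from the same matrix (computed if
#'   `NULL`).
#' @param replicon replicon name.
#' @param alpha significance level for both p and q (default 0.05).
#' @param min_count minimum observed count, exclusive (default 2: kept pairs
#'   have count > 2).
#' @param filter if `FALSE`, return every tested pair with its p and q
#'   (no selection); used for calibration diagnostics.
#' @return A `sig_interactions` data frame: `bin_i`, `bin_j` (local 0-based),
#'   `observed`, `expected`, `p`, `q`, `distance_bp`; attribute `n_tested`.
#' @export
call_significant <- function(m, replicon, expected = NULL, alpha = 0.05,
                             min_count = 2, filter = TRUE) {
  if (!is_raw(m)) stop("call_significant works on raw counts")
  if (is.null(expected)) expected <- expected_model(m, replicon)
  pt <- cis_pair_table(m, replicon)
  mu <- expected$expected[match(pt$distance_bp, expected$distance_bp)]
  tested <- !is.na(mu)
  n_skipped <- sum(!tested)
  obs <- pt$value[tested]
  mu_t <- mu[tested]
  p <- stats::ppois(obs - 1, mu_t, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  keep <- if (filter) p < alpha & q < alpha & obs > min_count
          else rep(TRUE, length(p))
  out <- data.frame(bin_i = pt$i[tested][keep] - 1L,
                    bin_j = pt$j[tested][keep] - 1L,
                    observed = obs[keep], expected = mu_t[keep],
                    p = p[keep], q = q[keep],
                    distance_bp = pt$distance_bp[tested][keep])
  out <- out[order(out$q, out$p), ]
  rownames(out) <- NULL
  attr(out, "replicon") <- replicon
  attr(out, "n_tested") <- sum(tested)
  attr(out, "n_skipped") <- n_skipped
  attr(out, "alpha") <- alpha
  class(out) <- c("sig_interactions", "data.frame")
  out
}

#' Proportion of significant contacts per distance band
#'
#' Classifies significant cis interactions by shorter-arc distance into
#' bands (default a single cut at 450 kb, separating short- from long-range
#' contacts) and reports the proportion of significant pairs in each band.
#'
#' @param sig a [call_significant()] result.
#' @param band_edges_bp internal band edges (default `450000`).
#' @return data frame `band`, `n`, `proportion` (proportions sum to 1).
#' @export
classify_distances <- function(sig, band_edges_bp = 450000) {
  if (!nrow(sig)) stop("no significant interactions to classify")
  edges <- sort(unique(band_edges_bp))
  breaks <- c(0, edges, Inf)
  labs <- character(length(breaks) - 1)
  labs[1] <- sprintf("<%g kb", edges[1] / 1000)
  if (length(edges) > 1)
    labs[2:(length(labs) - 1)] <- sprintf("%g-%g kb", edges[-length(edges)] / 1000,
                                          edges[-1] / 1000)
  labs[length(labs)] <- sprintf(">%g kb", edges[length(edges)] / 1000)
  band <- cut(sig$distance_bp, breaks = breaks, labels = labs, right = FALSE)
  n <- as.integer(table(band))
  data.frame(band = labs, n = n, proportion = n / sum(n))
}

#' Expression-stratified P(s) curves
#'
#' Genes are classified by expression into `high` (top 10%), `low` (bottom
#' 10%) and `moderate` (the rest); each bin takes the maximum class of the
#' genes it overlaps (high > moderate > low). One decay curve is computed per
#' class over the cis pairs whose anchor bin carries that class (each
#' ordered pair contributes to its anchor's class).
#'
#' @param m a [contact_matrix()].
#' @param genes a gene table with `expression_value` (see [read_genes()]).
#' @param replicon replicon name.
#' @param quantile_frac class quantile (default 0.10).
#' @return named list of [ps_curve()] objects (classes with no bins are
#'   absent, with a warning).
#' @export
stratified_ps <- function(m, genes, replicon, quantile_frac = 0.10) {
  bins <- m$bins
  cls_gene <- expression_class(genes, quantile_frac)
  bin_cls <- bin_expression_class(genes, cls_gene, bins, replicon)
  rows <- replicon_rows(bins, replicon)
  n <- length(rows)
  s <- bin_size_of(bins)
  circular <- replicon_is_circular(bins, replicon)
  sub <- m$matrix[rows, rows, drop = FALSE]
  mask <- m$mask[rows]
  out <- list()
  for (cl in c("high", "moderate", "low")) {
    anchors <- which(bin_cls == cl & mask)
    if (!length(anchors)) {
      warning("no bins in expression class '", cl, "'")
      next
    }
    pairs_i <- rep(anchors, each = n)
    pairs_j <- rep(seq_len(n), times = length(anchors))
    keep <- pairs_i != pairs_j & mask[pairs_j]
    d <- circ_bin_dist(pairs_i[keep], pairs_j[keep], n, circular) * s
    v <- sub[cbind(pairs_i[keep], pairs_j[keep])]
    stratum <- factor(d)
    cur <- data.frame(distance_bp = as.numeric(levels(stratum)),
                      mean_value = as.numeric(tapply(v, stratum, mean)),
                      n_pairs = as.integer(table(stratum)))
    cur <- cur[order(cur$distance_bp), ]
    rownames(cur) <- NULL
    attr(cur, "replicon") <- replicon
    attr(cur, "bin_size_bp") <- s
    class(cur) <- c("ps_curve", "data.frame")
    out[[cl]] <- cur
  }
  out
}

# per-gene expression class: high (top q), low (bottom q), moderate
expression_class <- function(genes, quantile_frac = 0.10) {
  e <- genes$expression_value
  if (is.null(e) || all(is.na(e))) stop("gene table lacks expression values")
  lo <- stats::quantile(e, quantile_frac, names = FALSE)
  hi <- stats::quantile(e, 1 - quantile_frac, names = FALSE)
  cls <- rep("moderate", length(e))
  cls[e <= lo] <- "low"
  cls[e >= hi] <- "high"
  # a constant track yields lo == hi: everything is moderate then
  if (lo == hi) cls[] <- "moderate"
  cls
}

# label replicon bins by the max class of overlapping genes
bin_expression_class <- function(genes, cls_gene, bins, replicon) {
  rows <- replicon_rows(bins, replicon)
  n <- length(rows)
  rank <- c(low = 1, moderate = 2, high = 3)
  score <- rep(0, n)
  g <- genes[genes$replicon_id == replicon, , drop = FALSE]
  cg <- cls_gene[genes$replicon_id == replicon]
  s <- bin_size_of(bins)
  for (k in seq_len(nrow(g))) {
    b1 <- floor(g$start_bp[k] / s) + 1
    b2 <- min(floor((g$end_bp[k] - 1) / s) + 1, n)
    idx <- b1:b2
    score[idx] <- pmax(score[idx], rank[[cg[k]]])
  }
  out <- rep(NA_character_, n)
  out[score > 0] <- names(rank)[score[score > 0]]
  out[is.na(out)] <- "moderate"
  out
}
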