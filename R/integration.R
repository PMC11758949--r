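#' Label genes as boundary or interior
#'
#' Boundary genes are those overlapping any CID boundary interval extended
#' by `flank_bins` bins on each side (half-open bp intervals, wrapping on
#' circular replicons); all other genes are interior.
#'
#' @param genes a [gene_table()].
#' @param bset a [call_boundaries()] result (or a list of them, one per
#'   replicon).
#' @param flank_bins extension of each boundary interval, in bins.
#' @return character vector (`"boundary"`/`"interior"`) aligned with `genes`.
#' @export
classify_genes_by_boundary <- function(genes, bset, flank_bins = 1) {
  bsets <- if (inherits(bset, "boundary_set")) list(bset) else bset
  labels <- rep("interior", nrow(genes))
  for (bs in bsets) {
    iv <- boundary_bp_intervals(bs, flank_bins)
    if (!nrow(iv)) next
    on_rep <- which(genes$replicon_id == bs$replicon)
    for (g in on_rep) {
      gs <- genes$start_bp[g]; ge <- genes$end_bp[g]
      if (any(iv$start < ge & gs < iv$end)) labels[g] <- "boundary"
    }
  }
  labels
}

# boundary intervals in bp, wrap-split on circular replicons
boundary_bp_intervals <- function(bs, flank_bins = 0) {
  if (!nrow(bs$boundaries))
    return(data.frame(start = numeric(), end = numeric()))
  s <- bs$bin_size_bp
  n <- bs$n_bins
  L <- n * s
  out <- list()
  for (k in seq_len(nrow(bs$boundaries))) {
    a <- bs$boundaries$start_bin[k]
    b <- bs$boundaries$end_bin[k]
    if (b < a) b <- b + n  # wrapped interval
    lo <- (a - flank_bins) * s
    hi <- (b + 1 + flank_bins) * s
    if (bs$circular) {
      lo_m <- lo %% L
      if (hi - lo >= L) {
        out[[length(out) + 1]] <- c(0, L)
      } else if ((lo_m + (hi - lo)) > L) {
        out[[length(out) + 1]] <- c(lo_m, L)
        out[[length(out) + 1]] <- c(0, (lo_m + (hi - lo)) - L)
      } else {
        out[[length(out) + 1]] <- c(lo_m, lo_m + (hi - lo))
      }
    } else {
      out[[length(out) + 1]] <- c(max(0, lo), min(L, hi))
    }
  }
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

#' Compare a gene feature between boundary and interior genes
#'
#' One-sided Mann-Whitney test of the feature between boundary and interior
#' genes. For `expression` and `length_bp` the alternative is that boundary
#' genes are larger (long, actively transcribed genes accumulate at CID
#' boundaries); for `gc` that boundary genes are lower (boundaries are
#' AT-rich).
#'
#' @param labels output of [classify_genes_by_boundary()].
#' @param genes the matching [gene_table()].
#' @param feature `"expression"`, `"length_bp"` or `"gc"`.
#' @param values optional numeric vector overriding the feature column
#'   (required for `"gc"` unless `genes$gc` exists).
#' @return list with `median_boundary`, `median_interior`, `p`,
#'   `alternative`, `n_boundary`, `n_interior`.
#' @export
boundary_feature_test <- function(labels, genes,
                                  feature = c("expression", "length_bp", "gc"),
                                  values = NULL) {
  feature <- match.arg(feature)
  if (is.null(values)) {
    values <- switch(feature,
      expression = genes$expression_value,
      length_bp = genes$end_bp - genes$start_bp,
      gc = genes$gc)
  }
  if (is.null(values)) stop("no values available for feature ", feature)
  xb <- values[labels == "boundary"]
  xi <- values[labels == "interior"]
  if (length(xb) < 5 || length(xi) < 5)
    stop("each group needs at least 5 genes")
  if (stats::sd(c(xb, xi)) == 0) stop("feature has no variation")
  alternative <- if (feature == "gc") "less" else "greater"
  wt <- stats::wilcox.test(xb, xi, alternative = alternative, exact = FALSE)
  list(median_boundary = stats::median(xb), median_interior = stats::median(xi),
       p = wt$p.value, alternative = alternative,
       n_boundary = length(xb), n_interior = length(xi))
}

#' Correlation between transcription and the contact-map diagonal
#'
#' Per-bin transcription (length-weighted mean expression of overlapping
#' genes) is correlated (Pearson) with the diagonal of the normalized
#' contact matrix — the short-range interaction frequency of each bin.
#'
#' @param m normalized [contact_matrix()].
#' @param genes a [gene_table()] with expression values.
#' @param replicon replicon name.
#' @return list with `r`, `p`, `n_bins`.
#' @export
diagonal_expression_correlation <- function(m, genes, replicon) {
  rows <- replicon_rows(m$bins, replicon)
  diag_track <- diag(m$matrix)[rows]
  expr_track <- bin_expression_track(genes, m$bins, replicon)
  ok <- m$mask[rows] & !is.na(expr_track)
  if (sum(ok) < 3) stop("too few bins with both signals")
  x <- expr_track[ok]; y <- diag_track[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant track")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_bins = sum(ok))
}

#' Sliding-window enrichment of differentially expressed genes
#'
#' Counts DEG midpoints in sliding windows (default 100 kb windows advanced
#' by 5 kb, wrapping on circular replicons) and assesses each window against
#' a permutation null in which the DEG labels are reassigned uniformly over
#' the annotated genes — preserving gene density along the genome.
#' Empirical p-values are BH-corrected across windows; the distance from
#' each window centre to the nearest CID boundary is reported when a
#' boundary set is supplied.
#'
#' @param degs a [deg_table()]; only genes with the requested `direction`
#'   are counted.
#' @param genes the [gene_table()] the DEG ids refer to.
#' @param replicon replicon name.
#' @param layout a [replicon_layout()] (for length/circularity).
#' @param window_bp,step_bp window size and step (defaults 100 kb / 5 kb).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @param direction `"up"` (default) or `"down"`.
#' @param boundaries optional [call_boundaries()] result for boundary
#'   distances.
#' @return A `window_enrichment` data frame: `window_start`, `window_end`
#'   (bp; end may exceed the replicon length for wrapped windows), `count`,
#'   `p`, `q`, `dist_to_boundary_bp`.
#' @export
sliding_window_enrichment <- function(degs, genes, replicon, layout,
                                      window_bp = 1e5, step_bp = 5e3,
                                      n_perm = 999, seed = 1,
                                      direction = "up", boundaries = NULL) {
  L <- layout$length_bp[match(replicon, layout$replicon_id)]
  if (is.na(L)) stop("unknown replicon: ", replicon)
  circular <- layout$circular[match(replicon, layout$replicon_id)]
  use_degs <- degs[degs$direction == direction, , drop = FALSE]
  if (!nrow(use_degs)) stop("no DEGs with direction '", direction, "'")
  g <- genes[genes$replicon_id == replicon, , drop = FALSE]
  mids <- ((g$start_bp + g$end_bp) / 2) %% L
  is_deg <- g$gene_id %in% use_degs$gene_id
  n_deg <- sum(is_deg)
  if (!n_deg) stop("no DEG maps to replicon ", replicon)
  k <- as.integer(round(window_bp / step_bp))
  n_cells <- as.integer(ceiling(L / step_bp))
  cell <- pmin(floor(mids / step_bp), n_cells - 1) + 1L
  n_windows <- if (circular) n_cells else max(1L, n_cells - k + 1L)
  window_count <- function(deg_cells) {
    cc <- tabulate(deg_cells, nbins = n_cells)
    cc2 <- if (circular) c(cc, cc[seq_len(k - 1)]) else cc
    cs <- cumsum(c(0, cc2))
    cs[(seq_len(n_windows)) + k] - cs[seq_len(n_windows)]
  }
  obs <- window_count(cell[is_deg])
  set.seed(seed)
  ge <- matrix(0L, nrow = n_windows, ncol = 1)
  exceed <- integer(n_windows)
  for (b in seq_len(n_perm)) {
    perm_cells <- cell[sample(length(cell), n_deg)]
    exceed <- exceed + (window_count(perm_cells) >= obs)
  }
  p <- (1 + exceed) / (n_perm + 1)
  q <- stats::p.adjust(p, method = "BH")
  window_start <- (seq_len(n_windows) - 1) * step_bp
  centre <- (window_start + window_bp / 2) %% L
  dist_b <- rep(NA_real_, n_windows)
  if (!is.null(boundaries) && nrow(boundaries$boundaries)) {
    bmid_bp <- (boundaries$boundaries$midpoint_bin + 0.5) *
      boundaries$bin_size_bp
    for (w in seq_len(n_windows)) {
      d <- if (circular) circular_distance_raw(centre[w], bmid_bp, L)
           else abs(centre[w] - bmid_bp)
      dist_b[w] <- min(d)
    }
  }
  out <- data.frame(window_start = window_start,
                    window_end = window_start + window_bp,
                    count = obs, p = p, q = q,
                    dist_to_boundary_bp = dist_b)
  attr(out, "replicon") <- replicon
  attr(out, "n_perm") <- n_perm
  attr(out, "n_deg") <- n_deg
  class(out) <- c("window_enrichment", "data.frame")
  out
}

#' Per-bin G+C content profile
#'
#' Fraction of G/C among unambiguous bases in each bin of a replicon;
#' ambiguity codes are excluded from the denominator.
#'
#' @param sequence a `Biostrings::DNAString`, `DNAStringSet` (first element)
#'   or plain character string for one replicon.
#' @param bins a [bin_genome()] table.
#' @param replicon replicon name.
#' @return numeric vector of per-bin G+C fractions in `[0, 1]` (`NaN` for
#'   bins with no unambiguous bases).
#' @export
gc_profile <- function(sequence, bins, replicon) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  if (inherits(sequence, "DNAStringSet")) sequence <- sequence[[1]]
  rows <- replicon_rows(bins, replicon)
  L <- replicon_length(bins, replicon)
  if (length(sequence) != L)
    stop(sprintf("sequence length %d does not match replicon length %g",
                 length(sequence), L))
  v <- Biostrings::Views(sequence, start = bins$start_bp[rows] + 1L,
                         end = bins$end_bp[rows])
  freq <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
  gc <- freq[, "C"] + freq[, "G"]
  tot <- rowSums(freq)
  as.numeric(gc / tot)
}

#' Mean G+C of boundary intervals and the fraction below the genome average
#'
#' @param gc_track per-bin G+C fractions (from [gc_profile()]).
#' @param bset a [call_boundaries()] result on the same replicon.
#' @param flank_bins flank added to each boundary interval, in bins.
#' @return list with `boundary_gc` (one mean per boundary), `genome_gc`
#'   (mean over all bins), `fraction_below` and `percent_below`.
#' @export
boundary_gc_summary <- function(gc_track, bset, flank_bins = 0) {
  n <- bset$n_bins
  if (length(gc_track) != n)
    stop("gc track length does not match the boundary set's replicon")
  genome_gc <- mean(gc_track, na.rm = TRUE)
  bgc <- numeric(0)
  if (nrow(bset$boundaries)) {
    bgc <- vapply(seq_len(nrow(bset$boundaries)), function(kk) {
      a <- bset$boundaries$start_bin[kk]
      b <- bset$boundaries$end_bin[kk]
      if (b < a) b <- b + n
      idx <- ((seq(a - flank_bins, b + flank_bins)) %% n) + 1
      mean(gc_track[idx], na.rm = TRUE)
    }, 0)
  }
  frac <- if (length(bgc)) mean(bgc < genome_gc) else NA_real_
  list(boundary_gc = bgc, genome_gc = genome_gc, fraction_below = frac,
       percent_below = 100 * frac)
}
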