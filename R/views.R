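#' Scalogram of local contact compaction
#'
#' For every valid bin of a replicon, finds the flanking half-width (bp) at
#' which the bin's cumulated cis contacts within `±w` first reach each of the
#' cumulative-fraction levels (default 15/30/45/60/75/100 % of the contacts it
#' makes within `±max_halfwidth_bp`). Locally compact regions reach high
#' fractions at small widths. Circular replicons wrap their flanks.
#'
#' @param m normalized [contact_matrix()].
#' @param replicon replicon to profile.
#' @param max_halfwidth_bp maximum flank half-width (default 500 kb; clipped
#'   with a warning to half the replicon length on circular replicons).
#' @param levels cumulative-fraction levels in (0, 1].
#' @return A `scalogram` object: matrix of half-widths (bp), one row per bin,
#'   one column per level; `NA` rows for masked bins.
#' @export
scalogram <- function(m, replicon, max_halfwidth_bp = 5e5,
                      levels = c(0.15, 0.30, 0.45, 0.60, 0.75, 1.00)) {
  stopifnot(inherits(m, "contact_matrix"))
  if (is_raw(m)) stop("scalogram expects a normalized matrix")
  if (any(levels <= 0 | levels > 1)) stop("levels must lie in (0, 1]")
  levels <- sort(levels)
  rows <- replicon_rows(m$bins, replicon)
  n <- length(rows)
  s <- bin_size_of(m$bins)
  circular <- replicon_is_circular(m$bins, replicon)
  W <- floor(max_halfwidth_bp / s)
  if (circular && W > floor((n - 1) / 2)) {
    W <- floor((n - 1) / 2)
    warning(sprintf(
      "max_halfwidth clipped to %g bp (half of circular replicon %s)",
      W * s, replicon))
  }
  W <- min(W, n - 1)
  sub <- m$matrix[rows, rows, drop = FALSE]
  mask <- m$mask[rows]
  out <- matrix(NA_real_, n, length(levels),
                dimnames = list(NULL, sprintf("%g%%", 100 * levels)))
  for (i in seq_len(n)) {
    if (!mask[i]) next
    # contact at signed offset o in -W..W (wrapping if circular)
    cum <- numeric(W + 1)
    cum[1] <- sub[i, i]
    if (W >= 1) {
      for (w in seq_len(W)) {
        up <- i - w; dn <- i + w
        v <- 0
        if (circular) {
          v <- sub[i, ((up - 1) %% n) + 1] + sub[i, ((dn - 1) %% n) + 1]
        } else {
          if (up >= 1) v <- v + sub[i, up]
          if (dn <= n) v <- v + sub[i, dn]
        }
        cum[w + 1] <- cum[w] + v
      }
    }
    total <- cum[W + 1]
    if (total <= 0) next
    frac <- cum / total
    out[i, ] <- vapply(levels, function(f) {
      (which(frac >= f - 1e-12)[1] - 1) * s
    }, 0)
  }
  structure(list(halfwidth_bp = out, levels = levels, replicon = replicon,
                 max_halfwidth_bp = W * s, bin_size_bp = s),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("scalogram of %s: %d bins, flank up to %g kb\n", x$replicon,
              nrow(x$halfwidth_bp), x$max_halfwidth_bp / 1000))
  cat("median half-width (kb) per level:\n")
  print(round(apply(x$halfwidth_bp, 2, stats::median, na.rm = TRUE) / 1000, 1))
  invisible(x)
}

#' @export
plot.scalogram <- function(x, ...) {
  hw <- x$halfwidth_bp / 1000
  n <- nrow(hw)
  cols <- grDevices::hcl.colors(ncol(hw), "Blue-Red")
  graphics::plot(NA, xlim = c(1, n), ylim = c(0, max(hw, na.rm = TRUE)),
                 xlab = "bin", ylab = "half-width (kb)",
                 main = paste("scalogram:", x$replicon), ...)
  for (k in rev(seq_len(ncol(hw))))
    graphics::polygon(c(seq_len(n), n, 1), c(hw[, k], 0, 0), col = cols[k],
                      border = NA)
  invisible(x)
}

#' Log2 ratio map between two normalized contact maps
#'
#' For each bin `i` and each genomic distance `k * bin_size` up to
#' `max_dist_bp`, computes `log2((a + eps) / (b + eps))` averaged over the
#' upstream and downstream partner at that distance. Used to visualise
#' condition contrasts (e.g. irradiated vs control) as a function of position
#' and distance. Antisymmetric: `ratio_map(a, b) == -ratio_map(b, a)`.
#'
#' @param a,b normalized [contact_matrix()] objects on the same bin table.
#' @param replicon replicon to profile.
#' @param max_dist_bp maximum distance from the diagonal (default 200 kb).
#' @param pseudocount stabiliser `eps`; default the 5th percentile of the
#'   pooled positive entries of both maps.
#' @return A `ratio_map` object: matrix `log2_ratio` with one row per bin and
#'   one column per distance (0 .. max_dist), `NA` where either input is
#'   masked.
#' @export
ratio_map <- function(a, b, replicon, max_dist_bp = 2e5, pseudocount = NULL) {
  check_same_bins(a, b)
  if (is_raw(a) || is_raw(b)) stop("ratio_map expects normalized matrices")
  if (!identical(a$mask, b$mask)) warning("masks differ; using intersection")
  mask_all <- a$mask & b$mask
  rows <- replicon_rows(a$bins, replicon)
  n <- length(rows)
  s <- bin_size_of(a$bins)
  circular <- replicon_is_circular(a$bins, replicon)
  K <- min(floor(max_dist_bp / s), if (circular) floor((n - 1) / 2) else n - 1)
  if (is.null(pseudocount)) {
    pool <- c(a$matrix[a$matrix > 0], b$matrix[b$matrix > 0])
    if (!length(pool)) stop("both maps are empty")
    pseudocount <- stats::quantile(pool, 0.05, names = FALSE)
  }
  sub_a <- a$matrix[rows, rows, drop = FALSE]
  sub_b <- b$matrix[rows, rows, drop = FALSE]
  mask <- mask_all[rows]
  out <- matrix(NA_real_, n, K + 1,
                dimnames = list(NULL, format((0:K) * s, scientific = FALSE,
                                             trim = TRUE)))
  i_all <- seq_len(n)
  for (k in 0:K) {
    if (circular) {
      up <- ((i_all - 1 - k) %% n) + 1
      dn <- ((i_all - 1 + k) %% n) + 1
    } else {
      up <- i_all - k; dn <- i_all + k
      up[up < 1] <- NA; dn[dn > n] <- NA
    }
    val <- rep(NA_real_, n)
    for (i in i_all) {
      if (!mask[i]) next
      num <- den <- 0; cnt <- 0
      for (p in unique(stats::na.omit(c(up[i], dn[i])))) {
        if (!mask[p]) next
        num <- num + log2((sub_a[i, p] + pseudocount) /
                          (sub_b[i, p] + pseudocount))
        cnt <- cnt + 1
      }
      if (cnt > 0) val[i] <- num / cnt
    }
    out[, k + 1] <- val
  }
  structure(list(log2_ratio = out, replicon = replicon, bin_size_bp = s,
                 pseudocount = pseudocount),
            class = "ratio_map")
}

#' @export
print.ratio_map <- function(x, ...) {
  cat(sprintf("ratio_map of %s: %d bins x %d distances, pseudocount %.3g\n",
              x$replicon, nrow(x$log2_ratio), ncol(x$log2_ratio),
              x$pseudocount))
  cat(sprintf("  mean log2 ratio %.3f (range %.2f .. %.2f)\n",
              mean(x$log2_ratio, na.rm = TRUE),
              min(x$log2_ratio, na.rm = TRUE),
              max(x$log2_ratio, na.rm = TRUE)))
  invisible(x)
}
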