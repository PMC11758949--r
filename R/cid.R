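#' Directionality index (DI) profile of a replicon
#'
#' For each bin `i`, sums its cis contacts with the `scale_bp / bin_size`
#' bins upstream (`A`) and downstream (`B`), excluding the main diagonal,
#' and scores the up/downstream bias as
#' `DI = sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)` with `E = (A + B)/2`
#' (`DI = 0` when `A + B = 0`). Strong negative-to-positive sign flips mark
#' boundaries of chromosomal interaction domains (CIDs). Windows wrap on
#' circular replicons and truncate at the ends of linear ones.
#'
#' @param m a [contact_matrix()] (raw or normalized; DI is invariant to
#'   global scaling and boundary calls use a percentile threshold).
#' @param replicon replicon to profile.
#' @param scale_bp window size (default 100 kb); must be a multiple of the
#'   bin size and at most half a circular replicon.
#' @return A `di_profile` data frame with columns `bin` (local 0-based
#'   offset), `A`, `B`, `E`, `di`, plus attributes `scale_bp`, `replicon`,
#'   `circular`, `n_bins`, `bin_size_bp`.
#' @export
directionality_index <- function(m, replicon, scale_bp = 1e5) {
  stopifnot(inherits(m, "contact_matrix"))
  rows <- replicon_rows(m$bins, replicon)
  n <- length(rows)
  s <- bin_size_of(m$bins)
  if (scale_bp %% s != 0)
    stop("scale_bp must be a multiple of the bin size")
  w <- as.integer(scale_bp / s)
  if (w < 1) stop("scale_bp smaller than one bin")
  circular <- replicon_is_circular(m$bins, replicon)
  if (circular && w > floor((n - 1) / 2))
    stop(sprintf("scale %g bp exceeds half of circular replicon %s",
                 scale_bp, replicon))
  sub <- m$matrix[rows, rows, drop = FALSE]
  mask <- m$mask[rows]
  A <- B <- numeric(n)
  for (i in seq_len(n)) {
    if (!mask[i]) next
    up <- i - seq_len(w); dn <- i + seq_len(w)
    if (circular) {
      up <- ((up - 1) %% n) + 1; dn <- ((dn - 1) %% n) + 1
    } else {
      up <- up[up >= 1]; dn <- dn[dn <= n]
    }
    A[i] <- sum(sub[i, up]); B[i] <- sum(sub[i, dn])
  }
  E <- (A + B) / 2
  di <- numeric(n)
  nz <- E > 0
  di[nz] <- sign(B[nz] - A[nz]) *
    ((A[nz] - E[nz])^2 / E[nz] + (B[nz] - E[nz])^2 / E[nz])
  out <- data.frame(bin = seq_len(n) - 1L, A = A, B = B, E = E, di = di)
  attr(out, "scale_bp") <- scale_bp
  attr(out, "replicon") <- replicon
  attr(out, "circular") <- circular
  attr(out, "n_bins") <- n
  attr(out, "bin_size_bp") <- s
  attr(out, "mask") <- mask
  class(out) <- c("di_profile", "data.frame")
  out
}

#' @export
print.di_profile <- function(x, ...) {
  cat(sprintf("DI profile of %s: %d bins, scale %g kb; |DI| median %.3g, max %.3g\n",
              attr(x, "replicon"), nrow(x), attr(x, "scale_bp") / 1000,
              stats::median(abs(x$di)), max(abs(x$di))))
  invisible(x)
}

#' @export
plot.di_profile <- function(x, ...) {
  graphics::plot(x$bin, x$di, type = "h",
                 col = ifelse(x$di >= 0, "firebrick", "forestgreen"),
                 xlab = "bin", ylab = "DI",
                 main = paste("DI:", attr(x, "replicon")), ...)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Call CID boundaries from a DI profile
#'
#' A boundary is placed at each transition from a run of at least
#' `min_run_bins` bins with `DI <= -min_abs_di` to a run of at least
#' `min_run_bins` bins with `DI >= +min_abs_di`, allowing at most one
#' intervening near-zero bin. The boundary interval spans the transition
#' bins; its midpoint bin is used for distance computations. CIDs are the
#' maximal segments between successive boundaries (wrapping on circular
#' replicons, where #CIDs = #boundaries; on linear replicons
#' #CIDs = #boundaries + 1).
#'
#' @param di a [directionality_index()] profile.
#' @param min_run_bins minimum run length on each side (default 3).
#' @param min_abs_di DI magnitude threshold; default the 60th percentile of
#'   `|DI|` over valid bins, which makes calls invariant to global matrix
#'   scaling.
#' @return A `boundary_set`: list with `boundaries` (data frame of
#'   `replicon`, `start_bin`, `end_bin`, `midpoint_bin`, local 0-based,
#'   inclusive) and `cids` (data frame of `replicon`, `start_bin`,
#'   `end_bin`, `size_bp`).
#' @export
call_boundaries <- function(di, min_run_bins = 3, min_abs_di = NULL) {
  stopifnot(inherits(di, "di_profile"))
  n <- attr(di, "n_bins")
  circular <- attr(di, "circular")
  replicon <- attr(di, "replicon")
  s <- attr(di, "bin_size_bp")
  mask <- attr(di, "mask")
  L <- n * s
  if (sum(mask) < 2 * min_run_bins) {
    warning("fewer than 2*min_run_bins valid bins; no boundaries callable")
    return(empty_boundary_set(replicon, n, circular, s))
  }
  if (is.null(min_abs_di))
    min_abs_di <- stats::quantile(abs(di$di[mask]), 0.60, names = FALSE)
  cls <- integer(n)
  cls[di$di <= -min_abs_di] <- -1L
  cls[di$di >= min_abs_di] <- 1L
  cls[!mask] <- 0L
  # rotate a circular track to start at a class change so runs do not split
  rot <- 0L
  if (circular && length(unique(cls)) > 1) {
    chg <- which(cls != cls[c(n, seq_len(n - 1))])
    rot <- chg[1] - 1L
    cls <- cls[((seq_len(n) - 1L + rot) %% n) + 1L]
  }
  r <- rle(cls)
  nr <- length(r$lengths)
  run_start <- cumsum(c(0L, r$lengths[-nr]))  # 0-based within rotated frame
  run_end <- run_start + r$lengths - 1L
  bounds <- list()
  next_run <- function(t, k) if (circular) ((t - 1L + k) %% nr) + 1L
                             else if (t + k <= nr) t + k else NA_integer_
  for (t in seq_len(nr)) {
    if (r$values[t] != -1L || r$lengths[t] < min_run_bins) next
    t2 <- next_run(t, 1L)
    if (is.na(t2)) next
    gap <- 0L
    if (r$values[t2] == 0L && r$lengths[t2] <= 1L) {
      gap <- r$lengths[t2]
      t2 <- next_run(t, 2L)
      if (is.na(t2)) next
    }
    if (r$values[t2] != 1L || r$lengths[t2] < min_run_bins) next
    b_start <- run_end[t]
    b_end <- run_start[t2]
    bounds[[length(bounds) + 1L]] <- c(b_start, b_end)
  }
  if (length(bounds)) {
    bm <- do.call(rbind, bounds)
    # undo rotation back to genome frame
    start_bin <- (bm[, 1] + rot) %% n
    end_bin <- (bm[, 2] + rot) %% n
    mid <- (bm[, 1] + floor((bm[, 2] - bm[, 1]) / 2) + rot) %% n
    o <- order(mid)
    boundaries <- data.frame(replicon = replicon,
                             start_bin = as.integer(start_bin[o]),
                             end_bin = as.integer(end_bin[o]),
                             midpoint_bin = as.integer(mid[o]),
                             stringsAsFactors = FALSE)
  } else {
    boundaries <- data.frame(replicon = character(), start_bin = integer(),
                             end_bin = integer(), midpoint_bin = integer(),
                             stringsAsFactors = FALSE)
  }
  cids <- cids_from_boundaries(boundaries$midpoint_bin, n, circular, s,
                               replicon)
  structure(list(boundaries = boundaries, cids = cids, replicon = replicon,
                 n_bins = n, circular = circular, bin_size_bp = s,
                 min_run_bins = min_run_bins, min_abs_di = min_abs_di),
            class = "boundary_set")
}

empty_boundary_set <- function(replicon, n, circular, s) {
  boundaries <- data.frame(replicon = character(), start_bin = integer(),
                           end_bin = integer(), midpoint_bin = integer(),
                           stringsAsFactors = FALSE)
  structure(list(boundaries = boundaries,
                 cids = cids_from_boundaries(integer(), n, circular, s,
                                             replicon),
                 replicon = replicon, n_bins = n, circular = circular,
                 bin_size_bp = s, min_run_bins = NA, min_abs_di = NA),
            class = "boundary_set")
}

# segments between successive boundary midpoints
cids_from_boundaries <- function(mids, n, circular, s, replicon) {
  mids <- sort(unique(as.integer(mids)))
  if (!length(mids)) {
    return(data.frame(replicon = replicon, start_bin = 0L,
                      end_bin = n - 1L, size_bp = n * s,
                      stringsAsFactors = FALSE))
  }
  if (circular) {
    from <- mids
    to <- c(mids[-1], mids[1] + n)
    size <- (to - from) * s
    data.frame(replicon = replicon, start_bin = from %% n,
               end_bin = (to - 1L) %% n, size_bp = size,
               stringsAsFactors = FALSE)
  } else {
    cuts <- c(0L, mids, n)
    from <- cuts[-length(cuts)]
    to <- cuts[-1]
    keep <- to > from
    data.frame(replicon = replicon, start_bin = from[keep],
               end_bin = to[keep] - 1L, size_bp = (to - from)[keep] * s,
               stringsAsFactors = FALSE)
  }
}

#' @export
print.boundary_set <- function(x, ...) {
  cat(sprintf("boundary_set on %s: %d boundaries, %d CIDs (threshold |DI| >= %.3g)\n",
              x$replicon, nrow(x$boundaries), nrow(x$cids),
              as.numeric(x$min_abs_di)))
  if (nrow(x$cids))
    cat(sprintf("  CID sizes: %g - %g kb (mean %.1f kb)\n",
                min(x$cids$size_bp) / 1000, max(x$cids$size_bp) / 1000,
                mean(x$cids$size_bp) / 1000))
  invisible(x)
}

#' @export
summary.boundary_set <- function(object, ...) {
  print(object)
  invisible(list(n_boundaries = nrow(object$boundaries),
                 n_cids = nrow(object$cids),
                 mean_cid_size_bp = mean(object$cids$size_bp)))
}

#' Compare two boundary sets
#'
#' Greedy nearest matching of boundary midpoints within `tol_bins` (circular
#' bin distance on circular replicons); each boundary is matched at most
#' once. Reports conserved (matched), lost (in `a` only) and gained (in `b`
#' only) boundaries, as used for cross-condition CID comparisons.
#'
#' @param a,b `boundary_set` objects on the same replicon, or integer vectors
#'   of midpoint bins (then `n_bins`/`circular` must be supplied).
#' @param tol_bins matching tolerance in bins (default 2).
#' @param n_bins,circular replicon geometry when `a`/`b` are plain vectors.
#' @return list with counts `n_conserved`, `n_lost`, `n_gained` and the
#'   matched pairs.
#' @export
compare_boundaries <- function(a, b, tol_bins = 2, n_bins = NULL,
                               circular = TRUE) {
  mids <- function(x) if (inherits(x, "boundary_set")) x$boundaries$midpoint_bin
                      else as.integer(x)
  if (inherits(a, "boundary_set")) { n_bins <- a$n_bins; circular <- a$circular }
  if (is.null(n_bins)) stop("n_bins required when comparing plain vectors")
  ma <- mids(a); mb <- mids(b)
  pairs <- NULL
  if (length(ma) && length(mb)) {
    d <- outer(ma, mb, function(i, j) circ_bin_dist(i, j, n_bins, circular))
    cand <- which(d <= tol_bins, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_a <- logical(length(ma)); used_b <- logical(length(mb))
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_a[i] && !used_b[j]) {
          used_a[i] <- used_b[j] <- TRUE
          keep[k] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand))
        pairs <- data.frame(a_bin = ma[cand[, 1]], b_bin = mb[cand[, 2]],
                            dist_bins = d[cand])
    }
  }
  n_match <- if (is.null(pairs)) 0L else nrow(pairs)
  list(n_conserved = n_match, n_lost = length(ma) - n_match,
       n_gained = length(mb) - n_match, pairs = pairs,
       tol_bins = tol_bins)
}

#' Precision/recall/F1 of called boundaries against planted truth
#'
#' @param called a `boundary_set` (or vector of midpoint bins).
#' @param truth_bins integer vector of planted boundary bins (local 0-based),
#'   or a `truth_spec` from [truth_spec()] (then `replicon` selects which
#'   planted set).
#' @param tol_bins match tolerance (default 2 bins).
#' @param replicon,n_bins,circular geometry when not inferable from `called`.
#' @return list with `precision`, `recall`, `f1`, `n_called`, `n_truth`. With
#'   empty truth, `recall` and `f1` are `NA` (not applicable).
#' @export
boundary_recovery <- function(called, truth_bins, tol_bins = 2,
                              replicon = NULL, n_bins = NULL,
                              circular = TRUE) {
  if (inherits(truth_bins, "truth_spec")) {
    if (is.null(replicon)) replicon <- if (inherits(called, "boundary_set"))
      called$replicon else truth_bins$layout$replicon_id[1]
    truth_bins <- truth_bins$boundaries[[replicon]]
    if (is.null(truth_bins)) truth_bins <- integer()
  }
  cmp <- compare_boundaries(called, truth_bins, tol_bins = tol_bins,
                            n_bins = n_bins, circular = circular)
  n_called <- cmp$n_conserved + cmp$n_lost
  n_truth <- cmp$n_conserved + cmp$n_gained
  precision <- if (n_called > 0) cmp$n_conserved / n_called else NA_real_
  recall <- if (n_truth > 0) cmp$n_conserved / n_truth else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall)
  else if (n_truth == 0) NA_real_ else 0
  list(precision = precision, recall = recall, f1 = f1,
       n_called = n_called, n_truth = n_truth, tol_bins = tol_bins)
}
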