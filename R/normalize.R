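#' Mask low-coverage bins before normalization
#'
#' Bins whose total (cis + trans) coverage is zero, or strictly below the
#' given quantile of the nonzero coverages, are masked. Standard hygiene
#' before iterative balancing: unsequenceable or repeat-collapsed bins
#' otherwise blow up the per-bin scaling factors.
#'
#' @param m raw [contact_matrix()].
#' @param min_coverage_quantile fraction in `[0, 1)`; `0` masks only
#'   zero-coverage bins.
#' @return Logical mask (`TRUE` = keep), combined with the matrix's existing
#'   mask.
#' @export
filter_bins <- function(m, min_coverage_quantile = 0) {
  stopifnot(inherits(m, "contact_matrix"))
  if (!is_raw(m)) stop("filter_bins expects a raw count matrix")
  q <- min_coverage_quantile
  if (length(q) != 1 || !is.finite(q) || q < 0 || q >= 1)
    stop("min_coverage_quantile must lie in [0, 1)")
  cov <- rowSums(m$matrix)
  keep <- cov > 0
  if (q > 0 && any(keep)) {
    thr <- stats::quantile(cov[keep], q, names = FALSE)
    keep <- keep & cov >= thr
  }
  keep & m$mask
}

#' Sequential component normalization (SCN)
#'
#' Iteratively divides each column vector of the valid submatrix by its norm,
#' then each row vector, until the maximum relative entry change between
#' iterations drops below `tol` (or `max_iter` is reached). The alternating
#' steps break exact symmetry, so the final matrix is re-symmetrized as
#' `(M + t(M))/2`. With `norm = "euclidean"` (the classical SCN choice)
#' converged valid rows have unit Euclidean norm; with `norm = "sum"` they
#' sum to one. The result is invariant to global scaling of the input.
#'
#' @param m raw [contact_matrix()] (apply [filter_bins()] first via `mask`).
#' @param norm `"euclidean"` or `"sum"`.
#' @param tol convergence tolerance on the max relative entry change.
#' @param max_iter iteration cap.
#' @param mask optional logical mask overriding the matrix's own.
#' @return An `scn_result` list: `matrix` (normalized [contact_matrix()]),
#'   `iterations`, `residual`, `converged`, `mask`.
#' @export
scn_normalize <- function(m, norm = c("euclidean", "sum"), tol = 1e-6,
                          max_iter = 200, mask = NULL) {
  stopifnot(inherits(m, "contact_matrix"))
  norm <- match.arg(norm)
  if (!is_raw(m)) stop("scn_normalize expects a raw count matrix")
  if (is.null(mask)) mask <- m$mask else mask <- mask & m$mask
  # bins with zero coverage cannot be balanced; drop them from the valid set
  mask <- mask & rowSums(m$matrix) > 0
  if (!any(mask)) stop("all bins are masked; nothing to normalize")
  idx <- which(mask)
  W <- m$matrix[idx, idx, drop = FALSE]
  norm_fun <- if (norm == "euclidean") {
    function(v) sqrt(colSums(v^2))
  } else {
    function(v) colSums(v)
  }
  it <- 0L
  residual <- Inf
  repeat {
    prev <- W
    cn <- norm_fun(W)
    cn[cn == 0] <- 1
    W <- sweep(W, 2, cn, "/")
    rn <- norm_fun(t(W))
    rn[rn == 0] <- 1
    W <- sweep(W, 1, rn, "/")
    it <- it + 1L
    denom <- pmax(abs(prev), .Machine$double.eps)
    residual <- max(abs(W - prev) / denom)
    if (residual < tol || it >= max_iter) break
  }
  converged <- residual < tol
  if (!converged)
    warning(sprintf("SCN did not converge in %d iterations (residual %.3g)",
                    max_iter, residual))
  W <- (W + t(W)) / 2
  out <- matrix(0, nrow(m$matrix), ncol(m$matrix))
  out[idx, idx] <- W
  cm <- contact_matrix(out, m$bins, state = "normalized", mask = mask,
                       note = sprintf("SCN (%s norm, %d iter)", norm, it))
  structure(list(matrix = cm, iterations = it, residual = residual,
                 converged = converged, mask = mask, norm = norm, tol = tol),
            class = "scn_result")
}

#' @export
print.scn_result <- function(x, ...) {
  cat(sprintf("SCN normalization: %d iterations, residual %.3g (%s), %s norm\n",
              x$iterations, x$residual,
              if (x$converged) "converged" else "NOT converged", x$norm))
  cat(sprintf("  valid bins: %d / %d\n", sum(x$mask), length(x$mask)))
  invisible(x)
}
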