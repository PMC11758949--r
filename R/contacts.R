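#' Construct a contact matrix
#'
#' Container for a square symmetric non-negative matrix of contact values over
#' the bins of a [bin_genome()] table, tagged as `raw_counts` or `normalized`,
#' with a valid-bin mask. Masked bins carry no contacts (their rows/columns
#' are zeroed).
#'
#' @param mat square numeric matrix, one row/column per bin.
#' @param bins the `bin_table` the matrix is indexed by.
#' @param state `"raw_counts"` or `"normalized"`.
#' @param mask logical vector, `TRUE` for valid bins (default all valid).
#' @param note free-text provenance note.
#' @param tol symmetry tolerance.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(mat, bins, state = c("raw_counts", "normalized"),
                           mask = NULL, note = "", tol = 1e-9) {
  state <- match.arg(state)
  stopifnot(inherits(bins, "bin_table"))
  mat <- as.matrix(mat)
  n <- nrow(bins)
  if (nrow(mat) != n || ncol(mat) != n)
    stop(sprintf("matrix is %dx%d but bin table has %d bins",
                 nrow(mat), ncol(mat), n))
  if (any(!is.finite(mat))) stop("contact matrix contains non-finite values")
  if (any(mat < 0)) stop("contact values must be non-negative")
  if (max(abs(mat - t(mat))) > tol * max(1, max(abs(mat))))
    stop("contact matrix is asymmetric beyond tolerance")
  if (state == "raw_counts" && any(abs(mat - round(mat)) > 1e-6))
    stop("raw contact matrix must contain integer counts")
  if (is.null(mask)) mask <- rep(TRUE, n)
  mask <- rep_len(as.logical(mask), n)
  mat[!mask, ] <- 0
  mat[, !mask] <- 0
  dimnames(mat) <- NULL
  structure(list(matrix = mat, bins = bins, state = state, mask = mask,
                 note = note),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix [%s]: %d bins (%d valid), total signal %.4g\n",
              x$state, nrow(x$matrix), sum(x$mask), sum(x$matrix)))
  if (nzchar(x$note)) cat(" note:", x$note, "\n")
  invisible(x)
}

#' @export
summary.contact_matrix <- function(object, ...) {
  m <- object$matrix
  ut <- m[upper.tri(m)]
  cat(sprintf("contact_matrix [%s]\n", object$state))
  cat(sprintf("  bins: %d (%d valid, %d masked)\n", nrow(m),
              sum(object$mask), sum(!object$mask)))
  cat(sprintf("  total: %.6g   nonzero pairs: %d / %d\n",
              sum(m), sum(ut > 0), length(ut)))
  per <- split(seq_len(nrow(m)), object$bins$replicon_id)
  for (r in names(per)) {
    idx <- per[[r]]
    cat(sprintf("  %s: %d bins, cis total %.6g\n", r, length(idx),
                sum(m[idx, idx, drop = FALSE])))
  }
  invisible(object)
}

#' @export
plot.contact_matrix <- function(x, log = TRUE, ...) {
  m <- x$matrix
  if (log) m <- log10(m + 1)
  n <- nrow(m)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Reds", rev = TRUE),
                  xlab = "bin", ylab = "bin", axes = FALSE, ...)
  graphics::box()
  invisible(x)
}

is_raw <- function(m) m$state == "raw_counts"

# cis submatrix for one replicon (values only; rows = local bin order)
cis_matrix <- function(m, replicon) {
  rows <- replicon_rows(m$bins, replicon)
  m$matrix[rows, rows, drop = FALSE]
}

#' Read a binned contact matrix from text
#'
#' Two plain-text layouts are supported: `dense` (tab-separated square numeric
#' table, optional header/rownames of `replicon:start-end` labels) and
#' `triplet` (three columns `bin_i`, `bin_j`, `count` with 0-based global bin
#' indices; `#` comments allowed). Triplet input listing only one triangle is
#' mirrored; missing pairs are zero.
#'
#' @param path file path.
#' @param bins the `bin_table` the file is indexed against.
#' @param format `"dense"` or `"triplet"`.
#' @param state state tag to apply (files carry values, not provenance).
#' @return A [contact_matrix()].
#' @export
read_contacts <- function(path, bins, format = c("triplet", "dense"),
                          state = c("raw_counts", "normalized")) {
  format <- match.arg(format)
  state <- match.arg(state)
  n <- nrow(bins)
  if (format == "dense") {
    first <- readLines(path, n = 1)
    has_header <- grepl("[A-Za-z]", first)
    tab <- utils::read.table(path, header = has_header, sep = "\t",
                             row.names = if (has_header) 1 else NULL,
                             check.names = FALSE)
    mat <- as.matrix(tab)
    if (nrow(mat) != n || ncol(mat) != n)
      stop(sprintf("dense matrix in '%s' is %dx%d, expected %dx%d",
                   path, nrow(mat), ncol(mat), n, n))
    if (!is.numeric(mat)) stop("dense matrix contains non-numeric entries")
  } else {
    lines <- readLines(path)
    keep <- !grepl("^\\s*(#|$)", lines)
    lines <- lines[keep]
    lineno <- which(keep)
    mat <- matrix(0, n, n)
    if (length(lines)) {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      bad <- which(lengths(parts) != 3)
      if (length(bad))
        stop(sprintf("triplet file '%s' line %d: expected 3 tab-separated fields",
                     path, lineno[bad[1]]))
      rec <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                    ncol = 3, byrow = TRUE)
      bad <- which(!stats::complete.cases(rec))
      if (length(bad))
        stop(sprintf("triplet file '%s' line %d: non-numeric field",
                     path, lineno[bad[1]]))
      bad <- which(rec[, 1] < 0 | rec[, 1] >= n | rec[, 2] < 0 | rec[, 2] >= n)
      if (length(bad))
        stop(sprintf("triplet file '%s' line %d: bin index out of range 0..%d",
                     path, lineno[bad[1]], n - 1L))
      bad <- which(rec[, 3] < 0)
      if (length(bad))
        stop(sprintf("triplet file '%s' line %d: negative count",
                     path, lineno[bad[1]]))
      i <- rec[, 1] + 1L; j <- rec[, 2] + 1L
      for (k in seq_len(nrow(rec))) {
        mat[i[k], j[k]] <- mat[i[k], j[k]] + rec[k, 3]
        if (i[k] != j[k]) mat[j[k], i[k]] <- mat[j[k], i[k]] + rec[k, 3]
      }
    }
  }
  contact_matrix(mat, bins, state = state,
                 note = sprintf("read from %s (%s)", basename(path), format))
}

#' Write a contact matrix to text
#'
#' @param m a [contact_matrix()].
#' @param path output file.
#' @param format `"triplet"` writes upper-triangle (incl. diagonal) nonzero
#'   entries as `bin_i<TAB>bin_j<TAB>count`; `"dense"` writes the full square
#'   table with `replicon:start-end` header labels.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(m, path, format = c("triplet", "dense")) {
  format <- match.arg(format)
  mat <- m$matrix
  if (format == "triplet") {
    idx <- which(upper.tri(mat, diag = TRUE) & mat != 0, arr.ind = TRUE)
    v <- mat[idx]
    fmt <- if (is_raw(m)) "%d\t%d\t%.15g" else "%d\t%d\t%.10e"
    writeLines(c("# bin_i\tbin_j\tcount",
                 sprintf(fmt, idx[, 1] - 1L, idx[, 2] - 1L, v)), path)
  } else {
    lab <- sprintf("%s:%d-%d", m$bins$replicon_id, m$bins$start_bp,
                   m$bins$end_bp)
    tab <- as.data.frame(mat)
    names(tab) <- lab
    utils::write.table(cbind(bin = lab, signif(tab, 10)), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Correlation between two raw replicate contact maps
#'
#' Pearson correlation over `log(count + 1)` of the upper-triangle *cis*
#' entries of jointly valid bins. Trans entries are excluded (sparse and
#' zero-dominated); the pseudocount avoids `log 0`. Replicates that agree are
#' merged downstream with [merge_replicates()].
#'
#' @param a,b raw [contact_matrix()] objects on the same bin table.
#' @return list with `r` (Pearson correlation) and `n_pairs`.
#' @export
replicate_correlation <- function(a, b) {
  check_same_bins(a, b)
  if (!is_raw(a) || !is_raw(b))
    stop("replicate correlation is defined on raw count matrices")
  mask <- a$mask & b$mask
  xs <- ys <- list()
  for (r in unique(a$bins$replicon_id)) {
    rows <- replicon_rows(a$bins, r)
    keep <- rows[mask[rows]]
    if (length(keep) < 2) next
    sub_a <- a$matrix[keep, keep, drop = FALSE]
    sub_b <- b$matrix[keep, keep, drop = FALSE]
    ut <- upper.tri(sub_a)
    xs[[r]] <- sub_a[ut]
    ys[[r]] <- sub_b[ut]
  }
  x <- log(unlist(xs) + 1)
  y <- log(unlist(ys) + 1)
  if (!length(x)) stop("no jointly valid cis pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero-variance input")
  list(r = stats::cor(x, y), n_pairs = length(x))
}

#' Merge raw replicate contact maps by element-wise summation
#'
#' @param ... raw [contact_matrix()] objects on the same bin table (or a
#'   single list of them).
#' @return A raw [contact_matrix()]; the valid mask is the intersection of
#'   the inputs' masks.
#' @export
merge_replicates <- function(...) {
  ms <- list(...)
  if (length(ms) == 1 && !inherits(ms[[1]], "contact_matrix")) ms <- ms[[1]]
  if (!length(ms)) stop("no matrices to merge")
  for (m in ms) {
    if (!inherits(m, "contact_matrix")) stop("inputs must be contact matrices")
    if (!is_raw(m)) stop("cannot merge normalized matrices: raw counts required")
  }
  if (length(ms) > 1) for (m in ms[-1]) check_same_bins(ms[[1]], m)
  mat <- Reduce(`+`, lapply(ms, `[[`, "matrix"))
  mask <- Reduce(`&`, lapply(ms, `[[`, "mask"))
  if (!any(mask)) warning("merged mask is empty: inputs have disjoint valid bins")
  contact_matrix(mat, ms[[1]]$bins, state = "raw_counts", mask = mask,
                 note = sprintf("merge of %d replicates", length(ms)))
}

check_same_bins <- function(a, b) {
  if (!identical(dim(a$matrix), dim(b$matrix)) ||
      !identical(a$bins$replicon_id, b$bins$replicon_id) ||
      !identical(a$bins$start_bp, b$bins$start_bp))
    stop("contact matrices are not on the same bin table")
  invisible(TRUE)
}
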