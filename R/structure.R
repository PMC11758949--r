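#' Build a structure model from coordinates
#'
#' A structure model holds one 3D coordinate per bin of one replicon. The
#' models produced here are *average structures*: the organism is polyploid,
#' so contacts (and hence coordinates) mix intra- and inter-copy
#' interactions, which no reconstruction can distinguish.
#'
#' @param coords n x 3 numeric matrix.
#' @param replicon replicon name.
#' @param bin local 0-based bin offsets (default `0:(n-1)`).
#' @param pos_bp genomic midpoint of each bin (bp); used for genomic-
#'   separation-restricted metrics.
#' @param length_bp replicon length (bp).
#' @param circular is the replicon circular?
#' @param provenance `"embedded"`, `"simulated"` or `"imported"`.
#' @param model_id free-text identifier.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(coords, replicon = "replicon", bin = NULL,
                            pos_bp = NULL, length_bp = NULL, circular = TRUE,
                            provenance = c("embedded", "simulated", "imported"),
                            model_id = "model") {
  provenance <- match.arg(provenance)
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  if (ncol(coords) != 3) stop("coords must have 3 columns")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  n <- nrow(coords)
  if (is.null(bin)) bin <- seq_len(n) - 1L
  if (is.null(pos_bp)) pos_bp <- as.numeric(bin)
  if (is.null(length_bp)) length_bp <- max(pos_bp) + min(diff(sort(pos_bp)),
                                                         na.rm = TRUE)
  structure(list(coords = coords, replicon = replicon, bin = as.integer(bin),
                 pos_bp = as.numeric(pos_bp), length_bp = length_bp,
                 circular = circular, provenance = provenance,
                 model_id = model_id),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model '%s' (%s): %d bins of %s, Rg %.4g\n",
              x$model_id, x$provenance, nrow(x$coords), x$replicon,
              radius_of_gyration(x)))
  invisible(x)
}

#' Embed a contact map into 3D by classical multidimensional scaling
#'
#' Converts positive normalized contacts to target distances
#' `d_ij = c_ij^(-1/alpha)`, completes missing pairwise distances by
#' shortest paths over the contact graph, and projects into three dimensions
#' by classical MDS, centring at the centroid. A deliberately simple,
#' documented embedding: adequate for metric-level comparisons (radius of
#' gyration, compactness), not for shape reconstruction.
#'
#' @param m normalized [contact_matrix()].
#' @param replicon replicon to embed.
#' @param alpha contact-to-distance exponent (default 1).
#' @return A [structure_model()] with provenance `"embedded"`.
#' @export
embed_structure <- function(m, replicon, alpha = 1) {
  stopifnot(inherits(m, "contact_matrix"))
  rows <- replicon_rows(m$bins, replicon)
  keep <- rows[m$mask[rows]]
  if (length(keep) < 4)
    stop("at least 4 valid bins are required for a 3D embedding")
  sub <- m$matrix[keep, keep, drop = FALSE]
  d <- matrix(NA_real_, nrow(sub), ncol(sub))
  pos <- sub > 0
  d[pos] <- sub[pos]^(-1 / alpha)
  diag(d) <- 0
  adj <- d
  adj[is.na(adj)] <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1)
    stop(sprintf("contact graph is disconnected (%d components of sizes %s)",
                 comp$no, paste(comp$csize, collapse = ", ")))
  if (any(is.na(d))) {
    sp <- igraph::distances(g)
    d[is.na(d)] <- sp[is.na(d)]
  }
  xy <- stats::cmdscale(stats::as.dist(d), k = 3)
  if (ncol(xy) < 3)  # degenerate planar/linear input: pad missing axes
    xy <- cbind(xy, matrix(0, nrow(xy), 3 - ncol(xy)))
  xy <- sweep(xy, 2, colMeans(xy))
  local_bin <- match(keep, rows) - 1L
  mids <- bin_midpoints(m$bins)[keep]
  structure_model(xy, replicon = replicon, bin = local_bin, pos_bp = mids,
                  length_bp = replicon_length(m$bins, replicon),
                  circular = replicon_is_circular(m$bins, replicon),
                  provenance = "embedded",
                  model_id = sprintf("mds_alpha%g", alpha))
}

#' Radius of gyration
#'
#' `Rg = sqrt(mean squared distance of the points from their centroid)`;
#' smaller values indicate a more compact structure.
#'
#' @param s a [structure_model()] (or bare n x 3 matrix).
#' @return Rg (same units as the coordinates).
#' @export
radius_of_gyration <- function(s) {
  x <- if (inherits(s, "structure_model")) s$coords else as.matrix(s)
  cen <- colMeans(x)
  sqrt(mean(rowSums(sweep(x, 2, cen)^2)))
}

#' Global and local compactness of a structure model
#'
#' Global compactness `GC` is the mean over all bin pairs of the inverse
#' spatial distance, with distances expressed in units of the model's radius
#' of gyration (so GC is invariant to uniform scaling). Local compactness
#' `LC(scale)` is the same mean restricted to pairs whose genomic separation
#' (shorter arc on circular replicons) is at most `scale`. Higher values
#' indicate a more compact structure; `LC` converges to `GC` as the scale
#' reaches the replicon length.
#'
#' @param s a [structure_model()].
#' @param local_scales_bp scales at which LC is evaluated (default 50-500 kb
#'   in 50 kb steps, clipped to the replicon).
#' @return list with `gc`, and `lc` (data frame `scale_bp`, `lc`, `n_pairs`).
#' @export
compactness <- function(s, local_scales_bp = seq(5e4, 5e5, by = 5e4)) {
  stopifnot(inherits(s, "structure_model"))
  n <- nrow(s$coords)
  if (n < 2) stop("at least 2 points required")
  D <- as.matrix(stats::dist(s$coords))
  ut <- upper.tri(D)
  dvals <- D[ut]
  if (any(dvals == 0)) {
    idx <- which(D == 0 & ut, arr.ind = TRUE)
    stop(sprintf("coincident points: bins %s and %s",
                 s$bin[idx[1, 1]], s$bin[idx[1, 2]]))
  }
  rg <- radius_of_gyration(s)
  inv <- rg / dvals
  gsep <- outer(s$pos_bp, s$pos_bp,
                function(a, b) if (s$circular)
                  circular_distance_raw(a, b, s$length_bp) else abs(a - b))
  gsep <- gsep[ut]
  # scales beyond the largest separation saturate at the all-pairs mean (GC)
  scales <- local_scales_bp
  lc <- vapply(scales, function(sc) {
    sel <- gsep <= sc
    if (!any(sel)) return(NA_real_)
    mean(inv[sel])
  }, 0)
  npair <- vapply(scales, function(sc) sum(gsep <= sc), 0L)
  list(gc = mean(inv),
       lc = data.frame(scale_bp = scales, lc = lc, n_pairs = npair),
       rg = rg)
}

# circular_distance without the range check (positions may equal L/2 exactly)
circular_distance_raw <- function(a, b, L) {
  d <- abs(a - b)
  pmin(d, L - d)
}

#' Spatial proximity test for protein-protein interaction pairs
#'
#' Maps each gene to the bin containing its midpoint, drops pairs mapping to
#' the same bin, and tests (one-sided Mann-Whitney) whether the spatial
#' distances of the PPI bin pairs are smaller than the distances of all
#' distinct valid bin pairs of the model.
#'
#' @param s a [structure_model()].
#' @param pairs two-column data frame or matrix: gene id pairs (if `genes`
#'   is supplied) or local 0-based bin pairs.
#' @param genes optional gene table used to map gene ids to midpoint bins.
#' @param bin_size_bp bin width used for the midpoint mapping (required with
#'   `genes`).
#' @return list with `median_ppi`, `median_all`, `p` (one-sided rank-sum),
#'   `n_pairs` (used), `n_same_bin` (dropped).
#' @export
ppi_distance_test <- function(s, pairs, genes = NULL, bin_size_bp = NULL) {
  stopifnot(inherits(s, "structure_model"))
  pairs <- as.matrix(pairs)
  if (ncol(pairs) < 2) stop("pairs must have two columns")
  if (!is.null(genes)) {
    if (is.null(bin_size_bp)) stop("bin_size_bp required to map genes to bins")
    unknown <- setdiff(unique(c(pairs[, 1], pairs[, 2])), genes$gene_id)
    if (length(unknown))
      stop("unknown gene ids: ", paste(utils::head(unknown, 5), collapse = ", "))
    mid <- (genes$start_bp + genes$end_bp) / 2
    gene_bin <- floor(mid / bin_size_bp)
    names(gene_bin) <- genes$gene_id
    b1 <- gene_bin[pairs[, 1]]
    b2 <- gene_bin[pairs[, 2]]
  } else {
    b1 <- as.integer(pairs[, 1]); b2 <- as.integer(pairs[, 2])
  }
  row_of <- match(b1, s$bin); row2 <- match(b2, s$bin)
  ok <- !is.na(row_of) & !is.na(row2)
  same <- ok & row_of == row2
  use <- ok & !same
  if (!any(use)) stop("no usable pairs after bin mapping")
  D <- as.matrix(stats::dist(s$coords))
  d_ppi <- D[cbind(row_of[use], row2[use])]
  d_all <- D[upper.tri(D)]
  wt <- stats::wilcox.test(d_ppi, d_all, alternative = "less", exact = FALSE)
  list(median_ppi = stats::median(d_ppi), median_all = stats::median(d_all),
       p = wt$p.value, n_pairs = sum(use), n_same_bin = sum(same))
}

#' Write / read structure coordinates as 4-column text
#'
#' Columns: `bin` (local 0-based), `x`, `y`, `z`, with a `#`-prefixed header
#' recording replicon, length and provenance.
#'
#' @param s a [structure_model()].
#' @param path file path.
#' @return `path` (write) / a [structure_model()] (read).
#' @export
write_structure <- function(s, path) {
  hdr <- sprintf("# replicon=%s length_bp=%g circular=%s provenance=%s model_id=%s",
                 s$replicon, s$length_bp, s$circular, s$provenance, s$model_id)
  lines <- sprintf("%d\t%.10g\t%.10g\t%.10g", s$bin, s$coords[, 1],
                   s$coords[, 2], s$coords[, 3])
  writeLines(c(hdr, "bin\tx\ty\tz", lines), path)
  invisible(path)
}

#' @rdname write_structure
#' @export
read_structure <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")][1]
  kv <- strsplit(strsplit(sub("^#\\s*", "", hdr), "\\s+")[[1]], "=")
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  structure_model(as.matrix(tab[, c("x", "y", "z")]),
                  replicon = meta[["replicon"]], bin = tab$bin,
                  length_bp = as.numeric(meta[["length_bp"]]),
                  circular = as.logical(meta[["circular"]]),
                  provenance = "imported", model_id = meta[["model_id"]])
}
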