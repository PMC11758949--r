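#' Define a replicon layout
#'
#' A replicon layout is the coordinate system of a (possibly multipartite)
#' bacterial genome: one record per replicon with its length and circularity.
#' Most bacterial replicons, including all four of *D. radiodurans*
#' (Chr1, Chr2, pMP1, pCP1), are circular.
#'
#' @param replicon_id character vector of unique replicon names.
#' @param length_bp integer vector of replicon lengths in base pairs (>= 1).
#' @param circular logical vector; is each replicon circular?
#' @return A `replicon_layout` data frame with columns `replicon_id`,
#'   `length_bp`, `circular`.
#' @examples
#' replicon_layout(c("Chr1", "Chr2"), c(2649000, 412000), c(TRUE, TRUE))
#' @export
replicon_layout <- function(replicon_id, length_bp, circular = TRUE) {
  replicon_id <- as.character(replicon_id)
  if (anyDuplicated(replicon_id))
    stop("replicon ids must be unique")
  if (length(length_bp) != length(replicon_id))
    stop("length_bp must match replicon_id in length")
  length_bp <- as.numeric(length_bp)
  if (any(!is.finite(length_bp)) || any(length_bp < 1))
    stop("replicon lengths must be >= 1 bp")
  circular <- rep_len(as.logical(circular), length(replicon_id))
  out <- data.frame(replicon_id = replicon_id, length_bp = length_bp,
                    circular = circular, stringsAsFactors = FALSE)
  class(out) <- c("replicon_layout", "data.frame")
  out
}

#' Default layout mirroring the D. radiodurans R1 genome
#'
#' Four circular replicons: the large chromosome Chr1 (2649 kb), the small
#' chromosome Chr2 (412 kb), the megaplasmid pMP1 (177 kb) and the small
#' plasmid pCP1 (46 kb). Used as the default genome for the synthetic-map
#' generator so fixture dimensions match the real study's scale.
#'
#' @return A [replicon_layout()].
#' @export
dr_genome_layout <- function() {
  replicon_layout(c("Chr1", "Chr2", "pMP1", "pCP1"),
                  c(2649000, 412000, 177000, 46000),
                  circular = TRUE)
}

#' Tile a genome into fixed-width bins
#'
#' Bins are 0-based half-open intervals `[start_bp, end_bp)` tiling each
#' replicon left to right without gaps; the last bin of a replicon may be
#' shorter. The global `bin_index` is contiguous across replicons in layout
#' order, so a genome-wide contact matrix concatenates replicons.
#'
#' @param layout a [replicon_layout()].
#' @param bin_size_bp bin width in bp (default 5000, the study resolution).
#' @return A `bin_table` data frame with columns `bin_index` (0-based),
#'   `replicon_id`, `start_bp`, `end_bp`, and attributes `bin_size_bp` and
#'   `layout`.
#' @examples
#' bins <- bin_genome(dr_genome_layout(), 5000)
#' table(bins$replicon_id)["Chr1"]  # 530 bins
#' @export
bin_genome <- function(layout, bin_size_bp = 5000) {
  stopifnot(inherits(layout, "replicon_layout"))
  bin_size_bp <- as.numeric(bin_size_bp)
  if (length(bin_size_bp) != 1 || !is.finite(bin_size_bp) || bin_size_bp < 1)
    stop("bin_size_bp must be a single positive number")
  pieces <- lapply(seq_len(nrow(layout)), function(k) {
    L <- layout$length_bp[k]
    n <- ceiling(L / bin_size_bp)
    start <- (seq_len(n) - 1) * bin_size_bp
    end <- pmin(start + bin_size_bp, L)
    data.frame(replicon_id = layout$replicon_id[k], start_bp = start,
               end_bp = end, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- cbind(bin_index = seq_len(nrow(out)) - 1L, out)
  attr(out, "bin_size_bp") <- bin_size_bp
  attr(out, "layout") <- layout
  class(out) <- c("bin_table", "data.frame")
  out
}

#' @export
print.bin_table <- function(x, ...) {
  cat(sprintf("bin_table: %d bins of %g bp over %d replicon(s)\n",
              nrow(x), attr(x, "bin_size_bp"),
              length(unique(x$replicon_id))))
  print.data.frame(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat(sprintf("... and %d more bins\n", nrow(x) - 6L))
  invisible(x)
}

bin_size_of <- function(bins) attr(bins, "bin_size_bp")
layout_of <- function(bins) attr(bins, "layout")

# 1-based row positions of a replicon's bins
replicon_rows <- function(bins, replicon) {
  rows <- which(bins$replicon_id == replicon)
  if (!length(rows)) stop("unknown replicon: ", replicon)
  rows
}

replicon_is_circular <- function(bins, replicon) {
  lay <- layout_of(bins)
  circ <- lay$circular[match(replicon, lay$replicon_id)]
  if (is.na(circ)) stop("unknown replicon: ", replicon)
  circ
}

replicon_length <- function(bins, replicon) {
  lay <- layout_of(bins)
  L <- lay$length_bp[match(replicon, lay$replicon_id)]
  if (is.na(L)) stop("unknown replicon: ", replicon)
  L
}

# midpoint (bp, local replicon coordinates) of each bin row
bin_midpoints <- function(bins) (bins$start_bp + bins$end_bp) / 2

# circular distance in bins between local 0-based bin offsets
circ_bin_dist <- function(i, j, n, circular = TRUE) {
  d <- abs(i - j)
  if (circular) pmin(d, n - d) else d
}

#' Read a replicon layout from a flat key-value (YAML) file
#'
#' Expected structure: a `replicons` list of records with `name`, `length`
#' and `circular` fields, plus an optional top-level `bin_size`.
#'
#' @param path file path.
#' @return a [replicon_layout()]; the file's `bin_size` (if any) is attached
#'   as attribute `bin_size_bp`.
#' @export
read_layout <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$replicons)) stop("layout file lacks a 'replicons' section")
  ids <- vapply(cfg$replicons, function(r) as.character(r$name), "")
  lens <- vapply(cfg$replicons, function(r) as.numeric(r$length), 0)
  circ <- vapply(cfg$replicons, function(r) isTRUE(r$circular), TRUE)
  out <- replicon_layout(ids, lens, circ)
  if (!is.null(cfg$bin_size)) attr(out, "bin_size_bp") <- as.numeric(cfg$bin_size)
  out
}
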