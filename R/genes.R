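#' Construct / read a gene table
#'
#' A gene table records `gene_id`, `replicon_id`, `start_bp`, `end_bp`
#' (0-based half-open), `strand`, and optionally `expression_value` (>= 0).
#' `read_genes()` accepts a tab-separated table with those column headers or
#' a GFF3 file (via rtracklayer; gene-type features are used and coordinates
#' converted to 0-based half-open).
#'
#' @param gene_id,replicon_id,start_bp,end_bp,strand,expression_value column
#'   vectors.
#' @param layout optional [replicon_layout()] used to validate coordinates.
#' @return A `gene_table` data frame.
#' @export
gene_table <- function(gene_id, replicon_id, start_bp, end_bp, strand = "+",
                       expression_value = NULL, layout = NULL) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop("gene ids must be unique")
  if (any(start_bp >= end_bp)) stop("gene start must be < end (half-open)")
  out <- data.frame(gene_id = gene_id,
                    replicon_id = as.character(replicon_id),
                    start_bp = as.numeric(start_bp),
                    end_bp = as.numeric(end_bp),
                    strand = rep_len(as.character(strand), length(gene_id)),
                    stringsAsFactors = FALSE)
  if (!is.null(expression_value)) {
    if (any(expression_value < 0, na.rm = TRUE))
      stop("expression values must be non-negative")
    out$expression_value <- as.numeric(expression_value)
  }
  if (!is.null(layout)) {
    L <- layout$length_bp[match(out$replicon_id, layout$replicon_id)]
    if (any(is.na(L))) stop("gene on unknown replicon")
    if (any(out$end_bp > L)) stop("gene coordinates exceed replicon length")
  }
  class(out) <- c("gene_table", "data.frame")
  out
}

#' @rdname gene_table
#' @param path file path for `read_genes()`.
#' @param format `"tsv"` (tab-separated with headers) or `"gff3"`.
#' @export
read_genes <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "replicon_id", "start_bp", "end_bp")
    if (!all(need %in% names(tab)))
      stop("gene table needs columns: ", paste(need, collapse = ", "))
    gene_table(tab$gene_id, tab$replicon_id, tab$start_bp, tab$end_bp,
               strand = if ("strand" %in% names(tab)) tab$strand else "+",
               expression_value = tab$expression_value)
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "gff3")
    df <- as.data.frame(gr)
    df <- df[df$type %in% c("gene", "CDS"), , drop = FALSE]
    ids <- if (!is.null(df$ID)) df$ID else df$Name
    gene_table(ids, as.character(df$seqnames), df$start - 1L, df$end,
               strand = as.character(df$strand))
  }
}

#' Construct / read a differentially-expressed-gene (DEG) table
#'
#' Records `gene_id`, `log2_fold_change`, `adjusted_p` and `direction`
#' (`"up"`/`"down"`, consistent with the sign of the fold change). The usual
#' filter (absolute fold change > 2, adjusted p < 0.05) is assumed applied
#' upstream by the differential-expression caller.
#'
#' @param gene_id,log2_fold_change,adjusted_p column vectors.
#' @return A `deg_table` data frame.
#' @export
deg_table <- function(gene_id, log2_fold_change, adjusted_p) {
  if (any(adjusted_p < 0 | adjusted_p > 1)) stop("adjusted p must be in [0,1]")
  direction <- ifelse(log2_fold_change >= 0, "up", "down")
  out <- data.frame(gene_id = as.character(gene_id),
                    log2_fold_change = as.numeric(log2_fold_change),
                    adjusted_p = as.numeric(adjusted_p),
                    direction = direction, stringsAsFactors = FALSE)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' @rdname deg_table
#' @param path tab-separated file with headers `gene_id`,
#'   `log2_fold_change`, `adjusted_p`.
#' @export
read_degs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2_fold_change", "adjusted_p")
  if (!all(need %in% names(tab)))
    stop("DEG table needs columns: ", paste(need, collapse = ", "))
  deg_table(tab$gene_id, tab$log2_fold_change, tab$adjusted_p)
}

#' Direction breakdown of a DEG table
#'
#' @param degs a [deg_table()].
#' @return data frame with `direction`, `n`, `percent` (of all DEGs).
#' @examples
#' d <- deg_table(paste0("g", 1:4), c(1.2, 2.1, -1.5, 3.0), rep(0.01, 4))
#' deg_direction_counts(d)
#' @export
deg_direction_counts <- function(degs) {
  n_up <- sum(degs$direction == "up")
  n_down <- sum(degs$direction == "down")
  total <- nrow(degs)
  data.frame(direction = c("up", "down"), n = c(n_up, n_down),
             percent = 100 * c(n_up, n_down) / total)
}

# length-weighted mean expression per bin of one replicon (NA where no gene)
bin_expression_track <- function(genes, bins, replicon) {
  rows <- replicon_rows(bins, replicon)
  n <- length(rows)
  s <- bin_size_of(bins)
  num <- den <- numeric(n)
  g <- genes[genes$replicon_id == replicon & !is.na(genes$expression_value), ,
             drop = FALSE]
  for (k in seq_len(nrow(g))) {
    b1 <- floor(g$start_bp[k] / s)
    b2 <- min(floor((g$end_bp[k] - 1) / s), n - 1)
    for (b in b1:b2) {
      lo <- max(g$start_bp[k], b * s)
      hi <- min(g$end_bp[k], (b + 1) * s)
      w <- hi - lo
      num[b + 1] <- num[b + 1] + w * g$expression_value[k]
      den[b + 1] <- den[b + 1] + w
    }
  }
  out <- rep(NA_real_, n)
  out[den > 0] <- num[den > 0] / den[den > 0]
  out
}
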