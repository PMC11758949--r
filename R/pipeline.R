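#' Read a pipeline configuration file
#'
#' Flat YAML with the keys used by [run_pipeline()]: `layout` (path to a
#' layout file) or an inline `replicons` section, `matrix` (path, triplet or
#' dense via `matrix_format`), optional `matrix2` for a second replicate,
#' `bin_size`, `min_coverage_quantile`, `norm`, `tol`, `di_scale`,
#' `min_run_bins`, `significance_alpha`, `min_count`, `window`, `step`,
#' `n_perm`, `seed`, `embed` (logical), `genes`/`degs`/`fasta` (paths,
#' optional), `outdir`.
#'
#' @param path YAML file.
#' @return named list of settings (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$config_dir <- dirname(normalizePath(path))
  class(cfg) <- "pipeline_config"
  cfg
}

cfg_default <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else cfg[[key]]
}

cfg_path <- function(cfg, key) {
  p <- cfg[[key]]
  if (is.null(p)) return(NULL)
  if (!file.exists(p) && !is.null(cfg$config_dir))
    p <- file.path(cfg$config_dir, p)
  p
}

#' Run the contact-map analysis pipeline end to end
#'
#' Stages: read (or simulate) the raw map, filter low-coverage bins, SCN
#' normalization, per-replicon DI and CID calling, distance-decay curves and
#' significant-contact detection, scalogram views, optional 3D embedding
#' with structure metrics, and (when gene/DEG tables are configured) the
#' integration analyses. Every output is written under `outdir` with a
#' manifest of files and checksums; a rerun with the same config and seed
#' is bit-identical for the deterministic stages.
#'
#' @param config a [read_pipeline_config()] list (or path to one).
#' @return manifest data frame (`file`, `md5`), invisibly; the manifest is
#'   also written to `outdir/manifest.tsv`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  outdir <- cfg_default(config, "outdir", "bact3c_out")
  seed <- cfg_default(config, "seed", 1)
  stage <- "validate"
  res <- tryCatch({
    mat_path <- cfg_path(config, "matrix")
    simulate <- isTRUE(config$simulate)
    if (!simulate && is.null(mat_path))
      stop("config lacks a 'matrix' path (or simulate: true)")
    if (!simulate && !file.exists(mat_path))
      stop("matrix file not found: ", mat_path)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

    stage <- "read"
    if (simulate) {
      spec <- truth_spec(seed = seed,
                         depth = cfg_default(config, "depth", 5e6))
      sim <- simulate_map(spec)
      map <- sim$map
      bins <- map$bins
      layout <- spec$layout
    } else {
      lay_path <- cfg_path(config, "layout")
      layout <- read_layout(lay_path)
      bin_size <- cfg_default(config, "bin_size",
                              cfg_default(attributes(layout), "bin_size_bp",
                                          5000))
      bins <- bin_genome(layout, bin_size)
      fmt <- cfg_default(config, "matrix_format", "triplet")
      map <- read_contacts(mat_path, bins, format = fmt)
      mat2 <- cfg_path(config, "matrix2")
      if (!is.null(mat2)) {
        rep2 <- read_contacts(mat2, bins, format = fmt)
        rc <- replicate_correlation(map, rep2)
        writeLines(sprintf("replicate_r\t%.6f\nn_pairs\t%d", rc$r,
                           rc$n_pairs), file.path(outdir, "replicates.tsv"))
        map <- merge_replicates(map, rep2)
      }
    }

    stage <- "filter"
    mask <- filter_bins(map, cfg_default(config, "min_coverage_quantile", 0))

    stage <- "normalize"
    nr <- scn_normalize(map, norm = cfg_default(config, "norm", "euclidean"),
                        tol = cfg_default(config, "tol", 1e-6), mask = mask)
    write_contacts(nr$matrix, file.path(outdir, "normalized.tsv"),
                   format = "triplet")
    writeLines(yaml::as.yaml(list(iterations = nr$iterations,
                                  residual = nr$residual,
                                  converged = nr$converged, seed = seed)),
               file.path(outdir, "normalize_log.yaml"))

    stage <- "domains"
    di_scale <- cfg_default(config, "di_scale", 1e5)
    boundary_sets <- list()
    for (r in layout$replicon_id) {
      n_r <- length(replicon_rows(bins, r))
      if (n_r * bin_size_of(bins) <= 2 * di_scale) next
      di <- directionality_index(map, r, scale_bp = di_scale)
      bs <- call_boundaries(di, min_run_bins = cfg_default(config,
                                                           "min_run_bins", 3))
      boundary_sets[[r]] <- bs
      utils::write.table(cbind(di[, c("bin", "di")]),
                         file.path(outdir, sprintf("di_%s.tsv", r)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(bs$boundaries,
                         file.path(outdir, sprintf("boundaries_%s.tsv", r)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(bs$cids,
                         file.path(outdir, sprintf("cids_%s.tsv", r)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    stage <- "significance"
    alpha <- cfg_default(config, "significance_alpha", 0.05)
    r1 <- layout$replicon_id[1]
    ps <- ps_curve(map, r1)
    utils::write.table(ps, file.path(outdir, sprintf("ps_%s.tsv", r1)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sig <- call_significant(map, r1, alpha = alpha,
                            min_count = cfg_default(config, "min_count", 2))
    utils::write.table(as.data.frame(sig),
                       file.path(outdir, sprintf("significant_%s.tsv", r1)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(sig)) {
      bands <- classify_distances(sig)
      utils::write.table(bands,
                         file.path(outdir, sprintf("distance_bands_%s.tsv", r1)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    stage <- "views"
    sg <- scalogram(nr$matrix, r1)
    utils::write.table(cbind(bin = seq_len(nrow(sg$halfwidth_bp)) - 1L,
                             sg$halfwidth_bp),
                       file.path(outdir, sprintf("scalogram_%s.tsv", r1)),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    if (isTRUE(cfg_default(config, "embed", FALSE))) {
      stage <- "structure"
      s <- embed_structure(nr$matrix, r1)
      write_structure(s, file.path(outdir, sprintf("structure_%s.tsv", r1)))
      cm <- compactness(s)
      writeLines(yaml::as.yaml(list(rg = radius_of_gyration(s), gc = cm$gc)),
                 file.path(outdir, sprintf("metrics_%s.yaml", r1)))
    }

    genes_path <- cfg_path(config, "genes")
    if (!is.null(genes_path)) {
      stage <- "integration"
      genes <- read_genes(genes_path)
      if (!is.null(boundary_sets[[r1]]) &&
          !is.null(genes$expression_value)) {
        labels <- classify_genes_by_boundary(genes, boundary_sets[[r1]])
        ft <- tryCatch(boundary_feature_test(labels, genes, "expression"),
                       error = function(e) NULL)
        if (!is.null(ft))
          writeLines(yaml::as.yaml(ft),
                     file.path(outdir, "boundary_expression_test.yaml"))
        dc <- diagonal_expression_correlation(nr$matrix, genes, r1)
        writeLines(yaml::as.yaml(dc),
                   file.path(outdir, "diagonal_correlation.yaml"))
      }
      degs_path <- cfg_path(config, "degs")
      if (!is.null(degs_path)) {
        degs <- read_degs(degs_path)
        we <- sliding_window_enrichment(
          degs, genes, r1, layout,
          window_bp = cfg_default(config, "window", 1e5),
          step_bp = cfg_default(config, "step", 5e3),
          n_perm = cfg_default(config, "n_perm", 999), seed = seed,
          boundaries = boundary_sets[[r1]])
        utils::write.table(as.data.frame(we),
                           file.path(outdir, "window_enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    TRUE
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  files <- list.files(outdir, full.names = TRUE, recursive = TRUE)
  files <- files[basename(files) != "manifest.tsv"]
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
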