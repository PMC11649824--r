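#' Read or write a gene-level expression table
#'
#' TSV with `gene_id`, one numeric column per sample, and a `mean` column
#' (recomputed on read if absent). Values are TPM-like, non-negative.
#'
#' @param path TSV file
#' @return data frame with unique `gene_id`, sample columns and `mean`
#' @export
read_expression <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  .stop_if(anyDuplicated(df$gene_id) > 0, "duplicate gene_id in expression table")
  num <- setdiff(names(df), "gene_id")
  .stop_if(any(df[num] < 0, na.rm = TRUE), "expression values must be >= 0")
  if (!"mean" %in% names(df))
    df$mean <- rowMeans(df[, num, drop = FALSE])
  df
}

#' @rdname read_expression
#' @param expression the expression data frame
#' @export
write_expression <- function(expression, path) {
  write.table(expression, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-position per-sample A/G mismatch counts
#'
#' Container for editing evidence: a position table plus aligned
#' `ref`/`alt` count matrices (positions x samples). `ref` counts the
#' transcript-sense reference base (A on `+`, T on `-`), `alt` the edited
#' base (G on `+`, C on `-`).
#'
#' @param positions data frame `chrom,pos,strand,ref_base`
#' @param ref,alt integer matrices, one column per sample
#' @return a list of class `editing_counts`
#' @export
editing_counts <- function(positions, ref, alt) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  .stop_if(nrow(ref) != nrow(positions) || nrow(alt) != nrow(positions),
           "count matrices must have one row per position")
  .stop_if(!identical(colnames(ref), colnames(alt)),
           "ref and alt must share sample columns")
  .stop_if(any(ref < 0) || any(alt < 0), "counts must be >= 0")
  structure(list(positions = positions, ref = ref, alt = alt,
                 samples = colnames(ref)),
            class = "editing_counts")
}

#' Read/write editing counts TSV
#'
#' Layout: `chrom, pos, strand, ref_base`, then `<sample>.ref` and
#' `<sample>.alt` column pairs.
#'
#' @param path TSV file
#' @return an [editing_counts()] object
#' @export
read_editing_counts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  refc <- grep("\\.ref$", names(df), value = TRUE)
  altc <- grep("\\.alt$", names(df), value = TRUE)
  samples <- sub("\\.ref$", "", refc)
  .stop_if(!setequal(samples, sub("\\.alt$", "", altc)),
           "mismatched .ref/.alt sample columns")
  ref <- as.matrix(df[paste0(samples, ".ref")])
  alt <- as.matrix(df[paste0(samples, ".alt")])
  colnames(ref) <- colnames(alt) <- samples
  editing_counts(df[c("chrom", "pos", "strand", "ref_base")], ref, alt)
}

#' @rdname read_editing_counts
#' @param counts an [editing_counts()] object
#' @export
write_editing_counts <- function(counts, path) {
  out <- counts$positions
  for (s in counts$samples) {
    out[[paste0(s, ".ref")]] <- counts$ref[, s]
    out[[paste0(s, ".alt")]] <- counts$alt[, s]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#' @param path TSV with columns `sample, condition, replicate`
#' @return the design data frame
#' @export
read_design <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  .stop_if(!all(c("sample", "condition", "replicate") %in% names(df)),
           "design needs sample, condition, replicate columns")
  df
}

#' Write/read a cell x gene UMI count matrix as MatrixMarket triplets
#'
#' `<prefix>.mtx` holds the sparse matrix, `<prefix>.cells.tsv` and
#' `<prefix>.genes.tsv` the dimension names.
#'
#' @param m a (sparse) matrix, cells in rows, genes in columns
#' @param prefix path prefix
#' @return the prefix, invisibly
#' @export
write_umi_matrix <- function(m, prefix) {
  sm <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                "generalMatrix"), "TsparseMatrix")
  Matrix::writeMM(sm, paste0(prefix, ".mtx"))
  writeLines(rownames(m), paste0(prefix, ".cells.tsv"))
  writeLines(colnames(m), paste0(prefix, ".genes.tsv"))
  invisible(prefix)
}

#' @rdname write_umi_matrix
#' @export
read_umi_matrix <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  rownames(m) <- readLines(paste0(prefix, ".cells.tsv"))
  colnames(m) <- readLines(paste0(prefix, ".genes.tsv"))
  m
}

#' Pipeline configuration with the study defaults
#'
#' Central registry of every tunable threshold and hyperparameter.
#' Defaults follow the established values of these assays where they
#' exist (TRIBE significance thresholds, iCLIP reproducibility quantile
#' and replicate support, window sizes, bin counts, fold count); the
#' remainder are documented package choices. Serializes losslessly to
#' JSON or YAML.
#'
#' @param ... named overrides of the defaults
#' @return a list of class `pipeline_config`
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    tribe = list(alpha = 0.01, fc_min = 1, ep_min = 0.01, min_reps = 2L),
    adar = list(n_adar_bins = 3L, n_expr_bins = 5L, fdr = 0.05,
                n_draws = 1000L, center_bin = 2L,
                max_iter = 200L, tol = 1e-6),
    iclip = list(quantile_q = 0.30, min_reps = 2L, extend = 4L,
                 min_nonzero_positions = 2L, keep_single_site_genes = TRUE),
    m6a = list(flank = 100L, max_shift = 20L),
    readers = list(seq_flank = 300L, label_window = 100L, folds = 5L,
                   top_n = 5000L, presence_window = 150L,
                   pwm_threshold = 0.8),
    stats = list(background_bins = 50L, exclusion_bp = 100L,
                 n_perm = 1000L, max_d = 500L, motif_max_d = 100L,
                 metagene_bins = 30L, coexpr_range = c(0.2, 0.8)))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  .validate_config(cfg)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

.validate_config <- function(cfg) {
  .stop_if(cfg$tribe$alpha <= 0 || cfg$tribe$alpha > 1, "alpha must be in (0,1]")
  .stop_if(cfg$iclip$quantile_q < 0 || cfg$iclip$quantile_q > 1,
           "quantile_q must be in [0,1]")
  .stop_if(cfg$adar$n_adar_bins < 2L, "need >= 2 ADAR bins")
  .stop_if(cfg$readers$folds < 2L, "need >= 2 folds")
  invisible(TRUE)
}

#' Read/write a pipeline configuration (JSON or YAML)
#' @param path file ending in `.json`, `.yml` or `.yaml`
#' @return a [pipeline_config()]
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param config a [pipeline_config()]
#' @export
write_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(unclass(config), path)
  else jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                            digits = NA, pretty = TRUE)
  invisible(path)
}
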