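#' Call candidate editing positions
#'
#' Retains positions with at least one mismatch (alt count > 0) in at
#' least one sample. Positions with an unknown reference base are skipped
#' with a warning.
#'
#' @param counts an [editing_counts()] object
#' @return the filtered [editing_counts()]
#' @export
call_candidate_positions <- function(counts) {
  known <- counts$positions$ref_base %in% c("A", "C", "G", "T")
  if (any(!known))
    warning(sum(!known), " positions with unknown reference base skipped")
  keep <- known & rowSums(counts$alt) > 0
  .subset_counts(counts, keep)
}

.subset_counts <- function(counts, keep) {
  out <- counts
  out$positions <- counts$positions[keep, , drop = FALSE]
  rownames(out$positions) <- NULL
  out$ref <- counts$ref[keep, , drop = FALSE]
  out$alt <- counts$alt[keep, , drop = FALSE]
  out
}

#' Filter candidates by strand-consistent mutation type
#'
#' Keeps A-to-G candidates on plus-strand genes and T-to-C candidates on
#' minus-strand genes (both are A-to-G in transcript space). Candidates
#' must carry a `gene_strand` column (see
#' [annotate_positions_to_genes()]); candidates without a gene are dropped
#' and counted in the `dropped_no_gene` attribute.
#'
#' @param counts an [editing_counts()] whose `positions` include
#'   `gene_strand`
#' @return the filtered [editing_counts()]
#' @export
filter_by_strand_mutation <- function(counts) {
  p <- counts$positions
  .stop_if(is.null(p$gene_strand),
           "candidates must be annotated with containing-gene strand first")
  no_gene <- is.na(p$gene_strand)
  keep <- !no_gene &
    ((p$gene_strand == "+" & p$ref_base == "A") |
       (p$gene_strand == "-" & p$ref_base == "T"))
  out <- .subset_counts(counts, keep)
  attr(out, "dropped_no_gene") <- sum(no_gene)
  out
}

#' Filter candidates by replicate agreement
#'
#' Keeps positions whose alt count is positive in at least `min_reps`
#' fusion samples.
#'
#' @param counts an [editing_counts()]
#' @param design design data frame (`sample, condition, replicate`) with
#'   conditions `fusion` and `control`
#' @param min_reps minimum supporting fusion replicates (default 2)
#' @return the filtered [editing_counts()]
#' @export
filter_replicate_agreement <- function(counts, design, min_reps = 2L) {
  fusion <- design$sample[design$condition == "fusion"]
  .stop_if(min_reps > length(fusion),
           "min_reps exceeds the number of fusion replicates")
  support <- rowSums(counts$alt[, fusion, drop = FALSE] > 0)
  .subset_counts(counts, support >= min_reps)
}

#' Assign editing positions to genes
#'
#' Positions are assigned to the overlapping representative gene model;
#' when several representative models overlap a position, the gene with
#' the higher control-line expression wins. Unassigned positions are
#' retained with `NA` gene.
#'
#' @param counts an [editing_counts()]
#' @param annotation a [transcript_annotation()]
#' @param expression expression table with `gene_id` and `mean` (used for
#'   tie-breaking; optional)
#' @return `counts` with `gene_id` and `gene_strand` position columns
#' @export
annotate_positions_to_genes <- function(counts, annotation, expression = NULL) {
  gr_p <- GenomicRanges::GRanges(
    counts$positions$chrom,
    IRanges::IRanges(counts$positions$pos + 1L, width = 1L), strand = "*")
  gg <- .gene_gr(annotation)
  hits <- GenomicRanges::findOverlaps(gr_p, gg, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  if (length(q) && !is.null(expression)) {
    ex <- expression$mean[match(gg$gene_id[s], expression$gene_id)]
    ex[is.na(ex)] <- 0
    o <- order(q, -ex)
    q <- q[o]; s <- s[o]
  }
  first <- !duplicated(q)
  q <- q[first]; s <- s[first]
  n <- nrow(counts$positions)
  gene_id <- rep(NA_character_, n); gene_strand <- rep(NA_character_, n)
  gene_id[q] <- gg$gene_id[s]
  gene_strand[q] <- as.character(GenomicRanges::strand(gg))[s]
  out <- counts
  out$positions$gene_id <- gene_id
  out$positions$gene_strand <- gene_strand
  out
}

# closed-form binomial likelihood-ratio statistic on a pooled 2x2 table
# (alt_f, ref_f, alt_c, ref_c); equivalent to the condition-term LRT of a
# binomial logistic GLM with pooled replicate counts
.lrt_2x2 <- function(alt_f, ref_f, alt_c, ref_c) {
  n_f <- alt_f + ref_f; n_c <- alt_c + ref_c
  p_f <- alt_f / n_f; p_c <- alt_c / n_c
  p_0 <- (alt_f + alt_c) / (n_f + n_c)
  term <- function(y, n, p) {
    out <- numeric(length(y))
    i <- y > 0; out[i] <- y[i] * log(y[i] / (n[i] * p[i]))
    j <- (n - y) > 0
    out[j] <- out[j] + (n - y)[j] * log((n - y)[j] / (n[j] * (1 - p[j])))
    out
  }
  2 * (term(alt_f, n_f, p_0) + term(alt_c, n_c, p_0))
}

#' Test differential editing between fusion and control samples
#'
#' Per position, a likelihood-ratio test of the condition term in a
#' binomial logistic model on pooled replicate counts, followed by
#' Benjamini-Hochberg adjustment across all tested positions. A position
#' is significant when the adjusted p-value is below `alpha`, the log2
#' fold-change of pooled editing proportions exceeds `fc_min`, and the
#' larger pooled editing proportion is at least `ep_min` (defaults: 0.01,
#' 1, 0.01). Fold-changes use a pseudo-proportion floor of
#' `1/(condition depth + 2)` to avoid log(0). Positions with zero depth in
#' either condition are flagged `untested`.
#'
#' @param counts an [editing_counts()]
#' @param design design data frame with conditions `fusion` and `control`
#'   (both require >= 2 samples)
#' @param alpha,fc_min,ep_min significance thresholds
#' @return data frame of class `editing_test`: position columns plus
#'   `ep_fusion`, `ep_control`, `log2fc`, `p`, `adj_p`, `significant`,
#'   `untested`
#' @export
test_differential_editing <- function(counts, design, alpha = 0.01,
                                      fc_min = 1, ep_min = 0.01) {
  fusion <- design$sample[design$condition == "fusion"]
  control <- design$sample[design$condition == "control"]
  .stop_if(length(fusion) < 2L || length(control) < 2L,
           "both conditions require >= 2 samples")
  alt_f <- rowSums(counts$alt[, fusion, drop = FALSE])
  ref_f <- rowSums(counts$ref[, fusion, drop = FALSE])
  alt_c <- rowSums(counts$alt[, control, drop = FALSE])
  ref_c <- rowSums(counts$ref[, control, drop = FALSE])
  n_f <- alt_f + ref_f; n_c <- alt_c + ref_c
  untested <- n_f == 0 | n_c == 0
  ep_f <- ifelse(n_f > 0, alt_f / n_f, NA_real_)
  ep_c <- ifelse(n_c > 0, alt_c / n_c, NA_real_)
  pf <- pmax(ep_f, 1 / (n_f + 2))
  pc <- pmax(ep_c, 1 / (n_c + 2))
  log2fc <- log2(pf / pc)
  p <- rep(NA_real_, length(n_f))
  ok <- !untested
  stat <- .lrt_2x2(alt_f[ok], ref_f[ok], alt_c[ok], ref_c[ok])
  p[ok] <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  adj_p <- rep(NA_real_, length(p))
  adj_p[ok] <- stats::p.adjust(p[ok], method = "BH")
  significant <- !untested & adj_p < alpha & log2fc > fc_min &
    pmax(ep_f, ep_c) >= ep_min
  out <- cbind(counts$positions,
               data.frame(ep_fusion = ep_f, ep_control = ep_c,
                          log2fc = log2fc, p = p, adj_p = adj_p,
                          significant = significant, untested = untested))
  class(out) <- c("editing_test", "data.frame")
  out
}

#' Genes with at least one significant editing position
#' @param results an `editing_test` data frame carrying `gene_id`
#' @return sorted character vector of target genes
#' @export
tribe_targets <- function(results) {
  .stop_if(is.null(results$gene_id), "results carry no gene_id; annotate first")
  sort(unique(results$gene_id[results$significant & !is.na(results$gene_id)]))
}
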