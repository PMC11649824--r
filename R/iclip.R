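#' Merge directly adjacent called peaks into summits
#'
#' Maximal runs of consecutive positions (genomic distance exactly 1,
#' same chromosome and strand) collapse to the position with the highest
#' peak-caller score; ties go to the leftmost position.
#'
#' @param peaks a `site_records` of called peaks (score = caller score)
#' @return a `site_records` of summits
#' @export
merge_adjacent_peaks <- function(peaks) {
  .stop_if(anyDuplicated(peaks[c("chrom", "pos", "strand")]) > 0,
           "duplicate peak positions")
  s <- sort_sites(peaks)
  newrun <- c(TRUE, !(s$chrom[-1] == s$chrom[-nrow(s)] &
                        s$strand[-1] == s$strand[-nrow(s)] &
                        s$pos[-1] == s$pos[-nrow(s)] + 1L))
  run <- cumsum(newrun)
  # leftmost max per run: order by run, then -score, then pos; take first
  o <- order(run, -s$score, s$pos)
  first <- o[!duplicated(run[o])]
  sort_sites(.as_site_records(s[sort(first), , drop = FALSE]))
}

# named total-count lookup per replicate: list of named numeric vectors
.xlink_lookup <- function(xlinks) {
  reps <- sort(unique(xlinks$sample_id))
  lapply(stats::setNames(reps, reps), function(r) {
    sub <- xlinks[xlinks$sample_id == r, , drop = FALSE]
    key <- paste(sub$chrom, sub$strand, sub$pos)
    tot <- rowsum(sub$score, key)
    stats::setNames(drop(tot), rownames(tot))
  })
}

#' Define 9-nt binding sites around summits and tally crosslinks
#'
#' Each summit is extended by 4 nt in both directions (positions
#' `summit-4 ... summit+4`, a 9-nt half-open interval
#' `[summit-4, summit+5)`). Per-replicate crosslink counts are tallied at
#' each of the 9 positions. Summits within 4 nt of a chromosome edge are
#' excluded (flagged in the `truncated` attribute).
#'
#' @param summits a `site_records` of summits (e.g. from
#'   [merge_adjacent_peaks()])
#' @param xlinks crosslink `site_records` with `sample_id` = replicate and
#'   `score` = crosslink count
#' @param chrom_lengths optional named vector for right-edge truncation
#' @return an object of class `binding_sites`: `sites` data frame
#'   (`chrom, summit, strand, start, end, score`), `rep_totals`
#'   (sites x replicates), `pos_counts` (sites x 9, replicate-pooled)
#' @export
define_binding_sites <- function(summits, xlinks, chrom_lengths = NULL) {
  ok <- summits$pos >= 4L
  if (!is.null(chrom_lengths))
    ok <- ok & summits$pos + 5L <= chrom_lengths[summits$chrom]
  truncated <- sum(!ok)
  s <- summits[ok, , drop = FALSE]
  lk <- .xlink_lookup(xlinks)
  reps <- names(lk)
  n <- nrow(s)
  pos_counts <- matrix(0, n, 9L, dimnames = list(NULL, as.character(-4:4)))
  rep_totals <- matrix(0, n, length(reps), dimnames = list(NULL, reps))
  for (r in reps) {
    v <- lk[[r]]
    for (o in -4:4) {
      key <- paste(s$chrom, s$strand, s$pos + o)
      cnt <- v[key]
      cnt[is.na(cnt)] <- 0
      pos_counts[, as.character(o)] <- pos_counts[, as.character(o)] + cnt
      rep_totals[, r] <- rep_totals[, r] + cnt
    }
  }
  out <- list(sites = data.frame(chrom = s$chrom, summit = s$pos,
                                 strand = s$strand, start = s$pos - 4L,
                                 end = s$pos + 5L, score = s$score,
                                 stringsAsFactors = FALSE),
              rep_totals = rep_totals, pos_counts = pos_counts,
              replicates = reps)
  attr(out, "truncated") <- truncated
  class(out) <- "binding_sites"
  out
}

#' @export
print.binding_sites <- function(x, ...) {
  cat(sprintf("%d binding sites (9 nt), %d replicates\n",
              nrow(x$sites), length(x$replicates)))
  invisible(x)
}

.subset_bs <- function(bs, keep) {
  bs$sites <- bs$sites[keep, , drop = FALSE]
  rownames(bs$sites) <- NULL
  bs$rep_totals <- bs$rep_totals[keep, , drop = FALSE]
  bs$pos_counts <- bs$pos_counts[keep, , drop = FALSE]
  bs
}

#' Remove single-position artifacts
#'
#' Sites whose replicate-pooled crosslinks fall on fewer than 2 of the 9
#' positions are removed (crosslinks at only 1 of 9 positions are
#' considered artifacts; zero-count sites are removed too).
#'
#' @param bs a `binding_sites` object
#' @param min_positions minimum occupied positions (default 2)
#' @return the filtered `binding_sites`
#' @export
remove_single_position_artifacts <- function(bs, min_positions = 2L) {
  .subset_bs(bs, rowSums(bs$pos_counts > 0) >= min_positions)
}

#' Reproducibility filter on per-replicate crosslink support
#'
#' For each replicate the threshold is the `q`-quantile (default 30%,
#' linear-interpolation quantile) of that replicate's distribution of
#' per-site crosslink totals; a site is kept when it is strictly above
#' the threshold in at least `min_reps` replicates (default 2).
#'
#' @param bs a `binding_sites` object
#' @param q quantile defining the minimal filtering threshold
#' @param min_reps minimum supporting replicates
#' @return the filtered `binding_sites`
#' @export
reproducibility_filter <- function(bs, q = 0.30, min_reps = 2L) {
  .stop_if(min_reps > length(bs$replicates),
           "min_reps exceeds the number of replicates")
  thr <- apply(bs$rep_totals, 2, stats::quantile, probs = q, names = FALSE)
  support <- rowSums(sweep(bs$rep_totals, 2, thr, `>`))
  .subset_bs(bs, support >= min_reps)
}

.bs_gr <- function(bs) {
  GenomicRanges::GRanges(bs$sites$chrom,
                         IRanges::IRanges(bs$sites$start + 1L, bs$sites$end),
                         strand = bs$sites$strand)
}

#' Subtract control binding sites
#'
#' Removes any site whose 9-nt interval shares at least one nucleotide
#' with a control site interval on the same strand.
#'
#' @param bs a `binding_sites` object
#' @param control a `binding_sites` object from the control channel
#' @return the filtered `binding_sites`
#' @export
subtract_control_sites <- function(bs, control) {
  if (nrow(control$sites) == 0L) return(bs)
  hits <- GenomicRanges::findOverlaps(.bs_gr(bs), .bs_gr(control))
  keep <- !(seq_len(nrow(bs$sites)) %in% S4Vectors::queryHits(hits))
  .subset_bs(bs, keep)
}

#' Assign binding sites to target genes
#'
#' Targets are the genes whose representative model overlaps at least one
#' surviving binding site (strand-matched). Also records each site's gene
#' in `bs$sites$gene_id` (first overlapping gene; `NA` if intergenic).
#'
#' @param bs a `binding_sites` object
#' @param annotation a [transcript_annotation()]
#' @return list with `targets` (sorted gene ids) and `bs` (annotated)
#' @export
assign_targets <- function(bs, annotation) {
  gg <- .gene_gr(annotation)
  hits <- GenomicRanges::findOverlaps(.bs_gr(bs), gg)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  first <- !duplicated(q)
  gene_id <- rep(NA_character_, nrow(bs$sites))
  gene_id[q[first]] <- gg$gene_id[s[first]]
  bs$sites$gene_id <- gene_id
  list(targets = sort(unique(gg$gene_id[s])), bs = bs)
}

#' Keep strong peaks: score above the per-gene median
#'
#' Within each gene, sites with a score strictly greater than that gene's
#' median site score are kept. Genes with a single site keep it by
#' default (the median is not a discriminator there); set
#' `keep_single = FALSE` for the strict rule.
#'
#' @param bs a `binding_sites` object with `gene_id` assigned
#' @param keep_single keep the only site of single-site genes
#' @return the filtered `binding_sites`
#' @export
strong_peak_filter <- function(bs, keep_single = TRUE) {
  .stop_if(is.null(bs$sites$gene_id), "sites carry no gene_id; assign first")
  g <- bs$sites$gene_id
  med <- stats::ave(bs$sites$score, g, FUN = stats::median)
  nsite <- stats::ave(bs$sites$score, g, FUN = length)
  keep <- !is.na(g) & (bs$sites$score > med |
                         (keep_single & nsite == 1L))
  .subset_bs(bs, keep)
}

#' Run the full iCLIP binding-site cascade
#'
#' Summit merging, 9-nt site definition with crosslink tallies,
#' single-position artifact removal, quantile reproducibility filtering,
#' control subtraction (the control channel is built the same way but is
#' not reproducibility-filtered) and target assignment.
#'
#' @param peaks called peaks (`site_records`)
#' @param xlinks replicate crosslinks (`site_records`, `sample_id` =
#'   replicate)
#' @param control_peaks,control_xlinks the control channel
#' @param annotation a [transcript_annotation()]
#' @param q,min_reps reproducibility parameters
#' @return list with `bs` (surviving `binding_sites`, gene-annotated) and
#'   `targets`
#' @export
iclip_pipeline <- function(peaks, xlinks, control_peaks, control_xlinks,
                           annotation, q = 0.30, min_reps = 2L) {
  bs <- define_binding_sites(merge_adjacent_peaks(peaks), xlinks)
  bs <- remove_single_position_artifacts(bs)
  bs <- reproducibility_filter(bs, q = q, min_reps = min_reps)
  if (nrow(control_peaks) > 0L) {
    cbs <- define_binding_sites(merge_adjacent_peaks(control_peaks),
                                control_xlinks)
    cbs <- remove_single_position_artifacts(cbs)
    bs <- subtract_control_sites(bs, cbs)
  }
  at <- assign_targets(bs, annotation)
  list(bs = at$bs, targets = at$targets)
}

#' Write binding sites as 9-nt BED intervals (summit in the name field)
#' @param bs a `binding_sites` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_binding_sites <- function(bs, path) {
  write_intervals(data.frame(chrom = bs$sites$chrom, start = bs$sites$start,
                             end = bs$sites$end,
                             name = sprintf("summit:%d", bs$sites$summit),
                             score = bs$sites$score,
                             strand = bs$sites$strand), path)
}
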