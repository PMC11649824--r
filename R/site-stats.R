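#' Construct a feature/position-matched background site set
#'
#' Pairs every true site with a background position in the same feature
#' type (5'UTR/CDS/3'UTR) at the same relative-position bin along the
#' feature (default 50 bins), drawn from a pool of genes — by default the
#' genes of the true set, or an expression-matched gene pool. Candidates
#' falling within `exclusion_bp` of any true site are rejected and
#' resampled, so the background's feature/bin histogram equals the true
#' set's exactly while avoiding the true sites themselves.
#'
#' @param true_sites `site_records`
#' @param annotation a [transcript_annotation()]
#' @param expression expression table (required when
#'   `expression_matched = TRUE`)
#' @param exclusion_bp minimum distance to any true site (default 100)
#' @param expression_matched draw the gene pool to match the expression
#'   distribution of the true genes instead of using them directly
#' @param bins relative-position bins per feature (default 50)
#' @param seed RNG seed
#' @param max_resample resampling attempts per site before erroring
#' @return list of class `background_set`: `background` (`site_records`),
#'   `pairs` (true index, feature, bin)
#' @export
matched_background <- function(true_sites, annotation, expression = NULL,
                               exclusion_bp = 100L,
                               expression_matched = FALSE, bins = 50L,
                               seed = 1L, max_resample = 1000L) {
  set.seed(seed)
  loc <- locate_sites(true_sites, annotation)
  ok <- !is.na(loc$feature)
  .stop_if(!all(ok), sum(!ok), " true sites not assignable to features")
  # integer bin arithmetic avoids float boundary noise
  bin <- pmin((loc$feature_offset * bins) %/% loc$feature_length,
              bins - 1L)
  pool <- unique(loc$gene_id)
  if (expression_matched) {
    .stop_if(is.null(expression), "expression required for matched pool")
    ex <- stats::setNames(expression$mean, expression$gene_id)
    br <- unique(stats::quantile(ex[pool], seq(0, 1, 0.1), na.rm = TRUE))
    br[1] <- -Inf; br[length(br)] <- Inf
    want <- table(cut(ex[pool], br))
    univ <- setdiff(names(ex), character(0))
    ub <- cut(ex[univ], br)
    pool <- unlist(lapply(seq_along(want), function(b) {
      cand <- univ[which(as.integer(ub) == b)]
      sample(cand, min(want[b], length(cand)))
    }))
  }
  # per (feature) lookup of pool genes that have the feature
  feat_genes <- lapply(c(utr5 = "utr5", cds = "cds", utr3 = "utr3"),
                       function(f) intersect(pool,
                                             annotation$gene_id[annotation$feature == f]))
  true_by_chrom <- split(true_sites$pos, true_sites$chrom)
  n <- nrow(true_sites)
  bchrom <- character(n); bpos <- integer(n); bstrand <- character(n)
  for (i in seq_len(n)) {
    f <- loc$feature[i]
    cand_genes <- feat_genes[[f]]
    .stop_if(length(cand_genes) == 0L,
             "no pool gene with feature ", f)
    placed <- FALSE
    for (tries in seq_len(max_resample)) {
      g <- cand_genes[sample.int(length(cand_genes), 1L)]
      sub <- annotation[annotation$gene_id == g &
                          annotation$feature == f, , drop = FALSE][1L, ]
      flen <- sub$end - sub$start
      # offsets whose relative position falls exactly in the target bin
      lo_off <- (bin[i] * flen + bins - 1L) %/% bins
      hi_off <- min(((bin[i] + 1L) * flen + bins - 1L) %/% bins - 1L,
                    flen - 1L)
      if (lo_off > hi_off) next   # feature too short for this bin
      off <- if (lo_off == hi_off) lo_off else
        sample(lo_off:hi_off, 1L)
      pos <- if (sub$strand == "+") sub$start + off
      else sub$end - 1L - off
      tp <- true_by_chrom[[sub$chrom]]
      if (!is.null(tp) && length(tp) && min(abs(tp - pos)) <= exclusion_bp)
        next
      bchrom[i] <- sub$chrom; bpos[i] <- pos; bstrand[i] <- sub$strand
      placed <- TRUE
      break
    }
    .stop_if(!placed,
             sprintf("no eligible background position for feature %s bin %d after %d attempts",
                     f, bin[i], max_resample))
  }
  bg <- site_records(chrom = bchrom, pos = bpos, strand = bstrand,
                     score = 0, sample_id = "")
  structure(list(background = bg,
                 pairs = data.frame(true_index = seq_len(n),
                                    feature = loc$feature, bin = bin)),
            class = "background_set")
}

#' Distance profile of query sites around anchor sites
#'
#' For every anchor, queries at each signed offset within `max_d` are
#' tallied (transcript orientation: negative = 5' of the anchor, so
#' minus-strand anchors are flipped); counts are also normalized per 1000
#' anchors. Only same-strand, same-chromosome pairs count.
#'
#' @param query_sites,anchor_sites `site_records`
#' @param max_d maximum absolute offset (default 500)
#' @param background_anchors optional matched anchor set profiled the
#'   same way
#' @return data frame of class `distance_profile`: `offset`, `count`,
#'   `per_1000` (+ `bg_count`, `bg_per_1000` when background given)
#' @export
distance_profile <- function(query_sites, anchor_sites, max_d = 500L,
                             background_anchors = NULL) {
  prof <- function(anchors) {
    counts <- integer(2L * max_d + 1L)
    gr_a <- GenomicRanges::resize(.sites_gr(anchors), 2L * max_d + 1L,
                                  fix = "center")
    hits <- GenomicRanges::findOverlaps(.sites_gr(query_sites), gr_a)
    q <- S4Vectors::queryHits(hits); a <- S4Vectors::subjectHits(hits)
    if (length(q)) {
      d <- query_sites$pos[q] - anchors$pos[a]
      d <- ifelse(anchors$strand[a] == "-", -d, d)
      tb <- table(factor(d, levels = -max_d:max_d))
      counts <- as.integer(tb)
    }
    counts
  }
  n_a <- nrow(anchor_sites)
  out <- data.frame(offset = -max_d:max_d, count = prof(anchor_sites))
  out$per_1000 <- 1000 * out$count / n_a
  if (!is.null(background_anchors)) {
    out$bg_count <- prof(background_anchors)
    out$bg_per_1000 <- 1000 * out$bg_count / nrow(background_anchors)
  }
  class(out) <- c("distance_profile", "data.frame")
  out
}

#' Motif occurrence profiles around anchor sites
#'
#' Counts literal motif occurrences (anchored at the match start,
#' transcript orientation) per offset within `max_d` of each anchor,
#' normalized per 1000 anchors.
#'
#' @param motifs character vector of literal patterns over `ACGTU`
#' @param anchor_sites `site_records`
#' @param genome a [Biostrings::DNAStringSet]
#' @param max_d maximum offset (default 100)
#' @param background_anchors optional matched anchors
#' @return named list of `distance_profile` data frames, one per motif
#' @export
motif_occurrence_profile <- function(motifs, anchor_sites, genome,
                                     max_d = 100L,
                                     background_anchors = NULL) {
  motifs <- chartr("U", "T", toupper(motifs))
  .stop_if(any(grepl("[^ACGT]", motifs)), "patterns must be over A/C/G/T/U")
  prof_one <- function(motif, anchors) {
    k <- nchar(motif)
    flank <- max_d + k - 1L
    seqs <- extract_window(genome, anchors$chrom, anchors$pos,
                           anchors$strand, flank)
    counts <- integer(2L * max_d + 1L)
    starts <- gregexpr(motif, seqs, fixed = TRUE)
    for (st in starts) {
      if (st[1] == -1L) next
      off <- as.integer(st) - (flank + 1L)      # match start vs anchor
      off <- off[abs(off) <= max_d]
      if (length(off))
        counts <- counts + as.integer(table(factor(off,
                                                   levels = -max_d:max_d)))
    }
    counts
  }
  stats::setNames(lapply(motifs, function(m) {
    out <- data.frame(offset = -max_d:max_d,
                      count = prof_one(m, anchor_sites))
    out$per_1000 <- 1000 * out$count / nrow(anchor_sites)
    if (!is.null(background_anchors)) {
      out$bg_count <- prof_one(m, background_anchors)
      out$bg_per_1000 <- 1000 * out$bg_count / nrow(background_anchors)
    }
    class(out) <- c("distance_profile", "data.frame")
    out
  }), motifs)
}

#' Scaled metagene profile over 5'UTR/CDS/3'UTR
#'
#' Maps each site to (feature, relative position in `[0,1)`) and
#' histograms the relative positions per feature over equal-width bins.
#' Unassignable sites are counted separately.
#'
#' @param sites `site_records`
#' @param annotation a [transcript_annotation()]
#' @param bins_per_feature histogram bins per feature (default 30)
#' @return list of class `metagene_profile`: `histogram` (data frame
#'   `feature, bin_mid, count, density`), `n_unassigned`, `n_sites`
#' @export
metagene_profile <- function(sites, annotation, bins_per_feature = 30L) {
  loc <- locate_sites(sites, annotation)
  ok <- !is.na(loc$feature) & !is.na(loc$frac)
  zl <- !is.na(loc$feature) & (is.na(loc$feature_length) |
                                 loc$feature_length == 0L)
  if (any(zl)) warning(sum(zl), " sites in zero-length features skipped")
  br <- seq(0, 1, length.out = bins_per_feature + 1L)
  rows <- lapply(c("utr5", "cds", "utr3"), function(f) {
    fr <- loc$frac[ok & loc$feature == f]
    cnt <- as.integer(table(cut(fr, br, right = FALSE,
                                include.lowest = TRUE)))
    data.frame(feature = f, bin_mid = (head(br, -1) + tail(br, -1)) / 2,
               count = cnt,
               density = cnt * bins_per_feature / max(1L, length(fr)))
  })
  structure(list(histogram = do.call(rbind, rows),
                 n_unassigned = sum(!ok & !zl), n_sites = nrow(sites)),
            class = "metagene_profile")
}

# folded permutation p-value, as printed: p = 1 - 2*(|hsum - n/2|/n)
.perm_p <- function(hsum, n_perm) 1 - 2 * (abs(hsum - n_perm / 2) / n_perm)

#' Permutation test of gene-set overlap with expression matching
#'
#' Draws `n_perm` random gene sets of size `|A|` from the universe with
#' the expression distribution of set A (stratified over A's expression
#' deciles), counts how often the random set overlaps set B more than A
#' does (`hsum`), and computes the folded permutation p-value
#' `p = 1 - 2 * (|hsum - n_perm/2| / n_perm)`. When no random set beats
#' the observed overlap (`hsum = 0`) the p-value is reported as the
#' sentinel `"<0.001"` (scaled to `n_perm`). One random matched set is
#' returned for Venn-style display of the expected chance overlap.
#'
#' @param setA,setB character gene sets (subsets of `universe`)
#' @param universe all eligible genes
#' @param expression expression table (`gene_id`, `mean`) covering the
#'   universe; `NULL` disables expression matching
#' @param n_perm permutations (default 1000)
#' @param seed RNG seed
#' @return list of class `overlap_test`: sizes, `observed`, `hsum`, `p`
#'   (numeric), `p_label` (may be the sentinel), `direction`,
#'   `example_set`
#' @export
overlap_permutation_test <- function(setA, setB, universe,
                                     expression = NULL, n_perm = 1000L,
                                     seed = 1L) {
  .stop_if(length(setA) > length(universe), "|A| exceeds the universe")
  .stop_if(!all(setA %in% universe) || !all(setB %in% universe),
           "setA and setB must be subsets of the universe")
  set.seed(seed)
  observed <- length(intersect(setA, setB))
  draw <- if (is.null(expression)) {
    function() sample(universe, length(setA))
  } else {
    ex <- stats::setNames(expression$mean, expression$gene_id)
    .stop_if(!all(universe %in% names(ex)),
             "expression must cover the universe")
    br <- unique(stats::quantile(ex[setA], seq(0, 1, 0.1)))
    br[1] <- -Inf; br[length(br)] <- Inf
    binA <- cut(ex[setA], br)
    binU <- cut(ex[universe], br)
    want <- table(binA)
    by_bin <- split(universe, binU)
    function() {
      unlist(lapply(names(want), function(b) {
        cand <- by_bin[[b]]
        k <- want[[b]]
        if (k == 0L) return(character(0))
        if (length(cand) >= k) sample(cand, k)
        else sample(universe, k)      # degenerate bin fallback
      }), use.names = FALSE)
    }
  }
  overlaps <- integer(n_perm)
  example_set <- NULL
  for (r in seq_len(n_perm)) {
    rs <- draw()
    if (r == 1L) example_set <- rs
    overlaps[r] <- length(intersect(rs, setB))
  }
  hsum <- sum(overlaps > observed)
  p <- .perm_p(hsum, n_perm)
  p_label <- if (hsum == 0L) sprintf("<%g", 1 / n_perm) else
    formatC(p, format = "g")
  structure(list(nA = length(setA), nB = length(setB),
                 n_universe = length(universe), observed = observed,
                 hsum = hsum, n_perm = n_perm, p = p, p_label = p_label,
                 direction = if (hsum < n_perm / 2) "enriched" else "depleted",
                 mean_random_overlap = mean(overlaps),
                 example_set = example_set),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("overlap test: |A|=%d |B|=%d observed=%d (chance mean %.1f)\n",
              x$nA, x$nB, x$observed, x$mean_random_overlap))
  cat(sprintf("  hsum=%d of %d permutations, p %s (%s)\n", x$hsum,
              x$n_perm, x$p_label, x$direction))
  invisible(x)
}

#' Strict and permissive target-set algebra
#'
#' The strict set is the intersection of two target-gene sets (e.g.
#' strong iCLIP targets with TRIBE targets); the permissive set is their
#' union.
#'
#' @param setA,setB character gene sets
#' @param mode `"strict"` (intersection) or `"permissive"` (union)
#' @return sorted character gene set
#' @export
define_target_sets <- function(setA, setB, mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  if (mode == "strict") sort(intersect(setA, setB))
  else sort(union(setA, setB))
}

#' Single-cell co-expression with an anchor gene by Fisher's exact test
#'
#' Anchor-positive cells are greedily matched 1:1 to the anchor-negative
#' cell of nearest total UMI count (without replacement; unmatched
#' anchor-positive cells are dropped and counted). For each gene
#' expressed in 20-80% of the matched cells, a 2x2 table of
#' (gene+/gene-) x (anchor+/anchor-) gives a Fisher odds ratio and
#' p-value; a high odds ratio indicates co-expression with the anchor.
#'
#' @param umi cells x genes count matrix
#' @param anchor_gene column name of the anchor
#' @param expr_range presence-fraction window for testable genes
#' @return data frame of class `coexpression_result`: `gene`, 2x2 counts,
#'   `odds_ratio`, `p`, `adj_p`; attribute `n_unmatched`
#' @export
coexpression_fisher <- function(umi, anchor_gene, expr_range = c(0.2, 0.8)) {
  .stop_if(!anchor_gene %in% colnames(umi), "anchor gene not in matrix")
  tot <- rowSums(umi)
  apos <- umi[, anchor_gene] > 0
  .stop_if(!any(!apos), "no anchor-negative cells")
  .stop_if(!any(apos), "no anchor-positive cells")
  pos_idx <- which(apos)[order(-tot[apos])]
  avail <- sort(tot[!apos])            # named totals of anchor- cells
  matched_pos <- integer(0); matched_neg <- character(0)
  for (i in pos_idx) {
    if (length(avail) == 0L) break
    j <- findInterval(tot[i], avail)
    j <- if (j == 0L) 1L else if (j >= length(avail)) length(avail) else {
      if (abs(avail[j] - tot[i]) <= abs(avail[j + 1L] - tot[i])) j else j + 1L
    }
    matched_pos <- c(matched_pos, i)
    matched_neg <- c(matched_neg, names(avail)[j])
    avail <- avail[-j]
  }
  n_unmatched <- sum(apos) - length(matched_pos)
  cells_pos <- rownames(umi)[matched_pos]
  cells_neg <- matched_neg
  sub <- umi[c(cells_pos, cells_neg), , drop = FALSE]
  grp <- rep(c(TRUE, FALSE), c(length(cells_pos), length(cells_neg)))
  pres <- sub > 0
  frac <- colMeans(pres)
  test_genes <- setdiff(colnames(umi)[frac >= expr_range[1] &
                                        frac <= expr_range[2]], anchor_gene)
  rows <- lapply(test_genes, function(g) {
    a <- sum(pres[grp, g]); b <- sum(!pres[grp, g])
    c2 <- sum(pres[!grp, g]); d <- sum(!pres[!grp, g])
    ft <- stats::fisher.test(matrix(c(a, b, c2, d), 2L))
    data.frame(gene = g, gpos_apos = a, gneg_apos = b, gpos_aneg = c2,
               gneg_aneg = d, odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$adj_p <- stats::p.adjust(out$p, method = "BH")
  attr(out, "n_unmatched") <- n_unmatched
  attr(out, "matched_pairs") <- data.frame(pos = cells_pos, neg = cells_neg)
  class(out) <- c("coexpression_result", "data.frame")
  out
}
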