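#' Label m6A sites by reader binding
#'
#' A site is labeled bound by a protein when at least one of that
#' protein's iCLIP sites lies within `window` nt (inclusive, `|delta| <=
#' window`) on the same strand.
#'
#' @param m6a_sites `site_records` of m6A positions
#' @param ect2_sites,alba4_sites protein binding-site positions
#'   (`site_records`; for 9-nt binding sites use the summit)
#' @param window distance in nt (default 100)
#' @return `m6a_sites` with added 0/1 columns `ect2_bound`, `alba4_bound`
#' @export
label_sites <- function(m6a_sites, ect2_sites, alba4_sites, window = 100L) {
  near <- function(prot) {
    if (nrow(prot) == 0L) return(integer(nrow(m6a_sites)))
    gr_m <- .sites_gr(m6a_sites)
    gr_p <- GenomicRanges::resize(.sites_gr(prot), 2L * window + 1L,
                                  fix = "center")
    hits <- GenomicRanges::findOverlaps(gr_m, gr_p)
    as.integer(seq_len(nrow(m6a_sites)) %in% S4Vectors::queryHits(hits))
  }
  out <- m6a_sites
  out$ect2_bound <- near(ect2_sites)
  out$alba4_bound <- near(alba4_sites)
  out
}

#' Partition genes into site-balanced folds
#'
#' Genes are assigned whole to folds (no gene appears in two folds) while
#' balancing the per-fold site totals greedily: genes are processed in
#' decreasing site-count order (randomized within count ties) and each
#' goes to the currently smallest fold.
#'
#' @param gene_id gene per site
#' @param k number of folds
#' @param seed RNG seed for tie randomization
#' @return integer fold id per site
#' @export
make_gene_folds <- function(gene_id, k = 5L, seed = 1L) {
  .stop_if(k < 2L, "k must be >= 2")
  genes <- table(gene_id)
  .stop_if(length(genes) < k, "fewer genes than folds")
  set.seed(seed)
  ord <- order(-as.integer(genes), stats::runif(length(genes)))
  fold_of_gene <- integer(length(genes))
  names(fold_of_gene) <- names(genes)[ord]
  load <- numeric(k)
  for (i in seq_along(ord)) {
    f <- which.min(load)
    fold_of_gene[i] <- f
    load[f] <- load[f] + as.integer(genes)[ord[i]]
  }
  unname(fold_of_gene[gene_id])
}

#' Train the dual-output binding CNN with gene-disjoint cross-validation
#'
#' For each fold, a two-headed CNN (shared convolutional trunk, separate
#' fully connected heads predicting ECT2 and ALBA4 binding) is trained on
#' the remaining folds and predicts the held-out fold, so every site gets
#' exactly one held-out prediction. Default architecture: 601-nt one-hot
#' input, five conv blocks (64 filters, kernel 8 then 6, ReLU, dropout
#' 0.2, batchnorm, max-pool 2), dense width 32, binary cross-entropy per
#' output.
#'
#' @param labeled labeled sites from [label_sites()] with `gene_id`
#' @param genome a [Biostrings::DNAStringSet]
#' @param spec a [cnn_spec()] with `n_outputs = 2` (default: the
#'   architecture above)
#' @param folds number of folds (default 5) or a precomputed fold vector
#' @param seq_flank half-window (default 300 nt, 601-nt sequences)
#' @return list of class `dual_cnn`: `predictions` (per site `p_ect2`,
#'   `p_alba4`, `fold`), `auc` (fold x output matrix), `models`, `spec`
#' @export
train_dual_cnn <- function(labeled, genome, spec = NULL, folds = 5L,
                           seq_flank = 300L) {
  if (is.null(spec))
    spec <- cnn_spec(input_len = 2L * seq_flank + 1L, n_outputs = 2L,
                     conv_filters = rep(64L, 5L),
                     kernel_sizes = c(8L, rep(6L, 4L)),
                     dense_units = 32L, dropout = 0.2)
  .stop_if(spec$n_outputs != 2L, "dual model needs n_outputs = 2")
  seq_flank <- (spec$input_len - 1L) %/% 2L
  fold <- if (length(folds) == 1L)
    make_gene_folds(labeled$gene_id, k = folds, seed = spec$seed)
  else folds
  k <- max(fold)
  seqs <- extract_window(genome, labeled$chrom, labeled$pos,
                         labeled$strand, seq_flank)
  X <- .onehot_batch(seqs)
  Y <- cbind(labeled$ect2_bound, labeled$alba4_bound)
  n <- nrow(labeled)
  preds <- matrix(NA_real_, n, 2L)
  auc <- matrix(NA_real_, k, 2L,
                dimnames = list(NULL, c("ect2", "alba4")))
  models <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    # leakage guard: gene-disjoint by construction, asserted anyway
    .stop_if(length(intersect(labeled$gene_id[tr], labeled$gene_id[!tr])) > 0,
             "gene leakage between train and test folds")
    m <- cnn_train(X[, , tr, drop = FALSE], Y[tr, , drop = FALSE], spec)
    p <- predict(m, X[, , !tr, drop = FALSE])
    preds[!tr, ] <- p
    for (h in 1:2)
      auc[f, h] <- .auc(Y[!tr, h], p[, h])
    models[[f]] <- m
  }
  predictions <- data.frame(labeled[c("chrom", "pos", "strand", "gene_id")],
                            p_ect2 = preds[, 1], p_alba4 = preds[, 2],
                            fold = fold)
  structure(list(predictions = predictions, auc = auc, models = models,
                 spec = spec, fold = fold, sequences = seqs),
            class = "dual_cnn")
}

#' @export
print.dual_cnn <- function(x, ...) {
  cat(sprintf("dual-output binding CNN, %d folds\n", nrow(x$auc)))
  cat(sprintf("  mean held-out AUC: ECT2 %.3f, ALBA4 %.3f\n",
              mean(x$auc[, 1]), mean(x$auc[, 2])))
  invisible(x)
}

#' Correlation of held-out binding probabilities
#' @param predictions the `predictions` data frame of a `dual_cnn` (or the
#'   object itself)
#' @return list with `pcc` and a 20x20 `density` table of the scatter
#' @export
predict_correlation <- function(predictions) {
  if (inherits(predictions, "dual_cnn"))
    predictions <- predictions$predictions
  p1 <- predictions$p_ect2; p2 <- predictions$p_alba4
  .stop_if(stats::sd(p1) == 0 || stats::sd(p2) == 0,
           "constant prediction vector: correlation undefined")
  br <- seq(0, 1, length.out = 21L)
  list(pcc = stats::cor(p1, p2),
       density = table(cut(p1, br, include.lowest = TRUE),
                       cut(p2, br, include.lowest = TRUE)))
}

# IUPAC code covering a base set
.iupac_code <- local({
  codes <- c(A = "A", C = "C", G = "G", T = "T",
             AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
             ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")
  function(bases) {
    key <- paste(sort(unique(bases)), collapse = "")
    unname(codes[key])
  }
})

# consensus name of a column-stochastic PWM (rows = positions, cols ACGT):
# single base when its frequency >= 0.5, else the degenerate code over
# bases with frequency >= 0.25 (N if none qualifies)
.pwm_consensus <- function(pwm) {
  paste(apply(pwm, 1, function(col) {
    b <- c("A", "C", "G", "T")
    if (max(col) >= 0.5) b[which.max(col)]
    else {
      set <- b[col >= 0.25]
      if (length(set) == 0L) "N" else .iupac_code(set)
    }
  }), collapse = "")
}

#' Extract first-layer filters as position weight matrices
#'
#' For every first-layer convolutional filter of every fold model, all
#' training sequences are scanned with the filter's pre-activation
#' cross-correlation score, the `top_n` highest-scoring positions are
#' collected, and the nucleotide frequencies at each of the kernel's
#' positions form a column-stochastic PWM with an IUPAC consensus name.
#'
#' @param dual a `dual_cnn` (its fold models and training sequences) or a
#'   single `cnn_model` plus `sequences`
#' @param sequences character vector of sequences to scan (defaults to
#'   the training sequences stored in the `dual_cnn`)
#' @param top_n high-scoring positions per filter (default 5000; all
#'   available positions if fewer match)
#' @return list of class `filter_pwms`: per filter a list with `pwm`
#'   (k x 4), `consensus`, `fold`, `filter`, `n_positions`
#' @export
extract_filter_pwms <- function(dual, sequences = NULL, top_n = 5000L) {
  models <- if (inherits(dual, "dual_cnn")) dual$models else list(dual)
  if (is.null(sequences)) {
    .stop_if(!inherits(dual, "dual_cnn"), "sequences required")
    sequences <- dual$sequences
  }
  X <- .onehot_batch(sequences)
  k <- models[[1]]$spec$kernel_sizes[1]
  L <- dim(X)[1]; N <- dim(X)[3]; P <- L - k + 1L
  # character matrix of sequences for k-mer retrieval
  chm <- matrix(unlist(strsplit(sequences, "", fixed = TRUE),
                       use.names = FALSE), nrow = L)
  out <- list()
  for (f in seq_along(models)) {
    filt <- .first_layer_filters(models[[f]])
    nf <- dim(filt)[3]
    Z <- .im2col(X, k)
    S <- Z %*% matrix(filt, k * 4L, nf)   # (P*N) x nf scores
    for (j in seq_len(nf)) {
      sc <- S[, j]
      nn <- min(top_n, length(sc))
      top <- order(sc, decreasing = TRUE)[seq_len(nn)]
      pos <- (top - 1L) %% P + 1L
      samp <- (top - 1L) %/% P + 1L
      freq <- matrix(0, k, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
      for (o in seq_len(k)) {
        ch <- chm[cbind(pos + o - 1L, samp)]
        tb <- table(factor(ch, levels = c("A", "C", "G", "T")))
        freq[o, ] <- as.numeric(tb)
      }
      tot <- rowSums(freq)
      pwm <- freq / ifelse(tot == 0, 1, tot)
      out[[length(out) + 1L]] <- list(pwm = pwm,
                                      consensus = .pwm_consensus(pwm),
                                      fold = f, filter = j,
                                      n_positions = nn)
    }
  }
  class(out) <- "filter_pwms"
  out
}

#' @export
print.filter_pwms <- function(x, ...) {
  cat(length(x), "filter PWMs; consensi:\n")
  cat(" ", paste(vapply(x, `[[`, "", "consensus"), collapse = " "), "\n")
  invisible(x)
}

# IUPAC-aware distance between a consensus and a literal motif: minimum
# over alignments of the number of motif positions not covered by the
# consensus code
.iupac_sets <- c(A = "A", C = "C", G = "G", T = "T", M = "AC", R = "AG",
                 W = "AT", S = "CG", Y = "CT", K = "GT", V = "ACG",
                 H = "ACT", D = "AGT", B = "CGT", N = "ACGT")

#' Alignment-minimal distance of a consensus to a literal motif
#'
#' Slides the shorter string along the longer; at each offset counts
#' motif positions whose base is not contained in the consensus IUPAC
#' code; returns the minimum.
#'
#' @param consensus IUPAC consensus string
#' @param motif literal motif (`ACGTU`)
#' @return integer distance
#' @export
consensus_motif_distance <- function(consensus, motif) {
  motif <- chartr("U", "T", toupper(motif))
  a <- strsplit(toupper(consensus), "")[[1]]
  b <- strsplit(motif, "")[[1]]
  if (length(a) < length(b)) { tmp <- a; a <- b; b <- tmp }
  best <- length(b)
  for (off in 0:(length(a) - length(b))) {
    win <- a[(off + 1):(off + length(b))]
    mism <- sum(vapply(seq_along(b), function(i) {
      set <- .iupac_sets[win[i]]
      is.na(set) || !grepl(b[i], set, fixed = TRUE)
    }, logical(1)))
    best <- min(best, mism)
  }
  best
}

#' Annotate motif presence around sites
#'
#' A site contains a motif when at least one match center lies within
#' `window` nt of the site position. Literal motifs (`ACGTU` strings)
#' match exactly; PWMs match where the log-odds score against a uniform
#' background reaches `threshold` of the maximum attainable score.
#'
#' @param sites `site_records`
#' @param genome a [Biostrings::DNAStringSet]
#' @param motif literal string or a k x 4 column-stochastic PWM
#' @param window half-window in nt (default 150)
#' @param threshold PWM score fraction (default 0.8)
#' @return logical vector, one entry per site
#' @export
annotate_motif_presence <- function(sites, genome, motif, window = 150L,
                                    threshold = 0.8) {
  k <- if (is.character(motif)) nchar(motif) else nrow(motif)
  seqs <- extract_window(genome, sites$chrom, sites$pos, sites$strand,
                         window + k)
  if (is.character(motif)) {
    motif <- chartr("U", "T", toupper(motif))
    .stop_if(grepl("[^ACGT]", motif), "motif must be over A/C/G/T/U")
    starts <- lapply(gregexpr(motif, seqs, fixed = TRUE), as.integer)
    L <- 2L * (window + k) + 1L
    center <- window + k + 1L
    vapply(starts, function(st) {
      if (st[1] == -1L) return(FALSE)
      mid <- st + (k - 1) / 2
      any(abs(mid - center) <= window)
    }, logical(1))
  } else {
    lo <- log(pmax(motif, 1e-6) / 0.25)
    maxsc <- sum(apply(lo, 1, max))
    X <- .onehot_batch(seqs)
    Z <- .im2col(X, k)
    # .im2col column order is channel-major (offset fastest), matching
    # the column-major layout of the k x 4 log-odds matrix
    sc <- matrix(Z %*% matrix(as.numeric(lo), ncol = 1L),
                 nrow = dim(X)[1] - k + 1L)
    L <- 2L * (window + k) + 1L
    center <- window + k + 1L
    P <- nrow(sc)
    mid <- seq_len(P) + (k - 1) / 2
    ok <- abs(mid - center) <= window
    apply(sc[ok, , drop = FALSE] >= threshold * maxsc, 2, any)
  }
}

#' Score protein-specific motif enrichment by logistic regression
#'
#' Per motif, fits `logit(P(present)) = a + b1 * p_ect2 + b2 * p_alba4`
#' on held-out binding predictions; the coefficient Z-scores are the
#' enrichment scores: `z_ect2` measures correspondence with ECT2 binding
#' controlling for ALBA4 binding, and vice versa. Motifs present (or
#' absent) everywhere are degenerate and flagged.
#'
#' @param presence named list (or single vector) of logical presence per
#'   site, one element per motif
#' @param predictions `dual_cnn` predictions data frame (held-out only)
#' @param z_threshold classification threshold on |Z| (default 2)
#' @return data frame of class `motif_scores`: `motif`, `z_ect2`,
#'   `z_alba4`, `classification`, `degenerate`
#' @export
score_motifs_glm <- function(presence, predictions, z_threshold = 2) {
  if (inherits(predictions, "dual_cnn"))
    predictions <- predictions$predictions
  if (!is.list(presence)) presence <- list(motif = presence)
  rows <- lapply(names(presence), function(nm) {
    y <- as.integer(presence[[nm]])
    if (length(unique(y)) < 2L) {
      warning("motif ", nm, " present or absent everywhere; degenerate")
      return(data.frame(motif = nm, z_ect2 = NA_real_, z_alba4 = NA_real_,
                        classification = "degenerate", degenerate = TRUE))
    }
    fit <- suppressWarnings(
      stats::glm(y ~ p_ect2 + p_alba4, family = stats::binomial(),
                 data = cbind(predictions, y = y)))
    sm <- summary(fit)$coefficients
    z1 <- sm["p_ect2", "z value"]; z2 <- sm["p_alba4", "z value"]
    cls <- if (z1 > z_threshold && z2 > z_threshold) "both"
    else if (z1 > z_threshold) "ECT2-specific"
    else if (z2 > z_threshold) "ALBA4-specific"
    else "neither"
    data.frame(motif = nm, z_ect2 = z1, z_alba4 = z2,
               classification = cls, degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("motif_scores", "data.frame")
  out
}

#' Write PWMs in MEME minimal format
#' @param pwms a `filter_pwms` list
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pwms_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: +", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s fold%d_filter%d", p$consensus, p$fold,
                       p$filter), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      nrow(p$pwm), p$n_positions), con)
    writeLines(apply(p$pwm, 1, function(r)
      paste(formatC(r, format = "f", digits = 6), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}
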