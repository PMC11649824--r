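#' Train the m6A site classifier
#'
#' Binary CNN separating true m6A sites from location-matched negative
#' sites on `2*flank + 1` nt windows (default flank 100). Cross-validated
#' performance uses gene-disjoint folds so that overlapping windows never
#' straddle the train/test split; the returned model is refit on all
#' sites for downstream position refinement.
#'
#' @param positives,negatives `site_records` (with a `gene_id` column if
#'   `folds > 0`); negatives should come from [matched_background()]
#' @param genome a [Biostrings::DNAStringSet]
#' @param spec a [cnn_spec()]; defaults to the four-block architecture
#'   (ReLU, batchnorm, max-pool 2) on `2*flank + 1` windows
#' @param flank half-window in bp
#' @param folds gene-disjoint CV folds for the AUC report (0 = skip)
#' @param displaced_negatives additional negatives per positive made by
#'   displacing the positive window by 3-25 nt (default 0). The network
#'   predicts the presence of m6A at the center point; displaced copies
#'   sharpen that center conditioning, which position refinement relies
#'   on. Held-out AUCs are always reported against the true negatives
#'   only.
#' @return list of class `m6a_classifier`: `model` ([cnn_train()] fit on
#'   all data), `fold_auc`, `spec`, `flank`
#' @export
train_m6a_classifier <- function(positives, negatives, genome, spec = NULL,
                                 flank = 100L, folds = 5L,
                                 displaced_negatives = 0L) {
  .stop_if(nrow(positives) == 0L || nrow(negatives) == 0L,
           "both classes must be non-empty")
  r <- nrow(positives) / nrow(negatives)
  if (r > 10 || r < 0.1)
    warning("class imbalance exceeds 10:1")
  if (is.null(spec))
    spec <- cnn_spec(input_len = 2L * flank + 1L,
                     conv_filters = c(64L, 64L, 64L, 64L),
                     kernel_sizes = c(8L, 6L, 6L, 6L))
  .stop_if(spec$input_len != 2L * flank + 1L,
           "spec input_len must equal 2*flank + 1")
  disp <- NULL
  if (displaced_negatives > 0L) {
    set.seed(child_seed(spec$seed, "displaced"))
    disp <- do.call(rbind, lapply(seq_len(displaced_negatives), function(j) {
      d <- positives[c("chrom", "pos", "strand")]
      d$gene_id <- positives$gene_id
      sh <- sample(c(-25:-3, 3:25), nrow(d), replace = TRUE)
      d$pos <- d$pos + ifelse(d$strand == "+", sh, -sh)
      d
    }))
  }
  sites <- rbind(positives[c("chrom", "pos", "strand")],
                 negatives[c("chrom", "pos", "strand")],
                 if (!is.null(disp)) disp[c("chrom", "pos", "strand")])
  y <- c(rep(1, nrow(positives)), rep(0, nrow(negatives)),
         rep(0, if (is.null(disp)) 0L else nrow(disp)))
  real <- seq_len(nrow(positives) + nrow(negatives))  # excl. displaced
  seqs <- extract_window(genome, sites$chrom, sites$pos, sites$strand, flank)
  X <- .onehot_batch(seqs)
  fold_auc <- NULL
  if (folds > 0L) {
    gid <- c(positives$gene_id, negatives$gene_id,
             if (!is.null(disp)) disp$gene_id)
    .stop_if(is.null(gid) || anyNA(gid),
             "gene_id required on all sites for gene-disjoint folds")
    fold <- make_gene_folds(gid, k = folds, seed = spec$seed)
    fold_auc <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      m <- cnn_train(X[, , tr, drop = FALSE], y[tr], spec)
      te <- intersect(which(!tr), real)
      .auc(y[te], predict(m, X[, , te, drop = FALSE])[, 1])
    }, numeric(1))
  }
  model <- cnn_train(X, y, spec)
  structure(list(model = model, fold_auc = fold_auc, spec = spec,
                 flank = flank), class = "m6a_classifier")
}

#' @export
print.m6a_classifier <- function(x, ...) {
  cat(sprintf("m6A site classifier (+/-%d bp windows)\n", x$flank))
  if (!is.null(x$fold_auc))
    cat("  held-out AUC per fold:",
        paste(sprintf("%.3f", x$fold_auc), collapse = " "), "\n")
  invisible(x)
}

#' Refine site positions by shift-and-maximize
#'
#' Evaluates the m6A model probability with the window center shifted by
#' every offset in `[-max_shift, +max_shift]` (transcript orientation:
#' positive = 3') and moves each site to the arg-max offset. Ties take
#' the smallest `|shift|`, then the negative one. Offsets whose window
#' leaves the chromosome are skipped; `max_shift = 0` is the identity.
#'
#' @param sites a `site_records`
#' @param classifier an `m6a_classifier` (or a bare `cnn_model` plus
#'   `flank`)
#' @param genome a [Biostrings::DNAStringSet]
#' @param max_shift maximum refinement shift in nt (default 20)
#' @return `sites` with updated `pos` and added columns `probability`,
#'   `shift`, `source_pos`
#' @export
refine_positions <- function(sites, classifier, genome, max_shift = 20L) {
  model <- if (inherits(classifier, "m6a_classifier")) classifier$model
  else classifier
  flank <- (model$spec$input_len - 1L) %/% 2L
  n <- nrow(sites)
  shifts <- -max_shift:max_shift
  chromlen <- stats::setNames(Biostrings::width(genome), names(genome))
  best_p <- rep(-Inf, n); best_s <- rep(NA_integer_, n)
  # genomic shift direction follows transcript orientation
  dirn <- ifelse(sites$strand == "+", 1L, -1L)
  ord <- order(abs(shifts), shifts)   # tie rule baked into update order
  for (s in shifts[ord]) {
    gp <- sites$pos + dirn * s
    valid <- gp - flank >= 0L & gp + flank < chromlen[sites$chrom]
    if (!any(valid)) next
    seqs <- extract_window(genome, sites$chrom[valid], gp[valid],
                           sites$strand[valid], flank)
    p <- predict(model, seqs)[, 1]
    upd <- which(valid)[p > best_p[valid]]
    pupd <- p[p > best_p[valid]]
    best_p[upd] <- pupd
    best_s[upd] <- s
  }
  out <- sites
  out$source_pos <- sites$pos
  out$shift <- best_s
  out$pos <- as.integer(sites$pos + dirn * best_s)
  out$probability <- best_p
  out
}

#' Build a non-overlapping m6A site compendium
#'
#' Union of the verbatim high-confidence (nanopore-derived) sites, which
#' are never shifted, with refined external site sets. Records landing on
#' the same position collapse to one: nanopore provenance wins, otherwise
#' the highest model probability is retained. Output positions are
#' pairwise distinct and deterministically sorted.
#'
#' @param refined_sets named list of refined `site_records` (with
#'   `probability` columns, as returned by [refine_positions()])
#' @param nanopore_set the reference `site_records` kept verbatim
#' @return a `site_records` with `source`, `probability`, `shift` columns
#' @export
build_compendium <- function(refined_sets, nanopore_set) {
  nano <- nanopore_set[c("chrom", "pos", "strand", "score", "sample_id")]
  nano$source <- "nanopore"
  nano$probability <- if (!is.null(nanopore_set$probability))
    nanopore_set$probability else NA_real_
  nano$shift <- 0L
  ext <- lapply(names(refined_sets), function(nm) {
    s <- refined_sets[[nm]]
    d <- s[c("chrom", "pos", "strand", "score", "sample_id")]
    d$source <- nm
    d$probability <- s$probability
    d$shift <- s$shift
    d
  })
  all <- rbind(nano, do.call(rbind, ext))
  # nanopore first, then decreasing probability; first per position wins
  pri <- ifelse(all$source == "nanopore", 0L, 1L)
  o <- order(all$chrom, all$pos, all$strand, pri,
             ifelse(is.na(all$probability), 1, -all$probability))
  all <- all[o, , drop = FALSE]
  keep <- !duplicated(all[c("chrom", "pos", "strand")])
  .as_site_records(all[keep, , drop = FALSE])
}
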