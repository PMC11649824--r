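#' Specification of the synthetic study world
#'
#' One object holds every generative choice: transcriptome geometry, m6A
#' landscape, reader binding and crosslink model, the hierarchical editing
#' model, and the single-cell matrix. Defaults emulate the study's data
#' structure: 3'UTR-enriched m6A, pyrimidine-rich elements planted slightly
#' 5' of bound sites (ALBA4-type crosslinks further upstream than
#' ECT2-type), replicated negative-binomial crosslink counts over a weak
#' control channel, binomial editing counts drawn exactly from the
#' hierarchical ADAR model, and a UMI matrix with planted co-expression.
#'
#' @param seed master seed; every generator derives its own stream from it
#' @param n_genes number of genes tiled on one synthetic chromosome
#' @param utr5_mean,cds_mean,utr3_mean mean feature lengths (nt)
#' @param m6a_per_gene mean m6A sites per gene (Poisson)
#' @param m6a_min_spacing minimum distance between m6A sites within a
#'   gene (nt; default 50)
#' @param metagene_weights length-3 probabilities of a site falling in
#'   5'UTR/CDS/3'UTR (must sum to 1)
#' @param bound_fraction_ect2,bound_fraction_alba4 marginal fractions of
#'   m6A sites bound by each reader
#' @param joint_bound_fraction fraction bound by both (dual targets)
#' @param motif_alba4,motif_ect2 motifs planted near bound sites
#'   (transcript sense; U allowed)
#' @param motif_plant_prob per-bound-site planting probability
#' @param offset_ect2,offset_alba4 `c(mean, sd)` of the signed crosslink
#'   offset relative to the m6A site (negative = 5')
#' @param n_replicates iCLIP replicates per channel
#' @param xlink_mean,xlink_disp negative-binomial crosslink counts per
#'   true site per replicate (mean, dispersion `size`)
#' @param background_rate_per_kb,control_rate_per_kb background/control
#'   crosslink density
#' @param drach plant a DRACH element (`GGACT`, center A on the site) at
#'   every m6A position
#' @param editing list of hierarchical-model truth: `beta0`, `beta_j`
#'   (length `n_adar_bins`, first 0), `gamma_k` (length `n_expr_bins`,
#'   first 0), `delta_jk` matrix, `tau_A`, `tau_B`, `depth_mean`
#' @param n_cells,anchor_frac,coexpr_theta,n_coexpr single-cell matrix:
#'   cells, anchor-positive fraction, planted odds ratio, number of
#'   co-expressed genes
#' @return a list of class `simulation_spec`
#' @export
simulation_spec <- function(seed = 1L,
                            n_genes = 120L,
                            utr5_mean = 150, cds_mean = 900, utr3_mean = 300,
                            m6a_per_gene = 3,
                            m6a_min_spacing = 50L,
                            metagene_weights = c(0.05, 0.25, 0.70),
                            bound_fraction_ect2 = 0.40,
                            bound_fraction_alba4 = 0.35,
                            joint_bound_fraction = 0.25,
                            motif_alba4 = "UAUUUU",
                            motif_ect2 = "UGUAUA",
                            motif_plant_prob = 0.95,
                            offset_ect2 = c(-10, 5),
                            offset_alba4 = c(-25, 8),
                            n_replicates = 3L,
                            xlink_mean = 6, xlink_disp = 2,
                            background_rate_per_kb = 0.3,
                            control_rate_per_kb = 0.15,
                            drach = TRUE,
                            editing = list(beta0 = -1.5,
                                           beta_j = c(0, 0.5, 1.0),
                                           gamma_k = c(0, 0, 0, 0, 0),
                                           delta_jk = NULL,
                                           tau_A = 4, tau_B = 4,
                                           depth_mean = 50),
                            n_cells = 2000L,
                            anchor_frac = 0.5,
                            coexpr_theta = 16,
                            n_coexpr = 10L) {
  .stop_if(abs(sum(metagene_weights) - 1) > 1e-8,
           "metagene_weights must sum to 1")
  .stop_if(any(c(bound_fraction_ect2, bound_fraction_alba4,
                 joint_bound_fraction) < 0) ||
             any(c(bound_fraction_ect2, bound_fraction_alba4,
                   joint_bound_fraction) > 1),
           "bound fractions must be in [0,1]")
  .stop_if(joint_bound_fraction > min(bound_fraction_ect2, bound_fraction_alba4),
           "joint_bound_fraction cannot exceed either marginal fraction")
  .stop_if(editing$tau_A <= 0 || editing$tau_B <= 0, "tau must be > 0")
  .stop_if(coexpr_theta <= 0, "coexpr_theta must be > 0")
  spec <- as.list(environment())
  class(spec) <- c("simulation_spec", "list")
  spec
}

#' Generate the synthetic world: genome, annotation, expression
#'
#' Genes are tiled along one synthetic chromosome with >= 200 nt gaps,
#' roughly half on the minus strand; feature lengths are gamma-distributed
#' around the spec means. Gene-level expression is log-normal.
#'
#' @param spec a [simulation_spec()]
#' @return list with `genome` ([Biostrings::DNAStringSet]), `annotation`
#'   ([transcript_annotation()]), `expression` (data frame) and `spec`
#' @export
simulate_world <- function(spec) {
  set.seed(child_seed(spec$seed, "world"))
  n <- spec$n_genes
  rlen <- function(mu) pmax(60L, as.integer(round(stats::rgamma(n, shape = 6, scale = mu / 6))))
  u5 <- rlen(spec$utr5_mean); cd <- rlen(spec$cds_mean); u3 <- rlen(spec$utr3_mean)
  gap <- 200L
  glen <- u5 + cd + u3
  starts <- cumsum(c(gap, head(glen + gap, -1L)))
  chrom_len <- starts[n] + glen[n] + gap
  .stop_if(chrom_len > 5e7, "infeasible packing: chromosome would exceed 50 Mb")
  strand <- rep(c("+", "-"), length.out = n)[sample(n)]
  gene_id <- sprintf("G%04d", seq_len(n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- starts[i]
    # transcript order utr5,cds,utr3; genomic order flips on minus strand
    if (strand[i] == "+") {
      b <- c(0L, u5[i], u5[i] + cd[i], glen[i])
      ft <- c("utr5", "cds", "utr3")
    } else {
      b <- c(0L, u3[i], u3[i] + cd[i], glen[i])
      ft <- c("utr3", "cds", "utr5")
    }
    st <- s + b[1:3]; en <- s + b[2:4]
    rows[[i]] <- data.frame(gene_id = gene_id[i], chrom = "ChrS",
                            strand = strand[i], feature = ft,
                            start = st, end = en, representative = TRUE,
                            stringsAsFactors = FALSE)
  }
  annotation <- transcript_annotation(do.call(rbind, rows))
  bases <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(genome) <- "ChrS"
  expr <- data.frame(gene_id = gene_id,
                     ctrl1 = round(stats::rlnorm(n, log(50), 1), 3),
                     ctrl2 = round(stats::rlnorm(n, log(50), 1), 3),
                     stringsAsFactors = FALSE)
  expr$mean <- rowMeans(expr[, c("ctrl1", "ctrl2")])
  list(genome = genome, annotation = annotation, expression = expr,
       spec = spec)
}

#' Plant the m6A landscape
#'
#' Draws per-gene site counts (Poisson), assigns each site to a feature by
#' the metagene weights (restricted to features the gene has), places it
#' uniformly within the feature with >= 10 nt spacing inside a gene, and
#' optionally writes a DRACH element (`GGACT`, site on the central A) into
#' the genome.
#'
#' @param world result of [simulate_world()]
#' @param spec a [simulation_spec()]
#' @return list with `sites` (a `site_records` with `gene_id`, `feature`
#'   columns) and the possibly modified `genome`
#' @export
simulate_m6a_landscape <- function(world, spec = world$spec) {
  set.seed(child_seed(spec$seed, "m6a"))
  ann <- world$annotation
  feats <- c("utr5", "cds", "utr3")
  out <- list(); k <- 0L
  for (g in unique(ann$gene_id)) {
    sub <- ann[ann$gene_id == g, , drop = FALSE]
    n_sites <- stats::rpois(1L, spec$m6a_per_gene)
    if (n_sites == 0L) next
    have <- feats[feats %in% sub$feature]
    w <- spec$metagene_weights[match(have, feats)]
    if (sum(w) == 0) next
    pos <- integer(0); ft <- character(0)
    for (s in seq_len(n_sites)) {
      # the feature is drawn once per site so that placement rejections
      # (spacing) do not bias the metagene distribution
      f <- sample(have, 1L, prob = w)
      iv <- sub[sub$feature == f, , drop = FALSE][1L, ]
      # keep 8 nt off the edges so planted DRACH stays inside the feature
      if (iv$end - iv$start <= 20L) next
      for (tries in seq_len(30L)) {
        p <- sample((iv$start + 8L):(iv$end - 9L), 1L)
        if (length(pos) == 0L || min(abs(pos - p)) >= spec$m6a_min_spacing) {
          pos <- c(pos, p); ft <- c(ft, f)
          break
        }
      }
    }
    if (length(pos) == 0L) next
    k <- k + 1L
    out[[k]] <- data.frame(gene_id = g, chrom = sub$chrom[1L],
                           strand = sub$strand[1L], pos = pos, feature = ft,
                           stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  sites <- site_records(chrom = df$chrom, pos = df$pos, strand = df$strand,
                        score = 1, sample_id = "")
  sites$gene_id <- df$gene_id
  sites$feature <- df$feature
  genome <- world$genome
  if (isTRUE(spec$drach)) {
    # GGACT with the methylated A (motif offset 2) on the site position;
    # .plant_motif takes the transcript-5' genomic start of the motif
    at <- ifelse(sites$strand == "+", sites$pos - 2L, sites$pos + 2L)
    genome <- .plant_motif(genome, sites$chrom, at, sites$strand, "GGACT")
  }
  list(sites = sites, genome = genome)
}

#' Simulate reader binding, crosslink replicates and called peaks
#'
#' Each m6A site gets Bernoulli bound labels with the spec's marginal and
#' joint fractions. For bound sites a true crosslink position is drawn
#' upstream (transcript 5') of the m6A site — nearer for ECT2-type, further
#' for ALBA4-type — and the reader motif is written into the genome at the
#' crosslink position. Per-replicate crosslink counts are negative
#' binomial; background crosslinks are scattered uniformly over
#' transcripts, and the control channel carries background only. Called
#' peaks (the peak-caller emulation) are emitted as adjacent-position
#' clusters around each true crosslink position plus singleton background
#' peaks.
#'
#' @param world result of [simulate_world()]
#' @param m6a result of [simulate_m6a_landscape()]
#' @param spec a [simulation_spec()]
#' @return list with per-protein crosslinks (`site_records` with
#'   `sample_id` = replicate), control crosslinks, called `peaks` per
#'   protein, the modified `genome`, and `truth` (per-site labels, true
#'   crosslink positions, motif plants)
#' @export
simulate_reader_sites <- function(world, m6a, spec = world$spec) {
  set.seed(child_seed(spec$seed, "readers"))
  sites <- m6a$sites
  n <- nrow(sites)
  p_joint <- spec$joint_bound_fraction
  p_e <- spec$bound_fraction_ect2; p_a <- spec$bound_fraction_alba4
  u <- stats::runif(n)
  # carve the unit interval into joint / ect2-only / alba4-only / none
  ect2 <- u < p_e
  alba4 <- (u < p_joint) | (u >= p_e & u < p_e + (p_a - p_joint))
  genome <- m6a$genome
  ann <- world$annotation
  gene_lu <- split(seq_len(nrow(ann)), ann$gene_id)

  motif_k <- max(nchar(spec$motif_alba4), nchar(spec$motif_ect2))
  draw_positions <- function(bound, off, avoid = NULL) {
    idx <- which(bound)
    res <- data.frame(site = idx, xpos = rep(NA_integer_, length(idx)))
    for (r in seq_along(idx)) {
      i <- idx[r]
      rows <- ann[gene_lu[[sites$gene_id[i]]], ]
      lo <- min(rows$start); hi <- max(rows$end) - 1L
      av <- if (is.null(avoid)) NA_integer_ else avoid$d[match(i, avoid$site)]
      for (tries in seq_len(50L)) {
        d <- as.integer(round(stats::rnorm(1, off[1], off[2])))
        if (abs(d) < 8L) next   # keep the DRACH element itself intact
        if (!is.na(av) && abs(d - av) < motif_k) next  # don't overwrite the
                                                       # other reader's motif
        xp <- if (sites$strand[i] == "+") sites$pos[i] + d else sites$pos[i] - d
        if (xp >= lo + 8L && xp <= hi - 8L) { res$xpos[r] <- xp; break }
      }
    }
    res[!is.na(res$xpos), , drop = FALSE]
  }
  tp_a <- draw_positions(alba4, spec$offset_alba4)
  d_a <- ifelse(sites$strand[tp_a$site] == "+",
                tp_a$xpos - sites$pos[tp_a$site],
                sites$pos[tp_a$site] - tp_a$xpos)
  tp_e <- draw_positions(ect2, spec$offset_ect2,
                         avoid = data.frame(site = tp_a$site, d = d_a))

  # plant the reader motif starting at the crosslink position
  plant <- stats::runif(nrow(tp_a)) < spec$motif_plant_prob
  if (any(plant))
    genome <- .plant_motif(genome, sites$chrom[tp_a$site[plant]],
                           tp_a$xpos[plant], sites$strand[tp_a$site[plant]],
                           spec$motif_alba4)
  plant_e <- stats::runif(nrow(tp_e)) < spec$motif_plant_prob
  if (any(plant_e))
    genome <- .plant_motif(genome, sites$chrom[tp_e$site[plant_e]],
                           tp_e$xpos[plant_e], sites$strand[tp_e$site[plant_e]],
                           spec$motif_ect2)

  tx_gr <- .gene_gr(ann)
  tx_len <- sum(GenomicRanges::width(tx_gr))

  background <- function(rate_per_kb) {
    lam <- rate_per_kb * tx_len / 1000
    nb <- stats::rpois(1L, lam)
    if (nb == 0L) return(site_records())
    gi <- sample(length(tx_gr), nb, replace = TRUE,
                 prob = GenomicRanges::width(tx_gr))
    pos <- GenomicRanges::start(tx_gr)[gi] - 1L +
      floor(stats::runif(nb) * GenomicRanges::width(tx_gr)[gi])
    base <- site_records(
      chrom = as.character(GenomicRanges::seqnames(tx_gr))[gi],
      pos = as.integer(pos),
      strand = as.character(GenomicRanges::strand(tx_gr))[gi],
      score = 1 + stats::rpois(nb, 0.3), sample_id = "")
    # weak events also truncate at neighboring nucleotides
    comp <- stats::runif(nb) < 0.7
    if (any(comp)) {
      nbr <- base[comp, , drop = FALSE]
      nbr$pos <- nbr$pos + sample(c(-1L, 1L), sum(comp), replace = TRUE)
      nbr$score <- 1 + stats::rpois(sum(comp), 0.2)
      base <- rbind(base, nbr[nbr$pos >= 0L, , drop = FALSE])
    }
    .as_site_records(base)
  }

  # crosslink events scatter around the true contact point, as
  # reverse-transcription truncations do around a bound site
  scatter_probs <- c(0.08, 0.17, 0.5, 0.17, 0.08)   # offsets -2..+2
  channel <- function(tp, label) {
    reps <- lapply(seq_len(spec$n_replicates), function(r) {
      cnt <- stats::rnbinom(nrow(tp), size = spec$xlink_disp,
                            mu = spec$xlink_mean)
      true_part <- if (any(cnt > 0L)) {
        ev_site <- rep(seq_len(nrow(tp)), cnt)
        ev_off <- sample(-2:2, length(ev_site), replace = TRUE,
                         prob = scatter_probs)
        key <- paste(ev_site, ev_off)
        agg <- rowsum(rep(1L, length(ev_site)), key)
        first <- !duplicated(key)
        si <- ev_site[first]; of <- ev_off[first]
        site_records(chrom = sites$chrom[tp$site[si]],
                     pos = tp$xpos[si] + of,
                     strand = sites$strand[tp$site[si]],
                     score = drop(agg[key[first], ]),
                     sample_id = sprintf("%s_rep%d", label, r))
      } else site_records()
      bg <- background(spec$background_rate_per_kb)
      if (nrow(bg)) bg$sample_id <- sprintf("%s_rep%d", label, r)
      sort_sites(rbind(true_part, bg))
    })
    do.call(rbind, reps)
  }
  xl_e <- channel(tp_e, "ect2")
  xl_a <- channel(tp_a, "alba4")
  xl_c <- {
    reps <- lapply(seq_len(spec$n_replicates), function(r) {
      bg <- background(spec$control_rate_per_kb)
      if (nrow(bg)) bg$sample_id <- sprintf("gfp_rep%d", r)
      bg
    })
    do.call(rbind, reps)
  }

  peaks_for <- function(tp, xl) {
    # peak-caller emulation: every crosslink-supported position is a
    # called peak scored by pooled evidence; true contact points form
    # clusters of directly adjacent peaks with the summit at the center
    truepk <- if (nrow(tp) > 0L) {
      base <- 5 + stats::rexp(nrow(tp), 1 / 5)
      mk <- function(off, frac) site_records(
        chrom = sites$chrom[tp$site], pos = tp$xpos + off,
        strand = sites$strand[tp$site], score = round(base * frac, 3),
        sample_id = "")
      rbind(mk(-1L, 0.6), mk(0L, 1.0), mk(1L, 0.5))
    } else site_records()
    pooled <- stats::aggregate(score ~ chrom + pos + strand, data = xl, sum)
    near_true <- if (nrow(tp) > 0L)
      pooled$pos %in% as.vector(outer(tp$xpos, -3:3, `+`)) else FALSE
    bgpk <- pooled[!near_true, , drop = FALSE]
    bgp <- if (nrow(bgpk)) site_records(
      chrom = bgpk$chrom, pos = bgpk$pos, strand = bgpk$strand,
      score = round(bgpk$score + stats::rexp(nrow(bgpk), 2), 3),
      sample_id = "") else site_records()
    pk <- rbind(truepk, bgp)
    pk <- pk[!duplicated(pk[c("chrom", "pos", "strand")]), , drop = FALSE]
    sort_sites(.as_site_records(pk))
  }
  pk_e <- peaks_for(tp_e, xl_e)
  pk_a <- peaks_for(tp_a, xl_a)
  pk_c <- peaks_for(tp_a[0, , drop = FALSE], xl_c)

  truth <- list(
    ect2_bound = ect2, alba4_bound = alba4,
    dual_bound = ect2 & alba4,
    ect2_xpos = tp_e, alba4_xpos = tp_a,
    alba4_motif_sites = tp_a$site[plant],
    ect2_motif_sites = tp_e$site[plant_e],
    target_genes_ect2 = sort(unique(sites$gene_id[tp_e$site])),
    target_genes_alba4 = sort(unique(sites$gene_id[tp_a$site])),
    dual_target_genes = sort(unique(sites$gene_id[ect2 & alba4])))
  list(ect2 = xl_e, alba4 = xl_a, control = xl_c,
       peaks = list(ect2 = pk_e, alba4 = pk_a, control = pk_c),
       genome = genome, truth = truth)
}

#' Simulate one full synthetic study
#'
#' Convenience wrapper running [simulate_world()],
#' [simulate_m6a_landscape()] and [simulate_reader_sites()] and returning
#' a self-consistent bundle whose genome already contains the planted
#' motifs.
#'
#' @param spec a [simulation_spec()]
#' @return list with `genome`, `annotation`, `expression`, `m6a_sites`,
#'   `xlinks` (per channel), `peaks`, `truth`, `spec`
#' @export
simulate_study <- function(spec = simulation_spec()) {
  world <- simulate_world(spec)
  m6a <- simulate_m6a_landscape(world, spec)
  rd <- simulate_reader_sites(world, m6a, spec)
  list(genome = rd$genome, annotation = world$annotation,
       expression = world$expression, m6a_sites = m6a$sites,
       xlinks = list(ect2 = rd$ect2, alba4 = rd$alba4, control = rd$control),
       peaks = rd$peaks, truth = rd$truth, spec = spec)
}
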