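#' Simulate binned editing counts from the hierarchical ADAR model
#'
#' Draws counts exactly from the generative model: for position `i`,
#' ADAR bin `j`, expression bin `k` and condition `c`,
#' `Y ~ Binomial(n, plogis(beta0 + beta_j + gamma_k + delta_jk + u_ic))`
#' with `u_ic ~ N(0, 1/tau_c)`. Expression bins cycle over positions;
#' depths are `Poisson(depth_mean * samples_per_cell) + 1`.
#'
#' @param spec a [simulation_spec()] (its `editing` element is used)
#' @param n_positions number of editing positions
#' @param conditions condition labels (two)
#' @param samples_per_cell samples pooled per (ADAR bin, condition) cell
#' @param share_u if `TRUE`, one `u_i` is drawn per position and used for
#'   both conditions (the no-condition-difference null)
#' @return list with `table` (a `binned_editing` data frame with columns
#'   `position_id, expr_bin, adar_bin, condition, n, y`) and `truth`
#'   (`u` matrix positions x conditions, `lc`, the fixed effects)
#' @export
simulate_editing_counts <- function(spec, n_positions,
                                    conditions = c("A", "B"),
                                    samples_per_cell = 2L,
                                    share_u = FALSE) {
  ed <- spec$editing
  .stop_if(ed$tau_A <= 0 || ed$tau_B <= 0, "tau must be > 0")
  .stop_if(length(conditions) != 2L, "exactly two conditions required")
  set.seed(child_seed(spec$seed, "editing"))
  nj <- length(ed$beta_j); nk <- length(ed$gamma_k)
  delta <- ed$delta_jk
  if (is.null(delta)) delta <- matrix(0, nj, nk)
  .stop_if(ed$beta_j[1] != 0 || ed$gamma_k[1] != 0 ||
             any(delta[1, ] != 0) || any(delta[, 1] != 0),
           "first factor levels must be zero (treatment coding)")
  P <- n_positions
  expr_bin <- rep(seq_len(nk), length.out = P)
  tau <- c(ed$tau_A, ed$tau_B)
  u <- cbind(stats::rnorm(P, 0, sqrt(1 / tau[1])),
             stats::rnorm(P, 0, sqrt(1 / tau[2])))
  if (share_u) u[, 2] <- u[, 1]
  colnames(u) <- conditions
  rows <- expand.grid(position_id = seq_len(P), adar_bin = seq_len(nj),
                      condition = conditions, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  rows$expr_bin <- expr_bin[rows$position_id]
  ci <- match(rows$condition, conditions)
  eta <- ed$beta0 + ed$beta_j[rows$adar_bin] + ed$gamma_k[rows$expr_bin] +
    delta[cbind(rows$adar_bin, rows$expr_bin)] +
    u[cbind(rows$position_id, ci)]
  rows$n <- stats::rpois(nrow(rows), ed$depth_mean * samples_per_cell) + 1L
  rows$y <- stats::rbinom(nrow(rows), rows$n, stats::plogis(eta))
  rows <- rows[order(rows$position_id, rows$condition, rows$adar_bin), ,
               drop = FALSE]
  rownames(rows) <- NULL
  class(rows) <- c("binned_editing", "data.frame")
  list(table = rows,
       truth = list(u = u, lc = u[, 1] - u[, 2], beta0 = ed$beta0,
                    beta_j = ed$beta_j, gamma_k = ed$gamma_k,
                    delta_jk = delta, tau = stats::setNames(tau, conditions)))
}

#' Simulate an ADAR-confounded two-condition editing study
#'
#' Emulates the failure mode motivating the correction model: the two
#' genetic backgrounds carry systematically different ADAR-fusion
#' expression, so editing differs between conditions through the
#' ADAR-dose effect `beta_j` alone, with no true per-position condition
#' difference (`u_iA = u_iB`). Returns per-sample counts for the naive
#' per-position test together with sample ADAR expression and per-position
#' gene expression for binning and the corrected model.
#'
#' @param spec a [simulation_spec()]
#' @param n_positions number of candidate editing positions
#' @param n_reps samples per condition
#' @return list with `counts` ([editing_counts()]), `design`,
#'   `adar_expression` (per sample), `gene_expression` (per position's
#'   gene), and `truth`
#' @export
simulate_confounded_editing <- function(spec, n_positions, n_reps = 5L) {
  ed <- spec$editing
  set.seed(child_seed(spec$seed, "confounded"))
  P <- n_positions
  nk <- length(ed$gamma_k)
  samples <- data.frame(
    sample = c(sprintf("A_rep%d", seq_len(n_reps)),
               sprintf("B_rep%d", seq_len(n_reps))),
    condition = rep(c("A", "B"), each = n_reps),
    replicate = rep(seq_len(n_reps), 2L),
    stringsAsFactors = FALSE)
  # confounded ADAR dose: condition A samples express the fusion high,
  # condition B low
  adar_expr <- stats::setNames(
    c(stats::rlnorm(n_reps, log(300), 0.15),
      stats::rlnorm(n_reps, log(60), 0.15)), samples$sample)
  # editing strength follows the ADAR-dose tertile (same rank rule the
  # analysis uses), which the condition split leaves heavily confounded
  r <- rank(adar_expr, ties.method = "first")
  adar_bin <- as.integer(ceiling(r * 3L / length(r)))
  expr_bin <- rep(seq_len(nk), length.out = P)
  gene_expression <- stats::rlnorm(P, log(50), 1)
  # order positions by expression so expr_bin matches expression quintiles
  gene_expression <- sort(gene_expression)[order(order(expr_bin))]
  u <- stats::rnorm(P, 0, sqrt(1 / ed$tau_A))   # shared across conditions
  ref <- alt <- matrix(0L, P, nrow(samples),
                       dimnames = list(NULL, samples$sample))
  for (s in seq_len(nrow(samples))) {
    eta <- ed$beta0 + ed$beta_j[adar_bin[s]] + ed$gamma_k[expr_bin] + u
    n <- stats::rpois(P, ed$depth_mean) + 1L
    y <- stats::rbinom(P, n, stats::plogis(eta))
    alt[, s] <- y; ref[, s] <- n - y
  }
  pos <- data.frame(chrom = "ChrS", pos = seq_len(P) * 10L, strand = "+",
                    ref_base = "A", stringsAsFactors = FALSE)
  list(counts = editing_counts(pos, ref, alt), design = samples,
       adar_expression = adar_expr, gene_expression = gene_expression,
       truth = list(u = u, adar_bin = adar_bin, expr_bin = expr_bin))
}

#' Simulate fusion-vs-control TRIBE editing counts
#'
#' Per-sample binomial A/G counts at candidate positions: a planted
#' fraction of positions is edited at `ep_fusion` in fusion samples and
#' `ep_control` in controls; the rest carry the background rate in both.
#'
#' @param seed RNG seed
#' @param n_positions candidate positions
#' @param n_fusion,n_control samples per condition
#' @param depth_mean per-sample depth (`Poisson(depth_mean) + 1`)
#' @param ep_fusion,ep_control editing proportions at planted positions
#' @param ep_background shared background mismatch rate elsewhere
#' @param frac_edited fraction of positions planted
#' @return list with `counts` ([editing_counts()]), `design`, `truth`
#'   (logical `edited` per position)
#' @export
simulate_tribe_counts <- function(seed = 1L, n_positions = 1000L,
                                  n_fusion = 5L, n_control = 5L,
                                  depth_mean = 50, ep_fusion = 0.15,
                                  ep_control = 0.01,
                                  ep_background = 0.001,
                                  frac_edited = 0.1) {
  set.seed(child_seed(seed, "tribe"))
  P <- n_positions
  design <- data.frame(
    sample = c(sprintf("fusion_rep%d", seq_len(n_fusion)),
               sprintf("ctrl_rep%d", seq_len(n_control))),
    condition = rep(c("fusion", "control"), c(n_fusion, n_control)),
    replicate = c(seq_len(n_fusion), seq_len(n_control)),
    stringsAsFactors = FALSE)
  edited <- seq_len(P) <= round(frac_edited * P)
  ref <- alt <- matrix(0L, P, nrow(design),
                       dimnames = list(NULL, design$sample))
  for (s in seq_len(nrow(design))) {
    ep <- ifelse(edited,
                 if (design$condition[s] == "fusion") ep_fusion else ep_control,
                 ep_background)
    n <- stats::rpois(P, depth_mean) + 1L
    y <- stats::rbinom(P, n, ep)
    alt[, s] <- y; ref[, s] <- n - y
  }
  pos <- data.frame(chrom = "ChrS", pos = seq_len(P) * 10L, strand = "+",
                    ref_base = "A", stringsAsFactors = FALSE)
  list(counts = editing_counts(pos, ref, alt), design = design,
       truth = list(edited = edited))
}

#' Simulate a cell x gene UMI matrix with planted co-expression
#'
#' An anchor gene is expressed in `anchor_frac` of cells; each co-expressed
#' gene is present with odds `theta`-fold higher in anchor-positive cells;
#' all other genes are independent of the anchor. Per-cell depth is
#' log-normal and scales every gene's count.
#'
#' @param spec a [simulation_spec()]
#' @param n_background number of independent background genes
#'   (default 200, so that the anchor-coupled genes contribute little to
#'   per-cell depth, as in real matrices)
#' @return list with `umi` (cells x genes matrix, anchor gene `"ECT2"`),
#'   and `truth` (`coexpressed` gene names, `theta`)
#' @export
simulate_umi_matrix <- function(spec, n_background = 200L) {
  .stop_if(spec$coexpr_theta <= 0, "theta must be > 0")
  set.seed(child_seed(spec$seed, "umi"))
  nc <- spec$n_cells
  co <- sprintf("CO%03d", seq_len(spec$n_coexpr))
  bg <- sprintf("BG%03d", seq_len(n_background))
  genes <- c("ECT2", co, bg)
  anchor <- stats::runif(nc) < spec$anchor_frac
  depth <- stats::rlnorm(nc, 0, 0.3)
  p0 <- 0.2
  odds1 <- spec$coexpr_theta * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  present <- matrix(0L, nc, length(genes), dimnames = list(
    sprintf("cell%04d", seq_len(nc)), genes))
  present[, "ECT2"] <- as.integer(anchor)
  for (g in co)
    present[, g] <- stats::rbinom(nc, 1L, ifelse(anchor, p1, p0))
  for (g in bg)
    present[, g] <- stats::rbinom(nc, 1L, 0.4)
  lam <- sweep(present * 2, 1, depth, `*`)
  umi <- matrix(stats::rpois(length(lam), lam) + present, nc,
                length(genes), dimnames = dimnames(present))
  list(umi = umi, truth = list(coexpressed = co, theta = spec$coexpr_theta,
                               anchor = anchor))
}
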