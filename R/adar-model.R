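#' Assign ADAR and expression bins
#'
#' Samples are split into tertiles of ADAR-fusion expression (ADAR_BIN)
#' and genes into quintiles of expression (EXPR_BIN), labeled ascending.
#' Assignment is rank-based with a stable first-occurrence tie rule, so
#' ties spanning a bin boundary resolve deterministically.
#'
#' @param adar_expression named numeric, ADAR expression per sample
#' @param gene_expression named numeric, expression per gene
#' @param n_adar_bins,n_expr_bins bin counts (defaults 3 and 5)
#' @return list with `adar_bin` (named integer per sample) and `expr_bin`
#'   (named integer per gene)
#' @export
assign_bins <- function(adar_expression, gene_expression,
                        n_adar_bins = 3L, n_expr_bins = 5L) {
  bin <- function(x, k, what) {
    .stop_if(length(x) < k, "fewer ", what, " than requested bins")
    .stop_if(length(unique(x)) < k,
             k, " bins requested of ", length(unique(x)),
             " distinct ", what, " values")
    r <- rank(x, ties.method = "first")
    stats::setNames(as.integer(ceiling(r * k / length(x))), names(x))
  }
  list(adar_bin = bin(adar_expression, n_adar_bins, "sample"),
       expr_bin = bin(gene_expression, n_expr_bins, "gene"))
}

#' Aggregate per-sample editing counts into the binned model table
#'
#' Pools alt (G) and ref (A) counts over samples sharing an
#' (ADAR bin, condition) cell, producing the `(position, adar_bin,
#' expr_bin, condition)` table the hierarchical model consumes.
#'
#' @param counts an [editing_counts()]
#' @param design design data frame (`sample`, `condition`)
#' @param adar_bin named integer, ADAR bin per sample
#' @param expr_bin integer vector, expression bin per position
#' @return a `binned_editing` data frame
#' @export
bin_editing_counts <- function(counts, design, adar_bin, expr_bin) {
  P <- nrow(counts$positions)
  .stop_if(length(expr_bin) != P, "expr_bin must have one entry per position")
  cells <- unique(data.frame(condition = design$condition,
                             adar_bin = adar_bin[design$sample]))
  rows <- list()
  for (r in seq_len(nrow(cells))) {
    smp <- design$sample[design$condition == cells$condition[r] &
                           adar_bin[design$sample] == cells$adar_bin[r]]
    y <- rowSums(counts$alt[, smp, drop = FALSE])
    n <- y + rowSums(counts$ref[, smp, drop = FALSE])
    rows[[r]] <- data.frame(position_id = seq_len(P),
                            adar_bin = cells$adar_bin[r],
                            condition = cells$condition[r],
                            expr_bin = expr_bin, n = n, y = y,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[out$n > 0, , drop = FALSE]
  out <- out[order(out$position_id, out$condition, out$adar_bin), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("binned_editing", "data.frame")
  out
}

#' Fit the ADAR-corrected hierarchical binomial model
#'
#' The model: `Y_ijkc ~ Binomial(n_ijkc, p_ijkc)` with
#' `logit(p) = beta0 + beta_j + gamma_k + delta_jk + u_ic`, where `j`
#' indexes ADAR bins, `k` expression bins, and `u_ic ~ N(0, 1/tau_c)` is a
#' position-specific random effect with condition-specific precision.
#' Identifiability uses treatment coding (first level of each factor
#' fixed at 0). Inference is a Laplace approximation: damped joint Newton
#' iterations locate the mode of the penalized binomial log-likelihood in
#' `(beta, u)` simultaneously — the sparse Hessian (random effects enter
#' block-diagonally) is solved exactly through its Schur complement, so
#' directions where fixed effects and random-effect means trade off
#' (e.g. an ADAR bin perfectly aligned with condition) are handled in one
#' step rather than by slow alternation. Posterior sds of `u_ic` come
#' from the corresponding diagonal of the inverse Hessian at the mode
#' (including fixed-effect uncertainty), and `tau_c` is updated by an
#' EM-type approximate marginal-likelihood step
#' `tau_c = G_c / sum_i(u_ic^2 + var(u_ic))`.
#'
#' @param table a `binned_editing` data frame with columns
#'   `position_id, adar_bin, expr_bin, condition, n, y`
#' @param max_iter maximum outer iterations
#' @param tol convergence tolerance on parameter changes
#' @param ridge ridge added to the fixed-effect normal equations
#' @return an object of class `adar_fit` with elements `beta` (named fixed
#'   effects), `beta_cov`, `u` (per position x condition posterior mean and
#'   sd), `tau` (named per condition), `converged`, `iterations`,
#'   `grad_norm`, plus the model frame bookkeeping
#' @export
fit_adar_model <- function(table, max_iter = 200L, tol = 1e-6,
                           ridge = 1e-8) {
  .stop_if(!all(c("position_id", "adar_bin", "expr_bin", "condition",
                  "n", "y") %in% names(table)),
           "table must have position_id, adar_bin, expr_bin, condition, n, y")
  .stop_if(any(table$y < 0 | table$y > table$n), "need 0 <= y <= n")
  conds <- sort(unique(as.character(table$condition)))
  .stop_if(length(conds) != 2L, "exactly two conditions required")
  # order-invariant canonical row order
  tb <- table[order(table$position_id, table$condition, table$adar_bin,
                    table$expr_bin), , drop = FALSE]
  jf <- factor(tb$adar_bin, levels = sort(unique(tb$adar_bin)))
  kf <- factor(tb$expr_bin, levels = sort(unique(tb$expr_bin)))
  X <- if (nlevels(kf) > 1L) stats::model.matrix(~ jf * kf)
  else stats::model.matrix(~ jf)
  # drop aliased columns (absent j x k cells)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- qx$pivot[-seq_len(qx$rank)]
    warning("dropping ", length(drop), " aliased fixed-effect columns")
    X <- X[, -drop, drop = FALSE]
  }
  colnames(X) <- sub("^jf", "adar", sub("kf", "expr", colnames(X)))
  y <- tb$y; n <- tb$n
  grp_key <- paste(tb$position_id, tb$condition, sep = "\r")
  grp <- match(grp_key, unique(grp_key))
  G <- max(grp)
  ginfo <- tb[!duplicated(grp_key), c("position_id", "condition")]
  cg <- match(ginfo$condition, conds)
  Gc <- tabulate(cg, 2L)
  p <- ncol(X)
  beta <- numeric(p); beta[1] <- stats::qlogis(max(1e-4, min(1 - 1e-4,
                                                             sum(y) / sum(n))))
  u <- numeric(G); tau <- c(1, 1)
  d <- rep(1, G)
  pll <- function(beta, u) {   # penalized binomial log-likelihood
    eta <- drop(X %*% beta) + u[grp]
    sum(y * eta - n * log1p(exp(eta))) - sum(tau[cg] * u^2) / 2
  }
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    tau_old <- tau
    eta <- drop(X %*% beta) + u[grp]
    mu <- stats::plogis(eta)
    w <- pmax(n * mu * (1 - mu), 1e-10)
    gb <- drop(crossprod(X, y - n * mu))
    gu <- drop(rowsum(y - n * mu, grp)) - tau[cg] * u
    d <- drop(rowsum(w, grp)) + tau[cg]
    Cg <- rowsum(X * w, grp)                  # G x p
    A <- crossprod(X, X * w) + diag(ridge, p)
    CDi <- Cg / d
    S <- A - crossprod(Cg, CDi)               # Schur complement
    db <- drop(solve(S + diag(ridge, p), gb - drop(crossprod(CDi, gu))))
    du <- (gu - drop(Cg %*% db)) / d
    # damped Newton: halve the step until the penalized loglik improves
    f0 <- pll(beta, u)
    step <- 1
    repeat {
      bn <- beta + step * db; un <- u + step * du
      if (pll(bn, un) >= f0 - 1e-10 || step < 1e-4) break
      step <- step / 2
    }
    beta <- beta + step * db; u <- u + step * du
    # tau-step: EM-type update from posterior mode and curvature; a
    # degenerate table with no overdispersion (all modes at zero) has its
    # precision at the boundary, so jump to the cap instead of crawling
    tau_max <- 1e6
    for (c2 in 1:2) {
      if (sum(u[cg == c2]^2) < 1e-12 * Gc[c2]) {
        tau[c2] <- tau_max
      } else {
        s <- sum(u[cg == c2]^2 + 1 / d[cg == c2])
        tau[c2] <- min(Gc[c2] / max(s, 1e-12), tau_max)
      }
    }
    delta <- max(abs(step * db), abs(step * du),
                 abs(tau - tau_old) / pmax(tau_old, 1))
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta) + u[grp]
  mu <- stats::plogis(eta)
  grad_beta <- drop(crossprod(X, y - n * mu))
  grad_norm <- sqrt(sum(grad_beta^2))
  if (!converged)
    stop("fit_adar_model did not converge after ", max_iter,
         " iterations (gradient norm ", signif(grad_norm, 3), ")")
  w <- pmax(n * mu * (1 - mu), 1e-10)
  d <- drop(rowsum(w, grp)) + tau[cg]
  Cg <- rowsum(X * w, grp)
  CDi <- Cg / d
  A <- crossprod(X, X * w) + diag(ridge, p)
  S <- A - crossprod(Cg, CDi)
  beta_cov <- solve(S + diag(ridge, p))
  # posterior var of u: D^-1 + D^-1 C' S^-1 C D^-1 (beta uncertainty in)
  hess_g <- 1 / (1 / d + rowSums((CDi %*% beta_cov) * CDi))
  names(beta) <- colnames(X)
  dimnames(beta_cov) <- list(colnames(X), colnames(X))
  udf <- data.frame(position_id = ginfo$position_id,
                    condition = ginfo$condition,
                    mean = u, sd = sqrt(1 / hess_g),
                    stringsAsFactors = FALSE)
  fit <- list(beta = beta, beta_cov = beta_cov, u = udf,
              tau = stats::setNames(tau, conds),
              conditions = conds,
              adar_levels = levels(jf), expr_levels = levels(kf),
              expr_bin_of_position = stats::setNames(
                tb$expr_bin[!duplicated(tb$position_id)],
                tb$position_id[!duplicated(tb$position_id)]),
              converged = converged, iterations = it,
              grad_norm = grad_norm,
              deviance = -2 * sum(stats::dbinom(y, n, mu, log = TRUE)),
              nobs = length(y))
  class(fit) <- "adar_fit"
  fit
}

# eta for arbitrary (adar_bin, expr_bin) under the fitted fixed effects
.fixed_eta <- function(fit, adar_bin, expr_bin) {
  jf <- factor(adar_bin, levels = fit$adar_levels)
  kf <- factor(expr_bin, levels = fit$expr_levels)
  X <- if (length(fit$expr_levels) > 1L)
    stats::model.matrix(~ jf * kf, data = data.frame(jf = jf, kf = kf))
  else stats::model.matrix(~ jf, data = data.frame(jf = jf))
  colnames(X) <- sub("^jf", "adar", sub("kf", "expr", colnames(X)))
  keep <- colnames(X) %in% names(fit$beta)
  drop(X[, keep, drop = FALSE] %*% fit$beta[colnames(X)[keep]])
}

#' @export
print.adar_fit <- function(x, ...) {
  cat("ADAR-corrected hierarchical binomial model\n")
  cat(sprintf("  %d observations, %d position x condition random effects\n",
              x$nobs, nrow(x$u)))
  cat(sprintf("  converged in %d iterations (gradient norm %.3g)\n",
              x$iterations, x$grad_norm))
  cat("  precisions tau:", paste(sprintf("%s = %.3f", names(x$tau), x$tau),
                                 collapse = ", "), "\n")
  cat("  fixed effects:\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
coef.adar_fit <- function(object, ...) object$beta

#' @export
summary.adar_fit <- function(object, ...) {
  se <- sqrt(diag(object$beta_cov))
  tab <- data.frame(estimate = object$beta, se = se,
                    z = object$beta / se,
                    p = 2 * stats::pnorm(-abs(object$beta / se)))
  out <- list(coefficients = tab, tau = object$tau,
              iterations = object$iterations, deviance = object$deviance,
              u_sd_range = range(object$u$sd))
  class(out) <- "summary.adar_fit"
  out
}

#' @export
print.summary.adar_fit <- function(x, ...) {
  cat("Fixed effects:\n"); print(round(x$coefficients, 4))
  cat("\nRandom-effect precisions:\n"); print(round(x$tau, 4))
  cat(sprintf("\nDeviance %.1f after %d iterations\n", x$deviance,
              x$iterations))
  invisible(x)
}

#' Predicted editing probabilities
#'
#' For `newdata` rows (`position_id, adar_bin, expr_bin, condition`),
#' returns fitted probabilities (or the linear predictor) including the
#' posterior-mean random effect of the (position, condition).
#'
#' @param object an `adar_fit`
#' @param newdata data frame; defaults to one row per known
#'   (position, condition) at the center ADAR bin
#' @param type `"response"` or `"link"`
#' @param ... unused
#' @export
predict.adar_fit <- function(object, newdata = NULL,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    newdata <- object$u[, c("position_id", "condition")]
    newdata$adar_bin <- object$adar_levels[
      ceiling(length(object$adar_levels) / 2)]
    newdata$expr_bin <- object$expr_bin_of_position[
      as.character(newdata$position_id)]
  }
  eta <- .fixed_eta(object, newdata$adar_bin, newdata$expr_bin)
  key <- paste(newdata$position_id, newdata$condition)
  um <- object$u$mean[match(key, paste(object$u$position_id,
                                       object$u$condition))]
  .stop_if(anyNA(um), "unknown position/condition in newdata")
  eta <- eta + um
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
fitted.adar_fit <- function(object, ...) predict(object)

#' Posterior contrasts of condition-specific random effects
#'
#' Computes `LC_i = u_iA - u_iB` per position from the fitted posterior,
#' either by posterior sampling (default, seeded) or analytically
#' (`Var = Var(u_iA) + Var(u_iB)`, valid as the two posteriors are
#' conditionally independent). Z-scores `mu/sigma` are converted to
#' two-sided normal p-values and Benjamini-Hochberg adjusted.
#'
#' @param fit an `adar_fit`
#' @param n_draws posterior draws for the sampling method (default 1000)
#' @param seed RNG seed for the draws
#' @param method `"sampling"` or `"analytic"`
#' @param fdr FDR level used for the `significant` flag (default 0.05)
#' @return data frame of class `adar_contrasts`: `position_id`, `mu_lc`,
#'   `sigma_lc`, `z`, `p`, `adj_p`, `direction`, `significant`
#' @export
contrast_random_effects <- function(fit, n_draws = 1000L, seed = 1L,
                                    method = c("sampling", "analytic"),
                                    fdr = 0.05) {
  method <- match.arg(method)
  cond <- fit$conditions
  uA <- fit$u[fit$u$condition == cond[1], ]
  uB <- fit$u[fit$u$condition == cond[2], ]
  common <- intersect(uA$position_id, uB$position_id)
  uA <- uA[match(common, uA$position_id), ]
  uB <- uB[match(common, uB$position_id), ]
  P <- length(common)
  if (method == "sampling") {
    set.seed(seed)
    dA <- matrix(stats::rnorm(P * n_draws, uA$mean, uA$sd), nrow = P)
    dB <- matrix(stats::rnorm(P * n_draws, uB$mean, uB$sd), nrow = P)
    lc <- dA - dB
    mu <- rowMeans(lc)
    sg <- apply(lc, 1, stats::sd)
  } else {
    mu <- uA$mean - uB$mean
    sg <- sqrt(uA$sd^2 + uB$sd^2)
  }
  flagged <- sg == 0
  if (any(flagged))
    warning(sum(flagged), " positions with zero contrast sd excluded")
  z <- ifelse(flagged, NA_real_, mu / sg)
  pv <- 2 * stats::pnorm(-abs(z))
  adj <- rep(NA_real_, P)
  adj[!flagged] <- stats::p.adjust(pv[!flagged], method = "BH")
  out <- data.frame(position_id = common, mu_lc = mu, sigma_lc = sg,
                    z = z, p = pv, adj_p = adj,
                    direction = ifelse(mu > 0,
                                       paste0("higher_in_", cond[1]),
                                       paste0("higher_in_", cond[2])),
                    significant = !is.na(adj) & adj < fdr,
                    stringsAsFactors = FALSE)
  class(out) <- c("adar_contrasts", "data.frame")
  out
}

#' Corrected editing proportions at the center ADAR bin
#'
#' Position-specific editing proportions with ADAR expression normalized
#' to the center bin:
#' `plogis(beta0 + beta_j* + gamma_k + delta_j*k + u_ic)`, with `j*` the
#' center ADAR bin and `k` the position's expression bin.
#'
#' @param fit an `adar_fit`
#' @param position_id positions (default: all fitted positions)
#' @param condition condition label (default: both, long format)
#' @param expr_bin override the expression bin (default: the position's)
#' @param center_bin index of the center ADAR bin (default middle level)
#' @return data frame `position_id, condition, proportion`
#' @export
corrected_editing_proportions <- function(fit, position_id = NULL,
                                          condition = NULL,
                                          expr_bin = NULL,
                                          center_bin = NULL) {
  if (is.null(center_bin))
    center_bin <- fit$adar_levels[ceiling(length(fit$adar_levels) / 2)]
  if (is.null(position_id)) position_id <- unique(fit$u$position_id)
  .stop_if(!all(as.character(position_id) %in%
                  names(fit$expr_bin_of_position)),
           "unknown position in position_id")
  conds <- if (is.null(condition)) fit$conditions else condition
  nd <- expand.grid(position_id = position_id, condition = conds,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nd$adar_bin <- center_bin
  nd$expr_bin <- if (is.null(expr_bin))
    fit$expr_bin_of_position[as.character(nd$position_id)]
  else rep_len(expr_bin, nrow(nd))
  nd$proportion <- predict(fit, nd, type = "response")
  nd[, c("position_id", "condition", "proportion")]
}

#' Directional bias of differential editing in dual-target genes
#'
#' Splits significant contrast positions by direction and summarizes how
#' strongly dual-bound targets account for the less-edited-in-condition-B
#' fraction: the per-direction fractions of significant sites lying in
#' dual targets, plus group medians of the log2 differential proportion
#' split by dual-target membership with a two-sample t-test.
#'
#' @param contrasts an `adar_contrasts` data frame
#' @param gene_id gene per contrast position (same order)
#' @param dual_target_genes character vector of dual-bound target genes
#' @param log2_diff optional per-position log2 differential proportion;
#'   defaults to `mu_lc / log(2)`
#' @return list with `fraction_down_dual`, `fraction_up_dual`,
#'   `median_dual`, `median_other`, `t_p`, `n_significant`
#' @export
classify_dual_target_bias <- function(contrasts, gene_id, dual_target_genes,
                                      log2_diff = NULL) {
  .stop_if(length(gene_id) != nrow(contrasts),
           "gene_id must align with contrasts")
  if (is.null(log2_diff)) log2_diff <- contrasts$mu_lc / log(2)
  sig <- contrasts$significant
  if (!any(sig)) {
    warning("no significant contrast positions")
    return(list(fraction_down_dual = NA_real_, fraction_up_dual = NA_real_,
                median_dual = NA_real_, median_other = NA_real_,
                t_p = NA_real_, n_significant = 0L))
  }
  dual <- gene_id %in% dual_target_genes
  down <- sig & contrasts$mu_lc > 0   # less edited in condition B
  up <- sig & contrasts$mu_lc < 0
  f <- function(m) if (sum(m) == 0L) NA_real_ else mean(dual[m])
  tp <- if (length(unique(dual)) == 2L)
    tryCatch(stats::t.test(log2_diff[dual], log2_diff[!dual])$p.value,
             error = function(e) NA_real_) else NA_real_
  list(fraction_down_dual = f(down), fraction_up_dual = f(up),
       median_dual = stats::median(log2_diff[dual]),
       median_other = stats::median(log2_diff[!dual]),
       t_p = tp, n_significant = sum(sig))
}
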