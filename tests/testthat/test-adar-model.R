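test_that("bin assignment is rank-based with deterministic ties", {
  b <- assign_bins(c(a = 10, b = 20, c = 30), setNames(runif(5), letters[1:5]))
  expect_equal(unname(b$adar_bin), c(1L, 2L, 3L))
  expect_error(assign_bins(c(1, 1, 2), setNames(runif(5), letters[1:5])),
               "3 bins requested of 2 distinct")
  g <- setNames(rnorm(1000), paste0("g", 1:1000))
  eb <- assign_bins(c(x = 1, y = 2, z = 3), g)$expr_bin
  expect_true(all(abs(table(eb) - 200) <= 1))
  # ties spanning a bin boundary resolve by stable first-occurrence rank
  tied <- assign_bins(c(s1 = 1, s2 = 5, s3 = 5, s4 = 5, s5 = 9, s6 = 9),
                      setNames(1:5, paste0("g", 1:5)))
  expect_equal(unname(tied$adar_bin), c(1L, 1L, 2L, 2L, 3L, 3L))
})

test_that("a balanced table recovers a near-zero intercept", {
  tb <- expand.grid(position_id = 1:30, adar_bin = 1:3,
                    condition = c("A", "B"), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  tb$expr_bin <- 1L
  tb$n <- 10000L
  tb$y <- 5000L
  fit <- fit_adar_model(tb)
  expect_lt(abs(coef(fit)["(Intercept)"]), 0.01)
  expect_true(all(abs(fit$u$mean) < 0.01))
  expect_s3_class(fit, "adar_fit")
  expect_output(print(fit), "hierarchical binomial")
})

test_that("the fit is invariant to row order", {
  spec <- simulation_spec(seed = 17)
  sim <- simulate_editing_counts(spec, 150)
  f1 <- fit_adar_model(sim$table)
  set.seed(1)
  f2 <- fit_adar_model(sim$table[sample(nrow(sim$table)), ])
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$u$mean, f2$u$mean, tolerance = 1e-8)
  expect_equal(f1$tau, f2$tau, tolerance = 1e-8)
})

test_that("posterior modes are shrunk toward zero relative to raw residuals", {
  spec <- simulation_spec(seed = 18)
  sim <- simulate_editing_counts(spec, 200)
  fit <- fit_adar_model(sim$table)
  # unpenalized per-(position, condition) mode given the fixed effects
  tb <- sim$table
  eta_fixed <- predict(fit, transform(tb, position_id = tb$position_id),
                       type = "link") -
    fit$u$mean[match(paste(tb$position_id, tb$condition),
                     paste(fit$u$position_id, fit$u$condition))]
  # direct Newton solve without the prior
  grp <- paste(tb$position_id, tb$condition)
  raw <- vapply(unique(grp), function(g) {
    i <- grp == g
    u <- 0
    for (it in 1:100) {
      mu <- plogis(eta_fixed[i] + u)
      g1 <- sum(tb$y[i] - tb$n[i] * mu)
      h <- sum(tb$n[i] * mu * (1 - mu))
      if (h < 1e-12) break
      step <- g1 / h
      u <- u + sign(step) * min(abs(step), 2)
      if (abs(step) < 1e-10) break
    }
    u
  }, numeric(1))
  post <- fit$u$mean[match(unique(grp), paste(fit$u$position_id,
                                              fit$u$condition))]
  expect_true(all(abs(post) <= abs(raw) + 1e-6))
})

test_that("the Laplace fit agrees with an independent glmmTMB fit", {
  spec <- simulation_spec(seed = 19, editing = list(
    beta0 = -1.2, beta_j = c(0, 0.4, 0.8), gamma_k = rep(0, 5),
    delta_jk = NULL, tau_A = 4, tau_B = 4, depth_mean = 50))
  sim <- simulate_editing_counts(spec, 250)
  fit <- fit_adar_model(sim$table)
  tb <- sim$table
  tb$jf <- factor(tb$adar_bin); tb$kf <- factor(tb$expr_bin)
  tb$pid <- factor(tb$position_id)
  tb$dA <- as.numeric(tb$condition == "A")
  tb$dB <- as.numeric(tb$condition == "B")
  ref <- glmmTMB::glmmTMB(
    cbind(y, n - y) ~ jf * kf + (0 + dA | pid) + (0 + dB | pid),
    family = binomial(), data = tb)
  expect_equal(unname(coef(fit)["(Intercept)"]),
               unname(glmmTMB::fixef(ref)$cond["(Intercept)"]),
               tolerance = 0.05)
  # random-effect posterior means track each other
  re <- glmmTMB::ranef(ref)$cond$pid
  uA <- fit$u$mean[fit$u$condition == "A"][order(
    fit$u$position_id[fit$u$condition == "A"])]
  expect_gt(cor(uA, re$dA[order(as.integer(rownames(re)))]), 0.98)
  # estimated precisions in the same range
  vc <- glmmTMB::VarCorr(ref)$cond
  tau_ref <- 1 / c(attr(vc$pid, "stddev")[1]^2)
  expect_lt(abs(log(fit$tau["A"] / tau_ref)), log(1.5))
})

test_that("contrasts combine posteriors linearly, with sampling-analytic agreement", {
  spec <- simulation_spec(seed = 20)
  sim <- simulate_editing_counts(spec, 120)
  fit <- fit_adar_model(sim$table)
  cs <- contrast_random_effects(fit, n_draws = 10000L, seed = 1)
  ca <- contrast_random_effects(fit, method = "analytic")
  expect_equal(cs$mu_lc, ca$mu_lc, tolerance = 0.05)
  expect_true(all(abs(cs$sigma_lc / ca$sigma_lc - 1) < 0.05))
  uA <- fit$u[fit$u$condition == "A", ]
  uB <- fit$u[fit$u$condition == "B", ]
  expect_equal(ca$mu_lc, uA$mean - uB$mean, tolerance = 1e-12)
  expect_true(all(ca$adj_p >= ca$p - 1e-12))
})

test_that("corrected proportions use the center ADAR bin and respond to u", {
  tb <- expand.grid(position_id = 1:20, adar_bin = 1:3,
                    condition = c("A", "B"), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  tb$expr_bin <- 1L; tb$n <- 20000L; tb$y <- 10000L
  fit <- fit_adar_model(tb)
  cp <- corrected_editing_proportions(fit)
  expect_equal(cp$proportion, rep(0.5, nrow(cp)), tolerance = 0.01)
  # monotonicity in the random effect: sites with larger u get larger
  # corrected proportions
  spec <- simulation_spec(seed = 21)
  sim <- simulate_editing_counts(spec, 100)
  fit2 <- fit_adar_model(sim$table)
  cp2 <- corrected_editing_proportions(fit2, condition = "A")
  uA <- fit2$u[fit2$u$condition == "A", ]
  k <- fit2$expr_bin_of_position[as.character(cp2$position_id)]
  same_k <- k == 1
  o <- order(uA$mean[match(cp2$position_id, uA$position_id)])
  expect_true(all(diff(cp2$proportion[o][same_k[o]]) >= -1e-12))
  expect_error(corrected_editing_proportions(fit2, position_id = 99999),
               "unknown position")
})

test_that("dual-target bias summaries reflect planted direction", {
  ctr <- data.frame(position_id = 1:100,
                    mu_lc = c(rep(1, 50), rep(-0.1, 50)),
                    sigma_lc = 0.1)
  ctr$z <- ctr$mu_lc / ctr$sigma_lc
  ctr$p <- 2 * pnorm(-abs(ctr$z))
  ctr$adj_p <- p.adjust(ctr$p, "BH")
  ctr$significant <- ctr$adj_p < 0.05
  class(ctr) <- c("adar_contrasts", "data.frame")
  gene <- c(rep("dual1", 50), rep("other", 50))
  out <- classify_dual_target_bias(ctr, gene, "dual1")
  expect_equal(out$fraction_down_dual, 1.0)
  expect_gt(out$median_dual, out$median_other)
  ctr$significant <- FALSE
  expect_warning(out0 <- classify_dual_target_bias(ctr, gene, "dual1"),
                 "no significant")
  expect_equal(out0$n_significant, 0L)
})
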