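test_that("the generated world is deterministic and correctly sized", {
  spec <- simulation_spec(seed = 4, n_genes = 40)
  a <- simulate_study(spec)
  b <- simulate_study(spec)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$m6a_sites, b$m6a_sites)
  expect_identical(a$xlinks, b$xlinks)
  expect_equal(length(unique(a$annotation$gene_id)), 40L)
  # roughly half the genes on the minus strand
  sd_by_gene <- tapply(a$annotation$strand, a$annotation$gene_id, `[`, 1)
  expect_gt(mean(sd_by_gene == "-"), 0.3)
  expect_lt(mean(sd_by_gene == "-"), 0.7)
})

test_that("feature lengths match the requested means", {
  spec <- simulation_spec(seed = 5, n_genes = 300, utr3_mean = 300)
  w <- simulate_world(spec)
  u3 <- w$annotation[w$annotation$feature == "utr3", ]
  len <- u3$end - u3$start
  se <- sd(len) / sqrt(length(len))
  expect_lt(abs(mean(len) - 300), 3 * se + 3)  # +3 for the integer floor
})

test_that("m6A sites follow the metagene weights and spacing rule", {
  spec <- simulation_spec(seed = 6, n_genes = 800, m6a_per_gene = 2.5,
                          m6a_min_spacing = 50L,
                          metagene_weights = c(0.05, 0.25, 0.70))
  w <- simulate_world(spec)
  m <- simulate_m6a_landscape(w, spec)
  expect_gt(nrow(m$sites), 1500)
  frac_u3 <- mean(m$sites$feature == "utr3")
  expect_lt(abs(frac_u3 - 0.70), 0.03)
  # all sites inside their gene's annotated feature, spacing respected
  loc <- locate_sites(m$sites, w$annotation)
  expect_identical(loc$gene_id, m$sites$gene_id)
  expect_identical(loc$feature, m$sites$feature)
  by_gene <- split(m$sites$pos, m$sites$gene_id)
  min_gap <- min(vapply(by_gene, function(p)
    if (length(p) < 2) Inf else min(diff(sort(p))), numeric(1)))
  expect_gte(min_gap, 50)

  spec2 <- simulation_spec(seed = 6, n_genes = 40,
                           metagene_weights = c(0, 0, 1))
  w2 <- simulate_world(spec2)
  m2 <- simulate_m6a_landscape(w2, spec2)
  expect_true(all(m2$sites$feature == "utr3"))
})

test_that("reader-site geometry and replication behave as configured", {
  # ALBA4-type crosslinks average ~25 nt 5' of the m6A site
  spec <- simulation_spec(seed = 7, n_genes = 600, m6a_per_gene = 2,
                          bound_fraction_alba4 = 0.6,
                          joint_bound_fraction = 0.2)
  w <- simulate_world(spec)
  m <- simulate_m6a_landscape(w, spec)
  rd <- simulate_reader_sites(w, m, spec)
  tp <- rd$truth$alba4_xpos
  expect_gt(nrow(tp), 500)
  s <- m$sites[tp$site, ]
  d <- ifelse(s$strand == "+", tp$xpos - s$pos, s$pos - tp$xpos)
  expect_lt(abs(mean(d) - (-25)), 1)
  expect_equal(sort(unique(rd$alba4$sample_id)),
               sprintf("alba4_rep%d", 1:3))

  # no binding -> background-only channels
  spec0 <- simulation_spec(seed = 7, n_genes = 30, bound_fraction_ect2 = 0,
                           bound_fraction_alba4 = 0, joint_bound_fraction = 0)
  w0 <- simulate_world(spec0)
  m0 <- simulate_m6a_landscape(w0, spec0)
  rd0 <- simulate_reader_sites(w0, m0, spec0)
  expect_equal(nrow(rd0$truth$alba4_xpos), 0L)
})

test_that("editing counts are drawn from the stated binomial model", {
  # all effects zero with an effectively degenerate random effect: the
  # editing proportion is logistic(0) = 1/2
  spec <- simulation_spec(seed = 9, editing = list(
    beta0 = 0, beta_j = c(0, 0, 0), gamma_k = rep(0, 5), delta_jk = NULL,
    tau_A = 1e8, tau_B = 1e8, depth_mean = 50))
  sim <- simulate_editing_counts(spec, n_positions = 2000)
  p_hat <- sum(sim$table$y) / sum(sim$table$n)
  se <- sqrt(0.25 / sum(sim$table$n))
  expect_lt(abs(p_hat - 0.5), 3 * se)

  # beta0 = -2 -> logistic(-2) ~ 0.119
  spec2 <- simulation_spec(seed = 10, editing = list(
    beta0 = -2, beta_j = c(0, 0, 0), gamma_k = rep(0, 5), delta_jk = NULL,
    tau_A = 1e8, tau_B = 1e8, depth_mean = 50))
  sim2 <- simulate_editing_counts(spec2, n_positions = 2000)
  p2 <- sum(sim2$table$y) / sum(sim2$table$n)
  expect_lt(abs(p2 - plogis(-2)), 3 * sqrt(plogis(-2) * (1 - plogis(-2)) /
                                             sum(sim2$table$n)))

  expect_identical(simulate_editing_counts(spec, 100)$table,
                   simulate_editing_counts(spec, 100)$table)
  bad <- spec; bad$editing$tau_A <- -1
  expect_error(simulate_editing_counts(bad, 10), "tau")
})

test_that("the UMI matrix has the requested shape and planted structure", {
  spec <- simulation_spec(seed = 11, n_cells = 500, coexpr_theta = 1)
  um <- simulate_umi_matrix(spec, n_background = 40L)
  expect_equal(dim(um$umi), c(500L, 1L + spec$n_coexpr + 40L))
  # theta = 1: co-expression genes are independent of the anchor
  anchor <- um$umi[, "ECT2"] > 0
  g <- um$umi[, um$truth$coexpressed[1]] > 0
  or <- (sum(g & anchor) * sum(!g & !anchor)) /
    max(1, sum(g & !anchor) * sum(!g & anchor))
  expect_lt(or, 2); expect_gt(or, 0.5)
  expect_error(simulate_umi_matrix(simulation_spec(coexpr_theta = -2)),
               "theta")
})

test_that("ground truth is resolvable against the generated world", {
  st <- small_world()
  # every labeled bound site indexes an existing m6A site
  expect_true(all(st$truth$alba4_xpos$site <= nrow(st$m6a_sites)))
  expect_true(all(st$truth$ect2_xpos$site <= nrow(st$m6a_sites)))
  # target gene sets name genes of the annotation
  expect_true(all(st$truth$dual_target_genes %in% st$annotation$gene_id))
  # planted crosslink positions fall inside their gene spans
  ann <- st$annotation
  tp <- st$truth$alba4_xpos
  g <- st$m6a_sites$gene_id[tp$site]
  lo <- tapply(ann$start, ann$gene_id, min)[g]
  hi <- tapply(ann$end, ann$gene_id, max)[g]
  expect_true(all(tp$xpos >= lo & tp$xpos < hi))
})
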