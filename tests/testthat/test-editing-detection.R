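make_counts <- function(P, samples, fill = 0L) {
  pos <- data.frame(chrom = "ChrS", pos = seq_len(P) * 10L, strand = "+",
                    ref_base = "A", stringsAsFactors = FALSE)
  z <- matrix(fill, P, length(samples), dimnames = list(NULL, samples))
  editing_counts(pos, ref = z + 30L, alt = z)
}

tribe_design <- function(nf = 5, nc = 5) data.frame(
  sample = c(sprintf("f%d", seq_len(nf)), sprintf("c%d", seq_len(nc))),
  condition = rep(c("fusion", "control"), c(nf, nc)),
  replicate = c(seq_len(nf), seq_len(nc)))

test_that("candidate calling keeps exactly the mismatch-bearing positions", {
  cnt <- make_counts(1000, c("f1", "f2"))
  planted <- sample(1000, 10)
  cnt$alt[planted, "f1"] <- 1L
  out <- call_candidate_positions(cnt)
  expect_equal(nrow(out$positions), 10L)
  expect_setequal(out$positions$pos, planted * 10L)

  # a single G read at an A site is enough; all-reference rows are not
  one <- make_counts(2, "f1"); one$alt[1, 1] <- 1L
  expect_equal(nrow(call_candidate_positions(one)$positions), 1L)
})

test_that("mutation-type filtering is strand-aware in transcript space", {
  cnt <- make_counts(4, "f1", fill = 1L)
  cnt$positions$ref_base <- c("A", "A", "T", "T")
  cnt$positions$gene_strand <- c("+", "-", "-", NA)
  out <- filter_by_strand_mutation(cnt)
  # A->G on +: kept; A->G on -: wrong sense; T->C on -: kept
  expect_equal(out$positions$ref_base, c("A", "T"))
  expect_equal(out$positions$gene_strand, c("+", "-"))
  expect_equal(attr(out, "dropped_no_gene"), 1L)
  cnt$positions$gene_strand <- NULL
  expect_error(filter_by_strand_mutation(cnt), "strand")
})

test_that("replicate agreement requires alt evidence in min_reps fusion samples", {
  des <- tribe_design()
  cnt <- make_counts(2, des$sample, fill = 0L)
  cnt$alt[1, "f1"] <- 5L                    # one replicate only
  cnt$alt[2, c("f1", "f3")] <- 2L           # two replicates
  out <- filter_replicate_agreement(cnt, des, min_reps = 2)
  expect_equal(out$positions$pos, 20L)
  expect_error(filter_replicate_agreement(cnt, des, min_reps = 6), "min_reps")

  # survivor count matches an independent per-row recount
  set.seed(3)
  big <- make_counts(500, des$sample)
  big$alt[] <- rbinom(length(big$alt), 30, 0.02)
  out2 <- filter_replicate_agreement(big, des, min_reps = 2)
  brute <- sum(apply(big$alt[, des$sample[des$condition == "fusion"]] > 0, 1,
                     sum) >= 2)
  expect_equal(nrow(out2$positions), brute)
})

test_that("filters are invariant to the order of input rows", {
  set.seed(4)
  des <- tribe_design()
  cnt <- make_counts(200, des$sample)
  cnt$alt[] <- rbinom(length(cnt$alt), 30, 0.05)
  perm <- sample(200)
  flip <- cnt
  flip$positions <- flip$positions[perm, ]; rownames(flip$positions) <- NULL
  flip$ref <- flip$ref[perm, ]; flip$alt <- flip$alt[perm, ]
  a <- filter_replicate_agreement(cnt, des, 2)
  b <- filter_replicate_agreement(flip, des, 2)
  expect_setequal(a$positions$pos, b$positions$pos)
})

test_that("the pooled binomial LRT matches a glm likelihood-ratio oracle", {
  des <- tribe_design(2, 2)
  cnt <- make_counts(1, des$sample)
  cnt$ref[1, ] <- c(40L, 40L, 50L, 50L)    # fusion A=80, control A=100
  cnt$alt[1, ] <- c(10L, 10L, 1L, 0L)      # fusion G=20, control G=1
  res <- test_differential_editing(cnt, des)
  expect_equal(res$ep_fusion, 0.2)
  expect_equal(res$ep_control, 1 / 101, tolerance = 1e-12)
  expect_equal(res$log2fc, log2(0.2 / (1 / 101)), tolerance = 1e-10)
  expect_gt(res$log2fc, 1)
  # independent oracle: binomial glm LRT on the pooled 2x2
  df <- data.frame(y = c(20, 1), n = c(100, 101), cond = c("f", "c"))
  m1 <- glm(cbind(y, n - y) ~ cond, binomial(), df)
  m0 <- glm(cbind(y, n - y) ~ 1, binomial(), df)
  p_oracle <- pchisq(deviance(m0) - deviance(m1), 1, lower.tail = FALSE)
  expect_equal(res$p, p_oracle, tolerance = 1e-8)
  expect_true(res$significant)

  # identical counts in both conditions: no change, not significant
  cnt$ref[1, ] <- 45L; cnt$alt[1, ] <- 5L
  res2 <- test_differential_editing(cnt, des)
  expect_equal(res2$log2fc, 0)
  expect_false(res2$significant)
})

test_that("significance respects all three thresholds jointly", {
  sim <- simulate_tribe_counts(seed = 6, n_positions = 300, frac_edited = 0.2)
  res <- test_differential_editing(sim$counts, sim$design)
  expect_true(all(res$adj_p[res$significant] < 0.01))
  expect_true(all(res$log2fc[res$significant] > 1))
  expect_true(all(pmax(res$ep_fusion, res$ep_control)[res$significant] >= 0.01))
  expect_true(all(res$adj_p >= res$p, na.rm = TRUE))
})

test_that("gene assignment prioritizes the higher-expressed overlapping model", {
  ann <- transcript_annotation(data.frame(
    gene_id = c("gA", "gA", "gB", "gB", "gC"),
    chrom = "ChrS", strand = "+",
    feature = c("cds", "utr3", "cds", "utr3", "cds"),
    start = c(0L, 300L, 350L, 600L, 2000L),
    end = c(300L, 500L, 600L, 900L, 2500L)))
  expr <- data.frame(gene_id = c("gA", "gB", "gC"), mean = c(10, 100, 5))
  cnt <- make_counts(3, "f1")
  cnt$positions$pos <- c(100L, 420L, 1500L)  # gA only; gA+gB overlap; intergenic
  out <- annotate_positions_to_genes(cnt, ann, expr)
  expect_equal(out$positions$gene_id, c("gA", "gB", NA))
  expect_equal(out$positions$gene_strand, c("+", "+", NA))
})

test_that("the TRIBE target set shrinks monotonically with alpha", {
  sim <- simulate_tribe_counts(seed = 7, n_positions = 800, frac_edited = 0.15,
                               ep_fusion = 0.08)
  res <- test_differential_editing(sim$counts, sim$design, alpha = 0.05)
  res$gene_id <- paste0("g", ceiling(seq_len(nrow(res)) / 4))
  t_loose <- tribe_targets(res)
  res2 <- test_differential_editing(sim$counts, sim$design, alpha = 0.001)
  res2$gene_id <- res$gene_id
  t_tight <- tribe_targets(res2)
  expect_true(all(t_tight %in% t_loose))
})
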