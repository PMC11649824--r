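test_that("matched backgrounds reproduce the feature/bin histogram exactly", {
  st <- small_world()
  true_sites <- st$m6a_sites
  bg <- matched_background(true_sites, st$annotation, exclusion_bp = 100,
                           seed = 3)
  expect_equal(nrow(bg$background), nrow(true_sites))
  loc_t <- locate_sites(true_sites, st$annotation)
  loc_b <- locate_sites(bg$background, st$annotation)
  bins <- 50L
  h <- function(loc) table(loc$feature,
                           pmin((loc$feature_offset * bins) %/%
                                  loc$feature_length, bins - 1L))
  expect_equal(h(loc_b), h(loc_t))
  # exclusion holds for every background site against every true site
  for (ch in unique(bg$background$chrom)) {
    tb <- true_sites$pos[true_sites$chrom == ch]
    bb <- bg$background$pos[bg$background$chrom == ch]
    dmin <- vapply(bb, function(p) min(abs(tb - p)), numeric(1))
    expect_gt(min(dmin), 100)
  }
})

test_that("the expression-matched pool preserves the background invariants", {
  st <- small_world()
  sub <- st$m6a_sites[1:80, ]
  bg <- matched_background(sub, st$annotation, expression = st$expression,
                           exclusion_bp = 100, expression_matched = TRUE,
                           seed = 9)
  expect_equal(nrow(bg$background), 80L)
  loc_t <- locate_sites(sub, st$annotation)
  loc_b <- locate_sites(bg$background, st$annotation)
  expect_identical(table(loc_b$feature), table(loc_t$feature))
  expect_error(matched_background(sub, st$annotation,
                                  expression_matched = TRUE),
               "expression required")
})

test_that("distance profiles count signed transcript-oriented offsets", {
  anchors <- site_records("c", seq(10000L, 509000L, 1000L), "+", 1)  # 500
  q <- site_records("c", anchors$pos[1:3] - 10L, "+", 1)
  pr <- distance_profile(q, anchors, max_d = 50)
  expect_equal(pr$count[pr$offset == -10], 3L)
  expect_equal(pr$per_1000[pr$offset == -10], 6.0)
  expect_equal(sum(pr$count), 3L)
  # query set = anchor set: spike of 1000 per 1000 at offset 0
  self <- distance_profile(anchors, anchors, max_d = 20)
  expect_equal(self$per_1000[self$offset == 0], 1000)
  # minus-strand anchors flip the sign (negative = transcript 5')
  am <- site_records("c", 5000L, "-", 1)
  qm <- site_records("c", 5010L, "-", 1)   # genomically 3'+10 = 5' on minus
  pm <- distance_profile(qm, am, max_d = 20)
  expect_equal(pm$count[pm$offset == -10], 1L)
})

test_that("distance profiles equal a brute-force all-pairs oracle", {
  set.seed(35)
  a <- site_records("c", sample(1:50000, 200), sample(c("+", "-"), 200, TRUE), 1)
  q <- site_records("c", sample(1:50000, 200), sample(c("+", "-"), 200, TRUE), 1)
  pr <- distance_profile(q, a, max_d = 300)
  brute <- integer(601)
  for (i in seq_len(200)) for (j in seq_len(200)) {
    if (a$strand[i] != q$strand[j]) next
    d <- q$pos[j] - a$pos[i]
    if (a$strand[i] == "-") d <- -d
    if (abs(d) <= 300) brute[d + 301] <- brute[d + 301] + 1L
  }
  expect_equal(pr$count, brute)
})

test_that("motif occurrence profiles match a regex-scan oracle", {
  st <- small_world()
  anchors <- st$m6a_sites[1:100, ]
  prof <- motif_occurrence_profile("TATTTT", anchors, st$genome,
                                   max_d = 100)[[1]]
  k <- 6L
  seqs <- extract_window(st$genome, anchors$chrom, anchors$pos,
                         anchors$strand, 100L + k - 1L)
  brute <- integer(201)
  for (s in seqs) {
    hits <- gregexpr("TATTTT", s, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    off <- as.integer(hits) - (100L + k)
    off <- off[abs(off) <= 100]
    for (o in off) brute[o + 101] <- brute[o + 101] + 1L
  }
  expect_equal(prof$count, brute)
  none <- motif_occurrence_profile("TTTTTTTTTTTTTTTT", anchors,
                                   st$genome, max_d = 50)[[1]]
  expect_true(all(none$count == 0))
  expect_error(motif_occurrence_profile("TAXTTT", anchors, st$genome),
               "A/C/G/T/U")
})

test_that("metagene profiles conserve counts and scale per feature", {
  ann <- transcript_annotation(data.frame(
    gene_id = "g", chrom = "c", strand = "+",
    feature = c("utr5", "cds", "utr3"),
    start = c(0L, 100L, 200L), end = c(100L, 200L, 300L)))
  s <- site_records("c", 150L, "+", 1)    # CDS nt 50 of 100 -> 0.5
  mp <- metagene_profile(s, ann, bins_per_feature = 10)
  h <- mp$histogram
  expect_equal(h$count[h$feature == "cds" & abs(h$bin_mid - 0.55) < 0.01], 1L)
  expect_equal(sum(h$count), 1L)

  st <- small_world()
  mp2 <- metagene_profile(st$m6a_sites, st$annotation)
  expect_equal(sum(mp2$histogram$count) + mp2$n_unassigned,
               nrow(st$m6a_sites))
  u3 <- st$m6a_sites[st$m6a_sites$feature == "utr3", ]
  mp3 <- metagene_profile(u3, st$annotation)
  h3 <- mp3$histogram
  expect_true(all(h3$count[h3$feature != "utr3"] == 0))
})

test_that("the folded permutation p-value formula is implemented verbatim", {
  expect_equal(coreader:::.perm_p(500, 1000), 1.0)
  expect_equal(coreader:::.perm_p(250, 1000), 0.5)
  expect_equal(coreader:::.perm_p(0, 1000), 0.0)
  expect_equal(coreader:::.perm_p(1000, 1000), 0.0)

  universe <- paste0("g", 1:500)
  expr <- data.frame(gene_id = universe, mean = rlnorm(500))
  # A = B strongly overlapping: no random draw beats the observed overlap
  A <- universe[1:60]
  ot <- overlap_permutation_test(A, A, universe, expr, n_perm = 200,
                                 seed = 1)
  expect_equal(ot$hsum, 0L)
  expect_equal(ot$p_label, "<0.005")
  expect_equal(ot$observed, 60L)
  expect_length(ot$example_set, 60L)
  expect_true(all(ot$example_set %in% universe))
  expect_error(overlap_permutation_test(paste0("x", 1:600), A, universe),
               "universe")
})

test_that("the permutation test is calibrated when A is itself random", {
  set.seed(36)
  universe <- paste0("g", 1:400)
  expr <- data.frame(gene_id = universe, mean = rlnorm(400))
  B <- sample(universe, 80)
  ps <- vapply(1:20, function(s) {
    A <- sample(universe, 50)
    overlap_permutation_test(A, B, universe, expr, n_perm = 200,
                             seed = s)$p
  }, numeric(1))
  expect_gte(median(ps), 0.3)
})

test_that("strict and permissive target sets are intersection and union", {
  expect_equal(define_target_sets(c("g1", "g2"), c("g2", "g3"), "strict"),
               "g2")
  expect_equal(define_target_sets(c("g1", "g2"), c("g2", "g3"), "permissive"),
               c("g1", "g2", "g3"))
  expect_length(define_target_sets("a", "b", "strict"), 0L)
  s <- define_target_sets(c("g1", "g2"), c("g2", "g3"), "strict")
  p <- define_target_sets(c("g1", "g2"), c("g2", "g3"), "permissive")
  expect_true(all(s %in% p))
})

test_that("co-expression matching pairs cells of similar depth", {
  spec <- simulation_spec(seed = 37, n_cells = 600, coexpr_theta = 16)
  um <- simulate_umi_matrix(spec)
  res <- coexpression_fisher(um$umi, "ECT2")
  pairs <- attr(res, "matched_pairs")
  tot <- rowSums(um$umi)
  gap <- mean(abs(tot[pairs$pos] - tot[pairs$neg]))
  expect_lt(gap, 0.1 * mean(tot))
  # genes below 20% presence among matched cells are not tested
  expect_true(all(res$gene %in% colnames(um$umi)))
  sub <- um$umi[c(pairs$pos, pairs$neg), ]
  frac <- colMeans(sub[, res$gene, drop = FALSE] > 0)
  expect_true(all(frac >= 0.2 & frac <= 0.8))
  # planted co-expression shows elevated odds ratios
  or_co <- res$odds_ratio[res$gene %in% um$truth$coexpressed]
  or_bg <- res$odds_ratio[!res$gene %in% um$truth$coexpressed]
  expect_gt(median(or_co), 4)
  expect_lt(median(or_bg), 2)
  expect_error(coexpression_fisher(um$umi, "nope"), "anchor")
})

test_that("worked 2x2 example: (80,20;20,80) has odds ratio near 16", {
  # conditional MLE from fisher.test differs slightly from the raw
  # cross-product 16; both are checked
  ft <- fisher.test(matrix(c(80, 20, 20, 80), 2))
  expect_equal((80 * 80) / (20 * 20), 16)
  expect_gt(ft$estimate, 10)
  expect_lt(ft$p.value, 1e-10)
})
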