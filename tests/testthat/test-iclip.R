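test_that("adjacent-peak merging picks the leftmost max-score summit", {
  pk <- site_records(chrom = "c", pos = c(100L, 101L, 102L), strand = "+",
                     score = c(5, 7, 6))
  expect_equal(merge_adjacent_peaks(pk)$pos, 101L)
  lone <- site_records("c", 500L, "+", 3)
  expect_equal(merge_adjacent_peaks(lone)$pos, 500L)
  tie <- site_records("c", c(10L, 11L), "+", c(4, 4))
  expect_equal(merge_adjacent_peaks(tie)$pos, 10L)
  dup <- site_records("c", c(10L, 10L), "+", c(1, 2))
  expect_error(merge_adjacent_peaks(dup), "duplicate")
})

test_that("merging matches a connected-components brute-force oracle", {
  set.seed(12)
  pos <- sort(sample(1:2000, 500))
  pos <- pos[!duplicated(pos)]
  pk <- site_records("c", pos, "+", round(runif(length(pos)), 3))
  got <- merge_adjacent_peaks(pk)
  # oracle: group maximal runs of consecutive positions, take argmax
  runs <- cumsum(c(1, diff(pos) != 1))
  oracle <- vapply(split(seq_along(pos), runs), function(i) {
    s <- pk$score[i]
    pos[i][which(s == max(s))[1]]
  }, numeric(1))
  expect_equal(got$pos, unname(sort(oracle)))
})

test_that("binding sites are 9-nt with exact crosslink tallies", {
  summit <- site_records("c", 100L, "+", 5)
  xl <- site_records("c", c(96L, 100L, 104L, 105L), "+",
                     c(2, 3, 1, 9), sample_id = "r1")
  bs <- define_binding_sites(summit, xl)
  expect_equal(bs$sites$start, 96L)
  expect_equal(bs$sites$end, 105L)          # [96, 105): -4..+4 inclusive
  expect_equal(unname(bs$rep_totals[1, "r1"]), 6)  # 105 is outside
  expect_equal(unname(bs$pos_counts[1, c("-4", "0", "4")]), c(2, 3, 1))

  none <- define_binding_sites(summit,
                               site_records("c", 500L, "+", 1, "r1"))
  expect_true(all(none$pos_counts == 0))
  edge <- define_binding_sites(site_records("c", 2L, "+", 1), xl)
  expect_equal(nrow(edge$sites), 0L)

  # recount oracle on a 50-site fixture with 3 replicates
  set.seed(13)
  sm <- site_records("c", sort(sample(seq(10, 5000, 10), 50)), "+", 1)
  xl3 <- site_records("c", sample(1:5000, 600, TRUE), "+",
                      score = sample(1:4, 600, TRUE),
                      sample_id = sample(c("r1", "r2", "r3"), 600, TRUE))
  bs3 <- define_binding_sites(sm, xl3)
  for (i in sample(50, 8)) for (r in c("r1", "r2", "r3")) {
    span <- (sm$pos[i] - 4):(sm$pos[i] + 4)
    brute <- sum(xl3$score[xl3$sample_id == r & xl3$pos %in% span])
    expect_equal(unname(bs3$rep_totals[i, r]), brute)
  }
})

test_that("single-position artifacts are removed, boundary at 2 of 9", {
  sm <- site_records("c", c(100L, 200L, 300L), "+", 1)
  xl <- rbind(site_records("c", 100L, "+", 10, "r1"),            # 1 position
              site_records("c", c(199L, 201L), "+", 1, "r1"))    # 2 positions
  bs <- define_binding_sites(sm, xl)
  out <- remove_single_position_artifacts(bs)
  expect_equal(out$sites$summit, 200L)   # summit-only and zero-count removed
})

test_that("the reproducibility filter applies strict per-replicate thresholds", {
  sm <- site_records("c", seq(100L, 1000L, 100L), "+", 1)
  set.seed(14)
  xl <- do.call(rbind, lapply(c("r1", "r2", "r3"), function(r)
    site_records("c", sm$pos, "+", sample(0:8, 10, TRUE), r)))
  xl <- xl[xl$score > 0, ]
  bs <- define_binding_sites(sm, xl)
  out <- reproducibility_filter(bs, q = 0.30, min_reps = 2)
  thr <- apply(bs$rep_totals, 2, quantile, probs = 0.30)
  keep <- rowSums(sweep(bs$rep_totals, 2, thr, `>`)) >= 2
  expect_equal(out$sites$summit, bs$sites$summit[keep])
  # q = 0 keeps a superset of any q > 0 (monotonicity)
  s0 <- reproducibility_filter(bs, q = 0, min_reps = 2)$sites$summit
  s3 <- reproducibility_filter(bs, q = 0.3, min_reps = 2)$sites$summit
  expect_true(all(s3 %in% s0))
  expect_error(reproducibility_filter(bs, min_reps = 9), "min_reps")
})

test_that("worked example: totals (5, 0, 2) against thresholds (1, 1, 1)", {
  sm <- site_records("c", 100L, "+", 1)
  # many weak decoy sites set each replicate's 30% quantile to 1
  decoys <- site_records("c", seq(200L, 2100L, 100L), "+", 1)
  xl <- rbind(
    site_records("c", c(98L, 100L), "+", c(2, 3), "r1"),
    site_records("c", c(99L, 101L), "+", 1, "r3"),
    do.call(rbind, lapply(c("r1", "r2", "r3"), function(r)
      site_records("c", decoys$pos, "+", 1, r))))
  bs <- define_binding_sites(rbind(sm, decoys), xl)
  i <- which(bs$sites$summit == 100L)
  expect_equal(unname(bs$rep_totals[i, ]), c(5, 0, 2))
  thr <- apply(bs$rep_totals, 2, quantile, probs = 0.30)
  expect_equal(unname(thr), c(1, 1, 1))
  out <- reproducibility_filter(bs, 0.30, 2)
  expect_true(100L %in% out$sites$summit)   # above 1 in r1 and r3
})

test_that("control subtraction removes >= 1 nt same-strand interval overlaps", {
  mk <- function(pos, strand = "+") {
    bs <- define_binding_sites(site_records("c", pos, strand, 1),
                               site_records("c", pos, strand, 1, "r1"))
    bs
  }
  bs <- mk(100L)
  expect_equal(nrow(subtract_control_sites(bs, mk(100L))$sites), 0L)
  expect_equal(nrow(subtract_control_sites(bs, mk(109L))$sites), 1L)  # abut
  expect_equal(nrow(subtract_control_sites(bs, mk(108L))$sites), 0L)
  expect_equal(nrow(subtract_control_sites(bs, mk(100L, "-"))$sites), 1L)

  set.seed(15)
  a <- define_binding_sites(
    site_records("c", sort(sample(seq(10, 9000, 9), 200)), "+", 1),
    site_records("c", 1L, "+", 1, "r1"))
  b <- define_binding_sites(
    site_records("c", sort(sample(seq(10, 9000, 7), 120)), "+", 1),
    site_records("c", 1L, "+", 1, "r1"))
  out <- subtract_control_sites(a, b)
  brute <- vapply(seq_len(nrow(a$sites)), function(i)
    !any(a$sites$start[i] < b$sites$end & b$sites$start < a$sites$end[i]),
    logical(1))
  expect_equal(out$sites$summit, a$sites$summit[brute])
})

test_that("strong peaks exceed the per-gene median score", {
  bs <- define_binding_sites(
    site_records("c", c(100L, 200L, 300L, 1000L, 2000L), "+", c(1, 2, 3, 4, 4)),
    site_records("c", 1L, "+", 1, "r1"))
  bs$sites$gene_id <- c("g1", "g1", "g1", "g2", "g2")
  out <- strong_peak_filter(bs)
  expect_equal(out$sites$summit, 300L)      # 3 > median 2; g2 all-equal drops
  single <- bs; single$sites$gene_id <- c("g1", "g1", "g1", "g2", "g3")
  out2 <- strong_peak_filter(single)
  expect_true(all(c(1000L, 2000L) %in% out2$sites$summit))  # singles kept
  out3 <- strong_peak_filter(single, keep_single = FALSE)
  expect_false(any(c(1000L, 2000L) %in% out3$sites$summit))
})

test_that("each cascade stage only removes sites and is idempotent", {
  st <- small_world()
  bs <- define_binding_sites(merge_adjacent_peaks(st$peaks$alba4),
                             st$xlinks$alba4)
  a <- remove_single_position_artifacts(bs)
  expect_true(all(a$sites$summit %in% bs$sites$summit))
  expect_equal(remove_single_position_artifacts(a)$sites, a$sites)
  r <- reproducibility_filter(a)
  expect_true(all(r$sites$summit %in% a$sites$summit))
})

test_that("the pipeline is a pure function of its inputs (bit-exact BED)", {
  st <- small_world()
  run <- function() {
    res <- iclip_pipeline(st$peaks$alba4, st$xlinks$alba4,
                          st$peaks$control, st$xlinks$control, st$annotation)
    path <- tempfile(fileext = ".bed")
    write_binding_sites(res$bs, path)
    on.exit(unlink(path))
    readLines(path)
  }
  expect_identical(run(), run())
})

test_that("targets are genes overlapping surviving sites, strand-matched", {
  st <- small_world()
  res <- iclip_pipeline(st$peaks$alba4, st$xlinks$alba4, st$peaks$control,
                        st$xlinks$control, st$annotation)
  expect_true(all(res$targets %in% st$annotation$gene_id))
  # intergenic site contributes nothing
  bs <- define_binding_sites(site_records("ChrS", 5L, "+", 1),
                             site_records("ChrS", 5L, "+", 1, "r1"))
  bs2 <- define_binding_sites(site_records("ChrS", 50L, "+", 1),
                              site_records("ChrS", 50L, "+", 1, "r1"))
  expect_equal(length(assign_targets(bs2, st$annotation)$targets), 0L)
})
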