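test_that("variant usage: stable proportions give p = 1, flips are caught", {
  ages <- 12
  stable <- rbind(seq(100, 320, length.out = ages) * 0.7,
                  seq(100, 320, length.out = ages) * 0.3)
  res <- variant_usage_test(stable)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  tot <- rep(1000, ages)
  shareA <- seq(0.9, 0.1, length.out = ages)
  flip <- rbind(tot * shareA, tot * (1 - shareA))
  res2 <- variant_usage_test(flip)
  expect_lt(res2$p, 1e-4)
  # direct chi-square computation on the constructed table
  expected <- outer(rowSums(flip), colSums(flip)) / sum(flip)
  stat_hand <- sum((flip - expected)^2 / expected)
  expect_equal(res2$statistic, stat_hand, tolerance = 1e-9)

  # a variant that is always zero reduces to the single-variant case
  res3 <- variant_usage_test(rbind(tot, 0))
  expect_false(res3$applicable)
  expect_equal(res3$p, 1)
  expect_error(variant_usage_test(matrix(tot, 1)), ">= 2 transcripts")
})

test_that("Durbin-Watson reproduces hand-computed values", {
  expect_equal(durbin_watson(rep(c(1, -1), 6)), 44 / 12)
  expect_equal(durbin_watson(1:12), 11 / 143)
  expect_error(durbin_watson(rep(2, 12)), "constant")
  expect_error(durbin_watson(c(1, 2)), "length >= 3")
})

test_that("DW is location-invariant, scale-invariant and centers on 2", {
  set.seed(101)
  x <- rnorm(12)
  d0 <- durbin_watson(x)
  expect_equal(durbin_watson(x + 7), d0)
  expect_equal(durbin_watson(x * -3.5), d0)
  m <- matrix(rnorm(5000 * 12), 5000, 12)
  dws <- apply(m, 1, durbin_watson)
  expect_lt(abs(mean(dws) - 2), 0.05)
  expect_true(all(dws >= 0 & dws <= 4))
})

test_that("permutation p-values flag smooth series and obey the add-one bound", {
  smooth <- archetype_profiles()$base[, "early"]
  p <- dw_pvalue(smooth, n_perm = 999, seed = 3)
  expect_lte(p, 0.01)
  expect_gte(p, 1 / 1000)
  set.seed(7)
  p_noise <- dw_pvalues(matrix(rnorm(50 * 12), 50, 12), 999, seed = 5)
  expect_true(all(p_noise >= 1 / 1000))
  expect_gt(mean(p_noise > 0.05), 0.8)
  expect_identical(dw_pvalue(smooth, seed = 11), dw_pvalue(smooth, seed = 11))
})

test_that("permutation p-values are near-uniform on exchangeable noise", {
  set.seed(13)
  p <- dw_pvalues(matrix(rnorm(400 * 12), 400, 12), 999, seed = 17)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 1e-3)
})

test_that("the two-stage filter requires expression then coherence", {
  d <- default_age_design()
  iso <- simulate_isoform_series(10, 10, seed = 19)
  # add a strongly autocorrelated but never-expressed candidate
  s <- archetype_profiles()$base[, "late"]
  dark <- 2^(-8 + 1.5 * rep(s, each = 3))
  vals <- rbind(iso$matrix$values, dark)
  em <- expression_matrix(vals, c(iso$matrix$feature_ids, "dark"),
                          d, "transcript")
  rec <- filter_novel_isoforms(em, seed = 23)
  expect_false(rec$passes_filter[rec$transcript_id == "dark"])
  expect_false(rec$expressed_any[rec$transcript_id == "dark"])
  auto <- iso$truth$autocorrelated[match(rec$transcript_id[1:20],
                                         iso$truth$transcript_id)]
  expect_true(all(rec$passes_filter[1:20][auto]))
  expect_true(mean(rec$passes_filter[1:20][!auto]) <= 0.2)
  expect_true(all(rec$dw >= 0 & rec$dw <= 4, na.rm = TRUE))
})

test_that("splice events classify the canonical toy topologies", {
  # reference with three exons; novel skips exon 2 joining 1-3
  ref <- transcript_model("ref", "g", "chr5", "+",
                          cbind(c(100, 300, 600), c(200, 400, 700)))
  skip <- transcript_model("n1", "g", "chr5", "+",
                           cbind(c(100, 600), c(200, 700)))
  ev <- classify_splice_event(skip, list(ref))
  expect_identical(ev$event_type, "exon_skip")
  expect_equal(c(ev$start, ev$end), c(300, 400))

  # two-exon reference; novel single exon retains the intron
  ref2 <- transcript_model("ref2", "g2", "chr5", "+",
                           cbind(c(100, 300), c(200, 400)))
  ret <- transcript_model("n2", "g2", "chr5", "+", cbind(100, 400))
  ev2 <- classify_splice_event(ret, list(ref2))
  expect_identical(ev2$event_type, "intron_retention")
  expect_equal(c(ev2$start, ev2$end), c(200, 300))

  # downstream start, all else identical
  alt <- transcript_model("n3", "g", "chr5", "+",
                          cbind(c(150, 300, 600), c(200, 400, 700)))
  ev3 <- classify_splice_event(alt, list(ref))
  expect_identical(ev3$event_type, "alt_start")

  # minus strand: the start boundary is the right-most coordinate
  refm <- transcript_model("refm", "gm", "chr5", "-",
                           cbind(c(100, 300), c(200, 400)))
  altm <- transcript_model("n4", "gm", "chr5", "-",
                           cbind(c(100, 300), c(200, 380)))
  evm <- classify_splice_event(altm, list(refm))
  expect_identical(evm$event_type, "alt_start")

  # no reference at all
  ev0 <- classify_splice_event(skip, list())
  expect_identical(ev0$event_type, "unclassified")
  # best-matching reference wins: give both, expect the 3-exon one chosen
  ev4 <- classify_splice_event(skip, list(ref2_far <- transcript_model(
    "far", "g", "chr5", "+", cbind(c(1000, 2000), c(1100, 2100))), ref))
  expect_identical(unique(ev4$reference_id), "ref")
  expect_error(classify_splice_event(
    skip, list(transcript_model("x", "g", "chr2", "+", cbind(1, 10)))),
    "share chrom")
})
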