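test_that("hypergeometric overlap matches exhaustive enumeration", {
  # all 5 draws hitting a 5-element set out of 10: 1 / C(10,5)
  expect_equal(hypergeom_overlap(10, 5, 5, 5), 1 / choose(10, 5))
  expect_equal(hypergeom_overlap(50, 10, 20, 0), 1)
  # direct enumeration oracle at small N
  p_enum <- sum(vapply(3:5, function(k)
    choose(6, k) * choose(6, 5 - k) / choose(12, 5), numeric(1)))
  expect_equal(hypergeom_overlap(12, 6, 5, 3), p_enum, tolerance = 1e-12)
  expect_error(hypergeom_overlap(10, 5, 5, 6), "overlap")
  expect_error(hypergeom_overlap(10, 11, 5, 2), "universe")
})

test_that("hypergeometric p is non-increasing in the overlap", {
  p <- vapply(0:20, function(k) hypergeom_overlap(100, 30, 20, k), numeric(1))
  expect_true(all(diff(p) <= 0))
})

test_that("fisher_right_tail equals the hypergeometric tail and fisher.test", {
  set.seed(61)
  for (i in 1:100) {
    N <- sample(20:200, 1)
    universe <- paste0("u", seq_len(N))
    term <- sample(universe, sample(N, 1))
    query <- sample(universe, sample(N, 1))
    res <- fisher_right_tail(query, term, universe)
    expect_equal(res$p, hypergeom_overlap(N, length(term), length(query),
                                          res$k), tolerance = 1e-12)
    if (i <= 10) {
      tab <- matrix(c(res$k, length(term) - res$k,
                      length(query) - res$k,
                      N - length(term) - length(query) + res$k), 2, 2)
      expect_equal(res$p,
                   fisher.test(tab, alternative = "greater")$p.value,
                   tolerance = 1e-9)
    }
  }
})

test_that("degenerate overlap configurations give p = 1", {
  u <- paste0("g", 1:30)
  expect_equal(fisher_right_tail(u, u, u)$p, 1)
  expect_equal(fisher_right_tail(u[1:10], u[11:30], u)$p, 1)
  expect_error(fisher_right_tail("x", u[1], u), "subsets")
  expect_error(fisher_right_tail(character(), u[1], character()), "empty")
})

test_that("chi-square independence matches the hand formula", {
  tab <- matrix(c(10, 20, 20, 10), 2, 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat_hand <- sum((tab - expected)^2 / expected)
  res <- chi_square_independence(tab)
  expect_equal(res$statistic, stat_hand)
  expect_identical(res$df, 1L)
  expect_equal(res$p, pchisq(stat_hand, 1, lower.tail = FALSE))

  flat <- matrix(c(5, 7, 5, 7), 2, 2, byrow = TRUE)
  res2 <- chi_square_independence(flat)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p, 1)

  expect_error(chi_square_independence(matrix(1:4, 1, 4)), "degenerate")
  expect_error(chi_square_independence(matrix(c(1, 0, 0, 1), 2, 2)),
               "expected count")
})

test_that("chi-square p-values are near-uniform under independence", {
  set.seed(67)
  p <- replicate(400, {
    tab <- matrix(rpois(4, 40), 2, 2)
    if (any(outer(rowSums(tab), colSums(tab)) / sum(tab) < 1)) NA_real_
    else chi_square_independence(tab)$p
  })
  p <- p[!is.na(p)]
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 1e-3)
})

test_that("activation z is the normalized sign-consistency sum", {
  obs <- c(a = 1, b = 1, c = 1, d = 1)
  exp4 <- c(a = 1, b = 1, c = 1, d = 1)
  expect_equal(activation_z(obs, exp4), 2)           # 4 / sqrt(4)
  exp_half <- c(a = 1, b = 1, c = -1, d = -1)
  expect_equal(activation_z(obs, exp_half), 0)
  obs9 <- setNames(rep(1, 9), letters[1:9])
  exp9 <- setNames(rep(-1, 9), letters[1:9])
  expect_equal(activation_z(obs9, exp9), -3)
  # unknown-direction targets are excluded
  expect_equal(activation_z(obs, c(a = 1, b = 0, c = 0, d = 0)), 1)
  expect_error(activation_z(obs, c(a = 0, b = 0, c = 0, d = 0)),
               "no targets")
})

test_that("BH adjustment reproduces the step-up hand computation", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # order-preserving in the p-value ranks
  set.seed(71)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("hit counts tally targets per group with conserved marginals", {
  assignments <- data.frame(
    feature_id = paste0("g", 1:8),
    group = c(rep("Prenatal and Neonatal", 6), "Adult", NA),
    stringsAsFactors = FALSE)
  net <- regulator_network(
    c(rep("R1", 6), "R2", "R2", "R3"),
    c(paste0("g", 1:6), "g7", "g8", "gX"),
    rep(1L, 9))
  hc <- hit_count_matrix(net, assignments)
  expect_equal(unname(hc["R1", ]), c(6, 0, 0, 0, 0, 0))
  expect_equal(sum(hc["R2", ]), 1)   # g8 is unassigned, gX unknown
  expect_equal(sum(hc["R3", ]), 0)
  # independent tally on a random fixture
  set.seed(73)
  asn <- data.frame(feature_id = paste0("g", 1:40),
                    group = sample(temporal_group_labels(), 40, TRUE),
                    stringsAsFactors = FALSE)
  all_pairs <- expand.grid(r = paste0("R", 1:5), t = paste0("g", 1:40),
                           stringsAsFactors = FALSE)
  pick <- all_pairs[sample(nrow(all_pairs), 60), ]
  net2 <- regulator_network(pick$r, pick$t)
  hc2 <- hit_count_matrix(net2, asn)
  for (r in rownames(hc2)) {
    tg <- unique(net2$target[net2$regulator == r])
    expect_equal(sum(hc2[r, ]), sum(tg %in% asn$feature_id))
  }
})

test_that("differential direction compares each age to the gene average", {
  d <- default_age_design()
  v <- rep(c(rep(10, 6), rep(1000, 6)), each = 3)
  em <- toy_matrix(matrix(v, 1, 36, byrow = TRUE), d)
  dd <- differential_direction(em)
  expect_true(all(dd[1, 1:6] == -1))
  expect_true(all(dd[1, 7:12] == 1))
})
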