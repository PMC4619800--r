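test_that("ICC hits the exact values on identical and opposite pairs", {
  s <- sin(seq(0, 3, length.out = 12))
  expect_equal(icc_winer(rbind(s, s)), 1)
  expect_equal(icc_winer(rbind(s, -s)), -1)
  expect_equal(icc_winer(rbind(s, s, s)), 1)
  expect_error(icc_winer(rbind(s, rep(2, 12))), "zero-variance")
  expect_error(icc_winer(matrix(s, 1)), "2 series")
  expect_error(icc_winer(matrix(rnorm(4), 2, 2)), "length >= 3")
})

test_that("pairwise ICC equals the Pearson correlation of the pair", {
  set.seed(83)
  for (i in 1:100) {
    x <- matrix(rnorm(24), 2, 12)
    z <- t(scale(t(x)))
    expect_equal(icc_winer(x), max(-1, min(1, cor(z[1, ], z[2, ]))),
                 tolerance = 1e-9)
  }
})

test_that("ICC equals the mean pairwise correlation for larger sets", {
  set.seed(89)
  for (m in c(3, 4, 6)) {
    x <- matrix(rnorm(m * 12), m, 12)
    expect_equal(icc_winer(x), max(-1, min(1, oracle_icc_mean_r(x))),
                 tolerance = 1e-9)
  }
})

# fixture: regulators with controlled series and target sets
module_fixture <- function(series, targets, group_genes,
                           design = default_age_design()) {
  regs <- names(series)
  vals <- do.call(rbind, lapply(series, function(s)
    2^(5 + rep(s, each = design$replicates))))
  em <- expression_matrix(vals, regs, design)
  edges_r <- unlist(mapply(function(r, tg) rep(r, length(tg)),
                           regs, targets[regs], SIMPLIFY = FALSE))
  edges_t <- unlist(targets[regs])
  net <- regulator_network(edges_r, edges_t, rep(1L, length(edges_r)))
  list(net = net, em = em, group = group_genes)
}

test_that("a clean co-regulating pair yields exactly one module", {
  s <- archetype_profiles()$base[, "early"]
  u <- archetype_profiles()$base[, "late"]
  g6 <- paste0("g", 1:6)
  fx <- module_fixture(
    list(A = s, B = s, C = u),
    list(A = g6, B = g6, C = paste0("g", 7:12)),
    group_genes = g6)
  mods <- find_modules(fx$net, fx$em, fx$group)
  expect_length(mods, 1L)
  expect_identical(mods[[1]]$regulators, c("A", "B"))
  expect_equal(mods[[1]]$icc, 1, tolerance = 1e-9)
  expect_length(mods[[1]]$targets, 6L)
})

test_that("fewer than min_targets shared genes blocks the merge", {
  s <- archetype_profiles()$base[, "early"]
  fx <- module_fixture(
    list(A = s, B = s),
    list(A = paste0("g", 1:4), B = paste0("g", 1:4)),
    group_genes = paste0("g", 1:4))
  expect_length(find_modules(fx$net, fx$em, fx$group), 0L)
  # the seed-only flag readmits deeper merges, not the first 2-tuple
  expect_length(find_modules(fx$net, fx$em, fx$group,
                             min_targets_seed_only = TRUE), 0L)
  expect_length(find_modules(fx$net, fx$em, fx$group, min_targets = 4L), 1L)
})

test_that("discovery equals exhaustive subset enumeration on small fixtures", {
  base <- archetype_profiles()$base
  g <- paste0("g", 1:10)
  set.seed(97)
  for (rep in 1:6) {
    n_reg <- sample(4:6, 1)
    regs <- LETTERS[seq_len(n_reg)]
    series <- lapply(regs, function(r) {
      w <- base %*% rnorm(3)
      drop(w / sd(w)) * sample(c(1, -1), 1)
    })
    names(series) <- regs
    targets <- lapply(regs, function(r) sample(g, sample(5:10, 1)))
    names(targets) <- regs
    fx <- module_fixture(series, targets, group_genes = g)
    mods <- find_modules(fx$net, fx$em, fx$group)
    got <- sort(vapply(mods, function(m)
      paste(m$regulators, collapse = "|"), character(1)))
    want <- oracle_module_subsets(fx$net, fx$em, fx$group)
    expect_identical(got, want, label = paste("fixture", rep))
    # every emitted module re-validates against both constraints
    for (m in mods) {
      expect_gte(abs(m$icc), 0.6)
      expect_gte(length(m$targets), 5L)
      shared <- Reduce(intersect, lapply(m$regulators, function(r)
        intersect(fx$net$target[fx$net$regulator == r], fx$group)))
      expect_setequal(m$targets, shared)
    }
  }
})

test_that("module discovery is order-independent and drops unknown regulators", {
  s <- archetype_profiles()$base[, "mid"]
  g6 <- paste0("g", 1:6)
  fx <- module_fixture(list(A = s, B = s, C = -s),
                       list(A = g6, B = g6, C = g6), g6)
  mods1 <- find_modules(fx$net, fx$em, fx$group)
  # permute edge order
  net2 <- fx$net[rev(seq_len(nrow(fx$net))), ]
  class(net2) <- class(fx$net)
  mods2 <- find_modules(net2, fx$em, fx$group)
  expect_identical(summarize_modules(mods1), summarize_modules(mods2))
  # {A,B} correlated, {A,C}/{B,C} anti-correlated, {A,B,C} mixed
  sm <- summarize_modules(mods1)
  expect_setequal(sm$regulators[sm$sign == "anti-correlated"],
                  c("A|C", "B|C"))
  # a regulator with no expression row is excluded with a warning
  net3 <- regulator_network(c(fx$net$regulator, "ghost"),
                            c(fx$net$target, "g1"),
                            c(fx$net$direction, 1L))
  expect_warning(find_modules(net3, fx$em, fx$group), "ghost")
})

test_that("summaries label ICC signs", {
  mods <- list(list(regulators = c("A", "B"), targets = paste0("g", 1:5),
                    icc = -0.7),
               list(regulators = c("C", "D"), targets = paste0("g", 1:6),
                    icc = 0.9))
  sm <- summarize_modules(mods)
  expect_identical(sm$sign, c("anti-correlated", "correlated"))
  expect_identical(nrow(summarize_modules(list())), 0L)
})
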