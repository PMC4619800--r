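# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive implementations, kept separate from the package code
# paths they check.

# ICC of standardized series equals the mean pairwise Pearson correlation;
# used as an algebraically independent route to the ANOVA-based ICC.
oracle_icc_mean_r <- function(x) {
  z <- t(scale(t(x)))
  cm <- cor(t(z))
  mean(cm[lower.tri(cm)])
}

# Exhaustive enumeration of regulator subsets satisfying the module
# constraints (|ICC| >= icc_cutoff on log2 age-mean series, >= min_targets
# shared in-group targets). Returns a sorted character vector of
# pipe-joined regulator sets.
oracle_module_subsets <- function(net, em, group_genes,
                                  icc_cutoff = 0.6, min_targets = 5L) {
  regs <- sort(unique(net$regulator))
  regs <- regs[regs %in% em$feature_ids]
  z <- age_means(em, log2 = TRUE)
  z <- z[match(regs, em$feature_ids), , drop = FALSE]
  targets <- lapply(regs, function(r)
    intersect(net$target[net$regulator == r], group_genes))
  names(targets) <- regs
  found <- character()
  for (size in 2:length(regs)) {
    for (comb in asplit(combn(regs, size), 2)) {
      tg <- Reduce(intersect, targets[comb])
      if (length(tg) < min_targets) next
      zz <- z[match(comb, regs), , drop = FALSE]
      if (any(apply(zz, 1, sd) == 0)) next
      if (abs(oracle_icc_mean_r(zz)) < icc_cutoff) next
      found <- c(found, paste(sort(comb), collapse = "|"))
    }
  }
  sort(found)
}

# Naive O(n^3) Lance-Williams agglomeration. Returns the sequence of
# merges, each a sorted list of the two merged leaf sets. linkage:
# "average" works on the given distances, "ward" on Ward's
# minimum-variance criterion via the Lance-Williams update of squared
# Euclidean distances. Ties broken by smallest involved indices.
oracle_agglomerate <- function(x, distance = "euclidean",
                               linkage = "average") {
  n <- nrow(x)
  D <- if (distance == "euclidean") as.matrix(dist(x))
       else 1 - cor(t(x))
  if (linkage == "ward") D <- D^2
  clusters <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  merges <- list()
  Dm <- D
  diag(Dm) <- Inf
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- c(NA, NA)
    bestd <- Inf
    for (a in idx) for (b in idx) {
      if (b <= a) next
      if (Dm[a, b] < bestd - 1e-12) {
        bestd <- Dm[a, b]
        best <- c(a, b)
      }
    }
    i <- best[1]; j <- best[2]
    merges[[step]] <- list(sort(clusters[[i]]), sort(clusters[[j]]))
    # Lance-Williams update into slot i
    for (k in idx) {
      if (k == i || k == j) next
      Dm[i, k] <- Dm[k, i] <- if (linkage == "average") {
        (sizes[i] * Dm[i, k] + sizes[j] * Dm[j, k]) / (sizes[i] + sizes[j])
      } else {
        ((sizes[i] + sizes[k]) * Dm[i, k] + (sizes[j] + sizes[k]) * Dm[j, k] -
           sizes[k] * Dm[i, j]) / (sizes[i] + sizes[j] + sizes[k])
      }
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }
  merges
}

# canonical form of an hclust merge matrix: sorted leaf-set pairs
hclust_merge_sets <- function(merge) {
  n <- nrow(merge) + 1L
  sets <- vector("list", nrow(merge))
  leaves <- function(v) {
    if (v < 0) -v else sort(unlist(sets[[v]]))
  }
  out <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    a <- leaves(merge[i, 1]); b <- leaves(merge[i, 2])
    sets[[i]] <- c(a, b)
    pair <- list(sort(a), sort(b))
    # order the two sides by their smallest leaf for comparability
    if (min(pair[[2]]) < min(pair[[1]])) pair <- pair[c(2, 1)]
    out[[i]] <- pair
  }
  out
}

canonical_merges <- function(merges) {
  lapply(merges, function(p) {
    if (min(p[[2]]) < min(p[[1]])) p <- p[c(2, 1)]
    p
  })
}

# small expression matrix built directly from a value matrix
toy_matrix <- function(values, design = default_age_design(),
                       level = "gene", prefix = "g") {
  expression_matrix(values,
                    sprintf("%s%03d", prefix, seq_len(nrow(values))),
                    design, level)
}
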