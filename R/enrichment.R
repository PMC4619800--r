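#' Upper-tail hypergeometric overlap p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of
#' observing an overlap of at least `k` between a set of size `K` and a
#' set of size `n` drawn from a universe of size `N`.
#'
#' @param N Universe size.
#' @param K Size of set 1.
#' @param n Size of set 2.
#' @param k Observed overlap.
#' @return The upper-tail p-value.
#' @export
hypergeom_overlap <- function(N, K, n, k) {
  if (K > N || n > N) stop("set sizes cannot exceed the universe")
  if (k > min(K, n)) stop("overlap cannot exceed the smaller set")
  if (k < max(0, K + n - N)) stop("overlap below the feasible minimum")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Right-tailed Fisher enrichment of a gene set in a query
#'
#' Builds the 2x2 membership table of query and term genes over the
#' universe and computes the right-tail exact p-value, which equals the
#' upper-tail hypergeometric probability of the observed overlap.
#'
#' @param query,term,universe Character vectors of gene ids; `query` and
#'   `term` must be subsets of `universe`.
#' @param term_id Optional label carried into the result.
#' @return One-row data.frame: `term_id`, `k` (overlap), `K` (term size),
#'   `n` (query size), `N` (universe size), `p`.
#' @export
fisher_right_tail <- function(query, term, universe, term_id = NA_character_) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  term <- unique(term)
  if (length(setdiff(query, universe)) || length(setdiff(term, universe))) {
    stop("query and term must be subsets of the universe")
  }
  k <- length(intersect(query, term))
  data.frame(term_id = term_id, k = k, K = length(term), n = length(query),
             N = length(universe),
             p = hypergeom_overlap(length(universe), length(term),
                                   length(query), k),
             stringsAsFactors = FALSE)
}

#' Chi-square test of independence
#'
#' Pearson chi-square with (r-1)(c-1) degrees of freedom on a
#' contingency table (e.g. molecule type by age or by temporal group).
#' Degenerate single-row or single-column tables are an error, as are
#' tables with any expected count below 1 (use an exact test there).
#'
#' @param tab Numeric matrix of counts.
#' @return List: `statistic`, `df`, `p`.
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("degenerate table: need >= 2 rows and >= 2 columns")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    stop("expected count below 1; use an exact test")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Activation z-score of a regulator
#'
#' Unweighted sign-consistency score: over the `Nz` targets with a known
#' expected direction, `z = sum(s_i) / sqrt(Nz)` where `s_i = +1` when
#' the observed direction of change matches the expected direction and
#' `-1` otherwise. Targets with expected direction 0 are excluded.
#' `|z| >= 2` is conventionally deemed a significant activation
#' (positive z) or inhibition (negative z).
#'
#' @param observed Named numeric vector of observed directions
#'   (+1 or -1) per target.
#' @param expected Named numeric vector of expected directions
#'   (+1, -1 or 0) per target from the regulator network.
#' @return The z-score.
#' @export
activation_z <- function(observed, expected) {
  common <- intersect(names(observed), names(expected))
  expected <- expected[common]
  observed <- observed[common]
  keep <- expected != 0
  if (!any(keep)) stop("no targets with a known expected direction")
  s <- ifelse(sign(observed[keep]) == sign(expected[keep]), 1, -1)
  sum(s) / sqrt(length(s))
}

#' Per-age differential direction of expression
#'
#' For each feature and age: the sign of the log2 ratio of the per-age
#' replicate-mean FPKM to the gene's average (geometric mean) expression
#' over all ages.
#'
#' @param em An [expression_matrix()].
#' @param pseudocount Added before the log ratio.
#' @return Numeric matrix (features x ages) with values in {-1, 0, +1}.
#' @export
differential_direction <- function(em, pseudocount = 1) {
  am <- age_means(em) + pseudocount
  gm <- exp(rowMeans(log(am)))
  sign(log2(am / gm))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate q-values: monotone in the p-value ranks
#' and capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Regulator-by-group target hit counts
#'
#' For each regulator in the network and each temporal group, the number
#' of its targets assigned to that group. Row sums equal each
#' regulator's total number of targets among the assigned features.
#'
#' @param net A [regulator_network()].
#' @param assignments An [assign_temporal_groups()] result.
#' @return Integer matrix, regulators x groups.
#' @export
hit_count_matrix <- function(net, assignments) {
  groups <- if (all(stats::na.omit(assignments$group) %in%
                    temporal_group_labels()))
    temporal_group_labels() else sort(unique(stats::na.omit(assignments$group)))
  regs <- sort(unique(net$regulator))
  grp_of <- assignments$group[match(net$target, assignments$feature_id)]
  out <- matrix(0L, length(regs), length(groups),
                dimnames = list(regs, groups))
  keep <- !is.na(grp_of)
  if (any(keep)) {
    tt <- table(factor(net$regulator[keep], levels = regs),
                factor(grp_of[keep], levels = groups))
    out[] <- as.integer(tt)
  }
  out
}
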