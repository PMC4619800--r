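#' Gene expression rank over ages
#'
#' Ranks a per-age expression series: the age with the highest expression
#' gets the highest rank (`n_ages`), the lowest gets rank 1, and ties
#' receive the average of the tied ranks. The rank vector of a gene
#' always sums to `n(n+1)/2` (78 for 12 ages) and is invariant under any
#' strictly increasing transform of the series.
#'
#' @param series Numeric vector of per-age (replicate-mean) expression.
#' @return Numeric vector of ranks, same length as `series`.
#' @export
gene_expression_rank <- function(series) {
  if (anyNA(series) || any(!is.finite(series))) stop("series must be finite")
  rank(series, ties.method = "average")
}

#' Per-age summary statistics
#'
#' For a set of features (by default the analysis set from `calls`),
#' computes per-age: mean and SD of log2(FPKM + 1) replicate means, the
#' number of features called expressed, median and SD of the gene
#' expression rank (GER, computed from per-age replicate means), and the
#' number of features attaining their maximal rank at that age.
#'
#' @param em An [expression_matrix()].
#' @param calls An [expression_calls()] computed on the same matrix.
#' @param features Feature ids to summarise; default
#'   [select_analysis_genes()] of `calls`.
#' @return data.frame with one row per age.
#' @export
age_summaries <- function(em, calls, features = select_analysis_genes(calls)) {
  if (!length(features)) stop("empty analysis set")
  idx <- match(features, em$feature_ids)
  if (anyNA(idx)) stop("features absent from matrix")
  lm2 <- age_means(em, log2 = TRUE)[idx, , drop = FALSE]
  am <- age_means(em)[idx, , drop = FALSE]
  ger <- t(apply(am, 1, gene_expression_rank))
  n_ages <- length(em$design$ages)
  at_max <- t(apply(ger, 1, function(r) r == max(r)))
  data.frame(
    age = em$design$ages,
    mean_log2_fpkm = colMeans(lm2),
    sd_log2_fpkm = apply(lm2, 2, stats::sd),
    n_expressed = colSums(calls$expressed[idx, , drop = FALSE]),
    median_ger = apply(ger, 2, stats::median),
    sd_ger = apply(ger, 2, stats::sd),
    n_at_max_rank = colSums(at_max)
  )
}

#' Mean expression profile per molecule type
#'
#' For each molecule type and age, the mean over genes of the
#' replicate-mean FPKM. Genes without an annotation row are treated as
#' `"other"`.
#'
#' @param em An [expression_matrix()] (gene level).
#' @param annotation A [gene_annotation()].
#' @param features Optional subset of gene ids (default: all rows).
#' @return Numeric matrix, molecule types x ages.
#' @export
type_profiles <- function(em, annotation, features = em$feature_ids) {
  idx <- match(features, em$feature_ids)
  if (anyNA(idx)) stop("features absent from matrix")
  am <- age_means(em)[idx, , drop = FALSE]
  type <- annotation$molecule_type[match(features, annotation$gene_id)]
  type[is.na(type)] <- "other"
  types <- intersect(molecule_types(), unique(type))
  out <- t(vapply(types,
                  function(tp) colMeans(am[type == tp, , drop = FALSE]),
                  numeric(ncol(am))))
  dimnames(out) <- list(types, paste0("d", em$design$ages))
  out
}
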