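#' Call per-age expressed status
#'
#' A feature is called expressed at an age when at least `min_replicates`
#' of its replicate FPKM values at that age are `>= theta_fpkm`.
#'
#' @param em An [expression_matrix()].
#' @param theta_fpkm FPKM threshold (>= 0, default 1).
#' @param min_replicates Minimum replicates at or above threshold
#'   (default 2; must be between 1 and the design's replicate count).
#' @return Logical matrix, features x ages.
#' @export
call_expressed <- function(em, theta_fpkm = 1, min_replicates = 2L) {
  if (theta_fpkm < 0) stop("theta_fpkm must be >= 0")
  reps <- em$design$replicates
  if (min_replicates < 1L || min_replicates > reps) {
    stop("min_replicates must be between 1 and ", reps)
  }
  d <- em$design
  out <- vapply(seq_along(d$ages), function(a) {
    rowSums(em$values[, age_columns(d, a), drop = FALSE] >= theta_fpkm) >=
      min_replicates
  }, logical(nrow(em$values)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(em$values))
  dimnames(out) <- list(em$feature_ids, paste0("d", d$ages))
  out
}

#' Test differential expression over the age series
#'
#' One-way ANOVA on `log2(FPKM + 1)` with age as the grouping factor,
#' per feature, followed by Benjamini-Hochberg adjustment across all
#' tested features. Degenerate cases are handled explicitly: when every
#' age has zero within-age variance, p is 0 if the age means differ and
#' 1 if the series is globally constant.
#'
#' @param em An [expression_matrix()] with >= 2 replicates per age.
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @return data.frame: `feature_id`, `p`, `q`, `is_differential`.
#' @export
test_differential <- function(em, alpha = 0.05) {
  if (em$design$replicates < 2L) stop("need >= 2 replicates per age")
  d <- em$design
  grp <- factor(rep(seq_along(d$ages), each = d$replicates))
  lv <- log2(em$values + 1)
  p <- vapply(seq_len(nrow(lv)), function(i) {
    y <- lv[i, ]
    wvar <- tapply(y, grp, stats::var)
    if (all(wvar == 0)) {
      mns <- tapply(y, grp, mean)
      return(if (stats::var(mns) > 0) 0 else 1)
    }
    stats::oneway.test(y ~ grp, var.equal = TRUE)$p.value
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  data.frame(feature_id = em$feature_ids, p = p, q = q,
             is_differential = q <= alpha, stringsAsFactors = FALSE)
}

#' Combined expression and differential calls
#'
#' Runs [call_expressed()] and [test_differential()] with one set of
#' thresholds and bundles the results.
#'
#' @inheritParams call_expressed
#' @inheritParams test_differential
#' @return An object of class `expression_calls`: list with `expressed`
#'   (logical features x ages), `differential` (data.frame), and the
#'   thresholds used.
#' @export
expression_calls <- function(em, theta_fpkm = 1, min_replicates = 2L,
                             alpha = 0.05) {
  structure(
    list(expressed = call_expressed(em, theta_fpkm, min_replicates),
         differential = test_differential(em, alpha),
         theta_fpkm = theta_fpkm, min_replicates = min_replicates,
         alpha = alpha),
    class = "expression_calls"
  )
}

#' Select analysis features
#'
#' The analysis set: features expressed at one or more ages AND
#' significantly differentially expressed over the series (BH-adjusted
#' q at or below the calls' alpha). Applied at gene level this yields the
#' analysis-genes; at transcript level, the transcript analysis set.
#'
#' @param calls An [expression_calls()] object.
#' @return Character vector of feature ids.
#' @export
select_analysis_genes <- function(calls) {
  expressed_any <- rowSums(calls$expressed) > 0
  diff_ok <- calls$differential$is_differential
  calls$differential$feature_id[expressed_any & diff_ok]
}
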