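#' Variant-usage shift test across ages
#'
#' Chi-square test of homogeneity on the transcript-by-age table of
#' per-age mean FPKM, i.e. of whether the relative usage (share) of a
#' gene's splice variants changes with age. The FPKM values act as the
#' weights, so ages with higher total expression carry more weight.
#' All-zero transcripts and zero-total ages are dropped; if fewer than
#' two transcripts or two ages remain the test is not applicable and
#' p = 1 is returned with `applicable = FALSE`.
#'
#' @param tab Numeric matrix: transcripts (rows, >= 2) x ages of per-age
#'   mean FPKM.
#' @return List: `p`, `statistic`, `df`, `applicable`, and
#'   `std_residuals` (per-cell standardized residuals, or NULL).
#' @export
variant_usage_test <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L) stop("need >= 2 transcripts; single-variant genes are not applicable")
  if (any(tab < 0)) stop("negative expression")
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    return(list(p = 1, statistic = 0, df = NA_integer_, applicable = FALSE,
                std_residuals = NULL))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(p = ct$p.value, statistic = unname(ct$statistic),
       df = unname(ct$parameter), applicable = TRUE,
       std_residuals = ct$stdres)
}

#' Durbin-Watson statistic of an expression series
#'
#' `d = sum((e_t - e_(t-1))^2) / sum(e_t^2)` on the mean-centered series
#' (no regression model is posited, so the residuals are deviations from
#' the mean). `d` lies in \[0, 4\]; values near 2 indicate no
#' autocorrelation and values below 2 positive autocorrelation, the
#' signature of temporally coherent expression.
#'
#' @param series Numeric vector, length >= 3, non-constant.
#' @return The statistic.
#' @export
durbin_watson <- function(series) {
  if (length(series) < 3L) stop("series must have length >= 3")
  e <- series - mean(series)
  den <- sum(e^2)
  if (den == 0) stop("constant series")
  sum(diff(e)^2) / den
}

# DW statistics for all rows of a matrix at once
dw_rows <- function(m) {
  e <- m - rowMeans(m)
  rowSums((e[, -1, drop = FALSE] - e[, -ncol(e), drop = FALSE])^2) /
    rowSums(e^2)
}

#' Permutation p-value for positive autocorrelation
#'
#' One-sided significance of a low Durbin-Watson statistic, obtained by
#' permuting the age order: `p = (1 + #{d_perm <= d_obs}) / (n_perm + 1)`.
#' Deterministic given the seed; the smallest attainable p is
#' `1 / (n_perm + 1)`.
#'
#' @param series Numeric vector (per-age values).
#' @param n_perm Number of permutations (>= 999).
#' @param seed Integer seed.
#' @return The permutation p-value.
#' @export
dw_pvalue <- function(series, n_perm = 999L, seed = 1L) {
  dw_pvalues(matrix(series, nrow = 1), n_perm, seed)
}

#' @rdname dw_pvalue
#' @param m Numeric matrix of series (rows); one shared set of seeded
#'   age permutations is applied to every row.
#' @export
dw_pvalues <- function(m, n_perm = 999L, seed = 1L) {
  m <- as.matrix(m)
  if (n_perm < 999L) stop("n_perm must be >= 999")
  if (ncol(m) < 3L) stop("series must have length >= 3")
  if (any(apply(m, 1, stats::sd) == 0)) stop("constant series")
  dobs <- dw_rows(m)
  n <- ncol(m)
  hits <- integer(nrow(m))
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      hits <- hits + (dw_rows(m[, sample(n), drop = FALSE]) <= dobs)
    }
  })
  (1 + hits) / (n_perm + 1)
}

#' Two-stage novel-isoform filter
#'
#' Stage 1 keeps candidates significantly expressed in at least one age;
#' stage 2 applies the Durbin-Watson permutation test for positive
#' autocorrelation to the stage-1 survivors, adjusts with
#' Benjamini-Hochberg across those survivors only, and keeps candidates
#' with adjusted p at or below `alpha`. This mirrors a two-stage
#' narrowing in which expression evidence and temporal coherence are
#' required in turn.
#'
#' @param em Transcript-level [expression_matrix()] of candidate novel
#'   isoforms.
#' @param alpha FDR level for the DW filter (default 0.05).
#' @param theta_fpkm,min_replicates Expression-call thresholds
#'   (see [call_expressed()]).
#' @param n_perm,seed Permutation-test settings.
#' @return data.frame of isoform records: `transcript_id`, `dw`, `p_dw`,
#'   `q_dw` (NA for stage-1 failures), `expressed_any`, `passes_filter`.
#' @export
filter_novel_isoforms <- function(em, alpha = 0.05, theta_fpkm = 1,
                                  min_replicates = 2L, n_perm = 999L,
                                  seed = 1L) {
  expressed_any <- rowSums(call_expressed(em, theta_fpkm, min_replicates)) > 0
  am <- age_means(em, log2 = TRUE)
  dw <- rep(NA_real_, nrow(am))
  ok <- apply(am, 1, stats::sd) > 0
  dw[ok] <- dw_rows(am[ok, , drop = FALSE])
  p <- rep(NA_real_, nrow(am))
  stage1 <- expressed_any & ok
  if (any(stage1)) {
    p[stage1] <- dw_pvalues(am[stage1, , drop = FALSE], n_perm, seed)
  }
  q <- rep(NA_real_, nrow(am))
  q[stage1] <- bh_adjust(p[stage1])
  data.frame(
    transcript_id = em$feature_ids,
    dw = dw, p_dw = p, q_dw = q,
    expressed_any = expressed_any,
    passes_filter = !is.na(q) & q <= alpha,
    stringsAsFactors = FALSE
  )
}

# do intervals [a1,a2) and [b1,b2) overlap?
.overlaps <- function(a, b) a[1] < b[2] && b[1] < a[2]

#' Classify the splice events of a novel transcript
#'
#' Compares a novel transcript model against the reference models of the
#' same gene and reports the alternative-splicing events that
#' distinguish it from the best-matching reference (the one sharing the
#' most splice junctions; ties go to the first). Rules, on 0-based
#' half-open exon chains:
#' \itemize{
#'   \item `exon_skip`: an internal reference exon has no overlapping
#'     novel exon and is fully contained in a novel intron.
#'   \item `intron_retention`: a novel exon fully contains a reference
#'     intron and extends into both flanking reference exons.
#'   \item `alternative_exon`: an internal novel exon overlaps no
#'     reference exon.
#'   \item `alt_start`: the transcription start boundary (strand-aware)
#'     differs from the reference.
#'   \item `alt_termination`: the transcription end boundary differs.
#' }
#' Multiple events may co-occur. With no reference available the single
#' event `"unclassified"` is returned.
#'
#' @param novel A [transcript_model()].
#' @param references List of [transcript_model()]s for the same gene.
#' @return data.frame: `event_type`, `start`, `end`, `reference_id`.
#' @export
classify_splice_event <- function(novel, references) {
  if (!length(references)) {
    return(data.frame(event_type = "unclassified", start = NA_real_,
                      end = NA_real_, reference_id = NA_character_,
                      stringsAsFactors = FALSE))
  }
  for (r in references) {
    if (r$chrom != novel$chrom || r$strand != novel$strand) {
      stop("novel and reference models must share chrom and strand")
    }
  }
  jset <- function(tm) {
    i <- transcript_introns(tm)
    paste(i[, 1], i[, 2])
  }
  nj <- jset(novel)
  shared <- vapply(references, function(r) length(intersect(jset(r), nj)),
                   integer(1))
  # tie-break junction matches by exonic overlap (bp) with the novel model
  overlap_bp <- vapply(references, function(r) {
    sum(vapply(seq_len(nrow(r$exons)), function(i) {
      sum(pmax(0, pmin(novel$exons[, 2], r$exons[i, 2]) -
                  pmax(novel$exons[, 1], r$exons[i, 1])))
    }, numeric(1)))
  }, numeric(1))
  ref <- references[[order(-shared, -overlap_bp)[1]]]
  re <- ref$exons
  ne <- novel$exons
  ri <- transcript_introns(ref)
  ni <- transcript_introns(novel)
  ev <- list()
  add <- function(type, s, e) {
    ev[[length(ev) + 1L]] <<- data.frame(
      event_type = type, start = s, end = e,
      reference_id = ref$transcript_id, stringsAsFactors = FALSE)
  }
  # exon skipping: internal reference exon inside a novel intron
  if (nrow(re) >= 3L) {
    for (i in 2:(nrow(re) - 1L)) {
      covered <- any(apply(ne, 1, .overlaps, b = re[i, ]))
      if (!covered && nrow(ni) &&
          any(ni[, 1] <= re[i, 1] & ni[, 2] >= re[i, 2])) {
        add("exon_skip", re[i, 1], re[i, 2])
      }
    }
  }
  # intron retention: novel exon spans a reference intron and both flanks
  if (nrow(ri)) {
    for (i in seq_len(nrow(ri))) {
      span <- apply(ne, 1, function(x)
        x[1] < ri[i, 1] && x[2] > ri[i, 2])
      if (any(span)) add("intron_retention", ri[i, 1], ri[i, 2])
    }
  }
  # alternative exon: internal novel exon with no reference-exon overlap
  if (nrow(ne) >= 3L) {
    for (i in 2:(nrow(ne) - 1L)) {
      if (!any(apply(re, 1, .overlaps, b = ne[i, ]))) {
        add("alternative_exon", ne[i, 1], ne[i, 2])
      }
    }
  }
  # strand-aware start / termination boundaries
  nspan <- transcript_span(novel)
  rspan <- transcript_span(ref)
  if (novel$strand == "+") {
    if (nspan[1] != rspan[1])
      add("alt_start", min(nspan[1], rspan[1]), max(nspan[1], rspan[1]))
    if (nspan[2] != rspan[2])
      add("alt_termination", min(nspan[2], rspan[2]), max(nspan[2], rspan[2]))
  } else {
    if (nspan[2] != rspan[2])
      add("alt_start", min(nspan[2], rspan[2]), max(nspan[2], rspan[2]))
    if (nspan[1] != rspan[1])
      add("alt_termination", min(nspan[1], rspan[1]), max(nspan[1], rspan[1]))
  }
  if (!length(ev)) {
    return(data.frame(event_type = character(), start = numeric(),
                      end = numeric(), reference_id = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, ev)
}
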