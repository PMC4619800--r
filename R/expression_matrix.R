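#' Expression matrix over an age series
#'
#' A validated container for FPKM (fragments per kilobase of transcript
#' per million mapped fragments) values of features (genes or
#' transcripts) over the samples of an [age_design()]. Rows are features,
#' columns are samples in design order.
#'
#' @param values Numeric matrix, one row per feature, one column per
#'   sample, all values finite and non-negative.
#' @param feature_ids Character vector of unique feature identifiers
#'   (defaults to the rownames of `values`).
#' @param design An [age_design()].
#' @param feature_level `"gene"` or `"transcript"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, feature_ids = rownames(values),
                              design = default_age_design(),
                              feature_level = c("gene", "transcript")) {
  feature_level <- match.arg(feature_level)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids)) stop("feature_ids are required")
  feature_ids <- as.character(feature_ids)
  if (nrow(values) != length(feature_ids)) {
    stop("row count (", nrow(values), ") != number of feature ids (",
         length(feature_ids), ")")
  }
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup)) stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  if (ncol(values) != n_samples(design)) {
    stop("column count (", ncol(values), ") != design samples (",
         n_samples(design), ")")
  }
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("negative or non-finite value at feature '", feature_ids[bad[1, 1]],
         "', sample '", design$labels[bad[1, 2]], "'")
  }
  dimnames(values) <- list(feature_ids, design$labels)
  structure(
    list(values = values, feature_ids = feature_ids, design = design,
         feature_level = feature_level),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), x$feature_level, "features x",
      ncol(x$values), "samples (", length(x$design$ages), "ages x",
      x$design$replicates, "replicates )\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Per-age replicate means
#'
#' Averages replicate columns within each age, optionally on the
#' log2(FPKM + pseudocount) scale.
#'
#' @param em An [expression_matrix()].
#' @param log2 If `TRUE`, average `log2(FPKM + pseudocount)` values.
#' @param pseudocount Added before the log transform.
#' @return Numeric matrix, features x ages.
#' @export
age_means <- function(em, log2 = FALSE, pseudocount = 1) {
  v <- em$values
  if (log2) v <- base::log2(v + pseudocount)
  d <- em$design
  out <- vapply(seq_along(d$ages),
                function(a) rowMeans(v[, age_columns(d, a), drop = FALSE]),
                numeric(nrow(v)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(v))
  dimnames(out) <- list(em$feature_ids, paste0("d", d$ages))
  out
}

# standardized (zero-mean, unit-SD) per-gene series of log2 age means;
# zero-variance rows come back as NA rows
standardize_age_means <- function(em) {
  m <- age_means(em, log2 = TRUE)
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  z <- (m - mu) / s
  z[s == 0, ] <- NA_real_
  z
}

#' Read a tab-delimited expression table
#'
#' The file must have a header row naming the sample columns (matching
#' the design labels `d{age}_r{rep}`) and a first column of feature
#' identifiers. Columns may appear in any order; they are reordered to
#' the design order.
#'
#' @param path File path.
#' @param design An [age_design()] describing the expected samples.
#' @param feature_level `"gene"` or `"transcript"`.
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, design = default_age_design(),
                                  feature_level = c("gene", "transcript")) {
  feature_level <- match.arg(feature_level)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(design$labels, colnames(df))
  if (length(missing)) {
    stop("missing sample column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  }
  ids <- as.character(df[[1]])
  vals <- df[, design$labels, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(col) & !is.na(vals[[j]]))
    if (length(bad)) {
      stop("non-numeric value '", vals[[j]][bad[1]], "' at feature '",
           ids[bad[1]], "', column '", design$labels[j], "'")
    }
    vals[[j]] <- col
  }
  expression_matrix(as.matrix(vals), ids, design, feature_level)
}

#' Write an expression table
#'
#' Writes a tab-delimited file readable by [read_expression_table()],
#' preserving full double precision (15 significant digits).
#'
#' @param em An [expression_matrix()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_expression_table <- function(em, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature_id", em$design$labels), collapse = "\t"), con)
  if (nrow(em$values)) {
    body <- apply(em$values, 1, function(r)
      paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
            collapse = "\t"))
    writeLines(paste(em$feature_ids, body, sep = "\t"), con)
  }
  invisible(path)
}
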