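#' Discover upstream regulatory modules by iterative ICC merging
#'
#' Identifies sets of regulators with similar or diametrical expression
#' patterns that share downstream targets within a temporal group.
#' Cycle 0 seeds one entry per regulator, holding its targets restricted
#' to the group. Cycle 1 attempts every pair of seeds; every later cycle
#' attempts merges of all pairs involving at least one entry added in
#' the previous cycle. A merge (union of regulator sets, intersection of
#' target sets) is admitted when the absolute ICC of the merged
#' regulators' standardized series is at least `icc_cutoff` and the
#' merged target set has at least `min_targets` genes. Entries are
#' de-duplicated by regulator set and the loop stops when a cycle adds
#' nothing. All entries with two or more regulators are returned.
#'
#' @param net A [regulator_network()].
#' @param regulator_expression An [expression_matrix()] whose rows cover
#'   the network's regulators; regulators without an expression row are
#'   dropped with a warning. ICCs are computed on per-age replicate-mean
#'   log2 series.
#' @param group_genes Non-empty character vector: the genes of the
#'   temporal group under analysis.
#' @param icc_cutoff Minimum absolute ICC (default 0.6).
#' @param min_targets Minimum shared target count (default 5).
#' @param min_targets_seed_only If `TRUE`, the target-count constraint is
#'   applied only when first forming 2-tuples, not on later merges.
#' @return List of modules; each a list with `regulators` (sorted),
#'   `targets` (sorted), `icc`. Sorted by decreasing size, then
#'   lexicographically.
#' @export
find_modules <- function(net, regulator_expression, group_genes,
                         icc_cutoff = 0.6, min_targets = 5L,
                         min_targets_seed_only = FALSE) {
  if (!length(group_genes)) stop("group_genes must be non-empty")
  if (icc_cutoff < 0 || icc_cutoff > 1) stop("icc_cutoff must be in [0, 1]")
  regs <- sort(unique(net$regulator))
  have <- regs %in% regulator_expression$feature_ids
  if (!all(have)) {
    warning("regulator(s) without expression excluded: ",
            paste(regs[!have], collapse = ", "))
    regs <- regs[have]
  }
  if (length(regs) < 2L) return(list())
  z <- age_means(regulator_expression, log2 = TRUE)
  z <- z[match(regs, regulator_expression$feature_ids), , drop = FALSE]
  targets0 <- lapply(regs, function(r)
    sort(intersect(regulator_targets(net, r), group_genes)))
  names(targets0) <- regs

  icc_of <- function(members) icc_winer(z[match(members, regs), , drop = FALSE])

  entries <- lapply(regs, function(r)
    list(regulators = r, targets = targets0[[r]], icc = NA_real_))
  keys <- regs
  new_idx <- seq_along(entries)

  try_merge <- function(e1, e2) {
    mr <- sort(union(e1$regulators, e2$regulators))
    mt <- sort(intersect(e1$targets, e2$targets))
    check_targets <- !(min_targets_seed_only && length(mr) > 2L)
    if (check_targets && length(mt) < min_targets) return(NULL)
    sds <- apply(z[match(mr, regs), , drop = FALSE], 1, stats::sd)
    if (any(sds == 0)) return(NULL)
    icc <- icc_of(mr)
    if (abs(icc) < icc_cutoff) return(NULL)
    list(regulators = mr, targets = mt, icc = icc)
  }

  cycle <- 0L
  repeat {
    cycle <- cycle + 1L
    prev_new <- new_idx
    added <- list()
    added_keys <- character()
    pairs <- if (cycle == 1L) {
      utils::combn(seq_along(regs), 2L, simplify = FALSE)
    } else {
      out <- list()
      for (i in prev_new) for (j in seq_along(entries)) {
        if (j < i || !(j %in% prev_new)) out[[length(out) + 1L]] <- c(i, j)
      }
      out
    }
    for (pr in pairs) {
      m <- try_merge(entries[[pr[1]]], entries[[pr[2]]])
      if (is.null(m)) next
      key <- paste(m$regulators, collapse = "|")
      if (key %in% keys || key %in% added_keys) next
      added[[length(added) + 1L]] <- m
      added_keys <- c(added_keys, key)
    }
    if (!length(added)) break
    new_idx <- length(entries) + seq_along(added)
    entries <- c(entries, added)
    keys <- c(keys, added_keys)
  }
  mods <- Filter(function(e) length(e$regulators) >= 2L, entries)
  ord <- order(-vapply(mods, function(m) length(m$regulators), integer(1)),
               vapply(mods, function(m) paste(m$regulators, collapse = "|"),
                      character(1)))
  mods[ord]
}

#' Summarise discovered regulatory modules
#'
#' @param modules A [find_modules()] result.
#' @return data.frame: `regulators` (pipe-separated), `size`,
#'   `n_targets`, `icc`, `sign` (`"correlated"` for positive ICC,
#'   `"anti-correlated"` for negative).
#' @export
summarize_modules <- function(modules) {
  if (!length(modules)) {
    return(data.frame(regulators = character(), size = integer(),
                      n_targets = integer(), icc = numeric(),
                      sign = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    regulators = vapply(modules, function(m)
      paste(m$regulators, collapse = "|"), character(1)),
    size = vapply(modules, function(m) length(m$regulators), integer(1)),
    n_targets = vapply(modules, function(m) length(m$targets), integer(1)),
    icc = vapply(modules, function(m) m$icc, numeric(1)),
    sign = vapply(modules, function(m)
      if (m$icc < 0) "anti-correlated" else "correlated", character(1)),
    stringsAsFactors = FALSE
  )
}
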