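#' Transcript model
#'
#' An exon-chain transcript structure. Exon intervals are stored 0-based
#' half-open; conversion from GTF's 1-based inclusive coordinates happens
#' only at the GTF boundary.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column numeric matrix of (start, end) intervals,
#'   0-based half-open. They are sorted by start; overlaps are an error.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stop("a transcript needs at least one exon")
  if (any(exons[, 2] <= exons[, 1])) {
    stop("exon with end <= start in transcript ", transcript_id)
  }
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons[-nrow(exons), 2] > exons[-1, 1])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  structure(
    list(transcript_id = as.character(transcript_id),
         gene_id = as.character(gene_id),
         chrom = as.character(chrom), strand = strand, exons = exons),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("transcript_model", x$transcript_id, "(", x$gene_id, ")",
      x$chrom, x$strand, nrow(x$exons), "exons\n")
  invisible(x)
}

# (end, start) pairs of the introns, 0-based half-open
transcript_introns <- function(tm) {
  e <- tm$exons
  if (nrow(e) < 2L) return(matrix(numeric(), ncol = 2,
                                  dimnames = list(NULL, c("start", "end"))))
  cbind(start = e[-nrow(e), 2], end = e[-1, 1])
}

transcript_span <- function(tm) c(tm$exons[1, 1], tm$exons[nrow(tm$exons), 2])

#' Read transcript models from a GTF file
#'
#' Parses exon features (via `rtracklayer`), groups them by
#' `transcript_id`, and converts the 1-based inclusive GTF coordinates to
#' the package's internal 0-based half-open convention.
#'
#' @param path GTF file path.
#' @return Named list of [transcript_model()] objects.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$transcript_id) || anyNA(mc$transcript_id)) {
    stop("exon feature without transcript_id in ", path)
  }
  gid <- if (is.null(mc$gene_id)) mc$transcript_id else mc$gene_id
  idx <- split(seq_along(gr), as.character(mc$transcript_id))
  out <- lapply(names(idx), function(tid) {
    i <- idx[[tid]]
    transcript_model(
      tid, as.character(gid[i[1]]),
      as.character(GenomicRanges::seqnames(gr)[i[1]]),
      as.character(GenomicRanges::strand(gr)[i[1]]),
      cbind(GenomicRanges::start(gr)[i] - 1, GenomicRanges::end(gr)[i])
    )
  })
  names(out) <- names(idx)
  out
}

#' Write transcript models to a GTF file
#'
#' Inverse of [read_gtf()]: internal 0-based half-open exon intervals are
#' converted back to 1-based inclusive GTF coordinates.
#'
#' @param models List of [transcript_model()] objects.
#' @param path Output GTF path.
#' @return The path, invisibly.
#' @export
write_gtf <- function(models, path) {
  rows <- lapply(models, function(tm) {
    GenomicRanges::GRanges(
      seqnames = tm$chrom,
      ranges = IRanges::IRanges(start = tm$exons[, 1] + 1, end = tm$exons[, 2]),
      strand = tm$strand,
      type = "exon", source = "ontodyn",
      gene_id = tm$gene_id, transcript_id = tm$transcript_id)
  })
  gr <- suppressWarnings(do.call(c, unname(rows)))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
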