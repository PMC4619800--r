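#' Closed vocabularies for gene annotation
#'
#' Molecule types and cellular localizations used by the annotation
#' table. Anything outside the vocabulary is mapped to `"other"`.
#'
#' @name annotation_vocab
#' @export
molecule_types <- function() {
  c("enzyme", "transporter", "transcription regulator", "kinase",
    "cytokine", "ion channel", "phosphatase", "translation regulator",
    "peptidase", "transmembrane receptor", "growth factor", "other")
}

#' @rdname annotation_vocab
#' @export
localizations <- function() {
  c("cytoplasm", "nucleus", "plasma membrane", "extracellular space", "other")
}

#' Gene annotation table
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param molecule_type Character vector drawn from [molecule_types()];
#'   unknown values become `"other"`.
#' @param localization Character vector drawn from [localizations()];
#'   unknown values become `"other"`.
#' @return A data.frame with class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id,
                            molecule_type = rep("other", length(gene_id)),
                            localization = rep("other", length(gene_id))) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop("duplicate gene_id in annotation")
  molecule_type <- as.character(molecule_type)
  localization <- as.character(localization)
  molecule_type[!molecule_type %in% molecule_types()] <- "other"
  localization[!localization %in% localizations()] <- "other"
  structure(
    data.frame(gene_id = gene_id, molecule_type = molecule_type,
               localization = localization, stringsAsFactors = FALSE),
    class = c("gene_annotation", "data.frame")
  )
}

#' Read / write a gene annotation TSV
#'
#' Three tab-separated columns with header: `gene_id`, `molecule_type`,
#' `localization`.
#'
#' @param path File path.
#' @return [read_gene_annotation()] returns a [gene_annotation()].
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gene_annotation(df$gene_id, df$molecule_type, df$localization)
}

#' @rdname read_gene_annotation
#' @param ann A [gene_annotation()].
#' @export
write_gene_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
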