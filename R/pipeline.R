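#' Pipeline run configuration
#'
#' Validates all thresholds and paths for [run_pipeline()]. Thresholds
#' outside their documented domains are rejected before any computation.
#'
#' @param gene_expression,transcript_expression Paths to gene- and
#'   transcript-level expression TSVs ([read_expression_table()] format).
#' @param network Path to the signed regulator network TSV (optional,
#'   `NA` to skip regulator stages).
#' @param annotation Path to the gene annotation TSV (optional).
#' @param novel_gtf,reference_gtf Paths to novel and reference GTFs
#'   (optional, both required for event classification).
#' @param out_dir Output directory (created if absent).
#' @param design An [age_design()].
#' @param theta_fpkm,min_replicates,alpha Expression-filter settings.
#' @param cutoff Factor-assignment absolute-correlation cutoff in (0, 1].
#' @param k Number of factors, or `"auto"` for Horn's parallel analysis.
#' @param icc_cutoff,min_targets Regulatory-module constraints.
#' @param z_threshold Absolute activation z-score deemed significant.
#' @param n_perm Durbin-Watson permutations.
#' @param horn_quantile Null quantile for Horn's parallel analysis.
#' @param seed Integer seed driving all stochastic steps.
#' @return A validated `run_config` list.
#' @export
run_config <- function(gene_expression,
                       transcript_expression = NA_character_,
                       network = NA_character_,
                       annotation = NA_character_,
                       novel_gtf = NA_character_,
                       reference_gtf = NA_character_,
                       out_dir = "ontodyn-out",
                       design = default_age_design(),
                       theta_fpkm = 1, min_replicates = 2L, alpha = 0.05,
                       cutoff = 0.7, k = "auto",
                       icc_cutoff = 0.6, min_targets = 5L,
                       z_threshold = 2, n_perm = 999L,
                       horn_quantile = 0.95, seed = 1L) {
  stopifnot(is.character(gene_expression), length(gene_expression) == 1L)
  if (theta_fpkm < 0) stop("theta_fpkm must be >= 0")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  if (icc_cutoff < 0 || icc_cutoff > 1) stop("icc_cutoff must be in [0, 1]")
  if (min_targets < 1L) stop("min_targets must be >= 1")
  if (z_threshold < 0) stop("z_threshold must be >= 0")
  if (n_perm < 999L) stop("n_perm must be >= 999")
  if (horn_quantile <= 0.5 || horn_quantile >= 1) {
    stop("horn_quantile must be in (0.5, 1)")
  }
  if (!identical(k, "auto") && (k < 1L || k >= length(design$ages))) {
    stop("k must be 'auto' or satisfy 1 <= k < n_ages")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: expression filtering, temporal summaries, factor
#' clustering, regulator enrichment and hit counts, regulatory-module
#' discovery (per temporal group), and novel-isoform filtering. Each
#' stage writes a TSV into the configured output directory; a
#' `manifest.json` records the configuration and md5 checksums of every
#' output, so two runs with the same config and seed are byte-identical.
#' A failing stage aborts with the stage name and cause.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  res <- list()
  outs <- character()
  emit <- function(df, file) {
    path <- file.path(config$out_dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outs <<- c(outs, path)
  }

  em <- stage("read_gene_expression",
              read_expression_table(config$gene_expression, config$design))
  calls <- stage("expression_filter",
                 expression_calls(em, config$theta_fpkm,
                                  config$min_replicates, config$alpha))
  res$analysis_genes <- select_analysis_genes(calls)
  emit(calls$differential, "differential.tsv")
  emit(data.frame(feature_id = res$analysis_genes), "analysis_genes.tsv")

  aem <- stage("subset_analysis_genes", {
    idx <- match(res$analysis_genes, em$feature_ids)
    expression_matrix(em$values[idx, , drop = FALSE], res$analysis_genes,
                      em$design, em$feature_level)
  })
  res$age_summaries <- stage("temporal_stats", age_summaries(em, calls))
  emit(res$age_summaries, "age_summaries.tsv")
  if (!is.na(config$annotation)) {
    ann <- stage("read_annotation", read_gene_annotation(config$annotation))
    tp <- stage("type_profiles", type_profiles(em, ann, res$analysis_genes))
    emit(data.frame(molecule_type = rownames(tp), tp, check.names = FALSE),
         "type_profiles.tsv")
    res$type_profiles <- tp
  }

  res$clustering <- stage("factor_clustering", {
    z <- standardize_age_means(aem)
    k <- config$k
    if (identical(k, "auto")) {
      k <- as.integer(horn_parallel_analysis(z, quantile = config$horn_quantile,
                                             seed = config$seed))
    }
    model <- fit_factor_model(z, k)
    assign <- assign_temporal_groups(aem, model, config$cutoff)
    list(k = k, model = model, assignments = assign)
  })
  emit(res$clustering$assignments, "temporal_groups.tsv")
  emit(data.frame(age = config$design$ages, res$clustering$model$loadings,
                  check.names = FALSE), "factor_loadings.tsv")

  if (!is.na(config$network)) {
    net <- stage("read_network", read_regulator_network(config$network))
    res$enrichment <- stage("regulator_enrichment", {
      assign <- res$clustering$assignments
      universe <- sort(unique(net$regulator))
      groups <- sort(unique(stats::na.omit(assign$group)))
      rows <- lapply(groups, function(g) {
        gg <- assign$feature_id[!is.na(assign$group) & assign$group == g]
        per_reg <- lapply(universe, function(rg) {
          tg <- regulator_targets(net, rg)
          k <- length(intersect(tg, gg))
          p <- hypergeom_overlap(length(assign$feature_id),
                                 length(intersect(tg, assign$feature_id)),
                                 length(gg), k)
          data.frame(group = g, regulator = rg, k = k, p = p,
                     stringsAsFactors = FALSE)
        })
        do.call(rbind, per_reg)
      })
      er <- do.call(rbind, rows)
      er$q <- bh_adjust(er$p)
      er
    })
    emit(res$enrichment, "regulator_enrichment.tsv")
    hc <- hit_count_matrix(net, res$clustering$assignments)
    emit(data.frame(regulator = rownames(hc), hc, check.names = FALSE),
         "hit_counts.tsv")
    res$modules <- stage("regulatory_modules", {
      assign <- res$clustering$assignments
      groups <- sort(unique(stats::na.omit(assign$group)))
      out <- lapply(groups, function(g) {
        gg <- assign$feature_id[!is.na(assign$group) & assign$group == g]
        mods <- find_modules(net, em, gg, config$icc_cutoff,
                             config$min_targets)
        if (length(mods)) cbind(group = g, summarize_modules(mods))
        else NULL
      })
      do.call(rbind, out)
    })
    if (!is.null(res$modules)) emit(res$modules, "modules.tsv")
  }

  if (!is.na(config$transcript_expression)) {
    tem <- stage("read_transcript_expression",
                 read_expression_table(config$transcript_expression,
                                       config$design, "transcript"))
    res$isoforms <- stage("novel_isoform_filter",
                          filter_novel_isoforms(tem, config$alpha,
                                                config$theta_fpkm,
                                                config$min_replicates,
                                                config$n_perm, config$seed))
    if (!is.na(config$novel_gtf) && !is.na(config$reference_gtf)) {
      novel <- stage("read_novel_gtf", read_gtf(config$novel_gtf))
      refs <- stage("read_reference_gtf", read_gtf(config$reference_gtf))
      ref_by_gene <- split(refs, vapply(refs, `[[`, "", "gene_id"))
      ev <- lapply(novel, function(tm) {
        e <- classify_splice_event(tm, ref_by_gene[[tm$gene_id]])
        if (nrow(e)) cbind(transcript_id = tm$transcript_id, e) else NULL
      })
      res$events <- do.call(rbind, ev)
      if (!is.null(res$events)) emit(res$events, "splice_events.tsv")
    }
    emit(res$isoforms, "isoforms.tsv")
  }

  manifest <- list(
    package = "ontodyn",
    version = as.character(utils::packageVersion("ontodyn")),
    config = config[setdiff(names(config), c("design"))],
    design = list(ages = config$design$ages,
                  replicates = config$design$replicates),
    outputs = as.list(tools::md5sum(sort(outs)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(res)
}

#' Write a complete synthetic study to disk
#'
#' Generates a coherent fixture set with known ground truth: a
#' gene-level expression matrix with planted temporal archetypes, a
#' signed regulator network with planted regulatory modules (regulator
#' rows appended to the matrix), a gene annotation table, a
#' transcript-level matrix mixing autocorrelated and white-noise series,
#' and reference plus novel GTFs carrying defined splice events. A
#' `truth.json` records every planted structure.
#'
#' @param out_dir Output directory.
#' @param n_genes Number of genes.
#' @param noise_sd Per-sample log2 noise SD.
#' @param design An [age_design()].
#' @param seed Integer seed.
#' @return Invisibly, a list with the file paths and the truth object.
#' @export
simulate_study <- function(out_dir, n_genes = 600L, noise_sd = 0.3,
                           design = default_age_design(), seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_expression(n_genes, noise_sd = noise_sd, design = design,
                             seed = seed)
  # plant one correlated and one anti-correlated module among the genes
  # of two temporal groups
  g1 <- head(sim$truth$gene_id[sim$truth$group == "Prenatal and Neonatal"], 6)
  g2 <- head(sim$truth$gene_id[sim$truth$group == "Adult"], 6)
  mods <- list(
    planted_module(c("regA", "regB"), g1, "Prenatal and Neonatal"),
    planted_module(c("regC", "regD"), g2, "Adult", anticorrelated = TRUE)
  )
  nw <- simulate_network(sim$matrix, mods, n_decoy_regulators = 4L,
                         n_decoy_edges = 12L, seed = seed + 1L)
  iso <- simulate_isoform_series(30L, 30L, design = design, seed = seed + 2L)
  ref <- transcript_model("ref1", "geneX", "chr1", "+",
                          cbind(c(100, 500, 900, 1300),
                                c(200, 650, 1050, 1500)))
  novel <- simulate_transcript_events(
    ref, c("exon_skip", "intron_retention", "alt_start"), seed = seed + 3L)
  ann <- withr::with_seed(seed + 4L, gene_annotation(
    sim$truth$gene_id,
    sample(molecule_types(), n_genes, replace = TRUE),
    sample(localizations(), n_genes, replace = TRUE)))

  paths <- list(
    gene_expression = file.path(out_dir, "genes.tsv"),
    transcript_expression = file.path(out_dir, "transcripts.tsv"),
    network = file.path(out_dir, "network.tsv"),
    annotation = file.path(out_dir, "annotation.tsv"),
    reference_gtf = file.path(out_dir, "reference.gtf"),
    novel_gtf = file.path(out_dir, "novel.gtf"),
    truth = file.path(out_dir, "truth.json")
  )
  write_expression_table(nw$matrix, paths$gene_expression)
  write_expression_table(iso$matrix, paths$transcript_expression)
  write_regulator_network(nw$network, paths$network)
  write_gene_annotation(ann, paths$annotation)
  write_gtf(list(ref), paths$reference_gtf)
  write_gtf(novel, paths$novel_gtf)
  truth <- list(
    genes = sim$truth,
    modules = lapply(mods, unclass),
    isoforms = iso$truth,
    events = names(novel)
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(list(paths = paths, truth = truth))
}
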