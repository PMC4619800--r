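#' Simulate an age-series expression matrix with known ground truth
#'
#' Generates FPKM values as
#' `2^(baseline_g + amplitude_g * shape_arch(g)(age) + eps)`, with
#' `eps ~ Normal(0, noise_sd)` per sample, around the six temporal
#' archetype shapes of [archetype_profiles()]. Null (non-differential)
#' genes have amplitude 0 and carry only baseline plus noise. Log-normal
#' noise on the log2 scale is used because the pipeline operates on
#' FPKM abundances, not counts.
#'
#' @param n_genes Number of genes (>= 1).
#' @param mix Proportions over the six archetypes plus a seventh "null"
#'   class; must be non-negative and sum to 1. Default: the six
#'   archetypes uniformly at 0.125 each plus 0.25 null.
#' @param baseline_log2_mean Mean of the per-gene baseline log2 FPKM;
#'   baselines are drawn uniformly within +/- `baseline_log2_spread`.
#' @param baseline_log2_spread Half-width of the baseline distribution.
#' @param amplitude_range Range of the per-gene amplitude multiplying the
#'   (unit-SD) archetype shape, drawn uniformly.
#' @param noise_sd SD of the per-sample Gaussian noise on log2 FPKM.
#' @param design An [age_design()].
#' @param seed Integer seed; the same seed reproduces the matrix exactly.
#' @return A list with `matrix` (an [expression_matrix()]) and `truth`
#'   (data.frame: `gene_id`, `group` ("null" for null genes), `amplitude`,
#'   `baseline`).
#' @export
simulate_expression <- function(n_genes,
                                mix = c(rep(0.125, 6), 0.25),
                                baseline_log2_mean = 5,
                                baseline_log2_spread = 3,
                                amplitude_range = c(0.8, 2.5),
                                noise_sd = 0.3,
                                design = default_age_design(),
                                seed = 1L) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (length(mix) == 6L) mix <- c(mix, 0)
  if (length(mix) != 7L || any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    stop("mix must be 6 or 7 non-negative proportions summing to 1")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  shapes <- archetype_profiles(design)$shapes
  classes <- c(temporal_group_labels(), "null")
  withr::with_seed(seed, {
    cls <- sample(classes, n_genes, replace = TRUE, prob = mix)
    amp <- stats::runif(n_genes, amplitude_range[1], amplitude_range[2])
    amp[cls == "null"] <- 0
    base <- stats::runif(n_genes, baseline_log2_mean - baseline_log2_spread,
                         baseline_log2_mean + baseline_log2_spread)
    ns <- n_samples(design)
    reps <- design$replicates
    mu <- matrix(rep(base, ns), n_genes, ns)
    for (j in which(cls != "null")) {
      mu[j, ] <- base[j] + amp[j] * rep(shapes[, cls[j]], each = reps)
    }
    vals <- 2^(mu + matrix(stats::rnorm(n_genes * ns, 0, noise_sd), n_genes, ns))
  })
  ids <- sprintf("g%04d", seq_len(n_genes))
  list(
    matrix = expression_matrix(vals, ids, design, "gene"),
    truth = data.frame(gene_id = ids, group = cls, amplitude = amp,
                       baseline = base, stringsAsFactors = FALSE)
  )
}

#' Specify a planted regulatory module
#'
#' @param regulators Character vector (>= 2) of regulator identifiers.
#' @param targets Character vector (>= 5 by default thresholds) of target
#'   gene identifiers; targets must exist in the companion matrix.
#' @param group The temporal group whose archetype shape the regulators
#'   follow.
#' @param anticorrelated If `TRUE`, regulators alternate between the
#'   shape and its negation, giving a module with negative intraclass
#'   correlation.
#' @return A `planted_module` list.
#' @export
planted_module <- function(regulators, targets, group,
                           anticorrelated = FALSE) {
  if (length(regulators) < 2L) stop("a module needs >= 2 regulators")
  if (!group %in% temporal_group_labels()) {
    stop("unknown temporal group: ", group)
  }
  structure(list(regulators = as.character(regulators),
                 targets = as.character(targets), group = group,
                 anticorrelated = isTRUE(anticorrelated)),
            class = "planted_module")
}

#' Simulate a signed regulator network around planted modules
#'
#' Builds a network containing every planted regulator -> target edge
#' plus random decoy regulators and edges, and appends expression rows
#' for all regulators to a companion matrix. Planted regulators follow
#' their module's archetype shape (alternating sign when the module is
#' anti-correlated); decoy regulators get independent noise series.
#'
#' @param em Companion [expression_matrix()] containing the target genes.
#' @param modules List of [planted_module()]s.
#' @param n_decoy_regulators,n_decoy_edges Decoy counts.
#' @param amplitude Amplitude of the regulator shape on log2 FPKM.
#' @param noise_sd SD of the per-sample noise on regulator series.
#' @param seed Integer seed.
#' @return A list with `network` (a [regulator_network()]), `matrix` (the
#'   input matrix with regulator rows appended) and `modules` (the
#'   planted list).
#' @export
simulate_network <- function(em, modules, n_decoy_regulators = 0L,
                             n_decoy_edges = 0L, amplitude = 2,
                             noise_sd = 0.1, seed = 1L) {
  shapes <- archetype_profiles(em$design)$shapes
  reps <- em$design$replicates
  ns <- n_samples(em$design)
  regs <- character(); targs <- character()
  reg_rows <- list()
  for (m in modules) {
    missing <- setdiff(m$targets, em$feature_ids)
    if (length(missing)) {
      stop("planted target(s) absent from matrix: ",
           paste(missing, collapse = ", "))
    }
    sgn <- rep(1, length(m$regulators))
    if (m$anticorrelated) sgn[seq_along(sgn) %% 2 == 0] <- -1
    for (i in seq_along(m$regulators)) {
      reg_rows[[m$regulators[i]]] <-
        amplitude * sgn[i] * rep(shapes[, m$group], each = reps)
    }
    regs <- c(regs, rep(m$regulators, each = length(m$targets)))
    targs <- c(targs, rep(m$targets, length(m$regulators)))
  }
  planted_key <- paste(regs, targs)
  withr::with_seed(seed, {
    decoy_ids <- sprintf("decoyR%03d", seq_len(n_decoy_regulators))
    for (id in decoy_ids) reg_rows[[id]] <- stats::rnorm(ns, 0, 1)
    if (n_decoy_edges > 0L) {
      if (!length(decoy_ids)) stop("decoy edges require decoy regulators")
      dr <- sample(decoy_ids, n_decoy_edges, replace = TRUE)
      dt <- sample(em$feature_ids, n_decoy_edges, replace = TRUE)
      dup <- duplicated(paste(dr, dt)) | paste(dr, dt) %in% planted_key
      dr <- dr[!dup]; dt <- dt[!dup]
      regs <- c(regs, dr); targs <- c(targs, dt)
    }
    base <- stats::runif(length(reg_rows), 3, 7)
    noise <- matrix(stats::rnorm(length(reg_rows) * ns, 0, noise_sd),
                    length(reg_rows), ns)
  })
  reg_mat <- 2^(base + do.call(rbind, reg_rows) + noise)
  all_vals <- rbind(em$values, reg_mat)
  out_mat <- expression_matrix(all_vals,
                               c(em$feature_ids, names(reg_rows)),
                               em$design, em$feature_level)
  list(network = regulator_network(regs, targs, rep(1L, length(regs))),
       matrix = out_mat, modules = modules)
}

#' Simulate transcript-level series with and without autocorrelation
#'
#' Autocorrelated series follow a randomly chosen archetype shape plus
#' small noise (temporally coherent expression); white-noise series are
#' i.i.d. on the log2 scale and hence exchangeable across ages.
#'
#' @param n_autocorrelated,n_whitenoise Series counts (>= 0).
#' @param amplitude Shape amplitude for autocorrelated series.
#' @param noise_sd Per-sample noise SD (both classes).
#' @param wn_sd SD of the age-level white-noise signal.
#' @param design An [age_design()].
#' @param seed Integer seed.
#' @return List with `matrix` (transcript-level [expression_matrix()])
#'   and `truth` (data.frame: `transcript_id`, `autocorrelated`).
#' @export
simulate_isoform_series <- function(n_autocorrelated, n_whitenoise,
                                    amplitude = 1.5, noise_sd = 0.15,
                                    wn_sd = 1,
                                    design = default_age_design(),
                                    seed = 1L) {
  if (n_autocorrelated < 0L || n_whitenoise < 0L) stop("counts must be >= 0")
  n <- n_autocorrelated + n_whitenoise
  if (n == 0L) stop("at least one series is required")
  shapes <- archetype_profiles(design)$shapes
  reps <- design$replicates
  ns <- n_samples(design)
  withr::with_seed(seed, {
    base <- stats::runif(n, 3, 7)
    arch <- sample(ncol(shapes), n, replace = TRUE)
    mu <- matrix(rep(base, ns), n, ns)
    for (j in seq_len(n_autocorrelated)) {
      mu[j, ] <- base[j] + amplitude * rep(shapes[, arch[j]], each = reps)
    }
    if (n_whitenoise > 0L) {
      for (j in n_autocorrelated + seq_len(n_whitenoise)) {
        mu[j, ] <- base[j] + rep(stats::rnorm(length(design$ages), 0, wn_sd),
                                 each = reps)
      }
    }
    vals <- 2^(mu + matrix(stats::rnorm(n * ns, 0, noise_sd), n, ns))
  })
  ids <- sprintf("t%04d", seq_len(n))
  list(
    matrix = expression_matrix(vals, ids, design, "transcript"),
    truth = data.frame(
      transcript_id = ids,
      autocorrelated = rep(c(TRUE, FALSE), c(n_autocorrelated, n_whitenoise)),
      stringsAsFactors = FALSE)
  )
}

#' Derive novel transcript models carrying requested splice events
#'
#' For each requested event type, returns a copy of the reference
#' transcript modified by exactly that event. Random choices (which
#' internal exon to skip, where to place an alternative exon) are
#' seeded and deterministic.
#'
#' @param reference A [transcript_model()].
#' @param events Character vector of event types among `"exon_skip"`,
#'   `"intron_retention"`, `"alternative_exon"`, `"alt_start"`,
#'   `"alt_termination"`.
#' @param shift Boundary shift (bp) used for `alt_start` /
#'   `alt_termination`.
#' @param seed Integer seed.
#' @return Named list of [transcript_model()]s, one per event.
#' @export
simulate_transcript_events <- function(reference, events, shift = 100,
                                       seed = 1L) {
  known <- c("exon_skip", "intron_retention", "alternative_exon",
             "alt_start", "alt_termination")
  bad <- setdiff(events, known)
  if (length(bad)) stop("unknown event type(s): ", paste(bad, collapse = ", "))
  e <- reference$exons
  n <- nrow(e)
  out <- list()
  withr::with_seed(seed, {
    for (k in seq_along(events)) {
      ev <- events[k]
      id <- paste0(reference$transcript_id, "_", ev, k)
      exons <- switch(ev,
        exon_skip = {
          if (n < 3L) stop("exon_skip needs a reference with >= 3 exons")
          drop <- sample(2:(n - 1L), 1L)
          e[-drop, , drop = FALSE]
        },
        intron_retention = {
          if (n < 2L) stop("intron_retention needs >= 2 exons")
          i <- sample(seq_len(n - 1L), 1L)
          merged <- c(e[i, 1], e[i + 1L, 2])
          rbind(e[seq_len(i - 1L), , drop = FALSE], merged,
                e[setdiff(seq_len(n), seq_len(i + 1L)), , drop = FALSE])
        },
        alternative_exon = {
          if (n < 2L) stop("alternative_exon needs >= 2 exons (an intron)")
          introns <- transcript_introns(reference)
          w <- introns[, 2] - introns[, 1]
          ok <- which(w >= 30)
          if (!length(ok)) stop("no intron long enough for an alternative exon")
          i <- ok[sample(length(ok), 1L)]
          mid <- floor((introns[i, 1] + introns[i, 2]) / 2)
          half <- floor(min(10, (introns[i, 2] - introns[i, 1]) / 4))
          rbind(e, c(mid - half, mid + half))
        },
        alt_start = {
          first <- if (reference$strand == "+") 1L else n
          len <- e[first, 2] - e[first, 1]
          d <- min(shift, len - 1)
          e2 <- e
          if (reference$strand == "+") e2[first, 1] <- e2[first, 1] + d
          else e2[first, 2] <- e2[first, 2] - d
          e2
        },
        alt_termination = {
          last <- if (reference$strand == "+") n else 1L
          len <- e[last, 2] - e[last, 1]
          d <- min(shift, len - 1)
          e2 <- e
          if (reference$strand == "+") e2[last, 2] <- e2[last, 2] - d
          else e2[last, 1] <- e2[last, 1] + d
          e2
        })
      out[[id]] <- transcript_model(id, reference$gene_id, reference$chrom,
                                    reference$strand, exons)
    }
  })
  out
}
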