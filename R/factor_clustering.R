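#' Horn's parallel analysis for the number of temporal factors
#'
#' Compares the eigenvalues of the age-by-age correlation matrix of the
#' standardized gene series against the eigenvalue distribution of
#' same-shaped standard-normal matrices. The retained factor count `k`
#' is the number of observed eigenvalues exceeding the chosen quantile
#' of the matched null eigenvalues.
#'
#' @param z Standardized gene x age matrix (e.g. from
#'   [assign_temporal_groups()]'s internal standardization, or any
#'   matrix of per-gene zero-mean unit-SD age series). Rows with NA are
#'   dropped.
#' @param n_sim Number of null matrices (>= 100, default 200).
#' @param quantile Null quantile in (0.5, 1), default 0.95.
#' @param seed Integer seed for the null simulation.
#' @return Integer `k`, with attributes `eigenvalues` (observed) and
#'   `thresholds` (null quantiles).
#' @export
horn_parallel_analysis <- function(z, n_sim = 200L, quantile = 0.95,
                                   seed = 1L) {
  z <- z[stats::complete.cases(z), , drop = FALSE]
  p <- ncol(z)
  if (p < 3L) stop("need at least 3 ages")
  if (n_sim < 100L) stop("n_sim must be >= 100")
  if (quantile <= 0.5 || quantile >= 1) stop("quantile must be in (0.5, 1)")
  n <- nrow(z)
  obs <- eigen(stats::cor(z), symmetric = TRUE, only.values = TRUE)$values
  # null matrices are row-standardized exactly like the observed data;
  # per-gene standardization makes rows zero-sum, which biases the age
  # correlations, and the null must share that structure
  null_eigs <- withr::with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      m <- matrix(stats::rnorm(n * p), n, p)
      m <- (m - rowMeans(m)) / apply(m, 1, stats::sd)
      eigen(stats::cor(m), symmetric = TRUE, only.values = TRUE)$values
    }, numeric(p))
  })
  thr <- apply(null_eigs, 1, stats::quantile, probs = quantile)
  # count leading consecutive exceedances: a factor is retained only if
  # every larger factor was also retained
  exceed <- obs > thr
  k <- if (all(exceed)) p else which(!exceed)[1] - 1L
  structure(as.integer(k), eigenvalues = obs, thresholds = thr)
}

# principal-axis factoring of a correlation matrix; returns age x k loadings
paf_loadings <- function(R, k, max_iter = 500L, tol = 1e-8) {
  h <- tryCatch(1 - 1 / diag(solve(R)),
                error = function(e) apply(abs(R - diag(diag(R))), 1, max))
  for (it in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h
    e <- eigen(Rr, symmetric = TRUE)
    L <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
    h2 <- rowSums(L^2)
    if (max(abs(h2 - h)) < tol) return(list(loadings = L, iterations = it))
    h <- h2
  }
  stop("principal-axis factoring did not converge in ", max_iter,
       " iterations")
}

varimax_criterion <- function(L) sum(apply(L^2, 2, stats::var))

# varimax with random orthogonal restarts; the plain single-start
# algorithm can stall in local optima on near-degenerate eigenstructures
varimax_restarts <- function(L, n_starts = 20L, seed = 421L) {
  best <- stats::varimax(L, normalize = FALSE)
  bestc <- varimax_criterion(best$loadings)
  p <- ncol(L)
  withr::with_seed(seed, {
    for (i in seq_len(n_starts)) {
      Tr <- qr.Q(qr(matrix(stats::rnorm(p * p), p, p)))
      v <- stats::varimax(L %*% Tr, normalize = FALSE)
      cc <- varimax_criterion(v$loadings)
      if (cc > bestc + 1e-12) {
        best <- v
        bestc <- cc
      }
    }
  })
  M <- best$loadings[]
  matrix(as.numeric(M), nrow = nrow(L))
}

#' Fit a common-factor model of the temporal structure
#'
#' Extracts `k` common factors from the age-by-age correlation matrix of
#' standardized gene series (principal-axis factoring by default,
#' maximum likelihood via [stats::factanal()] as an option) and rotates
#' the loadings with varimax (random-restart, unnormalized). Because the
#' genes are the observations and the ages the variables, each rotated
#' loading column is a temporal profile.
#'
#' @param z Standardized gene x age matrix (NA rows dropped).
#' @param k Number of factors, `1 <= k < n_ages`.
#' @param method `"paf"` (default) or `"ml"`.
#' @param rotate If `FALSE`, return unrotated loadings (communalities are
#'   unaffected either way, rotation being orthogonal).
#' @param n_starts Random varimax restarts.
#' @return Object of class `factor_model`: list with `loadings`
#'   (ages x k), `eigenvalues`, `communalities`, `k`, `method`.
#' @export
fit_factor_model <- function(z, k, method = c("paf", "ml"), rotate = TRUE,
                             n_starts = 20L) {
  method <- match.arg(method)
  z <- z[stats::complete.cases(z), , drop = FALSE]
  p <- ncol(z)
  if (k < 1L || k >= p) stop("k must satisfy 1 <= k < n_ages")
  R <- stats::cor(z)
  L <- if (method == "paf") {
    paf_loadings(R, k)$loadings
  } else {
    f <- stats::factanal(covmat = R, factors = k, n.obs = nrow(z),
                         rotation = "none")
    matrix(as.numeric(f$loadings[]), nrow = p)
  }
  if (rotate && k > 1L) L <- varimax_restarts(L, n_starts)
  rownames(L) <- colnames(z)
  colnames(L) <- paste0("F", seq_len(k))
  structure(
    list(loadings = L,
         eigenvalues = eigen(R, symmetric = TRUE, only.values = TRUE)$values,
         communalities = rowSums(L^2), k = k, method = method),
    class = "factor_model"
  )
}

#' @export
print.factor_model <- function(x, ...) {
  cat("factor_model:", x$k, "factors (", x$method, ") over",
      nrow(x$loadings), "ages\n")
  print(round(x$loadings, 3))
  invisible(x)
}

# choose per-factor orientation and early/mid/late roles jointly, by
# matching loading peak positions to target positions; enumerating all
# orientation/role combinations avoids the instability of canonicalizing
# each factor's sign in isolation
orient_and_role <- function(V, targets = NULL) {
  k <- ncol(V)
  n <- nrow(V)
  if (is.null(targets)) targets <- round(c(1, 0.4 * n, n))
  stopifnot(k == 3L)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  best <- NULL
  bestcost <- Inf
  for (o in 0:7) {
    sg <- ifelse(bitwAnd(o, 2^(0:2)) > 0, -1, 1)
    pk <- vapply(1:3, function(j) which.max(sg[j] * V[, j]), integer(1))
    for (pi in 1:6) {
      role <- perms[pi, ]
      cost <- sum(abs(pk - targets[role]))
      if (cost < bestcost) {
        bestcost <- cost
        best <- list(sign = sg, role = role)
      }
    }
  }
  best
}

#' Assign genes to temporal groups
#'
#' Correlates each gene's standardized age-mean series with every rotated
#' loading column and assigns the gene to the factor with the highest
#' absolute correlation, provided that correlation is at or above
#' `cutoff` (default 0.7). The sign of the correlation distinguishes the
#' expression (+) from the suppression (-) sub-cluster, and the (factor,
#' sign) pair maps to one of the six temporal group labels according to
#' the temporal position of each loading's peak: early-peaking factor
#' + -> "Prenatal and Neonatal", - -> "Adolescent and Adult"; mid-peaking
#' + -> "Neonatal and Adolescent", - -> "Prenatal and Adult";
#' late-peaking + -> "Adult", - -> "Neonatal". Zero-variance gene series
#' are returned unassigned and flagged.
#'
#' @param em An [expression_matrix()].
#' @param model A [fit_factor_model()] result fitted on the same ages.
#' @param cutoff Absolute-correlation threshold in (0, 1], default 0.7.
#' @return data.frame: `feature_id`, `factor`, `r`, `sign`, `group`
#'   (NA when unassigned), `assigned`, `zero_variance`.
#' @export
assign_temporal_groups <- function(em, model, cutoff = 0.7) {
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  if (nrow(model$loadings) != length(em$design$ages)) {
    stop("model was fitted on a different number of ages")
  }
  z <- standardize_age_means(em)
  V <- model$loadings
  use_groups <- model$k == 3L
  if (use_groups) {
    orr <- orient_and_role(V)
    V <- sweep(V, 2, orr$sign, "*")
  }
  r <- suppressWarnings(stats::cor(t(z), V))
  zerovar <- !stats::complete.cases(z)
  r[zerovar, ] <- 0
  fac <- max.col(abs(r), ties.method = "first")
  rbest <- r[cbind(seq_len(nrow(r)), fac)]
  assigned <- abs(rbest) >= cutoff & !zerovar
  grp <- rep(NA_character_, nrow(r))
  if (use_groups) {
    role <- orr$role[fac]
    grp[assigned] <- group_label(role[assigned],
                                 ifelse(rbest[assigned] > 0, 1L, -1L))
  } else {
    grp[assigned] <- paste0("F", fac[assigned],
                            ifelse(rbest[assigned] > 0, "+", "-"))
  }
  data.frame(
    feature_id = em$feature_ids,
    factor = ifelse(assigned, fac, NA_integer_),
    r = rbest,
    sign = ifelse(assigned, ifelse(rbest > 0, "+", "-"), NA_character_),
    group = grp,
    assigned = assigned,
    zero_variance = zerovar,
    stringsAsFactors = FALSE
  )
}

#' Deterministic hierarchical clustering of expression rows
#'
#' Agglomerative clustering with the two distance/linkage combinations
#' used for temporal heatmaps: Euclidean distance with Ward linkage
#' (`ward.D2` on Euclidean distances) or correlation distance (1 - r)
#' with average linkage. Ward with correlation distance is rejected as an
#' invalid combination.
#'
#' @param x Numeric matrix; rows are clustered.
#' @param distance `"euclidean"` or `"correlation"`.
#' @param linkage `"ward"` or `"average"`.
#' @return List with `order` (leaf ordering), `merge`, `height`, and the
#'   underlying `hclust` object.
#' @export
hier_cluster_order <- function(x, distance = c("euclidean", "correlation"),
                               linkage = c("ward", "average")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (nrow(x) < 2L) stop("need >= 2 rows")
  if (linkage == "ward" && distance == "correlation") {
    stop("Ward linkage requires Euclidean distance")
  }
  d <- if (distance == "euclidean") stats::dist(x)
       else stats::as.dist(1 - stats::cor(t(x)))
  hc <- stats::hclust(d, method = if (linkage == "ward") "ward.D2"
                                  else "average")
  list(order = hc$order, merge = hc$merge, height = hc$height, hclust = hc)
}
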