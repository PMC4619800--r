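#' The six temporal group labels
#'
#' Labels of the six temporal expression groups, in (factor, sign) order:
#' early factor +/-, mid factor +/-, late factor +/-.
#'
#' @return Character vector of length 6.
#' @export
temporal_group_labels <- function() {
  c("Prenatal and Neonatal", "Adolescent and Adult",
    "Neonatal and Adolescent", "Prenatal and Adult",
    "Adult", "Neonatal")
}

# label for (role in 1:3 = early/mid/late, sign in {+1,-1})
group_label <- function(role, sign) {
  temporal_group_labels()[(role - 1L) * 2L + ifelse(sign > 0, 1L, 2L)]
}

#' Temporal archetype profiles
#'
#' Builds the three base temporal profiles (early-high declining,
#' mid-development peak, late rise) over the ages of a design, and from
#' them the six archetype shapes (each base profile and its negation)
#' that define the six temporal groups.
#'
#' The base profiles start from qualitative sigmoid/bump curves and are
#' refined by alternating projections until they are simultaneously
#' zero-mean and unit-SD over ages, exactly mutually uncorrelated, of
#' equal row norm at every age, and a varimax fixed point. These
#' properties make the generative model self-consistent with
#' correlation-based factor extraction and varimax rotation: in the
#' noiseless limit the fitted loadings coincide with the base profiles.
#'
#' @param design An [age_design()].
#' @return A list with `base` (ages x 3 matrix, columns early/mid/late)
#'   and `shapes` (ages x 6 matrix, columns named by the six
#'   [temporal_group_labels()]).
#' @export
archetype_profiles <- function(design = default_age_design()) {
  n <- length(design$ages)
  t <- seq_len(n)
  std <- function(x) (x - mean(x)) / stats::sd(x)
  # qualitative seeds, parameterised by fractional position along the series
  f1 <- 1 / (1 + exp((t - 0.40 * n) / (0.058 * n)))   # early-high, declines
  f2 <- exp(-0.5 * ((t - 0.375 * n) / (0.067 * n))^2) # mid-development peak
  f3 <- 1 / (1 + exp(-(t - 0.825 * n) / (0.050 * n))) # rises late
  M <- cbind(std(f1), std(f2), std(f3))
  for (i in seq_len(500)) {
    M <- sweep(M, 2, colMeans(M))
    e <- eigen(crossprod(M), symmetric = TRUE)
    M <- M %*% (e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors))
    rn <- sqrt(rowSums(M^2))
    M <- M * (sqrt(ncol(M) / nrow(M)) / rn)
  }
  V <- stats::varimax(M, normalize = FALSE)$loadings[]
  V <- matrix(as.numeric(V), nrow = n)
  # orient each column so its peak-time role is unambiguous, then order
  # columns early/mid/late by peak position
  for (j in 1:3) if (abs(min(V[, j])) > max(V[, j])) V[, j] <- -V[, j]
  V <- V[, order(apply(V, 2, which.max)), drop = FALSE]
  base <- apply(V, 2, std)
  colnames(base) <- c("early", "mid", "late")
  rownames(base) <- paste0("d", design$ages)
  shapes <- cbind(base[, 1], -base[, 1], base[, 2], -base[, 2],
                  base[, 3], -base[, 3])
  colnames(shapes) <- temporal_group_labels()
  list(base = base, shapes = shapes)
}
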