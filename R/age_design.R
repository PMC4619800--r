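#' Age-series experimental design
#'
#' Describes an ordered developmental age series with a fixed number of
#' biological replicates per age. Sample columns are laid out age-major,
#' replicate-minor, and are named `d{age}_r{rep}` (e.g. `d-2_r1`).
#'
#' @param ages Numeric vector of ages in days, strictly increasing,
#'   length at least 3. Negative ages denote days before birth.
#' @param replicates Positive integer, number of replicates per age.
#' @return An object of class `age_design` with elements `ages`,
#'   `replicates` and `labels` (sample column names in design order).
#' @examples
#' d <- age_design(c(-2, 0, 5), 3)
#' d$labels
#' @export
age_design <- function(ages, replicates = 3L) {
  ages <- as.numeric(ages)
  if (length(ages) < 3L) {
    stop("an age design needs at least 3 ages, got ", length(ages))
  }
  if (anyNA(ages) || any(!is.finite(ages))) stop("ages must be finite")
  if (any(diff(ages) <= 0)) stop("ages must be strictly increasing")
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    stop("replicates must be a positive integer")
  }
  labels <- as.vector(t(outer(ages, seq_len(replicates),
                              function(a, r) sprintf("d%g_r%d", a, r))))
  structure(
    list(ages = ages, replicates = replicates, labels = labels),
    class = "age_design"
  )
}

#' Default 12-age by 3-replicate design
#'
#' The default developmental design: 12 ages from 2 days before birth to
#' 60 days after (-2, 0, 1, 3, 5, 10, 15, 20, 25, 30, 45, 60), three
#' biological replicates each, 36 samples in total.
#'
#' @return An [age_design()] object.
#' @export
default_age_design <- function() {
  age_design(c(-2, 0, 1, 3, 5, 10, 15, 20, 25, 30, 45, 60), 3L)
}

#' @export
print.age_design <- function(x, ...) {
  cat("age_design:", length(x$ages), "ages x", x$replicates, "replicates\n")
  cat("  ages (days):", paste(x$ages, collapse = ", "), "\n")
  invisible(x)
}

n_samples <- function(design) length(design$ages) * design$replicates

# column indices of the replicates of age index a
age_columns <- function(design, a) {
  (a - 1L) * design$replicates + seq_len(design$replicates)
}
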