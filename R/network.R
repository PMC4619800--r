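#' Signed regulator-target network
#'
#' A set of regulator -> target edges with an expected direction of
#' effect: `+1` (target up when the regulator is active), `-1` (target
#' down), or `0` (association with unknown sign).
#'
#' @param regulator,target Character vectors of equal length.
#' @param direction Integer vector in `{-1, 0, 1}` (default all `0`).
#' @return A `regulator_network`: a data.frame with columns `regulator`,
#'   `target`, `direction` and class attribute `regulator_network`.
#' @export
regulator_network <- function(regulator = character(), target = character(),
                              direction = rep(0L, length(regulator))) {
  regulator <- as.character(regulator)
  target <- as.character(target)
  direction <- as.integer(direction)
  if (length(target) != length(regulator) ||
      length(direction) != length(regulator)) {
    stop("regulator, target and direction must have equal length")
  }
  if (length(direction) && !all(direction %in% c(-1L, 0L, 1L))) {
    stop("direction must be -1, 0 or +1")
  }
  key <- paste(regulator, target, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate edge: ", sub("\r", " -> ", d, fixed = TRUE))
  }
  structure(
    data.frame(regulator = regulator, target = target,
               direction = direction, stringsAsFactors = FALSE),
    class = c("regulator_network", "data.frame")
  )
}

.direction_tokens <- c("+1" = 1L, "1" = 1L, "up" = 1L,
                       "-1" = -1L, "down" = -1L,
                       "0" = 0L, "unknown" = 0L)

#' Read a regulator network from a 3-column TSV
#'
#' Columns: regulator, target, direction. Direction tokens `+1`, `1`,
#' `up` map to `+1`; `-1`, `down` to `-1`; `0`, `unknown` to `0`. A
#' header line `regulator  target  direction` is permitted and skipped.
#' Duplicate edges (even with agreeing direction) are an error.
#'
#' @param path File path.
#' @return A [regulator_network()].
#' @export
read_regulator_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(regulator_network())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 3L)) {
    bad <- which(lengths(fields) != 3L)[1]
    stop("line ", bad, " of ", path, " does not have 3 tab-separated fields")
  }
  m <- do.call(rbind, fields)
  if (tolower(m[1, 3]) == "direction") m <- m[-1, , drop = FALSE]
  if (!nrow(m)) return(regulator_network())
  tok <- tolower(trimws(m[, 3]))
  dir <- .direction_tokens[tok]
  if (anyNA(dir)) {
    stop("malformed direction token '", m[which(is.na(dir))[1], 3], "' in ", path)
  }
  regulator_network(m[, 1], m[, 2], unname(dir))
}

#' Write a regulator network as TSV
#'
#' @param net A [regulator_network()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_regulator_network <- function(net, path) {
  utils::write.table(
    data.frame(regulator = net$regulator, target = net$target,
               direction = as.character(net$direction)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# target set of one regulator
regulator_targets <- function(net, regulator) {
  unique(net$target[net$regulator == regulator])
}
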