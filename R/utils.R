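#' @importFrom rlang %||%
NULL

str_tail <- function(x, k) {
  n <- nchar(x)
  k <- pmin(k, n)
  substr(x, n - k + 1, n)
}

str_head <- function(x, k) {
  substr(x, 1, pmin(k, nchar(x)))
}

#' Levenshtein distance between junction strings
#'
#' Thin wrapper over [utils::adist()] (unit insertion/deletion/substitution
#' costs), used by the satellite noise filter.
#'
#' @param a,b Character vectors (recycled).
#' @return Integer vector of edit distances.
#' @export
junction_distance <- function(a, b) {
  if (length(a) == length(b)) {
    as.integer(diag(utils::adist(a, b)))
  } else {
    as.integer(utils::adist(a, b))
  }
}
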