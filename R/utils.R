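#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same cells
#' (pair-counting form), used to score recovery of planted communities:
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b labelings of equal length (any atomic type).
#' @return numeric ARI.
#' @export
ariScore <- function(a, b) {
  if (length(a) != length(b))
    stop("labelings must have equal length", call. = FALSE)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_index - expected)
}

# BiocNeighbors warns when kd-tree queries hit tied distances; ties are
# expected on discrete profile vectors and resolved deterministically for
# a given input, so the warning is muffled at these call sites.
.quietTies <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("tied distances", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}
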