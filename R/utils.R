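#' Adjusted Rand index between two partitions
#'
#' Agreement between two flat partitions of the same items, corrected for
#' chance. Used to compare recovered OTU/CTU partitions against planted
#' ground truth; 1 means identical up to label bijection, 0 is the chance
#' expectation.
#'
#' @param a,b vectors of cluster labels of equal length (any atomic type).
#' @return a number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  tot <- comb2(n)
  expected <- sum_i * sum_j / tot
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

# Deterministic integer RNG seed derived from a base seed and a stage tag.
# Keeps derived seeds well below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop2 <- function(...) stop(..., call. = FALSE)
warn2 <- function(...) warning(..., call. = FALSE)
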