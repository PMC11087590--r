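#' Adjusted Rand index between two labelings
#'
#' Used to score recovery of planted cluster structure against truth.
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# fraction of `truth` ids recovered in `called`
recall_of <- function(truth, called) {
  if (!length(truth)) return(NA_real_)
  mean(truth %in% called)
}

# fraction of `called` ids that are true
precision_of <- function(truth, called) {
  if (!length(called)) return(NA_real_)
  mean(called %in% truth)
}
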