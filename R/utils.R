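#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same samples;
#' 1 for identical partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Numeric ARI.
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

#' Split a pair id into its two pathway ids
#' @param pair_id Character "idA-idB" string(s).
#' @return Character matrix with two columns.
#' @export
split_pair_id <- function(pair_id) {
  parts <- strsplit(as.character(pair_id), "-", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stop("malformed pair id: ", pair_id[bad][1L])
  matrix(unlist(parts), ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("first", "second")))
}
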