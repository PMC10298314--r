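# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: everything is computed by literal enumeration.

# ssGSEA by explicit position-by-position re-summation (O(n^2)).
oracle_ssgsea <- function(expression, gene_set, alpha) {
  n <- length(expression)
  ord <- order(-expression)  # stable: ties keep input order
  genes_sorted <- names(expression)[ord]
  rho <- (n + 1) - seq_len(n)  # weight of position p
  in_set <- genes_sorted %in% gene_set
  denom_in <- sum((rho[in_set])^alpha)
  n_out <- sum(!in_set)
  total <- 0
  for (p in seq_len(n)) {
    p_in <- sum((rho[seq_len(p)][in_set[seq_len(p)]])^alpha) / denom_in
    p_out <- sum(!in_set[seq_len(p)]) / n_out
    total <- total + (p_in - p_out)
  }
  total
}

# Pearson chi-square by literal sum of (O - E)^2 / E over the four cells.
oracle_chi2 <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  n <- sum(obs)
  stat <- 0
  for (i in 1:2) for (j in 1:2) {
    e <- sum(obs[i, ]) * sum(obs[, j]) / n
    stat <- stat + (obs[i, j] - e)^2 / e
  }
  stat
}

# Maximal cliques by subset enumeration (graphs up to ~12 nodes), then the
# MCC score sum((|C|-1)!) per node. `edges` is a 2-column character matrix.
oracle_mcc <- function(nodes, edges) {
  adj <- matrix(FALSE, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    adj[edges[r, 1], edges[r, 2]] <- TRUE
    adj[edges[r, 2], edges[r, 1]] <- TRUE
  }
  nn <- length(nodes)
  is_clique <- function(s) {
    if (length(s) < 2) return(TRUE)
    all(adj[s, s][upper.tri(matrix(0, length(s), length(s)))])
  }
  cliques <- list()
  for (mask in seq_len(2^nn - 1)) {
    s <- which(bitwAnd(mask, 2^(seq_len(nn) - 1)) > 0)
    if (length(s) >= 2 && is_clique(s)) cliques[[length(cliques) + 1]] <- s
  }
  maximal <- Filter(function(s) {
    !any(vapply(setdiff(seq_len(nn), s), function(v) is_clique(c(s, v)), TRUE))
  }, cliques)
  score <- setNames(numeric(nn), nodes)
  for (s in maximal) score[s] <- score[s] + factorial(length(s) - 1)
  score
}

# AUC as the fraction of concordant positive/negative score pairs (+1/2 ties).
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Small deterministic activity matrix for pair-construction tests.
toy_activity <- function(m = 4, n = 3, seed = 11) {
  set.seed(seed)
  matrix(rnorm(m * n), m, n,
         dimnames = list(sprintf("pw%02d", seq_len(m)), sprintf("s%d", seq_len(n))))
}

# The stated planted-effect worlds used by the recovery tests.
flip_config <- function() {
  sim_config(effects = data.frame(pathway = c("path01", "path02"),
                                  group = "AD", delta = c(2, -2)))
}
five_pathway_config <- function() {
  sim_config(effects = data.frame(pathway = sprintf("path%02d", 1:5),
                                  group = "AD", delta = c(1, -1, 1, -1, 1)))
}
subtype_config <- function() {
  sim_config(effects = data.frame(
    pathway = rep(c("path01", "path02", "path03", "path04"), 2),
    group = rep(c("S1", "S2"), each = 4),
    delta = c(1.5, -1.5, 1.5, -1.5, -1.5, 1.5, -1.5, 1.5)))
}
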