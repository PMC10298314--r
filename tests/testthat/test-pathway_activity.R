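test_that("single-sample score matches hand-derived values and the oracle", {
  e <- setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  # frozen from the position-by-position oracle: 5/9 + 1 + 2/3 + 1/3 + 0
  expect_equal(ssgsea_sample(e, c("g1", "g2"), alpha = 1), 23 / 9, tolerance = 1e-12)
  # rank invariance: doubling expression changes nothing
  expect_equal(ssgsea_sample(2 * e, c("g1", "g2"), alpha = 1), 23 / 9, tolerance = 1e-12)
  # bottom-ranked set scores negative (oracle value -2.5 at alpha = 0)
  expect_equal(ssgsea_sample(e, c("g4", "g5"), alpha = 0), -2.5, tolerance = 1e-12)
  expect_lt(ssgsea_sample(e, c("g4", "g5"), alpha = 0), 0)

  expect_error(ssgsea_sample(e, c("x1", "x2"), 0.25), "no genes")
  expect_error(ssgsea_sample(e, paste0("g", 1:5), 0.25), "complement")
})

test_that("score equals the brute-force oracle on random instances", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(8:50, 1)
    genes <- paste0("g", seq_len(n))
    e <- setNames(rnorm(n), genes)
    alpha <- sample(c(0, 0.25, 1), 1)
    for (s in 1:3) {
      set_size <- sample(2:(n - 2), 1)
      gs <- sample(genes, set_size)
      expect_equal(ssgsea_sample(e, gs, alpha), oracle_ssgsea(e, gs, alpha),
                   tolerance = 1e-10)
    }
  }
})

test_that("score is rank-based: invariant under strictly increasing transforms", {
  set.seed(5)
  e <- setNames(rnorm(30), paste0("g", 1:30))
  gs <- paste0("g", c(2, 9, 17, 25))
  ref <- ssgsea_sample(e, gs, alpha = 0.25)
  expect_equal(ssgsea_sample(exp(e), gs, alpha = 0.25), ref, tolerance = 1e-12)
  expect_equal(ssgsea_sample(rank(e), gs, alpha = 0.25), ref, tolerance = 1e-12)
})

test_that("two-set partition scores have opposite signs at alpha = 0", {
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    genes <- paste0("g", seq_len(n))
    e <- setNames(rnorm(n), genes)
    u <- sample(genes, sample(2:(n - 2), 1))
    v <- setdiff(genes, u)
    su <- ssgsea_sample(e, u, alpha = 0)
    sv <- ssgsea_sample(e, v, alpha = 0)
    if (abs(su) > 1e-12) expect_lt(su * sv, 1e-12)
  }
})

test_that("matrix scoring honours shape, order, coverage and normalization", {
  set.seed(21)
  genes <- paste0("g", 1:40)
  vals <- matrix(rnorm(120), 40, 3, dimnames = list(genes, c("s1", "s2", "s3")))
  cat2 <- gene_set_catalog(c("pwA", "pwB"),
                           genes = list(genes[1:8], genes[30:40]))
  act <- ssgsea_matrix(vals, cat2, alpha = 0.25, normalize = FALSE)
  expect_equal(dim(act), c(2L, 3L))
  expect_identical(rownames(act), c("pwA", "pwB"))
  # matrix path equals the per-sample oracle
  for (j in 1:3) for (i in 1:2) {
    expect_equal(act[i, j], oracle_ssgsea(vals[, j], cat2$genes[[i]], 0.25),
                 tolerance = 1e-10)
  }
  # catalog order permutes rows, values unchanged
  act_rev <- ssgsea_matrix(vals, gene_set_catalog(c("pwB", "pwA"),
                           genes = list(genes[30:40], genes[1:8])),
                           alpha = 0.25, normalize = FALSE)
  expect_equal(act_rev[c("pwA", "pwB"), ], act[c("pwA", "pwB"), ])
  # normalization is one global positive factor; pairwise signs survive
  act_n <- ssgsea_matrix(vals, cat2, alpha = 0.25, normalize = TRUE)
  ratio <- act / act_n
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-9)
  expect_gt(ratio[1, 1], 0)
  expect_identical(sign(act[1, ] - act[2, ]), sign(act_n[1, ] - act_n[2, ]))
  # coverage: genes absent from the matrix are dropped, few genes -> error
  cat_missing <- gene_set_catalog("pwC", genes = list(c(genes[1:3], "absent")))
  expect_equal(unname(attr(ssgsea_matrix(vals, cat_missing), "coverage")), 3)
  cat_thin <- gene_set_catalog("pwD", genes = list(c(genes[1], "absent")))
  expect_error(ssgsea_matrix(vals, cat_thin), "pwD")
})
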