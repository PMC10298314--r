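test_that("pair construction follows catalog order with the tie-as-+1 rule", {
  act <- matrix(c(0.2, 0.5, 0.5), 3, 1,
                dimnames = list(c("p1", "p2", "p3"), "k1"))
  mpp <- build_mpp(act)
  expect_identical(mpp$pair_ids, c("p1-p2", "p1-p3", "p2-p3"))
  expect_equal(unname(mpp$delta[, 1]), c(-0.3, -0.3, 0))
  expect_equal(unname(mpp$indicator[, 1]), c(-1, -1, 1))  # tie -> +1

  expect_equal(nrow(build_mpp(toy_activity(m = 2))$delta), 1)
  expect_error(build_mpp(toy_activity(m = 1)), "at least 2")

  # choose(m, 2) rows; lexicographic in catalog indices
  a <- toy_activity(m = 6)
  mpp6 <- build_mpp(a)
  expect_length(mpp6$pair_ids, choose(6, 2))
  expect_identical(mpp6$pair_ids[1:5], paste0("pw01-", sprintf("pw%02d", 2:6)))
  # antisymmetry: reversing catalog order negates delta and (away from exact
  # ties) flips the indicator of the relabeled pair
  rev_mpp <- build_mpp(a[6:1, , drop = FALSE])
  expect_equal(unname(rev_mpp$delta["pw02-pw01", ]),
               unname(-mpp6$delta["pw01-pw02", ]), tolerance = 1e-12)
  nz <- mpp6$delta["pw01-pw02", ] != 0
  expect_equal(unname(rev_mpp$indicator["pw02-pw01", nz]),
               unname(-mpp6$indicator["pw01-pw02", nz]))
})

test_that("2x2 chi-square reproduces the printed cohort example and the oracle", {
  r <- chi_square_2x2(288, 200, 282, 205)
  expect_equal(round(r$p, 3), 0.725)
  expect_equal(r$chi2, oracle_chi2(288, 200, 282, 205), tolerance = 1e-10)
  expect_equal(round(r$chi2, 4), 0.1239)

  flat <- chi_square_2x2(10, 10, 10, 10)
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)

  # invariance to swapping rows / swapping both columns
  r2 <- chi_square_2x2(282, 205, 288, 200)
  expect_equal(r2$chi2, r$chi2, tolerance = 1e-12)
  r3 <- chi_square_2x2(200, 288, 205, 282)
  expect_equal(r3$chi2, r$chi2, tolerance = 1e-12)

  expect_error(chi_square_2x2(0, 0, 5, 5), "degenerate")
  expect_error(chi_square_2x2(3, 0, 5, 0), "degenerate")
  expect_error(chi_square_2x2(-1, 2, 3, 4), "nonnegative")
})

test_that("Holm adjustment matches hand-stepped values and its dominance bounds", {
  # hand computation: sorted p * (M - k + 1), running max, cap at 1
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(c(0.04, 0.01, 0.03)), c(0.06, 0.03, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.5, 0.9)), c(1, 1))
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(9)
  for (rep in 1:10) {
    p <- runif(sample(1:30, 1))
    adj <- holm_adjust(p)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
  }
})

test_that("the differential screen counts, tests, adjusts and skips correctly", {
  set.seed(4)
  act <- toy_activity(m = 5, n = 40, seed = 4)
  groups <- rep(c("non-AD", "AD"), each = 20)
  mpp <- build_mpp(act)
  scr <- differential_screen(mpp, groups, alpha_adj = 0.01, reference = "non-AD")
  expect_equal(nrow(scr), choose(5, 2))
  # count conservation
  expect_true(all(scr$a + scr$b == 20))
  expect_true(all(scr$c + scr$d == 20))
  # screen result matches chi_square_2x2 per pair
  for (i in which(!scr$skipped)) {
    ref <- chi_square_2x2(scr$a[i], scr$b[i], scr$c[i], scr$d[i])
    expect_equal(scr$chi2[i], ref$chi2, tolerance = 1e-10)
    expect_equal(scr$p[i], ref$p, tolerance = 1e-10)
  }
  expect_equal(scr$p_adj[!scr$skipped], holm_adjust(scr$p[!scr$skipped]))
  # invariant to sample column order
  perm <- sample(ncol(act))
  scr_p <- differential_screen(build_mpp(act[, perm]), groups[perm],
                               alpha_adj = 0.01, reference = "non-AD")
  expect_equal(scr_p[order(scr_p$pair_id), c("a", "b", "c", "d", "p")],
               scr[order(scr$pair_id), c("a", "b", "c", "d", "p")],
               ignore_attr = TRUE)
  expect_error(differential_screen(mpp, rep("AD", 40)), "two groups")
})

test_that("a constant ordering is skipped as degenerate, never flagged", {
  act <- toy_activity(m = 3, n = 30, seed = 2)
  act[1, ] <- act[2, ] + 5  # pw01 always above pw02
  mpp <- build_mpp(act)
  scr <- differential_screen(mpp, rep(c("non-AD", "AD"), 15), alpha_adj = 0.01)
  row <- scr[scr$pair_id == "pw01-pw02", ]
  expect_true(row$skipped)
  expect_false(row$flagged)
  expect_true(is.na(row$p_adj))
  # and the Holm family excludes it: M = number of non-skipped tests
  expect_equal(scr$p_adj[!scr$skipped], holm_adjust(scr$p[!scr$skipped]))
})

test_that("a strongly planted flipped pair is flagged on simulated data", {
  ds <- generate_dataset(flip_config(), seed = 1)
  act <- ssgsea_matrix(ds$expr, ds$catalog)
  scr <- differential_screen(build_mpp(act), ds$expr$metadata$group,
                             alpha_adj = 0.01, reference = "non-AD")
  expect_gt(length(ds$truth$truth_pairs), 0)
  expect_true(all(ds$truth$truth_pairs %in% scr$pair_id[scr$flagged]))
})
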