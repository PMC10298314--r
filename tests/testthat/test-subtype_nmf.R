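test_that("exp transform is positive, monotone and hits the closed forms", {
  ind <- matrix(c(-1, 1, 0, 1), 2)
  out <- exp_transform(ind)
  expect_equal(out, exp(ind))
  expect_true(all(out > 0))
  expect_equal(sort(unique(as.vector(exp_transform(matrix(c(-1, 1), 1))))),
               c(exp(-1), exp(1)))
  expect_equal(exp_transform(0), 1)
  expect_error(exp_transform(c(1, Inf)), "finite")
})

test_that("multiplicative KL updates drive a factorizable matrix to ~zero loss", {
  set.seed(12)
  W0 <- matrix(runif(40, 0.5, 2), 20, 2)
  H0 <- matrix(runif(30, 0.5, 2), 2, 15)
  V <- W0 %*% H0
  fit <- nmf_factorize(V, k = 2, seed = 1, max_iter = 3000, tol = 0)
  expect_lte(fit$trace[length(fit$trace)], 1e-6 * fit$trace[1])
  expect_true(all(fit$W > 0) && all(fit$H > 0))
  # reconstruction close in relative terms
  expect_lt(max(abs(fit$W %*% fit$H - V)) / max(V), 0.01)
})

test_that("the KL objective never increases and fits are seed-deterministic", {
  set.seed(3)
  V <- matrix(rexp(20 * 12) + 0.1, 20, 12)
  f1 <- nmf_factorize(V, k = 3, seed = 9, max_iter = 300)
  f2 <- nmf_factorize(V, k = 3, seed = 9, max_iter = 300)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)
  expect_true(all(diff(f1$trace) <= 1e-9))
  expect_false(identical(f1$W, nmf_factorize(V, k = 3, seed = 10, max_iter = 300)$W))
  expect_error(nmf_factorize(matrix(c(-1, 1, 1, 1), 2), k = 2), "exp_transform")
  expect_error(nmf_factorize(V, k = 1), "rank")
})

test_that("consensus metrics behave on a perfectly separable instance", {
  # two blocks of samples drawn from different archetypes
  set.seed(6)
  arch <- cbind(c(rep(5, 10), rep(0.2, 10)), c(rep(0.2, 10), rep(5, 10)))
  V <- cbind(arch[, rep(1, 8)], arch[, rep(2, 7)]) + matrix(runif(20 * 15, 0, 0.05), 20)
  colnames(V) <- sprintf("s%02d", 1:15)
  cc <- consensus_cluster(V, k_range = 2:3, nrun = 4, seed = 2, max_iter = 400)
  cons <- cc$results[["2"]]$consensus
  expect_true(isSymmetric(cons))
  expect_equal(unname(diag(cons)), rep(1, 15))
  expect_true(all(cons >= 0 & cons <= 1))
  # identical runs give a binary consensus with dispersion 1 and cophenetic 1
  expect_true(all(cons %in% c(0, 1)))
  expect_equal(cc$metrics$dispersion[cc$metrics$k == 2], 1)
  expect_equal(cc$metrics$cophenetic[cc$metrics$k == 2], 1, tolerance = 1e-9)
  # cluster 1 is the larger block
  asg <- cc$results[["2"]]$assignments
  expect_equal(unname(asg[1:8]), rep(1, 8))
  expect_equal(unname(asg[9:15]), rep(2, 7))
  # permutation equivariance of the consensus
  perm <- c(3, 1, 15, 7, 2, 10, 4, 12, 5, 9, 14, 6, 11, 8, 13)
  cc_p <- consensus_cluster(V[, perm], k_range = 2:3, nrun = 4, seed = 2,
                            max_iter = 400)
  expect_equal(cc_p$results[["2"]]$consensus,
               cons[perm, perm], tolerance = 1e-12)
  expect_error(consensus_cluster(V, k_range = 2:40, nrun = 3), "valid ranks")
})

test_that("rank selection follows cophenetic max with dispersion tie-breaks", {
  m <- data.frame(k = 2:4, cophenetic = c(0.99, 0.90, 0.85),
                  dispersion = c(0.9, 0.8, 0.7), silhouette = c(0.8, 0.7, 0.6))
  expect_equal(select_rank(m), 2)
  m$cophenetic <- c(0.9, 0.99, 0.99)
  m$dispersion <- c(0.9, 0.7, 0.8)
  expect_equal(select_rank(m), 4)  # tie on cophenetic, higher dispersion wins
  m$cophenetic <- rep(0.9, 3)
  m$dispersion <- rep(0.5, 3)
  m$silhouette <- rep(0.5, 3)
  expect_equal(select_rank(m), 2)  # all equal -> smallest k
})

test_that("planted subtypes are recovered with rank 2 and high agreement", {
  ds <- generate_dataset(subtype_config(), seed = 2)
  mpp <- build_mpp(ssgsea_matrix(ds$expr, ds$catalog))
  scr <- differential_screen(mpp, ds$expr$metadata$group, reference = "non-AD")
  cases <- ds$expr$metadata$sample[ds$expr$metadata$group == "AD"]
  st <- nmf_subtype(mpp, scr$pair_id[scr$flagged], cases, k_range = 2:4,
                    nrun = 6, seed = 2, max_iter = 500)
  expect_equal(st$k, 2)
  ari <- adjusted_rand_index(st$assignments[cases], ds$truth$subtype[cases])
  expect_gte(ari, 0.9)
  # consensus nearly binary: within-subtype ~1, across ~0
  cons <- st$results[["2"]]$consensus
  expect_gte(st$metrics$dispersion[st$metrics$k == 2], 0.9)
})
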