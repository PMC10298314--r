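test_that("generation is deterministic and respects the additive model", {
  cfg <- sim_config()
  a <- generate_dataset(cfg, seed = 7)
  b <- generate_dataset(cfg, seed = 7)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$expr$values, generate_dataset(cfg, seed = 8)$expr$values))

  # null model: no truth pairs, labels partition the samples
  expect_length(a$truth$truth_pairs, 0)
  expect_equal(sum(a$expr$metadata$group == "non-AD"), cfg$n_nonAD)
  expect_equal(as.integer(table(a$expr$metadata$subtype)[c("S1", "S2")]),
               c(cfg$n_S1, cfg$n_S2))

  # planted shift: group difference of pathway-gene means ~ delta (sd 0.1)
  cfg2 <- sim_config(sd = 0.1,
                     effects = data.frame(pathway = "path01", group = "AD", delta = 2))
  ds <- generate_dataset(cfg2, seed = 3)
  p1_genes <- ds$catalog$genes[[1]]
  ad <- ds$expr$metadata$group == "AD"
  diff <- mean(ds$expr$values[p1_genes, ad]) - mean(ds$expr$values[p1_genes, !ad])
  # Monte-Carlo s.e. of the group-mean difference at sd = 0.1 is ~0.002
  expect_equal(diff, 2, tolerance = 0.01)
  # background genes carry no shift
  bg <- setdiff(rownames(ds$expr$values), unlist(ds$catalog$genes))
  expect_lt(abs(mean(ds$expr$values[bg, ad]) - mean(ds$expr$values[bg, !ad])), 0.05)
})

test_that("least squares on the planted design recovers each delta", {
  cfg <- sim_config(sd = 0.1, n_nonAD = 60, n_S1 = 50, n_S2 = 50,
                    effects = data.frame(pathway = c("path01", "path02", "path03"),
                                         group = c("AD", "S1", "S2"),
                                         delta = c(1.2, -0.8, 0.6)))
  ds <- generate_dataset(cfg, seed = 5)
  stratum <- ifelse(ds$expr$metadata$group == "non-AD", "nonAD",
                    ds$expr$metadata$subtype)
  for (p in 1:3) {
    pg <- ds$catalog$genes[[p]]
    # per-sample pathway mean, centered per gene, regressed on the stratum design
    y <- colMeans(ds$expr$values[pg, ])
    fit <- lm(y ~ 0 + factor(stratum, levels = c("nonAD", "S1", "S2")))
    est <- coef(fit)[2:3] - coef(fit)[1]  # subtype minus control
    truth <- ds$truth$shifts[p, c("S1", "S2")]
    se <- summary(fit)$coefficients[2:3, 2] * sqrt(2)
    expect_true(all(abs(est - truth) < 3 * se),
                info = sprintf("pathway %d shift recovery", p))
  }
})

test_that("gene pool and effect-table validation reject bad configs", {
  expect_error(sim_config(n_S1 = 0), "n_S1")
  expect_error(sim_config(effects = data.frame(pathway = "p", group = "X", delta = 1)),
               "AD, S1, S2")
  bad <- sim_config(effects = data.frame(pathway = "nope", group = "AD", delta = 1))
  expect_error(generate_dataset(bad), "unknown pathway")
})

test_that("null screen calibration matches the nominal chi-square level", {
  cfg <- sim_config()
  cal <- null_screen_calibration(cfg, n_replicates = 20, alpha = 0.05,
                                 alpha_adj = 0.01, seed = 42)
  expect_gte(cal$fp_fraction, 0.01)
  expect_lte(cal$fp_fraction, 0.10)
  # Holm FWER at 0.01: allow ~0.01 + 3 Monte-Carlo s.e.
  expect_lte(cal$fwer, 0.01 + 3 * sqrt(0.01 * 0.99 / cal$n_replicates))
  expect_error(null_screen_calibration(flip_config(), n_replicates = 2),
               "null configuration")
  # alpha = 1 flags everything by construction
  expect_equal(null_screen_calibration(cfg, n_replicates = 2, alpha = 1,
                                       seed = 1)$fp_fraction, 1)
})
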