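test_that("the generator is deterministic in the seed", {
  cfg <- sim_config(n = 30, K = 40, beta = 0.5, seed = 42)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$table, d2$table)
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
  expect_identical(d1$y, d2$y)
  expect_identical(d1$A, d2$A)
})

test_that("tables are sparse compositions at the calibrated zero fraction", {
  zf <- vapply(1:8, function(s) {
    tab <- simulate_table(sim_config(seed = s))$table
    expect_equal(unname(rowSums(tab)), rep(1, 100), tolerance = 1e-8)
    mean(tab == 0)
  }, 0)
  expect_true(all(zf >= 0.6))
  expect_true(all(abs(zf - 0.7) < 0.05))
})

test_that("scenario fixes the link function and selection mode", {
  expect_equal(sim_config(scenario = "S1")$link, "identity")
  expect_equal(sim_config(scenario = "S2")$link, "identity")
  expect_equal(sim_config(scenario = "S3")$link, "cbrt")
  expect_equal(sim_config(scenario = "S4")$link, "sin")
  expect_error(sim_config(K = 10, n_clusters = 20, scenario = "S1"),
               "n_clusters")
  expect_error(sim_config(beta = -1), "nonnegative")
})

test_that("associated OTU selection follows the scenario's rule", {
  tt <- simulate_table(sim_config(n = 40, K = 60, seed = 3))
  # abundance-ranked: every member at least as abundant as every non-member
  set.seed(1)
  A2 <- select_associated_otus(tt$table, tt$tree, "S2", assoc_frac = 0.1)
  mu <- colMeans(tt$table)
  expect_gte(min(mu[A2]), max(mu[-A2]))
  expect_equal(length(A2), 6)

  # tree-based: clusters partition all OTUs; selection hits the target size
  pd <- as.dist(ape::cophenetic.phylo(tt$tree))
  cl <- cutree(hclust(pd, method = "average"), k = 20)
  expect_equal(length(cl), 60)
  expect_equal(sort(unique(cl)), 1:20)
  set.seed(2)
  A1 <- select_associated_otus(tt$table, tt$tree, "S1", assoc_frac = 0.1)
  expect_gte(length(A1), 6)
  # selected set is a union of whole clusters
  picked <- unique(cl[A1])
  expect_setequal(A1, which(cl %in% picked))
})

test_that("the standardized aggregate signal has mean zero and unit variance", {
  ds <- simulate_dataset(sim_config(n = 50, K = 60, beta = 1, seed = 4))
  expect_lt(abs(mean(ds$signal)), 1e-8)
  expect_equal(sd(ds$signal), 1, tolerance = 1e-8)
})

test_that("outcome models reproduce their linear predictors exactly", {
  cfg <- sim_config(n = 200, K = 30, scenario = "S3", beta = 1.3,
                    outcome = "binary", seed = 5)
  tt <- simulate_table(cfg)
  set.seed(6)
  A <- select_associated_otus(tt$table, tt$tree, "S3")
  signal <- scale(rowSums(tt$table[, A]))[, 1]
  set.seed(7)
  out <- simulate_outcome_binary(signal, cfg)
  # invert the logistic to recover the linear predictor, then isolate the
  # link term: must equal the real signed cube root of the signal
  eta <- log(out$p / (1 - out$p))
  link_term <- (eta - 0.5 * out$x1 - 0.5 * out$x2) / cfg$beta
  expect_equal(link_term, sign(signal) * abs(signal)^(1 / 3), tolerance = 1e-12)
  expect_true(all(out$y %in% c(0, 1)))

  # linear predictor zero gives probability one half
  cfg0 <- sim_config(n = 5, K = 10, scenario = "S2", beta = 0, seed = 8)
  set.seed(9)
  out0 <- simulate_outcome_binary(rep(0, 5), cfg0)
  p_at_zero <- 1 / (1 + exp(-(0.5 * out0$x1 + 0.5 * out0$x2)))
  expect_equal(out0$p, p_at_zero, tolerance = 1e-12)
})

test_that("continuous outcomes carry the scenario signal", {
  cfg <- sim_config(n = 3000, K = 30, scenario = "S1", beta = 2, seed = 10)
  set.seed(11)
  signal <- rnorm(3000)
  out <- simulate_outcome_continuous(signal, cfg)
  resid <- out$y - 0.5 * out$x1 - 0.5 * out$x2 - cfg$beta * signal
  # what remains is the standard normal noise
  expect_lt(abs(mean(resid)), 0.1)
  expect_equal(sd(resid), 1, tolerance = 0.06)

  # under correlated mode the confounder tracks the signal
  cfgc <- sim_config(n = 3000, K = 30, scenario = "S1", beta = 0,
                     covariate_mode = "correlated", seed = 12)
  set.seed(13)
  outc <- simulate_outcome_continuous(signal, cfgc)
  expect_equal(cor(outc$x2, signal), 0.5, tolerance = 0.08)
  expect_equal(sd(outc$x2), 1, tolerance = 0.06)
})

test_that("replicate runner returns per-replicate p-values and sane rates", {
  cfg <- sim_config(n = 30, K = 40, beta = 0, seed = 14)
  one <- replicate_study(cfg, n_reps = 1, distances = "bc", r = 1)
  expect_true(one$rejection_rate %in% c(0, 1))
  expect_equal(length(one$pvalues), 1)

  few <- replicate_study(cfg, n_reps = 5, distances = "bc", r = c(0.5, 1))
  expect_equal(length(few$pvalues), 5)
  expect_true(all(few$pvalues > 0 & few$pvalues < 1))
})

test_that("correlated confounders reduce power at equal effect size", {
  # directional check at desk scale, allowing one binomial standard error
  ind <- replicate_study(sim_config(n = 80, K = 150, scenario = "S2",
                                    beta = 1, covariate_mode = "independent",
                                    seed = 15), n_reps = 60)
  cor <- replicate_study(sim_config(n = 80, K = 150, scenario = "S2",
                                    beta = 1, covariate_mode = "correlated",
                                    seed = 15), n_reps = 60)
  se <- sqrt(ind$se^2 + cor$se^2)
  expect_lte(cor$rejection_rate, ind$rejection_rate + se)
})
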