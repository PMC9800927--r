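test_that("chains are reproducible given the seed", {
  p <- quick_panel(n = 60, m = 100, seed = 71)
  d <- build_designs(impute_mean(p$g))
  cfg <- mcmc_config(n_iter = 400, burn_in = 100, thin = 2, seed = 9,
                     pi_a = 0.9)
  f1 <- run_bayesB(p$y, d, cfg)
  f2 <- run_bayesB(p$y, d, cfg)
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$a, f2$a)
  # a different seed moves the chain
  f3 <- run_bayesB(p$y, d, mcmc_config(n_iter = 400, burn_in = 100,
                                       thin = 2, seed = 10, pi_a = 0.9))
  expect_false(identical(f1$chains$var_e, f3$chains$var_e))
})

test_that("null data at pi = 0.99 yields near-zero inclusion", {
  withr::with_seed(81, {
    cfg <- sim_config("custom", n_clones = 150, m_markers = 300, var_a = 1,
                      var_d = 0, var_e = 1, seed = 81)
    g <- simulate_genotypes(cfg)
    y <- rnorm(150)                       # pure noise, no marker signal
  })
  names(y) <- g$clone_ids
  d <- build_designs(g)
  fit <- run_bayesB(y, d, mcmc_config(n_iter = 2000, burn_in = 500,
                                      seed = 5, pi_a = 0.99))
  expect_lt(mean(fit$incl_a), 0.05)
})

test_that("large-effect markers are recovered by inclusion probability", {
  withr::with_seed(82, {
    cfg <- sim_config("custom", n_clones = 250, m_markers = 400, var_a = 1,
                      var_d = 0, var_e = 1, seed = 82)
    g <- simulate_genotypes(cfg)
    causal <- sample(400, 10)
    beta <- rep(0, 400)
    beta[causal] <- sample(c(-1, 1), 10, replace = TRUE)  # uniformly large
    d <- build_designs(g)
    gv <- as.vector(d$Z_add %*% beta)
    gv <- gv * sqrt(1 / var(gv))          # h2 = 0.5
    y <- setNames(gv + rnorm(250), g$clone_ids)
  })
  fit <- run_bayesB(y, d, mcmc_config(n_iter = 3000, burn_in = 1000,
                                      seed = 6, pi_a = 0.975))
  top <- order(-fit$incl_a)[1:10]
  expect_gte(length(intersect(top, causal)), 5)
})

test_that("Bayes C-pi estimates the exclusion probability", {
  cfg_mc <- mcmc_config(n_iter = 2000, burn_in = 500, seed = 7)
  # all-null: pi-hat near 1
  cfg <- sim_config("custom", n_clones = 300, m_markers = 150, var_a = 1,
                    var_d = 0, var_e = 1, seed = 83)
  g <- simulate_genotypes(cfg)
  withr::with_seed(83, y_null <- setNames(rnorm(300), g$clone_ids))
  d <- build_designs(g)
  fit_null <- run_bayesCpi(y_null, d, cfg_mc)
  expect_gt(fit_null$pi_hat_a, 0.9)
  # dense architecture, every marker causal with small effects: pi-hat low
  cfg2 <- sim_config("custom", n_clones = 150, m_markers = 200, var_a = 1,
                     var_d = 0, var_e = 1, seed = 84)
  g2 <- simulate_genotypes(cfg2)
  d2 <- build_designs(g2)
  withr::with_seed(84, {
    beta <- rnorm(200, 0, 1)
    gv <- as.vector(d2$Z_add %*% beta)
    gv <- gv * sqrt(4 / var(gv))          # strong polygenic signal
    y_dense <- setNames(gv + rnorm(150), g2$clone_ids)
  })
  fit_dense <- run_bayesCpi(y_dense, d2, cfg_mc)
  expect_lt(fit_dense$pi_hat_a, 0.5)
})

test_that("with pi = 0 posterior means approach SNP-BLUP solutions", {
  p <- quick_panel(n = 200, m = 500, var_a = 1, var_d = 0, var_e = 1,
                   seed = 85)
  d <- build_designs(p$g)
  fit <- run_bayesCpi(p$y, d, mcmc_config(n_iter = 4000, burn_in = 1000,
                                          thin = 5, seed = 8))
  # force full inclusion instead: Bayes B at pi = 0 with common-variance-free
  fitB <- run_bayesB(p$y, d, mcmc_config(n_iter = 4000, burn_in = 1000,
                                         thin = 5, seed = 8, pi_a = 0))
  G <- additive_G(d)
  ridge <- snp_blup_oracle(p$y, list(d$Z_add),
                           1 / G$scaling_constant, 1, seq_along(p$y))
  expect_gt(cor(unname(fitB$gebv), ridge), 0.98)
  expect_gt(cor(unname(fit$gebv), ridge), 0.95)
})

test_that("variance accounting: A-only model has var_g equal to var_a", {
  p <- quick_panel(n = 80, m = 120, seed = 86)
  d <- build_designs(p$g)
  fit <- run_bayesB(p$y, d, mcmc_config(n_iter = 500, burn_in = 100,
                                        seed = 3, pi_a = 0.5))
  expect_identical(fit$chains$var_a, fit$chains$var_g)
  expect_equal(fit$var_a, fit$var_g)
  h <- heritabilities(fit)
  expect_equal(h[["h2"]], h[["H2"]])
})

test_that("posterior mean of mu is near zero on centered null data", {
  withr::with_seed(87, {
    cfg <- sim_config("custom", n_clones = 200, m_markers = 100, var_a = 1,
                      var_d = 0, var_e = 1, seed = 87)
    g <- simulate_genotypes(cfg)
    y <- rnorm(200); y <- y - mean(y)
  })
  names(y) <- g$clone_ids
  fit <- run_bayesB(y, build_designs(g),
                    mcmc_config(n_iter = 1500, burn_in = 500, seed = 4,
                                pi_a = 0.9))
  expect_lt(abs(fit$mu), 3 / sqrt(200))
})

test_that("Raftery-Lewis dependence factor separates iid from sticky chains", {
  withr::with_seed(91, iid <- rnorm(5000))
  rl <- raftery_lewis(iid)
  expect_gt(rl$dependence_factor, 0.5)
  expect_lt(rl$dependence_factor, 2)
  withr::with_seed(92, {
    ar <- numeric(20000)
    for (i in 2:20000) ar[i] <- 0.95 * ar[i - 1] + rnorm(1)
  })
  expect_gt(raftery_lewis(ar)$dependence_factor, 5)
  expect_error(raftery_lewis(rep(1, 5000)), "constant")
  expect_error(raftery_lewis(rnorm(100)), "too short")
})
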