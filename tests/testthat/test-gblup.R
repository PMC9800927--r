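test_that("single identity kernel reproduces ridge shrinkage closed form", {
  withr::with_seed(4, y <- rnorm(20, mean = 5))
  names(y) <- paste0("c", 1:20)
  I_k <- diag(20); dimnames(I_k) <- list(names(y), names(y))
  fit <- fit_gblup(y, list(additive = I_k), fix_components = c(2, 1))
  shrink <- 2 / (2 + 1) * (y - mean(y))
  expect_equal(unname(fit$gebv), unname(shrink), tolerance = 1e-8)
  expect_equal(fit$mu, mean(y), tolerance = 1e-8)
})

test_that("G-BLUP equals SNP-BLUP on small instances (A and A+D)", {
  withr::with_seed(12, {
    dos <- matrix(sample(0:2, 32, replace = TRUE), 8, 4,
                  dimnames = list(paste0("c", 1:8), paste0("m", 1:4)))
    y <- rnorm(8, 3)
  })
  names(y) <- rownames(dos)
  g <- genotype_matrix(dos, orient_major = FALSE)
  d <- build_designs(g)
  G <- additive_G(d)
  Dc <- dominance_classical(d)
  cG <- G$scaling_constant
  cD <- Dc$scaling_constant
  var_a <- 1.3; var_d <- 0.7; var_e <- 0.9

  # additive model: GEBV == Z alpha-hat from the marker-effect MME
  fitA <- fit_gblup(y, list(additive = G), fix_components = c(var_a, var_e))
  oracleA <- snp_blup_oracle(y, list(d$Z_add), var_a / cG, var_e, 1:8)
  expect_lt(max(abs(unname(fitA$gebv) - oracleA)), 1e-6)

  # additive + dominance model: GEGV == Z alpha + H delta
  fitAD <- fit_gblup(y, list(additive = G, dominance = Dc),
                     fix_components = c(var_a, var_d, var_e))
  oracleAD <- snp_blup_oracle(y, list(d$Z_add, d$H_classical),
                              c(var_a / cG, var_d / cD), var_e, 1:8)
  expect_lt(max(abs(unname(fitAD$gegv) - oracleAD)), 1e-6)
})

test_that("REML recovers h2 = 0.5 in most simulation replicates", {
  # sd(h2-hat) ~ sqrt(2m)/n for an unrelated panel, so the marker count is
  # kept at 500 to make a +/-0.1 window a ~1.6 sd event per replicate
  hits <- 0
  for (s in 1:20) {
    p <- quick_panel(n = 500, m = 500, var_a = 1, var_d = 0, var_e = 1,
                     seed = 100 + s)
    G <- condition_psd(additive_G(build_designs(p$g)))
    fit <- fit_gblup(p$y, list(additive = G))
    h2 <- heritabilities(fit)[["h2"]]
    if (h2 >= 0.4 && h2 <= 0.6) hits <- hits + 1
  }
  expect_gte(hits, 16)   # >= 80% of runs
})

test_that("A+D fit on purely additive data keeps dominance variance small", {
  ratios <- vapply(1:6, function(s) {
    p <- quick_panel(n = 200, m = 600, var_a = 1, var_d = 0, var_e = 1,
                     seed = 200 + s)
    d <- build_designs(p$g)
    fit <- fit_gblup(p$y, list(additive = condition_psd(additive_G(d)),
                               dominance = condition_psd(
                                 dominance_classical(d))))
    fit$components[["dominance"]] / fit$var_g
  }, numeric(1))
  expect_lt(mean(ratios), 0.15)
})

test_that("heritability ratios are exact functions of the components", {
  h <- heritabilities(17.0, var_e = 32.0, var_g = 17.0)
  expect_equal(unname(h[["h2"]]), 17 / 49)
  expect_equal(heritabilities(0, var_e = 1)[["h2"]], 0)
  expect_error(heritabilities(0, var_e = 0), "undefined")
  # H2 >= h2 always, both in [0, 1]
  h2 <- heritabilities(1.2, var_d = 0.8, var_e = 3)
  expect_gte(h2[["H2"]], h2[["h2"]])
  expect_true(all(h2 >= 0 & h2 <= 1))
})

test_that("masked duplicate clones receive the observed copy's GEBV", {
  p <- quick_panel(n = 40, m = 120, seed = 31)
  dos <- rbind(p$g$dosages, dup = p$g$dosages[1, ])
  rownames(dos)[41] <- "dup_of_1"
  g <- genotype_matrix(dos, orient_major = FALSE)
  G <- condition_psd(additive_G(build_designs(g)))
  fit <- fit_gblup(p$y, list(additive = G))   # dup_of_1 unphenotyped
  pred <- predict_clones(fit)
  expect_equal(pred$gebv[pred$clone == "dup_of_1"],
               unname(fit$gebv[p$g$clone_ids[1]]), tolerance = 1e-6)
  expect_error(predict_clones(fit, "nonexistent"), "nonexistent")
})

test_that("zero genetic variance yields null predictions", {
  withr::with_seed(44, y <- rnorm(30))
  names(y) <- paste0("c", 1:30)
  K <- diag(30); dimnames(K) <- list(names(y), names(y))
  fit <- fit_gblup(y, list(additive = K), fix_components = c(1e-12, 1))
  expect_lt(max(abs(fit$gebv)), 1e-9)
})

test_that("predictions are invariant to a constant shift of the response", {
  p <- quick_panel(n = 60, m = 150, seed = 52)
  G <- condition_psd(additive_G(build_designs(p$g)))
  f1 <- fit_gblup(p$y, list(additive = G))
  f2 <- fit_gblup(p$y + 100, list(additive = G))
  expect_equal(f1$gebv, f2$gebv, tolerance = 1e-4)
  expect_equal(f2$mu - f1$mu, 100, tolerance = 1e-4)
})

test_that("RKHS is the same solver with a kernel label", {
  p <- quick_panel(n = 60, m = 150, seed = 53)
  K <- condition_psd(gaussian_kernel(p$g))
  fitK <- fit_gblup(p$y, list(genotypic = K))
  fitG <- fit_gblup(p$y, list(additive = K))
  expect_equal(unname(fitK$gegv), unname(fitG$gegv), tolerance = 1e-10)
  expect_null(fitK$gebv)
  expect_equal(heritabilities(fitK)[["h2"]], 0)  # no additive term labelled
})

test_that("restricted log-likelihood never decreases along the trace", {
  p <- quick_panel(n = 80, m = 200, var_a = 1, var_d = 0.5, var_e = 1,
                   seed = 61)
  d <- build_designs(p$g)
  fit <- fit_gblup(p$y, list(additive = condition_psd(additive_G(d)),
                             dominance = condition_psd(
                               dominance_classical(d))))
  expect_true(all(diff(fit$trace$loglik) >= -1e-6))
  expect_true(fit$converged)
})
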