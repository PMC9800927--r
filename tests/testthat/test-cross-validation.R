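test_that("cross-validation plans are balanced, seeded, and hashed", {
  ids <- paste0("c", 1:10)
  plan <- make_cv_plan(ids, n_folds = 5, n_reps = 3, seed = 1)
  sizes <- table(plan$fold[plan$rep == 1])
  expect_true(all(sizes == 2))
  # folds partition the clones within every rep
  for (r in 1:3)
    expect_setequal(plan$clone[plan$rep == r], ids)
  expect_identical(make_cv_plan(ids, seed = 1), plan)
  # different seeds give different plans (collision check over 100 seeds)
  hashes <- vapply(1:100, function(s)
    attr(make_cv_plan(paste0("c", 1:50), seed = s), "hash"), character(1))
  expect_equal(length(unique(hashes)), 100)
  # unbalanced n: fold sizes differ by at most 1
  p2 <- make_cv_plan(paste0("c", 1:23), n_folds = 5, n_reps = 1, seed = 2)
  expect_lte(diff(range(table(p2$fold))), 1)
})

test_that("fold statistics implement the predictive ability and bias", {
  withr::with_seed(14, b <- rnorm(40))
  # predictions identical to the validation BLUPs: r = 1, bias = 1
  st <- cv_stats(b, b, b, b)
  expect_equal(unname(st), c(1, 1))
  # halved training predictions double the dispersion bias
  st2 <- cv_stats(b, b, 0.5 * b, b)
  expect_equal(st2[["bias"]], 2)
  # r invariant to affine prediction rescale; bias scales inversely
  st3 <- cv_stats(3 * b + 2, b, 3 * b + 2, b)
  expect_equal(st3[["r"]], 1)
  expect_equal(st3[["bias"]], st[["bias"]] / 3)
  # degenerate predictions: NA bias with a warning
  expect_warning(st4 <- cv_stats(b, b, rep(1, 40), b), "zero")
  expect_true(is.na(st4[["bias"]]))
})

test_that("cv_evaluate produces one record per rep x fold with the plan hash", {
  p <- quick_panel(n = 80, m = 150, var_a = 1, var_d = 0.5, var_e = 1,
                   seed = 15)
  rec <- data.frame(clone = names(p$y), blup = p$y, dblup = p$y)
  dat <- cv_data(p$g, rec, mcmc = mcmc_config(n_iter = 300, burn_in = 100,
                                              seed = 2, pi_a = 0.9,
                                              pi_d = 0.9))
  plan <- make_cv_plan(names(p$y), n_folds = 5, n_reps = 3, seed = 3)
  res <- cv_evaluate("GBLUP_A", plan, dat)
  expect_s3_class(res, "cv_result")
  expect_equal(nrow(res), 15)
  expect_true(all(res$r >= -1 & res$r <= 1))
  expect_identical(attr(res, "plan_hash"), attr(plan, "hash"))
  # the same plan hash is shared by a second method's results
  res2 <- cv_evaluate("RKHS", plan, dat)
  expect_identical(attr(res2, "plan_hash"), attr(res, "plan_hash"))
  expect_error(cv_evaluate("not_a_method", plan, dat))
})

test_that("predictions track held-out signal and a null method does not", {
  p <- quick_panel(n = 150, m = 100, var_a = 3, var_d = 0, var_e = 1,
                   seed = 16)
  rec <- data.frame(clone = names(p$y), blup = p$y, dblup = p$y)
  dat <- cv_data(p$g, rec, mcmc = mcmc_config(n_iter = 300, burn_in = 100,
                                              seed = 2, pi_a = 0.9,
                                              pi_d = 0.9))
  plan <- make_cv_plan(names(p$y), seed = 4)
  res <- cv_evaluate("GBLUP_A", plan, dat)
  expect_gt(mean(res$r), 0.3)
  # null response: predictive ability hovers around zero
  withr::with_seed(17, y0 <- setNames(rnorm(150), names(p$y)))
  rec0 <- data.frame(clone = names(y0), blup = y0, dblup = y0)
  dat0 <- cv_data(p$g, rec0, mcmc = mcmc_config(n_iter = 300,
                                                burn_in = 100, seed = 2,
                                                pi_a = 0.9, pi_d = 0.9))
  res0 <- cv_evaluate("GBLUP_A", plan, dat0)
  expect_lt(abs(mean(res0$r)), 0.15)
})

make_fake_cv <- function(means, sd = 0.02, seed = 31) {
  withr::with_seed(seed, do.call(rbind, lapply(names(means), function(m) {
    cells <- expand.grid(rep = 1:3, fold = 1:5)
    data.frame(method = m, rep = cells$rep, fold = cells$fold,
               r = means[[m]] + rnorm(15, 0, sd),
               bias = 1 + rnorm(15, 0, sd))
  })))
}

test_that("method comparison separates shifted methods and not clones", {
  # identical distributions: non-significant, shared letter
  same <- make_fake_cv(c(A = 0.5, B = 0.5))
  cmp <- compare_methods(same)
  expect_gt(cmp$predictive_ability$p_value, 0.05)
  expect_equal(length(unique(cmp$predictive_ability$letters)), 1L)
  # one method shifted by +5 SD: significant with distinct letters
  apart <- make_fake_cv(c(A = 0.5, B = 0.6), sd = 0.02)
  cmp2 <- compare_methods(apart)
  expect_lt(cmp2$predictive_ability$p_value, 0.05)
  expect_equal(length(unique(cmp2$predictive_ability$letters)), 2L)
  # three methods, one shifted: only the shifted one is set apart
  three <- make_fake_cv(c(A = 0.5, B = 0.5, C = 0.65), sd = 0.02)
  cmp3 <- compare_methods(three)
  lt <- cmp3$predictive_ability$letters
  expect_identical(unname(lt["A"]), unname(lt["B"]))
  expect_false(lt["C"] %in% lt[c("A", "B")])
  expect_error(compare_methods(make_fake_cv(c(A = 0.5))), "2 methods")
})
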