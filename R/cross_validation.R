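#' Seeded k-fold cross-validation plan
#'
#' Balanced fold assignment (sizes differing by at most one) per repetition,
#' deterministic given the seed. The same plan object is served to every
#' prediction method so method comparisons share partitions; its hash is
#' stamped into every result.
#'
#' @param clone_ids character vector of clone ids.
#' @param n_folds folds per repetition (default 5).
#' @param n_reps repetitions (default 3).
#' @param seed RNG seed.
#' @return Data frame of class `cv_plan` (clone, rep, fold) with attributes
#'   `seed` and `hash`.
#' @export
make_cv_plan <- function(clone_ids, n_folds = 5, n_reps = 3, seed = 1L) {
  n <- length(clone_ids)
  stopifnot(n >= n_folds)
  plan <- with_seed(seed, do.call(rbind, lapply(seq_len(n_reps), function(r) {
    folds <- sample(rep_len(seq_len(n_folds), n))
    data.frame(clone = clone_ids, rep = r, fold = folds,
               stringsAsFactors = FALSE)
  })))
  rownames(plan) <- NULL
  attr(plan, "seed") <- seed
  attr(plan, "hash") <- rlang::hash(plan[c("clone", "rep", "fold")])
  class(plan) <- c("cv_plan", "data.frame")
  plan
}

#' Methods known to the cross-validation driver
#' @export
cv_methods <- function() c("GBLUP_A", "GBLUP_AD_classical",
                           "GBLUP_AD_genotypic", "RKHS",
                           "BayesB_A", "BayesB_AD")

#' Assemble shared inputs for cross-validation
#'
#' Builds marker designs and the four relationship matrices once, aligns the
#' stage-one records, and (when the MCMC config leaves `pi` unset) estimates
#' the Bayes B inclusion priors in-pipeline with Bayes C-pi on the full data.
#'
#' @param genotypes an imputed (or raw; imputed internally)
#'   [genotype_matrix()].
#' @param records stage-one output: data frame with `clone`, `blup` and
#'   `dblup` columns (see [deregress()]).
#' @param mcmc an [mcmc_config()] used by the Bayes methods.
#' @param kernel_h Gaussian-kernel bandwidth for RKHS.
#' @return List of class `cv_data`.
#' @export
cv_data <- function(genotypes, records, mcmc = mcmc_config(),
                    kernel_h = 1) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            all(c("clone", "blup", "dblup") %in% names(records)))
  g <- if (genotypes$imputed) genotypes else impute_mean(genotypes)
  common <- intersect(g$clone_ids, records$clone)
  if (length(common) < 10)
    stop("fewer than 10 clones shared between genotypes and records")
  keep <- match(common, g$clone_ids)
  g <- genotype_matrix(g$dosages[keep, , drop = FALSE],
                       orient_major = FALSE, imputed = TRUE)
  rec <- records[match(common, records$clone), , drop = FALSE]
  designs <- build_designs(g, center_additive = TRUE)
  kernels <- list(
    G = condition_psd(additive_G(designs)),
    D_classical = condition_psd(dominance_classical(designs)),
    D_genotypic = condition_psd(dominance_genotypic(designs)),
    K = condition_psd(gaussian_kernel(g, h = kernel_h)))
  y_d <- setNames(rec$dblup, rec$clone)
  if (is.na(mcmc$pi_a)) {
    cpi_a <- run_bayesCpi(y_d, designs, mcmc, with_dominance = FALSE)
    mcmc$pi_a <- cpi_a$pi_hat_a
  }
  if (is.na(mcmc$pi_d)) {
    cpi_ad <- run_bayesCpi(y_d, designs, mcmc, with_dominance = TRUE)
    mcmc$pi_d <- cpi_ad$pi_hat_d
  }
  structure(list(genotypes = g, designs = designs, kernels = kernels,
                 records = rec, y_d = y_d,
                 blup = setNames(rec$blup, rec$clone), mcmc = mcmc),
            class = "cv_data")
}

#' Fold-level prediction statistics
#'
#' Predictive ability `r = cor(pred_val, obs_val)` and dispersion bias
#' `b = cov(pred_train, obs_train) / var(pred_train)`; a bias of 1 means the
#' predictions are correctly dispersed, above 1 under-dispersed.
#'
#' @param pred_val,obs_val predictions and observed values on the held-out
#'   clones.
#' @param pred_train,obs_train same on the training clones.
#' @return Named vector `c(r = ..., bias = ...)`; bias is `NA` (with a
#'   warning) when the training predictions have zero variance.
#' @export
cv_stats <- function(pred_val, obs_val, pred_train, obs_train) {
  r_hat <- cor(pred_val, obs_val)
  b_hat <- if (var(pred_train) > 0)
    cov(pred_train, obs_train) / var(pred_train)
  else {
    warning("zero prediction variance; bias recorded as NA")
    NA_real_
  }
  c(r = r_hat, bias = b_hat)
}

# Fit one method on the training clones and return predictions for all
# clones (training fits carry their own training predictions).
.cv_fit_predict <- function(method, data, train_ids) {
  y_tr <- data$y_d[train_ids]
  kern <- switch(method,
    GBLUP_A = list(additive = data$kernels$G),
    GBLUP_AD_classical = list(additive = data$kernels$G,
                              dominance = data$kernels$D_classical),
    GBLUP_AD_genotypic = list(additive = data$kernels$G,
                              dominance = data$kernels$D_genotypic),
    RKHS = list(genotypic = data$kernels$K),
    NULL)
  if (!is.null(kern)) {
    fit <- fit_gblup(y_tr, kern)
    pred <- if (method == "GBLUP_A") fit$gebv else fit$gegv
    return(pred)   # named over all clones
  }
  with_dom <- method == "BayesB_AD"
  fit <- run_bayesB(y_tr, data$designs, data$mcmc, with_dominance = with_dom)
  # marker effects generalize to all clones through the designs
  all_ids <- data$designs$clone_ids
  ga <- as.vector(data$designs$Z_add %*% fit$a)
  gd <- if (with_dom) as.vector(data$designs$H_classical %*% fit$d) else 0
  pred <- if (with_dom) ga + gd else ga
  setNames(pred, all_ids)
}

#' Cross-validated predictive ability and bias for one method
#'
#' For every repetition and fold, the fold's clones are masked, the method is
#' trained on the remaining folds, and two statistics are computed:
#' predictive ability `r = cor(pred_val, BLUP_val)` against the stage-one
#' BLUPs of the held-out clones (or deregressed BLUPs if
#' `validate_against = "dblup"`), and dispersion bias
#' `b = cov(pred_train, BLUP_train) / var(pred_train)` on the training
#' partition. Predictions are GEBVs for additive models and GEGVs for
#' additive-dominant and RKHS models.
#'
#' @param method one of [cv_methods()].
#' @param plan a [make_cv_plan()].
#' @param data a [cv_data()].
#' @param validate_against `"blup"` (default) or `"dblup"`.
#' @param bias_on `"train"` (default, as defined) or `"validation"`.
#' @return Data frame of class `cv_result` (method, rep, fold, r, bias) with
#'   the plan hash as attribute `plan_hash`.
#' @export
cv_evaluate <- function(method, plan, data,
                        validate_against = c("blup", "dblup"),
                        bias_on = c("train", "validation")) {
  method <- match.arg(method, cv_methods())
  validate_against <- match.arg(validate_against)
  bias_on <- match.arg(bias_on)
  stopifnot(inherits(plan, "cv_plan"), inherits(data, "cv_data"))
  obs <- if (validate_against == "blup") data$blup else data$y_d
  plan <- plan[plan$clone %in% names(data$y_d), , drop = FALSE]
  out <- list()
  # Bayes chains per fold get fold-specific sub-seeds for independence
  fold_seed <- function(r, f) data$mcmc$seed + 1000L * r + f
  for (r in sort(unique(plan$rep))) {
    prep <- plan[plan$rep == r, ]
    for (f in sort(unique(prep$fold))) {
      val_ids <- prep$clone[prep$fold == f]
      train_ids <- prep$clone[prep$fold != f]
      d <- data
      d$mcmc$seed <- fold_seed(r, f)
      pred <- .cv_fit_predict(method, d, train_ids)
      bias_ids <- if (bias_on == "train") train_ids else val_ids
      st <- cv_stats(pred[val_ids], obs[val_ids],
                     pred[bias_ids], data$blup[bias_ids])
      out[[length(out) + 1]] <- data.frame(method = method, rep = r,
                                           fold = f, r = st[["r"]],
                                           bias = st[["bias"]],
                                           stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "plan_hash") <- attr(plan, "hash") %||%
    rlang::hash(plan[c("clone", "rep", "fold")])
  class(res) <- c("cv_result", "data.frame")
  res
}

#' Compare prediction methods across shared cross-validation cells
#'
#' Fits, for each statistic (predictive ability and bias), the mixed model
#' `value ~ method + (1 | rep:fold)` by maximum likelihood, tests the method
#' effect with a likelihood-ratio chi-square against the no-method model,
#' and groups method means with a Tukey all-pairs comparison rendered as a
#' compact letter display.
#'
#' @param results one or more `cv_result` data frames (rbind-ed); all must
#'   carry the same plan hash.
#' @param alpha family-wise level for the Tukey letters.
#' @return List of class `method_comparison` with one entry per statistic:
#'   `chisq`, `df`, `p_value`, `means` (per method), `letters`.
#' @export
compare_methods <- function(results, alpha = 0.05) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, results)
  if (length(unique(results$method)) < 2)
    stop("need at least 2 methods to compare")
  hashes <- attr(results, "plan_hash")
  results$cell <- interaction(results$rep, results$fold)
  results$method <- factor(results$method)
  one_stat <- function(col) {
    d <- results[!is.na(results[[col]]), ]
    d$.y <- d[[col]]
    full <- lme4::lmer(.y ~ method + (1 | cell), data = d, REML = FALSE,
                       control = lme4::lmerControl(check.conv.singular =
                           lme4::.makeCC("ignore", tol = 1e-4)))
    null <- lme4::lmer(.y ~ 1 + (1 | cell), data = d, REML = FALSE,
                       control = lme4::lmerControl(check.conv.singular =
                           lme4::.makeCC("ignore", tol = 1e-4)))
    lrt <- anova(null, full)
    gl <- multcomp::glht(full, linfct = multcomp::mcp(method = "Tukey"))
    letters <- multcomp::cld(gl, level = alpha)$mcletters$Letters
    means <- tapply(d$.y, d$method, mean)
    list(chisq = lrt$Chisq[2], df = lrt$Df[2],
         p_value = lrt$`Pr(>Chisq)`[2],
         significant = lrt$`Pr(>Chisq)`[2] <= alpha,
         means = means, letters = letters[names(means)])
  }
  structure(list(predictive_ability = one_stat("r"),
                 bias = one_stat("bias")),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  for (stat in names(x)) {
    s <- x[[stat]]
    cat(sprintf("%s: chisq(%d) = %.2f, p = %.4g%s\n", stat, s$df, s$chisq,
                s$p_value, if (s$significant) " *" else ""))
    tab <- data.frame(mean = round(s$means, 4),
                      group = toupper(s$letters))
    print(tab)
  }
  invisible(x)
}
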