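#' MCMC settings for the Bayesian marker-effect samplers
#'
#' Defaults follow common genomic-prediction practice for germplasm panels:
#' 20,000 iterations, 4,000 burn-in, thinning of 10. Effect-variance
#' hyperparameters use a scaled-inverse-chi-square with `df_eff` degrees of
#' freedom whose scale is solved at run time so the prior genetic variance
#' matches `r2_prior` of the phenotypic variance, split equally across effect
#' classes; the residual prior is centered on `(1 - r2_prior) * var(y)`.
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in discarded initial iterations (must be `< n_iter`).
#' @param thin thinning interval for stored samples.
#' @param seed RNG seed; every run with the same seed yields identical
#'   chains.
#' @param pi_a,pi_d prior exclusion probability per effect class for Bayes B
#'   (ignored by Bayes C-pi, which estimates them); `NA` means "use the
#'   in-pipeline Bayes C-pi estimate".
#' @param df_eff,df_res prior degrees of freedom for effect and residual
#'   variances.
#' @param r2_prior prior proportion of phenotypic variance attributed to
#'   markers when solving the prior scales.
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 20000, burn_in = 4000, thin = 10,
                        seed = 1L, pi_a = NA_real_, pi_d = NA_real_,
                        df_eff = 5, df_res = 5, r2_prior = 0.5) {
  stopifnot(burn_in < n_iter, thin >= 1,
            is.na(pi_a) || (pi_a >= 0 && pi_a < 1),
            is.na(pi_d) || (pi_d >= 0 && pi_d < 1))
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 pi_a = pi_a, pi_d = pi_d, df_eff = df_eff, df_res = df_res,
                 r2_prior = r2_prior),
            class = "mcmc_config")
}

# Solve the scaled-inv-chisq scale so the prior-mean per-marker effect
# variance yields `v_target` genetic variance given design column variances.
.solve_prior_scale <- function(v_target, X, pi, df) {
  col_var <- sum(apply(X, 2, var))
  if (col_var <= 0) col_var <- 1
  per_marker <- v_target / (max(1 - pi, 0.01) * col_var)
  per_marker * (df - 2) / df
}

.run_bayes <- function(y, designs, cfg, with_dominance, common_var) {
  stopifnot(inherits(designs, "marker_designs"), inherits(cfg, "mcmc_config"))
  ids <- names(y) %||% designs$clone_ids
  idx <- match(ids, designs$clone_ids)
  if (anyNA(idx)) stop("response clones missing from the marker designs")
  Z <- designs$Z_add[idx, , drop = FALSE]
  H <- if (with_dominance) designs$H_classical[idx, , drop = FALSE] else NULL
  vy <- var(y)
  n_classes <- 1 + with_dominance
  # Bayes C-pi treats pi as a parameter: the config value (default 0.9,
  # a sparse start) is only the chain's initial state
  pi_default <- if (common_var) 0.9 else 0.5
  pi_a <- if (is.na(cfg$pi_a)) pi_default else cfg$pi_a
  pi_d <- if (is.na(cfg$pi_d)) pi_default else cfg$pi_d
  # Bayes C-pi adapts the per-marker scale to the sampled pi, so its base
  # scale is solved at full inclusion; Bayes B bakes pi into the scale.
  scale_pi_a <- if (common_var) 0 else pi_a
  scale_pi_d <- if (common_var) 0 else pi_d
  scale_a <- .solve_prior_scale(cfg$r2_prior * vy / n_classes, Z, scale_pi_a,
                                cfg$df_eff)
  scale_d <- if (with_dominance)
    .solve_prior_scale(cfg$r2_prior * vy / n_classes, H, scale_pi_d,
                       cfg$df_eff)
  else 0
  scale_res <- (1 - cfg$r2_prior) * vy * (cfg$df_res - 2) / cfg$df_res
  raw <- with_seed(cfg$seed, .bayes_sampler_cpp(
    y = as.numeric(y), Z = Z, H_ = H,
    n_iter = cfg$n_iter, burn_in = cfg$burn_in, thin = cfg$thin,
    pi_a = pi_a, pi_d = pi_d, common_var = common_var,
    df_eff = cfg$df_eff, scale_a = scale_a, scale_d = scale_d,
    df_res = cfg$df_res, scale_res = scale_res))
  ga <- as.vector(Z %*% raw$a)
  gd <- if (with_dominance) as.vector(H %*% raw$d) else rep(0, length(y))
  chains <- data.frame(var_a = raw$chain_var_a, var_d = raw$chain_var_d,
                       var_g = raw$chain_var_g, var_e = raw$chain_var_e,
                       pi_a = raw$chain_pi_a, pi_d = raw$chain_pi_d,
                       mu = raw$chain_mu)
  structure(list(
    method = if (common_var) "BayesCpi" else "BayesB",
    with_dominance = with_dominance,
    mu = raw$mu,
    a = setNames(as.numeric(raw$a), colnames(Z)),
    d = if (with_dominance) setNames(as.numeric(raw$d), colnames(H)) else NULL,
    incl_a = as.numeric(raw$incl_a),
    incl_d = if (with_dominance) as.numeric(raw$incl_d) else NULL,
    gebv = setNames(ga, ids),
    gegv = setNames(ga + gd, ids),
    var_a = mean(chains$var_a), var_d = mean(chains$var_d),
    var_g = mean(chains$var_g), var_e = mean(chains$var_e),
    pi_hat_a = mean(chains$pi_a),
    pi_hat_d = if (with_dominance) mean(chains$pi_d) else NA_real_,
    chains = chains,
    n_samples = raw$n_samples,
    config = cfg,
    clone_ids = ids
  ), class = "bayes_fit")
}

#' Bayes B marker-effect model
#'
#' Gibbs sampler for additive (and optionally dominance) marker effects with
#' a point mass at zero (prior exclusion probability `pi` per class) and
#' per-marker scaled-inverse-chi-square effect variances. The additive class
#' uses the centered additive design; the dominance class uses the classical
#' dominance design. Genomic variances are reported as posterior means of the
#' per-iteration variance of the genetic values across clones.
#'
#' @param y named numeric vector of deregressed BLUPs.
#' @param designs a [build_designs()] result covering the response clones.
#' @param cfg an [mcmc_config()]; if `pi_a`/`pi_d` are `NA`, they are first
#'   estimated in-pipeline by [run_bayesCpi()] on the same data.
#' @param with_dominance include the dominance effect class.
#' @return Object of class `bayes_fit` with posterior means (`mu`, `a`, `d`),
#'   inclusion probabilities, GEBV/GEGV per clone, variance components
#'   (`var_a`, `var_d`, `var_g`, `var_e`), and thinned variance chains.
#' @export
run_bayesB <- function(y, designs, cfg = mcmc_config(),
                       with_dominance = FALSE) {
  if (is.na(cfg$pi_a) || (with_dominance && is.na(cfg$pi_d))) {
    cpi <- run_bayesCpi(y, designs, cfg, with_dominance = with_dominance)
    if (is.na(cfg$pi_a)) cfg$pi_a <- cpi$pi_hat_a
    if (with_dominance && is.na(cfg$pi_d)) cfg$pi_d <- cpi$pi_hat_d
  }
  .run_bayes(y, designs, cfg, with_dominance, common_var = FALSE)
}

#' Bayes C-pi marker-effect model
#'
#' As [run_bayesB()] but with a single effect variance per class and the
#' exclusion probability `pi` sampled from its Beta posterior (uniform
#' prior). The posterior mean `pi_hat` per class is exported for use as the
#' Bayes B prior.
#'
#' @inheritParams run_bayesB
#' @return A `bayes_fit` with `pi_hat_a` (and `pi_hat_d`).
#' @export
run_bayesCpi <- function(y, designs, cfg = mcmc_config(),
                         with_dominance = FALSE) {
  .run_bayes(y, designs, cfg, with_dominance, common_var = TRUE)
}

#' @export
print.bayes_fit <- function(x, ...) {
  cat(sprintf(paste0("bayes_fit [%s%s]: %d clones, %d stored samples\n",
                     "  var_a %.4g  var_d %.4g  var_g %.4g  var_e %.4g",
                     "  pi_a %.3f\n"),
              x$method, if (x$with_dominance) " A+D" else " A",
              length(x$clone_ids), x$n_samples,
              x$var_a, x$var_d, x$var_g, x$var_e, x$pi_hat_a))
  invisible(x)
}

#' @rdname heritabilities
#' @export
heritabilities.bayes_fit <- function(x, ...) {
  heritabilities.default(x$var_a, var_e = x$var_e, var_g = x$var_g)
}

#' Raftery-Lewis run-length diagnostic
#'
#' Two-state Markov-chain diagnostic on the dichotomized chain: how many
#' iterations and what burn-in are needed to estimate the `q` quantile to
#' within `+/- r` with probability `s`, and the dependence factor (required
#' iterations relative to an independent chain). Typically applied to the
#' residual-variance chain of the Gibbs sampler.
#'
#' @param chain numeric vector (or `mcmc` object) of posterior draws.
#' @param q quantile of interest (default 0.025).
#' @param r tolerated margin around the quantile (default 0.005).
#' @param s probability of attaining the margin (default 0.95).
#' @return List: `burn_in`, `n_required`, `n_min`, `dependence_factor`.
#' @export
raftery_lewis <- function(chain, q = 0.025, r = 0.005, s = 0.95) {
  chain <- as.numeric(chain)
  if (sd(chain) == 0)
    stop("constant chain: dichotomization is degenerate, diagnostic undefined")
  n_min <- ceiling(qnorm((1 + s) / 2)^2 * q * (1 - q) / r^2)
  if (length(chain) < n_min)
    stop("chain too short for (q, r, s): need at least ", n_min,
         " iterations, have ", length(chain))
  res <- coda::raftery.diag(coda::mcmc(chain), q = q, r = r, s = s)
  m <- res$resmatrix
  list(burn_in = as.numeric(m[1, "M"]),
       n_required = as.numeric(m[1, "N"]),
       n_min = as.numeric(m[1, "Nmin"]),
       dependence_factor = as.numeric(m[1, "I"]))
}
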