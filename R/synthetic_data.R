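#' Simulation configuration for a clonal germplasm panel
#'
#' Describes the study conditions emulated by the generator: a heterozygous
#' clonal panel of ~900 clones genotyped at thousands of SNPs and evaluated
#' in ~20 unbalanced location-year trials with replicate structure. Trait
#' profiles carry plot-level variance targets calibrated to additive-dominant
#' variance partitions typical of cassava root traits:
#'
#' * `FRY_like` (fresh root yield, t/ha): dominance-dominated,
#'   `var_a = 6.4`, `var_d = 11.5`, `var_e = 28.5` (h2 ~ 0.14, H2 ~ 0.39).
#' * `DRY_like` (dry root yield, t/ha): `var_a = 0.71`, `var_d = 0.78`,
#'   `var_e = 2.55` (h2 ~ 0.18, H2 ~ 0.37).
#' * `DMC_like` (dry matter content, %): additive-dominated,
#'   `var_a = 1.92`, `var_d = 0.18`, `var_e = 1.92` (h2 ~ 0.48, H2 ~ 0.52).
#'
#' @param profile trait architecture; `"custom"` requires explicit variances.
#' @param n_clones,m_markers panel dimensions.
#' @param var_a,var_d,var_e plot-level variance targets (profile defaults).
#' @param mu trait mean (profile default).
#' @param freq_range allele-frequency range for simulated markers.
#' @param inbreeding_F departure from Hardy-Weinberg heterozygosity
#'   (negative = excess heterozygosity, as in clonal panels); default 0.
#' @param n_location_years,reps_per_trial,trial_incidence,missing_plot_rate
#'   trial structure: number of location-year trials, replicates each, the
#'   probability a clone is planted in a given trial (unbalancedness), and
#'   the rate of lost plots.
#' @param var_trial,var_rep variances of the location-year shifts and
#'   rep-within-trial effects; default to `var_e` and `var_e / 4`.
#' @param seed root seed for the generator.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(profile = c("FRY_like", "DRY_like", "DMC_like",
                                   "custom"),
                       n_clones = 900, m_markers = 3000,
                       var_a = NULL, var_d = NULL, var_e = NULL, mu = NULL,
                       freq_range = c(0.05, 0.95), inbreeding_F = 0,
                       n_location_years = 20, reps_per_trial = 3,
                       trial_incidence = 0.3, missing_plot_rate = 0.05,
                       var_trial = NULL, var_rep = NULL, seed = 1L) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
    FRY_like = list(var_a = 6.4, var_d = 11.5, var_e = 28.5, mu = 20),
    DRY_like = list(var_a = 0.71, var_d = 0.78, var_e = 2.55, mu = 7),
    DMC_like = list(var_a = 1.92, var_d = 0.18, var_e = 1.92, mu = 32),
    custom = list(var_a = NULL, var_d = NULL, var_e = NULL, mu = 0))
  var_a <- var_a %||% defaults$var_a
  var_d <- var_d %||% defaults$var_d
  var_e <- var_e %||% defaults$var_e
  mu <- mu %||% defaults$mu
  if (is.null(var_a) || is.null(var_d) || is.null(var_e))
    stop("custom profile requires var_a, var_d and var_e")
  stopifnot(var_a >= 0, var_d >= 0, var_e >= 0,
            trial_incidence > 0, trial_incidence <= 1)
  structure(list(profile = profile, n_clones = n_clones,
                 m_markers = m_markers, var_a = var_a, var_d = var_d,
                 var_e = var_e, mu = mu, freq_range = freq_range,
                 inbreeding_F = inbreeding_F,
                 n_location_years = n_location_years,
                 reps_per_trial = reps_per_trial,
                 trial_incidence = trial_incidence,
                 missing_plot_rate = missing_plot_rate,
                 var_trial = var_trial %||% var_e,
                 var_rep = var_rep %||% (var_e / 4),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a genotyped clonal panel
#'
#' Draws per-marker allele frequencies uniformly from `freq_range` and
#' genotypes from (possibly inbreeding-perturbed) Hardy-Weinberg class
#' frequencies: `f(MM) = p^2 + F p q`, `f(Mm) = 2 p q (1 - F)`,
#' `f(mm) = q^2 + F p q`.
#'
#' @param cfg a [sim_config()].
#' @return A [genotype_matrix()] (not orientation-flipped, so simulated
#'   frequencies are traceable).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_clones; m <- cfg$m_markers; F <- cfg$inbreeding_F
    p <- runif(m, cfg$freq_range[1], cfg$freq_range[2])
    q <- 1 - p
    fMM <- pmax(p^2 + F * p * q, 0)
    fMm <- pmax(2 * p * q * (1 - F), 0)
    fmm <- pmax(q^2 + F * p * q, 0)
    tot <- fMM + fMm + fmm
    dos <- vapply(seq_len(m), function(j)
      sample(c(2, 1, 0), n, replace = TRUE,
             prob = c(fMM[j], fMm[j], fmm[j]) / tot[j]),
      numeric(n))
    dimnames(dos) <- list(sprintf("clone_%04d", seq_len(n)),
                          sprintf("m%05d", seq_len(m)))
    genotype_matrix(dos, orient_major = FALSE)
  })
}

#' Simulate additive and dominance genetic values
#'
#' Draws per-marker additive and dominance coefficients i.i.d. normal on the
#' centered additive and classical dominance designs (so the two variance
#' components are orthogonal under Hardy-Weinberg proportions) and rescales
#' each so the realized variance across clones hits the configured target
#' exactly.
#'
#' @param g a [genotype_matrix()] from [simulate_genotypes()].
#' @param cfg a [sim_config()].
#' @param dominance_scale `"classical"` (orthogonal; default) or
#'   `"genotypic"` (Su-scale) dominance design for effect simulation.
#' @return List of class `sim_truth`: `breeding` (true breeding values),
#'   `dominance` (true dominance deviations), `genotypic` (their sum), the
#'   marker coefficient vectors, and the realized variances.
#' @export
simulate_effects <- function(g, cfg, dominance_scale = c("classical",
                                                         "genotypic")) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(cfg, "sim_config"))
  dominance_scale <- match.arg(dominance_scale)
  designs <- build_designs(impute_mean(g), center_additive = TRUE)
  H <- if (dominance_scale == "classical") designs$H_classical
       else designs$H_genotypic
  with_seed(cfg$seed + 1L, {
    m <- ncol(designs$Z_add)
    alpha <- rnorm(m)
    a_val <- as.vector(designs$Z_add %*% alpha)
    if (cfg$var_a > 0 && var(a_val) > 0) {
      sc <- sqrt(cfg$var_a / var(a_val))
      alpha <- alpha * sc; a_val <- a_val * sc
    } else { alpha <- alpha * 0; a_val <- a_val * 0 }
    delta <- rnorm(m)
    d_val <- as.vector(H %*% delta)
    if (cfg$var_d > 0 && var(d_val) > 0) {
      sc <- sqrt(cfg$var_d / var(d_val))
      delta <- delta * sc; d_val <- d_val * sc
    } else { delta <- delta * 0; d_val <- d_val * 0 }
    ids <- g$clone_ids
    structure(list(breeding = setNames(a_val, ids),
                   dominance = setNames(d_val, ids),
                   genotypic = setNames(a_val + d_val, ids),
                   alpha = alpha, delta = delta,
                   realized_var_a = var(a_val), realized_var_d = var(d_val),
                   dominance_scale = dominance_scale),
              class = "sim_truth")
  })
}

#' Simulate an unbalanced multi-trial phenotype table
#'
#' Generates plot records `y = mu + trial + rep(trial) + g_clone + e` for a
#' random clone-trial incidence pattern (each clone planted in each trial
#' with probability `trial_incidence`, forced into at least one trial), then
#' drops plots at `missing_plot_rate`. For DMC-profile configurations the
#' air/water weights `WA`/`WW` are back-solved from each plot's DMC value so
#' [dmc_from_weights()] recovers it exactly.
#'
#' @param truth a [simulate_effects()] result (uses `genotypic` values).
#' @param cfg a [sim_config()].
#' @return Data frame (clone, location, year, rep, value, and `wa_kg` /
#'   `ww_kg` for DMC profiles) of class `trial_table`, with the trait column
#'   named after the profile.
#' @export
simulate_trials <- function(truth, cfg) {
  stopifnot(inherits(truth, "sim_truth"), inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 2L, {
    ids <- names(truth$genotypic)
    n <- length(ids)
    nt <- cfg$n_location_years
    locs <- rep(c("LocA", "LocB"), length.out = nt)
    years <- 2011 + (seq_len(nt) - 1) %/% 2
    beta <- rnorm(nt, 0, sqrt(cfg$var_trial))
    inc <- matrix(rbinom(n * nt, 1, cfg$trial_incidence), n, nt)
    none <- rowSums(inc) == 0
    if (any(none))
      inc[cbind(which(none), sample.int(nt, sum(none), replace = TRUE))] <- 1
    rows <- list()
    for (t in seq_len(nt)) {
      present <- which(inc[, t] == 1)
      if (length(present) == 0) next
      for (r in seq_len(cfg$reps_per_trial)) {
        rep_eff <- rnorm(1, 0, sqrt(cfg$var_rep))
        val <- cfg$mu + beta[t] + rep_eff + truth$genotypic[present] +
          rnorm(length(present), 0, sqrt(cfg$var_e))
        rows[[length(rows) + 1]] <- data.frame(
          clone = ids[present], location = locs[t], year = years[t],
          rep = r, value = val, stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    keep <- runif(nrow(tab)) >= cfg$missing_plot_rate
    tab <- tab[keep, , drop = FALSE]
    trait <- sub("_like$", "", cfg$profile)
    names(tab)[names(tab) == "value"] <- trait
    if (cfg$profile == "DMC_like") {
      # invert the gravimetric formula at WA = 5 kg
      dmc <- pmax(tab[[trait]], 17)     # keep weights physical
      tab[[trait]] <- dmc
      tab$wa_kg <- 5
      tab$ww_kg <- 5 * (1 - 158.3 / (dmc + 142))
    }
    class(tab) <- c("trial_table", "data.frame")
    tab
  })
}

#' One-call simulation of a full study panel
#'
#' @param cfg a [sim_config()].
#' @return List: `genotypes`, `truth`, `trials`, `trait` (column name),
#'   `config`.
#' @export
simulate_panel <- function(cfg) {
  g <- simulate_genotypes(cfg)
  truth <- simulate_effects(g, cfg)
  trials <- simulate_trials(truth, cfg)
  list(genotypes = g, truth = truth, trials = trials,
       trait = sub("_like$", "", cfg$profile), config = cfg)
}
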