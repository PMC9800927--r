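#' Pipeline run configuration
#'
#' Collects every setting of the end-to-end analysis: simulation (or input
#' paths), QC thresholds, methods, cross-validation, MCMC, and the selection
#' grids. All randomness flows from `seed`, expanded deterministically per
#' stage.
#'
#' @param profile synthetic trait profile (see [sim_config()]) when
#'   simulating; ignored if `genotype_path`/`phenotype_path` are given.
#' @param n_clones,m_markers simulated panel size.
#' @param genotype_path,phenotype_path optional real inputs (TSV/VCF, CSV).
#' @param trait trait column name; defaults to the profile's.
#' @param min_call_rate,min_maf QC thresholds.
#' @param methods prediction methods to cross-validate.
#' @param n_folds,n_reps cross-validation layout.
#' @param mcmc an [mcmc_config()].
#' @param grid a [selection_grid()].
#' @param seed root seed.
#' @return List of class `pipeline_config` with a content `hash`.
#' @export
pipeline_config <- function(profile = "FRY_like", n_clones = 200,
                            m_markers = 500, genotype_path = NULL,
                            phenotype_path = NULL, trait = NULL,
                            min_call_rate = 0.90, min_maf = 0.05,
                            methods = cv_methods(), n_folds = 5, n_reps = 3,
                            mcmc = mcmc_config(), grid = selection_grid(),
                            seed = 1L) {
  methods <- match.arg(methods, cv_methods(), several.ok = TRUE)
  cfg <- list(profile = profile, n_clones = n_clones, m_markers = m_markers,
              genotype_path = genotype_path, phenotype_path = phenotype_path,
              trait = trait %||% sub("_like$", "", profile),
              min_call_rate = min_call_rate, min_maf = min_maf,
              methods = methods, n_folds = n_folds, n_reps = n_reps,
              mcmc = mcmc, grid = grid, seed = as.integer(seed))
  cfg$hash <- rlang::hash(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

.stage_file <- function(outdir, name) file.path(outdir, name)

.require_artifact <- function(outdir, name, stage) {
  f <- .stage_file(outdir, name)
  if (!file.exists(f))
    stop("missing artifact '", name, "': run stage '", stage, "' first")
  f
}

.write_manifest <- function(outdir, stage, config, extra = list()) {
  man <- c(list(stage = stage, config_hash = config$hash,
                seed = config$seed, timestamp = as.character(Sys.time())),
           extra)
  jsonlite::write_json(man, .stage_file(outdir, paste0("manifest_", stage,
                                                       ".json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, reading each stage's inputs from
#' `outdir` and writing versioned outputs plus a per-stage manifest carrying
#' the config hash and seed. Stages: `simulate` (synthetic panel),
#' `stage1` (trial mixed model, BLUPs, deregression), `kinship`
#' (relationship matrices), `fit` (full-data model fits and heritabilities),
#' `cv` (cross-validated predictive ability/bias and method comparison),
#' `select` (selection differentials, efficiency, kappa), `report`
#' (aggregated summary tables).
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if absent).
#' @param stages subset of stages to run; each stage is individually
#'   re-runnable against existing artifacts.
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "stage1", "kinship", "fit",
                                    "cv", "select", "report")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  if ("simulate" %in% stages) {
    if (!is.null(config$genotype_path)) {
      file.copy(config$genotype_path, .stage_file(outdir, "genotypes.tsv"),
                overwrite = TRUE)
      file.copy(config$phenotype_path, .stage_file(outdir, "phenotypes.csv"),
                overwrite = TRUE)
      truth <- NULL
    } else {
      sim <- simulate_panel(sim_config(profile = config$profile,
                                       n_clones = config$n_clones,
                                       m_markers = config$m_markers,
                                       seed = config$seed))
      write_genotypes_tsv(sim$genotypes,
                          .stage_file(outdir, "genotypes.tsv"))
      write.table(sim$trials, .stage_file(outdir, "phenotypes.csv"),
                  sep = ",", quote = FALSE, row.names = FALSE)
      truth <- data.frame(clone = names(sim$truth$genotypic),
                          breeding = sim$truth$breeding,
                          dominance = sim$truth$dominance,
                          genotypic = sim$truth$genotypic)
      write.table(truth, .stage_file(outdir, "true_values.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      res$simulate <- sim
    }
    .write_manifest(outdir, "simulate", config)
  }

  if ("stage1" %in% stages) {
    f <- .require_artifact(outdir, "phenotypes.csv", "simulate")
    phe <- read.table(f, header = TRUE, sep = ",", stringsAsFactors = FALSE)
    s1 <- fit_stage1(phe, config$trait)
    rec <- deregress(s1)
    write.table(rec, .stage_file(outdir, "stage1_records.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(var_clone = s1$var_clone, var_rep = s1$var_rep,
           var_e = s1$var_e, H2_pheno = s1$H2_pheno),
      .stage_file(outdir, "stage1_components.json"),
      auto_unbox = TRUE, digits = NA)
    .write_manifest(outdir, "stage1", config,
                    list(n_records = s1$n_records, n_clones = nrow(rec)))
    res$stage1 <- s1
  }

  load_inputs <- function() {
    gf <- .require_artifact(outdir, "genotypes.tsv", "simulate")
    rf <- .require_artifact(outdir, "stage1_records.tsv", "stage1")
    g <- impute_mean(quality_filter(load_genotypes(gf),
                                    config$min_call_rate, config$min_maf))
    rec <- read.table(rf, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    list(g = g, rec = rec)
  }

  if ("kinship" %in% stages) {
    inp <- load_inputs()
    designs <- build_designs(inp$g)
    for (nm in c("additive_G", "dominance_classical", "dominance_genotypic"))
      write_relationship_tsv(get(nm)(designs),
                             .stage_file(outdir, paste0(nm, ".tsv")))
    write_relationship_tsv(gaussian_kernel(inp$g),
                           .stage_file(outdir, "gaussian_kernel.tsv"))
    .write_manifest(outdir, "kinship", config,
                    list(n_markers = ncol(inp$g$dosages)))
  }

  if (any(c("fit", "cv", "select") %in% stages)) {
    inp <- load_inputs()
    mc <- config$mcmc
    mc$seed <- config$seed + 10L
    cvd <- cv_data(inp$g, inp$rec, mcmc = mc)
  }

  if ("fit" %in% stages) {
    fits <- list(
      GBLUP_A = fit_gblup(cvd$y_d, list(additive = cvd$kernels$G)),
      GBLUP_AD_classical = fit_gblup(cvd$y_d,
        list(additive = cvd$kernels$G, dominance = cvd$kernels$D_classical)),
      RKHS = fit_gblup(cvd$y_d, list(genotypic = cvd$kernels$K)))
    h <- t(vapply(fits, heritabilities, numeric(2)))
    comp <- do.call(rbind, lapply(names(fits), function(nm) {
      f <- fits[[nm]]
      data.frame(method = nm,
                 var_a = if ("additive" %in% names(f$components))
                   f$components[["additive"]] else NA_real_,
                 var_g = f$var_g, var_e = f$components[["residual"]],
                 h2 = h[nm, "h2"], H2 = h[nm, "H2"])
    }))
    write.table(comp, .stage_file(outdir, "fit_components.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    .write_manifest(outdir, "fit", config)
    res$fit <- fits
  }

  if ("cv" %in% stages) {
    plan <- make_cv_plan(names(cvd$y_d), config$n_folds, config$n_reps,
                         seed = config$seed + 20L)
    cvres <- lapply(config$methods, cv_evaluate, plan = plan, data = cvd)
    all_res <- do.call(rbind, cvres)
    attr(all_res, "plan_hash") <- attr(plan, "hash")
    write.table(all_res, .stage_file(outdir, "cv_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (length(config$methods) >= 2) {
      cmp <- compare_methods(all_res)
      cmp_tab <- do.call(rbind, lapply(names(cmp), function(s)
        data.frame(statistic = s, method = names(cmp[[s]]$means),
                   mean = as.numeric(cmp[[s]]$means),
                   group = toupper(cmp[[s]]$letters),
                   p_value = cmp[[s]]$p_value)))
      write.table(cmp_tab, .stage_file(outdir, "method_comparison.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      res$comparison <- cmp
    }
    .write_manifest(outdir, "cv", config,
                    list(plan_hash = attr(plan, "hash")))
    res$cv <- all_res
  }

  if ("select" %in% stages) {
    f <- .require_artifact(outdir, "cv_results.tsv", "cv")
    preds <- lapply(setNames(config$methods, config$methods), function(m) {
      p <- .cv_fit_predict(m, cvd, names(cvd$y_d))
      p[names(cvd$y_d)]
    })
    rep_sel <- selection_report(preds, cvd$blup, config$grid)
    write.table(rep_sel$differentials,
                .stage_file(outdir, "selection_differentials.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(rep_sel$kappa, .stage_file(outdir, "selection_kappa.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    .write_manifest(outdir, "select", config)
    res$select <- rep_sel
  }

  if ("report" %in% stages) {
    parts <- c("stage1_components.json", "fit_components.tsv",
               "cv_results.tsv", "selection_differentials.tsv")
    missing <- parts[!file.exists(file.path(outdir, parts))]
    if (length(missing) > 0)
      stop("cannot build report; missing: ",
           paste(missing, collapse = ", "),
           " (run the corresponding stages first)")
    cvr <- read.table(.stage_file(outdir, "cv_results.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
    summary_tab <- aggregate(cbind(r, bias) ~ method, data = cvr, FUN = mean)
    write.table(summary_tab, .stage_file(outdir, "report_cv_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    .write_manifest(outdir, "report", config)
    res$report <- summary_tab
  }

  invisible(res)
}
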