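#' Dry matter content from specific-gravity weights
#'
#' Converts the air weight (`WA`) and underwater weight (`WW`) of a root
#' sample into dry matter content via the gravimetric calibration
#' `DMC(%) = (WA / (WA - WW)) * 158.3 - 142`. Values outside the plausible
#' trait amplitude (17-38%) are returned unclamped but flagged via a message.
#'
#' @param WA air weight of the sample (kg), must exceed `WW`.
#' @param WW weight of the same sample submerged in water (kg), `>= 0`.
#' @param warn_range plausible DMC range; values outside are logged as suspect.
#' @return DMC in percent (vectorized).
#' @export
dmc_from_weights <- function(WA, WW, warn_range = c(17, 38)) {
  if (any(WA <= 0)) stop("WA must be positive")
  if (any(WW < 0)) stop("WW must be non-negative")
  if (any(WA <= WW))
    stop("WA must exceed WW (submerged weight cannot reach air weight)")
  dmc <- (WA / (WA - WW)) * 158.3 - 142
  n_sus <- sum(dmc < warn_range[1] | dmc > warn_range[2])
  if (n_sus > 0)
    message(n_sus, " DMC value(s) outside the plausible range [",
            warn_range[1], ", ", warn_range[2], "]%; check weights")
  dmc
}

#' Dry root yield from fresh yield and dry matter content
#'
#' @param fry fresh root yield (t/ha), `>= 0`.
#' @param dmc dry matter content in percent, in (0, 100).
#' @return Dry root yield in t/ha: `fry * dmc / 100`.
#' @export
dry_from_fry_dmc <- function(fry, dmc) {
  if (any(fry < 0)) stop("FRY must be non-negative")
  if (any(dmc <= 0 | dmc >= 100)) stop("DMC must be in (0, 100) percent")
  fry * dmc / 100
}

#' Stage-one trial mixed model
#'
#' Fits, by REML, `y = mu + clone + loc.year + rep(loc.year) + e` across all
#' trials jointly: clone random, location-year combination fixed, replicate
#' nested in location-year random. Returns per-clone BLUPs and their
#' prediction error variances (PEV, from the conditional variances of the
#' random-effect solutions), variance components, and the phenotypic
#' broad-sense heritability `H2 = var_clone / (var_clone + var_e)`.
#'
#' Location-years carrying a single record leave the fixed design singular
#' and are dropped with a warning.
#'
#' @param trials data frame with columns `clone`, `location`, `year`, `rep`
#'   and the trait column named in `trait`.
#' @param trait name of the trait column to analyse.
#' @return Object of class `stage1_fit`: variance components (`var_clone`,
#'   `var_rep`, `var_e`), `fixed_effects` (per location-year), a `records`
#'   data frame (clone, blup, pev, reliability), `H2_pheno`, `trait`,
#'   and the underlying `lme4` fit.
#' @export
fit_stage1 <- function(trials, trait) {
  stopifnot(is.data.frame(trials),
            all(c("clone", "location", "year", "rep") %in% names(trials)),
            trait %in% names(trials))
  d <- trials[!is.na(trials[[trait]]), , drop = FALSE]
  d$loc_year <- interaction(d$location, d$year, drop = TRUE)
  if (nlevels(d$loc_year) < 2)
    stop("need at least 2 location-year trials for the joint model")
  singles <- names(which(table(d$loc_year) < 2))
  if (length(singles) > 0) {
    warning("dropping ", length(singles),
            " location-year(s) with a single record: ",
            paste(singles, collapse = ", "))
    d <- d[!(d$loc_year %in% singles), , drop = FALSE]
    d$loc_year <- droplevels(d$loc_year)
  }
  d$clone <- factor(d$clone)
  d$rep_in_trial <- interaction(d$loc_year, d$rep, drop = TRUE)
  d$.y <- d[[trait]]
  fit <- lme4::lmer(.y ~ 0 + loc_year + (1 | clone) + (1 | rep_in_trial),
                    data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular =
                                                  lme4::.makeCC("ignore", tol = 1e-4)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_clone <- vc$vcov[vc$grp == "clone"]
  var_rep <- vc$vcov[vc$grp == "rep_in_trial"]
  var_e <- vc$vcov[vc$grp == "Residual"]
  re <- lme4::ranef(fit, condVar = TRUE)
  blup <- re$clone[["(Intercept)"]]
  pev <- as.vector(attr(re$clone, "postVar"))
  records <- data.frame(clone = rownames(re$clone), blup = blup, pev = pev,
                        reliability = if (var_clone > 0) 1 - pev / var_clone
                                      else 0,
                        stringsAsFactors = FALSE)
  structure(list(
    var_clone = var_clone, var_rep = var_rep, var_e = var_e,
    fixed_effects = lme4::fixef(fit),
    records = records,
    H2_pheno = var_clone / (var_clone + var_e),
    trait = trait, n_records = nrow(d), model = fit
  ), class = "stage1_fit")
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat(sprintf(paste0("stage1_fit [%s]: %d clones, %d records\n",
                     "  var_clone %.4g  var_rep %.4g  var_e %.4g  H2 %.3f\n"),
              x$trait, nrow(x$records), x$n_records,
              x$var_clone, x$var_rep, x$var_e, x$H2_pheno))
  invisible(x)
}

#' Deregress stage-one BLUPs
#'
#' Removes BLUP shrinkage: `dblup = blup / (1 - PEV / var_clone)`, the
#' denominator being the clone's reliability. Clones whose reliability falls
#' below `reliability_floor` are excluded (near-zero reliabilities blow the
#' quotient up); the count is reported via a message.
#'
#' @param fit a [fit_stage1()] result.
#' @param reliability_floor minimum reliability retained (default 0.05).
#' @return Data frame (clone, blup, pev, reliability, dblup) for retained
#'   clones.
#' @export
deregress <- function(fit, reliability_floor = 0.05) {
  stopifnot(inherits(fit, "stage1_fit"))
  if (fit$var_clone <= 0)
    stop("clonal variance is zero; deregression undefined")
  rec <- fit$records
  keep <- rec$reliability >= reliability_floor
  if (!any(keep))
    stop("no clone reaches reliability ", reliability_floor,
         " (PEV ~ var_clone for all); cannot deregress")
  if (any(!keep))
    message(sum(!keep), " clone(s) below reliability floor ",
            reliability_floor, " excluded from deregression")
  rec <- rec[keep, , drop = FALSE]
  rec$dblup <- rec$blup / rec$reliability
  rownames(rec) <- NULL
  rec
}
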