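#' Selection differential for a ranked selection
#'
#' Mean merit of the top `ceiling(sp * n)` clones by `ranking_values`, minus
#' the overall mean merit. Phenotypic selection ranks by the merit itself
#' (stage-one BLUP); genomic selection ranks by GEBV/GEGV while merit stays
#' on the BLUP scale. Ties at the cut are broken by clone id for
#' determinism (and logged).
#'
#' @param ranking_values named numeric vector used to rank clones.
#' @param merit_values named numeric vector of merit (same clones).
#' @param sp selection proportion in (0, 1].
#' @return Selection differential in merit units.
#' @export
selection_differential <- function(ranking_values, merit_values, sp) {
  stopifnot(sp > 0, sp <= 1)
  ids <- names(ranking_values) %||% as.character(seq_along(ranking_values))
  if (!is.null(names(merit_values))) {
    if (!setequal(ids, names(merit_values)))
      stop("ranking and merit vectors cover different clones")
    merit_values <- merit_values[ids]
  }
  n <- length(ranking_values)
  k <- ceiling(sp * n)
  ord <- order(-ranking_values, ids)
  cut_val <- ranking_values[ord][k]
  if (k < n && sum(ranking_values == cut_val) > 1)
    message("tie at the selection cut broken by clone id")
  sel <- ord[seq_len(k)]
  mean(merit_values[sel]) - mean(merit_values)
}

#' Relative efficiency of genomic over phenotypic selection
#'
#' `efficiency = SD_GS / (SD_PS * ratio)` where `ratio` is the
#' genomic-to-conventional breeding-cycle length ratio (GB/PB): shortening
#' the cycle (ratio < 1) scales the per-time genomic response up.
#'
#' @param sd_gs genomic selection differential.
#' @param sd_ps phenotypic selection differential (non-zero).
#' @param ratio breeding-cycle length ratio in (0, 1].
#' @return Dimensionless efficiency (vectorized over any argument).
#' @export
efficiency <- function(sd_gs, sd_ps, ratio) {
  if (any(ratio <= 0)) stop("cycle-length ratio must be positive")
  if (any(sd_ps == 0)) stop("phenotypic selection differential is zero; ",
                            "efficiency undefined")
  sd_gs / (sd_ps * ratio)
}

#' Cohen's kappa for two binary selections
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement `p_e` from the marginal selection frequencies. Two
#' identical constant vectors agree perfectly (`kappa = 1`); two different
#' constant vectors have no chance-corrected agreement (`kappa = 0`, with a
#' warning).
#'
#' @param selected_a,selected_b binary (0/1 or logical) vectors of equal
#'   length.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(selected_a, selected_b) {
  a <- as.integer(as.logical(selected_a))
  b <- as.integer(as.logical(selected_b))
  stopifnot(length(a) == length(b), length(a) > 0)
  n <- length(a)
  p_o <- mean(a == b)
  pa1 <- mean(a); pb1 <- mean(b)
  p_e <- pa1 * pb1 + (1 - pa1) * (1 - pb1)
  if (pa1 %in% c(0, 1) && pb1 %in% c(0, 1)) {
    if (p_o == 1) return(1)       # identical constant selections
    warning("both selections constant but different; kappa set to 0")
    return(0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Selection grid defaults
#'
#' @param proportions selection proportions (default 5-30% by 5%).
#' @param ratios genomic/conventional breeding-cycle length ratios.
#' @return List of class `selection_grid`.
#' @export
selection_grid <- function(proportions = seq(0.05, 0.30, by = 0.05),
                           ratios = c(1.00, 0.80, 0.65, 0.60, 0.40, 0.20)) {
  stopifnot(all(proportions > 0 & proportions < 1),
            all(ratios > 0 & ratios <= 1))
  structure(list(proportions = proportions, ratios = ratios),
            class = "selection_grid")
}

#' Selection differentials, efficiencies and selection coincidence
#'
#' For each method's predictions and each selection proportion on the grid,
#' computes the genomic selection differential (ranking by prediction, merit
#' on the stage-one BLUP scale), the phenotypic differential (ranking by
#' BLUP), the efficiency over the breeding-cycle ratio grid, and Cohen's
#' kappa between every pair of selection rules (each method and phenotypic
#' BLUP selection) at each proportion.
#'
#' @param predictions named list of named numeric prediction vectors (one
#'   per method).
#' @param blup named numeric vector of stage-one BLUPs (the merit scale).
#' @param grid a [selection_grid()].
#' @return List of class `selection_report`: `differentials` (tidy data
#'   frame: method, sp, ratio, sd_gs, sd_ps, efficiency) and `kappa`
#'   (method_a, method_b, sp, kappa).
#' @export
selection_report <- function(predictions, blup, grid = selection_grid()) {
  stopifnot(is.list(predictions), length(predictions) >= 1,
            !is.null(names(blup)))
  rules <- c(predictions, list(BLUP_phenotypic = blup))
  rules <- lapply(rules, function(v) v[names(blup)])
  rows <- list(); krows <- list()
  n <- length(blup)
  for (sp in grid$proportions) {
    sd_ps <- selection_differential(blup, blup, sp)
    sel_sets <- lapply(rules, function(v) {
      k <- ceiling(sp * n)
      ord <- order(-v, names(blup))
      as.integer(seq_along(v) %in% ord[seq_len(k)])
    })
    for (m in names(predictions)) {
      sd_gs <- selection_differential(rules[[m]], blup, sp)
      for (ratio in grid$ratios)
        rows[[length(rows) + 1]] <- data.frame(
          method = m, sp = sp, ratio = ratio, sd_gs = sd_gs, sd_ps = sd_ps,
          efficiency = efficiency(sd_gs, sd_ps, ratio),
          stringsAsFactors = FALSE)
    }
    nm <- names(rules)
    for (i in seq_along(nm)) for (j in seq_along(nm)) if (i < j)
      krows[[length(krows) + 1]] <- data.frame(
        method_a = nm[i], method_b = nm[j], sp = sp,
        kappa = cohen_kappa(sel_sets[[i]], sel_sets[[j]]),
        stringsAsFactors = FALSE)
  }
  structure(list(differentials = do.call(rbind, rows),
                 kappa = do.call(rbind, krows)),
            class = "selection_report")
}
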