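#' G-BLUP / kernel mixed model by average-information REML
#'
#' Fits `y = 1*mu + sum_k u_k + e` with `u_k ~ N(0, K_k sigma2_k)` for one or
#' two genomic random terms (additive G; additive + dominance D; or a single
#' Gaussian kernel for RKHS) and `e ~ N(0, I sigma2_e)`. Variance components
#' are estimated by average-information (AI) REML with an EM fallback
#' whenever an AI step would leave the parameter space or reduce the
#' restricted likelihood; components are clamped at `1e-8`. One record per
#' clone is assumed, so the incidence of each random term is a selection of
#' kernel rows.
#'
#' Clones present in the kernels but absent from `y` are treated as
#' genotyped-unphenotyped: their effects are predicted from the covariance
#' structure (whole-matrix mixed-model-equations solve with masked records),
#' which is how cross-validation predictions are produced.
#'
#' @param y named numeric vector of responses (deregressed BLUPs), names are
#'   clone ids; every name must appear in every kernel.
#' @param kernels named list of `relationship_matrix` objects (or plain
#'   matrices with dimnames), all over the same clone set. Use names
#'   `additive`, `dominance`, or `genotypic` to label terms.
#' @param fix_components optional numeric vector
#'   `c(<one per kernel>, residual)`: skip REML and solve at these values.
#' @param max_iter,tol_comp,tol_loglik convergence controls: stop when the
#'   largest relative component change is below `tol_comp` or the restricted
#'   log-likelihood moves by less than `tol_loglik`.
#' @param verbose print the iteration trace.
#' @return Object of class `gblup_fit`: `components` (named, incl.
#'   `residual`), `var_g` (sum of genetic components), `mu`, `solutions`
#'   (matrix, all kernel clones x terms), `gebv` (additive solutions if an
#'   additive term exists), `gegv` (sum over genetic terms), `loglik`,
#'   `trace`, `converged`, `clone_ids`, `observed_ids`.
#' @export
fit_gblup <- function(y, kernels, fix_components = NULL,
                      max_iter = 500, tol_comp = 1e-6, tol_loglik = 1e-8,
                      verbose = FALSE) {
  stopifnot(length(kernels) >= 1, !is.null(names(y)))
  Ks <- lapply(kernels, function(k)
    if (inherits(k, "relationship_matrix")) k$values else as.matrix(k))
  if (is.null(names(Ks)) || any(!nzchar(names(Ks))))
    names(Ks) <- paste0("term", seq_along(Ks))
  all_ids <- rownames(Ks[[1]])
  for (K in Ks) {
    if (is.null(rownames(K))) stop("kernels must carry clone ids as dimnames")
    if (!identical(rownames(K), all_ids))
      stop("all kernels must cover the same clones in the same order")
  }
  missing_ids <- setdiff(names(y), all_ids)
  if (length(missing_ids) > 0)
    stop("clone(s) absent from the relationship matrices: ",
         paste(head(missing_ids, 5), collapse = ", "))
  obs <- match(names(y), all_ids)
  n <- length(y)
  if (n < 10 && is.null(fix_components))
    stop("need at least 10 phenotyped clones to estimate variance components")
  Ko <- lapply(Ks, function(K) K[obs, obs, drop = FALSE])
  nk <- length(Ko)
  X <- matrix(1, n, 1)

  # estimation runs on the unit-variance scale so the 1e-8 component clamp
  # and the convergence tolerances are scale-free; components are mapped
  # back by var(y) afterwards
  y_sc <- if (is.null(fix_components) && var(y) > 0) sqrt(var(y)) else 1
  yw <- y / y_sc

  reml_pieces <- function(theta) {
    V <- diag(theta[nk + 1], n)
    for (k in seq_len(nk)) V <- V + theta[k] * Ko[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    XtVX <- crossprod(X, Vinv %*% X)
    P <- Vinv - Vinv %*% X %*% solve(XtVX, crossprod(X, Vinv))
    Py <- P %*% yw
    ll <- -0.5 * (2 * sum(log(diag(ch))) + determinant(XtVX)$modulus[1] +
                    sum(yw * Py))
    list(P = P, Py = Py, loglik = as.numeric(ll))
  }

  theta0 <- rep(var(yw) / (nk + 1), nk + 1)
  names(theta0) <- c(names(Ko), "residual")

  if (!is.null(fix_components)) {
    stopifnot(length(fix_components) == nk + 1)
    theta <- setNames(as.numeric(fix_components), names(theta0))
    pieces <- reml_pieces(theta)
    if (is.null(pieces)) stop("supplied components give a singular V")
    trace <- data.frame(iter = 0, loglik = pieces$loglik)
    converged <- TRUE
  } else {
    theta <- theta0
    clamp <- 1e-8
    pieces <- reml_pieces(theta)
    if (is.null(pieces)) stop("could not initialize REML (singular V)")
    trace <- data.frame(iter = 0, loglik = pieces$loglik)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      P <- pieces$P; Py <- pieces$Py
      PV <- vector("list", nk + 1)
      for (k in seq_len(nk)) PV[[k]] <- P %*% Ko[[k]]
      PV[[nk + 1]] <- P
      score <- numeric(nk + 1)
      quad <- numeric(nk + 1)        # y' P V_k P y
      for (k in seq_len(nk + 1)) {
        Vk_Py <- if (k <= nk) Ko[[k]] %*% Py else Py
        quad[k] <- sum(Py * Vk_Py)
        score[k] <- -0.5 * (sum(diag(PV[[k]])) - quad[k])
      }
      AI <- matrix(0, nk + 1, nk + 1)
      for (i in seq_len(nk + 1)) {
        Vi_Py <- if (i <= nk) Ko[[i]] %*% Py else Py
        PVi_Py <- P %*% Vi_Py
        for (j in i:(nk + 1)) {
          Vj_Py <- if (j <= nk) Ko[[j]] %*% Py else Py
          AI[i, j] <- AI[j, i] <- 0.5 * sum(Vj_Py * PVi_Py)
        }
      }
      # components pinned at the boundary with an inward-pointing gradient
      # are held fixed; updating them keeps the AI system ill-conditioned
      free <- !(theta <= clamp * 2 & score < 0)
      if (!any(free)) { converged <- TRUE; break }
      step_ok <- FALSE
      prop <- theta
      step <- tryCatch(solve(AI[free, free, drop = FALSE], score[free]),
                       error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step))) {
        # full AI step, then halved steps if it overshoots the boundary
        for (frac in c(1, 0.5, 0.25, 0.1)) {
          prop[free] <- pmax(theta[free] + frac * step, clamp)
          cand <- reml_pieces(prop)
          if (!is.null(cand) && cand$loglik >= pieces$loglik - 1e-10) {
            step_ok <- TRUE
            break
          }
        }
      }
      if (!step_ok) {
        # multiplicative fixed-point step first (larger moves toward a
        # boundary), falling back to the additive EM step (guaranteed
        # uphill) if it does not improve the restricted likelihood
        tr_pv <- vapply(PV, function(m) sum(diag(m)), numeric(1))
        prop <- theta
        prop[free] <- pmax(theta[free] * quad[free] /
                             pmax(tr_pv[free], 1e-12), clamp)
        cand <- reml_pieces(prop)
        if (is.null(cand) || cand$loglik < pieces$loglik - 1e-10) {
          prop <- theta
          prop[free] <- pmax(theta[free] + theta[free]^2 / n *
                               (quad[free] - tr_pv[free]), clamp)
          cand <- reml_pieces(prop)
          if (is.null(cand)) stop("REML failed: singular V during EM step")
        }
      }
      dcomp <- max(abs(prop - theta) / pmax(abs(theta), 1e-6))
      dll <- abs(cand$loglik - pieces$loglik)
      theta <- setNames(prop, names(theta0))
      pieces <- cand
      trace <- rbind(trace, data.frame(iter = it, loglik = pieces$loglik))
      if (verbose)
        message(sprintf("iter %3d  loglik %.6f  %s", it, pieces$loglik,
                        paste(sprintf("%s=%.4g", names(theta), theta),
                              collapse = "  ")))
      if (dcomp < tol_comp || dll < tol_loglik) { converged <- TRUE; break }
    }
    if (!converged) {
      stop("AI-REML did not converge in ", max_iter, " iterations; ",
           "final components: ",
           paste(sprintf("%s=%.4g", names(theta), theta * y_sc^2),
                 collapse = ", "))
    }
    theta <- theta * y_sc^2
  }

  Py <- pieces$Py / y_sc
  # BLUE of mu and BLUPs of all kernel clones (incl. unphenotyped)
  V <- diag(theta[nk + 1], n)
  for (k in seq_len(nk)) V <- V + theta[k] * Ko[[k]]
  Vinv <- chol2inv(chol(V))
  XtVX <- crossprod(X, Vinv %*% X)
  mu <- as.numeric(solve(XtVX, crossprod(X, Vinv %*% y)))
  sol <- matrix(0, length(all_ids), nk,
                dimnames = list(all_ids, names(Ko)))
  for (k in seq_len(nk))
    sol[, k] <- theta[k] * (Ks[[k]][, obs, drop = FALSE] %*% Py)
  genetic <- setdiff(names(theta), "residual")
  gegv <- rowSums(sol)
  gebv <- if ("additive" %in% colnames(sol)) sol[, "additive"] else NULL
  structure(list(
    components = theta,
    var_g = sum(theta[genetic]),
    mu = mu,
    solutions = sol,
    gebv = gebv,
    gegv = gegv,
    loglik = pieces$loglik,
    trace = trace,
    converged = converged,
    clone_ids = all_ids,
    observed_ids = names(y),
    fixed = !is.null(fix_components)
  ), class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  h <- heritabilities(x)
  cat(sprintf(paste0("gblup_fit: %d clones (%d phenotyped), terms: %s\n",
                     "  components: %s\n  h2 = %.3f  H2 = %.3f  (loglik %.3f",
                     ", %d iter)\n"),
              length(x$clone_ids), length(x$observed_ids),
              paste(setdiff(names(x$components), "residual"), collapse = "+"),
              paste(sprintf("%s=%.4g", names(x$components), x$components),
                    collapse = "  "),
              h[["h2"]], h[["H2"]], x$loglik, max(x$trace$iter)))
  invisible(x)
}

#' Narrow- and broad-sense genomic heritability
#'
#' `h2 = var_a / (var_g + var_e)` and `H2 = var_g / (var_g + var_e)`, where
#' `var_g` is the total genomic variance (sum of genetic components, or the
#' kernel variance for RKHS). The default method takes the components
#' directly, which is how published variance-component tables are turned
#' into heritabilities.
#'
#' @param x a `gblup_fit`, `bayes_fit`, or (default method) the additive
#'   variance component.
#' @param ... passed between methods.
#' @return Named numeric vector `c(h2 = ..., H2 = ...)`.
#' @export
heritabilities <- function(x, ...) UseMethod("heritabilities")

#' @rdname heritabilities
#' @param var_g total genomic variance; defaults to `x + var_d`.
#' @param var_d dominance variance (default 0).
#' @param var_e residual variance.
#' @export
heritabilities.default <- function(x, var_e, var_d = 0, var_g = x + var_d,
                                   ...) {
  var_a <- x
  denom <- var_g + var_e
  if (denom <= 0) stop("heritability undefined: var_g + var_e is zero")
  c(h2 = var_a / denom, H2 = var_g / denom)
}

#' @rdname heritabilities
#' @export
heritabilities.gblup_fit <- function(x, ...) {
  var_e <- x$components[["residual"]]
  var_a <- if ("additive" %in% names(x$components))
    x$components[["additive"]] else 0
  heritabilities.default(var_a, var_e = var_e, var_g = x$var_g)
}

#' Predictions for genotyped, unphenotyped clones
#'
#' Extracts GEBV (additive solutions) and GEGV (summed genetic solutions)
#' for the requested clones from a fitted model whose kernels already cover
#' them.
#'
#' @param fit a `gblup_fit`.
#' @param target_clones clone ids; default: all kernel clones not phenotyped.
#' @return Data frame (clone, gebv or NA, gegv).
#' @export
predict_clones <- function(fit, target_clones = NULL) {
  stopifnot(inherits(fit, "gblup_fit"))
  if (is.null(target_clones))
    target_clones <- setdiff(fit$clone_ids, fit$observed_ids)
  absent <- setdiff(target_clones, fit$clone_ids)
  if (length(absent) > 0)
    stop("clone(s) not in the fitted relationship matrices: ",
         paste(head(absent, 5), collapse = ", "))
  idx <- match(target_clones, fit$clone_ids)
  data.frame(clone = target_clones,
             gebv = if (is.null(fit$gebv)) NA_real_ else fit$gebv[idx],
             gegv = fit$gegv[idx],
             stringsAsFactors = FALSE)
}
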