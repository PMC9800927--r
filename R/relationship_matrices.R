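#' Relationship matrix container
#'
#' Tags a symmetric clone-by-clone covariance structure with its kind and the
#' scaling constant (denominator) used to build it.
#'
#' @param values symmetric numeric matrix with clone ids as dimnames.
#' @param kind one of `"additive"`, `"dom_classical"`, `"dom_genotypic"`,
#'   `"gaussian_kernel"`.
#' @param scaling_constant the denominator (or kernel bandwidth context) used.
#' @param bending_applied whether a PSD-restoring diagonal shift was applied.
#' @return Object of class `relationship_matrix`.
#' @export
relationship_matrix <- function(values,
                                kind = c("additive", "dom_classical",
                                         "dom_genotypic", "gaussian_kernel"),
                                scaling_constant = NA_real_,
                                bending_applied = FALSE) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("relationship matrix must be square")
  if (max(abs(values - t(values))) > 1e-10)
    stop("relationship matrix not symmetric to 1e-10")
  values <- (values + t(values)) / 2
  structure(list(values = values, kind = kind,
                 clone_ids = rownames(values),
                 scaling_constant = scaling_constant,
                 bending_applied = bending_applied),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("relationship_matrix [%s]: %d clones, scaling %.6g%s\n",
              x$kind, nrow(x$values), x$scaling_constant,
              if (x$bending_applied) ", bent to PSD" else ""))
  invisible(x)
}

#' @export
dim.relationship_matrix <- function(x) dim(x$values)

#' Additive genomic relationship matrix (VanRaden)
#'
#' `G = Z Z' / (2 * sum(p_i (1 - p_i)))` from the additive marker design.
#' With the centered coding the expected diagonal is 1 under
#' Hardy-Weinberg proportions.
#'
#' @param designs a [build_designs()] result.
#' @param denominator override for the scaling constant.
#' @return A `relationship_matrix` of kind `"additive"`.
#' @export
additive_G <- function(designs, denominator = NULL) {
  stopifnot(inherits(designs, "marker_designs"))
  if (ncol(designs$Z_add) < 2) stop("need at least 2 markers")
  denom <- denominator %||% (2 * sum(designs$p * designs$q))
  if (denom <= 0) stop("zero or negative denominator for G")
  relationship_matrix(tcrossprod(designs$Z_add) / denom, "additive",
                      scaling_constant = denom)
}

#' Classical (breeding) dominance relationship matrix
#'
#' `D = H H' / sum((2 p_i q_i)^2)` with the classical dominance coding,
#' which keeps dominance deviations orthogonal to breeding values under
#' Hardy-Weinberg proportions (Vitezica-type parameterization).
#'
#' @inheritParams additive_G
#' @return A `relationship_matrix` of kind `"dom_classical"`.
#' @export
dominance_classical <- function(designs, denominator = NULL) {
  stopifnot(inherits(designs, "marker_designs"))
  denom <- denominator %||% sum((2 * designs$p * designs$q)^2)
  if (denom <= 0) stop("zero or negative denominator for D")
  relationship_matrix(tcrossprod(designs$H_classical) / denom,
                      "dom_classical", scaling_constant = denom)
}

#' Genotypic dominance relationship matrix
#'
#' `D* = H* H*' / sum(2 p_i q_i (1 - 2 p_i q_i))` with the genotypic
#' (Su-type) heterozygosity coding.
#'
#' @inheritParams additive_G
#' @return A `relationship_matrix` of kind `"dom_genotypic"`.
#' @export
dominance_genotypic <- function(designs, denominator = NULL) {
  stopifnot(inherits(designs, "marker_designs"))
  tpq <- 2 * designs$p * designs$q
  denom <- denominator %||% sum(tpq * (1 - tpq))
  if (denom <= 0) stop("zero or negative denominator for D*")
  relationship_matrix(tcrossprod(designs$H_genotypic) / denom,
                      "dom_genotypic", scaling_constant = denom)
}

#' Gaussian kernel over marker genotypes
#'
#' `K = exp(-h * D / median(D))` where `D` holds squared (default) or plain
#' Euclidean distances between clone rows of the -1/0/1 coded marker matrix
#' and the median is taken over off-diagonal entries.
#'
#' @param g an imputed [genotype_matrix()] or a [build_designs()] result.
#' @param h bandwidth reduction coefficient; default 1.
#' @param squared use squared Euclidean distances (default) or plain.
#' @return A `relationship_matrix` of kind `"gaussian_kernel"` with unit
#'   diagonal and entries in (0, 1].
#' @export
gaussian_kernel <- function(g, h = 1, squared = TRUE) {
  stopifnot(h > 0)
  M <- if (inherits(g, "genotype_matrix")) g$dosages - 1
       else if (inherits(g, "marker_designs")) {
         # uncentered -1/0/1 coding regardless of additive centering choice
         stop("pass the genotype_matrix, not designs, to gaussian_kernel")
       } else as.matrix(g)
  D <- as.matrix(dist(M))^if (squared) 2 else 1
  off <- D[lower.tri(D)]
  med <- median(off)
  if (!is.finite(med) || med <= 0)
    stop("all pairwise distances are zero; kernel undefined")
  K <- exp(-h * D / med)
  diag(K) <- 1
  relationship_matrix(K, "gaussian_kernel", scaling_constant = med)
}

#' Condition a relationship matrix to positive semidefiniteness
#'
#' If the smallest eigenvalue is below `-tol`, shifts the diagonal by
#' `|min eigenvalue| + epsilon` so the result is positive definite while the
#' off-diagonal structure is preserved.
#'
#' @param r a `relationship_matrix`.
#' @param epsilon diagonal inflation beyond the PSD boundary (default 1e-6);
#'   must be > 0 when the input is indefinite.
#' @param tol eigenvalue tolerance below which no action is taken.
#' @return The input, possibly diagonal-shifted, with `bending_applied` set.
#' @export
condition_psd <- function(r, epsilon = 1e-6, tol = 1e-8) {
  stopifnot(inherits(r, "relationship_matrix"))
  ev_min <- min(eigen(r$values, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min >= -tol) return(r)
  if (epsilon <= 0)
    stop("matrix is indefinite (min eigenvalue ", signif(ev_min, 4),
         "); epsilon > 0 required to bend it to PSD")
  out <- r
  diag(out$values) <- diag(out$values) + (-ev_min + epsilon)
  out$bending_applied <- TRUE
  out
}

#' Round-trip relationship matrices through TSV
#' @param r a `relationship_matrix`
#' @param path output path
#' @export
write_relationship_tsv <- function(r, path) {
  out <- data.frame(clone = r$clone_ids, r$values, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_relationship_tsv
#' @param kind matrix kind tag to restore
#' @export
read_relationship_tsv <- function(path, kind = "additive") {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  relationship_matrix(m, kind = kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
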