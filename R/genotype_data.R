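#' Genotype matrix container
#'
#' Bundles a clones-by-markers SNP dosage matrix with per-marker allele
#' frequencies. Dosages count copies of the major allele (0, 1, 2); missing
#' calls are `NA` internally. Markers are oriented so that the tracked allele
#' is the major one (`p >= 0.5`) unless `orient_major = FALSE`.
#'
#' @param dosages numeric matrix, clones in rows, markers in columns, values
#'   in `{0, 1, 2}` or `NA`; dimnames give clone and marker ids.
#' @param orient_major flip markers with frequency below 0.5 so the counted
#'   allele is always the major one.
#' @param imputed logical, whether missing dosages have been filled in
#'   (imputed dosages may be fractional).
#' @return An object of class `genotype_matrix`: list with `dosages`, `p`
#'   (major/counted allele frequency per marker), `q = 1 - p`, `clone_ids`,
#'   `marker_ids`, `imputed`, `oriented`.
#' @export
genotype_matrix <- function(dosages, orient_major = TRUE, imputed = FALSE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("clone_", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("m", seq_len(ncol(dosages)))
  if (anyDuplicated(rownames(dosages)))
    stop("duplicate clone ids in genotype matrix")
  if (anyDuplicated(colnames(dosages)))
    stop("duplicate marker ids in genotype matrix")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosages must lie in [0, 2]; found values outside (bad coding?)")
  p <- colMeans(dosages, na.rm = TRUE) / 2
  if (orient_major) {
    flip <- !is.na(p) & p < 0.5
    if (any(flip)) {
      dosages[, flip] <- 2 - dosages[, flip]
      p[flip] <- 1 - p[flip]
    }
  }
  structure(list(
    dosages = dosages,
    p = p, q = 1 - p,
    clone_ids = rownames(dosages),
    marker_ids = colnames(dosages),
    imputed = imputed,
    oriented = orient_major
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d clones x %d markers (%s, %s)\n",
              nrow(x$dosages), ncol(x$dosages),
              if (x$imputed) "imputed" else
                sprintf("%.2f%% missing", 100 * mean(is.na(x$dosages))),
              if (x$oriented) "major-allele oriented" else "as loaded"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Load SNP genotypes from a TSV or VCF file
#'
#' TSV dialect: header row of marker ids, first column the clone id, dosage
#' entries 0/1/2 with -1 (or NA) for missing. VCF: biallelic SNPs read from
#' the GT field; multiallelic records are dropped with a message; `./.` is
#' missing.
#'
#' @param path file path; format inferred from the extension unless `format`
#'   is given.
#' @param format `"tsv"`, `"vcf"`, or `"auto"`.
#' @param orient_major see [genotype_matrix()].
#' @return A [genotype_matrix()].
#' @export
load_genotypes <- function(path, format = c("auto", "tsv", "vcf"),
                           orient_major = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    biall <- vcfR::is.biallelic(vcf)
    if (any(!biall)) {
      message(sum(!biall), " non-biallelic record(s) skipped")
      vcf <- vcf[biall, ]
    }
    gt <- vcfR::extract.gt(vcf, element = "GT")
    dos <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
                  dimnames = list(colnames(gt), rownames(gt)))
    gtt <- t(gt)
    dos[grepl("^0[/|]0", gtt)] <- 0
    dos[grepl("^(0[/|]1|1[/|]0)", gtt)] <- 1
    dos[grepl("^1[/|]1", gtt)] <- 2
    g <- genotype_matrix(dos, orient_major = orient_major)
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(tab[[1]])
    if (anyDuplicated(ids)) stop("duplicate clone ids in ", path)
    dos <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(dos) <- "double"
    dos[dos == -1] <- NA_real_
    bad <- dos[!is.na(dos)]
    if (any(!(bad %in% c(0, 1, 2))))
      stop("TSV dosages must be 0/1/2 with -1 for missing; found ",
           paste(unique(bad[!(bad %in% c(0, 1, 2))]), collapse = ", "))
    rownames(dos) <- ids
    g <- genotype_matrix(dos, orient_major = orient_major)
  }
  g
}

#' Write a genotype matrix in the package TSV dialect
#' @param g a [genotype_matrix()]
#' @param path output path
#' @export
write_genotypes_tsv <- function(g, path) {
  dos <- g$dosages
  dos[is.na(dos)] <- -1
  out <- data.frame(clone = rownames(dos), dos, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Marker quality filtering
#'
#' Removes markers below a minimum call rate and at or below a minimum minor
#' allele frequency (strict `>` retention rule on MAF).
#'
#' @param g a [genotype_matrix()]
#' @param min_call_rate minimum fraction of non-missing calls (default 0.90).
#' @param min_maf minor allele frequency threshold; markers with
#'   `MAF <= min_maf` are removed (default 0.05).
#' @return Filtered [genotype_matrix()] with attribute `filter_report`
#'   (counts removed per criterion).
#' @export
quality_filter <- function(g, min_call_rate = 0.90, min_maf = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"),
            min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1)
  call_rate <- colMeans(!is.na(g$dosages))
  maf <- pmin(g$p, 1 - g$p)
  fail_cr <- call_rate < min_call_rate
  fail_maf <- !(maf > min_maf)          # strict ">" retention
  keep <- !(fail_cr | fail_maf)
  if (!any(keep))
    stop("quality_filter removed every marker (call rate >= ", min_call_rate,
         ", MAF > ", min_maf, ")")
  out <- genotype_matrix(g$dosages[, keep, drop = FALSE],
                         orient_major = g$oriented, imputed = g$imputed)
  attr(out, "filter_report") <- list(
    n_in = ncol(g$dosages), n_out = sum(keep),
    removed_call_rate = sum(fail_cr), removed_maf = sum(fail_maf),
    min_call_rate = min_call_rate, min_maf = min_maf)
  out
}

#' Mean-dosage imputation
#'
#' Replaces each missing dosage by `2 p_i`, the marker's mean dosage. The
#' result is flagged as imputed and may contain fractional dosages.
#'
#' @param g a [genotype_matrix()]
#' @return Imputed [genotype_matrix()] with no missing values.
#' @export
impute_mean <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  dos <- g$dosages
  if (anyNA(dos)) {
    miss <- which(is.na(dos), arr.ind = TRUE)
    dos[miss] <- (2 * g$p)[miss[, 2]]
  }
  genotype_matrix(dos, orient_major = FALSE, imputed = TRUE)
}

#' Marker design matrices for additive and dominance effects
#'
#' Builds the three marker codings used downstream: the additive design
#' (dosage - 1, i.e. -1/0/1, optionally column-centered), the classical
#' (breeding) dominance design with genotype codes
#' `MM -> -2q^2, Mm -> 2pq, mm -> -2p^2` (orthogonal to the additive design
#' under Hardy-Weinberg proportions), and the genotypic dominance design
#' `MM -> -2pq, Mm -> p^2+q^2, mm -> -2pq`. Fractional (imputed) dosages are
#' rounded to the nearest genotype class for the dominance designs only.
#'
#' @param g an imputed [genotype_matrix()] (no missing values).
#' @param center_additive subtract each additive column's mean (`2p - 1`),
#'   expressing breeding values as deviations; default `TRUE`.
#' @return List of class `marker_designs`: `Z_add`, `H_classical`,
#'   `H_genotypic` (all n x m), `p`, `q`, `coding_note`.
#' @export
build_designs <- function(g, center_additive = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(g$dosages))
    stop("build_designs requires an imputed genotype matrix (no NA)")
  p <- g$p; q <- g$q
  if (any(p <= 0 | p >= 1))
    stop("monomorphic marker(s) present (p in {0,1}); run quality_filter first")
  dos <- g$dosages
  n <- nrow(dos); m <- ncol(dos)
  Z <- dos - 1
  if (center_additive) Z <- sweep(Z, 2, 2 * p - 1)
  cls <- round(dos)                      # genotype class: 2=MM, 1=Mm, 0=mm
  Hc <- matrix(0, n, m, dimnames = dimnames(dos))
  Hg <- Hc
  for (k in 0:2) {
    idx <- cls == k
    hc_code <- switch(as.character(k),
                      "2" = -2 * q^2, "1" = 2 * p * q, "0" = -2 * p^2)
    hg_code <- switch(as.character(k),
                      "2" = -2 * p * q, "1" = p^2 + q^2, "0" = -2 * p * q)
    Hc[idx] <- matrix(hc_code, n, m, byrow = TRUE)[idx]
    Hg[idx] <- matrix(hg_code, n, m, byrow = TRUE)[idx]
  }
  structure(list(
    Z_add = Z, H_classical = Hc, H_genotypic = Hg, p = p, q = q,
    clone_ids = rownames(dos),
    coding_note = paste0(
      "additive: dosage-1", if (center_additive) " centered by 2p-1" else "",
      "; classical dominance: -2q^2/2pq/-2p^2; ",
      "genotypic dominance: -2pq/p^2+q^2/-2pq; ",
      "fractional dosages rounded to class for dominance designs")
  ), class = "marker_designs")
}
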