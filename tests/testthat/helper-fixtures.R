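# Shared fixtures and independent oracles, built in code at test time.

# Tiny dosage matrix with known frequencies.
tiny_genotypes <- function(dosages = rbind(c(0, 2), c(1, 1), c(2, 2)),
                           clone_ids = NULL, orient_major = TRUE) {
  if (is.null(clone_ids)) clone_ids <- paste0("c", seq_len(nrow(dosages)))
  rownames(dosages) <- clone_ids
  colnames(dosages) <- paste0("m", seq_len(ncol(dosages)))
  genotype_matrix(dosages, orient_major = orient_major)
}

# Write a dosage TSV in the package dialect and return the path.
write_tiny_tsv <- function(dosages, path = tempfile(fileext = ".tsv")) {
  rownames(dosages) <- rownames(dosages) %||%
    paste0("c", seq_len(nrow(dosages)))
  colnames(dosages) <- colnames(dosages) %||%
    paste0("m", seq_len(ncol(dosages)))
  df <- data.frame(clone = rownames(dosages), dosages, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal VCF text with the given ALT fields (comma = multiallelic).
write_tiny_vcf <- function(n_markers = 5, triallelic_at = integer(),
                           path = tempfile(fileext = ".vcf")) {
  samples <- c("c1", "c2", "c3")
  gts <- c("0/0", "0/1", "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(n_markers), function(i) {
    alt <- if (i %in% triallelic_at) "C,G" else "C"
    paste(c("1", i * 100, paste0("snp", i), "A", alt, ".", "PASS", ".",
            "GT", sample(gts, 3, replace = TRUE)), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# Independent SNP-BLUP (ridge) oracle: solve the marker-effect mixed model
# equations directly at fixed variance ratios and return fitted genetic
# values for all rows of the designs.
snp_blup_oracle <- function(y, designs_list, var_marker, var_e, obs_idx) {
  W <- do.call(cbind, lapply(seq_along(designs_list), function(k)
    designs_list[[k]][obs_idx, , drop = FALSE]))
  lambda <- unlist(lapply(seq_along(designs_list), function(k)
    rep(var_e / var_marker[k], ncol(designs_list[[k]]))))
  X <- matrix(1, length(y), 1)
  # MME: [X'X X'W; W'X W'W + diag(lambda)] [b; a] = [X'y; W'y]
  C <- rbind(cbind(crossprod(X), crossprod(X, W)),
             cbind(crossprod(W, X), crossprod(W) + diag(lambda)))
  rhs <- c(crossprod(X, y), crossprod(W, y))
  sol <- solve(C, rhs)
  eff <- sol[-1]
  Wall <- do.call(cbind, designs_list)
  as.vector(Wall %*% eff)
}

# Cohen's kappa recomputed from the 2x2 agreement table counts.
kappa_from_table <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  p_o <- (n11 + n00) / n
  p_e <- ((n11 + n10) * (n11 + n01) + (n01 + n00) * (n10 + n00)) / n^2
  if (p_e >= 1) return(if (p_o == 1) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

# Small phenotyped panel for engine tests: plot-free, direct clone values.
quick_panel <- function(n = 150, m = 300, var_a = 1, var_d = 0, var_e = 1,
                        seed = 1) {
  cfg <- sim_config("custom", n_clones = n, m_markers = m, var_a = var_a,
                    var_d = var_d, var_e = var_e, mu = 0, seed = seed)
  g <- simulate_genotypes(cfg)
  truth <- simulate_effects(g, cfg)
  y <- withr::with_seed(seed + 99,
                        truth$genotypic + rnorm(n, 0, sqrt(var_e)))
  names(y) <- g$clone_ids
  list(g = g, truth = truth, y = y, cfg = cfg)
}
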