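test_that("additive G matches hand computation and VanRaden scaling", {
  # two p = 0.5 markers, clone 1 homozygous MM at both:
  # centered Z row = (1, 1), denom = 2 * (0.25 + 0.25) = 1 -> diagonal 2
  dos <- rbind(c(2, 2), c(1, 1), c(0, 0), c(1, 1))
  g <- genotype_matrix(dos, orient_major = FALSE)
  G <- additive_G(build_designs(g))
  expect_equal(unname(G$values[1, 1]), 2)
  expect_equal(G$scaling_constant, 1)
  # duplicated clones: off-diagonal equals each one's diagonal
  expect_equal(G$values[2, 4], G$values[2, 2])
  expect_error(additive_G(build_designs(g), denominator = 0), "denominator")
})

test_that("mean diagonal of G is ~1 on a simulated HWE panel", {
  cfg <- sim_config("custom", n_clones = 2000, m_markers = 5000, var_a = 1,
                    var_d = 0, var_e = 1, seed = 5)
  g <- simulate_genotypes(cfg)
  d <- build_designs(g)
  G <- additive_G(d)
  expect_gt(mean(diag(G$values)), 0.95)
  expect_lt(mean(diag(G$values)), 1.05)
  D <- dominance_classical(d)
  expect_gt(mean(diag(D$values)), 0.9)
  expect_lt(mean(diag(D$values)), 1.1)
  # COV(a, d) = 0 surrogate: G and D are elementwise uncorrelated off-diagonal
  off <- upper.tri(G$values)
  expect_lt(abs(mean((G$values * D$values)[off])), 0.005)
})

test_that("classical dominance entries are (2pq)^2-scaled hand values", {
  dos <- cbind(c(1, 1, 1), c(1, 0, 2))   # marker 1 all het (p=0.5)
  g <- genotype_matrix(dos, orient_major = FALSE)
  d <- build_designs(g)
  D1 <- dominance_classical(d, denominator = (2 * 0.5 * 0.5)^2)
  # contribution of marker 1 alone: 0.5 * 0.5 / 0.25 = 1 for all pairs
  H1 <- d$H_classical[, 1, drop = FALSE]
  expect_equal(unname((tcrossprod(H1) / 0.25)[1, 2]), 1)
  # identical clones give identical rows
  dos2 <- rbind(c(1, 2), c(1, 2), c(0, 1))
  g2 <- genotype_matrix(dos2, orient_major = FALSE)
  D2 <- dominance_classical(build_designs(g2))
  expect_equal(D2$values[1, ], D2$values[2, ])
})

test_that("genotypic and classical dominance coincide when all p = 0.5", {
  withr::with_seed(2, {
    dos <- matrix(sample(0:2, 80, replace = TRUE), 10, 8)
  })
  g <- genotype_matrix(dos, orient_major = FALSE)
  g$p[] <- 0.5; g$q[] <- 0.5           # force exact p = 0.5 codings
  d <- build_designs(g)
  Dc <- dominance_classical(d)
  Dg <- dominance_genotypic(d)
  expect_equal(Dc$values, Dg$values, tolerance = 1e-12)
})

test_that("single-marker genotypic dominance diagonal is 1 for a het clone", {
  # heterozygote code p^2+q^2 = 0.5 at p = 0.5; denominator 2pq(1-2pq) = 0.25
  dos <- cbind(c(1, 0, 2, 1))
  g <- genotype_matrix(dos, orient_major = FALSE)
  d <- build_designs(g)
  Dg <- dominance_genotypic(d)
  expect_equal(unname(Dg$values[1, 1]), 0.5^2 / 0.25)
})

test_that("gaussian kernel has unit diagonal, exp(-1) at the median", {
  withr::with_seed(7, {
    dos <- matrix(sample(0:2, 120, replace = TRUE), 12, 10)
  })
  dos[2, ] <- dos[1, ]                  # identical pair
  g <- genotype_matrix(dos, orient_major = FALSE)
  K <- gaussian_kernel(g, h = 1)
  expect_equal(unname(K$values[1, 2]), 1)
  expect_true(all(diag(K$values) == 1))
  expect_true(all(K$values > 0 & K$values <= 1))
  # an off-diagonal pair exactly at the median distance maps to exp(-1)
  Dsq <- as.matrix(dist(dos - 1))^2
  med <- median(Dsq[lower.tri(Dsq)])
  at_med <- which(Dsq == med & upper.tri(Dsq), arr.ind = TRUE)
  if (nrow(at_med) > 0)
    expect_equal(unname(K$values[at_med[1, 1], at_med[1, 2]]), exp(-1))
  # h -> 0 limit: all entries -> 1
  K0 <- gaussian_kernel(g, h = 1e-12)
  expect_true(all(abs(K0$values - 1) < 1e-9))
  # degenerate: all clones identical
  allsame <- genotype_matrix(matrix(1, 5, 4), orient_major = FALSE)
  expect_error(gaussian_kernel(allsame), "zero")
})

test_that("condition_psd bends only indefinite matrices", {
  ids <- paste0("c", 1:4)
  m <- diag(4); dimnames(m) <- list(ids, ids)
  r <- relationship_matrix(m, "additive")
  expect_false(condition_psd(r)$bending_applied)
  # duplicated clones -> rank deficient, min eigenvalue 0: no bending needed
  dup <- tcrossprod(rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)))
  dimnames(dup) <- list(ids, ids)
  rd <- condition_psd(relationship_matrix(dup, "additive"))
  ev <- eigen(rd$values, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  # indefinite input is shifted to PSD; epsilon = 0 refuses
  ind <- m; ind[1, 2] <- ind[2, 1] <- 2
  ri <- relationship_matrix(ind, "additive")
  bent <- condition_psd(ri)
  expect_true(bent$bending_applied)
  expect_gte(min(eigen(bent$values, only.values = TRUE)$values), -1e-8)
  expect_error(condition_psd(ri, epsilon = 0), "epsilon")
})

test_that("constructors commute with clone reordering and marker shuffles", {
  withr::with_seed(9, {
    dos <- matrix(sample(0:2, 200, replace = TRUE), 20, 10,
                  dimnames = list(paste0("c", 1:20), paste0("m", 1:10)))
    perm <- sample(20)
    mperm <- sample(10)
  })
  g <- genotype_matrix(dos, orient_major = FALSE)
  gp <- genotype_matrix(dos[perm, ], orient_major = FALSE)
  gm <- genotype_matrix(dos[, mperm], orient_major = FALSE)
  for (ctor in list(function(x) additive_G(build_designs(x)),
                    function(x) dominance_classical(build_designs(x)),
                    function(x) dominance_genotypic(build_designs(x)),
                    gaussian_kernel)) {
    A <- ctor(g)$values
    expect_equal(ctor(gp)$values, A[perm, perm], tolerance = 1e-12)
    expect_equal(ctor(gm)$values, A, tolerance = 1e-12)
  }
  # allele-orientation flips leave centered G unchanged
  flipped <- dos
  flipped[, 1:5] <- 2 - flipped[, 1:5]
  gf <- genotype_matrix(flipped, orient_major = FALSE)
  expect_equal(additive_G(build_designs(gf))$values,
               additive_G(build_designs(g))$values, tolerance = 1e-12)
})

test_that("relationship matrices round-trip through TSV", {
  g <- tiny_genotypes(rbind(c(0, 1, 2), c(1, 1, 0), c(2, 0, 1),
                            c(1, 2, 1)))
  G <- additive_G(build_designs(impute_mean(g)))
  path <- tempfile(fileext = ".tsv")
  write_relationship_tsv(G, path)
  G2 <- read_relationship_tsv(path, kind = "additive")
  expect_equal(G2$values, G$values, tolerance = 1e-12)
  expect_equal(G2$clone_ids, G$clone_ids)
})
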