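test_that("the VanRaden matrix reproduces the hand-worked two-sample case", {
  g <- toy_geno(rbind(c(0L, 2L), c(2L, 0L)))
  G <- vanraden_grm(g)
  # p = (0.5, 0.5), Z = [[-1,1],[1,-1]], denom = 2 * (0.25 + 0.25) = 1
  expect_equal(unname(G$values), rbind(c(2, -2), c(-2, 2)), tolerance = 1e-12)
  expect_equal(G$n_markers, 2L)
})

test_that("a single fully heterozygous sample yields a zero matrix", {
  g <- toy_geno(matrix(c(1L, 1L, 1L), 1, 3))
  G <- vanraden_grm(g)
  expect_equal(unname(G$values), matrix(0, 1, 1))
})

test_that("the mean GRM diagonal is near one for an equilibrium population", {
  cfg <- sim_config(n_samples = 500, n_markers = 5000, n_chromosomes = 26,
                    seed = 61)
  g <- simulate_genotypes(cfg)
  G <- vanraden_grm(g)
  expect_equal(mean(diag(G$values)), 1, tolerance = 0.05)
})

test_that("the fused computation equals the textbook two-pass oracle", {
  pop <- sim_pop(n = 30, m = 50, seed = 37)
  G <- vanraden_grm(pop$geno)
  expect_equal(unname(G$values), unname(vanraden_oracle(pop$geno$dosages)),
               tolerance = 1e-10)
})

test_that("G is the denominator-weighted recombination of any partition", {
  pop <- sim_pop(n = 40, m = 60, seed = 41)
  g <- pop$geno
  G <- vanraden_grm(g)
  ids <- g$map$id
  part <- partition_markers(g, ids[c(3, 10, 25, 44, 59)])
  g1 <- subset_geno(g, markers = part$prior)
  g2 <- subset_geno(g, markers = part$remaining)
  G1 <- vanraden_grm(g1); G2 <- vanraden_grm(g2)
  d_of <- function(gg) {
    p <- colMeans(gg$dosages) / 2
    2 * sum(p * (1 - p))
  }
  d1 <- d_of(g1); d2 <- d_of(g2)
  recomb <- (d1 * G1$values + d2 * G2$values) / (d1 + d2)
  expect_equal(G$values, recomb, tolerance = 1e-10)
})

test_that("the GRM is invariant to marker-order permutation", {
  pop <- sim_pop(n = 25, m = 40, seed = 43)
  set.seed(1); perm <- sample(40)
  g2 <- geno_matrix(pop$geno$dosages[, perm], pop$geno$map[perm, ],
                    pop$geno$samples, validate = FALSE)
  expect_equal(vanraden_grm(pop$geno)$values, vanraden_grm(g2)$values,
               tolerance = 1e-12)
})

test_that("monomorphic markers are excluded with a warning and all-mono errors", {
  dos <- cbind(c(0L, 1L, 2L), c(0L, 0L, 0L))
  expect_warning(G <- vanraden_grm(toy_geno(dos)), "monomorphic")
  expect_equal(G$n_markers, 1L)
  expect_error(vanraden_grm(toy_geno(cbind(c(2L, 2L), c(0L, 0L)))),
               "monomorphic")
})

test_that("marker partitions are disjoint, exhaustive and validated", {
  pop <- sim_pop(n = 20, m = 100, seed = 47)
  part <- partition_markers(pop$geno, pop$geno$map$id[11:15])
  expect_length(part$prior, 5)
  expect_length(part$remaining, 95)
  expect_setequal(c(part$prior, part$remaining), pop$geno$map$id)

  expect_error(partition_markers(pop$geno, character(0)), "empty")
  expect_error(partition_markers(pop$geno, pop$geno$map$id), "G2")
  expect_error(partition_markers(pop$geno, "nope"), "absent")
})

test_that("blending weights come from genetic-variance shares and sum to one", {
  pop <- sim_pop(n = 30, m = 60, seed = 53)
  part <- partition_markers(pop$geno, pop$geno$map$id[1:10])
  G1 <- vanraden_grm(subset_geno(pop$geno, markers = part$prior))
  G2 <- vanraden_grm(subset_geno(pop$geno, markers = part$remaining))

  G3 <- blend_grm(G1, G2, 1.369, 1.083)
  expect_equal(G3$gamma, 1.369 / (1.369 + 1.083), tolerance = 1e-15)
  expect_identical(G3$gamma + blend_grm(G2, G1, 1.083, 1.369)$gamma, 1)

  even <- blend_grm(G1, G2, 2, 2)
  expect_equal(even$values, (G1$values + G2$values) / 2, tolerance = 1e-12)
  expect_equal(even$gamma, 0.5)

  zero <- blend_grm(G1, G2, 0, 3.1)
  expect_identical(zero$values, G2$values)
  expect_equal(zero$gamma, 0)

  expect_error(blend_grm(G1, G2, 0, 0), "zero")
  Gs <- vanraden_grm(subset_geno(pop$geno, samples = pop$geno$samples[1:10]))
  expect_error(blend_grm(G1, Gs, 1, 1), "same samples")
})

test_that("conditioning lifts the spectrum floor only when needed", {
  I10 <- structure(list(values = diag(10), samples = sprintf("s%02d", 1:10),
                        n_markers = NA_integer_, gamma = NULL,
                        conditioned = FALSE), class = "grm")
  out <- condition_psd(I10)
  expect_false(out$conditioned)
  expect_identical(out$values, I10$values)

  pop <- sim_pop(n = 10, m = 3, seed = 59)
  G <- vanraden_grm(pop$geno)  # rank-deficient: 10 samples, 3 markers
  Gc <- condition_psd(G)
  expect_true(Gc$conditioned)
  ev <- eigen(Gc$values, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
  expect_silent(solve(Gc$values))

  # a convex blend of two conditioned matrices is already PSD
  part <- partition_markers(pop$geno, pop$geno$map$id[1])
  G1 <- condition_psd(vanraden_grm(subset_geno(pop$geno, markers = part$prior)))
  G2 <- condition_psd(vanraden_grm(subset_geno(pop$geno,
                                               markers = part$remaining)))
  G3 <- blend_grm(G1, G2, 1, 2)
  expect_false(condition_psd(G3)$conditioned)
})

test_that("GRM principal components separate diverged subpopulations", {
  # two subpopulations with shifted allele frequencies
  set.seed(71)
  n <- 60; m <- 120
  p1 <- runif(m, 0.1, 0.9)
  shift <- ifelse(p1 < 0.5, 0.35, -0.35)
  p2 <- p1 + shift
  dos <- rbind(
    sapply(p1, function(p) rbinom(n / 2, 2, p)),
    sapply(p2, function(p) rbinom(n / 2, 2, p)))
  G <- vanraden_grm(toy_geno(dos))
  pc <- grm_pca(G, k = 2)
  grp <- rep(c("a", "b"), each = n / 2)
  expect_true(max(pc$PC1[grp == "a"]) < min(pc$PC1[grp == "b"]) ||
                min(pc$PC1[grp == "a"]) > max(pc$PC1[grp == "b"]))

  ev <- attr(pc, "eigenvalues")
  expect_true(all(diff(ev) <= 1e-8))
  expect_lt(abs(sum(pc$PC1 * pc$PC2)) /
              max(sum(pc$PC1^2), 1e-12), 1e-6)
  expect_error(grm_pca(G, k = 1000), "exceed")
})

test_that("LD decays with distance and duplicated markers give r2 = 1", {
  # duplicated column at 150 kb
  set.seed(73)
  x <- rbinom(200, 2, 0.4)
  dos <- cbind(x, rbinom(200, 2, 0.3), x)
  g <- toy_geno(dos, pos = c(100000L, 200000L, 250000L))
  ld <- ld_decay(g, max_dist_bp = 5e5, bin_bp = 1e5)
  bin <- ld[ld$bin_start == 100001, ]
  expect_equal(bin$mean_r2, 1, tolerance = 1e-12)

  # Markov-LD simulation: near bins exceed far bins, 20/20 seeds
  monotone <- vapply(1:20, function(s) {
    cfg <- sim_config(n_samples = 150, n_markers = 40, n_chromosomes = 1,
                      chrom_length_bp = 4e6, ld_rho = 1e-6, maf_min = 0.1,
                      seed = 300 + s)
    g <- simulate_genotypes(cfg)
    ld <- ld_decay(g, max_dist_bp = 4e6, bin_bp = 1e6)
    ld$mean_r2[1] > ld$mean_r2[nrow(ld)]
  }, logical(1))
  expect_true(all(monotone))
})

test_that("GRMs round-trip through both text layouts", {
  pop <- sim_pop(n = 12, m = 30, seed = 79)
  G <- vanraden_grm(pop$geno)
  for (fmt in c("matrix", "gcta")) {
    prefix <- file.path(tempdir(), paste0("g_", fmt))
    write_grm(G, prefix, format = fmt)
    G2 <- read_grm(prefix, format = fmt)
    expect_equal(G2$values, G$values, tolerance = 1e-12)
    expect_identical(G2$samples, G$samples)
  }
})
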