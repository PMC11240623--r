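test_that("the fixed-effect design is treatment-coded with rank repair", {
  ph <- data.frame(id = sprintf("s%d", 1:4), ww = c(28, 29, 30, 27),
                   herd = c("A", "A", "B", "B"),
                   birth_type = c("1", "2", "1", "2"))
  d <- build_design(ph, ph$id)
  expect_equal(ncol(d$X), 3)  # intercept + herd + birth type
  expect_equal(unname(d$X[, 1]), rep(1, 4))

  ph$herd <- "A"
  expect_message(d1 <- build_design(ph, ph$id), "single level")
  expect_equal(ncol(d1$X), 2)

  # herd aliased with birth type: one column dropped
  ph2 <- data.frame(id = sprintf("s%d", 1:6), ww = rnorm(6, 28),
                    herd = rep(c("A", "B"), each = 3),
                    birth_type = rep(c("1", "2"), each = 3))
  expect_message(d2 <- build_design(ph2, ph2$id), "aliased")
  expect_equal(ncol(d2$X), 2)
  expect_equal(qr(d2$X)$rank, ncol(d2$X))
})

test_that("heritability is the genetic share of total variance", {
  expect_equal(round(heritability(1.135, 8.153), 3), 0.122)
  expect_equal(heritability(0, 5), 0)
  expect_error(heritability(0, 0), "zero")
  expect_error(heritability(-1, 2), "non-negative")
})

test_that("AI-REML matches the brute-force restricted-likelihood oracle", {
  for (s in c(101, 102, 103)) {
    pop <- sim_pop(n = 12, m = 40, seed = s, h2_target = 0.5)
    G <- condition_psd(vanraden_grm(pop$geno))
    d <- build_design(pop$pheno, G$samples)
    vc <- reml_fit(d, G)
    oracle <- reml_grid_oracle(d$y, d$X, G$values[d$idx, d$idx])
    scale <- vc$sigma_a2 + vc$sigma_e2
    expect_lt(abs(vc$sigma_a2 - oracle$theta[1]) / scale, 1e-4)
    expect_lt(abs(vc$sigma_e2 - oracle$theta[2]) / scale, 1e-4)
    expect_equal(vc$loglik, oracle$loglik, tolerance = 1e-6)
  }
})

test_that("REML recovers a moderate heritability on one simulated draw", {
  pop <- sim_pop(n = 600, m = 1200, seed = 107, h2_target = 0.3)
  G <- condition_psd(vanraden_grm(pop$geno))
  fit <- gblup(ww ~ herd + birth_type, data = pop$pheno, g = G)
  expect_true(fit$varcomp$converged)
  expect_lt(abs(fit$varcomp$h2 - 0.3), 0.12)
  expect_equal(fit$varcomp$h2,
               fit$varcomp$sigma_a2 / (fit$varcomp$sigma_a2 +
                                         fit$varcomp$sigma_e2),
               tolerance = 1e-12)
  tr <- attr(fit$varcomp, "ll_trace")
  expect_true(all(diff(tr) >= -1e-10))
})

test_that("a pure-noise trait gives near-zero heritability", {
  low <- 0L
  for (s in 1:10) {
    cfg <- sim_config(n_samples = 300, n_markers = 400, n_chromosomes = 4,
                      h2_target = 0.001, seed = 400 + s)
    g <- simulate_genotypes(cfg)
    sim <- simulate_phenotypes(g, cfg)
    G <- condition_psd(vanraden_grm(g))
    vc <- reml_fit(build_design(sim$pheno, G$samples), G)
    if (vc$h2 < 0.1) low <- low + 1L
  }
  expect_gte(low, 9L)
})

test_that("estimates are invariant to sample-order permutation", {
  pop <- sim_pop(n = 100, m = 150, seed = 109)
  G <- condition_psd(vanraden_grm(pop$geno))
  fit <- gblup(ww ~ herd + birth_type, data = pop$pheno, g = G)
  set.seed(2); perm <- sample(nrow(pop$pheno))
  fit2 <- gblup(ww ~ herd + birth_type, data = pop$pheno[perm, ], g = G)
  expect_equal(fit2$varcomp$sigma_a2, fit$varcomp$sigma_a2, tolerance = 1e-8)
  expect_equal(fit2$varcomp$sigma_e2, fit$varcomp$sigma_e2, tolerance = 1e-8)
  expect_equal(fit2$gebv[names(fit$gebv)], fit$gebv, tolerance = 1e-6)
})

test_that("GEBVs are translation-invariant; the intercept absorbs shifts", {
  pop <- sim_pop(n = 90, m = 120, seed = 113)
  G <- condition_psd(vanraden_grm(pop$geno))
  fit <- gblup(ww ~ herd + birth_type, data = pop$pheno, g = G)
  ph2 <- pop$pheno; ph2$ww <- ph2$ww + 5
  fit2 <- gblup(ww ~ herd + birth_type, data = ph2, g = G)
  # REML estimates agree to optimizer precision; the BLUP solve itself
  # is exactly translation-invariant at fixed variance components
  expect_equal(fit2$varcomp$sigma_a2, fit$varcomp$sigma_a2, tolerance = 1e-5)
  expect_equal(unname(coef(fit2)["(Intercept)"] - coef(fit)["(Intercept)"]),
               5, tolerance = 1e-6)
  d1 <- build_design(pop$pheno, G$samples)
  d2 <- build_design(ph2, G$samples)
  vc <- fit$varcomp
  expect_equal(gblup_predict(d2, G, vc)$gebv, gblup_predict(d1, G, vc)$gebv,
               tolerance = 1e-8)
})

test_that("a zero genetic variance yields all-zero GEBVs with a warning", {
  pop <- sim_pop(n = 40, m = 60, seed = 127)
  G <- condition_psd(vanraden_grm(pop$geno))
  d <- build_design(pop$pheno, G$samples)
  vc <- structure(list(sigma_a2 = 0, sigma_e2 = 9, h2 = 0, loglik = NA,
                       n_iter = 0L, converged = TRUE,
                       beta = c(`(Intercept)` = 28)), class = "varcomp")
  expect_warning(tab <- gblup_predict(d, G, vc), "zero")
  expect_true(all(tab$gebv == 0))
})

test_that("a duplicated genotype row receives its twin's GEBV", {
  pop <- sim_pop(n = 50, m = 80, seed = 131)
  g <- pop$geno
  dup <- g$dosages[c(seq_len(50), 7), ]
  samples <- c(g$samples, "clone")
  g2 <- geno_matrix(dup, g$map, samples, validate = FALSE)
  G <- vanraden_grm(g2)  # unconditioned: V stays invertible via sigma_e2
  d <- build_design(pop$pheno, G$samples)  # clone unphenotyped
  vc <- reml_fit(d, G)
  pred <- gblup_predict(d, G, vc, predict_ids = c(g$samples[7], "clone"))
  expect_equal(pred$gebv[1], pred$gebv[2], tolerance = 1e-8)
  expect_identical(pred$in_training, c(TRUE, FALSE))
})

test_that("GBLUP equals ridge SNP-BLUP with the matched penalty", {
  pop <- sim_pop(n = 50, m = 200, seed = 137)
  g <- pop$geno
  G <- vanraden_grm(g)
  d <- build_design(pop$pheno, G$samples)
  vc <- reml_fit(d, G)

  p <- colMeans(g$dosages) / 2
  Z <- sweep(g$dosages, 2, 2 * p, "-")
  cdenom <- 2 * sum(p * (1 - p))
  lambda <- vc$sigma_e2 / vc$sigma_a2

  # GLS fixed effects at the REML estimates, then both routes
  V <- vc$sigma_a2 * G$values + diag(vc$sigma_e2, nrow(Z))
  beta <- solve(crossprod(d$X, solve(V, d$X)), crossprod(d$X, solve(V, d$y)))
  r <- d$y - drop(d$X %*% beta)

  gebv_grm <- gblup_predict(d, G, vc)$gebv
  a_hat <- solve(crossprod(Z) + diag(lambda * cdenom, ncol(Z)),
                 crossprod(Z, r))
  gebv_ridge <- drop(Z %*% a_hat)
  expect_equal(unname(gebv_grm), unname(gebv_ridge), tolerance = 1e-6)
})

test_that("gblup methods expose coefficients, residuals and simulations", {
  pop <- sim_pop(n = 60, m = 90, seed = 139)
  G <- condition_psd(vanraden_grm(pop$geno))
  fit <- gblup(ww ~ herd + birth_type, data = pop$pheno, g = G)
  expect_s3_class(fit, "gblup")
  expect_named(coef(fit))
  expect_equal(length(residuals(fit)), 60)
  expect_equal(fitted(fit) + residuals(fit), fit$y, tolerance = 1e-12)
  expect_equal(nrow(predict(fit)), 60)
  sm <- summary(fit)
  expect_s3_class(sm, "summary.gblup")
  sims <- simulate(fit, nsim = 3, seed = 1, g = G)
  expect_equal(dim(sims), c(60L, 3L))
  expect_equal(unname(sapply(sims, mean)), rep(mean(fit$y), 3),
               tolerance = 3 * sd(fit$y))
})
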