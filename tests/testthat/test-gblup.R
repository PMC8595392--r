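test_that("single-trait REML matches the grid-search oracle on repeated records", {
  ## balanced one-way design: 100 unrelated individuals, 2 records each
  set.seed(71)
  n_ind <- 100
  h2_true <- 0.4
  u <- rnorm(n_ind, 0, sqrt(h2_true))
  y <- 10 + rep(u, each = 2) + rnorm(2 * n_ind, 0, sqrt(1 - h2_true))
  ids <- sprintf("i%03d", seq_len(n_ind))
  ph <- data.frame(id = rep(ids, each = 2), trait = "t1", value = y)
  G <- diag(n_ind); dimnames(G) <- list(ids, ids)
  fit <- reml_fit(model_spec(list(t1 = ~ 1)), ph, G)
  expect_equal(fit$method, "direct")
  h2_fit <- unname(fit$theta["var_a"] / sum(fit$theta))
  h2_grid <- grid_reml_h2(y, rep(ids, each = 2))
  expect_lt(abs(h2_fit - h2_grid), 0.01)   # 2-decimal-place agreement
})

test_that("eigen and direct REML paths agree to numerical precision", {
  dat <- small_gblup_data(seed = 303, n_ind = 120, n_sites = 250)
  spec <- model_spec(list(t1 = ~ sex, t2 = ~ sex + age))
  f1 <- reml_fit(spec, dat$ph, dat$G, method = "eigen")
  f2 <- reml_fit(spec, dat$ph, dat$G, method = "direct")
  expect_equal(f1$theta, f2$theta, tolerance = 1e-6)
  expect_equal(as.numeric(logLik(f1)), as.numeric(logLik(f2)), tolerance = 1e-8)
})

test_that("REML log-likelihood never decreases across iterations", {
  dat <- small_gblup_data(seed = 305, n_ind = 150, n_sites = 250)
  spec <- model_spec(list(t1 = ~ sex + year_season, t2 = ~ sex + year_season + age))
  fit <- reml_fit(spec, dat$ph, dat$G)
  expect_gte(min(diff(fit$loglik)), -1e-6)
  expect_true(fit$converged)
})

test_that("estimates escape a boundary initialization", {
  dat <- small_gblup_data(seed = 307, n_ind = 200, n_sites = 300,
                          var_a = c(10, 80), var_e = c(5, 60))
  ph1 <- dat$ph[dat$ph$trait == "t1", ]
  spec <- model_spec(list(t1 = ~ sex + year_season))
  init <- c(var_a = 1e-6, var_e = var(ph1$value))
  fit <- reml_fit(spec, ph1, dat$G, init = init)
  expect_gt(fit$theta["var_a"], 1)
})

test_that("single-trait fit equals a two-trait fit with the second trait absent", {
  dat <- small_gblup_data(seed = 309, n_ind = 100, n_sites = 200)
  ph1 <- dat$ph[dat$ph$trait == "t1", ]
  f1 <- reml_fit(model_spec(list(t1 = ~ sex)), ph1, dat$G, method = "direct")
  spec2 <- model_spec(list(t1 = ~ sex, t2 = ~ 1))
  f2 <- reml_fit(spec2, ph1, dat$G)   # no t2 records at all
  expect_equal(f2$method, "direct")
  expect_equal(unname(f1$theta["var_a"]), unname(f2$theta["var_a1"]),
               tolerance = 1e-6)
  expect_equal(unname(f1$theta["var_e"]), unname(f2$theta["var_e1"]),
               tolerance = 1e-6)
})

test_that("GEBVs shrink to zero as the additive variance vanishes", {
  dat <- small_gblup_data(seed = 311, n_ind = 80, n_sites = 150)
  ph1 <- dat$ph[dat$ph$trait == "t1", ]
  spec <- model_spec(list(t1 = ~ sex))
  des <- lcgblup:::build_design(spec, transform(ph1, trait = as.character(trait)),
                                rownames(dat$G$G))
  sol <- lcgblup:::gebv_solve(c(1e-10, var(ph1$value)), des, dat$G$G, 1L,
                              masked = integer(0))
  expect_lt(max(abs(sol$u)), 1e-6)
})

test_that("MME solution equals the direct matrix formula on a toy", {
  dat <- small_gblup_data(seed = 313, n_ind = 20, n_sites = 100)
  ph1 <- dat$ph[dat$ph$trait == "t1", ]
  spec <- model_spec(list(t1 = ~ sex))
  fit <- reml_fit(spec, ph1, dat$G)
  ## direct formula: u = va * G Z' V^{-1} (y - X bhat)
  G <- dat$G$G
  ids <- rownames(G)
  ord <- match(ph1$id, ids)
  X <- model.matrix(~ sex, ph1)
  va <- fit$theta["var_a"]; ve <- fit$theta["var_e"]
  V <- va * G[ord, ord] + ve * diag(nrow(ph1))
  Vi <- solve(V)
  bhat <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% ph1$value)
  u_direct <- va * G[, ord] %*% Vi %*% (ph1$value - X %*% bhat)
  expect_equal(unname(fit$gebv[, 1]), unname(u_direct[, 1]), tolerance = 1e-6)
  expect_equal(unname(coef(fit)$t1), unname(bhat[, 1]), tolerance = 1e-6)
})

test_that("an unphenotyped near-twin inherits its twin's breeding value", {
  dat <- small_gblup_data(seed = 317, n_ind = 60, n_sites = 200)
  G <- dat$G$G
  n <- nrow(G)
  ## duplicate individual 1 as an unphenotyped twin
  G2 <- rbind(cbind(G, G[, 1]), c(G[1, ], G[1, 1]))
  twin <- "twin"
  dimnames(G2) <- list(c(rownames(G), twin), c(rownames(G), twin))
  G2 <- G2 + diag(1e-6, n + 1)
  ph1 <- dat$ph[dat$ph$trait == "t1", ]
  fit <- reml_fit(model_spec(list(t1 = ~ sex)), ph1, G2)
  expect_equal(fit$gebv[twin, 1], fit$gebv[1, 1], tolerance = 0.01)
})

test_that("scale equivariance: c*y maps to c^2 variances and c*u", {
  dat <- small_gblup_data(seed = 319, n_ind = 100, n_sites = 200)
  ph1 <- dat$ph[dat$ph$trait == "t1", ]
  spec <- model_spec(list(t1 = ~ sex))
  f1 <- reml_fit(spec, ph1, dat$G)
  ph_c <- ph1; ph_c$value <- 3 * ph_c$value
  f2 <- reml_fit(spec, ph_c, dat$G)
  expect_equal(unname(f2$theta), unname(9 * f1$theta), tolerance = 1e-3)
  expect_equal(unname(f2$gebv[, 1]), unname(3 * f1$gebv[, 1]), tolerance = 1e-3)
})

test_that("GEBV accuracy increases with heritability", {
  accs <- vapply(c(0.1, 0.5, 0.9), function(h2) {
    mean(vapply(1:3, function(s) {
      sim <- simulate_population(K = 6, n_sites = 300, n_ind = 250,
                                 seed = child_seed(s, 401))
      tp <- trait_params(var_a = 10 * h2, var_e = 10 * (1 - h2), n_qtl = 200,
                         sex_levels = 0, ys_levels = 0)
      ph <- simulate_phenotypes(sim$truth, tp, seed = child_seed(s, 402))
      G <- stabilize_grm(grm_genotype(sim$truth$genotypes))
      fit <- reml_fit(model_spec(list(t1 = ~ 1)), ph, G)
      cor(fit$gebv[, 1], ph$tbv)
    }, 0))
  }, 0)
  expect_true(all(diff(accs) > 0))
  expect_true(all(accs > 0))
})

test_that("rank-deficient fixed effects are reported with the guilty columns", {
  dat <- small_gblup_data(seed = 321, n_ind = 50, n_sites = 100)
  ph1 <- dat$ph[dat$ph$trait == "t1", ]
  ph1$dup <- as.numeric(ph1$sex == "s1")   # aliased with sex
  expect_error(reml_fit(model_spec(list(t1 = ~ sex + dup)), ph1, dat$G),
               "rank deficient")
})

test_that("genetic parameters compute the standard ratios", {
  gp <- genetic_parameters(list(var_a = c(4, 9), var_e = c(4, 27),
                                cov_a = 3, cov_e = 2))
  expect_equal(gp$h2, c(0.5, 0.25))
  expect_equal(gp$rg, 3 / 6)
  expect_equal(gp$rp, 5 / sqrt(8 * 36))
  gp0 <- genetic_parameters(list(var_a = c(1, 1), var_e = c(1, 1),
                                 cov_a = 0, cov_e = 0))
  expect_equal(gp0$rg, 0)
  expect_equal(gp0$rp, 0)
  expect_error(genetic_parameters(list(var_a = 0, var_e = 0)), "zero total")
})

test_that("precomputed eigendecomposition reproduces the direct fit", {
  dat <- small_gblup_data(seed = 323, n_ind = 100, n_sites = 200)
  ph1 <- dat$ph[dat$ph$trait == "t1", ]
  spec <- model_spec(list(t1 = ~ sex))
  f1 <- reml_fit(spec, ph1, dat$G)
  f2 <- reml_fit(spec, ph1, grm_eigen(dat$G))
  expect_equal(f1$theta, f2$theta, tolerance = 1e-10)
})
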