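test_that("compression matches direct arithmetic on a toy panel", {
  g <- matrix(c(0, 1, 1, 2,
                2, 0, 1, 1), 4)
  y <- c(0.5, -1, 0.2, 1.1)
  std <- standardize_data(g, y)
  sm <- compress_to_summary(std)
  z_hand <- t(std$g_bar) %*% std$y_bar / sqrt(4)
  u_hand <- t(std$g_bar) %*% std$g_bar / 4
  expect_equal(sm$z, drop(z_hand), tolerance = 1e-12)
  expect_equal(sm$ld, u_hand, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(diag(sm$ld), rep(1, 2), tolerance = 1e-12)
  expect_equal(sm$beta_se, std$sigma_y / (2 * std$sigma_g),
               tolerance = 1e-12)
  ## phenotype equal to SNP j's standardized genotype: z = sqrt(n) U[, j]
  std_j <- standardize_data(g, std$g_bar[, 2])
  sm_j <- compress_to_summary(std_j)
  expect_equal(sm_j$z, sqrt(4) * sm$ld[, 2], tolerance = 1e-10)
})

test_that("compression preserves the rank of the predictor matrix", {
  for (i in 1:10) {
    ds <- make_dataset(n = 50 + 10 * i, m = 2 + i, ld_rho = 0.6,
                       seed = 300 + i)
    w <- compute_weights(ds$std$mafs, weight_spec("beta_density"))
    C <- diag(ds$std$m)
    M <- sweep(ds$std$g_bar, 2,
               (ds$std$sigma_g / ds$std$sigma_y) * w, "*") %*% C
    pred <- build_predictor(ds$summary, w, C)
    expect_identical(pred$rank, sumraa:::mat_rank(M))
  }
})

test_that("summary dataset validation enforces the LD contract", {
  u_bad <- matrix(c(1, 0.5, 0.2, 1), 2)
  expect_error(summary_dataset(c(1, 2), u_bad, n = 100), "symmetric")
  u_diag <- matrix(c(1.5, 0.2, 0.2, 1), 2)
  expect_error(summary_dataset(c(1, 2), u_diag, n = 100), "diagonal")
  u_npd <- matrix(c(1, 2, 2, 1), 2)
  expect_error(summary_dataset(c(1, 2), u_npd, n = 100),
               "positive semidefinite")
})

test_that("fixed-effects summary test: null statistic and single-SNP closed form", {
  u <- diag(2)
  sm0 <- summary_dataset(c(0, 0), u, n = 50, beta_se = c(0.1, 0.1))
  res0 <- fe_test_summary(sm0, C = diag(2))
  expect_identical(res0$statistic, 0)
  expect_identical(res0$p_value, 1)
  ## m = 1: R^2 = z^2 / n, F = (n - 2) R^2 / (1 - R^2)
  z <- 1.7; n <- 40
  sm1 <- summary_dataset(z, matrix(1), n = n, beta_se = 0.2)
  res1 <- fe_test_summary(sm1, C = diag(1))
  expect_equal(res1$r_squared, z^2 / n, tolerance = 1e-12)
  expect_equal(res1$statistic,
               (n - 2) * (z^2 / n) / (1 - z^2 / n), tolerance = 1e-12)
  expect_identical(res1$df, c(1L, 38L))
})

test_that("random-effects summary test: single SNP and burden row assembly", {
  ## single SNP, identity weight/scaling: Q = z^2 (unit normalizer)
  z <- 2.1
  sm1 <- summary_dataset(z, matrix(1), n = 30, beta_se = 1)
  res1 <- re_test_summary(sm1, C = diag(1), normalizer = "unit")
  expect_equal(res1$statistic, z^2, tolerance = 1e-12)
  expect_equal(res1$eigenvalues, 1, tolerance = 1e-12)
  expect_equal(res1$p_value, pchisq(z^2, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  ## burden on a 3-SNP toy: Q = (e' W Stilde^-1 z)^2, eigenvalue
  ## e' W Stilde^-1 U Stilde^-1 W e  (Table-row convention: unit normalizer)
  zv <- c(1.2, -0.4, 0.8)
  u <- matrix(c(1, 0.3, 0.1,
                0.3, 1, 0.5,
                0.1, 0.5, 1), 3)
  se <- c(0.11, 0.09, 0.15)
  w <- c(1.5, 1, 0.5)
  sm <- summary_dataset(zv, u, n = 200, beta_se = se)
  res <- re_test_summary(sm, weights = w,
                         C = build_c_operator(c_operator_spec("burden"),
                                              m = 3),
                         normalizer = "unit")
  q_hand <- (sum(w / se * zv))^2
  lam_hand <- drop(t(w / se) %*% u %*% (w / se))
  expect_equal(res$statistic, q_hand, tolerance = 1e-12)
  expect_equal(res$eigenvalues, lam_hand, tolerance = 1e-12)
})

test_that("summary Q is invariant to joint SNP permutation", {
  set.seed(23)
  ds <- make_dataset(n = 150, m = 7, ld_rho = 0.5, seed = 23)
  sm <- ds$summary
  w <- compute_weights(sm$mafs, weight_spec("beta_density"))
  base <- re_test_summary(sm, weights = w, C = diag(7))
  perm <- sample(7)
  sm_p <- summary_dataset(sm$z[perm], sm$ld[perm, perm], n = sm$n,
                          beta_se = sm$beta_se[perm],
                          snp_ids = sm$snp_ids[perm],
                          mafs = sm$mafs[perm])
  res_p <- re_test_summary(sm_p, weights = w[perm], C = diag(7))
  expect_equal(res_p$statistic, base$statistic, tolerance = 1e-12)
  expect_equal(res_p$p_value, base$p_value, tolerance = 1e-10)
})

test_that("missing beta SEs fall back to identity scaling with a warning", {
  sm <- summary_dataset(c(1, -1), diag(2), n = 100)
  expect_warning(res <- re_test_summary(sm, C = diag(2),
                                        normalizer = "unit"),
                 "identity scaling")
  expect_equal(res$statistic, 2, tolerance = 1e-12)
})

test_that("pca eigenvectors agree between data levels up to sign", {
  ds <- make_dataset(n = 120, m = 6, ld_rho = 0.6, seed = 31)
  std <- ds$std; sm <- ds$summary
  w <- compute_weights(std$mafs, weight_spec("beta_density"))
  cov_ind <- (w %o% w) * crossprod(std$g_tilde)
  ws <- w / sm$beta_se
  cov_sum <- (ws %o% ws) * sm$ld
  Ci <- build_c_operator(c_operator_spec("pca", k_components = 3), m = 6,
                         cov_matrix = cov_ind)
  Cs <- build_c_operator(c_operator_spec("pca", k_components = 3), m = 6,
                         cov_matrix = cov_sum)
  for (j in 1:3) {
    expect_lt(min(max(abs(Ci[, j] - Cs[, j])),
                  max(abs(Ci[, j] + Cs[, j]))), 1e-9)
  }
})

test_that("skat_o summary reduces to skat at rho 0 and burden at rho 1", {
  ds <- make_dataset(n = 180, m = 5, ld_rho = 0.4, seed = 41,
                     causal = 2, effects = 0.3)
  sm <- ds$summary
  w <- compute_weights(sm$mafs, weight_spec("beta_density"))
  skat <- re_test_summary(sm, weights = w, C = diag(5), method = "skat")
  so0 <- skat_o_summary(sm, weights = w, rho_grid = 0)
  expect_equal(so0$statistic, skat$statistic, tolerance = 1e-12)
  expect_equal(so0$p_value, skat$p_value, tolerance = 1e-12)
  ## rho = 1: Q equals the burden Q ( (e' W Stilde^-1 z)^2 / n )
  so1 <- skat_o_summary(sm, weights = w, rho_grid = 1)
  burden <- re_test_summary(sm, weights = w,
                            C = build_c_operator(
                              c_operator_spec("burden"), m = 5))
  expect_equal(so1$statistic, burden$statistic, tolerance = 1e-10)
  expect_equal(so1$p_value, burden$p_value, tolerance = 1e-8)
})

test_that("skat_o grid combination is reproducible and sane", {
  ds <- make_dataset(n = 150, m = 6, ld_rho = 0.5, seed = 53,
                     causal = 3, effects = 0.4)
  w <- compute_weights(ds$summary$mafs, weight_spec("beta_density"))
  r1 <- skat_o_summary(ds$summary, weights = w, n_draws = 2000, seed = 9)
  r2 <- skat_o_summary(ds$summary, weights = w, n_draws = 2000, seed = 9)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$stat_kind, "minP")
  expect_true(r1$p_value >= r1$statistic)  # multiplicity never helps
  expect_error(skat_o_summary(ds$summary, rho_grid = c(0.5, 2)), "0, 1")
})

test_that("lasso recovers the closed form at lambda 0 and soft-thresholds when U = I", {
  ds <- make_dataset(n = 200, m = 6, ld_rho = 0.5, seed = 61,
                     causal = c(1, 4), effects = c(0.4, -0.3))
  sm <- ds$summary
  fit0 <- lasso_fit(sm, lambda = 0)
  closed <- solve(sm$ld, sm$z)     # X = I: (X'UX)^-1 X'z = U^-1 z
  expect_lt(max(abs(fit0$beta_hat - closed)), 1e-8)
  expect_true(fit0$converged)
  ## objective path never increases
  expect_true(all(diff(fit0$objective_path) <= 1e-8))
  ## orthogonal design: U = I, X = I -> soft-thresholding of z at lambda/2
  z <- c(2.0, -0.7, 0.3)
  smo <- summary_dataset(z, diag(3), n = 100, beta_se = rep(1, 3))
  for (lam in c(0.5, 1.5, 3)) {
    fit <- lasso_fit(smo, x = build_predictor(smo, NULL, diag(3)),
                     lambda = lam)
    expect_equal(fit$beta_hat, sign(z) * pmax(abs(z) - lam / 2, 0),
                 tolerance = 1e-10)
  }
  ## huge penalty shrinks everything to zero, objective = z' U^-1 z
  fit_inf <- lasso_fit(sm, lambda = 1e8)
  expect_identical(fit_inf$beta_hat, rep(0, 6))
  expect_equal(fit_inf$objective_value,
               drop(crossprod(sm$z, solve(sm$ld, sm$z))),
               tolerance = 1e-10)
})

test_that("object-level combination covers the generic Z-score model", {
  ## single object: p equals the two-sided normal p-value
  z1 <- 1.96
  res1 <- combine_object_level(z1, matrix(1), c_operator_spec("skat"))
  expect_equal(res1$p_value, 2 * pnorm(abs(z1), lower.tail = FALSE),
               tolerance = 1e-8)
  ## independent objects, C = I: Q = sum z^2 with a chi^2_m tail
  z <- c(1.1, -0.6, 2.0, 0.3)
  res <- combine_object_level(z, diag(4), c_operator_spec("skat"))
  expect_equal(res$statistic, sum(z^2), tolerance = 1e-12)
  expect_equal(res$p_value, pchisq(sum(z^2), 4, lower.tail = FALSE),
               tolerance = 1e-10)
  ## fixed-effects combination requires n
  expect_error(combine_object_level(z, diag(4), c_operator_spec("mlr")),
               "requires n")
  res_fe <- combine_object_level(z, diag(4), c_operator_spec("mlr"),
                                 n = 500)
  expect_identical(res_fe$stat_kind, "F")
  ## metaUSAT-style skat_o factor: CC' = rho U + (1 - rho) I
  u <- matrix(0.4, 3, 3); diag(u) <- 1
  res_so <- combine_object_level(c(1, 0.5, -0.2), u,
                                 c_operator_spec("skat_o", rho = 0.3))
  lam_expect <- eigen(0.3 * u %*% u + 0.7 * u, only.values = TRUE)$values
  expect_equal(sort(res_so$eigenvalues, decreasing = TRUE),
               sort(lam_expect, decreasing = TRUE), tolerance = 1e-8)
})

test_that("correlation of null Z scores reproduces the genotype LD", {
  ## Many null phenotypes on one fixed panel: cov(z) ~ U entrywise
  reps <- 3000
  cfg <- simulation_config(400, 4, ld_decay_rho = 0.7, seed = 71)
  panel <- simulate_genotypes(cfg)
  set.seed(72)
  ymat <- matrix(rnorm(400 * reps), 400)
  gbar <- scale(panel$dosages) * sqrt(400 / 399)  # n-denominator scaling
  zmat <- crossprod(gbar, scale(ymat) * sqrt(400 / 399)) / sqrt(400)
  emp <- cor(t(zmat))
  u <- crossprod(gbar) / 400
  expect_lt(max(abs(emp - u)), 0.05)
})
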