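test_that("standardization centers, scales and is idempotent", {
  panel <- tiny_panel()
  y <- tiny_phenotype()
  std <- standardize_data(panel, y)
  expect_lt(max(abs(colMeans(std$g_bar))), 1e-10)
  expect_lt(max(abs(colMeans(std$g_tilde))), 1e-10)
  expect_equal(colSums(std$g_bar^2) / std$n, rep(1, 3), tolerance = 1e-12)
  expect_equal(sum(std$y_bar^2) / std$n, 1, tolerance = 1e-12)
  ## constant phenotype shift changes nothing
  std_shift <- standardize_data(panel, y + 10)
  expect_equal(std_shift$y_bar, std$y_bar, tolerance = 1e-12)
  expect_equal(std_shift$g_bar, std$g_bar)
  ## already-standardized input is unchanged
  std2 <- standardize_data(std$g_bar, std$y_bar)
  expect_equal(std2$y_bar, std$y_bar, tolerance = 1e-12)
  expect_equal(std2$g_bar, std$g_bar, tolerance = 1e-12)
  expect_error(standardize_data(panel, rep(1, 5)), "zero variance")
  expect_error(standardize_data(panel, y[1:4]), "length")
})

test_that("hand-checked column (0,1,1,2) standardizes to (-1,0,0,1)/sqrt(0.5)", {
  g <- matrix(c(0, 1, 1, 2), 4)
  y <- c(1, 0, 2, 5)
  std <- standardize_data(g, y)
  expect_equal(std$g_tilde[, 1], c(-1, 0, 0, 1))
  expect_equal(std$sigma_g, sqrt(0.5), tolerance = 1e-14)
  expect_equal(std$g_bar[, 1], c(-1, 0, 0, 1) / sqrt(0.5),
               tolerance = 1e-14)
})

test_that("single-SNP fixed-effects test reduces to squared correlation / OLS", {
  set.seed(8)
  g <- matrix(rbinom(60, 2, 0.3), 60, 1)
  y <- 0.4 * g[, 1] + rnorm(60)
  std <- standardize_data(g, y)
  res <- fe_test_individual(std, C = diag(1))
  expect_equal(res$r_squared, cor(y, g[, 1])^2, tolerance = 1e-10)
  ## against a textbook least-squares fit
  fit <- summary(lm(y ~ g[, 1]))
  expect_equal(res$statistic, fit$fstatistic[["value"]], tolerance = 1e-8)
  expect_identical(res$df, c(1L, 58L))
  expect_equal(res$p_value,
               pf(fit$fstatistic[["value"]], 1, 58, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("orthogonal phenotype gives F = 0, p = 1; perfect fit gives p ~ 0", {
  set.seed(1)
  g <- matrix(c(0, 1, 1, 2, 0, 2,
                2, 1, 0, 1, 2, 0), 6)
  gc <- sweep(g, 2, colMeans(g))
  y0 <- residuals(lm(rnorm(6) ~ gc))        # orthogonal to both columns
  std0 <- standardize_data(g, y0)
  res0 <- fe_test_individual(std0, C = diag(2))
  expect_equal(res0$r_squared, 0, tolerance = 1e-12)
  expect_equal(res0$statistic, 0, tolerance = 1e-10)
  expect_equal(res0$p_value, 1, tolerance = 1e-10)
  ## noiseless phenotype = centered causal dosage
  ds <- make_dataset(n = 80, m = 4, ld_rho = 0, seed = 3)
  y_perfect <- ds$panel$dosages[, 2] - mean(ds$panel$dosages[, 2])
  stdp <- standardize_data(ds$panel, y_perfect)
  resp <- fe_test_individual(stdp, C = diag(4), method = "mlr")
  expect_gt(resp$r_squared, 1 - 1e-10)
  expect_lt(resp$p_value, 1e-12)
})

test_that("rank-deficient predictors raise an informative error", {
  set.seed(2)
  g <- matrix(rbinom(40, 2, 0.4), 20, 2)
  g <- cbind(g, g[, 1] + g[, 2])            # exactly collinear
  std <- standardize_data(g, rnorm(20))
  expect_error(fe_test_individual(std, C = diag(3)), "rank deficient")
})

test_that("single-SNP score test gives Q = z^2 with a chi^2_1 p-value", {
  set.seed(5)
  g <- matrix(rbinom(100, 2, 0.25), 100, 1)
  y <- rnorm(100)
  std <- standardize_data(g, y)
  z <- sum(std$g_bar[, 1] * std$y_bar) / sqrt(100)
  res <- re_test_individual(std, weights = 1 / std$sigma_g * std$sigma_y,
                            C = matrix(1))   # W S^-1 = I
  expect_equal(res$statistic, z^2, tolerance = 1e-12)
  expect_equal(res$eigenvalues, 1, tolerance = 1e-12)
  expect_equal(res$p_value, pchisq(z^2, 1, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("n-side and m-side kernel spectra coincide", {
  for (i in 1:20) {
    ds <- make_dataset(n = 40 + 5 * i, m = 3 + (i %% 6), ld_rho = 0.4,
                       seed = 100 + i)
    std <- ds$std
    w <- compute_weights(std$mafs, weight_spec("beta_density"))
    M <- sweep(std$g_bar, 2, (std$sigma_g / std$sigma_y) * w, "*")
    K <- tcrossprod(M) / std$n                  # n x n kernel
    lam_n <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    lam_m <- eigen(crossprod(M) / std$n, symmetric = TRUE,
                   only.values = TRUE)$values
    k <- length(lam_m)
    expect_equal(sort(lam_n, decreasing = TRUE)[1:k], sort(lam_m,
                 decreasing = TRUE), tolerance = 1e-8)
    ## and the re test reports exactly the m-side spectrum
    res <- re_test_individual(std, weights = w, C = diag(std$m),
                              method = "skat")
    keep <- lam_m > 1e-12 * max(lam_m)
    expect_equal(res$eigenvalues, sort(lam_m[keep], decreasing = TRUE),
                 tolerance = 1e-10)
  }
})

test_that("burden Q matches the direct matrix-arithmetic assembly", {
  panel <- tiny_panel()
  y <- tiny_phenotype()
  std <- standardize_data(panel, y)
  w <- c(0.5, 2, 1)
  res <- re_test_individual(std, weights = w,
                            C = build_c_operator(c_operator_spec("burden"),
                                                 m = 3))
  ## direct assembly: M' ybar with M = Gbar S^-1 W e = (Gtilde w) / sigma_y
  score <- sum((std$g_tilde %*% w) * std$y_bar) / std$sigma_y
  lam <- sum((std$g_tilde %*% w)^2) / std$sigma_y^2 / std$n
  expect_equal(res$statistic, score^2 / std$n, tolerance = 1e-12)
  expect_equal(res$eigenvalues, lam, tolerance = 1e-12)
})

test_that("Q is invariant to phenotype sign flip and SNP permutation", {
  set.seed(17)
  ds <- make_dataset(n = 120, m = 6, ld_rho = 0.5, seed = 17)
  w <- compute_weights(ds$std$mafs, weight_spec("beta_density"))
  base <- re_test_individual(ds$std, weights = w, C = diag(6))
  flip <- standardize_data(ds$panel, -ds$pheno$values)
  expect_equal(re_test_individual(flip, weights = w,
                                  C = diag(6))$statistic,
               base$statistic, tolerance = 1e-12)
  perm <- sample(6)
  panel_p <- genotype_panel(ds$panel$dosages[, perm],
                            snp_ids = ds$panel$snp_ids[perm],
                            positions = sort(ds$panel$positions[perm]),
                            sample_ids = ds$panel$sample_ids)
  std_p <- standardize_data(panel_p, ds$pheno)
  res_p <- re_test_individual(std_p, weights = w[perm], C = diag(6))
  expect_equal(res_p$statistic, base$statistic, tolerance = 1e-12)
  expect_equal(res_p$eigenvalues, base$eigenvalues, tolerance = 1e-10)
})

test_that("fixed-effects p-values are uniform under the null", {
  reps <- 400
  ps <- vapply(seq_len(reps), function(i) {
    ds <- make_dataset(n = 60, m = 4, ld_rho = 0.3, seed = 5000 + i)
    fe_test_individual(ds$std, C = diag(4), method = "mlr")$p_value
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
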