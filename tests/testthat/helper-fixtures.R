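## Shared fixtures: everything is generated in code, no stored data.

## A tiny deterministic panel for hand-arithmetic oracles.
tiny_panel <- function() {
  d <- matrix(c(0, 1, 1, 2, 0,
                2, 1, 0, 1, 2,
                0, 0, 1, 2, 1), nrow = 5)
  genotype_panel(d, snp_ids = c("a", "b", "c"),
                 positions = c(100, 250, 900))
}

tiny_phenotype <- function() c(0.3, -1.1, 0.4, 2.0, -0.6)

## One simulated dataset in both representations.
make_dataset <- function(n = 200, m = 8, ld_rho = 0.5, seed = 1,
                         causal = integer(), effects = numeric(),
                         maf_range = c(0.05, 0.5)) {
  cfg <- simulation_config(n, m, maf_range = maf_range,
                           ld_decay_rho = ld_rho,
                           causal_indices = causal,
                           effect_sizes = effects, seed = seed)
  panel <- simulate_genotypes(cfg)
  pheno <- simulate_phenotype(panel, cfg)
  std <- standardize_data(panel, pheno)
  list(cfg = cfg, panel = panel, pheno = pheno, std = std,
       summary = compress_to_summary(std))
}

## Run one method through both formulations and return both results.
both_paths <- function(ds, method, weights = NULL, ...) {
  list(individual = raa_test(ds$std, method = method, weights = weights, ...),
       summary = raa_test(ds$summary, method = method, weights = weights,
                          ...))
}

expect_paths_equal <- function(pair, tol = 1e-10) {
  ri <- pair$individual; rs <- pair$summary
  expect_equal(rs$statistic, ri$statistic, tolerance = tol)
  expect_equal(rs$p_value, ri$p_value, tolerance = tol)
  expect_identical(rs$rank, ri$rank)
  if (!is.null(ri$df)) expect_identical(rs$df, ri$df)
  if (!is.null(ri$eigenvalues)) {
    ## relative to the spectral radius: eigenvalues at the numerical-noise
    ## floor (~1e-12 of the largest) carry no relative precision of their own
    expect_identical(length(rs$eigenvalues), length(ri$eigenvalues))
    expect_lt(max(abs(sort(rs$eigenvalues) - sort(ri$eigenvalues))) /
                max(ri$eigenvalues), tol)
  }
  invisible(pair)
}
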