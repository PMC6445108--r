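#' Simulation settings for a genomic region
#'
#' Describes one simulated region under the additive linear model
#' \eqn{y = \mu + G\beta + \xi}: the number of individuals and SNPs, the
#' minor-allele-frequency spectrum, the strength of linkage disequilibrium
#' between adjacent SNPs, which SNPs are causal and with what effects, and
#' the residual noise level.
#'
#' Linkage disequilibrium is produced by a latent first-order
#' autoregressive Gaussian process: each haplotype allele is a threshold of
#' an AR(1) Gaussian with lag-one autocorrelation \code{ld_decay_rho}, and
#' the dosage is the sum of two independent haplotypes, so genotypes are in
#' Hardy-Weinberg proportions and adjacent-SNP correlation increases
#' monotonically with \code{ld_decay_rho} (analytic value:
#' \code{\link{expected_adjacent_ld}}).
#'
#' @param n_individuals,n_snps positive integers.
#' @param maf_range length-2 numeric in (0, 0.5]; per-SNP allele
#'   frequencies are drawn uniformly from this interval.
#' @param ld_decay_rho latent AR(1) autocorrelation in [0, 1).
#' @param causal_indices integer indices (possibly empty) of causal SNPs.
#' @param effect_sizes numeric effects, one per causal SNP (fixed-effect
#'   generation; ignored when \code{effect_kind = "random"}).
#' @param noise_sd residual standard deviation \eqn{\sigma_y} (> 0).
#' @param effect_kind \code{"fixed"} (use \code{effect_sizes}) or
#'   \code{"random"} (draw effects afresh per phenotype replicate with
#'   variance \code{tau2}).
#' @param tau2 nonnegative variance of random effects.
#' @param seed integer seed; genotype generation uses \code{seed} and
#'   phenotype generation uses \code{seed + 1}, so the pair
#'   (config, operation) is fully deterministic.
#' @return A validated list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_individuals, n_snps,
                              maf_range = c(0.05, 0.5),
                              ld_decay_rho = 0,
                              causal_indices = integer(),
                              effect_sizes = numeric(),
                              noise_sd = 1,
                              effect_kind = c("fixed", "random"),
                              tau2 = 0,
                              seed = 1L) {
  effect_kind <- match.arg(effect_kind)
  stopifnot(n_individuals >= 2, n_snps >= 1,
            length(maf_range) == 2L)
  if (any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  if (ld_decay_rho < 0 || ld_decay_rho >= 1) {
    stop("ld_decay_rho must be in [0, 1)")
  }
  causal_indices <- as.integer(causal_indices)
  if (length(causal_indices) &&
      (any(causal_indices < 1L) || any(causal_indices > n_snps))) {
    stop("causal_indices out of range")
  }
  if (effect_kind == "fixed" &&
      length(effect_sizes) != length(causal_indices)) {
    stop("effect_sizes must have one entry per causal SNP")
  }
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (tau2 < 0) stop("tau2 must be nonnegative")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_snps = as.integer(n_snps),
                 maf_range = as.numeric(maf_range),
                 ld_decay_rho = as.numeric(ld_decay_rho),
                 causal_indices = causal_indices,
                 effect_sizes = as.numeric(effect_sizes),
                 noise_sd = as.numeric(noise_sd),
                 effect_kind = effect_kind,
                 tau2 = as.numeric(tau2),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Genotype panel
#'
#' An n-by-m matrix of allele dosages (0/1/2) with SNP metadata.  Columns
#' that are constant across the sample (monomorphic in the sample) carry no
#' association information and break the per-SNP scaling (which divides by
#' the genotypic standard deviation), so they are dropped with a warning.
#'
#' @param dosages numeric n-by-m matrix with values in \{0, 1, 2\}.
#' @param snp_ids,positions,sample_ids metadata; positions must be strictly
#'   increasing nonnegative integers.
#' @param mafs optional per-SNP sample minor allele frequencies; computed
#'   from \code{dosages} when missing.
#' @return An object of class \code{genotype_panel}.
#' @export
genotype_panel <- function(dosages, snp_ids = NULL, positions = NULL,
                           sample_ids = NULL, mafs = NULL) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages); m <- ncol(dosages)
  snp_ids <- snp_ids %||% paste0("snp_", seq_len(m))
  positions <- positions %||% seq_len(m)
  sample_ids <- sample_ids %||% paste0("ind_", seq_len(n))
  stopifnot(length(snp_ids) == m, length(positions) == m,
            length(sample_ids) == n)
  if (m > 1 && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing")
  }
  keep <- apply(dosages, 2L, function(col) length(unique(col)) > 1L)
  if (!any(keep)) {
    stop("all SNP columns are monomorphic in the sample; ",
         "increase the number of individuals")
  }
  if (!all(keep)) {
    warning(sum(!keep), " monomorphic SNP column(s) dropped: ",
            paste(snp_ids[!keep], collapse = ", "))
    dosages <- dosages[, keep, drop = FALSE]
    snp_ids <- snp_ids[keep]
    positions <- positions[keep]
    if (!is.null(mafs)) mafs <- mafs[keep]
  }
  if (is.null(mafs)) {
    f <- colMeans(dosages) / 2
    mafs <- pmin(f, 1 - f)
  }
  structure(list(dosages = dosages,
                 snp_ids = as.character(snp_ids),
                 positions = as.numeric(positions),
                 sample_ids = as.character(sample_ids),
                 mafs = as.numeric(mafs)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype panel:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "SNPs; MAF range",
      paste(signif(range(x$mafs), 3), collapse = "-"), "\n")
  invisible(x)
}

#' Simulate a genotype panel
#'
#' Draws dosages for \code{config$n_snps} SNPs in \code{config$n_individuals}
#' unrelated individuals under the latent-AR(1) LD scheme described in
#' \code{\link{simulation_config}}.  Deterministic given the config (the
#' seed is part of the config); the caller's RNG state is untouched.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return A \code{\link{genotype_panel}} (monomorphic columns dropped with
#'   a warning; an error if nothing polymorphic remains).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_individuals; m <- config$n_snps
  rho <- config$ld_decay_rho
  with_seed(config$seed, {
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    positions <- cumsum(sample.int(5000L, m, replace = TRUE) + 99L)
    thresh <- stats::qnorm(maf, lower.tail = FALSE)
    draw_haplotype <- function() {
      z <- matrix(0, n, m)
      z[, 1L] <- stats::rnorm(n)
      if (m > 1L) {
        innov_sd <- sqrt(1 - rho^2)
        for (j in 2:m) {
          z[, j] <- rho * z[, j - 1L] + innov_sd * stats::rnorm(n)
        }
      }
      sweep(z, 2L, thresh, ">") * 1L
    }
    dosages <- draw_haplotype() + draw_haplotype()
    genotype_panel(dosages,
                   snp_ids = paste0("snp_", seq_len(m)),
                   positions = positions,
                   sample_ids = paste0("ind_", seq_len(n)))
  })
}

#' Analytic adjacent-SNP dosage correlation of the simulator
#'
#' Closed-form (one-dimensional quadrature) target for the correlation
#' between dosages of two adjacent SNPs generated by the latent-AR(1)
#' threshold scheme: with latent correlation \eqn{\rho} and allele
#' frequencies \eqn{p_1, p_2}, the allele-level correlation is
#' \eqn{(P_{11} - p_1 p_2)/\sqrt{p_1 q_1 p_2 q_2}} where \eqn{P_{11}} is the
#' bivariate-normal upper orthant probability; dosages, being sums of two
#' independent haplotypes, have the same correlation.
#'
#' @param maf1,maf2 allele frequencies in (0, 0.5].
#' @param rho latent autocorrelation in [0, 1).
#' @return The expected dosage correlation.
#' @export
expected_adjacent_ld <- function(maf1, maf2, rho) {
  if (rho == 0) return(0)
  t1 <- stats::qnorm(maf1, lower.tail = FALSE)
  t2 <- stats::qnorm(maf2, lower.tail = FALSE)
  p11 <- stats::integrate(function(x) {
    stats::dnorm(x) * stats::pnorm((rho * x - t2) / sqrt(1 - rho^2))
  }, t1, Inf, rel.tol = 1e-10)$value
  (p11 - maf1 * maf2) /
    sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
}

#' Simulate a phenotype for a genotype panel
#'
#' Generates \eqn{y = G_{causal}\beta + \xi}, \eqn{\xi \sim N(0,
#' \sigma_y^2 I)}.  Effects are the configured \code{effect_sizes}
#' (\code{effect_kind = "fixed"}) or drawn \eqn{N(0, \tau^2)} per call
#' (\code{effect_kind = "random"}).  An empty causal set yields a pure-noise
#' null phenotype.  Generation applies no SNP weighting or smoothing:
#' weights and the method operator C belong to analysis, not to the truth.
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param config the \code{\link{simulation_config}} (its
#'   \code{causal_indices} refer to the panel's current columns).
#' @param trait_id label for the trait.
#' @return An object of class \code{phenotype_vector}: \code{values} and
#'   \code{trait_id}.
#' @export
simulate_phenotype <- function(panel, config, trait_id = "trait") {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(config, "simulation_config"))
  n <- nrow(panel$dosages)
  if (n != config$n_individuals) {
    stop("panel and config sample sizes disagree")
  }
  idx <- config$causal_indices
  if (length(idx) && max(idx) > ncol(panel$dosages)) {
    stop("causal_indices exceed the panel's column count")
  }
  with_seed(config$seed + 1L, {
    signal <- 0
    if (length(idx)) {
      beta <- if (config$effect_kind == "fixed") config$effect_sizes
              else stats::rnorm(length(idx), 0, sqrt(config$tau2))
      signal <- as.vector(panel$dosages[, idx, drop = FALSE] %*% beta)
    }
    values <- signal + stats::rnorm(n, 0, config$noise_sd)
    structure(list(values = values, trait_id = trait_id),
              class = "phenotype_vector")
  })
}

#' @export
print.phenotype_vector <- function(x, ...) {
  cat("phenotype '", x$trait_id, "': n = ", length(x$values),
      ", mean = ", signif(mean(x$values), 4),
      ", sd = ", signif(stats::sd(x$values), 4), "\n", sep = "")
  invisible(x)
}

pheno_values <- function(pheno) {
  if (inherits(pheno, "phenotype_vector")) pheno$values else as.numeric(pheno)
}
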