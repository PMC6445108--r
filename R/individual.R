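#' Standardize phenotype and genotypes
#'
#' Centers the phenotype and every genotype column (equivalent to
#' projecting out the intercept) and scales them to the declared variance
#' convention, producing the quantities the tests are written in:
#' \code{y_bar} (standardized trait), \code{g_bar} (column-standardized
#' genotypes) and \code{g_tilde} (centered-only genotypes).  Under the
#' default n-denominator convention each column of \code{g_bar} has second
#' moment exactly 1 and \code{crossprod(g_bar)/n} is a correlation matrix
#' with unit diagonal.
#'
#' @param genotypes a \code{\link{genotype_panel}} or numeric matrix with
#'   no constant column.
#' @param phenotype a \code{phenotype_vector} or numeric vector.
#' @param denom variance denominator convention (\code{"n"} default).
#' @return An object of class \code{standardized_data}: \code{y_bar},
#'   \code{g_bar}, \code{g_tilde}, the scale factors \code{sigma_y} and
#'   \code{sigma_g}, \code{n}, \code{m} and SNP metadata.
#' @export
standardize_data <- function(genotypes, phenotype,
                             denom = c("n", "n_minus_1")) {
  denom <- match.arg(denom)
  panel <- if (inherits(genotypes, "genotype_panel")) genotypes else NULL
  g <- if (is.null(panel)) as.matrix(genotypes) else panel$dosages
  y <- pheno_values(phenotype)
  if (length(y) != nrow(g)) {
    stop("phenotype length does not match the number of individuals")
  }
  n <- nrow(g); m <- ncol(g)
  sigma_y <- sd_denom(y, denom)
  if (sigma_y == 0) stop("phenotype has zero variance")
  y_bar <- (y - mean(y)) / sigma_y
  g_tilde <- sweep(g, 2L, colMeans(g), "-")
  sigma_g <- col_sds(g, denom)
  if (any(sigma_g == 0)) {
    stop("monomorphic genotype column(s): ",
         paste(which(sigma_g == 0), collapse = ", "))
  }
  g_bar <- sweep(g_tilde, 2L, sigma_g, "/")
  structure(list(y_bar = y_bar, g_bar = g_bar, g_tilde = g_tilde,
                 sigma_y = sigma_y, sigma_g = sigma_g,
                 n = n, m = m, denom = denom,
                 snp_ids = if (is.null(panel)) colnames(g) %||%
                             paste0("snp_", seq_len(m)) else panel$snp_ids,
                 positions = if (is.null(panel)) seq_len(m)
                             else panel$positions,
                 mafs = if (is.null(panel)) NULL else panel$mafs),
            class = "standardized_data")
}

#' @export
print.standardized_data <- function(x, ...) {
  cat("standardized data: n =", x$n, ", m =", x$m,
      "(denominator:", x$denom, ")\n")
  invisible(x)
}

#' Region test result
#'
#' @param method method label.
#' @param statistic the F or Q statistic.
#' @param stat_kind \code{"F"}, \code{"Q"} or \code{"minP"}.
#' @param p_value p-value in [0, 1].
#' @param df numerator/denominator degrees of freedom (F tests).
#' @param eigenvalues mixture eigen-weights (Q tests).
#' @param r_squared coefficient of determination (F tests).
#' @param rank rank of the predictor matrix.
#' @param diagnostics named list (condition number, normalizer, tail
#'   method, ...).
#' @return An object of class \code{raa_result}.
#' @export
raa_result <- function(method, statistic, stat_kind, p_value,
                       df = NULL, eigenvalues = NULL, r_squared = NULL,
                       rank = NA_integer_, diagnostics = list()) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(method = method, statistic = statistic,
                 stat_kind = stat_kind, p_value = p_value, df = df,
                 eigenvalues = eigenvalues, r_squared = r_squared,
                 rank = as.integer(rank), diagnostics = diagnostics),
            class = "raa_result")
}

#' @export
print.raa_result <- function(x, ...) {
  cat("region-based association test:", x$method, "\n")
  cat("  ", x$stat_kind, " = ", signif(x$statistic, 6), sep = "")
  if (!is.null(x$df)) cat("  df = (", paste(x$df, collapse = ", "), ")",
                          sep = "")
  if (!is.null(x$eigenvalues)) cat("  [", length(x$eigenvalues),
                                   " eigenvalues]", sep = "")
  cat("\n  p =", format(x$p_value, digits = 6), "\n")
  invisible(x)
}

norm_factor <- function(n, normalizer) {
  switch(normalizer, n = n, n_minus_1 = n - 1, unit = 1,
         stop("unknown normalizer"))
}

## Predictor matrix at the individual level: M = Gbar S^-1 W C.  Since
## Gbar S^-1 = Gtilde / sigma_y, this equals (Gtilde diag(w) C) / sigma_y.
individual_predictor <- function(std, weights, C) {
  m <- std$m
  weights <- weights %||% rep(1, m)
  stopifnot(length(weights) == m, nrow(C) == m)
  sweep(std$g_bar, 2L, (std$sigma_g / std$sigma_y) * weights, "*") %*% C
}

fe_from_score <- function(b, A, n, r, nn, method, cond) {
  k <- length(b)
  r2 <- drop(crossprod(b, solve(A, b))) / nn
  r2 <- min(max(r2, 0), 1)
  if (n - 1 - r < 1) stop("sample size too small for the F test (n <= r + 1)")
  f_stat <- if (r2 >= 1) Inf else (n - 1 - r) / r * r2 / (1 - r2)
  p <- stats::pf(f_stat, r, n - 1 - r, lower.tail = FALSE)
  raa_result(method = method, statistic = f_stat, stat_kind = "F",
             p_value = p, df = as.integer(c(r, n - 1 - r)), r_squared = r2,
             rank = r,
             diagnostics = list(condition_number = cond, k = k))
}

re_from_score <- function(score, A, nn, method, mixture_method = "auto") {
  q_stat <- sum(score^2) / nn
  lam <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values /
    nn
  scale <- max(abs(lam), .Machine$double.xmin)
  if (any(lam < -1e-10 * max(scale, 1))) {
    stop("kernel has genuinely negative eigenvalues: inconsistent inputs")
  }
  lam[lam < 0] <- 0
  if (max(lam) <= 0) stop("degenerate kernel: all eigenvalues are zero")
  mix <- chi2_mixture(lam)
  p <- mixture_sf(mix, q_stat, method = mixture_method)
  raa_result(method = method, statistic = q_stat, stat_kind = "Q",
             p_value = as.numeric(p), eigenvalues = mix$lambdas,
             rank = length(mix$lambdas),
             diagnostics = list(tail_method = attr(p, "method_used")))
}

#' Fixed-effects (F) region test on individual-level data
#'
#' Tests H0: beta = 0 in the standardized model
#' \eqn{\bar y = \bar G S^{-1} W C \beta + \bar\xi} via the coefficient of
#' determination
#' \eqn{R^2 = \frac{1}{n}\bar y^T M (M^T M)^{-1} M^T \bar y} with
#' \eqn{M = \bar G S^{-1} W C}, and
#' \eqn{F = \frac{n-1-r}{r}\frac{R^2}{1-R^2}} on \eqn{(r, n-1-r)} degrees
#' of freedom, \eqn{r = rank(M)}.
#'
#' @param std a \code{\link{standardized_data}}.
#' @param weights diagonal of W (numeric vector) or \code{NULL} for unit
#'   weights.
#' @param C the m-by-k method operator (see
#'   \code{\link{build_c_operator}}).
#' @param normalizer \code{"n"} (default) or \code{"n_minus_1"}; the same
#'   convention must be used on the summary path for exact equivalence.
#' @param method label recorded in the result.
#' @return A \code{\link{raa_result}} with \code{stat_kind = "F"}.
#' @export
fe_test_individual <- function(std, weights = NULL, C,
                               normalizer = c("n", "n_minus_1"),
                               method = attr(C, "method") %||% "fe") {
  normalizer <- match.arg(normalizer)
  stopifnot(inherits(std, "standardized_data"))
  M <- individual_predictor(std, weights, C)
  r <- mat_rank(M)
  k <- ncol(M)
  if (r < k) {
    stop("predictor matrix Gbar S^-1 W C is rank deficient (rank ", r,
         " < k = ", k, "); reduce k",
         if (identical(attr(C, "method"), "pca"))
           " (fewer principal components)" else "")
  }
  A <- crossprod(M)
  b <- crossprod(M, std$y_bar)
  fe_from_score(b, A, std$n, r, norm_factor(std$n, normalizer),
                method, condition_number(A))
}

#' Random-effects (Q) region test on individual-level data
#'
#' Score test of H0: tau^2 = 0 for random effects with
#' \eqn{Cov(\beta) \propto C C^T}:
#' \eqn{Q = \frac{1}{n}\bar y^T M M^T \bar y} with
#' \eqn{M = \bar G S^{-1} W C}; under the null Q follows the weighted
#' chi-square mixture with weights \eqn{eigen(\frac{1}{n} M^T M)}, the
#' nonzero eigenvalues of the n-by-n kernel
#' \eqn{K = \frac{1}{n} M M^T} (the k-side and n-side spectra coincide).
#'
#' @inheritParams fe_test_individual
#' @param normalizer \code{"n"} (default), \code{"n_minus_1"}, or
#'   \code{"unit"} (no normalization, the raw-score convention of the
#'   summary-statistic formulation); Q and the eigenvalues scale together,
#'   so the p-value is identical under any choice.
#' @return A \code{\link{raa_result}} with \code{stat_kind = "Q"}.
#' @export
re_test_individual <- function(std, weights = NULL, C,
                               normalizer = c("n", "n_minus_1", "unit"),
                               method = attr(C, "method") %||% "re") {
  normalizer <- match.arg(normalizer)
  stopifnot(inherits(std, "standardized_data"))
  M <- individual_predictor(std, weights, C)
  nn <- norm_factor(std$n, normalizer)
  re_from_score(crossprod(M, std$y_bar), crossprod(M), nn, method)
}
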