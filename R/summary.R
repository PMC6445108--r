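#' Summary-statistic dataset
#'
#' The summary-level inputs of the model: per-SNP GWAS Z scores \code{z},
#' the SNP-by-SNP correlation (LD) matrix \code{U} with unit diagonal, the
#' sample size \code{n} behind the Z scores, and optionally the per-SNP
#' beta standard errors (only needed for SNP weighting/scaling; when
#' absent, the scaling matrix defaults to the identity with a warning at
#' test time).
#'
#' @param z numeric vector of m Z scores.
#' @param ld m-by-m symmetric positive-semidefinite matrix with unit
#'   diagonal (asymmetry up to 1e-10 is symmetrized; diagonal must be 1
#'   within 1e-8; eigenvalues below \code{-1e-8 * max} are an error).
#' @param n sample size behind the Z scores (must be supplied explicitly;
#'   it is not guessed from meta-analysis provenance).
#' @param beta_se optional positive beta standard errors.
#' @param snp_ids,mafs,positions optional SNP metadata.
#' @return An object of class \code{summary_dataset}.
#' @export
summary_dataset <- function(z, ld, n, beta_se = NULL, snp_ids = NULL,
                            mafs = NULL, positions = NULL) {
  z <- as.numeric(z)
  ld <- as.matrix(ld)
  m <- length(z)
  stopifnot(nrow(ld) == m, ncol(ld) == m, n >= 2)
  if (max(abs(ld - t(ld))) > 1e-10) {
    stop("LD matrix is not symmetric (max asymmetry ",
         format(max(abs(ld - t(ld)))), ")")
  }
  ld <- (ld + t(ld)) / 2
  if (max(abs(diag(ld) - 1)) > 1e-8) {
    stop("LD matrix diagonal must be 1")
  }
  ev <- eigen(ld, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("LD matrix is not positive semidefinite (eigenvalue ",
         format(min(ev)), ")")
  }
  if (!is.null(beta_se)) {
    beta_se <- as.numeric(beta_se)
    stopifnot(length(beta_se) == m)
    if (any(beta_se <= 0)) stop("beta standard errors must be positive")
  }
  structure(list(z = z, ld = ld, n = as.integer(n), beta_se = beta_se,
                 snp_ids = as.character(snp_ids %||%
                                          paste0("snp_", seq_len(m))),
                 mafs = if (is.null(mafs)) NULL else as.numeric(mafs),
                 positions = as.numeric(positions %||% seq_len(m)),
                 m = m),
            class = "summary_dataset")
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat("summary dataset: m =", x$m, "SNPs, n =", x$n,
      if (is.null(x$beta_se)) "(no beta SEs)" else "(with beta SEs)", "\n")
  invisible(x)
}

#' Compress individual-level data to summary statistics
#'
#' Applies the linear compression \eqn{A = \bar G^T/\sqrt{n}} to the
#' standardized model: \eqn{z = \bar G^T \bar y/\sqrt{n}} (the GWAS
#' SNP-level Z scores) and \eqn{U = \bar G^T\bar G/n} (the SNP-by-SNP
#' correlation matrix).  The compression preserves the rank of the
#' predictor matrix, so no information relevant to the region test is
#' lost.  Beta standard errors are back-computed as
#' \eqn{\sigma_y/(\sqrt{n}\,\sigma_{g_i})}.
#'
#' @param std a \code{\link{standardized_data}}.
#' @return A \code{\link{summary_dataset}}.
#' @export
compress_to_summary <- function(std) {
  stopifnot(inherits(std, "standardized_data"))
  nn <- if (std$denom == "n") std$n else std$n - 1L
  z <- drop(crossprod(std$g_bar, std$y_bar)) / sqrt(nn)
  U <- crossprod(std$g_bar) / nn
  beta_se <- std$sigma_y / (sqrt(nn) * std$sigma_g)
  summary_dataset(z = z, ld = U, n = std$n, beta_se = beta_se,
                  snp_ids = std$snp_ids, mafs = std$mafs,
                  positions = std$positions)
}

summary_scaling_diag <- function(sumdat) {
  if (is.null(sumdat$beta_se)) {
    warning("no beta standard errors supplied; using an identity scaling ",
            "matrix (weights act directly on the Z scale)")
    rep(1, sumdat$m)
  } else sumdat$beta_se
}

#' Build the summary-level predictor matrix X
#'
#' \eqn{X = \tilde S^{-1} W C}: the m-by-k matrix that weights
#' (\eqn{\tilde S^{-1}}, \eqn{W}) and smooths/compresses (\eqn{C}) the
#' summary model \eqn{z = U X \beta + \bar\xi_m}.
#'
#' @param sumdat a \code{\link{summary_dataset}}.
#' @param weights diagonal of W or \code{NULL} for unit weights.
#' @param C the m-by-k method operator.
#' @return An object of class \code{predictor_matrix}: the matrix \code{x}
#'   and the recorded \code{rank} of \eqn{U X}.
#' @export
build_predictor <- function(sumdat, weights = NULL, C) {
  stopifnot(inherits(sumdat, "summary_dataset"))
  m <- sumdat$m
  weights <- weights %||% rep(1, m)
  stopifnot(length(weights) == m, nrow(C) == m)
  s_tilde <- summary_scaling_diag(sumdat)
  x <- (weights / s_tilde) * C
  structure(list(x = x, rank = mat_rank(sumdat$ld %*% x)),
            class = "predictor_matrix")
}

as_predictor <- function(sumdat, x_or_weights, C = NULL) {
  if (inherits(x_or_weights, "predictor_matrix")) return(x_or_weights)
  build_predictor(sumdat, x_or_weights, C)
}

#' Fixed-effects (F) region test from summary statistics
#'
#' Summary-level formulation of the F test:
#' \eqn{R^2 = \frac{1}{n} z^T X (X^T U X)^{-1} X^T z} with
#' \eqn{r = rank(UX)}, \eqn{F = \frac{n-1-r}{r}\frac{R^2}{1-R^2}}.  When
#' z and U are computed from the same genotypes
#' (\code{\link{compress_to_summary}}), the result is identical to
#' \code{\link{fe_test_individual}} under the same normalizer.
#'
#' @param sumdat a \code{\link{summary_dataset}}.
#' @param weights diagonal of W, or a \code{predictor_matrix} (in which
#'   case \code{C} is ignored).
#' @param C the m-by-k method operator.
#' @param normalizer \code{"n"} (default) or \code{"n_minus_1"}.
#' @param method label recorded in the result.
#' @return A \code{\link{raa_result}} with \code{stat_kind = "F"}.
#' @export
fe_test_summary <- function(sumdat, weights = NULL, C = NULL,
                            normalizer = c("n", "n_minus_1"),
                            method = attr(C, "method") %||% "fe") {
  normalizer <- match.arg(normalizer)
  pred <- as_predictor(sumdat, weights, C)
  X <- pred$x
  A <- crossprod(X, sumdat$ld %*% X)
  r <- pred$rank
  k <- ncol(X)
  rank_a <- mat_rank(A)
  if (rank_a < k) {
    stop("X'UX is singular (rank ", rank_a, " < k = ", k,
         ", condition number ", format(condition_number(A), digits = 3),
         "); reduce k or drop collinear SNPs")
  }
  b <- crossprod(X, sumdat$z)
  fe_from_score(b, A, sumdat$n, r, norm_factor(sumdat$n, normalizer),
                method, condition_number(A))
}

#' Random-effects (Q) region test from summary statistics
#'
#' Summary-level score statistic \eqn{Q = z^T X X^T z} (algebraically equal
#' to \eqn{z^T U^{-1/2} K_s U^{-1/2} z} with kernel
#' \eqn{K_s = U^{1/2} X X^T U^{1/2}}, but computed without any matrix
#' square root so singular U needs no special handling), with null
#' mixture weights \eqn{eigen(X^T U X)} taken from the k-by-k side.
#' With the default normalizer both Q and the eigenvalues are divided by
#' n, matching the individual-level convention exactly; \code{"unit"}
#' gives the raw summary-level form.
#'
#' @inheritParams fe_test_summary
#' @param normalizer \code{"n"} (default), \code{"n_minus_1"} or
#'   \code{"unit"}; the p-value is invariant to the choice.
#' @return A \code{\link{raa_result}} with \code{stat_kind = "Q"}.
#' @export
re_test_summary <- function(sumdat, weights = NULL, C = NULL,
                            normalizer = c("n", "n_minus_1", "unit"),
                            method = attr(C, "method") %||% "re") {
  normalizer <- match.arg(normalizer)
  pred <- as_predictor(sumdat, weights, C)
  X <- pred$x
  nn <- norm_factor(sumdat$n, normalizer)
  re_from_score(crossprod(X, sumdat$z), crossprod(X, sumdat$ld %*% X),
                nn, method)
}

## Matrix square root of U for drawing z ~ N(0, U); tolerant of singular U.
ld_factor <- function(U) {
  e <- eigen(U, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  e$vectors %*% (sqrt(lam) * t(e$vectors))
}

#' SKAT-O from summary statistics
#'
#' Runs the random-effects test over a grid of effect-correlation values
#' \eqn{\rho} (via the exchangeable factor
#' \eqn{C_\rho C_\rho^T = \rho e e^T + (1-\rho) I}) and combines them.
#' With a single grid value the per-rho analytic result is returned
#' directly (so \code{rho_grid = 0} reproduces SKAT and
#' \code{rho_grid = 1} reproduces the burden Q).  With a grid, the
#' combined statistic is the minimum per-rho p-value, calibrated by
#' seeded Monte-Carlo draws of \eqn{z \sim N(0, U)}; inside the min-p
#' ranking the same moment-matched tail approximation is applied to the
#' observed and the drawn statistics so the combination is
#' self-consistent, while the reported per-rho p-values use the primary
#' inversion.
#'
#' @param sumdat a \code{\link{summary_dataset}}.
#' @param weights diagonal of W or \code{NULL}.
#' @param rho_grid values in [0, 1]; default
#'   \eqn{\{0, 0.1^2, ..., 0.5^2, 1\}}.
#' @param n_draws Monte-Carlo draws for the min-p calibration.
#' @param seed integer seed for the calibration draws.
#' @param normalizer as in \code{\link{re_test_summary}}.
#' @return A \code{\link{raa_result}} with \code{stat_kind = "minP"} (or
#'   \code{"Q"} for a single-value grid); \code{diagnostics$per_rho} holds
#'   the per-rho table.
#' @export
skat_o_summary <- function(sumdat, weights = NULL,
                           rho_grid = c(0, (1:5 / 10)^2, 1),
                           n_draws = 1e4, seed = 1L,
                           normalizer = c("n", "n_minus_1", "unit")) {
  normalizer <- match.arg(normalizer)
  if (length(rho_grid) == 0L) stop("rho_grid must be nonempty")
  if (any(rho_grid < 0 | rho_grid > 1)) stop("rho_grid values outside [0, 1]")
  m <- sumdat$m
  preds <- lapply(rho_grid, function(r) {
    C <- build_c_operator(c_operator_spec("skat_o", rho = r), m = m)
    build_predictor(sumdat, weights, C)
  })
  per_rho <- lapply(preds, function(p) {
    re_test_summary(sumdat, p, normalizer = normalizer, method = "skat_o")
  })
  if (length(rho_grid) == 1L) {
    res <- per_rho[[1L]]
    res$diagnostics$rho <- rho_grid
    return(res)
  }
  nn <- norm_factor(sumdat$n, normalizer)
  lambdas <- lapply(preds, function(p) {
    lam <- eigen(crossprod(p$x, sumdat$ld %*% p$x), symmetric = TRUE,
                 only.values = TRUE)$values / nn
    chi2_mixture(pmax(lam, 0))$lambdas
  })
  q_obs <- vapply(per_rho, function(r) r$statistic, numeric(1))
  p_obs_rank <- vapply(seq_along(rho_grid), function(i) {
    liu_sf(lambdas[[i]], q_obs[i])
  }, numeric(1))
  min_p_obs <- min(p_obs_rank)
  min_p_draws <- with_seed(seed, {
    L <- ld_factor(sumdat$ld)
    zdraw <- L %*% matrix(stats::rnorm(m * n_draws), m)
    pmat <- vapply(seq_along(rho_grid), function(i) {
      qs <- colSums(crossprod(preds[[i]]$x, zdraw)^2) / nn
      liu_sf(lambdas[[i]], qs)
    }, numeric(n_draws))
    do.call(pmin, as.data.frame(pmat))
  })
  p_comb <- (1 + sum(min_p_draws <= min_p_obs)) / (n_draws + 1)
  raa_result(method = "skat_o", statistic = min_p_obs, stat_kind = "minP",
             p_value = p_comb,
             rank = per_rho[[1L]]$rank,
             diagnostics = list(
               per_rho = data.frame(
                 rho = rho_grid, Q = q_obs,
                 p = vapply(per_rho, function(r) r$p_value, numeric(1))),
               rho_min = rho_grid[which.min(p_obs_rank)],
               n_draws = n_draws, seed = seed))
}

#' Lasso estimation of effect sizes from summary statistics
#'
#' Minimizes the summary-level lasso objective
#' \deqn{(z - U X \beta)^T U^{-1} (z - U X \beta) + \lambda \sum_j |\beta_j|}
#' by cyclic coordinate descent.  At \eqn{\lambda = 0} the minimizer is the
#' closed-form estimate \eqn{(X^T U X)^{-1} X^T z}; for large \eqn{\lambda}
#' all coefficients shrink to zero.  Near-singular U (smallest eigenvalue
#' below 1e-8 of the largest) is ridge-stabilized as \eqn{U + \epsilon I}
#' with a message.
#'
#' @param sumdat a \code{\link{summary_dataset}}.
#' @param x a \code{predictor_matrix} from \code{\link{build_predictor}},
#'   or \code{NULL} for the unweighted identity predictor.
#' @param lambda nonnegative penalty.
#' @param ridge_epsilon ridge constant applied only when U is
#'   near-singular.
#' @param max_iter,tol coordinate-descent controls.
#' @return An object of class \code{lasso_fit}: \code{beta_hat},
#'   \code{lambda}, \code{objective_value}, \code{objective_path},
#'   \code{converged}, \code{n_iter}.
#' @export
lasso_fit <- function(sumdat, x = NULL, lambda, ridge_epsilon = 1e-6,
                      max_iter = 10000L, tol = 1e-12) {
  stopifnot(inherits(sumdat, "summary_dataset"), lambda >= 0)
  if (is.null(x)) {
    x <- structure(list(x = diag(sumdat$m), rank = mat_rank(sumdat$ld)),
                   class = "predictor_matrix")
  }
  X <- if (inherits(x, "predictor_matrix")) x$x else as.matrix(x)
  U <- sumdat$ld
  ev <- eigen(U, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8 * max(ev)) {
    message("LD matrix near-singular (min eigenvalue ",
            format(min(ev), digits = 3), "); applying ridge U + ",
            ridge_epsilon, " I")
    U <- U + ridge_epsilon * diag(sumdat$m)
  }
  z <- sumdat$z
  A <- crossprod(X, U %*% X)          # X' U X
  b <- drop(crossprod(X, z))          # X' z
  const <- drop(crossprod(z, solve(U, z)))  # z' U^-1 z
  k <- length(b)
  objective <- function(beta) {
    const - 2 * sum(beta * b) + drop(crossprod(beta, A %*% beta)) +
      lambda * sum(abs(beta))
  }
  soft <- function(u, t) sign(u) * pmax(abs(u) - t, 0)
  beta <- numeric(k)
  obj_path <- objective(beta)
  converged <- FALSE
  iter <- 0L
  if (all(diag(A) > 0)) {
    for (iter in seq_len(max_iter)) {
      delta_max <- 0
      for (j in seq_len(k)) {
        resid_j <- b[j] - sum(A[j, ] * beta) + A[j, j] * beta[j]
        new_bj <- soft(resid_j, lambda / 2) / A[j, j]
        delta_max <- max(delta_max, abs(new_bj - beta[j]))
        beta[j] <- new_bj
      }
      obj_path <- c(obj_path, objective(beta))
      if (delta_max < tol) { converged <- TRUE; break }
    }
  } else stop("X'UX has a nonpositive diagonal entry")
  if (!converged) {
    warning("coordinate descent did not converge in ", max_iter,
            " iterations; returning the partial solution")
  }
  structure(list(beta_hat = beta, lambda = lambda,
                 objective_value = objective(beta),
                 objective_path = obj_path,
                 converged = converged, n_iter = iter),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat("lasso fit: lambda =", x$lambda, ", ", sum(x$beta_hat != 0),
      "nonzero of", length(x$beta_hat), "coefficients, objective =",
      signif(x$objective_value, 6),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Combine dependent Z scores of any level
#'
#' Generic multi-object combination: the model \eqn{z = U C \beta + \bar\xi}
#' applied to Z scores computed at arbitrary genetic objects (SNPs, regions,
#' or traits), with the weight and scaling matrices set to the identity.
#' \code{U} is the correlation matrix of the Z scores — equal under the
#' null to the genotype LD (same trait, different SNPs) or to the
#' phenotypic correlation (different traits, same genotypes).  Methods map
#' to fixed effects (mlr/pca/flm: F test, requires \code{n}) or random
#' effects (burden/skat/skat_o: Q test).  For \code{skat_o} the
#' effect-correlation factor follows the multi-object form
#' \eqn{C C^T = \rho U + (1-\rho) I}.
#'
#' @param z numeric vector of Z scores.
#' @param u correlation matrix of the Z scores.
#' @param c_spec a \code{\link{c_operator_spec}}.
#' @param n sample size (required for fixed-effects methods; used for
#'   normalization otherwise only if \code{normalizer} demands it).
#' @param rho_grid optional grid for skat_o min-p combination (as in
#'   \code{\link{skat_o_summary}}).
#' @param normalizer normalization of Q; default \code{"unit"} here since
#'   object-level Z scores carry no per-observation scale.
#' @param ... passed to \code{\link{skat_o_summary}} (e.g. \code{n_draws},
#'   \code{seed}).
#' @return A \code{\link{raa_result}}.
#' @export
combine_object_level <- function(z, u, c_spec, n = NULL, rho_grid = NULL,
                                 normalizer = "unit", ...) {
  stopifnot(inherits(c_spec, "c_operator_spec"))
  m <- length(z)
  n_eff <- n %||% (m + 2L)   # placeholder when only RE normalization "unit"
  sumdat <- summary_dataset(z = z, ld = u, n = n_eff,
                            beta_se = rep(1, m))
  fe_methods <- c("mlr", "pca", "flm")
  if (c_spec$method %in% fe_methods) {
    if (is.null(n)) stop("fixed-effects combination requires n")
    C <- build_c_operator(c_spec, m = m, positions = seq_len(m),
                          cov_matrix = sumdat$ld)
    return(fe_test_summary(sumdat, weights = NULL, C = C,
                           normalizer = "n"))
  }
  if (c_spec$method == "skat_o") {
    if (!is.null(rho_grid) && length(rho_grid) > 1L) {
      stop("multi-object skat_o with a rho grid is not supported; ",
           "supply a single rho via c_spec")
    }
    ## metaUSAT-style factor: C C' = rho U + (1 - rho) I
    C <- sym_sqrt(c_spec$rho * u + (1 - c_spec$rho) * diag(m))
    attr(C, "method") <- "skat_o"
    return(re_test_summary(sumdat, weights = NULL, C = C,
                           normalizer = normalizer, method = "skat_o"))
  }
  C <- build_c_operator(c_spec, m = m)
  re_test_summary(sumdat, weights = NULL, C = C, normalizer = normalizer,
                  method = c_spec$method)
}
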