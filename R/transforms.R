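#' SNP weighting scheme
#'
#' Weights let rarer variants contribute more.  Three schemes:
#' \describe{
#'   \item{threshold}{\eqn{w_i = 1} if \eqn{MAF_i > c}, else 0 — hard
#'     frequency filtering.}
#'   \item{beta_density}{\eqn{w_i = MAF_i^{a-1}(1-MAF_i)^{b-1}/B(a,b)}, the
#'     Beta(a, b) density at the MAF; the field-standard continuous
#'     up-weighting of rare variants (e.g. a = 1, b = 25).}
#'   \item{external}{user-supplied nonnegative weights, e.g. functional
#'     predictions from annotation tools.}
#' }
#'
#' @param scheme one of \code{"beta_density"}, \code{"threshold"},
#'   \code{"external"}.
#' @param threshold_c frequency threshold in (0, 0.5] (threshold scheme).
#' @param beta_a,beta_b positive shape parameters (beta_density scheme).
#' @param external_weights nonnegative weights (external scheme).
#' @return A validated list of class \code{weight_spec}.
#' @export
weight_spec <- function(scheme = c("beta_density", "threshold", "external"),
                        threshold_c = 0.05, beta_a = 1, beta_b = 25,
                        external_weights = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "threshold" && (threshold_c <= 0 || threshold_c > 0.5)) {
    stop("threshold_c must be in (0, 0.5]")
  }
  if (scheme == "beta_density" && (beta_a <= 0 || beta_b <= 0)) {
    stop("beta_a and beta_b must be positive")
  }
  if (scheme == "external") {
    if (is.null(external_weights) || any(external_weights < 0)) {
      stop("external scheme requires nonnegative external_weights")
    }
  }
  structure(list(scheme = scheme, threshold_c = threshold_c,
                 beta_a = beta_a, beta_b = beta_b,
                 external_weights = external_weights),
            class = "weight_spec")
}

#' Compute the diagonal of the SNP weight matrix W
#'
#' @param mafs minor allele frequencies, each in (0, 0.5].
#' @param spec a \code{\link{weight_spec}}; \code{NULL} means unit weights.
#' @return Numeric vector of nonnegative weights (the diagonal of W).
#' @examples
#' compute_weights(c(0.01, 0.10), weight_spec("threshold", threshold_c = 0.05))
#' compute_weights(0.01, weight_spec("beta_density", beta_a = 1, beta_b = 25))
#' @export
compute_weights <- function(mafs, spec = NULL) {
  mafs <- as.numeric(mafs)
  if (any(mafs <= 0 | mafs > 0.5)) {
    stop("MAFs must lie in (0, 0.5] (minor-allele convention)")
  }
  if (is.null(spec)) return(rep(1, length(mafs)))
  stopifnot(inherits(spec, "weight_spec"))
  switch(spec$scheme,
    threshold = as.numeric(mafs > spec$threshold_c),
    beta_density = stats::dbeta(mafs, spec$beta_a, spec$beta_b),
    external = {
      if (length(spec$external_weights) != length(mafs)) {
        stop("external_weights length does not match the number of SNPs")
      }
      as.numeric(spec$external_weights)
    })
}

#' Method operator specification
#'
#' The operator C linearly transforms the weighted genotypes and defines
#' the method family:
#' \describe{
#'   \item{burden}{C is an m-by-1 vector of ones (collapse to one score).}
#'   \item{mlr, skat}{C is the m-by-m identity.}
#'   \item{pca}{C holds the first k eigenvectors of the weighted genotype
#'     covariance (individual level) or of the weighted, scaled LD matrix
#'     (summary level); k may be given directly or chosen as the smallest
#'     number of components covering \code{var_explained} of total
#'     variance (default 0.85).}
#'   \item{flm}{C holds k basis functions (Fourier or B-spline) evaluated
#'     at SNP positions normalized to [0, 1].}
#'   \item{skat_o}{C is the symmetric square root of
#'     \eqn{R = \rho e e^T + (1-\rho) I}, the exchangeable
#'     effect-correlation matrix interpolating SKAT (\eqn{\rho = 0}) and
#'     burden (\eqn{\rho = 1}).}
#' }
#'
#' @param method one of \code{"mlr"}, \code{"burden"}, \code{"pca"},
#'   \code{"flm"}, \code{"skat"}, \code{"skat_o"}.
#' @param k_components number of principal components (pca); \code{NULL}
#'   selects by \code{var_explained}.
#' @param var_explained target variance-explained fraction for automatic
#'   k selection (pca).
#' @param basis \code{"fourier"} or \code{"bspline"} (flm).
#' @param k_basis number of basis functions (flm).
#' @param spline_order B-spline order, at least 2 (flm, bspline).
#' @param rho effect correlation in [0, 1] (skat_o).
#' @return A validated list of class \code{c_operator_spec}.
#' @export
c_operator_spec <- function(method = c("mlr", "burden", "pca", "flm",
                                       "skat", "skat_o"),
                            k_components = NULL, var_explained = 0.85,
                            basis = c("fourier", "bspline"),
                            k_basis = NULL, spline_order = 4L,
                            rho = 0) {
  method <- match.arg(method)
  basis <- match.arg(basis)
  if (!is.null(k_components) && k_components < 1) {
    stop("k_components must be a positive integer")
  }
  if (method == "flm") {
    if (is.null(k_basis) || k_basis < 1) {
      stop("flm requires a positive k_basis")
    }
    if (basis == "bspline") {
      if (spline_order < 2) stop("spline_order must be at least 2")
      if (k_basis < spline_order) {
        stop("k_basis must be at least spline_order")
      }
    }
  }
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  structure(list(method = method, k_components = k_components,
                 var_explained = var_explained, basis = basis,
                 k_basis = if (is.null(k_basis)) NULL else as.integer(k_basis),
                 spline_order = as.integer(spline_order),
                 rho = as.numeric(rho)),
            class = "c_operator_spec")
}

## Fourier basis {1, sin(2 pi j t), cos(2 pi j t), ...} truncated to k
## columns, evaluated at t in [0, 1].
fourier_basis <- function(t, k) {
  out <- matrix(0, length(t), k)
  out[, 1L] <- 1
  j <- 1L
  col <- 2L
  while (col <= k) {
    out[, col] <- sin(2 * pi * j * t)
    col <- col + 1L
    if (col <= k) {
      out[, col] <- cos(2 * pi * j * t)
      col <- col + 1L
    }
    j <- j + 1L
  }
  out
}

## B-spline basis of the given order with uniform interior knots on [0, 1].
bspline_basis <- function(t, k, order) {
  n_interior <- k - order
  interior <- if (n_interior > 0) {
    seq(0, 1, length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
  } else numeric()
  knots <- c(rep(0, order), interior, rep(1, order))
  splines::splineDesign(knots, t, ord = order)
}

normalize_positions <- function(positions) {
  rng <- range(positions)
  if (rng[1] == rng[2]) return(rep(0.5, length(positions)))
  (positions - rng[1]) / (rng[2] - rng[1])
}

## Closed-form symmetric square root of R = rho e e' + (1 - rho) I:
## eigenvalues are 1 + (m-1) rho (on e) and 1 - rho (elsewhere).
skat_o_factor <- function(m, rho) {
  s1 <- sqrt(1 - rho)
  s2 <- sqrt(1 + (m - 1) * rho)
  mat <- matrix((s2 - s1) / m, m, m)
  diag(mat) <- diag(mat) + s1
  mat
}

#' Build the method operator C
#'
#' @param spec a \code{\link{c_operator_spec}}.
#' @param m number of SNPs in the region.
#' @param positions physical SNP positions (required for flm); the basis is
#'   evaluated at positions normalized affinely to [0, 1], so any affine
#'   rescaling of positions leaves C unchanged.
#' @param cov_matrix m-by-m weighted covariance to decompose (required for
#'   pca): \eqn{W\tilde G^T \tilde G W} at the individual level or
#'   \eqn{W\tilde S^{-1} U \tilde S^{-1} W} at the summary level, which are
#'   proportional and therefore share eigenvectors.
#' @return An m-by-k matrix with attribute \code{method}; for pca also
#'   attributes \code{var_explained} (achieved fraction) and orthonormal
#'   columns; for skat_o the symmetric square root of R.
#' @export
build_c_operator <- function(spec, m, positions = NULL, cov_matrix = NULL) {
  stopifnot(inherits(spec, "c_operator_spec"), m >= 1)
  C <- switch(spec$method,
    burden = matrix(1, m, 1L),
    mlr = diag(m),
    skat = diag(m),
    skat_o = skat_o_factor(m, spec$rho),
    pca = {
      if (is.null(cov_matrix)) stop("pca requires cov_matrix")
      stopifnot(nrow(cov_matrix) == m, ncol(cov_matrix) == m)
      e <- eigen((cov_matrix + t(cov_matrix)) / 2, symmetric = TRUE)
      lam <- pmax(e$values, 0)
      pos <- sum(lam > 1e-12 * max(lam))
      k <- spec$k_components
      if (is.null(k)) {
        frac <- cumsum(lam) / sum(lam)
        k <- which(frac >= spec$var_explained)[1L]
      }
      if (k > pos) {
        stop("k_components (", k, ") exceeds the rank (", pos,
             ") of the covariance matrix")
      }
      vecs <- e$vectors[, seq_len(k), drop = FALSE]
      ## deterministic sign: largest-magnitude loading positive
      for (j in seq_len(k)) {
        i <- which.max(abs(vecs[, j]))
        if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
      }
      attr(vecs, "var_explained") <- sum(lam[seq_len(k)]) / sum(lam)
      vecs
    },
    flm = {
      if (is.null(positions)) stop("flm requires SNP positions")
      stopifnot(length(positions) == m)
      k <- spec$k_basis
      if (k > m) stop("k_basis must not exceed the number of SNPs")
      t_norm <- normalize_positions(positions)
      if (spec$basis == "fourier") fourier_basis(t_norm, k)
      else bspline_basis(t_norm, k, spec$spline_order)
    })
  attr(C, "method") <- spec$method
  C
}

#' Scaling matrix S (individual level) or S-tilde (summary level)
#'
#' The diagonal scaling that converts centered genotypes to the
#' standardized scale: at the individual level
#' \eqn{s_{ii} = \sigma_y/\sigma_{g_i}}; at the summary level
#' \eqn{\tilde s_{ii} = se(\beta_{GWAS,i})}, related by
#' \eqn{s_{ii} = \sqrt{n}\,\tilde s_{ii}}.
#'
#' @param diag_values strictly positive diagonal entries.
#' @param mode \code{"individual"} or \code{"summary"}.
#' @param n sample size (links the two modes).
#' @return An object of class \code{scaling_matrix}.
#' @export
scaling_matrix <- function(diag_values, mode = c("individual", "summary"),
                           n) {
  mode <- match.arg(mode)
  diag_values <- as.numeric(diag_values)
  if (any(diag_values <= 0) || any(!is.finite(diag_values))) {
    stop("scaling diagonal must be strictly positive and finite")
  }
  structure(list(diag_values = diag_values, mode = mode, n = as.integer(n)),
            class = "scaling_matrix")
}

#' @export
print.scaling_matrix <- function(x, ...) {
  cat("scaling matrix (", x$mode, " mode), m = ", length(x$diag_values),
      ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Scaling matrix from genotypes
#'
#' Individual-level S with \eqn{s_{ii} = \sigma_y / \sigma_{g_i}}.  The
#' same variance denominator (n by default) is used everywhere in the
#' package so that the compressed LD matrix has an exactly unit diagonal.
#'
#' @param x a \code{\link{genotype_panel}} or dosage matrix.
#' @param trait_sd positive trait standard deviation \eqn{\sigma_y}.
#' @param denom variance denominator convention, \code{"n"} (default) or
#'   \code{"n_minus_1"}.
#' @return A \code{\link{scaling_matrix}} in individual mode.
#' @export
scaling_from_genotypes <- function(x, trait_sd,
                                   denom = c("n", "n_minus_1")) {
  denom <- match.arg(denom)
  g <- if (inherits(x, "genotype_panel")) x$dosages else as.matrix(x)
  if (trait_sd <= 0) stop("trait_sd must be positive")
  sg <- col_sds(g, denom)
  if (any(sg == 0)) {
    stop("zero genotype variance in column(s) ",
         paste(which(sg == 0), collapse = ", "))
  }
  scaling_matrix(trait_sd / sg, mode = "individual", n = nrow(g))
}

#' Scaling matrix from GWAS beta standard errors
#'
#' Summary-level S-tilde whose diagonal is the per-SNP GWAS beta standard
#' error; the implied individual-level S is \eqn{\sqrt{n}} times it.
#'
#' @param beta_ses positive standard errors.
#' @param n GWAS sample size.
#' @return A \code{\link{scaling_matrix}} in summary mode.
#' @export
scaling_from_summary <- function(beta_ses, n) {
  if (any(beta_ses <= 0)) stop("beta standard errors must be positive")
  scaling_matrix(as.numeric(beta_ses), mode = "summary", n = n)
}

#' Convert a scaling matrix between individual and summary modes
#'
#' Uses \eqn{S = \sqrt{n}\,\tilde S}.
#'
#' @param s a \code{\link{scaling_matrix}}.
#' @param mode target mode.
#' @return A \code{\link{scaling_matrix}} in the requested mode.
#' @export
scaling_as <- function(s, mode = c("individual", "summary")) {
  mode <- match.arg(mode)
  stopifnot(inherits(s, "scaling_matrix"))
  if (s$mode == mode) return(s)
  d <- if (mode == "individual") s$diag_values * sqrt(s$n)
       else s$diag_values / sqrt(s$n)
  scaling_matrix(d, mode = mode, n = s$n)
}
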