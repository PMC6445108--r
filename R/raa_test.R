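#' Run a region-based association test on either data level
#'
#' One-call interface over the six method families.  Dispatches on the
#' class of \code{data}: a \code{\link{genotype_panel}} (with
#' \code{phenotype}) runs the individual-level formulation; a
#' \code{\link{summary_dataset}} runs the summary-statistic formulation.
#' Fixed-effects methods (\code{mlr}, \code{pca}, \code{flm}) yield an F
#' test; random-effects methods (\code{burden}, \code{skat},
#' \code{skat_o}) yield a weighted-chi-square Q test.  Both levels share
#' the weight scheme, the operator C and the normalizer, so results are
#' identical when the summary statistics were compressed from the same
#' genotypes.
#'
#' @param data a \code{genotype_panel} or \code{summary_dataset} (or a
#'   \code{standardized_data}).
#' @param phenotype phenotype vector (individual level only).
#' @param method one of \code{"mlr"}, \code{"pca"}, \code{"flm"},
#'   \code{"burden"}, \code{"skat"}, \code{"skat_o"}.
#' @param weights a \code{\link{weight_spec}}, a numeric vector of
#'   per-SNP weights, or \code{NULL} for unit weights.  MLR conventionally
#'   runs unweighted.
#' @param c_spec a \code{\link{c_operator_spec}}; built from
#'   \code{method} and \code{...} when \code{NULL}.
#' @param normalizer \code{"n"} (default) or \code{"n_minus_1"}
#'   (\code{"unit"} additionally allowed for random-effects methods).
#' @param rho_grid for \code{skat_o} on summary data: a grid triggers the
#'   Monte-Carlo min-p combination; a single value (or \code{c_spec$rho})
#'   runs the fixed-rho test.
#' @param ... further arguments to \code{\link{c_operator_spec}} (e.g.
#'   \code{k_components}, \code{k_basis}, \code{basis}, \code{rho}) or to
#'   \code{\link{skat_o_summary}}.
#' @return A \code{\link{raa_result}}.
#' @export
raa_test <- function(data, phenotype = NULL, method, weights = NULL,
                     c_spec = NULL, normalizer = "n", rho_grid = NULL,
                     ...) {
  dots <- list(...)
  spec_args <- dots[names(dots) %in%
                      names(formals(c_operator_spec))]
  other_args <- dots[!names(dots) %in% names(spec_args)]
  if (!is.null(rho_grid) && length(rho_grid) == 1L) {
    spec_args$rho <- rho_grid     # a single grid value is just a fixed rho
    rho_grid <- NULL
  }
  if (is.null(c_spec)) {
    c_spec <- do.call(c_operator_spec, c(list(method = method), spec_args))
  }
  if (inherits(data, "genotype_panel")) {
    if (is.null(phenotype)) stop("individual-level mode needs a phenotype")
    data <- standardize_data(data, phenotype)
  }
  if (inherits(data, "standardized_data")) {
    std <- data
    w <- resolve_weights(weights, std$mafs, std$m)
    C <- build_c_for(c_spec, m = std$m, positions = std$positions,
                     cov_individual = function() {
                       wg <- sweep(std$g_tilde, 2L, w, "*")
                       crossprod(wg)
                     })
    return(run_level_test(c_spec$method,
                          fe = function() fe_test_individual(
                            std, w, C, normalizer = normalizer,
                            method = c_spec$method),
                          re = function() re_test_individual(
                            std, w, C, normalizer = normalizer,
                            method = c_spec$method)))
  }
  if (inherits(data, "summary_dataset")) {
    sumdat <- data
    w <- resolve_weights(weights, sumdat$mafs, sumdat$m)
    if (c_spec$method == "skat_o" && !is.null(rho_grid) &&
        length(rho_grid) > 1L) {
      return(do.call(skat_o_summary,
                     c(list(sumdat, weights = w, rho_grid = rho_grid,
                            normalizer = normalizer), other_args)))
    }
    C <- build_c_for(c_spec, m = sumdat$m, positions = sumdat$positions,
                     cov_individual = function() {
                       s <- summary_scaling_diag(sumdat)
                       ws <- w / s
                       (ws %o% ws) * sumdat$ld
                     })
    return(run_level_test(c_spec$method,
                          fe = function() fe_test_summary(
                            sumdat, w, C, normalizer = normalizer,
                            method = c_spec$method),
                          re = function() re_test_summary(
                            sumdat, w, C, normalizer = normalizer,
                            method = c_spec$method)))
  }
  stop("data must be a genotype_panel, standardized_data or summary_dataset")
}

resolve_weights <- function(weights, mafs, m) {
  if (is.null(weights)) return(rep(1, m))
  if (inherits(weights, "weight_spec")) {
    if (is.null(mafs)) stop("a weight_spec needs per-SNP MAFs")
    return(compute_weights(mafs, weights))
  }
  stopifnot(length(weights) == m)
  as.numeric(weights)
}

build_c_for <- function(c_spec, m, positions, cov_individual) {
  needs_cov <- c_spec$method == "pca"
  build_c_operator(c_spec, m = m, positions = positions,
                   cov_matrix = if (needs_cov) cov_individual() else NULL)
}

run_level_test <- function(method, fe, re) {
  if (method %in% c("mlr", "pca", "flm")) fe() else re()
}
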