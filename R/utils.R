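`%||%` <- function(a, b) if (is.null(a)) b else a

## sd with an n (population) or n-1 denominator; the n denominator is the
## package default so that the LD matrix U = crossprod(Gbar)/n has an exactly
## unit diagonal.
sd_denom <- function(x, denom = c("n", "n_minus_1")) {
  denom <- match.arg(denom)
  n <- length(x)
  v <- sum((x - mean(x))^2) / if (denom == "n") n else (n - 1L)
  sqrt(v)
}

col_sds <- function(x, denom = c("n", "n_minus_1")) {
  denom <- match.arg(denom)
  n <- nrow(x)
  xc <- sweep(x, 2L, colMeans(x), "-")
  v <- colSums(xc^2) / if (denom == "n") n else (n - 1L)
  sqrt(v)
}

## Numerical rank from singular values, LAPACK-style tolerance.
mat_rank <- function(m, tol = NULL) {
  if (length(m) == 0L) return(0L)
  d <- svd(m, nu = 0L, nv = 0L)$d
  if (is.null(tol)) tol <- max(dim(m)) * .Machine$double.eps * max(d, 0)
  sum(d > tol)
}

condition_number <- function(m) {
  d <- svd(m, nu = 0L, nv = 0L)$d
  d <- d[d > 0]
  if (length(d) == 0L) return(Inf)
  max(d) / min(d)
}

## Symmetric PSD square root by eigendecomposition.  Small negative
## eigenvalues (numerical noise) are clipped to zero; genuinely negative
## spectra are an input error.
sym_sqrt <- function(a, clip_tol = 1e-8) {
  a <- (a + t(a)) / 2
  e <- eigen(a, symmetric = TRUE)
  lam <- e$values
  scale <- max(abs(lam), 1)
  if (any(lam < -clip_tol * scale)) {
    stop("matrix is not positive semidefinite (eigenvalue ",
         format(min(lam)), ")")
  }
  lam[lam < 0] <- 0
  e$vectors %*% (sqrt(lam) * t(e$vectors))
}

## Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clamp01 <- function(p) pmin(pmax(p, 0), 1)
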