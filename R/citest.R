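#' Sample partial correlation
#'
#' Partial correlation of columns `x` and `y` given the columns in `z`,
#' computed by inverting the relevant block of the sample correlation matrix.
#' With an empty conditioning set this is the ordinary Pearson correlation.
#'
#' @param data numeric matrix (samples x variables).
#' @param x,y column indices or names.
#' @param z conditioning columns (possibly empty).
#' @return the partial correlation, in \[-1, 1\].
#' @export
partial_correlation <- function(data, x, y, z = integer(0)) {
  data <- as.matrix(data)
  cols <- resolve_cols(data, c(x, y, z))
  if (nrow(data) <= length(z) + 2)
    stop("need more than |z| + 2 samples for a partial correlation")
  C <- stats::cor(data[, cols, drop = FALSE])
  pcor_from_cor(C, 1L, 2L, seq_along(cols)[-(1:2)])
}

resolve_cols <- function(data, cols) {
  if (is.character(cols)) {
    idx <- match(cols, colnames(data))
    if (anyNA(idx)) stop("unknown columns: ", paste(cols[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(cols)
}

#' Partial correlation from a correlation matrix
#'
#' Workhorse shared by the CI test and the PC-stable skeleton: the partial
#' correlation of variables `i` and `j` given the set `S`, from the joint
#' correlation matrix. Rank-deficient conditioning blocks fall back to the
#' pseudo-inverse with a warning rather than failing silently.
#'
#' @param C correlation matrix.
#' @param i,j variable indices.
#' @param S integer vector of conditioning indices (may be empty).
#' @return partial correlation, clamped to \[-1, 1\].
#' @export
pcor_from_cor <- function(C, i, j, S = integer(0)) {
  if (length(S) == 0L) return(C[i, j])
  ij <- c(i, j)
  Czz <- C[S, S, drop = FALSE]
  Cxz <- C[ij, S, drop = FALSE]
  W <- tryCatch(solve(Czz, t(Cxz)), error = function(e) NULL)
  if (is.null(W)) {
    warning("rank-deficient conditioning set; using pseudo-inverse")
    s <- svd(Czz)
    pos <- s$d > max(s$d) * 1e-12
    pinv <- s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
    W <- pinv %*% t(Cxz)
  }
  Sc <- C[ij, ij, drop = FALSE] - Cxz %*% W   # conditional covariance (Schur)
  if (Sc[1, 1] <= 0 || Sc[2, 2] <= 0) return(0)
  r <- Sc[1, 2] / sqrt(Sc[1, 1] * Sc[2, 2])
  max(min(r, 1), -1)
}

#' Fisher-z p-value for a (partial) correlation
#'
#' Two-sided p-value of the z-transformed correlation,
#' `z = atanh(r) * sqrt(n - |S| - 3)`, against the standard normal.
#' `|r| = 1` is treated as certain dependence (p = 0).
#'
#' @param r (partial) correlation.
#' @param n sample size.
#' @param s_size conditioning-set size.
#' @return two-sided p-value.
#' @export
fisher_z_pvalue <- function(r, n, s_size = 0) {
  if (n <= s_size + 3)
    stop("sample size too small for the Fisher z transform (need n > |S| + 3)")
  if (abs(r) >= 1) return(0)
  z <- atanh(r) * sqrt(n - s_size - 3)
  2 * stats::pnorm(-abs(z))
}

#' Conditional-independence test
#'
#' Partial-correlation test with the Fisher z transform: the engine under
#' both CITL's undirected-graph construction and the PC-stable baselines.
#' Declares dependence when the two-sided p-value falls below `alpha`.
#'
#' @inheritParams partial_correlation
#' @param alpha type-one error in (0,1).
#' @return a list of class `citl_ci_test` with `partial_correlation`,
#'   `z_statistic`, `p_value`, `dependent` and `conditioning_set`.
#' @export
ci_test <- function(data, x, y, z = integer(0), alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  data <- as.matrix(data)
  n <- nrow(data)
  if (n <= length(z) + 3)
    stop("sample size too small for the Fisher z transform (need n > |S| + 3)")
  r <- partial_correlation(data, x, y, z)
  p <- fisher_z_pvalue(r, n, length(z))
  zstat <- if (abs(r) >= 1) sign(r) * Inf else atanh(r) * sqrt(n - length(z) - 3)
  structure(list(partial_correlation = r, z_statistic = zstat, p_value = p,
                 dependent = p < alpha, conditioning_set = z, n = n,
                 alpha = alpha),
            class = "citl_ci_test")
}

#' @export
print.citl_ci_test <- function(x, ...) {
  cat(sprintf("CI test: r = %.4f, z = %.2f, p = %.3g -> %s (alpha = %g, |S| = %d)\n",
              x$partial_correlation, x$z_statistic, x$p_value,
              if (x$dependent) "dependent" else "independent",
              x$alpha, length(x$conditioning_set)))
  invisible(x)
}
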