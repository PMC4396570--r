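#' Convert methylation beta values to M values
#'
#' M values are the log2 ratio of methylated to unmethylated signal,
#' `log2(beta / (1 - beta))`. The M scale is unbounded and approximately
#' variance-stabilized, which is why the linear modelling in this package
#' operates on M values rather than on the bounded beta proportions.
#' A beta of 0.50 maps to M = 0; a beta of 0.80 to M = 2.
#'
#' Betas at or beyond the clipping bounds are clipped to
#' `[eps, 1 - eps]` before the logit so the transform stays finite.
#'
#' @param beta numeric vector or matrix of methylation proportions in
#'   `[0, 1]`. `NA` is propagated.
#' @param eps clipping constant; values outside `(eps, 1 - eps)` are
#'   clipped. Default 0.001.
#' @return object of the same shape on the M scale. The number of clipped
#'   entries is attached as attribute `"n_clipped"` when positive.
#' @seealso [m_to_beta()] for the inverse transform.
#' @export
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8))  # -2, 0, 2
beta_to_m <- function(beta, eps = 0.001) {
  if (!is.numeric(beta)) stop("'beta' must be numeric")
  rng <- range(beta, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1)) {
    stop("beta values must lie in [0, 1]; observed range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  }
  clipped <- sum(beta < eps | beta > 1 - eps, na.rm = TRUE)
  b <- pmin(pmax(beta, eps), 1 - eps)
  m <- log2(b / (1 - b))
  if (!is.null(dim(beta))) dim(m) <- dim(beta)
  dimnames(m) <- dimnames(beta)
  if (clipped > 0) attr(m, "n_clipped") <- clipped
  m
}

#' Convert M values back to beta proportions
#'
#' Exact inverse of [beta_to_m()] away from its clipping bounds:
#' `2^m / (1 + 2^m)`.
#'
#' @param m numeric vector or matrix of finite M values. `NA` is propagated.
#' @return object of the same shape on the beta scale, in `(0, 1)`.
#' @export
m_to_beta <- function(m) {
  if (!is.numeric(m)) stop("'m' must be numeric")
  if (any(!is.finite(m) & !is.na(m))) {
    stop("non-finite M values are not allowed")
  }
  # plogis on the log2 scale avoids overflow of 2^m for large |m|
  b <- stats::plogis(m * log(2))
  if (!is.null(dim(m))) dim(b) <- dim(m)
  dimnames(b) <- dimnames(m)
  b
}

#' Quantile-normalize a probe-by-sample matrix
#'
#' Forces every sample (column) onto a common distribution: the mean of
#' the per-sample order statistics. Ties within a column receive the mean
#' of the target values they span. This mirrors the quantile method used
#' for array preprocessing; delegation is to
#' [limma::normalizeQuantiles()] with `ties = TRUE`.
#'
#' Quantile normalization is idempotent: applying it twice equals applying
#' it once.
#'
#' @param x numeric matrix, probes in rows, samples in columns, at least
#'   two columns. Missing cells are rejected unless `impute = TRUE`, in
#'   which case they are first replaced by the column median and the
#'   imputed count is attached as attribute `"n_imputed"`.
#' @param impute replace missing cells by the column median before
#'   normalizing? Default `FALSE`.
#' @return normalized matrix with the dimnames of `x`.
#' @export
quantile_normalize <- function(x, impute = FALSE) {
  if (!is.matrix(x) || !is.numeric(x)) stop("'x' must be a numeric matrix")
  if (ncol(x) < 2) {
    warning("single-column matrix: quantile normalization is a no-op")
    return(x)
  }
  n_imputed <- 0L
  if (anyNA(x)) {
    if (!impute) {
      stop("matrix contains missing values; set impute = TRUE to ",
           "replace them by column medians")
    }
    n_imputed <- sum(is.na(x))
    for (j in seq_len(ncol(x))) {
      miss <- is.na(x[, j])
      if (any(miss)) x[miss, j] <- stats::median(x[, j], na.rm = TRUE)
    }
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  if (n_imputed > 0) attr(out, "n_imputed") <- n_imputed
  out
}
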