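# Two-step empirical-Bayes differential methylation over repeated samples.
#
# Step 1 fits, per probe, an ordinary least-squares model with age as a
# categorical factor and individual as fixed blocks, yielding a residual
# variance and the first-vs-last-age contrast. Step 2 pools the per-probe
# variances into a scaled-chi-square prior (method of moments on the log
# variances) and forms a moderated t-statistic for the contrast, tested
# against Student's t with augmented degrees of freedom and corrected by
# Bonferroni.

#' Fit per-probe linear models with age and individual
#'
#' Ordinary least squares on the shared design
#' `~ factor(age) + factor(individual)` (treatment coding; first age and
#' first individual as baselines). Because all probes share one design, the
#' decomposition is computed once and applied to the whole matrix. The
#' contrast reported as `logfc` is the difference of age-level means,
#' last contrast age minus first (default: the dataset's extreme ages),
#' i.e. the M-value change over the study window adjusted for individual.
#'
#' Rank-deficient designs are handled with a pseudoinverse and flagged via
#' the `rank_deficient` attribute. An all-constant probe keeps `s2 = 0`.
#' An auxiliary F-test on the individual block is reported per probe
#' (`p_individual`); it classifies probes also affected by individual but
#' is never used for exclusion.
#'
#' @param dataset a [meth_dataset()] on the M scale.
#' @param contrast_ages length-2 numeric, the two ages (months) to
#'   contrast; default first and last observed ages.
#' @return object of class `probe_fits`: list with
#'   \describe{
#'     \item{fits}{data.frame `probe_id`, `logfc`, `s2`, `df_resid`,
#'       `p_individual`}
#'     \item{c_g}{contrast standard-error factor, shared across probes
#'       (square root of the contrast quadratic form in the design Gram
#'       inverse)}
#'     \item{contrast_ages}{the contrasted ages}
#'   }
#' @export
fit_probe_models <- function(dataset, contrast_ages = NULL) {
  stopifnot(inherits(dataset, "meth_dataset"))
  if (dataset$scale != "M") {
    stop("dataset must be on the M scale; use convert_scale(dataset, 'M')")
  }
  sm <- dataset$samples
  ages <- sort(unique(sm$age_months))
  if (length(ages) < 2) stop("need at least 2 distinct ages")
  if (length(unique(sm$individual_id)) < 2) {
    stop("need at least 2 individuals")
  }
  if (is.null(contrast_ages)) contrast_ages <- c(ages[1], ages[length(ages)])
  if (!all(contrast_ages %in% ages)) {
    stop("contrast ages ", paste(contrast_ages, collapse = ", "),
         " not all present in the sample sheet")
  }

  agef <- factor(sm$age_months, levels = ages)
  indf <- factor(sm$individual_id)
  X <- stats::model.matrix(~ agef + indf)
  n <- nrow(X)
  # order by sample id internally so results are invariant to input order
  ord <- order(sm$sample_id)
  Y <- t(dataset$values[, ord, drop = FALSE])   # samples x probes
  X <- X[ord, , drop = FALSE]

  qrX <- qr(X)
  r <- qrX$rank
  rank_deficient <- r < ncol(X)
  if (!rank_deficient) {
    coefs <- qr.coef(qrX, Y)                      # p x nprobes
    res <- qr.resid(qrX, Y)
    XtXinv <- matrix(0, ncol(X), ncol(X))
    XtXinv[qrX$pivot, qrX$pivot] <- chol2inv(qr.R(qrX))  # undo column pivoting
    rownames(XtXinv) <- colnames(XtXinv) <- colnames(X)
  } else {
    Xp <- MASS::ginv(X)
    coefs <- Xp %*% Y
    rownames(coefs) <- colnames(X)
    res <- Y - X %*% coefs
    XtXinv <- MASS::ginv(crossprod(X))
    rownames(XtXinv) <- colnames(XtXinv) <- colnames(X)
  }
  d <- n - r
  if (d <= 0) stop("no residual degrees of freedom (n = rank of design)")
  s2 <- colSums(res^2) / d

  # contrast vector over coefficients: age level a2 minus a1 under
  # treatment coding (baseline level has no column)
  cvec <- numeric(ncol(X)); names(cvec) <- colnames(X)
  lab <- function(a) paste0("agef", a)
  if (contrast_ages[2] != ages[1]) cvec[lab(contrast_ages[2])] <- 1
  if (contrast_ages[1] != ages[1]) cvec[lab(contrast_ages[1])] <- -1
  logfc <- as.numeric(crossprod(cvec, coefs))
  c_g <- sqrt(as.numeric(t(cvec) %*% XtXinv %*% cvec))

  # auxiliary F-test on the individual block (reduced model: age only)
  ind_cols <- grepl("^indf", colnames(X))
  X0 <- X[, !ind_cols, drop = FALSE]
  qr0 <- qr(X0)
  rss0 <- colSums(qr.resid(qr0, Y)^2)
  rss1 <- colSums(res^2)
  q <- r - qr0$rank
  p_individual <- rep(NA_real_, ncol(Y))
  ok <- s2 > 0 & q > 0
  Fstat <- ((rss0 - rss1) / q) / s2
  p_individual[ok] <- stats::pf(Fstat[ok], q, d, lower.tail = FALSE)
  p_individual[!ok & q > 0] <- 0  # perfect fit with individual structure

  structure(list(
    fits = data.frame(probe_id = colnames(Y), logfc = logfc, s2 = s2,
                      df_resid = d, p_individual = p_individual,
                      stringsAsFactors = FALSE, row.names = NULL),
    c_g = c_g,
    contrast_ages = contrast_ages,
    rank_deficient = rank_deficient), class = "probe_fits")
}

#' Solve trigamma(x) = y for x > 0
#'
#' Newton iteration on the monotone decreasing trigamma function, with
#' asymptotic starting values at both extremes.
#' @noRd
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(NaN)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (iter in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif) < 1e-10 * x) break
    }
    x
  }, numeric(1))
}

#' Estimate the scaled-chi-square variance prior across probes
#'
#' Models the per-probe residual variances as
#' `s_g^2 | sigma_g^2 ~ sigma_g^2 * chisq(d_g)/d_g` with
#' `1/sigma_g^2 ~ chisq(d_0)/(d_0 s_0^2)` and recovers `(d_0, s_0^2)` by
#' the method of moments on the log variances: with
#' `e_g = log(s_g^2) - digamma(d_g/2) + log(d_g/2)`,
#' `E[e_g] = log(s_0^2) + digamma(d_0/2) - log(d_0/2)` and
#' `Var[e_g] = trigamma(d_g/2) + trigamma(d_0/2)`. The excess of the
#' empirical variance of `e_g` over the mean `trigamma(d_g/2)` is inverted
#' through the trigamma function to give `d_0`. If there is no excess
#' dispersion the prior is degenerate: `d_0 = Inf` and
#' `s_0^2 = mean(s_g^2)`.
#'
#' Probes with zero or non-finite variance are excluded from estimation
#' (but still moderated later); at least 10 usable probes are required.
#'
#' @param fits a `probe_fits` object from [fit_probe_models()], or a
#'   data.frame with columns `s2` and `df_resid`.
#' @return list of class `moderation_prior` with `d0`, `s02`, and
#'   `n_used`.
#' @export
estimate_prior <- function(fits) {
  ft <- if (inherits(fits, "probe_fits")) fits$fits else fits
  stopifnot(all(c("s2", "df_resid") %in% names(ft)))
  use <- is.finite(ft$s2) & ft$s2 > 0 & ft$df_resid > 0
  if (sum(use) < 10) {
    stop("need at least 10 probes with positive variance and residual df; ",
         "have ", sum(use))
  }
  s2 <- ft$s2[use]
  d <- ft$df_resid[use]
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(d / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- mean(s2)
  }
  structure(list(d0 = d0, s02 = s02, n_used = n),
            class = "moderation_prior")
}

#' @export
print.moderation_prior <- function(x, ...) {
  cat(sprintf("moderation_prior: d0 = %s, s0^2 = %.4g (from %d probes)\n",
              format(x$d0, digits = 4), x$s02, x$n_used))
  invisible(x)
}

#' Moderated t-test for the age contrast
#'
#' Shrinks each probe's residual variance toward the prior,
#' `s2_post = (d0 * s02 + d * s2) / (d0 + d)`, and forms
#' `t = logfc / (sqrt(s2_post) * c_g)`, referred to Student's t with
#' `d0 + d` degrees of freedom (two-sided). P values are
#' Bonferroni-corrected over `n_tested` and each probe is classified as
#' `age_methylated` (significant, logfc > 0), `age_demethylated`
#' (significant, logfc < 0) or `not_significant`.
#'
#' Degenerate probes (posterior variance zero) get `p = 0` when the
#' contrast is non-zero (flagged in the `degenerate` column) and `t = 0`
#' when it is zero.
#'
#' @param fits a `probe_fits` object from [fit_probe_models()].
#' @param prior a `moderation_prior` from [estimate_prior()]. `d0 = 0` is
#'   allowed and reproduces the classical unmoderated contrast t.
#' @param n_tested number of tests for the Bonferroni correction; default
#'   the number of probes in `fits`.
#' @param alpha significance level on the Bonferroni-corrected p (default
#'   0.01).
#' @return data.frame of class `diffmeth_table`: `probe_id`, `logfc`, `t`,
#'   `p`, `p_bonf`, `direction`, `p_individual`, `degenerate`, with
#'   attributes `alpha`, `n_tested`, `contrast_ages`.
#' @export
moderated_t <- function(fits, prior, n_tested = NULL, alpha = 0.01) {
  stopifnot(inherits(fits, "probe_fits"),
            inherits(prior, "moderation_prior"))
  ft <- fits$fits
  if (is.null(n_tested)) n_tested <- nrow(ft)
  stopifnot(n_tested >= 1, alpha > 0, alpha < 1)
  d0 <- prior$d0; s02 <- prior$s02
  d <- ft$df_resid
  s2_post <- if (is.infinite(d0)) rep(s02, nrow(ft))
             else (d0 * s02 + d * ft$s2) / (d0 + d)
  df_total <- d0 + d
  se <- sqrt(s2_post) * fits$c_g
  degenerate <- se == 0
  tstat <- ifelse(degenerate, ifelse(ft$logfc == 0, 0, Inf * sign(ft$logfc)),
                  ft$logfc / se)
  p <- ifelse(degenerate & ft$logfc != 0, 0,
              2 * stats::pt(abs(tstat), df = df_total, lower.tail = FALSE))
  p_bonf <- bonferroni(p, n_tested)
  direction <- ifelse(p_bonf < alpha & ft$logfc > 0, "age_methylated",
                      ifelse(p_bonf < alpha & ft$logfc < 0,
                             "age_demethylated", "not_significant"))
  out <- data.frame(probe_id = ft$probe_id, logfc = ft$logfc, t = tstat,
                    p = p, p_bonf = p_bonf, direction = direction,
                    p_individual = ft$p_individual,
                    degenerate = degenerate,
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "n_tested") <- n_tested
  attr(out, "contrast_ages") <- fits$contrast_ages
  class(out) <- c("diffmeth_table", "data.frame")
  out
}

#' Bonferroni correction
#'
#' Family-wise error correction: `min(1, p * n_tested)`.
#'
#' @param p probabilities in `[0, 1]`.
#' @param n_tested number of tests (>= 1).
#' @return corrected probabilities.
#' @export
bonferroni <- function(p, n_tested) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must be in [0, 1]")
  if (n_tested < 1) stop("n_tested must be >= 1")
  pmin(1, p * n_tested)
}
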