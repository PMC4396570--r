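# Independent least-squares oracle: builds indicator columns by hand and
# solves the normal equations per probe. Shares no code with the package fit.
normal_equations_oracle <- function(dataset, contrast_ages) {
  sm <- dataset$samples
  ages <- sort(unique(sm$age_months))
  inds <- sort(unique(sm$individual_id))
  X <- cbind(1, sapply(ages[-1], function(a) as.numeric(sm$age_months == a)),
             sapply(inds[-1], function(i) as.numeric(sm$individual_id == i)))
  colnames(X) <- c("intercept", paste0("age", ages[-1]),
                   paste0("ind", inds[-1]))
  XtX <- t(X) %*% X
  XtXinv <- solve(XtX)
  d <- nrow(X) - ncol(X)
  cvec <- numeric(ncol(X)); names(cvec) <- colnames(X)
  if (contrast_ages[2] != ages[1]) cvec[paste0("age", contrast_ages[2])] <- 1
  if (contrast_ages[1] != ages[1]) cvec[paste0("age", contrast_ages[1])] <- -1
  res <- apply(dataset$values, 1, function(y) {
    beta <- XtXinv %*% (t(X) %*% y)
    r <- y - X %*% beta
    c(logfc = sum(cvec * beta), s2 = sum(r^2) / d)
  })
  list(logfc = res["logfc", ], s2 = res["s2", ], df = d,
       c_g = sqrt(drop(t(cvec) %*% XtXinv %*% cvec)))
}

test_that("per-probe fits match an explicit normal-equations oracle", {
  ds <- small_m_dataset(n_ind = 4, ages = c(3, 12, 60), n_probes = 20,
                        seed = 21)
  fits <- fit_probe_models(ds)
  oracle <- normal_equations_oracle(ds, c(3, 60))
  expect_equal(fits$fits$logfc, unname(oracle$logfc), tolerance = 1e-10)
  expect_equal(fits$fits$s2, unname(oracle$s2), tolerance = 1e-10)
  expect_equal(fits$fits$df_resid, rep(oracle$df, 20))
  expect_equal(fits$c_g, oracle$c_g, tolerance = 1e-12)
})

test_that("fits are invariant to sample order and honour planted structure", {
  ds <- small_m_dataset(seed = 22)
  perm <- sample(ncol(ds$values))
  ds_shuf <- meth_dataset(ds$values[, perm], ds$samples[perm, ], scale = "M")
  f1 <- fit_probe_models(ds)
  f2 <- fit_probe_models(ds_shuf)
  expect_equal(f1$fits, f2$fits, tolerance = 1e-12)

  # individual-offset-only probe: logfc 0
  sheet <- data.frame(sample_id = paste0("s", 1:4),
                      individual_id = c("a", "a", "b", "b"),
                      age_months = c(3, 60, 3, 60))
  m <- matrix(c(1, 1, 5, 5), 1, 4,
              dimnames = list("p1", sheet$sample_id))
  f <- fit_probe_models(meth_dataset(m, sheet, scale = "M"))
  expect_equal(f$fits$logfc, 0)
  expect_equal(f$fits$s2, 0)

  # exact planted contrast, zero noise: logfc = delta
  m2 <- matrix(c(0, 3, 2, 5), 1, 4,
               dimnames = list("p1", sheet$sample_id))  # +3 at 60m, ind b +2
  f2 <- fit_probe_models(meth_dataset(m2, sheet, scale = "M"))
  expect_equal(f2$fits$logfc, 3)
})

test_that("fit preconditions are enforced", {
  ds <- small_m_dataset(seed = 30)
  beta_ds <- meth_dataset(m_to_beta(ds$values), ds$samples, scale = "beta")
  expect_error(fit_probe_models(beta_ds), "M scale")
  expect_error(fit_probe_models(ds, contrast_ages = c(3, 48)),
               "not all present")
  one_age <- meth_dataset(ds$values[, ds$samples$age_months == 3],
                          ds$samples[ds$samples$age_months == 3, ],
                          scale = "M")
  expect_error(fit_probe_models(one_age), "2 distinct ages")
})

test_that("prior estimation: degenerate and error cases", {
  same <- data.frame(s2 = rep(1.7, 50), df_resid = 10)
  pr <- estimate_prior(same)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s02, 1.7)
  expect_error(estimate_prior(data.frame(s2 = c(1, 2), df_resid = 5)),
               "at least 10")
})

test_that("prior estimation agrees with the established empirical-Bayes
           moderation machinery on random variances", {
  set.seed(41)
  d <- 30
  s2 <- 0.8 * rchisq(3000, 6) / 6 * (0.5 + rgamma(3000, 2, 2))
  pr <- estimate_prior(data.frame(s2 = s2, df_resid = d))
  sq <- limma::squeezeVar(s2, df = d)
  expect_equal(pr$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(pr$s02, sq$var.prior, tolerance = 1e-6)
  # and the shrunk posterior variances coincide
  fits <- structure(list(
    fits = data.frame(probe_id = paste0("p", seq_along(s2)),
                      logfc = rnorm(3000), s2 = s2, df_resid = d,
                      p_individual = NA_real_),
    c_g = 0.5, contrast_ages = c(3, 60), rank_deficient = FALSE),
    class = "probe_fits")
  tab <- moderated_t(fits, pr)
  s2_post <- (pr$d0 * pr$s02 + d * s2) / (pr$d0 + d)
  expect_equal(s2_post, sq$var.post, tolerance = 1e-6)
  expect_equal(tab$t, fits$fits$logfc / (sqrt(sq$var.post) * 0.5),
               tolerance = 1e-6)
})

test_that("moderation limits: d0 = 0 gives the classical contrast t,
           d0 = Inf gives full shrinkage", {
  ds <- small_m_dataset(n_ind = 5, ages = c(3, 24, 60), n_probes = 30,
                        seed = 50)
  fits <- fit_probe_models(ds)
  zero_prior <- structure(list(d0 = 0, s02 = 1, n_used = 30),
                          class = "moderation_prior")
  tab0 <- moderated_t(fits, zero_prior)
  classical_t <- fits$fits$logfc / (sqrt(fits$fits$s2) * fits$c_g)
  expect_equal(tab0$t, classical_t, tolerance = 1e-10)
  classical_p <- 2 * pt(abs(classical_t), fits$fits$df_resid,
                        lower.tail = FALSE)
  expect_equal(tab0$p, classical_p, tolerance = 1e-10)

  inf_prior <- structure(list(d0 = Inf, s02 = 0.123, n_used = 30),
                         class = "moderation_prior")
  tabI <- moderated_t(fits, inf_prior)
  expect_equal(tabI$t, fits$fits$logfc / (sqrt(0.123) * fits$c_g),
               tolerance = 1e-12)
})

test_that("|t| is monotone: increasing in |logfc|, decreasing in s2", {
  base <- data.frame(probe_id = paste0("p", 1:4),
                     logfc = c(1, 2, 1, 1), s2 = c(1, 1, 1, 4),
                     df_resid = 10, p_individual = NA_real_)
  fits <- structure(list(fits = base, c_g = 0.4, contrast_ages = c(3, 60),
                         rank_deficient = FALSE), class = "probe_fits")
  prior <- structure(list(d0 = 4, s02 = 1, n_used = 100),
                     class = "moderation_prior")
  tab <- moderated_t(fits, prior)
  expect_gt(abs(tab$t[2]), abs(tab$t[1]))  # larger |logfc|
  expect_lt(abs(tab$t[4]), abs(tab$t[3]))  # larger s2
})

test_that("bonferroni correction is a capped product", {
  expect_equal(bonferroni(1e-8, 485577), 4.85577e-3)
  expect_equal(bonferroni(0.5, 10), 1)
  expect_equal(bonferroni(0, 12345), 0)
  expect_error(bonferroni(1.2, 10), "0, 1")
  expect_error(bonferroni(0.5, 0), "n_tested")
})

test_that("on the standard synthetic run every planted probe keeps its sign
           and the direction rule follows the corrected p", {
  sim <- standard_sim(seed = 2015)
  ds <- convert_scale(sim$dataset, "M")
  fits <- fit_probe_models(ds)
  tab <- moderated_t(fits, estimate_prior(fits))
  planted <- sim$truth[sim$truth$class %in%
                         c("age_methylated", "age_demethylated"), ]
  got <- tab[match(planted$probe_id, tab$probe_id), ]
  expect_true(all(sign(got$logfc) == sign(planted$true_delta_m)))
  # direction call consistency for the whole table
  sig <- tab$p_bonf < attr(tab, "alpha")
  expect_identical(tab$direction == "age_methylated", sig & tab$logfc > 0)
  expect_identical(tab$direction == "age_demethylated", sig & tab$logfc < 0)
})

test_that("full fit matrix agrees with limma's linear-model engine", {
  sim <- generate_dataset(sim_config(n_probes = 200, seed = 61))
  ds <- convert_scale(sim$dataset, "M")
  sm <- ds$samples
  ord <- order(sm$sample_id)
  design <- model.matrix(~ factor(age_months) + factor(individual_id),
                         data = sm[ord, ])
  lf <- limma::lmFit(ds$values[, ord], design)
  fits <- fit_probe_models(ds)
  agecol <- paste0("factor(age_months)", 60)
  expect_equal(fits$fits$logfc, unname(lf$coefficients[, agecol]),
               tolerance = 1e-9)
  expect_equal(fits$fits$s2, unname(lf$sigma^2), tolerance = 1e-9)
  expect_equal(fits$c_g, unname(lf$stdev.unscaled[1, agecol]),
               tolerance = 1e-9)
})
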