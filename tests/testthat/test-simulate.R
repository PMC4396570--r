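test_that("config validation rejects impossible study designs", {
  expect_error(sim_config(seed = NULL), "seed")
  expect_error(sim_config(frac_age_methylated = 0.6,
                          frac_age_demethylated = 0.6, seed = 1),
               "fractions")
  expect_error(sim_config(frac_snp_probes = -0.1, seed = 1), "fractions")
  expect_error(sim_config(timepoints_months = c(3, 3, 6), seed = 1),
               "strictly increasing")
  expect_error(sim_config(n_individuals = 1, seed = 1), "individuals")
  expect_error(sim_config(n_probes = 5, seed = 1), "probes")
})

test_that("same config and seed give bit-identical output", {
  cfg <- sim_config(n_probes = 100, seed = 33)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a, b)
  # manifest alone is also seed-stable
  expect_identical(generate_manifest(cfg, seed = 5),
                   generate_manifest(cfg, seed = 5))
})

test_that("probe classes are exhaustive, exclusive and honour fractions", {
  cfg <- sim_config(n_probes = 1000, seed = 12)
  sim <- generate_dataset(cfg)
  expect_equal(nrow(sim$truth), 1000)
  expect_setequal(unique(sim$truth$class),
                  c("age_methylated", "age_demethylated", "null",
                    "snp_affected", "celltype_confounded"))
  cnt <- table(sim$truth$class)
  expect_equal(unname(cnt["age_methylated"]), 50)
  expect_equal(unname(cnt["age_demethylated"]), 50)
  expect_equal(unname(cnt["snp_affected"]), 20)
  expect_equal(unname(cnt["celltype_confounded"]), 20)
  # no planted effects requested -> no age-labelled rows
  sim0 <- generate_dataset(sim_config(n_probes = 100,
                                      frac_age_methylated = 0,
                                      frac_age_demethylated = 0, seed = 2))
  expect_equal(sum(sim0$truth$class %in%
                     c("age_methylated", "age_demethylated")), 0)
})

test_that("dropout keeps first/last samples and lands near the target rate", {
  cfg <- sim_config(seed = 77)  # 10 individuals x 7 timepoints, 15% dropout
  sim <- generate_dataset(cfg)
  sm <- sim$dataset$samples
  # every individual keeps the 3- and 60-month samples
  for (ind in unique(sm$individual_id)) {
    ages <- sm$age_months[sm$individual_id == ind]
    expect_true(all(c(3, 60) %in% ages))
  }
  # column count is binomial around 70 * 0.85; 5 sd covers any seed
  expect_gt(nrow(sm), 70 * 0.85 - 5 * sqrt(70 * 0.15 * 0.85))
  expect_lt(nrow(sm), 70 * 0.85 + 5 * sqrt(70 * 0.15 * 0.85))
  # and is reproducible
  expect_equal(nrow(generate_dataset(cfg)$dataset$samples), nrow(sm))
})

test_that("null probes are age-flat; planted probes hit their delta-M", {
  sim <- standard_sim(seed = 101)
  M <- sim$m_values
  sm <- sim$dataset$samples
  g <- age_ramp(sm$age_months, c(3, 6, 12, 24, 36, 48, 60))
  first <- sm$age_months == 3; last <- sm$age_months == 60

  nulls <- sim$truth$class == "null"
  # slope of per-timepoint mean-of-null-probe-means against g
  tp_means <- tapply(colMeans(M[nulls, ]), sm$age_months, mean)
  gv <- age_ramp(as.numeric(names(tp_means)), c(3, 6, 12, 24, 36, 48, 60))
  fit <- lm(tp_means ~ gv)
  slope <- coef(summary(fit))["gv", ]
  expect_lt(abs(slope["Estimate"]), 3 * slope["Std. Error"] + 1e-8)

  for (cl in c("age_methylated", "age_demethylated")) {
    idx <- sim$truth$class == cl
    dmean <- rowMeans(M[idx, last, drop = FALSE]) -
      rowMeans(M[idx, first, drop = FALSE])
    want <- if (cl == "age_methylated") 2 else -2
    # per-probe sampling error: two means of ~10 samples at sd ~ 0.7
    expect_equal(mean(dmean), want, tolerance = 0.15)
    expect_true(all(abs(dmean - want) < 1.5))
  }
})

test_that("snp-affected probes are trimodal across individuals, flat in time", {
  sim <- standard_sim(seed = 55)
  sm <- sim$dataset$samples
  snp_idx <- which(sim$truth$class == "snp_affected")
  expect_gt(length(snp_idx), 10)
  g <- age_ramp(sm$age_months, c(3, 6, 12, 24, 36, 48, 60))
  ind <- factor(sm$individual_id)
  within_var <- between_var <- slope <- numeric(length(snp_idx))
  for (i in seq_along(snp_idx)) {
    y <- sim$m_values[snp_idx[i], ]
    mu_i <- tapply(y, ind, mean)
    between_var[i] <- var(mu_i)
    within_var[i] <- mean(tapply(y, ind, var), na.rm = TRUE)
    slope[i] <- coef(lm(y ~ g + ind))["g"]
  }
  # genotype separation (+-1.5 M) dwarfs the 0.5-sd within-individual noise
  # for probes where genotypes actually differ across individuals
  expect_gt(median(between_var / within_var), 3)
  # no systematic time trend
  expect_lt(abs(mean(slope)), 0.15)
  expect_lt(mean(abs(slope) > 0.75), 0.1)
})

test_that("manifest has the documented vocabulary and geometry", {
  cfg <- sim_config(n_probes = 500, seed = 9)
  man <- generate_manifest(cfg, seed = 10)
  mf <- man$probes
  expect_equal(nrow(mf), 500)
  expect_true(all(mf$island_relation %in%
                    c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                      "OpenSea")))
  long <- expand_gene_annotations(mf)
  genic <- long[!is.na(long$gene), ]
  expect_true(all(genic$region %in%
                    c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body",
                      "3'UTR")))
  # annotated genes exist in the gene model, on the probe's chromosome
  expect_true(all(genic$gene %in% man$genes$gene))
  # some probes carry two annotations; all are emitted
  multi <- table(genic$probe_id)
  expect_gt(sum(multi == 2), 0)
  # intergenic probes have an empty gene field
  expect_gt(sum(mf$gene == ""), 0)
  expect_true(all(mf$position >= 1))
})
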