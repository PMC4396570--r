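# Shared fixtures, built in code.

# small longitudinal dataset on the M scale with known structure:
# n_ind individuals x ages, probe values = mu + beta*g(age) + u_i + noise
small_m_dataset <- function(n_ind = 4, ages = c(3, 12, 60), n_probes = 20,
                            sd = 0.3, seed = 1) {
  set.seed(seed)
  samples <- expand.grid(individual = seq_len(n_ind), age = ages)
  sheet <- data.frame(
    sample_id = sprintf("i%02d_a%02d", samples$individual, samples$age),
    individual_id = sprintf("i%02d", samples$individual),
    age_months = samples$age, stringsAsFactors = FALSE)
  m <- matrix(rnorm(n_probes * nrow(sheet), 0, sd), n_probes,
              dimnames = list(sprintf("p%03d", seq_len(n_probes)),
                              sheet$sample_id))
  meth_dataset(m, sheet, scale = "M")
}

# the standard validation conditions: 10 individuals x 7 timepoints,
# 2000 probes, planted delta-M 2, residual and individual sd 0.5
standard_sim <- function(seed = 2015) generate_dataset(sim_config(seed = seed))

# a diffmeth-like table from explicit columns (for filter/region tests)
fake_sig_table <- function(probe_id, logfc,
                           direction = ifelse(logfc > 0, "age_methylated",
                                              ifelse(logfc < 0,
                                                     "age_demethylated",
                                                     "not_significant"))) {
  data.frame(probe_id = probe_id, logfc = logfc,
             t = logfc, p = 1e-9, p_bonf = 1e-6, direction = direction,
             stringsAsFactors = FALSE)
}

# minimal manifest rows
fake_manifest <- function(probe_id, chromosome, position, gene, region,
                          island_relation = "OpenSea",
                          regulatory_feature = "", dhs = FALSE,
                          enhancer = FALSE, dmr_class = "") {
  data.frame(probe_id = probe_id, chromosome = chromosome,
             position = position, island_relation = island_relation,
             gene = gene, region = region,
             regulatory_feature = regulatory_feature, dhs = dhs,
             enhancer = enhancer, dmr_class = dmr_class,
             stringsAsFactors = FALSE)
}
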