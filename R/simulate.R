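# Synthetic longitudinal methylation data with planted ground truth.
# The generator emulates the design of a repeated-sampling early-childhood
# blood study: a small cohort measured at fixed ages, with dropouts, additive
# age effects on the M scale, per-individual offsets, genotype-driven
# trimodal probes, and probes confounded by drifting cell composition.

#' Run code with a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates. The defaults mirror
#' a cohort of ten individuals sampled at 3, 6, 12, 24, 36, 48 and 60
#' months with roughly 15% of planned samples lost to quality control, and
#' the effect and noise scales used throughout this package's validation:
#' a planted first-to-last M-value change of 2 against residual and
#' between-individual standard deviations of 0.5.
#'
#' @param n_individuals number of individuals (>= 2).
#' @param timepoints_months strictly increasing ages in months.
#' @param dropout_rate expected fraction of individual-by-timepoint samples
#'   removed. An individual's first and last samples are never removed, so
#'   the first-vs-last contrast stays estimable; the removal probability of
#'   interior samples is scaled up so the overall expected fraction matches.
#' @param n_probes number of probes (>= 10).
#' @param frac_age_methylated,frac_age_demethylated,frac_snp_probes,frac_celltype_probes
#'   fractions of probes planted in each class; must be non-negative and sum
#'   to at most 1. The remainder are null probes.
#' @param effect_delta_m planted M-value change from the first to the last
#'   timepoint (positive; the sign is set by the probe class).
#' @param sigma_resid residual standard deviation on the M scale.
#' @param sigma_individual standard deviation of the per-individual offset.
#' @param seed integer RNG seed; required, so every dataset is reproducible.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 10,
                       timepoints_months = c(3, 6, 12, 24, 36, 48, 60),
                       dropout_rate = 0.15,
                       n_probes = 2000,
                       frac_age_methylated = 0.05,
                       frac_age_demethylated = 0.05,
                       frac_snp_probes = 0.02,
                       frac_celltype_probes = 0.02,
                       effect_delta_m = 2,
                       sigma_resid = 0.5,
                       sigma_individual = 0.5,
                       seed = NULL) {
  if (is.null(seed) || is.na(seed)) {
    stop("'seed' is required: the generator is only meaningful reproducibly")
  }
  fr <- c(frac_age_methylated, frac_age_demethylated,
          frac_snp_probes, frac_celltype_probes)
  if (any(fr < 0) || sum(fr) > 1) {
    stop("probe-class fractions must be non-negative and sum to at most 1")
  }
  if (any(diff(timepoints_months) <= 0)) {
    stop("timepoints_months must be strictly increasing")
  }
  if (n_individuals < 2) stop("need at least 2 individuals")
  if (n_probes < 10) stop("need at least 10 probes")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate in [0, 1)")
  if (effect_delta_m < 0) stop("effect_delta_m must be non-negative")
  structure(list(
    n_individuals = as.integer(n_individuals),
    timepoints_months = as.numeric(timepoints_months),
    dropout_rate = dropout_rate,
    n_probes = as.integer(n_probes),
    frac_age_methylated = frac_age_methylated,
    frac_age_demethylated = frac_age_demethylated,
    frac_snp_probes = frac_snp_probes,
    frac_celltype_probes = frac_celltype_probes,
    effect_delta_m = effect_delta_m,
    sigma_resid = sigma_resid,
    sigma_individual = sigma_individual,
    seed = as.integer(seed)), class = "sim_config")
}

#' Age ramp: linear in log2(age), normalized to [0, 1]
#'
#' Methylation trajectories in early childhood change fastest in infancy;
#' a log-age ramp front-loads the planted change accordingly. Normalized so
#' `g(last) - g(first) = 1`, making the planted first-to-last contrast
#' exactly `effect_delta_m`.
#'
#' @param age_months numeric ages.
#' @param timepoints the configured timepoints (first/last set the range).
#' @return values in `[0, 1]`.
#' @export
age_ramp <- function(age_months, timepoints) {
  lo <- log2(timepoints[1]); hi <- log2(timepoints[length(timepoints)])
  (log2(age_months) - lo) / (hi - lo)
}

#' Generate a synthetic longitudinal methylation dataset
#'
#' Draws M values as `mu_p + beta_p * g(age) + u_i + eps`, where `g` is the
#' normalized log-age ramp ([age_ramp()]), `beta_p` is the signed planted
#' effect for age-modified probes and 0 otherwise, `u_i` is a per-individual
#' offset and `eps` exchangeable residual noise. SNP-affected probes get a
#' per-individual genotype drawn under Hardy-Weinberg at the tabulated MAF,
#' mapped to three baseline M levels (heterozygote midway) and constant over
#' time. Cell-confounded probes get an additive term proportional to a
#' simulated granulocyte fraction that drifts with age. Betas are the
#' inverse-logit2 of the M values.
#'
#' The same config (which carries the seed) always produces bit-identical
#' output.
#'
#' @param config a [sim_config()].
#' @return list with elements:
#'   \describe{
#'     \item{dataset}{[meth_dataset()] of beta values}
#'     \item{m_values}{the underlying M-value matrix (pre inverse-logit)}
#'     \item{truth}{data.frame `probe_id`, `class`, `true_delta_m`}
#'     \item{manifest}{probe annotation data.frame (see [generate_manifest()])}
#'     \item{gene_model}{data.frame `gene`, `chromosome`, `tss`, `strand`}
#'     \item{snps}{SNP table data.frame}
#'     \item{classifier}{character vector of cell-type classifier probe ids}
#'     \item{gene_sets}{named list of gene sets (one planted age-enriched)}
#'   }
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    tp <- config$timepoints_months
    n_ind <- config$n_individuals
    n_tp <- length(tp)

    # sample layout with protected first/last timepoints
    grid <- expand.grid(individual = seq_len(n_ind), timepoint = seq_len(n_tp))
    interior <- grid$timepoint != 1 & grid$timepoint != n_tp
    p_int <- if (any(interior))
      min(1, config$dropout_rate * nrow(grid) / sum(interior)) else 0
    drop <- interior & stats::runif(nrow(grid)) < p_int
    grid <- grid[!drop, , drop = FALSE]
    grid <- grid[order(grid$individual, grid$timepoint), , drop = FALSE]
    samples <- data.frame(
      sample_id = sprintf("ind%02d_t%02d", grid$individual, tp[grid$timepoint]),
      individual_id = sprintf("ind%02d", grid$individual),
      age_months = tp[grid$timepoint],
      stringsAsFactors = FALSE)
    n_s <- nrow(samples)
    g <- age_ramp(samples$age_months, tp)

    # probe classes
    n_p <- config$n_probes
    n_meth <- round(config$frac_age_methylated * n_p)
    n_demeth <- round(config$frac_age_demethylated * n_p)
    n_snp <- round(config$frac_snp_probes * n_p)
    n_cell <- round(config$frac_celltype_probes * n_p)
    cls <- rep("null", n_p)
    idx <- sample.int(n_p)  # shuffle so classes are interleaved along the array
    take <- function(k) { out <- idx[seq_len(k)]; idx <<- idx[-seq_len(k)]; out }
    i_meth <- if (n_meth) take(n_meth) else integer(0)
    i_demeth <- if (n_demeth) take(n_demeth) else integer(0)
    i_snp <- if (n_snp) take(n_snp) else integer(0)
    i_cell <- if (n_cell) take(n_cell) else integer(0)
    cls[i_meth] <- "age_methylated"
    cls[i_demeth] <- "age_demethylated"
    cls[i_snp] <- "snp_affected"
    cls[i_cell] <- "celltype_confounded"
    probe_ids <- sprintf("cg%08d", seq_len(n_p))

    # baseline M: bimodal plus an intermediate component, like array data
    comp <- sample(1:3, n_p, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    mu <- c(-3, 3, 0)[comp] + stats::rnorm(n_p, 0, c(1, 1, 1.5)[comp])

    beta_p <- numeric(n_p)
    beta_p[i_meth] <- config$effect_delta_m
    beta_p[i_demeth] <- -config$effect_delta_m

    u <- stats::rnorm(n_ind, 0, config$sigma_individual)
    u_s <- u[grid$individual]

    M <- matrix(mu, n_p, n_s) +
      outer(beta_p, g) +
      matrix(rep(u_s, each = n_p), n_p, n_s) +
      matrix(stats::rnorm(n_p * n_s, 0, config$sigma_resid), n_p, n_s)

    # SNP-affected probes: genotype-set baseline, constant in time.
    # MAF above the conventional 0.01 filter threshold so these probes are
    # the ones a MAF filter should catch.
    snp_maf <- stats::runif(n_snp, 0.05, 0.5)
    geno_shift <- 1.5
    for (k in seq_along(i_snp)) {
      q <- snp_maf[k]
      geno <- sample(0:2, n_ind, replace = TRUE,
                     prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
      M[i_snp[k], ] <- mu[i_snp[k]] + (geno[grid$individual] - 1) * geno_shift +
        stats::rnorm(n_s, 0, config$sigma_resid)
    }

    # cell-confounded probes: additive loading on a granulocyte fraction
    # that drifts upward with age (so confounding mimics an age effect)
    gran <- pmin(pmax(0.35 + 0.25 * g + stats::rnorm(n_s, 0, 0.05), 0.05), 0.95)
    cell_load <- sample(c(-1, 1), n_cell, replace = TRUE) * stats::runif(n_cell, 2, 4)
    if (n_cell > 0) {
      M[i_cell, ] <- M[i_cell, , drop = FALSE] +
        outer(cell_load, gran - mean(gran))
    }

    dimnames(M) <- list(probe_ids, samples$sample_id)
    beta_vals <- m_to_beta(M)

    truth <- data.frame(probe_id = probe_ids, class = cls,
                        true_delta_m = beta_p, stringsAsFactors = FALSE)

    man <- generate_manifest(config, seed = config$seed + 1L)

    snps <- data.frame(probe_id = character(0),
                       distance_to_query_bp = integer(0),
                       maf = numeric(0), stringsAsFactors = FALSE)
    if (n_snp > 0) {
      snps <- data.frame(
        probe_id = probe_ids[i_snp],
        distance_to_query_bp = sample(0:49, n_snp, replace = TRUE),
        maf = snp_maf, stringsAsFactors = FALSE)
    }
    # also tabulate rare SNPs (MAF <= 0.01) on a few null probes: these must
    # survive the strict "above threshold" filter
    n_rare <- min(length(which(cls == "null")), max(0L, n_snp))
    if (n_rare > 0) {
      rare_idx <- sample(which(cls == "null"), n_rare)
      snps <- rbind(snps, data.frame(
        probe_id = probe_ids[rare_idx],
        distance_to_query_bp = sample(0:49, n_rare, replace = TRUE),
        maf = stats::runif(n_rare, 0, 0.01), stringsAsFactors = FALSE))
    }

    classifier <- probe_ids[i_cell]

    gene_sets <- generate_gene_sets(man$probes, truth, seed = config$seed + 2L)

    list(dataset = meth_dataset(beta_vals, samples, scale = "beta"),
         m_values = M,
         truth = truth,
         manifest = man$probes,
         gene_model = man$genes,
         snps = snps,
         classifier = classifier,
         gene_sets = gene_sets)
  })
}

#' Generate a probe annotation manifest and gene model
#'
#' Assigns each probe a chromosome (1-22), 1-based position, CpG-island
#' relation, zero or more (gene, region) annotations — about 70% of probes
#' are genic, and a minority carry two transcript annotations, all of which
#' downstream counts use — plus regulatory-feature strings, DHS/enhancer
#' flags and a DMR class. A gene model of TSS positions with strand is
#' returned alongside, with probe positions laid out around their gene's
#' TSS consistently with the annotated region.
#'
#' @param config a [sim_config()] (only `n_probes` is used).
#' @param seed RNG seed for the manifest draw.
#' @return list with `probes` (manifest data.frame) and `genes`
#'   (gene model data.frame: `gene`, `chromosome`, `tss`, `strand`).
#' @export
generate_manifest <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    n_p <- config$n_probes
    n_genes <- max(20L, round(n_p / 10))
    chrom_w <- 23 - (1:22)           # larger chromosomes hold more genes
    gene_chr <- sample(1:22, n_genes, replace = TRUE, prob = chrom_w)
    # genes cluster along the genome: about half are placed within 200 kb
    # of an earlier gene on the same chromosome, so neighbouring/overlapping
    # transcripts exist as they do on real arrays
    tss <- integer(n_genes)
    for (i in seq_len(n_genes)) {
      earlier <- which(gene_chr[seq_len(i - 1)] == gene_chr[i])
      if (length(earlier) > 0 && stats::runif(1) < 0.5) {
        anchor <- tss[sample(earlier, 1)]
        tss[i] <- max(1L, anchor + sample(c(-1, 1), 1) * sample.int(2e5, 1))
      } else {
        tss[i] <- sample.int(2e8, 1)
      }
    }
    genes <- data.frame(
      gene = sprintf("GENE%04d", seq_len(n_genes)),
      chromosome = paste0("chr", gene_chr),
      tss = tss,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      stringsAsFactors = FALSE)

    probe_ids <- sprintf("cg%08d", seq_len(n_p))
    genic <- stats::runif(n_p) < 0.7
    region_vocab <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR")
    region_prob <- c(0.15, 0.10, 0.10, 0.05, 0.45, 0.15)
    offset_for <- function(region) {
      # bp offset from the TSS in gene orientation
      switch(region,
        "TSS1500" = -sample(201:1500, 1),
        "TSS200"  = -sample(1:200, 1),
        "5'UTR"   = sample(1:500, 1),
        "1stExon" = sample(501:1000, 1),
        "Body"    = sample(1001:50000, 1),
        "3'UTR"   = sample(50001:52000, 1))
    }

    chromosome <- character(n_p); position <- integer(n_p)
    gene_field <- character(n_p); region_field <- character(n_p)
    for (i in seq_len(n_p)) {
      if (genic[i]) {
        gi <- sample.int(n_genes, 1)
        reg <- sample(region_vocab, 1, prob = region_prob)
        off <- offset_for(reg)
        pos <- if (genes$strand[gi] == "+") genes$tss[gi] + off
               else genes$tss[gi] - off
        gs <- genes$gene[gi]; rs <- reg
        if (stats::runif(1) < 0.1) {
          # isoform/antisense second annotation: nearest other gene on the
          # same chromosome, only if it is genuinely local (< 1 Mb)
          same_chr <- which(genes$chromosome == genes$chromosome[gi])
          same_chr <- setdiff(same_chr, gi)
          if (length(same_chr) > 0) {
            gj <- same_chr[which.min(abs(genes$tss[same_chr] - genes$tss[gi]))]
            if (abs(genes$tss[gj] - genes$tss[gi]) < 1e6) {
              gs <- c(gs, genes$gene[gj])
              rs <- c(rs, sample(region_vocab, 1, prob = region_prob))
            }
          }
        }
        chromosome[i] <- genes$chromosome[gi]
        position[i] <- max(1L, as.integer(pos))
        gene_field[i] <- paste(gs, collapse = ";")
        region_field[i] <- paste(rs, collapse = ";")
      } else {
        chromosome[i] <- paste0("chr", sample(1:22, 1, prob = chrom_w))
        position[i] <- sample.int(2e8, 1)
        gene_field[i] <- ""
        region_field[i] <- ""
      }
    }

    island_vocab <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                      "OpenSea")
    island <- sample(island_vocab, n_p, replace = TRUE,
                     prob = c(0.31, 0.12, 0.11, 0.05, 0.05, 0.36))
    promoter_like <- region_field %in% c("TSS200", "TSS1500") |
      grepl("^TSS", region_field)
    regulatory <- ifelse(promoter_like & stats::runif(n_p) < 0.6,
                         "Promoter_Associated",
                         ifelse(stats::runif(n_p) < 0.1,
                                "Unclassified_Cell_type_specific", ""))
    dmr <- sample(c("", "c-DMR", "r-DMR"), n_p, replace = TRUE,
                  prob = c(0.9, 0.04, 0.06))
    probes <- data.frame(
      probe_id = probe_ids,
      chromosome = chromosome,
      position = position,
      island_relation = island,
      gene = gene_field,
      region = region_field,
      regulatory_feature = regulatory,
      dhs = stats::runif(n_p) < 0.2,
      enhancer = stats::runif(n_p) < 0.25,
      dmr_class = dmr,
      stringsAsFactors = FALSE)
    list(probes = probes, genes = genes)
  })
}

#' Generate synthetic gene sets (GMT-style) with one planted enriched set
#'
#' Random sets drawn from the manifest's gene universe, plus one set
#' (`AGE_PLANTED`) built preferentially from genes hosting planted
#' age-modified probes, so enrichment machinery can be validated against
#' known truth.
#'
#' @param manifest probe annotation data.frame.
#' @param truth truth table from [generate_dataset()].
#' @param seed RNG seed.
#' @param n_sets number of random sets besides the planted one.
#' @return named list of character gene vectors.
#' @export
generate_gene_sets <- function(manifest, truth, seed, n_sets = 20) {
  with_seed(seed, {
    long <- expand_gene_annotations(manifest)
    universe <- sort(unique(long$gene[!is.na(long$gene)]))
    sets <- lapply(seq_len(n_sets), function(i) {
      sz <- sample(10:min(60, length(universe)), 1)
      sample(universe, sz)
    })
    names(sets) <- sprintf("RANDOM_SET_%02d", seq_len(n_sets))
    age_probes <- truth$probe_id[truth$class %in%
                                   c("age_methylated", "age_demethylated")]
    age_genes <- unique(long$gene[long$probe_id %in% age_probes &
                                    !is.na(long$gene)])
    if (length(age_genes) >= 5) {
      k <- max(5, round(0.8 * length(age_genes)))
      planted <- sample(age_genes, min(k, length(age_genes)))
      filler <- sample(setdiff(universe, planted),
                       min(5, length(setdiff(universe, planted))))
      sets$AGE_PLANTED <- unique(c(planted, filler))
    }
    sets
  })
}

#' Write all simulated artifacts to a directory
#'
#' Emits the file formats the reading side of the package understands:
#' beta matrix TSV, sample sheet CSV, manifest CSV, gene model CSV, SNP
#' table CSV, classifier list (one id per line), gene sets GMT and truth
#' table TSV.
#'
#' @param sim result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_simulated_data <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    matrix = file.path(dir, "beta_matrix.tsv"),
    samples = file.path(dir, "sample_sheet.csv"),
    manifest = file.path(dir, "manifest.csv"),
    gene_model = file.path(dir, "gene_model.csv"),
    snps = file.path(dir, "snp_table.csv"),
    classifier = file.path(dir, "celltype_classifier.txt"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "truth.tsv"))
  write_matrix_tsv(sim$dataset$values, paths["matrix"])
  utils::write.csv(sim$dataset$samples, paths["samples"], row.names = FALSE)
  utils::write.csv(sim$manifest, paths["manifest"], row.names = FALSE)
  utils::write.csv(sim$gene_model, paths["gene_model"], row.names = FALSE)
  utils::write.csv(sim$snps, paths["snps"], row.names = FALSE)
  writeLines(sim$classifier, paths["classifier"])
  write_gmt(sim$gene_sets, paths["gene_sets"])
  write_table_tsv(sim$truth, paths["truth"])
  invisible(paths)
}
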