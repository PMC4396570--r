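test_that("nearest TSS: sign follows strand, bins follow absolute distance", {
  gm <- data.frame(gene = "G1", chromosome = "chr1", tss = 10000,
                   strand = "+")
  pr <- data.frame(probe_id = "p1", chromosome = "chr1", position = 10500)
  td <- nearest_tss(pr, gm)
  expect_equal(td$signed_distance_bp, 500)
  expect_equal(as.character(td$bin), "[0,5kb)")

  gm2 <- data.frame(gene = "G2", chromosome = "chr1", tss = 70000,
                    strand = "+")
  pr2 <- data.frame(probe_id = "p2", chromosome = "chr1", position = 10000)
  td2 <- nearest_tss(pr2, gm2)
  expect_equal(td2$signed_distance_bp, -60000)  # upstream of a + gene
  expect_equal(as.character(td2$bin), "[50,500kb)")

  # minus strand flips the sign convention
  gm3 <- data.frame(gene = "G3", chromosome = "chr1", tss = 10000,
                    strand = "-")
  td3 <- nearest_tss(pr, gm3)  # probe at 10500, downstream would be < tss
  expect_equal(td3$signed_distance_bp, -500)

  # beyond the 1,000 kb window: flagged, not assigned
  far <- data.frame(probe_id = "p4", chromosome = "chr1", position = 2e6 + 1)
  td4 <- nearest_tss(far, gm)
  expect_true(td4$no_tss)
  expect_true(is.na(td4$nearest_gene))

  # exact-distance tie broken toward the gene the probe is upstream of
  gm5 <- data.frame(gene = c("A", "B"), chromosome = "chr1",
                    tss = c(900, 1100), strand = c("+", "+"))
  pr5 <- data.frame(probe_id = "p5", chromosome = "chr1", position = 1000)
  td5 <- nearest_tss(pr5, gm5)
  expect_equal(td5$nearest_gene, "B")
  expect_equal(td5$signed_distance_bp, -100)
})

test_that("nearest TSS matches the all-pairs minimum oracle", {
  set.seed(91)
  gm <- data.frame(gene = sprintf("G%02d", 1:10),
                   chromosome = sample(c("chr1", "chr2"), 10, replace = TRUE),
                   tss = sample.int(3e6, 10),
                   strand = sample(c("+", "-"), 10, replace = TRUE))
  pr <- data.frame(probe_id = sprintf("p%03d", 1:100),
                   chromosome = sample(c("chr1", "chr2"), 100,
                                       replace = TRUE),
                   position = sample.int(3e6, 100))
  got <- nearest_tss(pr, gm)
  for (i in 1:100) {
    same <- gm[gm$chromosome == pr$chromosome[i], ]
    d <- abs(pr$position[i] - same$tss)
    if (nrow(same) == 0 || min(d) > 1e6) {
      expect_true(got$no_tss[i])
    } else {
      expect_equal(got$abs_distance_bp[i], min(d))
    }
  }
  # binned fractions over probes with a hit sum to 1
  hit <- got[!got$no_tss, ]
  expect_equal(sum(table(hit$bin)) / nrow(hit), 1)
})

test_that("location distributions use all annotations with hand-counted
           fractions", {
  mf <- fake_manifest(
    paste0("p", 1:6), "chr1", (1:6) * 100,
    gene = c("A;B", "A", "", "C", "C;C", "D"),
    region = c("Body;Body", "TSS200", "", "Body", "Body;5'UTR", "TSS1500"),
    island_relation = c("Island", "Island", "OpenSea", "N_Shore",
                        "OpenSea", "S_Shelf"),
    regulatory_feature = c("", "Promoter_Associated", "", "", "",
                           "Promoter_Associated_Cell_type_specific"),
    dhs = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  sig <- fake_sig_table(paste0("p", 1:6), c(1, 1, 1, -1, -1, -1))
  ld <- location_distribution(sig, mf)
  gs_m <- ld[ld$group == "age_methylated" &
               ld$category_type == "gene_structure", ]
  # methylated: p1 Body+Body, p2 TSS200, p3 Intergenic -> 4 annotations
  expect_equal(gs_m$denominator[1], 4)
  expect_equal(gs_m$count[gs_m$category == "Body"], 2)
  expect_equal(gs_m$count[gs_m$category == "TSS200"], 1)
  expect_equal(gs_m$count[gs_m$category == "Intergenic"], 1)
  gs_d <- ld[ld$group == "age_demethylated" &
               ld$category_type == "gene_structure", ]
  # demethylated: p4 Body, p5 Body+5'UTR, p6 TSS1500 -> 4 annotations
  expect_equal(gs_d$count[gs_d$category == "Body"], 2)
  expect_equal(gs_d$count[gs_d$category == "5'UTR"], 1)
  # island fractions are per probe and sum to 1 over the vocabulary
  isl <- ld[ld$category_type == "island_relation", ]
  for (gp in unique(isl$group)) {
    expect_equal(sum(isl$fraction[isl$group == gp]), 1)
  }
  expect_equal(isl$count[isl$group == "age_methylated" &
                           isl$category == "Island"], 2)
  # regulatory flags are per probe
  reg <- ld[ld$category_type == "regulatory", ]
  expect_equal(reg$count[reg$group == "age_demethylated" &
                           reg$category == "promoter_associated"], 1)
  expect_equal(reg$count[reg$group == "age_methylated" &
                           reg$category == "dhs"], 1)
  # unknown categories are rejected
  bad <- mf; bad$island_relation[1] <- "Lagoon"
  expect_error(location_distribution(sig, bad), "unknown island")
})

test_that("chromosome distribution: exact match gives r = 1, proportional
           sampling stays highly correlated, degenerate input flagged", {
  mf <- fake_manifest(sprintf("p%03d", 1:300),
                      rep(paste0("chr", 1:6), times = c(80, 70, 60, 40,
                                                        30, 20)),
                      1:300, gene = "", region = "")
  # observed == expected: take every probe as significant
  sig_all <- fake_sig_table(mf$probe_id, rep(1, 300))
  cd <- chromosome_distribution(sig_all, mf)
  expect_equal(cd$pearson_r, 1)
  expect_equal(cd$table$observed_fraction, cd$table$expected_fraction)
  # seeded proportional subset
  set.seed(92)
  sub <- fake_sig_table(sample(mf$probe_id, 120), rep(1, 120))
  expect_gt(chromosome_distribution(sub, mf)$pearson_r, 0.9)
  # single chromosome: undefined correlation
  mf1 <- mf[mf$chromosome == "chr1", ]
  sig1 <- fake_sig_table(mf1$probe_id[1:10], rep(1, 10))
  expect_warning(cd1 <- chromosome_distribution(sig1, mf1), "fewer than 2")
  expect_true(is.na(cd1$pearson_r))
  # probe missing from the manifest is an error
  stray <- fake_sig_table("ghost", 1)
  expect_error(chromosome_distribution(stray, mf), "ghost")
})
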