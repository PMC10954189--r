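test_that("ZW bookkeeping holds: Z allele count is 2 minus is_female", {
  st <- simulate_study(small_config(seed = 21))
  zmk <- st$map$marker[st$map$chrom == "chrZ"]
  g <- st$genotypes
  zf <- as.matrix(g[g$sex == "female", zmk])
  zm <- as.matrix(g[g$sex == "male", zmk])
  expect_true(all(zf %in% 0:1))
  expect_true(all(zm %in% 0:2))
  amk <- st$map$marker[st$map$chrom != "chrZ"]
  expect_true(all(as.matrix(g[, amk]) %in% 0:2))
  expect_equal(sum(g$sex == "male"), 69)
  expect_equal(sum(g$sex == "female"), 55)
})

test_that("with recombination suppressed every haplotype is a founder haplotype", {
  # a chromosome of (almost) zero genetic length cannot recombine, so each
  # individual's genotype must be constant across its markers
  cfg <- sim_config(
    seed = 4,
    chromosomes = tibble::tibble(name = "chr1", length_cm = 1e-9,
                                 length_bp = 2e4, is_z = FALSE),
    n_windows_per_chrom = 20, n_markers_per_chrom = 8
  )
  g <- simulate_pedigree(cfg)
  mk <- sprintf("chr1_m%02d", 1:8)
  gm <- as.matrix(g[, mk])
  expect_true(all(apply(gm, 1, function(x) length(unique(x)) == 1)))
})

test_that("autosomal wild-allele frequency matches the founder-weighted expectation", {
  # every F1 receives the wild sire's gamete, so the F1 (and expected F8)
  # autosomal wild-allele frequency is 0.5; the tolerance combines binomial
  # sampling in the final draw with drift over the 6 post-F1 transitions
  cfg <- sim_config(
    seed = 2026, n_males = 5000, n_females = 5000, pop_size = 2000,
    chromosomes = tibble::tibble(name = "chr1", length_cm = 50,
                                 length_bp = 1e4, is_z = FALSE),
    n_markers_per_chrom = 1, n_windows_per_chrom = 10
  )
  g <- simulate_pedigree(cfg)
  freq <- mean(g$chr1_m01) / 2
  se <- sqrt(0.25 * (6 / (2 * 2000) + 1 / (2 * 10000)))
  expect_lt(abs(freq - 0.5), 3 * se)
})

test_that("identical configurations reproduce bit-identical studies", {
  cfg <- small_config(seed = 77, planted = list(
    planted_effect("MHM_block",
                   block_windows = window_id("chrZ", seq(0, 7000, by = 1000)),
                   male_multiplier = 3.3)
  ))
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$methylation, s2$methylation)
  expect_identical(s1$expression, s2$expression)
})

test_that("noise-free generation returns the per-window baseline exactly", {
  cfg <- small_config(seed = 5, n_autosomes = 1, dispersion = 0,
                      baseline_sd = 0, batch_effect = 0, indiv_sd = 0)
  st <- simulate_study(cfg)
  raw <- denormalize_methylation(st$methylation)
  vals <- as.matrix(raw[raw$chrom == "chr1", value_cols(raw)])
  base <- round(cfg$mean_coverage * cfg$window_size_bp / cfg$read_length)
  expect_true(all(vals == base))
})

test_that("a planted MHM block realizes its male:female fold in raw counts", {
  blockw <- window_id("chr1", seq(5000, 12000, by = 1000))
  cfg <- small_config(seed = 9, n_males = 400, n_females = 400,
                      batch_effect = 0, planted = list(
                        planted_effect("MHM_block", block_windows = blockw,
                                       male_multiplier = 3.3)
                      ))
  st <- simulate_study(cfg)
  raw <- denormalize_methylation(st$methylation)
  vals <- as.matrix(raw[raw$window_id %in% blockw, value_cols(raw)])
  sex <- st$samples$sex[match(colnames(vals), st$samples$id)]
  ratio <- mean(rowMeans(vals[, sex == "male"])) /
    mean(rowMeans(vals[, sex == "female"]))
  expect_lt(abs(ratio - 3.3) / 3.3, 0.10)
})

test_that("a zero-effect methQTL leaves marker-window associations null-calibrated", {
  cfg <- small_config(seed = 31, n_windows = 100, planted = list(
    planted_effect("cis_methQTL", target = "chr1_5000",
                   source_marker = "chr1_m03", additive_effect = 0)
  ))
  st <- simulate_study(cfg)
  d <- st$genotypes$chr1_m03
  sexf <- factor(st$samples$sex)
  m <- as.matrix(st$methylation[st$methylation$chrom != "chrZ",
                                st$genotypes$id])
  pvals <- apply(m, 1, function(y) {
    summary(lm(y ~ d + sexf))$coefficients["d", "Pr(>|t|)"]
  })
  # autosomal windows are unlinked to any effect: rejection rate ~ alpha
  alpha <- 0.05
  se <- sqrt(alpha * (1 - alpha) / length(pvals))
  expect_lt(abs(mean(pvals < alpha) - alpha), 3 * se + 0.01)
})

test_that("planted effects that would drive the mean negative are rejected", {
  cfg <- small_config(seed = 6, planted = list(
    planted_effect("cis_methQTL", target = "chr1_0",
                   source_marker = "chr1_m01", additive_effect = -0.9)
  ))
  expect_error(simulate_study(cfg), "negative mean")
})

test_that("expression couplings and sex-interaction cancellation behave as planted", {
  # meth -> expr coupling of zero leaves expression independent of methylation
  cfg0 <- small_config(seed = 15, planted = list(
    planted_effect("eQTL", target = "ps_001", coupling_window = "chr1_3000",
                   coupling_coef = 0, direction = "meth_to_expr")
  ))
  st0 <- simulate_study(cfg0)
  e <- as.numeric(st0$expression[st0$expression$probeset == "ps_001",
                                 st0$genotypes$id])
  m <- as.numeric(st0$methylation[st0$methylation$window_id == "chr1_3000",
                                  st0$genotypes$id])
  expect_lt(abs(cor(e, m)), 0.25)

  # equal-magnitude opposite-sign per-sex slopes cancel in the pooled fit
  cfg1 <- small_config(seed = 16, n_males = 300, n_females = 300, planted = list(
    planted_effect("eQTL", target = "ps_001", source_marker = "chr1_m05",
                   additive_effect = 0, sex_interaction_effect = 1)
  ))
  st1 <- simulate_study(cfg1)
  e <- log2(as.numeric(st1$expression[st1$expression$probeset == "ps_001",
                                      st1$genotypes$id]))
  d <- st1$genotypes$chr1_m05
  sex <- st1$samples$sex
  pooled <- coef(lm(e ~ d))["d"]
  b_male <- coef(lm(e[sex == "male"] ~ d[sex == "male"]))[2]
  b_female <- coef(lm(e[sex == "female"] ~ d[sex == "female"]))[2]
  expect_gt(b_male, 0.2)
  expect_lt(b_female, -0.2)
  expect_lt(abs(pooled), 0.15)
})

test_that("a planted G -> M -> E chain shows partial-correlation attenuation", {
  cfg <- small_config(seed = 18, n_males = 300, n_females = 300, planted = list(
    planted_effect("cis_methQTL", target = "chr1_4000",
                   source_marker = "chr1_m04", additive_effect = 0.5),
    planted_effect("eQTL", target = "ps_001", coupling_window = "chr1_4000",
                   coupling_coef = 1, direction = "meth_to_expr")
  ))
  st <- simulate_study(cfg)
  ids <- st$genotypes$id
  g <- st$genotypes$chr1_m04
  m <- as.numeric(st$methylation[st$methylation$window_id == "chr1_4000", ids])
  e <- log2(as.numeric(st$expression[st$expression$probeset == "ps_001", ids]))
  marginal <- cor(g, e)
  partial <- cor(resid(lm(g ~ m)), resid(lm(e ~ m)))
  expect_gt(abs(marginal), 0.2)
  expect_lt(abs(partial), abs(marginal) / 2)
})

test_that("a study round-trips through its TSV export", {
  st <- simulate_study(small_config(seed = 41, n_windows = 10))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  back <- read_meth_matrix(file.path(dir, "methylation.tsv"))
  ord <- order(st$methylation$chrom, st$methylation$start)
  expect_equal(back$window_id, st$methylation$window_id[ord])
  samples <- read_sample_sheet(file.path(dir, "samples.tsv"))
  expect_identical(samples$sex, st$samples$sex)
})
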