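# A minimal deterministic map for constructed-genotype tests.
toy_map <- function(n_mark = 3, chrom = "chr1", spacing_cm = 20,
                    spacing_bp = 1e6, is_z = FALSE) {
  tibble::tibble(
    marker = sprintf("%s_m%02d", chrom, seq_len(n_mark)),
    chrom = chrom,
    cm = (seq_len(n_mark) - 1) * spacing_cm,
    bp = (seq_len(n_mark) - 1) * spacing_bp,
    is_z = is_z
  )
}

toy_genotypes <- function(gmat, sex = rep("male", nrow(gmat)),
                          map = toy_map(ncol(gmat))) {
  colnames(gmat) <- map$marker
  dplyr::bind_cols(
    tibble::tibble(id = sprintf("ind_%03d", seq_len(nrow(gmat))),
                   sex = sex,
                   batch = rep(c("b1", "b2"), length.out = nrow(gmat))),
    tibble::as_tibble(gmat)
  )
}

test_that("genotype probabilities are degenerate at typed markers", {
  map <- toy_map(3)
  g <- toy_genotypes(matrix(c(0, 1, 2, 2, 1, 0), 2, 3, byrow = TRUE))
  pr <- genotype_probs(g, map, step = 5)
  cc <- pr$chroms$chr1
  for (k in 1:3) {
    j <- which(cc$grid$pos_cm == map$cm[k])
    obs <- as.matrix(g[, map$marker])[, k]
    expect_equal(cc$probs[cbind(1:2, j, obs + 1)], c(1, 1))
  }
  expect_equal(apply(cc$probs, c(1, 2), sum), matrix(1, 2, ncol(cc$dosage)))
})

test_that("midpoint probabilities equal the explicit transition-matrix product", {
  map <- toy_map(2, spacing_cm = 20)
  g <- toy_genotypes(matrix(c(0, 0), 1, 2))
  pr <- genotype_probs(g, map, step = 10)
  cc <- pr$chroms$chr1
  j <- which(cc$grid$pos_cm == 10)
  r10 <- 0.5 * (1 - exp(-2 * 10 / 100))
  T10 <- zmethqtl:::trans3(r10)
  oracle <- T10[1, ] * T10[, 1]
  oracle <- oracle / sum(oracle)
  expect_equal(cc$probs[1, j, ], oracle, tolerance = 1e-12)
})

test_that("female Z pseudomarkers carry exactly two states summing to one", {
  map <- toy_map(3, chrom = "chrZ", is_z = TRUE)
  gmat <- matrix(c(0, 1, 1, 2, 1, 0), 2, 3, byrow = TRUE)
  gmat[1, ] <- c(0, 1, 1)   # female, hemizygous codes
  g <- toy_genotypes(gmat, sex = c("female", "male"), map = map)
  pr <- genotype_probs(g, map, step = 1)
  cc <- pr$chroms$chrZ
  expect_true(all(cc$probs[1, , 3] == 0))
  expect_equal(rowSums(cc$probs[1, , ]), rep(1, nrow(cc$grid)))
  expect_true(all(cc$dosage[1, ] <= 1 + 1e-12))
})

test_that("single-marker scans equal the explicit least-squares oracle", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(40:124, 1)
    map <- toy_map(2, spacing_cm = 30)
    gmat <- cbind(rbinom(n, 2, 0.5), rbinom(n, 2, 0.5))
    sex <- sample(c("male", "female"), n, replace = TRUE)
    g <- toy_genotypes(gmat, sex = sex, map = map)
    samples <- g[, c("id", "sex", "batch")]
    y <- rnorm(n) + 0.3 * gmat[, 1] + 0.2 * (sex == "male")
    pr <- genotype_probs(g, map, step = 30)
    sc <- scan_qtl(pr, setNames(y, g$id), samples)
    X0 <- cbind(1, sex == "male", g$batch == "b2")
    for (k in 1:2) {
      j <- which(sc$pos_cm == map$cm[k])
      expect_equal(sc$lod[j], lod_oracle(y, gmat[, k], X0), tolerance = 1e-8)
    }
  }
})

test_that("a noise-free genotype phenotype pins the peak with near-zero residual", {
  set.seed(5)
  n <- 80
  map <- toy_map(3)
  gmat <- matrix(rbinom(3 * n, 2, 0.5), n, 3)
  g <- toy_genotypes(gmat, map = map)
  samples <- g[, c("id", "sex", "batch")]
  y <- as.numeric(gmat[, 2])
  pr <- genotype_probs(g, map, step = 2)
  sc <- scan_qtl(pr, setNames(y, g$id), samples)
  pk <- scan_peak(sc)
  expect_equal(pk$pos_cm, map$cm[2])
  expect_gt(pk$lod, 100)
})

test_that("LOD curves are invariant to affine transforms of the phenotype", {
  set.seed(6)
  n <- 60
  map <- toy_map(3)
  g <- toy_genotypes(matrix(rbinom(3 * n, 2, 0.5), n, 3), map = map)
  samples <- g[, c("id", "sex", "batch")]
  y <- rnorm(n)
  pr <- genotype_probs(g, map, step = 5)
  s1 <- scan_qtl(pr, setNames(y, g$id), samples)
  s2 <- scan_qtl(pr, setNames(7 - 3.2 * y, g$id), samples)
  expect_equal(s1$lod, s2$lod, tolerance = 1e-10)

  s3 <- scan_qtl(pr, setNames(rep(4, n), g$id), samples)
  expect_true(all(s3$lod == 0))
})

test_that("the sex-interaction flag uses a strict 1-LOD margin", {
  grid <- tibble::tibble(chrom = "chr1", pos_cm = c(0, 10), marker = NA,
                         lod = c(7, 5))
  add <- structure(grid, class = c("lod_scan", class(grid)))
  int1 <- dplyr::mutate(add, lod = c(8.1, 5))
  int2 <- dplyr::mutate(add, lod = c(8.0, 5))
  expect_true(sex_interaction_flag(add, int1))
  expect_false(sex_interaction_flag(add, int2))
})

test_that("cis/trans classification closes the 50-cM boundary", {
  map <- toy_map(6, spacing_cm = 20, spacing_bp = 1e6)
  rec <- tibble::tibble(
    chrom = "chr1",
    pos_cm = c(49, 50, 51, 20),
    phen_chrom = c("chr1", "chr1", "chr1", "chr2"),
    phen_bp = c(0, 0, 0, 0)
  )
  out <- classify_cis_trans(rec, map)
  expect_equal(out$classification, c("cis", "cis", "trans", "trans"))

  rec$phen_chrom[1] <- NA
  expect_equal(classify_cis_trans(rec, map)$classification[1], "unplaced")
})

test_that("QC drops small genotype classes at the stated boundary", {
  g <- toy_genotypes(matrix(c(rep(0, 9), rep(1, 60), rep(2, 55)), ncol = 1),
                     map = toy_map(1))
  pm <- matrix(rnorm(124), 1, 124, dimnames = list("w", g$id))
  rec <- tibble::tibble(phenotype = "w", marker = "chr1_m01", lod = 4)
  out <- qc_filter(rec, g, pm, g[, c("id", "sex", "batch")])
  expect_equal(nrow(out), 0)

  g2 <- toy_genotypes(matrix(c(rep(0, 10), rep(1, 60), rep(2, 54)), ncol = 1),
                      map = toy_map(1))
  pm2 <- matrix(rnorm(124), 1, 124, dimnames = list("w", g2$id))
  out2 <- qc_filter(rec, g2, pm2, g2[, c("id", "sex", "batch")])
  expect_equal(nrow(out2), 1)
  expect_equal(out2$min_class_n, 10L)
})

test_that("a single massive outlier driving a peak is caught by leave-one-out", {
  # the association exists only because one rare-homozygote individual has a
  # 10-SD phenotype; the leave-one-out rescan collapses it
  set.seed(8)
  n <- 60
  d <- c(rep(0, 30), rep(1, 27), rep(2, 3))
  y <- rnorm(n)
  y[n] <- y[n] + 10
  g <- toy_genotypes(matrix(d, ncol = 1), map = toy_map(1))
  pm <- matrix(y, 1, n, dimnames = list("w", g$id))
  samples <- g[, c("id", "sex", "batch")]
  X0 <- cbind(1, g$batch == "b2")
  lod_full <- lod_oracle(y, d, X0)
  rec <- tibble::tibble(phenotype = "w", marker = "chr1_m01", lod = lod_full)
  out <- qc_filter(rec, g, pm, samples, min_class = 2,
                   loo_threshold = lod_full * 0.5)
  expect_true(out$outlier_flag)
  expect_equal(nrow(qc_filter(rec, g, pm, samples, min_class = 2,
                              loo_threshold = lod_full * 0.5,
                              drop_outliers = TRUE)), 0)
})

test_that("support intervals drop 1.5 LOD and degrade gracefully when flat", {
  grid <- tibble::tibble(chrom = "chr1", pos_cm = 0:10, marker = NA,
                         lod = c(0:5, 4:0))
  sc <- structure(grid, class = c("lod_scan", class(grid)))
  ci <- support_interval(sc, drop = 1.5)
  expect_equal(c(ci$ci_lo_cm, ci$ci_hi_cm), c(4, 6))

  flat <- dplyr::mutate(grid, lod = 2)
  sc2 <- structure(flat, class = c("lod_scan", class(flat)))
  ci2 <- support_interval(sc2, peak = sc2[5, ], drop = 1.5)
  expect_equal(c(ci2$ci_lo_cm, ci2$ci_hi_cm), c(0, 10))

  map <- toy_map(3, spacing_cm = 5, spacing_bp = 1e6)
  ci3 <- support_interval(sc, drop = 1.5, map = map)
  expect_equal(ci3$ci_lo_bp, 0)        # nearest typed marker at/below 4 cM
  expect_equal(ci3$ci_hi_bp, 2e6)      # nearest typed marker at/above 6 cM
})

test_that("permutation thresholds order correctly and reject tiny runs", {
  set.seed(12)
  st <- simulate_study(small_config(seed = 61, n_windows = 10))
  pr <- genotype_probs(st$genotypes, st$map, step = 10)
  phen <- matrix(rnorm(5 * 124), 5, 124)
  thr <- permutation_thresholds(pr, st$samples, phen, n_perm = 40)
  expect_gt(thr$significant, thr$suggestive)
  expect_gt(thr$suggestive, 0)
  expect_error(permutation_thresholds(pr, st$samples, phen, n_perm = 10),
               "n_perm")
})

test_that("stratified permutations are no more extreme than free ones under a sex effect", {
  set.seed(14)
  st <- simulate_study(small_config(seed = 62, n_windows = 10))
  pr <- genotype_probs(st$genotypes, st$map, step = 10)
  sexnum <- as.numeric(st$samples$sex == "male")
  phen <- t(replicate(5, 2 * sexnum + rnorm(124, 0, 0.5)))
  set.seed(1); free <- permutation_thresholds(pr, st$samples, phen, n_perm = 200)
  set.seed(1); strat <- permutation_thresholds(pr, st$samples, phen, n_perm = 200,
                                               stratify_by_sex = TRUE)
  expect_lte(strat$significant, free$significant)
})

test_that("map_qtl recovers a strong planted cis QTL end to end", {
  cfg <- small_config(seed = 71, n_windows = 12, planted = list(
    planted_effect("cis_methQTL", target = "chr1_6000",
                   source_marker = "chr1_m04", additive_effect = 0.8)
  ))
  st <- simulate_study(cfg)
  phen <- st$methylation[st$methylation$window_id == "chr1_6000", ]
  recs <- map_qtl(phen, st$genotypes, st$map, st$samples, step = 2, lod_min = 3)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$chrom, "chr1")
  truth_cm <- st$map$cm[st$map$marker == "chr1_m04"]
  expect_lt(abs(recs$pos_cm - truth_cm), 20)
  expect_equal(recs$classification, "cis")
  expect_true(recs$ci_lo_cm <= recs$pos_cm && recs$ci_hi_cm >= recs$pos_cm)
})
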