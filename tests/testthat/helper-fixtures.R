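# Shared generators for desk-scale synthetic studies.

# A reduced genome: fewer windows so study simulation stays fast.
small_config <- function(seed = 1, n_autosomes = 2, n_windows = 20, ...) {
  sim_config(
    seed = seed,
    chromosomes = sim_chromosomes(n_autosomes = n_autosomes,
                                  n_windows_per_chrom = n_windows),
    n_windows_per_chrom = n_windows,
    ...
  )
}

# A wide methylation-like matrix built directly from a value matrix.
make_meth <- function(values, chrom = "chr1", window_size = 1000,
                      ids = sprintf("ind_%03d", seq_len(ncol(values)))) {
  starts <- (seq_len(nrow(values)) - 1) * window_size
  colnames(values) <- ids
  dplyr::bind_cols(
    tibble::tibble(window_id = window_id(chrom, starts),
                   chrom = chrom, start = starts),
    tibble::as_tibble(values)
  )
}

make_samples <- function(ids, sex, batch = rep(c("b1", "b2"), length.out = length(ids))) {
  tibble::tibble(id = ids, sex = sex, batch = batch)
}

# Brute-force two-sided Wilcoxon rank-sum p by full enumeration of labelings.
exact_wilcox_oracle <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(length(pooled), nx)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  ple <- mean(w_all <= w_obs)
  pge <- mean(w_all >= w_obs)
  min(1, 2 * min(ple, pge))
}

# Closed-form single-marker Haley-Knott LOD by direct least squares on the
# full design matrix (the independent oracle for the scan).
lod_oracle <- function(y, d, X0) {
  rss0 <- sum(resid(lm(y ~ X0 - 1))^2)
  rss1 <- sum(resid(lm(y ~ X0 + d - 1))^2)
  (length(y) / 2) * log10(rss0 / rss1)
}
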