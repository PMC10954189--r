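#' Configure a synthetic advanced-intercross study
#'
#' Builds the configuration for the simulator, which emulates the design of a
#' wild x domestic chicken advanced intercross: a single wild (Red
#' Junglefowl-like) founding male crossed to three domestic founding females,
#' intercrossed to the 8th generation, with 124 phenotyped individuals
#' (69 males ZZ, 55 females ZW) by default. Genotypes are founder-allele
#' dosages at a sparse linkage map (~16 cM autosomal spacing, ~15 cM on Z),
#' methylation phenotypes are negative-binomial read counts in 1-kb windows
#' at MeDIP-like coverage (~3.4x), and expression is array-like and
#' log-normal.
#'
#' @param n_males,n_females Final-generation sample sizes (defaults 69 / 55).
#' @param n_generations Number of intercross generations (default 8).
#' @param chromosomes Tibble with columns `name`, `length_cm`, `length_bp`,
#'   `is_z` (exactly one Z); default [sim_chromosomes()].
#' @param n_markers_per_chrom Markers per chromosome, evenly spaced (default 12).
#' @param n_windows_per_chrom Contiguous 1-kb methylation windows per
#'   chromosome (default 200, a desk-scale stand-in for the study's ~1M
#'   genome-wide / 82k Z windows).
#' @param window_size_bp Window size (default 1000).
#' @param mean_coverage Mean sequencing depth per base (default 3.4).
#' @param read_length Mean read length in bp (default 136); together with
#'   `mean_coverage` it sets the expected reads per window.
#' @param dispersion Negative-binomial overdispersion of window counts
#'   (variance `mu + dispersion * mu^2`); `0` gives deterministic, noise-free
#'   counts (the small-dispersion limit).
#' @param indiv_sd SD of a multiplicative log-normal noise term per
#'   (window, individual) pair, emulating biological between-individual
#'   methylation variation beyond count noise (default 0.4; `0` disables).
#' @param baseline_sd Log-normal SD of per-window baseline levels (default
#'   0.5; `0` makes all windows share the same baseline).
#' @param z_dose_ratio Baseline male:female mean coverage ratio on Z windows
#'   (default 1.7, the Z-wide average observed in hypothalamus).
#' @param batch_effect Multiplicative shift applied to the second batch
#'   (default 0.05); two batches are simulated so covariate code paths are
#'   exercised.
#' @param n_genes Number of background expression probesets (default 40).
#' @param expr_noise_sd Residual SD of log2 expression (default 0.3).
#' @param scale Normalization scale constant (default 1e6).
#' @param pop_size Intermediate-generation population size (default 200).
#' @param planted List of [planted_effect()] objects — the ground truth.
#' @param seed Integer seed; the whole study is a deterministic function of
#'   the configuration including this seed.
#' @return A validated `sim_config` list.
#' @seealso [simulate_study()], [planted_effect()]
#' @export
sim_config <- function(n_males = 69, n_females = 55, n_generations = 8,
                       chromosomes = sim_chromosomes(),
                       n_markers_per_chrom = 12, n_windows_per_chrom = 200,
                       window_size_bp = 1000, mean_coverage = 3.4,
                       read_length = 136, dispersion = 0.3,
                       indiv_sd = 0.4, baseline_sd = 0.5, z_dose_ratio = 1.7,
                       batch_effect = 0.05, n_genes = 40,
                       expr_noise_sd = 0.3, scale = 1e6,
                       pop_size = 200, planted = list(), seed = 1L) {
  cfg <- list(
    n_males = n_males, n_females = n_females, n_generations = n_generations,
    chromosomes = tibble::as_tibble(chromosomes),
    n_markers_per_chrom = n_markers_per_chrom,
    n_windows_per_chrom = n_windows_per_chrom,
    window_size_bp = window_size_bp, mean_coverage = mean_coverage,
    read_length = read_length, dispersion = dispersion,
    indiv_sd = indiv_sd, baseline_sd = baseline_sd, z_dose_ratio = z_dose_ratio,
    batch_effect = batch_effect, n_genes = n_genes,
    expr_noise_sd = expr_noise_sd, scale = scale,
    pop_size = pop_size, planted = planted, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  ch <- cfg$chromosomes
  stopifnot(all(c("name", "length_cm", "length_bp", "is_z") %in% names(ch)))
  if (cfg$n_males + cfg$n_females <= 0) stop("zero founders: need at least one individual")
  if (cfg$window_size_bp <= 0) stop("window_size_bp must be positive")
  if (sum(ch$is_z) > 1) stop("at most one chromosome may be the Z")
  if (any(ch$length_cm <= 0) || any(ch$length_bp <= 0)) stop("chromosome lengths must be positive")
  if (cfg$n_markers_per_chrom < 1) stop("chromosome with no markers")
  if (cfg$n_generations < 1) stop("need at least one generation")
  for (pe in cfg$planted) {
    if (!inherits(pe, "planted_effect")) stop("planted must be a list of planted_effect objects")
  }
  invisible(cfg)
}

#' @rdname sim_config
#' @param n_autosomes Number of autosomes (default 3).
#' @param autosome_length_cm,z_length_cm Genetic lengths; defaults give ~16 cM
#'   autosomal and ~15 cM Z marker spacing with 12 markers.
#' @export
sim_chromosomes <- function(n_autosomes = 3, autosome_length_cm = 176,
                            z_length_cm = 165, n_windows_per_chrom = 200,
                            window_size_bp = 1000) {
  bp <- n_windows_per_chrom * window_size_bp
  tibble::tibble(
    name = c(paste0("chr", seq_len(n_autosomes)), "chrZ"),
    length_cm = c(rep(autosome_length_cm, n_autosomes), z_length_cm),
    length_bp = bp,
    is_z = c(rep(FALSE, n_autosomes), TRUE)
  )
}

#' Declare a ground-truth effect for the simulator
#'
#' @param kind One of `"cis_methQTL"`, `"trans_methQTL"`, `"eQTL"`,
#'   `"MHM_block"`, `"FHM_block"`, `"sex_shift"`.
#' @param target Window id (methylation effects) or probeset id (eQTL).
#' @param source_marker Marker id driving the effect (QTL kinds).
#' @param additive_effect Fractional change in mean per copy of the wild
#'   allele (multiplicative model `mu * (1 + beta * dosage)`).
#' @param sex_interaction_effect Difference in the allelic effect between the
#'   sexes (male slope `beta + delta/2`, female slope `beta - delta/2`).
#' @param male_multiplier Fold applied to male means in block windows
#'   (e.g. 3.3 for an MHM block; < 1 yields a female-hyper-methylated block).
#' @param block_windows Character vector of contiguous window ids
#'   (MHM/FHM/sex_shift kinds).
#' @param male_expr_multiplier For `MHM_block`: fold applied to male
#'   expression of genes within 100 kb of the block (default 1, no
#'   suppression).
#' @param coupling_window,coupling_coef,direction For `eQTL`: optional
#'   coupling between the target gene and a methylation window, with
#'   `direction` `"meth_to_expr"` or `"expr_to_meth"`; `coupling_coef` is in
#'   SD units.
#' @return A `planted_effect` object.
#' @export
planted_effect <- function(kind = c("cis_methQTL", "trans_methQTL", "eQTL",
                                    "MHM_block", "FHM_block", "sex_shift"),
                           target = NULL, source_marker = NULL,
                           additive_effect = 0, sex_interaction_effect = 0,
                           male_multiplier = 1, block_windows = NULL,
                           male_expr_multiplier = 1,
                           coupling_window = NULL, coupling_coef = 0,
                           direction = c("meth_to_expr", "expr_to_meth")) {
  kind <- match.arg(kind)
  if (male_multiplier <= 0) stop("male_multiplier must be positive")
  if (kind %in% c("MHM_block", "FHM_block")) {
    if (is.null(block_windows) || !length(block_windows)) {
      stop("block effects need block_windows")
    }
    st <- parse_window_id(block_windows)
    if (length(unique(st$chrom)) != 1 ||
        !all(diff(sort(st$start)) == diff(sort(st$start))[1])) {
      stop("block_windows must be contiguous windows on one chromosome")
    }
  }
  structure(
    list(kind = kind, target = target, source_marker = source_marker,
         additive_effect = additive_effect,
         sex_interaction_effect = sex_interaction_effect,
         male_multiplier = male_multiplier, block_windows = block_windows,
         male_expr_multiplier = male_expr_multiplier,
         coupling_window = coupling_window, coupling_coef = coupling_coef,
         direction = match.arg(direction)),
    class = "planted_effect"
  )
}

#' Marker map implied by a simulation configuration
#'
#' Markers are evenly spaced in cM along each chromosome with bp positions
#' spread linearly across the chromosome, so cM and bp orders agree.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `marker`, `chrom`, `cm`, `bp`, `is_z`.
#' @export
sim_marker_map <- function(config) {
  purrr::pmap_dfr(config$chromosomes, function(name, length_cm, length_bp, is_z) {
    n <- config$n_markers_per_chrom
    tibble::tibble(
      marker = sprintf("%s_m%02d", name, seq_len(n)),
      chrom = name,
      cm = if (n == 1) length_cm / 2 else seq(0, length_cm, length.out = n),
      bp = if (n == 1) round(length_bp / 2) else round(seq(0, length_bp - 1, length.out = n)),
      is_z = is_z
    )
  })
}

haldane_r <- function(d_cm) 0.5 * (1 - exp(-2 * d_cm / 100))

# One meiosis for many parents at once: h1/h2 are n x m haplotype matrices,
# rfrac the m-1 inter-marker recombination fractions.
meiosis <- function(h1, h2, rfrac) {
  n <- nrow(h1)
  m <- ncol(h1)
  state <- matrix(0L, n, m)
  state[, 1] <- as.integer(runif(n) < 0.5)
  if (m > 1) {
    sw <- matrix(runif(n * (m - 1)) < rep(rfrac, each = n), n, m - 1)
    for (j in 2:m) state[, j] <- (state[, j - 1] + sw[, j - 1]) %% 2L
  }
  out <- h1
  out[state == 1L] <- h2[state == 1L]
  out
}

# Internal population representation: list(sex = chr vector,
# auto = list(chrom -> list(h1, h2)), z = list(h1, h2)); female rows of z$h2
# are NA (the W carries no markers).
sim_offspring <- function(pop, n_off, rlist, z_name) {
  males <- which(pop$sex == "male")
  females <- which(pop$sex == "female")
  if (!length(males) || !length(females)) {
    stop("a generation lost one sex entirely; increase pop_size")
  }
  sire <- sample(males, n_off, replace = TRUE)
  dam <- sample(females, n_off, replace = TRUE)
  sex <- ifelse(runif(n_off) < 0.5, "male", "female")

  auto <- lapply(names(pop$auto), function(ch) {
    r <- rlist[[ch]]
    h <- pop$auto[[ch]]
    list(
      h1 = meiosis(h$h1[sire, , drop = FALSE], h$h2[sire, , drop = FALSE], r),
      h2 = meiosis(h$h1[dam, , drop = FALSE], h$h2[dam, , drop = FALSE], r)
    )
  })
  names(auto) <- names(pop$auto)

  z <- NULL
  if (!is.null(pop$z)) {
    r <- rlist[[z_name]]
    z_pat <- meiosis(pop$z$h1[sire, , drop = FALSE], pop$z$h2[sire, , drop = FALSE], r)
    z_mat <- pop$z$h1[dam, , drop = FALSE]   # dam's single Z, transmitted intact
    h2 <- z_mat
    h2[sex == "female", ] <- NA_integer_     # daughters get the W instead
    z <- list(h1 = z_pat, h2 = h2)
  }
  list(sex = sex, auto = auto, z = z)
}

#' Simulate an advanced-intercross pedigree
#'
#' Founds the cross with one wild male (fixed for the wild allele, ZZ) and
#' three domestic females (fixed for the domestic allele, ZW), then
#' intercrosses by random mating for `n_generations`. Recombination follows
#' the Haldane map function between adjacent markers. ZW transmission: sires
#' pass a recombined Z to all offspring; dams pass their single Z intact to
#' sons and the (untyped) W to daughters.
#'
#' @param config A [sim_config()].
#' @param map Marker map, by default [sim_marker_map()] of `config`.
#' @return A tibble with columns `id`, `sex`, `batch`, then one dosage column
#'   per marker: copies of the wild allele, `{0,1,2}` on autosomes and the
#'   male Z, `{0,1}` on the hemizygous female Z.
#' @export
simulate_pedigree <- function(config, map = sim_marker_map(config)) {
  chroms <- config$chromosomes
  z_name <- if (any(chroms$is_z)) chroms$name[chroms$is_z] else NULL
  by_chrom <- split(map, map$chrom)

  rlist <- lapply(by_chrom, function(m) haldane_r(diff(m$cm)))

  # Founders: rows 1 = wild male, 2:4 = domestic females.
  n_mark <- vapply(by_chrom, nrow, 1L)
  founder <- list(
    sex = c("male", "female", "female", "female"),
    auto = lapply(by_chrom[setdiff(names(by_chrom), z_name)], function(m) {
      h <- matrix(c(1L, 0L, 0L, 0L), 4, nrow(m))
      list(h1 = h, h2 = h)
    }),
    z = NULL
  )
  if (!is.null(z_name)) {
    mz <- nrow(by_chrom[[z_name]])
    h1 <- matrix(c(1L, 0L, 0L, 0L), 4, mz)
    h2 <- matrix(c(1L, NA, NA, NA), 4, mz)
    founder$z <- list(h1 = h1, h2 = h2)
  }

  pop <- founder
  for (g in seq_len(config$n_generations - 1)) {
    pop <- sim_offspring(pop, config$pop_size, rlist, z_name)
  }
  # Final generation: draw until both sex quotas are filled.
  need <- c(male = config$n_males, female = config$n_females)
  got <- NULL
  guard <- 0
  while (is.null(got) || sum(got$sex == "male") < need["male"] ||
         sum(got$sex == "female") < need["female"]) {
    batch_n <- max(50, 2 * sum(need))
    off <- sim_offspring(pop, batch_n, rlist, z_name)
    got <- if (is.null(got)) off else {
      list(
        sex = c(got$sex, off$sex),
        auto = purrr::map2(got$auto, off$auto, function(a, b) {
          list(h1 = rbind(a$h1, b$h1), h2 = rbind(a$h2, b$h2))
        }),
        z = if (is.null(got$z)) NULL else {
          list(h1 = rbind(got$z$h1, off$z$h1), h2 = rbind(got$z$h2, off$z$h2))
        }
      )
    }
    guard <- guard + 1
    if (guard > 100) stop("could not fill sex quotas")
  }
  keep <- c(
    which(got$sex == "male")[seq_len(need["male"])],
    which(got$sex == "female")[seq_len(need["female"])]
  )
  sex <- got$sex[keep]
  n <- length(keep)

  geno <- matrix(NA_real_, n, nrow(map),
                 dimnames = list(NULL, unlist(lapply(by_chrom, function(m) m$marker))))
  for (ch in setdiff(names(by_chrom), z_name)) {
    h <- got$auto[[ch]]
    geno[, by_chrom[[ch]]$marker] <- h$h1[keep, , drop = FALSE] + h$h2[keep, , drop = FALSE]
  }
  if (!is.null(z_name)) {
    h1 <- got$z$h1[keep, , drop = FALSE]
    h2 <- got$z$h2[keep, , drop = FALSE]
    zg <- h1
    is_m <- sex == "male"
    zg[is_m, ] <- h1[is_m, , drop = FALSE] + h2[is_m, , drop = FALSE]
    geno[, by_chrom[[z_name]]$marker] <- zg
  }
  geno <- geno[, map$marker, drop = FALSE]  # restore map order

  tibble::tibble(
    id = sprintf("ind_%03d", seq_len(n)),
    sex = sex,
    batch = sample(rep(c("b1", "b2"), length.out = n))
  ) |>
    dplyr::bind_cols(tibble::as_tibble(geno))
}

sample_sheet <- function(genotypes) genotypes[, c("id", "sex", "batch")]

sim_windows <- function(config) {
  purrr::pmap_dfr(config$chromosomes, function(name, length_cm, length_bp, is_z) {
    starts <- seq(0, by = config$window_size_bp,
                  length.out = config$n_windows_per_chrom)
    tibble::tibble(window_id = window_id(name, starts), chrom = name,
                   start = starts, is_z = is_z)
  })
}

# Per-sex allelic slope implied by a planted QTL effect.
planted_slopes <- function(pe) {
  c(male = pe$additive_effect + pe$sex_interaction_effect / 2,
    female = pe$additive_effect - pe$sex_interaction_effect / 2)
}

#' Generate window methylation counts with planted effects
#'
#' Per window and individual a read count is drawn with mean
#' `baseline * (1 + beta_sex * dosage) * sex_multipliers * batch_shift`, where
#' the baseline male:female dose ratio on Z windows defaults to ~1.7 and MHM /
#' FHM block multipliers and sex shifts are applied to male means in their
#' block windows. Counts are negative binomial with variance
#' `mu + dispersion * mu^2` (deterministic when `dispersion = 0`), then
#' normalized per individual by total read count ([normalize_methylation()]).
#'
#' @param genotypes Genotype tibble from [simulate_pedigree()].
#' @param truth List of [planted_effect()] objects.
#' @param config The [sim_config()].
#' @return A normalized wide methylation tibble (see
#'   [normalize_methylation()]); the raw counts are recoverable via
#'   [denormalize_methylation()].
#' @export
generate_methylation <- function(genotypes, truth, config) {
  win <- sim_windows(config)
  n_w <- nrow(win)
  ids <- genotypes$id
  n <- length(ids)
  sex <- genotypes$sex
  is_m <- sex == "male"

  base_count <- config$mean_coverage * config$window_size_bp / config$read_length
  baseline <- base_count * exp(rnorm(n_w, 0, config$baseline_sd))

  mu <- matrix(baseline, n_w, n)
  mu[win$is_z, is_m] <- mu[win$is_z, is_m] * config$z_dose_ratio

  for (pe in truth) {
    if (pe$kind %in% c("MHM_block", "FHM_block", "sex_shift")) {
      rows <- match(pe$block_windows, win$window_id)
      if (anyNA(rows)) stop("invalid planted effect: unknown block window")
      mu[rows, is_m] <- mu[rows, is_m] * pe$male_multiplier
    } else if (pe$kind %in% c("cis_methQTL", "trans_methQTL")) {
      row <- match(pe$target, win$window_id)
      if (is.na(row)) stop("invalid planted effect: unknown target window ", pe$target)
      if (!pe$source_marker %in% names(genotypes)) {
        stop("invalid planted effect: unknown source marker ", pe$source_marker)
      }
      d <- genotypes[[pe$source_marker]]
      sl <- planted_slopes(pe)
      fac <- 1 + ifelse(is_m, sl["male"], sl["female"]) * d
      if (any(fac <= 0, na.rm = TRUE)) {
        stop("invalid planted effect: requested negative mean (effect too large)")
      }
      mu[row, ] <- mu[row, ] * fac
    }
  }
  mu[, genotypes$batch == "b2"] <- mu[, genotypes$batch == "b2"] * (1 + config$batch_effect)
  if (config$indiv_sd > 0) {
    mu <- mu * exp(matrix(rnorm(n_w * n, 0, config$indiv_sd), n_w, n))
  }

  counts <- if (config$dispersion == 0) {
    round(mu)
  } else {
    matrix(rnbinom(n_w * n, mu = mu, size = 1 / config$dispersion), n_w, n)
  }
  dimnames(counts) <- list(win$window_id, ids)
  wide <- dplyr::bind_cols(win[, c("window_id", "chrom", "start")],
                           tibble::as_tibble(counts))
  normalize_methylation(wide, scale = config$scale)
}

sim_genes <- function(config) {
  ch <- config$chromosomes
  n <- config$n_genes
  chrom <- rep(ch$name, length.out = n)
  slot <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  per_chrom <- stats::ave(seq_len(n), chrom, FUN = length)
  len <- ch$length_bp[match(chrom, ch$name)]
  start <- round(len * slot / (per_chrom + 1))
  tibble::tibble(
    probeset = sprintf("ps_%03d", seq_len(n)),
    gene_name = sprintf("gene%03d", seq_len(n)),
    gene_chrom = chrom,
    gene_start = start,
    gene_end = start + 2000
  )
}

#' Generate array-like expression with planted eQTL and couplings
#'
#' Expression is log-normal per probeset: a gene-level baseline on log2 scale
#' plus planted additive (and sex-interacting) eQTL effects, optional coupling
#' to a methylation window (for causality tests), male suppression near MHM
#' blocks, and Gaussian noise.
#'
#' @inheritParams generate_methylation
#' @param methylation Normalized methylation tibble (for couplings).
#' @return A wide tibble with probeset annotation columns (`probeset`,
#'   `gene_name`, `gene_chrom`, `gene_start`, `gene_end`) and one column per
#'   individual.
#' @export
generate_expression <- function(genotypes, methylation, truth, config) {
  genes <- sim_genes(config)
  ids <- genotypes$id
  n <- length(ids)
  is_m <- genotypes$sex == "male"

  log2e <- matrix(rnorm(nrow(genes), 8, 1), nrow(genes), n)
  for (pe in truth) {
    if (pe$kind == "eQTL") {
      row <- match(pe$target, genes$probeset)
      if (is.na(row)) stop("invalid planted effect: unknown probeset ", pe$target)
      if (!is.null(pe$source_marker)) {
        d <- genotypes[[pe$source_marker]]
        sl <- planted_slopes(pe)
        log2e[row, ] <- log2e[row, ] + ifelse(is_m, sl["male"], sl["female"]) * d
      }
      if (!is.null(pe$coupling_window) && pe$direction == "meth_to_expr" &&
          pe$coupling_coef != 0) {
        mrow <- match(pe$coupling_window, methylation$window_id)
        if (is.na(mrow)) stop("coupling references a nonexistent window")
        mv <- as.numeric(methylation[mrow, value_cols(methylation)])
        log2e[row, ] <- log2e[row, ] + pe$coupling_coef * as.numeric(scale(mv))
      }
    } else if (pe$kind == "MHM_block" && pe$male_expr_multiplier != 1) {
      st <- parse_window_id(pe$block_windows)
      near <- genes$gene_chrom == st$chrom[1] &
        genes$gene_start <= max(st$start) + config$window_size_bp + 1e5 &
        genes$gene_end >= min(st$start) - 1e5
      log2e[near, is_m] <- log2e[near, is_m] + log2(pe$male_expr_multiplier)
    }
  }
  log2e <- log2e + matrix(rnorm(nrow(genes) * n, 0, config$expr_noise_sd),
                          nrow(genes), n)
  expr <- 2^log2e
  dimnames(expr) <- list(genes$probeset, ids)
  dplyr::bind_cols(genes, tibble::as_tibble(expr))
}

#' Simulate a complete study
#'
#' Runs [simulate_pedigree()], [generate_methylation()] and
#' [generate_expression()] under the configuration's seed, then applies any
#' planted expression-to-methylation couplings (the target window's
#' normalized values gain a component proportional to the standardized
#' expression of the coupled gene).
#'
#' @param config A [sim_config()].
#' @return A `sim_study` list: `config`, `map`, `genotypes`, `samples`,
#'   `methylation`, `expression`, `truth`.
#' @export
simulate_study <- function(config) {
  set.seed(config$seed)
  map <- sim_marker_map(config)
  genotypes <- simulate_pedigree(config, map)
  methylation <- generate_methylation(genotypes, config$planted, config)
  expression <- generate_expression(genotypes, methylation, config$planted, config)

  for (pe in config$planted) {
    if (pe$kind == "eQTL" && !is.null(pe$coupling_window) &&
        pe$direction == "expr_to_meth" && pe$coupling_coef != 0) {
      mrow <- match(pe$coupling_window, methylation$window_id)
      if (is.na(mrow)) stop("coupling references a nonexistent window")
      erow <- match(pe$target, expression$probeset)
      ev <- as.numeric(expression[erow, value_cols(expression)])
      cols <- value_cols(methylation)
      mv <- as.numeric(methylation[mrow, cols])
      methylation[mrow, cols] <- as.list(
        pmax(0, mv + pe$coupling_coef * sd(mv) * as.numeric(scale(ev)))
      )
    }
  }

  structure(
    list(config = config, map = map, genotypes = genotypes,
         samples = sample_sheet(genotypes), methylation = methylation,
         expression = expression, truth = config$planted),
    class = "sim_study"
  )
}

#' Write a simulated study to TSV files plus a truth ledger
#'
#' @param study A `sim_study` from [simulate_study()].
#' @param outdir Output directory (created if needed).
#' @return The directory, invisibly. Files: `marker_map.tsv`,
#'   `genotypes.tsv`, `methylation.tsv`, `expression.tsv`, `samples.tsv`,
#'   `truth.json`.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(study$map, file.path(outdir, "marker_map.tsv"))
  readr::write_tsv(study$genotypes, file.path(outdir, "genotypes.tsv"))
  write_matrix_tsv(study$methylation, file.path(outdir, "methylation.tsv"))
  write_matrix_tsv(study$expression, file.path(outdir, "expression.tsv"), id_col = "probeset")
  write_sample_sheet(study$samples, file.path(outdir, "samples.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(lapply(study$truth, unclass),
                         file.path(outdir, "truth.json"), auto_unbox = TRUE)
  }
  invisible(outdir)
}

#' Simulate a genotype-anchored causal triple
#'
#' Draws `(G, E, M)` from one of the single-anchor causal structures used for
#' edge orientation: `G -> E -> M`, `G -> M -> E`, or `E <- G -> M`
#' (independent given G). Useful for exercising [leo_nb_orient()].
#'
#' @param n Sample size.
#' @param direction `"g_e_m"`, `"g_m_e"` or `"independent"`.
#' @param b1,b2 Path coefficients (anchor to first variable, first to second).
#' @param noise_sd Residual SD of each structural equation.
#' @return A tibble with columns `g`, `e`, `m`.
#' @export
simulate_causal_triple <- function(n, direction = c("g_e_m", "g_m_e", "independent"),
                                   b1 = 1, b2 = 1, noise_sd = 1) {
  direction <- match.arg(direction)
  g <- rbinom(n, 2, 0.5)
  e1 <- rnorm(n, 0, noise_sd)
  e2 <- rnorm(n, 0, noise_sd)
  if (direction == "g_e_m") {
    e <- b1 * g + e1
    m <- b2 * e + e2
  } else if (direction == "g_m_e") {
    m <- b1 * g + e1
    e <- b2 * m + e2
  } else {
    e <- b1 * g + e1
    m <- b1 * g + e2
  }
  tibble::tibble(g = g, e = e, m = m)
}
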