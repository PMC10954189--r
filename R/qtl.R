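trans3 <- function(r) {
  matrix(c((1 - r)^2,      2 * r * (1 - r),      r^2,
           r * (1 - r),    (1 - r)^2 + r^2,      r * (1 - r),
           r^2,            2 * r * (1 - r),      (1 - r)^2),
         3, 3, byrow = TRUE)
}

trans2 <- function(r) {
  matrix(c(1 - r, r, r, 1 - r), 2, 2, byrow = TRUE)
}

#' Conditional genotype probabilities on a pseudomarker grid
#'
#' At each pseudomarker, computes `P(genotype | flanking typed markers)` under
#' a Markov model along the chromosome with Haldane recombination fractions:
#' 3 dosage states on autosomes and the male Z, 2 states on the hemizygous
#' female Z. At a typed marker the distribution is degenerate on the observed
#' state; missing genotypes defer to the nearest typed flanking markers.
#'
#' @param genotypes Genotype tibble (`id`, `sex`, `batch`, then one dosage
#'   column per marker).
#' @param map Marker map tibble (`marker`, `chrom`, `cm`, `bp`, `is_z`);
#'   cM must be non-decreasing and bp strictly increasing per chromosome.
#' @param step Pseudomarker spacing in cM (default 1).
#' @return A `geno_probs` object: per chromosome a list with `grid`
#'   (tibble `chrom`, `pos_cm`, `marker`), `probs` (individuals x positions x
#'   3 array; female-Z rows use the first two states), and `dosage`
#'   (individuals x positions expected dosages). Individual ids and sexes are
#'   carried along.
#' @export
genotype_probs <- function(genotypes, map, step = 1) {
  ids <- genotypes$id
  sex <- genotypes$sex
  out <- list()
  for (ch in unique(map$chrom)) {
    mm <- map[map$chrom == ch, ]
    if (is.unsorted(mm$cm)) stop("inconsistent map: cM not sorted on ", ch)
    if (any(diff(mm$bp) <= 0)) stop("inconsistent map: bp not increasing on ", ch)
    if (any(diff(mm$cm) < 0)) stop("inconsistent map on ", ch)
    G <- as.matrix(genotypes[, mm$marker, drop = FALSE])
    n <- nrow(G)
    is_z <- mm$is_z[1]
    female <- is_z & sex == "female"

    pos <- sort(unique(c(seq(0, max(mm$cm), by = step), mm$cm)))
    npos <- length(pos)
    probs <- array(0, c(n, npos, 3))
    mk_at <- match(round(pos, 9), round(mm$cm, 9))
    complete <- !anyNA(G)

    groups <- if (is_z) list(which(!female), which(female)) else list(seq_len(n))
    for (j in seq_len(npos)) {
      p <- pos[j]
      for (grp in groups) {
        if (!length(grp)) next
        nst <- if (is_z && all(female[grp])) 2L else 3L
        if (complete) {
          lcand <- which(mm$cm <= p)
          rcand <- which(mm$cm > p)
          l <- if (length(lcand)) max(lcand) else NA
          rr <- if (length(rcand)) min(rcand) else NA
          if (!is.na(l) && mm$cm[l] == p) {
            pr <- matrix(0, length(grp), nst)
            pr[cbind(seq_along(grp), G[grp, l] + 1)] <- 1
          } else {
            tm <- function(d) if (nst == 2) trans2(haldane_r(d)) else trans3(haldane_r(d))
            a <- if (!is.na(l)) tm(p - mm$cm[l])[G[grp, l] + 1, , drop = FALSE] else
              matrix(1, length(grp), nst)
            b <- if (!is.na(rr)) t(tm(mm$cm[rr] - p))[G[grp, rr] + 1, , drop = FALSE] else
              matrix(1, length(grp), nst)
            pr <- a * b
            pr <- pr / rowSums(pr)
          }
          probs[cbind(rep(grp, nst), j, rep(seq_len(nst), each = length(grp)))] <- pr
        } else {
          for (i in grp) {
            typed <- which(!is.na(G[i, ]))
            if (!length(typed)) {
              pr <- if (nst == 2) c(0.5, 0.5) else c(0.25, 0.5, 0.25)
            } else {
              lcand <- typed[mm$cm[typed] <= p]
              rcand <- typed[mm$cm[typed] > p]
              l <- if (length(lcand)) max(lcand) else NA
              rr <- if (length(rcand)) min(rcand) else NA
              if (!is.na(l) && mm$cm[l] == p) {
                pr <- rep(0, nst)
                pr[G[i, l] + 1] <- 1
              } else {
                tm <- function(d) if (nst == 2) trans2(haldane_r(d)) else trans3(haldane_r(d))
                a <- if (!is.na(l)) tm(p - mm$cm[l])[G[i, l] + 1, ] else rep(1, nst)
                b <- if (!is.na(rr)) tm(mm$cm[rr] - p)[, G[i, rr] + 1] else rep(1, nst)
                pr <- a * b
                pr <- pr / sum(pr)
              }
            }
            probs[i, j, seq_len(nst)] <- pr
          }
        }
      }
    }
    dosage <- probs[, , 2, drop = FALSE][, , 1] + 2 * probs[, , 3, drop = FALSE][, , 1]
    dim(dosage) <- c(n, npos)
    out[[ch]] <- list(
      grid = tibble::tibble(chrom = ch, pos_cm = pos, marker = mm$marker[mk_at]),
      probs = probs, dosage = dosage, is_z = is_z
    )
  }
  structure(list(chroms = out, ids = ids, sex = sex), class = "geno_probs")
}

# Covariate design from a sample sheet: intercept, sex, batch indicators.
covariate_matrix <- function(samples, covariates = c("sex", "batch")) {
  X <- matrix(1, nrow(samples), 1, dimnames = list(samples$id, "intercept"))
  if ("sex" %in% covariates && length(unique(samples$sex)) > 1) {
    X <- cbind(X, sex_male = as.numeric(samples$sex == "male"))
  }
  if ("batch" %in% covariates && length(unique(samples$batch)) > 1) {
    b <- factor(samples$batch)
    for (lev in levels(b)[-1]) {
      X <- cbind(X, as.numeric(b == lev))
      colnames(X)[ncol(X)] <- paste0("batch_", lev)
    }
  }
  if (qr(X)$rank < ncol(X)) stop("collinear covariates")
  X
}

# Precompute everything y-independent for fast repeated scans.
scan_engine <- function(probs, samples, covariates = c("sex", "batch")) {
  samples <- samples[match(probs$ids, samples$id), ]
  X0 <- covariate_matrix(samples, covariates)
  qr0 <- qr(X0)
  Q <- qr.Q(qr0)
  sexm <- as.numeric(samples$sex == "male")
  D <- do.call(cbind, lapply(probs$chroms, function(cc) cc$dosage))
  grid <- dplyr::bind_rows(lapply(probs$chroms, function(cc) cc$grid))
  Dres <- D - Q %*% crossprod(Q, D)
  E <- D * sexm
  Eres <- E - Q %*% crossprod(Q, E)
  list(Q = Q, grid = grid, Dres = Dres, Eres = Eres,
       dd = colSums(Dres^2), ee = colSums(Eres^2), de = colSums(Dres * Eres),
       n = nrow(D), ids = probs$ids)
}

# LOD curve for one phenotype vector (aligned to engine ids).
scan_lod <- function(eng, y, interactive = FALSE) {
  ry <- y - eng$Q %*% crossprod(eng$Q, y)
  rss0 <- sum(ry^2)
  if (rss0 < 1e-12) return(rep(0, length(eng$dd)))
  u <- as.numeric(crossprod(eng$Dres, ry))
  if (!interactive) {
    expl <- ifelse(eng$dd > 1e-10, u^2 / eng$dd, 0)
  } else {
    v <- as.numeric(crossprod(eng$Eres, ry))
    det <- eng$dd * eng$ee - eng$de^2
    expl2 <- (eng$ee * u^2 - 2 * eng$de * u * v + eng$dd * v^2) / det
    expl1 <- ifelse(eng$dd > 1e-10, u^2 / eng$dd, 0)
    expl <- ifelse(det > 1e-10 * pmax(eng$dd * eng$ee, 1e-300), expl2, expl1)
  }
  rss1 <- pmax(rss0 - expl, 1e-300)
  (eng$n / 2) * log10(rss0 / rss1)
}

#' Haley-Knott LOD scan for one phenotype
#'
#' Regresses the phenotype on expected genotype dosages at every pseudomarker
#' with sex and batch covariates (plus a genotype-by-sex term when
#' `interactive = TRUE`), reporting
#' `LOD = (n/2) log10(RSS_null / RSS_full)` where the null model retains the
#' covariates. A constant phenotype yields LOD 0 everywhere.
#'
#' @param probs A [genotype_probs()] object.
#' @param phenotype Numeric vector named by individual id, or aligned to the
#'   genotype table order.
#' @param samples Sample sheet.
#' @param interactive Fit the genotype-by-sex interactive model.
#' @param covariates Covariates to include (default sex and batch).
#' @return A `lod_scan` tibble: `chrom`, `pos_cm`, `marker`, `lod`, with the
#'   fitted model label in attribute `"model"`.
#' @export
scan_qtl <- function(probs, phenotype, samples, interactive = FALSE,
                     covariates = c("sex", "batch")) {
  if (!is.null(names(phenotype))) phenotype <- phenotype[probs$ids]
  if (anyNA(phenotype)) stop("missing phenotype values are not supported; subset first")
  eng <- scan_engine(probs, samples, covariates)
  lod <- scan_lod(eng, phenotype, interactive)
  out <- eng$grid
  out$lod <- lod
  class(out) <- c("lod_scan", class(out))
  attr(out, "model") <- if (interactive) "sex-interactive" else "additive"
  out
}

#' Peak of a LOD curve
#'
#' @param scan A `lod_scan` tibble.
#' @return A one-row tibble (`chrom`, `pos_cm`, `marker`, `lod`).
#' @export
scan_peak <- function(scan) scan[which.max(scan$lod), ]

#' Flag a sex-interacting QTL
#'
#' A QTL is sex-interactive when the best sex-interactive model fit exceeds
#' the best additive fit by strictly more than 1 LOD. By default the two
#' curves' maxima are compared, so loci whose per-sex effects cancel in the
#' pooled additive fit are still assessed at their detection point; passing
#' `peak` compares the curves at that position instead.
#'
#' @param scan_add,scan_int Additive and sex-interactive `lod_scan`s on the
#'   same grid.
#' @param peak Optional one-row peak tibble at which to compare (default:
#'   each curve's own maximum).
#' @return Logical flag.
#' @export
sex_interaction_flag <- function(scan_add, scan_int, peak = NULL) {
  if (is.null(peak)) {
    return((max(scan_int$lod) - max(scan_add$lod)) > 1.0)
  }
  i <- which(scan_add$chrom == peak$chrom & scan_add$pos_cm == peak$pos_cm)[1]
  (scan_int$lod[i] - scan_add$lod[i]) > 1.0
}

#' Permutation significance thresholds
#'
#' For each sampled phenotype, permutes individual labels `n_perm` times,
#' rescans, records the genome-wide maximum LOD per permutation, and keeps
#' that phenotype's top 5% of maxima. The kept values are pooled across
#' phenotypes; the significant threshold is the 95th percentile of the pool
#' and the suggestive threshold the 80th.
#'
#' @param probs A [genotype_probs()] object.
#' @param samples Sample sheet.
#' @param phenotypes Matrix of phenotypes (rows = phenotypes, columns =
#'   individuals in genotype order) — e.g. rows sampled from a methylation
#'   matrix.
#' @param n_perm Permutations per phenotype (at least 20, or the 5% tail is
#'   undefined).
#' @param interactive Scan with the sex-interactive model.
#' @param stratify_by_sex Permute within sex strata instead of freely
#'   (default `FALSE`: free permutation with sex retained as a covariate).
#' @param tail Per-phenotype tail kept (default 0.05).
#' @return A tibble `significant`, `suggestive`; the pooled tail values are in
#'   attribute `"pool"`.
#' @export
permutation_thresholds <- function(probs, samples, phenotypes, n_perm = 100,
                                   interactive = FALSE, stratify_by_sex = FALSE,
                                   tail = 0.05) {
  if (n_perm < 20) stop("n_perm too small to define the 5% tail (need >= 20)")
  if (is.vector(phenotypes)) phenotypes <- matrix(phenotypes, nrow = 1)
  eng <- scan_engine(probs, samples)
  sex <- probs$sex
  keep_k <- max(1, ceiling(tail * n_perm))
  pool <- numeric(0)
  for (ph in seq_len(nrow(phenotypes))) {
    y <- as.numeric(phenotypes[ph, ])
    maxes <- vapply(seq_len(n_perm), function(b) {
      idx <- if (stratify_by_sex) {
        o <- seq_along(y)
        for (s in unique(sex)) o[sex == s] <- sample(o[sex == s])
        o
      } else sample(seq_along(y))
      max(scan_lod(eng, y[idx], interactive))
    }, 0)
    pool <- c(pool, sort(maxes, decreasing = TRUE)[seq_len(keep_k)])
  }
  out <- tibble::tibble(
    significant = as.numeric(quantile(pool, 0.95)),
    suggestive = as.numeric(quantile(pool, 0.80))
  )
  attr(out, "pool") <- pool
  out
}

#' Interpolate genetic position from physical position
#'
#' Linear interpolation between the chromosome's markers, clamped at the
#' terminal markers.
#'
#' @param map Marker map.
#' @param chrom Chromosome name(s).
#' @param bp Physical position(s).
#' @return Genetic position(s) in cM (NA for unknown chromosome).
#' @export
interp_cm <- function(map, chrom, bp) {
  vapply(seq_along(chrom), function(i) {
    if (is.na(chrom[i])) return(NA_real_)
    mm <- map[map$chrom == chrom[i], ]
    if (!nrow(mm)) return(NA_real_)
    if (nrow(mm) == 1) return(mm$cm)
    stats::approx(mm$bp, mm$cm, xout = bp[i], rule = 2, ties = "ordered")$y
  }, 0)
}

#' Classify QTL as cis or trans
#'
#' A QTL is cis when its peak lies on the same chromosome as its phenotype
#' and within `margin` cM of the phenotype's interpolated genetic position
#' (boundary included); otherwise trans. Phenotypes without a genomic
#' location are `"unplaced"`.
#'
#' @param records QTL record tibble with `chrom`, `pos_cm` (peak) and
#'   `phen_chrom`, `phen_bp` (phenotype location, NA allowed).
#' @param map Marker map (for bp-to-cM interpolation).
#' @param margin Cis margin in cM (default 50).
#' @return `records` with a `classification` column.
#' @export
classify_cis_trans <- function(records, map, margin = 50) {
  phen_cm <- interp_cm(map, records$phen_chrom, records$phen_bp)
  records$classification <- dplyr::case_when(
    is.na(records$phen_chrom) ~ "unplaced",
    records$chrom != records$phen_chrom ~ "trans",
    is.na(phen_cm) ~ "unplaced",
    abs(records$pos_cm - phen_cm) <= margin ~ "cis",
    TRUE ~ "trans"
  )
  records
}

#' 1.5-LOD support interval
#'
#' The widest contiguous interval around the peak on which the LOD stays
#' within `drop` of the peak LOD, expanded outward to the nearest flanking
#' typed markers for bp reporting.
#'
#' @param scan A `lod_scan`.
#' @param peak Optional peak row (default the scan maximum).
#' @param drop LOD drop (default 1.5).
#' @param map Optional marker map for flanking-marker bp expansion.
#' @return A one-row tibble: `chrom`, `ci_lo_cm`, `ci_hi_cm` and, with a map,
#'   `ci_lo_marker`, `ci_hi_marker`, `ci_lo_bp`, `ci_hi_bp`.
#' @export
support_interval <- function(scan, peak = scan_peak(scan), drop = 1.5, map = NULL) {
  cc <- scan[scan$chrom == peak$chrom, ]
  i <- which(cc$pos_cm == peak$pos_cm)[1]
  thr <- cc$lod[i] - drop
  lo <- i
  while (lo > 1 && cc$lod[lo - 1] >= thr) lo <- lo - 1
  hi <- i
  while (hi < nrow(cc) && cc$lod[hi + 1] >= thr) hi <- hi + 1
  out <- tibble::tibble(chrom = peak$chrom,
                        ci_lo_cm = cc$pos_cm[lo], ci_hi_cm = cc$pos_cm[hi])
  if (!is.null(map)) {
    mm <- map[map$chrom == peak$chrom, ]
    lo_idx <- max(c(1L, which(mm$cm <= out$ci_lo_cm)))
    hi_idx <- min(c(nrow(mm), which(mm$cm >= out$ci_hi_cm)))
    out$ci_lo_marker <- mm$marker[lo_idx]
    out$ci_hi_marker <- mm$marker[hi_idx]
    out$ci_lo_bp <- mm$bp[lo_idx]
    out$ci_hi_bp <- mm$bp[hi_idx]
  }
  out
}

#' Genotype-class counts at a marker
#'
#' @param genotypes Genotype tibble.
#' @param marker Marker id.
#' @return Named integer vector of counts per observed dosage class.
#' @export
genotype_class_counts <- function(genotypes, marker) {
  g <- round(genotypes[[marker]])
  table(g[!is.na(g)])
}

#' Quality-control filter for QTL records
#'
#' Drops records with fewer than `min_class` individuals in any genotype
#' class at the peak marker, and flags records whose peak is driven by a
#' single influential observation: the most influential phenotype value
#' (largest DFFITS in the peak-marker fit) is removed and the peak LOD
#' recomputed; if it falls below `loo_threshold` the record is flagged
#' (and dropped when `drop_outliers = TRUE`). The leave-one-out check is an
#' automated surrogate for visual outlier inspection.
#'
#' @param records QTL record tibble with columns `phenotype`, `marker`, `lod`.
#' @param genotypes Genotype tibble.
#' @param phenotypes Matrix or wide tibble of phenotype values (rows named by
#'   phenotype id, columns by individual).
#' @param samples Sample sheet.
#' @param min_class Minimum genotype-class size (default 10).
#' @param loo_threshold LOD threshold for the leave-one-out check (NULL
#'   disables it).
#' @param drop_outliers Drop flagged records instead of only flagging.
#' @return Filtered records with added columns `min_class_n` and
#'   `outlier_flag`.
#' @export
qc_filter <- function(records, genotypes, phenotypes, samples,
                      min_class = 10, loo_threshold = NULL,
                      drop_outliers = FALSE) {
  if (!nrow(records)) return(records)
  if (is.data.frame(phenotypes)) {
    pm <- as_value_matrix(phenotypes)
  } else pm <- phenotypes
  records$min_class_n <- vapply(unname(records$marker), function(mk) {
    as.integer(min(genotype_class_counts(genotypes, mk)))
  }, 1L, USE.NAMES = FALSE)
  records$outlier_flag <- FALSE
  if (!is.null(loo_threshold)) {
    X0 <- covariate_matrix(samples[match(genotypes$id, samples$id), ])
    for (k in seq_len(nrow(records))) {
      y <- pm[records$phenotype[k], genotypes$id]
      d <- genotypes[[records$marker[k]]]
      okc <- complete.cases(y, d)
      fit <- lm(y[okc] ~ X0[okc, -1, drop = FALSE] + d[okc])
      infl <- abs(stats::dffits(fit))
      worst <- which(okc)[which.max(infl)]
      keep <- setdiff(which(okc), worst)
      lod_loo <- marker_lod(y[keep], d[keep], X0[keep, , drop = FALSE])
      records$outlier_flag[k] <- lod_loo < loo_threshold
    }
  }
  records <- records[records$min_class_n >= min_class, ]
  if (drop_outliers) records <- records[!records$outlier_flag, ]
  records
}

# Single-marker Haley-Knott LOD by direct least squares.
marker_lod <- function(y, d, X0) {
  ok <- complete.cases(y, d)
  y <- y[ok]; d <- d[ok]; X0 <- X0[ok, , drop = FALSE]
  rss0 <- sum(qr.resid(qr(X0), y)^2)
  rss1 <- sum(qr.resid(qr(cbind(X0, d)), y)^2)
  if (rss0 < 1e-12) return(0)
  (length(y) / 2) * log10(rss0 / max(rss1, 1e-300))
}

#' Map QTL for a set of phenotypes
#'
#' Runs additive and sex-interactive Haley-Knott scans for each phenotype,
#' flags sex interactions (interactive LOD more than 1 above additive at the
#' peak), computes 1.5-LOD support intervals, classifies cis/trans against
#' the phenotype location, and applies the genotype-class QC filter.
#'
#' @param phenotypes Wide phenotype tibble (methylation windows or expression
#'   probesets, one column per individual).
#' @param genotypes,map,samples Study components.
#' @param probs Optional precomputed [genotype_probs()].
#' @param step Pseudomarker step in cM (default 2).
#' @param lod_min Retain records with (model-appropriate) LOD at least this
#'   (default 3).
#' @param min_class QC minimum genotype-class count (default 10).
#' @param margin Cis margin in cM (default 50).
#' @return A tibble of QTL records: `phenotype`, `phen_chrom`, `phen_bp`,
#'   peak `chrom`, `pos_cm`, `marker`, `lod` (of the reported model),
#'   `lod_add`, `lod_int`, `sex_interaction`, support-interval columns,
#'   `classification`, `min_class_n`.
#' @export
map_qtl <- function(phenotypes, genotypes, map, samples,
                    probs = NULL, step = 2, lod_min = 3,
                    min_class = 10, margin = 50) {
  if (is.null(probs)) probs <- genotype_probs(genotypes, map, step = step)
  pm <- as_value_matrix(phenotypes)[, genotypes$id, drop = FALSE]
  has_loc <- all(c("chrom", "start") %in% names(phenotypes))
  eng <- scan_engine(probs, samples)
  grid <- eng$grid
  nearest_marker <- vapply(seq_len(nrow(grid)), function(j) {
    mm <- map[map$chrom == grid$chrom[j], ]
    mm$marker[which.min(abs(mm$cm - grid$pos_cm[j]))]
  }, "")

  recs <- purrr::map_dfr(seq_len(nrow(pm)), function(k) {
    y <- pm[k, ]
    lod_a <- scan_lod(eng, y, interactive = FALSE)
    lod_i <- scan_lod(eng, y, interactive = TRUE)
    sexint <- (max(lod_i) - max(lod_a)) > 1.0
    j <- if (sexint) which.max(lod_i) else which.max(lod_a)
    lod_rep <- if (sexint) lod_i[j] else lod_a[j]
    if (lod_rep < lod_min) return(NULL)
    curve <- grid
    curve$lod <- if (sexint) lod_i else lod_a
    class(curve) <- c("lod_scan", class(curve))
    ci <- support_interval(curve, peak = curve[j, ], map = map)
    tibble::tibble(
      phenotype = rownames(pm)[k],
      phen_chrom = if (has_loc) phenotypes$chrom[k] else NA_character_,
      phen_bp = if (has_loc) phenotypes$start[k] else NA_real_,
      chrom = grid$chrom[j], pos_cm = grid$pos_cm[j],
      marker = nearest_marker[j],
      lod = lod_rep, lod_add = lod_a[j], lod_int = lod_i[j],
      sex_interaction = sexint,
      ci_lo_cm = ci$ci_lo_cm, ci_hi_cm = ci$ci_hi_cm,
      ci_lo_marker = ci$ci_lo_marker, ci_hi_marker = ci$ci_hi_marker,
      ci_lo_bp = ci$ci_lo_bp, ci_hi_bp = ci$ci_hi_bp
    )
  })
  if (!nrow(recs)) return(recs)
  recs <- classify_cis_trans(recs, map, margin = margin)
  qc_filter(recs, genotypes, pm, samples, min_class = min_class)
}
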