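#' Read the bundled MHM-adjacent gene table
#'
#' The bundled table lists, per MHM block, the probesets within 100 kb:
#' average expression overall and per sex, the sex-difference p-value, the
#' male:female expression ratio, and how many of the block's 1-kb methylation
#' windows each gene's expression correlates with (total / negative /
#' positive slope t). Probesets whose array ids were not recoverable carry
#' synthetic stable ids (`est_01` ...). Genes not on the array have NA
#' expression fields but are retained for gene counting.
#'
#' @param path Path to a TSV in the same layout (default: the bundled table).
#' @return A tibble, one row per (block, probeset).
#' @export
read_mhm_gene_table <- function(path = zmethqtl_example("mhm_gene_table.tsv")) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    block = readr::col_integer(),
                    probeset = readr::col_character(),
                    gene_name = readr::col_character()
                  ))
}

#' @rdname read_mhm_gene_table
#' @export
read_fhm_window_table <- function(path = zmethqtl_example("fhm_window_table.tsv")) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_mhm_gene_table
#' @export
read_trans_hotspot_table <- function(path = zmethqtl_example("trans_hotspot_table.tsv")) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Deduplicate genes repeated across adjacent blocks
#'
#' Blocks in close proximity share neighbouring genes, so the per-block gene
#' table repeats probesets. This collapses to one record per probeset.
#' Expression fields must be identical across a probeset's rows (they
#' describe the gene, not the block) — conflicting duplicates are an error.
#' Correlation counts differ across blocks by construction; each gene keeps
#' the counts of its row with the most correlations.
#'
#' @param records Gene table as from [read_mhm_gene_table()].
#' @return One row per probeset.
#' @export
dedupe_genes <- function(records) {
  expr_cols <- c("avg_exp", "avg_exp_male", "avg_exp_female",
                 "wilcox_pval", "mf_ratio")
  chk <- records |>
    dplyr::group_by(.data$probeset) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(expr_cols),
                                   ~ dplyr::n_distinct(.x) > 1),
                     .groups = "drop")
  bad <- chk$probeset[rowSums(as.matrix(chk[, expr_cols])) > 0]
  if (length(bad)) {
    stop("inconsistent input: duplicated probesets with conflicting expression: ",
         paste(bad, collapse = ", "))
  }
  records |>
    dplyr::group_by(.data$probeset) |>
    dplyr::arrange(dplyr::desc(.data$n_corr), .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$block, .data$probeset)
}

#' Classify genes as balanced, male-biased unbalanced, or female-biased
#'
#' Applied to deduplicated, expression-bearing genes: `female_biased` when
#' the sex-difference p is strictly below `alpha` and the male:female ratio
#' is below 1; `male_biased_unbalanced` when p is strictly below `alpha` and
#' the ratio above 1; `balanced` otherwise (including the p = alpha
#' boundary).
#'
#' @param records Deduplicated gene records ([dedupe_genes()]); rows without
#'   expression values are dropped.
#' @param alpha Significance level for a sex difference (default 0.05).
#' @return `records` restricted to expression-bearing genes with a `class`
#'   column.
#' @export
classify_genes <- function(records, alpha = 0.05) {
  records <- records[!is.na(records$avg_exp), ]
  records$class <- dplyr::case_when(
    records$wilcox_pval < alpha & records$mf_ratio < 1 ~ "female_biased",
    records$wilcox_pval < alpha & records$mf_ratio > 1 ~ "male_biased_unbalanced",
    TRUE ~ "balanced"
  )
  records
}

#' Per-class expression summaries
#'
#' Mean and sample SD (n-1 denominator) of the male and female average
#' expression within each class, rounded to integers. A single-gene class
#' reports SD 0 with `sd_undefined = TRUE`.
#'
#' @param labelled Classified records from [classify_genes()].
#' @return A tibble: `class`, `n`, `mean_male`, `sd_male`, `mean_female`,
#'   `sd_female`, `sd_undefined`.
#' @export
group_summary <- function(labelled) {
  labelled |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_male = round(mean(.data$avg_exp_male)),
      sd_male = ifelse(dplyr::n() > 1, round(sd(.data$avg_exp_male)), 0),
      mean_female = round(mean(.data$avg_exp_female)),
      sd_female = ifelse(dplyr::n() > 1, round(sd(.data$avg_exp_female)), 0),
      sd_undefined = dplyr::n() < 2,
      .groups = "drop"
    )
}

#' Welch test of balanced versus male-biased unbalanced expression
#'
#' Two-sided Welch two-sample t-test of the per-gene average expression of
#' the given sex, balanced minus male-biased unbalanced.
#'
#' @param labelled Classified records.
#' @param sex `"male"` or `"female"`.
#' @return A tibble: `statistic`, `df`, `pvalue`.
#' @export
balanced_vs_unbalanced_test <- function(labelled, sex = c("male", "female")) {
  sex <- match.arg(sex)
  col <- if (sex == "male") "avg_exp_male" else "avg_exp_female"
  x <- labelled[[col]][labelled$class == "balanced"]
  y <- labelled[[col]][labelled$class == "male_biased_unbalanced"]
  if (length(x) < 2 || length(y) < 2) stop("both classes need at least 2 genes")
  tt <- t.test(x, y, var.equal = FALSE)
  tibble::tibble(statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 pvalue = tt$p.value)
}

#' Per-class methylation-correlation rates
#'
#' Mean number of significant methylation-window correlations per gene
#' within each class, split by slope sign (2 dp). Each gene's counts enter
#' once (after [dedupe_genes()]).
#'
#' @param labelled Classified records.
#' @return A tibble: `class`, `n_genes`, `mean_total`, `mean_positive`,
#'   `mean_negative`.
#' @export
correlation_summary <- function(labelled) {
  labelled |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      mean_total = round(mean(.data$n_corr), 2),
      mean_positive = round(mean(.data$n_pos), 2),
      mean_negative = round(mean(.data$n_neg), 2),
      .groups = "drop"
    )
}

#' Count significant methylation-expression correlations within a block
#'
#' For each gene within `flank` of the block and each 1-kb window inside the
#' block, fits `expression ~ methylation + sex` and counts windows whose
#' slope is significant after multiplicity adjustment over the block's
#' gene-by-window family, split by slope sign.
#'
#' @param block One block row (from [find_blocks()]): `chrom`, `start`, `end`.
#' @param expression Wide expression tibble with gene coordinates.
#' @param methylation Wide normalized methylation tibble.
#' @param samples Sample sheet.
#' @param flank Gene-to-block distance limit in bp (default 100000).
#' @param adjust Multiplicity adjustment (default `"BH"`).
#' @param alpha Adjusted significance level (default 0.05).
#' @return A tibble: `probeset`, `n_corr`, `n_pos`, `n_neg` (with
#'   `n_corr = n_pos + n_neg`).
#' @export
count_block_correlations <- function(block, expression, methylation, samples,
                                     flank = 1e5, adjust = "BH", alpha = 0.05) {
  near <- expression$gene_chrom == block$chrom &
    interval_distance(block$start, block$end,
                      expression$gene_start, expression$gene_end) <= flank
  genes <- expression$probeset[near]
  win <- methylation$chrom == block$chrom &
    methylation$start >= block$start & methylation$start < block$end
  wins <- methylation$window_id[win]
  if (!length(genes) || !length(wins)) {
    return(tibble::tibble(probeset = genes, n_corr = 0L,
                          n_pos = 0L, n_neg = 0L))
  }
  em <- as_value_matrix(expression)
  mm <- as_value_matrix(methylation)
  ids <- intersect(colnames(em), colnames(mm))
  sex <- factor(samples$sex[match(ids, samples$id)])

  grid <- tidyr::crossing(probeset = genes, window_id = wins)
  st <- purrr::map_dfr(seq_len(nrow(grid)), function(k) {
    s <- lm_slope_stats(em[grid$probeset[k], ids], mm[grid$window_id[k], ids],
                        covar = sex)
    tibble::tibble(t = s["t"], p = s["p"])
  })
  grid <- dplyr::bind_cols(grid, st)
  grid$padj <- p.adjust(grid$p, method = adjust)
  grid$sig <- !is.na(grid$padj) & grid$padj < alpha
  grid |>
    dplyr::group_by(.data$probeset) |>
    dplyr::summarise(
      n_corr = sum(.data$sig),
      n_pos = sum(.data$sig & .data$t > 0),
      n_neg = sum(.data$sig & .data$t < 0),
      .groups = "drop"
    )
}
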