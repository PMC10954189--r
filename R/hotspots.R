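#' Aggregate trans QTL into hotspots
#'
#' Groups trans QTL records by peak marker, optionally merges groups at
#' adjacent markers whose members' confidence intervals all mutually overlap,
#' retains groups with at least `min_count` members, and reports each
#' hotspot's minimal shared span: the intersection of the member support
#' intervals (`[max of lows, min of highs]`). A group whose intersection is
#' empty falls back to the union span with a warning.
#'
#' @param records QTL record tibble with columns `phenotype`, `marker`,
#'   `chrom`, plus support-interval bp bounds `ci_lo_bp`, `ci_hi_bp`.
#' @param map Marker map (for marker order/adjacency and positions).
#' @param min_count Minimum member QTL per hotspot (default 10).
#' @param merge_adjacent Merge groups at consecutive markers when every
#'   pairwise member-interval overlap is non-empty (default TRUE).
#' @return A tibble shaped like a hotspot report: `hotspot`, `num_qtl`,
#'   `marker` (peak marker(s), comma-separated when merged), `chrom`, `pos`
#'   (bp of the modal peak marker), `ci_lo_pos`, `ci_hi_pos`, `ci_size`, and
#'   a list-column `members` of phenotype ids.
#' @export
find_hotspots <- function(records, map, min_count = 10, merge_adjacent = TRUE) {
  empty <- tibble::tibble(hotspot = character(), num_qtl = integer(),
                          marker = character(), chrom = character(),
                          pos = numeric(), ci_lo_pos = numeric(),
                          ci_hi_pos = numeric(), ci_size = numeric(),
                          members = list())
  if (!nrow(records)) return(empty)
  records <- dplyr::arrange(records, .data$phenotype)
  groups <- split(records, records$marker)

  # Order groups along the map so adjacency is well-defined.
  ord <- order(match(names(groups), map$marker))
  groups <- groups[ord]

  if (merge_adjacent && length(groups) > 1) {
    merged <- list(groups[[1]])
    for (g in groups[-1]) {
      last <- merged[[length(merged)]]
      mk_last <- map$marker[max(match(unique(last$marker), map$marker))]
      mk_new <- g$marker[1]
      adjacent <- map$chrom[match(mk_new, map$marker)] ==
        map$chrom[match(mk_last, map$marker)] &&
        abs(match(mk_new, map$marker) - match(mk_last, map$marker)) == 1
      both <- dplyr::bind_rows(last, g)
      all_overlap <- max(both$ci_lo_bp) <= min(both$ci_hi_bp)
      if (adjacent && all_overlap) {
        merged[[length(merged)]] <- both
      } else {
        merged <- c(merged, list(g))
      }
    }
    groups <- merged
  }

  groups <- groups[vapply(groups, nrow, 1L) >= min_count]
  if (!length(groups)) return(empty)

  out <- purrr::imap_dfr(groups, function(g, nm) {
    lo <- max(g$ci_lo_bp)
    hi <- min(g$ci_hi_bp)
    if (lo > hi) {
      warning("empty interval intersection at marker ", g$marker[1],
              "; falling back to the union span")
      lo <- min(g$ci_lo_bp)
      hi <- max(g$ci_hi_bp)
    }
    peak_mk <- names(sort(table(g$marker), decreasing = TRUE))[1]
    tibble::tibble(
      num_qtl = nrow(g),
      marker = paste(unique(g$marker), collapse = ","),
      chrom = g$chrom[1],
      pos = map$bp[match(peak_mk, map$marker)],
      ci_lo_pos = lo, ci_hi_pos = hi, ci_size = hi - lo,
      members = list(g$phenotype)
    )
  })
  out <- dplyr::arrange(out, match(out$chrom, unique(map$chrom)), out$pos)
  out$hotspot <- paste0("hotspot_", seq_len(nrow(out)))
  dplyr::select(out, "hotspot", dplyr::everything())
}

#' Summarise a hotspot table
#'
#' @param hotspots Tibble from [find_hotspots()] (or a table with `chrom`,
#'   `ci_size`, and optionally a `members` list-column with target phenotype
#'   window ids and a `z_chrom` name).
#' @param z_chrom Name of the Z chromosome (default `"chrZ"`, with a bare
#'   `"Z"` also recognised).
#' @return A list: `n_hotspots`, `mean_span_mb` (arithmetic mean of
#'   `ci_size` in Mb, 2 dp), `per_chrom` (tibble of counts), and
#'   `autosome_to_z` / `on_z` counts of hotspots located off/on the Z.
#' @export
hotspot_summary <- function(hotspots, z_chrom = "chrZ") {
  if (!nrow(hotspots)) {
    return(list(n_hotspots = 0L, mean_span_mb = NA_real_,
                per_chrom = tibble::tibble(chrom = character(), n = integer()),
                autosome_to_z = 0L, on_z = 0L))
  }
  on_z <- hotspots$chrom %in% c(z_chrom, "Z")
  list(
    n_hotspots = nrow(hotspots),
    mean_span_mb = round(mean(hotspots$ci_size) / 1e6, 2),
    per_chrom = dplyr::count(hotspots, .data$chrom),
    autosome_to_z = sum(!on_z),
    on_z = sum(on_z)
  )
}

#' Count annotated genes within hotspot spans
#'
#' Optional helper mirroring the `num_genes` column of a hotspot report.
#'
#' @param hotspots Hotspot tibble.
#' @param annotation Gene annotation tibble with `chrom`, `start`, `end`.
#' @return `hotspots` with a `num_genes` column (genes whose interval
#'   overlaps the hotspot span, boundaries closed).
#' @export
hotspot_gene_counts <- function(hotspots, annotation) {
  hotspots$num_genes <- vapply(seq_len(nrow(hotspots)), function(i) {
    sum(annotation$chrom == hotspots$chrom[i] &
          annotation$start <= hotspots$ci_hi_pos[i] &
          annotation$end >= hotspots$ci_lo_pos[i])
  }, 1L)
  hotspots
}
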