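#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the per-model fits of a causal orientation
#'
#' @param x A `causal_fit` from [leo_nb_orient()].
#' @param ... Unused.
#' @return One row per candidate path model: `model`, `chisq`, `df`,
#'   `pvalue`, and whether it was the best-fitting model.
#' @export
tidy.causal_fit <- function(x, ...) {
  out <- x$fits[, c("model", "chisq", "df", "pvalue")]
  out$best <- out$model == x$best_model
  out
}

#' One-row summary of a causal orientation
#'
#' @param x A `causal_fit`.
#' @param ... Unused.
#' @return A tibble: `orientation`, `leo_nb_oca`, `leo_nb_cpa`,
#'   `model_pvalue`, `significant`, `suggestive`, `caveat`, `n`.
#' @export
glance.causal_fit <- function(x, ...) {
  tibble::tibble(orientation = x$orientation,
                 leo_nb_oca = x$leo_nb_oca,
                 leo_nb_cpa = x$leo_nb_cpa,
                 model_pvalue = x$model_pvalue,
                 significant = x$significant,
                 suggestive = x$suggestive,
                 caveat = x$caveat,
                 n = x$n)
}

#' One-row summary of a LOD scan
#'
#' @param x A `lod_scan`.
#' @param ... Unused.
#' @return A tibble with the peak position, peak LOD and the fitted model.
#' @export
glance.lod_scan <- function(x, ...) {
  pk <- scan_peak(x)
  tibble::tibble(chrom = pk$chrom, pos_cm = pk$pos_cm, marker = pk$marker,
                 max_lod = pk$lod, model = attr(x, "model") %||% "additive")
}

#' @importFrom rlang %||%
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
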