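# Cross-sectional cohort analysis: per-sample temperate proportions and
# two-group comparison by the Wilcoxon rank-sum test.

#' Summarize one sample's prediction records
#'
#' Counts predicted labels and computes the temperate proportion
#' `n_temperate / (n_temperate + n_virulent)`; uncertain calls are
#' excluded from the proportion but counted. Proportions are per contig,
#' unweighted by length; set `length_weighted = TRUE` to weight each
#' contig by its length in bp instead.
#'
#' @param records Prediction data frame for one sample (columns `label`
#'   and, if length weighting, `length`).
#' @param sample_id Sample identifier.
#' @param source `"virome"` (experimental phages) or `"metagenome_phage"`
#'   (phage contigs identified computationally in bulk metagenomes).
#' @param length_weighted Weight contigs by length when `TRUE`.
#' @return One-row data frame with counts, `temperate_proportion` (`NA`
#'   when no certain call exists) and a `flagged` indicator.
#' @export
summarize_sample <- function(records, sample_id,
                             source = c("virome", "metagenome_phage"),
                             length_weighted = FALSE) {
  source <- match.arg(source)
  stopifnot(is.data.frame(records), "label" %in% names(records))
  n_v <- sum(records$label == "virulent")
  n_t <- sum(records$label == "temperate")
  n_u <- sum(records$label == "uncertain")
  if (length_weighted) {
    stopifnot("length" %in% names(records))
    w_v <- sum(records$length[records$label == "virulent"])
    w_t <- sum(records$length[records$label == "temperate"])
    prop <- if (w_v + w_t > 0) w_t / (w_v + w_t) else NA_real_
  } else {
    prop <- if (n_v + n_t > 0) n_t / (n_v + n_t) else NA_real_
  }
  data.frame(sample_id = sample_id, source = source,
             n_virulent = n_v, n_temperate = n_t, n_uncertain = n_u,
             temperate_proportion = prop, flagged = is.na(prop),
             stringsAsFactors = FALSE)
}

#' Compare temperate proportions between two sample groups
#'
#' Two-sided Wilcoxon rank-sum test with the Hodges-Lehmann estimate of
#' the location shift (group 1 minus group 2) and its 95% confidence
#' interval. The exact null distribution is used for group sizes up to 12
#' per side without ties; larger or tied samples use the normal
#' approximation with continuity correction.
#'
#' @param group1,group2 Numeric vectors of per-sample temperate
#'   proportions (`NA`s dropped; each group needs >= 2 defined values).
#' @param conf_level Confidence level of the interval.
#' @return An object of class `cohort_comparison`: list with `p_value`,
#'   `location_shift`, `conf_int`, `exact`, `n1`, `n2`.
#' @examples
#' compare_groups(c(0.1, 0.2), c(0.8, 0.9))$p_value  # 1/3
#' @export
compare_groups <- function(group1, group2, conf_level = 0.95) {
  g1 <- group1[!is.na(group1)]
  g2 <- group2[!is.na(group2)]
  if (length(g1) < 2 || length(g2) < 2)
    stop("each group needs at least 2 defined proportions")
  ties <- anyDuplicated(c(g1, g2)) > 0
  exact <- length(g1) <= 12 && length(g2) <= 12 && !ties
  wt <- withCallingHandlers(
    wilcox.test(g1, g2, alternative = "two.sided", conf.int = TRUE,
                conf.level = conf_level, exact = exact, correct = TRUE),
    # with very small groups the widest achievable interval is returned;
    # that is the intended behaviour, not something to warn the caller about
    warning = function(w) {
      if (grepl("conf.level not achievable", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(p_value = unname(wt$p.value),
                 location_shift = unname(wt$estimate),
                 conf_int = unname(wt$conf.int),
                 exact = exact, n1 = length(g1), n2 = length(g2)),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf(paste0("Two-sided Wilcoxon rank-sum (%s): p = %.4g\n",
                     "  difference in location = %.4g, CI = (%.4g, %.4g)\n"),
              if (x$exact) "exact" else "normal approximation",
              x$p_value, x$location_shift, x$conf_int[1], x$conf_int[2]))
  invisible(x)
}

#' Collect defined temperate proportions from sample summaries
#'
#' @param summaries Data frame of rows from [summarize_sample()].
#' @return Numeric vector of defined (non-flagged) proportions.
#' @export
temperate_proportions <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            "temperate_proportion" %in% names(summaries))
  summaries$temperate_proportion[!is.na(summaries$temperate_proportion)]
}
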