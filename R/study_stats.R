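# Study-level statistics: test-retest repeatability (within-subject CoV),
# paired pre/post comparisons (Wilcoxon signed-rank), repeated-measures
# analysis of the BOLD timecourse, percent-of-baseline series, and the
# Pearson correlation between the related diffusion parameters ADC and D.
# Significance is assessed at 5%; no multiple-testing correction is applied
# across parameters or regions.

as_pairs <- function(value_1, value_2) {
  if (is.data.frame(value_1)) {
    df <- value_1
    if (!all(c("value_1", "value_2") %in% names(df)))
      stop_invalid("paired data.frame needs columns value_1 and value_2")
    value_1 <- df$value_1; value_2 <- df$value_2
  }
  ok <- is.finite(value_1) & is.finite(value_2)
  if (!all(ok)) warning(sum(!ok), " incomplete pair(s) dropped")
  cbind(value_1[ok], value_2[ok])
}

#' Within-subject coefficient of variation
#'
#' Test-retest repeatability of paired measurements as the within-subject
#' root-mean-square CoV,
#' `100 * sqrt( (1 / 2N) * sum_i (d_i / m_i)^2 )`,
#' where `d_i` and `m_i` are the difference and mean of pair i. The
#' statistic is invariant to rescaling all measurements and to swapping the
#' two scans within any pair.
#'
#' @param value_1,value_2 Paired measurements (scan 1 / scan 2), or a
#'   data.frame with columns `value_1`, `value_2` as first argument.
#' @return CoV in percent.
#' @examples
#' cov_repeatability(c(100, 120), c(110, 118))
#' @export
cov_repeatability <- function(value_1, value_2 = NULL) {
  p <- as_pairs(value_1, value_2)
  m <- rowMeans(p)
  bad <- m <= 0
  if (any(bad)) {
    warning(sum(bad), " pair(s) with non-positive mean dropped")
    p <- p[!bad, , drop = FALSE]; m <- m[!bad]
  }
  if (nrow(p) == 0L) stop_invalid("no usable pairs for CoV")
  d <- p[, 1] - p[, 2]
  100 * sqrt(sum((d / m)^2) / (2 * nrow(p)))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided Wilcoxon signed-rank test on paired differences, with the
#' exact null distribution for up to 25 non-zero pairs and the normal
#' approximation with continuity correction beyond. Zero differences are
#' removed (Wilcoxon's convention); if every difference is zero the test is
#' degenerate and p = 1 is reported with a note. The significance flag uses
#' the 5% level.
#'
#' @inheritParams cov_repeatability
#' @return A list: `statistic` (V), `p_value`, `n` (non-zero pairs),
#'   `significant` (p < 0.05), `note`.
#' @export
paired_test <- function(value_1, value_2 = NULL) {
  p <- as_pairs(value_1, value_2)
  d <- p[, 1] - p[, 2]
  nz <- d != 0
  if (!any(nz)) {
    return(list(statistic = NA_real_, p_value = 1, n = 0L,
                significant = FALSE,
                note = "all paired differences are zero (degenerate)"))
  }
  if (sum(nz) < 2L)
    warning("fewer than two non-zero pairs; the test has no power")
  exact <- sum(nz) <= 25L
  ht <- suppressWarnings(
    wilcox.test(p[, 1], p[, 2], paired = TRUE, exact = exact,
                correct = TRUE, alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n = sum(nz), significant = ht$p.value < 0.05,
       note = if (any(!nz)) paste(sum(!nz), "zero difference(s) removed")
              else NA_character_)
}

check_timecourse <- function(tc) {
  need <- c("unit_id", "timepoint", "value")
  if (!is.data.frame(tc) || !all(need %in% names(tc)))
    stop_invalid("timecourse needs columns unit_id, timepoint, value")
  if (!is.factor(tc$timepoint)) {
    tc$timepoint <- factor(tc$timepoint, levels = unique(tc$timepoint))
  }
  levs <- levels(tc$timepoint)
  complete <- tapply(tc$timepoint, tc$unit_id,
                     function(t) length(unique(t)) == length(levs))
  bad <- names(complete)[!complete]
  if (length(bad)) {
    warning("unit(s) with incomplete timecourse dropped: ",
            paste(bad, collapse = ", "))
    tc <- tc[!tc$unit_id %in% bad, , drop = FALSE]
  }
  ok <- is.finite(tc$value)
  if (!all(ok)) {
    bad_units <- unique(tc$unit_id[!ok])
    warning("unit(s) with non-finite values dropped: ",
            paste(bad_units, collapse = ", "))
    tc <- tc[!tc$unit_id %in% bad_units, , drop = FALSE]
  }
  tc$timepoint <- droplevels(tc$timepoint)
  tc
}

#' Repeated-measures analysis of a BOLD timecourse
#'
#' One-way repeated-measures ANOVA of T2* across timepoints, with the
#' kidney as the subject unit. When the omnibus test is significant at 5%,
#' pairwise paired comparisons are reported for each post-baseline
#' timepoint against baseline (flag `sig_vs_baseline`) and against the
#' previous timepoint (`sig_vs_previous`).
#'
#' @param tc Long data.frame with columns `unit_id`, `timepoint` (the first
#'   level is the baseline), `value`. Units with incomplete timecourses
#'   are dropped with a warning.
#' @return A list: `omnibus_p`, `n_units`, and `table` (one row per
#'   post-baseline timepoint with p-values and 5% significance flags).
#' @export
bold_timecourse_test <- function(tc) {
  tc <- check_timecourse(tc)
  levs <- levels(tc$timepoint)
  n_units <- length(unique(tc$unit_id))
  if (n_units < 2L)
    stop_invalid("need at least two units with complete timecourses")
  tc$unit_id <- factor(tc$unit_id)
  fit <- aov(value ~ timepoint + Error(unit_id / timepoint), data = tc)
  sm <- summary(fit)
  tab <- sm[["Error: unit_id:timepoint"]][[1]]
  omnibus_p <- tab["timepoint", "Pr(>F)"]
  wide <- tapply(tc$value, list(tc$unit_id, tc$timepoint), mean)
  posts <- levs[-1]
  res <- data.frame(timepoint = posts, p_vs_baseline = NA_real_,
                    p_vs_previous = NA_real_, sig_vs_baseline = FALSE,
                    sig_vs_previous = FALSE, stringsAsFactors = FALSE)
  # paired t-test; zero-variance differences make the test degenerate
  safe_t <- function(x, y) {
    tryCatch(t.test(x, y, paired = TRUE)$p.value,
             error = function(e) if (isTRUE(all.equal(x, y))) 1 else NA_real_)
  }
  if (is.finite(omnibus_p) && omnibus_p < 0.05) {
    for (k in seq_along(posts)) {
      prev <- levs[k]
      res$p_vs_baseline[k] <- safe_t(wide[, posts[k]], wide[, levs[1]])
      res$p_vs_previous[k] <- safe_t(wide[, posts[k]], wide[, prev])
    }
    res$sig_vs_baseline <- !is.na(res$p_vs_baseline) & res$p_vs_baseline < 0.05
    res$sig_vs_previous <- !is.na(res$p_vs_previous) & res$p_vs_previous < 0.05
  }
  list(omnibus_p = omnibus_p, n_units = n_units, table = res)
}

#' Percent-of-baseline timecourse
#'
#' Expresses each unit's timecourse as a percentage of its own baseline
#' (first timepoint level), and summarises the cohort as mean +/- standard
#' error per timepoint. The baseline timepoint is 100% identically.
#'
#' @inheritParams bold_timecourse_test
#' @return A list: `per_unit` (unit_id, timepoint, percent) and `cohort`
#'   (timepoint, mean_percent, se_percent, n).
#' @export
percent_change <- function(tc) {
  tc <- check_timecourse(tc)
  levs <- levels(tc$timepoint)
  base <- tc[tc$timepoint == levs[1], ]
  baseline <- setNames(base$value, base$unit_id)
  if (any(baseline <= 0))
    stop_invalid("baseline values must be positive for percent change")
  tc$percent <- 100 * tc$value / baseline[as.character(tc$unit_id)]
  cohort <- do.call(rbind, lapply(levs, function(l) {
    v <- tc$percent[tc$timepoint == l]
    data.frame(timepoint = l, mean_percent = mean(v),
               se_percent = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0,
               n = length(v), stringsAsFactors = FALSE)
  }))
  list(per_unit = tc[, c("unit_id", "timepoint", "percent")],
       cohort = cohort)
}

#' Pearson correlation between ADC and D
#'
#' Correlation of the perfusion-insensitive ADC with the IVIM tissue
#' diffusivity D across ROI medians; close agreement (r near 1) indicates
#' that perfusion effects are removed at high b-values.
#'
#' @param adc,d Paired ROI medians (any consistent units).
#' @return A list: `r`, `n`, `note` (`NA` unless the correlation is
#'   undefined through zero variance).
#' @export
correlate_adc_d <- function(adc, d) {
  ok <- is.finite(adc) & is.finite(d)
  adc <- adc[ok]; d <- d[ok]
  if (length(adc) < 3L) stop_invalid("need at least three paired values")
  if (sd(adc) == 0 || sd(d) == 0)
    return(list(r = NA_real_, n = length(adc),
                note = "undefined: zero variance in one of the vectors"))
  list(r = cor(adc, d), n = length(adc), note = NA_character_)
}
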